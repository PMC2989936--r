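---
title: "Methods: origin probabilities, scan models, and the cross simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: origin probabilities, scan models, and the cross simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The design and the three models

`f2scan` targets the classic three-generation F2 resource population:
two divergent founder breeds (here labelled Duroc and Pietrain), a
small set of F0 grandparents, F1 parents carrying exactly one
chromosome set of each breed origin, and a large F2 generation in which
breed-origin mosaics segregate.  Phenotypes are quantitative traits
recorded on the F2 (body weights, ultrasonic backfat depths, loin
muscle areas and the like); genotypes are multi-allelic microsatellites
on a sex-averaged Haldane-cM linkage map, which is taken as an input
(map estimation is a preprocessing step for an external tool and out of
scope here).

Three single-QTL least-squares models are fitted at every grid
position, all sharing the fixed-effect block `Xb` (sex and litter by
default, plus any covariates such as early body weight for growth-rate
traits):

* line-cross: `y = Xb + a·Pa + d·Pd + e`, which assumes the founder
  breeds are fixed for alternative QTL alleles; `Pa = P11 − P22` and
  `Pd = P12 + P21` are the breed-origin regression covariates, so `a`
  is half the difference between the two homozygous breed-origin means
  and `d` the heterozygote deviation;
* half-sib: `y = Xb + s_i + αHS_i·Ps + e`, a within-family haplotype
  contrast per F1 sire, which detects QTL still segregating inside a
  founder breed;
* combined: `y = Xb + s_i + a·Pa + d·Pd + αCB_i·Ps + e`, where the
  per-sire substitution effects are deviations from the average
  breed-origin effects.

The reduced model for every test keeps the fixed effects (and the sire
main effects for HS/CB) and omits only the QTL terms, so the F ratio
tests exactly the additive/dominance/substitution contrasts.  One
consequence of the breeding design is that sire main effects are
exactly collinear with the litter factor (each litter has one sire);
the QR-pivoting fit tolerates this, and it does not affect the QTL test
because the sire terms appear in both the full and the reduced model.
A second consequence is that the half-sib numerator degrees of freedom
are not fixed at the number of sires: a sire whose `Ps` column is
constant at a position (e.g. he is homozygous along the chromosome)
contributes no contrast, his column is dropped after residualization,
and the degrees of freedom shrink accordingly.

The profile statistic reported per position is −log10 of the upper-tail
F probability (computed on the log scale, so huge F ratios do not
underflow); raw F ratios are retained for threshold comparisons.

# Breed-origin probabilities

The covariates come from a joint hidden-process computation per F2
individual.  First, every F1 parent is phased against its F0
genotypes: at a heterozygous marker the two alleles are assigned to the
Duroc-derived and Pietrain-derived haplotype when exactly one ordering
is compatible with the F0 genotypes; when both orderings are
compatible the marker is flagged ambiguous.  By the symmetry of the
compatible cases, the true phase at an ambiguous marker is uniform
given the founder data, so ambiguous markers are treated as carrying no
phase information rather than receiving a hard call — this avoids
propagating phase errors at the cost of a little information.  Phase is
marginalized independently per marker; linkage between the ambiguous
marker and its phased neighbours through the F0→F1 meiosis is ignored,
a deliberate simplification whose residual bias was not detectable in
the package's recovery experiments.

Second, each F2's two parental gametes are tracked as a joint
four-state Markov chain along the chromosome (paternal origin ×
maternal origin, origin meaning which parental haplotype the gamete
segment derives from, labelled by breed).  Transitions between
positions d cM apart use the Haldane recombination fraction
`r = (1 − e^(−2d/100))/2`, consistent with no crossover interference.
Emissions marginalize the unordered offspring genotype over both
paternal/maternal allele assignments, each weighted by its likelihood
given the two parents' phased haplotypes; a missing genotype is an
uninformative emission, and a genotype impossible under every
assignment raises a Mendelian error naming the individual and marker
(the same incompatibilities are caught up front by
`validate_dataset()`).  A forward–backward pass over the union of
marker positions and grid positions yields the exact posterior of the
four origin states at every node; the grid runs in integer steps from
0 to the last marker and always contains the exact marker positions,
with the marker-conditioned value used where the two coincide.  The
posterior is exact for this model: the test suite checks it to 1e−9
against brute-force enumeration of all gamete source paths.

`Ps`, the half-sib covariate, is the marginal paternal-gamete
posterior for the sire's haplotype 1.  The haplotype labelling is
arbitrary but fixed per sire (the Duroc-derived haplotype is used, so
the same phasing serves all three models).  Note that `Ps` can remain
at 1/2 at a marker where breed origin is fully resolved: if sire and
dam share haplotype alleles, the paternal/maternal split of a
heterozygote is unresolvable even though its breed-origin genotype is
not.

Information content summarizes, per position, how much of the
complete-information variance of the covariates the marker data
recover: `Var(Pa)/0.5` for the additive and `Var(Pd)/0.25` for the
dominance dimension (population variances across individuals; the
denominators are the F2 complete-information values from the 1:2:1
origin distribution), clipped to [0, 1].

# Significance and localization

*FDR.*  Benjamini–Hochberg step-up is applied per trait × model over
the nominal P values of all genome grid positions; the reported "FDR
F-ratio" is the smallest observed F among rejected positions.  Plain
B-H is used despite the strong positional correlation of the tests —
the package also provides permutation thresholds precisely so that the
two calibrations can be compared on any dataset.  The per-trait family
(positions only, not positions × traits) is a design choice.

*Permutation.*  Churchill–Doerge thresholds permute whole phenotype
records (trait plus fixed-effect columns) against the genotype-derived
quantities (origin coefficients and sire identities), so the
fixed-effect structure is preserved under the null; the maximum F over
the scope (chromosome or genome) is recorded per permutation and the
threshold is the empirical 95th percentile with type-7 interpolation.
Seeds are mandatory for every resampling routine and are recorded in
the returned objects.

*Calling.*  QTL are local profile maxima above the threshold, selected
greedily by descending F subject to a 30-cM minimum separation per
chromosome, ties broken toward the lower cM; flanking markers are read
from the map and effects are reported at the peak with their OLS
standard errors.  Combined-model calls are filtered by a novelty rule:
a CB call within 30 cM of an LC or HS call for the same trait on the
same chromosome is dropped, so the combined model only ever adds QTL.

*Position CIs.*  The 95% confidence interval for a QTL position is a
nonparametric case bootstrap: F2 individuals are resampled with
replacement, the single-chromosome scan is refitted per resample
(factor levels re-derived per resample, degenerate constant-trait
resamples redrawn and counted), and the 2.5th–97.5th percentiles of
the peak positions form the interval.  The choice of case bootstrap —
rather than, say, a support-drop rule — is a design decision; it is
simple, model-agnostic, and its coverage is exercised in the recovery
tests.

# The simulator

`simulate_cross()` reproduces the emulated breeding design by default:
4 Duroc F0 sires × 15 Pietrain F0 dams, 56 F1 of which 6 males and 50
females are used, 954 F2 allocated to 141 litters (sizes 6–7) in 11
farrowing groups, F1 matings cycling dams and sires so each dam meets
several sires.  Meioses place crossovers by a Poisson process at one
per Morgan (matching the Haldane map used in inference), founder marker
alleles are drawn per breed from configurable frequencies — the default
panel has 4 alleles with breed-skewed frequencies
(0.50/0.30/0.15/0.05 vs its mirror image), chosen to mimic partially
informative microsatellites rather than a fully breed-diagnostic panel,
because half-sib power depends on that partial informativeness; a
breed-disjoint panel is available for tests that need certainty.  QTL
are extra loci on the same chromosomes, either breed-fixed (Q fixed in
Duroc, q in Pietrain) or within-breed segregating at stated per-breed
frequencies; `balanced_founders = TRUE` draws the founder QTL alleles
from an exactly balanced pool, representing the "same frequency in both
breeds" scenario without the large chance breed contrasts that
binomial draws over only 19 founders produce.

Phenotypes follow the fitted model exactly:
`y = μ + sex ± half the sex difference + litter effect + Σ(a·w_a + d·w_d) + e`,
with true origin codes `w_a ∈ {−1,0,1}`, `w_d ∈ {0,1}` (allele-count
codes for within-breed QTL), litter effects drawn once from
N(0, σ²_litter), and Gaussian residuals.  `trait_config()` decomposes a
target marginal SD into sex, litter and residual components
(`σ²_e = SD² − (sex/2)² − σ²_litter`), so the simulator can reproduce a
trait's descriptive statistics; the defaults for the reference backfat
trait are mean 19.89 mm, SD 6.40 mm, a 2.0-mm sex difference and a
1.5-mm litter SD — the sex and litter magnitudes are the package's own
choice of realistic values, since marginal trait means and SDs alone do
not determine them.  Litter effects are simulated as random but fitted as
fixed, matching practice for many small litters.  Because the QTL
covariates are conditional expectations of the true codes given the
marker data, the least-squares effect estimates are unbiased under this
generative model; the acceptance experiments verify this at the full
design size.

All randomness flows from one master seed through named per-stage
substreams (founders, F1 meioses, F2 meioses, sexes, missingness,
phenotypes), so enlarging one stage never perturbs another stage's
draws, and `simulate_phenotypes()` can regenerate phenotypes for a
fixed genome.

The default whole-genome map (`default_study_map()`) approximates the
emulated genome with 136 markers on 18 autosomes — nine chromosomes at
19.5-cM mean spacing and nine at 28.2 cM.  Marker count and mean
spacings are honoured exactly; the implied total (~2,700 cM) is below
the reported genome length, because count, spacings and total cannot
all hold under even spacing and the per-chromosome maps are not
available.  Simulation studies in this package use explicit short maps
anyway.

What the simulator does **not** emulate: genotyping error (beyond
missingness), segregation distortion, selection or non-random mating,
polygenic background variation, X-linked loci, and crossover
interference.  Passing tests therefore demonstrate correctness of the
machinery and calibration under the stated generative model, not
robustness to those real-data complications.

# Numerical choices

* Forward–backward works on scaled probabilities (row-normalized per
  node) to avoid underflow; posteriors are renormalized and the derived
  covariates clamped to their theoretical ranges against 1-ulp
  spillover.
* Per-position fits use Frisch–Waugh residualization against a single
  QR of the fixed-effect design; estimates, SEs and SSEs are
  numerically identical to refitting the full design (asserted against
  a normal-equations oracle at 1e−8).  QTL columns whose residualized
  norm is below `1e−10·n` are declared non-estimable; if all are
  dropped the position reports F = 0 by convention.
* `SSE_full = 0` with a positive numerator yields an `Inf` F sentinel,
  and −log10 P is capped (default 300).
* Percentiles use quantile type 7 everywhere; B-H q-values are the
  standard suffix-minimum of `m·p_(j)/j`, capped at 1.
* Grid/marker ties resolve to the marker-conditioned posterior.

# Problem sizes in the test suite

The suite favours exactness checks (enumeration and normal-equations
oracles) at tiny sizes, and runs the stochastic studies at sizes chosen
to keep the whole suite comfortably interactive: the two
parameter-recovery experiments use 60 replicates of the full 954-pig
design (the acceptance script runs 200), permutation calibration uses
100 null replicates of a 160-pig, two-chromosome genome with 100
permutations each, and the sharpening comparison contrasts 477 vs 954
pigs with 60-resample bootstrap intervals.  All stochastic assertions
are Monte-Carlo-aware: recovery tolerances are two MC standard errors
of the replicate mean, and the permutation type-I count is tested
against its exact binomial band.

# Known limitations

* Single-QTL models only: no two-QTL fits, epistasis or imprinting, and
  no variance-component (random QTL) models.
* Phase ambiguity is marginalized per marker, not jointly along the
  chromosome; with highly informative microsatellite panels the
  difference is negligible, but for poorly informative panels a full
  multi-locus phasing model would recover slightly more information.
* B-H FDR on a dense grid of correlated tests controls FDR over
  positions, which is permissive for borderline secondary peaks on
  chromosomes that already carry a strong QTL; the permutation
  thresholds are the conservative alternative.
* Maternal half-sib families are not modelled (dam haplotypes enter
  only through the breed-origin covariates), matching the six-family
  paternal design the package targets.
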