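Package: f2scan
Title: Least-Squares QTL Genome Scans for Three-Generation F2 Crosses
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Interval mapping of quantitative trait loci (QTL) in
    three-generation F2 crosses between divergent founder breeds, using
    least-squares regression on breed-of-origin and sire-haplotype
    transmission probabilities.  Infers F1 parental haplotype phase from
    founder genotypes, propagates breed-of-origin probabilities along each
    chromosome to a 1-cM grid by a forward-backward algorithm under the
    Haldane map function, and fits line-cross, half-sib, and combined
    models at every grid position.  Significance is assessed by
    Benjamini-Hochberg false discovery rate and by Churchill-Doerge
    permutation thresholds; QTL position confidence intervals are obtained
    by case bootstrap.  A simulator for the full three-generation design
    (founders, meioses, multi-allelic microsatellite markers, QTL, and
    phenotypes with known truth) supports power and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, tools
Suggests: testthat (>= 3.0.0), yaml, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
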