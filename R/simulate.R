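# Deterministic per-stage seed derived from one master seed, so that
# adding draws to one simulation stage never perturbs another stage.
.substream <- function(seed, stage) {
  u <- utf8ToInt(stage)
  h <- sum(u * seq_along(u)) * 1103
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

#' Default marker map emulating the reference resource-population genome
#'
#' Eighteen autosomes with evenly spaced microsatellite markers: nine
#' chromosomes carry 9 markers at 19.5-cM mean spacing (the chromosomes
#' that received additional markers) and nine carry 6-7 markers at
#' 28.2-cM spacing, 136 markers in all.
#'
#' @return A [linkage_map()].
#' @export
default_study_map <- function() {
  dense <- c(3, 4, 5, 6, 7, 12, 15, 16, 18)
  rows <- list()
  for (ch in 1:18) {
    nmk <- if (ch %in% dense) 9L else if (ch == 1) 7L else 6L
    sp <- if (ch %in% dense) 19.5 else 28.2
    rows[[ch]] <- data.frame(chrom = as.character(ch),
                             marker = sprintf("C%dM%d", ch, seq_len(nmk)),
                             pos_cM = (seq_len(nmk) - 1) * sp)
  }
  m <- do.call(rbind, rows)
  linkage_map(m$chrom, m$marker, m$pos_cM)
}

#' Trait configuration helper
#'
#' Describes one simulated trait: its base mean, its marginal standard
#' deviation, and how that SD decomposes into a sex difference, a litter
#' SD and the residual SD.  When `resid_sd` is `NULL` it is chosen so
#' that, absent QTL, the marginal SD equals `sd`:
#' \eqn{\sigma_e^2 = sd^2 - (sex/2)^2 - litter^2}.
#'
#' @param name Trait name.
#' @param mean,sd Marginal mean and SD (e.g. the observed descriptive
#'   statistics of the emulated trait).
#' @param sex_effect Male minus female difference, trait units.
#' @param litter_sd SD of the common-litter effects.
#' @param resid_sd Residual SD; derived from `sd` if `NULL`.
#' @return A list usable in `sim_config(traits = list(...))`.
#' @export
trait_config <- function(name = "trait", mean = 0, sd = 1,
                         sex_effect = 0.3 * sd, litter_sd = 0.25 * sd,
                         resid_sd = NULL) {
  if (is.null(resid_sd)) {
    v <- sd^2 - (sex_effect / 2)^2 - litter_sd^2
    if (v <= 0) stop("sex and litter components exceed the marginal SD")
    resid_sd <- sqrt(v)
  }
  if (resid_sd <= 0) stop("residual SD must be positive")
  list(name = name, mean = mean, sd = sd, sex_effect = sex_effect,
       litter_sd = litter_sd, resid_sd = resid_sd)
}

#' Simulation configuration for the three-generation cross
#'
#' Describes the breeding design (founder counts, F1 usage, F2 and
#' litter counts), the marker panel (map plus per-breed allele
#' frequencies), the QTL, and the simulated trait(s).  Defaults mirror
#' the emulated resource population: 4 Duroc F0 sires x 15 Pietrain F0
#' dams, 6 F1 sires and 50 F1 dams, 954 F2 in 141 litters across 11
#' farrowing groups, and 4-allele microsatellites with breed-skewed
#' frequencies.
#'
#' @param map A [linkage_map()] (default [default_study_map()]).
#' @param n_f0_sires,n_f0_dams Duroc sire and Pietrain dam founder
#'   counts.
#' @param n_f1_sires,n_f1_dams F1 parents used to produce the F2.
#' @param n_f2,n_litters,n_groups F2 design size.
#' @param freq_duroc,freq_pietrain Marker allele frequencies per breed
#'   (recycled over markers); each must sum to 1.
#' @param qtl `data.frame` with columns `chrom`, `pos_cM`, `mode`
#'   (`"breed-fixed"` or `"within-breed"`), `a`, `d`, and for
#'   within-breed mode `freq_q_duroc`, `freq_q_pietrain` (frequency of
#'   the Q allele per breed); optional `trait` column (defaults to the
#'   first trait).
#' @param traits List of [trait_config()] entries.
#' @param balanced_founders For within-breed QTL, draw founder QTL
#'   alleles from a pool with exact per-breed frequencies instead of
#'   binomial sampling (represents breeds segregating at exactly the
#'   stated frequency).
#' @param missing_rate Fraction of marker genotypes set to missing.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(map = default_study_map(),
                       n_f0_sires = 4, n_f0_dams = 15,
                       n_f1_sires = 6, n_f1_dams = 50,
                       n_f2 = 954, n_litters = 141, n_groups = 11,
                       freq_duroc = c(0.50, 0.30, 0.15, 0.05),
                       freq_pietrain = c(0.05, 0.15, 0.30, 0.50),
                       qtl = NULL,
                       traits = list(trait_config("BF10_22wk", 19.89, 6.40,
                                                  sex_effect = 2.0,
                                                  litter_sd = 1.5)),
                       balanced_founders = FALSE,
                       missing_rate = 0) {
  stopifnot(inherits(map, "linkage_map"))
  if (abs(sum(freq_duroc) - 1) > 1e-8 || abs(sum(freq_pietrain) - 1) > 1e-8)
    stop("allele frequencies must sum to 1 per breed")
  if (length(freq_duroc) != length(freq_pietrain))
    stop("breeds must share one allele label set")
  if (n_litters > n_f2) stop("more litters than F2 individuals")
  if (min(n_f0_sires, n_f0_dams, n_f1_sires, n_f1_dams) < 1)
    stop("all parent counts must be at least 1")
  tn <- vapply(traits, `[[`, character(1), "name")
  if (anyDuplicated(tn)) stop("duplicated trait names")
  if (!is.null(qtl)) {
    qtl <- as.data.frame(qtl, stringsAsFactors = FALSE)
    need <- c("chrom", "pos_cM", "mode", "a", "d")
    if (!all(need %in% names(qtl)))
      stop("qtl needs columns ", paste(need, collapse = ", "))
    qtl$chrom <- as.character(qtl$chrom)
    if (!all(qtl$mode %in% c("breed-fixed", "within-breed")))
      stop("qtl mode must be 'breed-fixed' or 'within-breed'")
    if (is.null(qtl$freq_q_duroc))
      qtl$freq_q_duroc <- ifelse(qtl$mode == "breed-fixed", 1, 0.5)
    if (is.null(qtl$freq_q_pietrain))
      qtl$freq_q_pietrain <- ifelse(qtl$mode == "breed-fixed", 0, 0.5)
    if (is.null(qtl$trait)) qtl$trait <- tn[1]
    if (!all(qtl$trait %in% tn)) stop("qtl trait not among the traits")
    fixed <- qtl$mode == "breed-fixed"
    if (any(fixed & (qtl$freq_q_duroc == 0 | qtl$freq_q_pietrain == 1)))
      stop("breed-fixed QTL requests fixation of a zero-frequency allele")
    for (i in seq_len(nrow(qtl))) {
      mm <- map[map$chrom == qtl$chrom[i], ]
      if (!nrow(mm)) stop("QTL chromosome ", qtl$chrom[i], " not on map")
      if (qtl$pos_cM[i] < 0 || qtl$pos_cM[i] > max(mm$pos_cM))
        stop("QTL position ", qtl$pos_cM[i],
             " outside chromosome ", qtl$chrom[i])
    }
  }
  structure(list(map = map, n_f0_sires = n_f0_sires, n_f0_dams = n_f0_dams,
                 n_f1_sires = n_f1_sires, n_f1_dams = n_f1_dams,
                 n_f2 = n_f2, n_litters = n_litters, n_groups = n_groups,
                 freq_duroc = freq_duroc, freq_pietrain = freq_pietrain,
                 qtl = qtl, traits = traits,
                 balanced_founders = balanced_founders,
                 missing_rate = missing_rate),
            class = "sim_config")
}

# Locus scaffold per chromosome: markers plus QTL pseudo-loci.
.loci <- function(config) {
  map <- config$map
  out <- list()
  for (ch in unique(map$chrom)) {
    mm <- map[map$chrom == ch, , drop = FALSE]
    pos <- mm$pos_cM
    name <- mm$marker
    is_marker <- rep(TRUE, nrow(mm))
    qtl_id <- rep(NA_integer_, nrow(mm))
    if (!is.null(config$qtl)) {
      qq <- which(config$qtl$chrom == ch)
      for (i in qq) {
        pos <- c(pos, config$qtl$pos_cM[i])
        name <- c(name, paste0("QTL", i))
        is_marker <- c(is_marker, FALSE)
        qtl_id <- c(qtl_id, i)
      }
    }
    o <- order(pos, is_marker)
    out[[ch]] <- list(pos = pos[o], name = name[o],
                      is_marker = is_marker[o], qtl_id = qtl_id[o])
  }
  out
}

#' Simulate phased founder genotypes
#'
#' Each F0 founder receives two haplotypes with marker alleles drawn
#' independently per locus from its breed's allele frequencies.  QTL
#' alleles follow the QTL mode: breed-fixed QTL fix allele Q in Duroc
#' and q in Pietrain; within-breed QTL draw Q at the stated per-breed
#' frequency (optionally from an exactly balanced founder pool).
#'
#' @param config A [sim_config()].
#' @param seed Random seed.
#' @return List with `ids`, `breed`, and `haplos`: per chromosome a
#'   list with allele array `alleles` (n x loci x 2) and breed-origin
#'   array `origin` (1 = Duroc, 2 = Pietrain).
#' @export
simulate_founders <- function(config, seed) {
  set.seed(.substream(seed, "founders"))
  loci <- .loci(config)
  ids <- c(paste0("D", seq_len(config$n_f0_sires)),
           paste0("P", seq_len(config$n_f0_dams)))
  breed <- rep(c("Duroc", "Pietrain"),
               c(config$n_f0_sires, config$n_f0_dams))
  n <- length(ids)
  na <- length(config$freq_duroc)
  haplos <- list()
  for (ch in names(loci)) {
    lc <- loci[[ch]]
    L <- length(lc$pos)
    al <- array(NA_integer_, c(n, L, 2), dimnames = list(ids, lc$name, NULL))
    or <- array(rep(ifelse(breed == "Duroc", 1L, 2L), L * 2), c(n, L, 2))
    for (k in seq_len(L)) {
      if (lc$is_marker[k]) {
        for (h in 1:2) {
          al[breed == "Duroc", k, h] <-
            sample.int(na, sum(breed == "Duroc"), replace = TRUE,
                       prob = config$freq_duroc)
          al[breed == "Pietrain", k, h] <-
            sample.int(na, sum(breed == "Pietrain"), replace = TRUE,
                       prob = config$freq_pietrain)
        }
      } else {
        q <- config$qtl[lc$qtl_id[k], ]
        draw <- function(fq, nb) {
          if (config$balanced_founders && q$mode == "within-breed") {
            pool <- rep(1:2, c(round(2 * nb * fq), 2 * nb - round(2 * nb * fq)))
            matrix(sample(pool), nb, 2)
          } else {
            matrix(1L + (stats::runif(2 * nb) >= fq), nb, 2)
          }
        }
        al[breed == "Duroc", k, ] <- draw(q$freq_q_duroc,
                                          sum(breed == "Duroc"))
        al[breed == "Pietrain", k, ] <- draw(q$freq_q_pietrain,
                                             sum(breed == "Pietrain"))
      }
    }
    haplos[[ch]] <- list(alleles = al, origin = or)
  }
  list(ids = ids, breed = breed, haplos = haplos)
}

#' Simulate one meiosis on one chromosome
#'
#' Crossovers follow a Poisson process at rate 1 per Morgan (no
#' interference, matching the Haldane map function); the gamete starts
#' on a fair-coin haplotype and switches source at every crossover.
#'
#' @param alleles Loci x 2 matrix of the parent's phased alleles.
#' @param pos_cM Locus positions, cM.
#' @param seed Optional seed.
#' @return List with `gamete` (allele per locus), `source` (1 or 2 per
#'   locus), and `crossovers` (positions, cM).
#' @export
simulate_meiosis <- function(alleles, pos_cM, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  src <- .meiosis_source(pos_cM)
  list(gamete = alleles[cbind(seq_along(pos_cM), src$source)],
       source = src$source, crossovers = src$crossovers)
}

.meiosis_source <- function(pos) {
  lo <- min(pos); hi <- max(pos)
  len_m <- (hi - lo) / 100
  ncx <- if (len_m > 0) stats::rpois(1, len_m) else 0L
  cx <- if (ncx > 0) sort(stats::runif(ncx, lo, hi)) else numeric(0)
  start <- sample.int(2L, 1L)
  source <- 1L + (start - 1L + findInterval(pos, cx, left.open = TRUE)) %% 2L
  list(source = source, crossovers = cx)
}

# One generation of gametes: for each offspring, one gamete from each
# parent per chromosome, propagating alleles and breed origins.
.make_offspring <- function(parents, sire_idx, dam_idx, ids, loci) {
  n <- length(ids)
  haplos <- list()
  for (ch in names(loci)) {
    pos <- loci[[ch]]$pos
    L <- length(pos)
    pal <- parents$haplos[[ch]]$alleles
    por <- parents$haplos[[ch]]$origin
    al <- array(NA_integer_, c(n, L, 2),
                dimnames = list(ids, loci[[ch]]$name, NULL))
    or <- array(NA_integer_, c(n, L, 2))
    for (j in seq_len(n)) {
      sp <- .meiosis_source(pos)$source
      ia <- matrix(pal[sire_idx[j], , ], ncol = 2)
      io <- matrix(por[sire_idx[j], , ], ncol = 2)
      al[j, , 1] <- ia[cbind(seq_len(L), sp)]
      or[j, , 1] <- io[cbind(seq_len(L), sp)]
      sm <- .meiosis_source(pos)$source
      ia <- matrix(pal[dam_idx[j], , ], ncol = 2)
      io <- matrix(por[dam_idx[j], , ], ncol = 2)
      al[j, , 2] <- ia[cbind(seq_len(L), sm)]
      or[j, , 2] <- io[cbind(seq_len(L), sm)]
    }
    haplos[[ch]] <- list(alleles = al, origin = or)
  }
  haplos
}

#' Simulate the full three-generation cross
#'
#' Produces founders, F1 parents, and F2 offspring allocated to litters
#' and farrowing groups; emits the unphased genotype table, the
#' pedigree, phenotypes per [simulate_phenotypes()], and a truth record
#' with the realized QTL genotype and breed-origin codes of every F2.
#'
#' @param config A [sim_config()].
#' @param seed Master seed; every stage derives its own substream.
#' @return List with `dataset` (an [f2_dataset()]) and `truth` (list
#'   with the `qtl` table and per-QTL data frames of true codes:
#'   `w_a` in -1/0/+1, `w_d` in 0/1, and the sire-haplotype indicator
#'   `ps_true`).
#' @export
simulate_cross <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  loci <- .loci(config)
  founders <- simulate_founders(config, seed)

  # F1: each F1 from one F0 dam (cycled) mated to an F0 sire (cycled)
  n_f1 <- config$n_f1_sires + config$n_f1_dams
  f1_ids <- c(paste0("F1M", seq_len(config$n_f1_sires)),
              paste0("F1F", seq_len(config$n_f1_dams)))
  f1_sex <- rep(c("M", "F"), c(config$n_f1_sires, config$n_f1_dams))
  dam0 <- ((seq_len(n_f1) - 1) %% config$n_f0_dams) + 1
  sire0 <- ((dam0 - 1) %% config$n_f0_sires) + 1
  set.seed(.substream(seed, "meioses_f1"))
  f1_haplos <- .make_offspring(founders, sire0,
                               config$n_f0_sires + dam0, f1_ids, loci)

  # F2: litters cycle over F1 dams and sires
  lit <- seq_len(config$n_litters)
  lit_dam <- ((lit - 1) %% config$n_f1_dams) + 1
  lit_sire <- ((lit - 1) %% config$n_f1_sires) + 1
  base <- config$n_f2 %/% config$n_litters
  sizes <- rep(base, config$n_litters)
  extra <- config$n_f2 - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  if (any(sizes < 1)) stop("infeasible litter allocation")
  f2_litter <- rep(lit, sizes)
  f2_ids <- sprintf("F2_%04d", seq_len(config$n_f2))
  f2_sire <- lit_sire[f2_litter]
  f2_dam <- lit_dam[f2_litter]
  set.seed(.substream(seed, "meioses_f2"))
  f1_parents <- list(haplos = f1_haplos)
  f2_haplos <- .make_offspring(f1_parents, f2_sire,
                               config$n_f1_sires + f2_dam, f2_ids, loci)
  set.seed(.substream(seed, "sexes"))
  f2_sex <- sample(c("M", "F"), config$n_f2, replace = TRUE)
  grp <- ceiling(lit * config$n_groups / config$n_litters)

  # pedigree
  ped <- rbind(
    data.frame(id = founders$ids, sire = NA, dam = NA, generation = "F0",
               breed = founders$breed,
               sex = rep(c("M", "F"),
                         c(config$n_f0_sires, config$n_f0_dams)),
               litter = NA, group = NA, stringsAsFactors = FALSE),
    data.frame(id = f1_ids, sire = founders$ids[sire0],
               dam = founders$ids[config$n_f0_sires + dam0],
               generation = "F1", breed = NA, sex = f1_sex,
               litter = NA, group = NA, stringsAsFactors = FALSE),
    data.frame(id = f2_ids, sire = f1_ids[f2_sire],
               dam = f1_ids[config$n_f1_sires + f2_dam],
               generation = "F2", breed = NA, sex = f2_sex,
               litter = paste0("L", f2_litter),
               group = paste0("G", grp[f2_litter]),
               stringsAsFactors = FALSE))

  # genotype table over markers only (QTL loci are dropped)
  all_ids <- c(founders$ids, f1_ids, f2_ids)
  mk <- config$map$marker
  a1 <- a2 <- matrix(NA_integer_, length(all_ids), length(mk),
                     dimnames = list(all_ids, mk))
  for (ch in names(loci)) {
    sel <- loci[[ch]]$is_marker
    mnames <- loci[[ch]]$name[sel]
    stack <- function(h) {
      f <- function(x) {
        y <- x[, sel, h, drop = FALSE]
        dim(y) <- dim(y)[1:2]
        y
      }
      rbind(f(founders$haplos[[ch]]$alleles),
            f(f1_haplos[[ch]]$alleles),
            f(f2_haplos[[ch]]$alleles))
    }
    a1[, mnames] <- stack(1)
    a2[, mnames] <- stack(2)
  }
  if (config$missing_rate > 0) {
    set.seed(.substream(seed, "missingness"))
    drop <- matrix(stats::runif(length(a1)) < config$missing_rate,
                   nrow(a1))
    a1[drop] <- NA_integer_
    a2[drop] <- NA_integer_
  }
  geno <- genotype_table(a1, a2)

  # truth at the QTL
  truth <- list(qtl = config$qtl, codes = list())
  if (!is.null(config$qtl)) {
    for (i in seq_len(nrow(config$qtl))) {
      ch <- config$qtl$chrom[i]
      k <- which(!is.na(loci[[ch]]$qtl_id) & loci[[ch]]$qtl_id == i)
      or_p <- f2_haplos[[ch]]$origin[, k, 1]
      or_m <- f2_haplos[[ch]]$origin[, k, 2]
      al_p <- f2_haplos[[ch]]$alleles[, k, 1]
      al_m <- f2_haplos[[ch]]$alleles[, k, 2]
      if (config$qtl$mode[i] == "breed-fixed") {
        w_a <- (or_p == 1) + (or_m == 1) - 1
        w_d <- as.numeric((or_p == 1) != (or_m == 1))
      } else {
        nq <- (al_p == 1) + (al_m == 1)
        w_a <- nq - 1
        w_d <- as.numeric(nq == 1)
      }
      truth$codes[[i]] <- data.frame(
        id = f2_ids, w_a = w_a, w_d = w_d,
        origin_pat = or_p, origin_mat = or_m,
        allele_pat = al_p, allele_mat = al_m,
        ps_true = as.numeric(or_p == 1),
        stringsAsFactors = FALSE)
    }
  }

  skeleton <- data.frame(id = f2_ids, sex = f2_sex,
                         litter = paste0("L", f2_litter),
                         stringsAsFactors = FALSE)
  ds <- f2_dataset(config$map, ped, geno, skeleton)
  ds$phenotypes <- simulate_phenotypes(ds, truth, config, seed)
  list(dataset = ds, truth = truth)
}

#' Simulate phenotypes from the truth record
#'
#' For every trait: \eqn{y = \mu + sex + litter + \sum_{QTL} (a w_a +
#' d w_d) + e}, with the true QTL genotype codes \eqn{w_a \in \{-1, 0,
#' 1\}} (breed origin, or Q-allele count minus one for within-breed
#' QTL) and \eqn{w_d \in \{0, 1\}}, litter effects drawn once from
#' \eqn{N(0, \sigma_{litter}^2)}, and residuals \eqn{N(0,
#' \sigma_e^2)}.
#'
#' @param dataset The simulated [f2_dataset()] (supplies sex and litter).
#' @param truth Truth record from [simulate_cross()].
#' @param config The [sim_config()].
#' @param seed Master seed (phenotype substream is derived from it).
#' @return Phenotype `data.frame` with columns `id`, `sex`, `litter`
#'   and one column per configured trait.
#' @export
simulate_phenotypes <- function(dataset, truth, config, seed) {
  ph <- dataset$phenotypes[c("id", "sex", "litter")]
  n <- nrow(ph)
  set.seed(.substream(seed, "phenotypes"))
  litters <- unique(ph$litter)
  for (tr in config$traits) {
    if (tr$resid_sd <= 0) stop("residual SD must be positive")
    le <- stats::setNames(stats::rnorm(length(litters), 0, tr$litter_sd),
                          litters)
    y <- tr$mean + ifelse(ph$sex == "M", tr$sex_effect / 2,
                          -tr$sex_effect / 2) + le[ph$litter]
    if (!is.null(config$qtl)) {
      for (i in seq_len(nrow(config$qtl))) {
        if (config$qtl$trait[i] != tr$name) next
        cd <- truth$codes[[i]]
        stopifnot(identical(cd$id, ph$id))
        y <- y + config$qtl$a[i] * cd$w_a + config$qtl$d[i] * cd$w_d
      }
    }
    y <- y + stats::rnorm(n, 0, tr$resid_sd)
    ph[[tr$name]] <- unname(y)
  }
  ph
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates the configured cross, computes origin
#' coefficients, and fits the scan model; summarizes effect estimates
#' at the true QTL position(s) and, optionally, full-scan peak
#' positions and FDR detection.
#'
#' @param config A [sim_config()] naming at least one QTL.
#' @param n_reps Number of replicates.
#' @param seeds Integer vector of per-replicate seeds (default
#'   `seq_len(n_reps)`).
#' @param model Scan model.
#' @param full_scan Also scan the whole grid, record the peak position
#'   per replicate, and count detections at the `fdr_q` FDR level
#'   (slower).
#' @param step Grid step for the full scan.
#' @param fdr_q FDR level used for detection when `full_scan = TRUE`.
#' @return A list of class `recovery_summary`: `estimates` (one row
#'   per replicate x QTL: `a_hat`, `d_hat`, their SEs), `summary` (per
#'   QTL: true values, mean and SD of the estimates, Monte-Carlo SE of
#'   the mean), and when `full_scan = TRUE` also `peaks` and
#'   `detection_rate`.
#' @export
recovery_experiment <- function(config, n_reps, seeds = seq_len(n_reps),
                                model = c("LC", "HS", "CB"),
                                full_scan = FALSE, step = 1,
                                fdr_q = 0.05) {
  model <- match.arg(model)
  if (is.null(config$qtl) || !nrow(config$qtl))
    stop("recovery experiment needs at least one configured QTL")
  stopifnot(length(seeds) == n_reps)
  qtl <- config$qtl
  est <- list()
  peaks <- matrix(NA_real_, n_reps, nrow(qtl))
  detected <- matrix(NA, n_reps, nrow(qtl))
  for (rep_i in seq_len(n_reps)) {
    sim <- simulate_cross(config, seeds[rep_i])
    phase <- phase_f1(sim$dataset)
    for (qi in seq_len(nrow(qtl))) {
      ch <- qtl$chrom[qi]
      tr <- qtl$trait[qi]
      pos_true <- qtl$pos_cM[qi]
      cf <- origin_coefficients(sim$dataset, phase = phase,
                                chromosomes = ch,
                                positions = stats::setNames(
                                  list(pos_true), ch))
      sc <- scan_qtl(sim$dataset, tr, model, coeffs = cf,
                     chromosomes = ch)
      row <- sc$profile[1, ]
      est[[length(est) + 1L]] <- data.frame(
        rep = rep_i, qtl = qi,
        a_hat = if ("a" %in% names(row)) row$a else NA_real_,
        a_se = if ("a_se" %in% names(row)) row$a_se else NA_real_,
        d_hat = if ("d" %in% names(row)) row$d else NA_real_,
        d_se = if ("d_se" %in% names(row)) row$d_se else NA_real_,
        F = row$F)
      if (full_scan) {
        cf2 <- origin_coefficients(sim$dataset, phase = phase,
                                   chromosomes = ch, step = step)
        sc2 <- scan_qtl(sim$dataset, tr, model, coeffs = cf2,
                        chromosomes = ch)
        peaks[rep_i, qi] <- sc2$peaks$pos_cM[1]
        calls <- call_qtl(sc2, fdr_q = fdr_q)
        detected[rep_i, qi] <- nrow(calls) > 0
      }
    }
  }
  est <- do.call(rbind, est)
  summ <- do.call(rbind, lapply(seq_len(nrow(qtl)), function(qi) {
    e <- est[est$qtl == qi, ]
    data.frame(qtl = qi, chrom = qtl$chrom[qi], pos_cM = qtl$pos_cM[qi],
               a_true = qtl$a[qi], d_true = qtl$d[qi],
               a_mean = mean(e$a_hat), a_sd = stats::sd(e$a_hat),
               a_mcse = stats::sd(e$a_hat) / sqrt(nrow(e)),
               d_mean = mean(e$d_hat), d_sd = stats::sd(e$d_hat),
               d_mcse = stats::sd(e$d_hat) / sqrt(nrow(e)))
  }))
  out <- list(estimates = est, summary = summ, model = model,
              n_reps = n_reps, seeds = seeds)
  if (full_scan) {
    out$peaks <- peaks
    out$detection_rate <- colMeans(detected)
  }
  class(out) <- "recovery_summary"
  out
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Recovery experiment: %d replicates, %s model\n",
              x$n_reps, x$model))
  print(x$summary, row.names = FALSE, digits = 4)
  if (!is.null(x$detection_rate))
    cat("Detection rate:", paste(round(x$detection_rate, 3),
                                 collapse = ", "), "\n")
  invisible(x)
}
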