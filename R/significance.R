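#' Benjamini-Hochberg step-up FDR
#'
#' Sorts the p-values ascending, finds the largest k with
#' \eqn{p_{(k)} \le k q / m}, rejects the k smallest, and computes
#' q-values as the running minimum of \eqn{m p_{(j)} / j} from the top.
#'
#' @param p P-values in \eqn{[0, 1]}.
#' @param q Target false discovery rate.
#' @return List with `p_threshold` (rejection threshold on p, `NA` if no
#'   rejection), `rejected` (logical, in input order), and `qvalues`
#'   (input order).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (!length(p)) stop("empty p-value input")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  crit <- seq_len(m) * q / m
  k <- max(c(0L, which(ps <= crit)))
  qv_sorted <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  qv <- numeric(m)
  qv[o] <- qv_sorted
  rejected <- logical(m)
  if (k > 0) rejected[o[seq_len(k)]] <- TRUE
  list(p_threshold = if (k > 0) ps[k] else NA_real_,
       rejected = rejected, qvalues = qv)
}

#' FDR F-ratio threshold for a genome scan
#'
#' Applies [bh_fdr()] to the nominal p-values of every grid position of
#' a scan and returns the smallest observed F ratio among rejected
#' positions — the "FDR F-ratio" at level `q`.
#'
#' @param scan A [scan_qtl()] result.
#' @param q FDR level.
#' @return List with `f_threshold` (`NA` if nothing is rejected),
#'   `p_threshold`, `n_rejected`, and `q`.
#' @export
fdr_f_threshold <- function(scan, q = 0.05) {
  p <- 10^(-scan$profile$neglog10P)
  b <- bh_fdr(p, q)
  list(f_threshold = if (any(b$rejected)) min(scan$profile$F[b$rejected])
       else NA_real_,
       p_threshold = b$p_threshold,
       n_rejected = sum(b$rejected), q = q)
}

#' Permutation significance thresholds
#'
#' Churchill-Doerge empirical thresholds: whole phenotype records
#' (trait plus fixed-effect factors and covariates) are permuted against
#' the genotype-derived origin coefficients (and sire identities), the
#' scan is recomputed, and the maximum F over the scope is recorded for
#' each permutation.  The threshold is the empirical `1 - level`
#' quantile (type-7 interpolation).
#'
#' @inheritParams scan_qtl
#' @param scope `"genome"` (one threshold from the genome-wide maximum)
#'   or `"chromosome"` (one threshold per chromosome).
#' @param n_perm Number of permutations (>= 19 for a 5% threshold).
#' @param seed Random seed (mandatory).
#' @param level Tail probability of the threshold (default 0.05).
#' @return List of class `perm_thresholds` with `thresholds` (named
#'   numeric), `max_f` (the permutation maxima, scope x n_perm),
#'   `scope`, `level`, `n_perm`, `seed`.
#' @export
permutation_thresholds <- function(dataset, trait,
                                   model = c("LC", "HS", "CB"),
                                   scope = c("genome", "chromosome"),
                                   n_perm = 1000, seed,
                                   coeffs = NULL, chromosomes = NULL,
                                   step = 1, positions = NULL,
                                   factors = c("sex", "litter"),
                                   covariates = NULL, level = 0.05) {
  model <- match.arg(model)
  scope <- match.arg(scope)
  if (missing(seed)) stop("a seed is required")
  if (n_perm < ceiling(1 / level) - 1)
    stop("n_perm too small for the ", level, " tail: need >= ",
         ceiling(1 / level) - 1)
  ctx <- .scan_context(dataset, trait, model, coeffs, chromosomes, step,
                       positions, factors, covariates)
  n <- length(ctx$design$y)
  chs <- names(ctx$Zlist)
  set.seed(seed)
  mx <- matrix(NA_real_, length(chs), n_perm, dimnames = list(chs, NULL))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    X <- .X_from_data(ctx$design$data, ctx$design$sire, sire_perm = perm)
    Zp <- lapply(ctx$Zlist, function(zz) {
      zz$arr <- zz$arr[perm, , , drop = FALSE]
      zz
    })
    prof <- .profile_engine(ctx$design$y, X, Zp)
    mx[, b] <- vapply(chs, function(ch)
      max(prof$F[prof$chrom == ch]), numeric(1))
  }
  thr <- if (scope == "genome") {
    c(genome = stats::quantile(apply(mx, 2, max), 1 - level, names = FALSE,
                               type = 7))
  } else {
    apply(mx, 1, stats::quantile, probs = 1 - level, names = FALSE,
          type = 7)
  }
  structure(list(thresholds = thr, max_f = mx, scope = scope,
                 level = level, n_perm = n_perm, seed = seed),
            class = "perm_thresholds")
}

#' @export
print.perm_thresholds <- function(x, ...) {
  cat(sprintf("Permutation thresholds (%s-wise, %d%% level, %d permutations, seed %s)\n",
              x$scope, round(100 * x$level), x$n_perm, format(x$seed)))
  print(round(x$thresholds, 3))
  invisible(x)
}

# Local maxima of F within one chromosome's profile (plateau-tolerant).
.local_maxima <- function(f) {
  n <- length(f)
  if (n == 1) return(1L)
  up <- c(TRUE, f[-1] >= f[-n])
  down <- c(f[-n] >= f[-1], TRUE)
  which(up & down)
}

#' Declare QTL from a scan profile
#'
#' Selects local maxima whose F ratio exceeds the threshold, greedily by
#' descending F subject to a minimum separation per chromosome, breaking
#' position ties toward the lower cM.  Effects are reported at the peak
#' position with their OLS standard errors; q-values come from
#' Benjamini-Hochberg over the whole profile.
#'
#' @param scan A [scan_qtl()] result.
#' @param threshold F-ratio threshold.  If `NULL`, the 5% FDR F-ratio
#'   (or `fdr_q`) from [fdr_f_threshold()] is used; if that is
#'   undefined (no rejections) an empty call set is returned.
#' @param fdr_q FDR level used when `threshold` is `NULL`.
#' @param min_sep Minimum separation between declared peaks, cM.
#' @return `data.frame` of class `qtl_calls` with columns `trait`,
#'   `model`, `chrom`, `pos_cM`, `flank_lo`, `flank_hi`, `F`,
#'   `neglog10P`, `fdr_q`, effect estimate/SE columns, `ci_lo`,
#'   `ci_hi` (filled by [bootstrap_position_ci()]).
#' @export
call_qtl <- function(scan, threshold = NULL, fdr_q = 0.05, min_sep = 30) {
  prof <- scan$profile
  qv <- bh_fdr(10^(-prof$neglog10P), fdr_q)$qvalues
  if (is.null(threshold)) {
    threshold <- fdr_f_threshold(scan, fdr_q)$f_threshold
    if (is.na(threshold)) threshold <- Inf
  }
  effnm <- setdiff(names(prof), c("chrom", "pos_cM", "F", "neglog10P",
                                  "df_num", "df_den"))
  picked <- list()
  for (ch in unique(prof$chrom)) {
    sel <- which(prof$chrom == ch)
    pp <- prof[sel, , drop = FALSE]
    cand <- .local_maxima(pp$F)
    cand <- cand[pp$F[cand] >= threshold]
    cand <- cand[order(-pp$F[cand], pp$pos_cM[cand])]
    taken <- numeric(0)
    for (i in cand) {
      if (all(abs(pp$pos_cM[i] - taken) >= min_sep)) {
        taken <- c(taken, pp$pos_cM[i])
        fl <- .flanking(scan$map, ch, pp$pos_cM[i])
        picked[[length(picked) + 1L]] <- cbind(
          data.frame(trait = scan$trait, model = scan$model, chrom = ch,
                     pos_cM = pp$pos_cM[i], flank_lo = fl[1],
                     flank_hi = fl[2], F = pp$F[i],
                     neglog10P = pp$neglog10P[i],
                     fdr_q = qv[sel[i]], stringsAsFactors = FALSE),
          pp[i, effnm, drop = FALSE])
      }
    }
  }
  out <- if (length(picked)) do.call(rbind, picked) else
    cbind(data.frame(trait = character(), model = character(),
                     chrom = character(), pos_cM = numeric(),
                     flank_lo = character(), flank_hi = character(),
                     F = numeric(), neglog10P = numeric(),
                     fdr_q = numeric()),
          prof[0, effnm, drop = FALSE])
  out$ci_lo <- rep(NA_real_, nrow(out))
  out$ci_hi <- rep(NA_real_, nrow(out))
  out <- out[order(out$chrom, out$pos_cM), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("qtl_calls", "data.frame")
  out
}

#' Keep only novel combined-model QTL
#'
#' Retains combined-model (CB) calls that have no line-cross or
#' half-sib call for the same trait within `window` cM on the same
#' chromosome, mirroring the declaration rule that combined-model QTL
#' are reported only when not already detected by the single-model
#' scans.
#'
#' @param calls_lc,calls_hs,calls_cb [call_qtl()] results for the three
#'   models over the same trait set.
#' @param window Exclusion window, cM.
#' @return The retained subset of `calls_cb`.
#' @export
combined_novelty_filter <- function(calls_lc, calls_hs, calls_cb,
                                    window = 30) {
  prior <- rbind(as.data.frame(calls_lc)[c("trait", "chrom", "pos_cM")],
                 as.data.frame(calls_hs)[c("trait", "chrom", "pos_cM")])
  keep <- vapply(seq_len(nrow(calls_cb)), function(i) {
    near <- prior$trait == calls_cb$trait[i] &
      prior$chrom == calls_cb$chrom[i] &
      abs(prior$pos_cM - calls_cb$pos_cM[i]) <= window
    !any(near)
  }, logical(1))
  calls_cb[keep, , drop = FALSE]
}

#' Bootstrap confidence interval for QTL position
#'
#' Nonparametric case bootstrap: F2 individuals are resampled with
#' replacement, the single-chromosome scan is recomputed for each
#' resample, and the 95% interval is the 2.5th-97.5th percentile of
#' the resampled peak positions.  Resamples with a constant trait are
#' redrawn (counted, capped at 100 redraws).
#'
#' @inheritParams scan_qtl
#' @param chromosome Chromosome carrying the called QTL.
#' @param n_boot Number of bootstrap resamples.
#' @param level Interval coverage (default 0.95).
#' @param seed Random seed (mandatory).
#' @return List of class `qtl_position_ci` with `ci` (lo/hi cM),
#'   `peaks` (resampled peak positions), `n_degenerate`, `level`,
#'   `seed`.
#' @export
bootstrap_position_ci <- function(dataset, trait,
                                  model = c("LC", "HS", "CB"),
                                  chromosome, n_boot = 1000, level = 0.95,
                                  seed, coeffs = NULL, step = 1,
                                  positions = NULL,
                                  factors = c("sex", "litter"),
                                  covariates = NULL) {
  model <- match.arg(model)
  if (missing(seed)) stop("a seed is required")
  ctx <- .scan_context(dataset, trait, model, coeffs,
                       chromosomes = chromosome, step = step,
                       positions = positions, factors = factors,
                       covariates = covariates, strict = FALSE)
  n <- length(ctx$design$y)
  zz <- ctx$Zlist[[chromosome]]
  set.seed(seed)
  peaks <- numeric(n_boot)
  n_degenerate <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::var(ctx$design$y[idx]) > 0) break
      n_degenerate <- n_degenerate + 1L
      if (n_degenerate > 100) stop("too many degenerate resamples")
    }
    X <- .X_from_data(ctx$design$data, ctx$design$sire, idx = idx)
    Zb <- list(ch = list(pos = zz$pos,
                         arr = zz$arr[idx, , , drop = FALSE],
                         colnames = zz$colnames))
    names(Zb) <- chromosome
    prof <- .profile_engine(ctx$design$y[idx], X, Zb)
    peaks[b] <- prof$pos_cM[which.max(prof$F)]
  }
  ci <- stats::quantile(peaks, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(ci = c(lo = ci[1], hi = ci[2]), peaks = peaks,
                 n_degenerate = n_degenerate, level = level, seed = seed),
            class = "qtl_position_ci")
}

#' @export
print.qtl_position_ci <- function(x, ...) {
  cat(sprintf("%.0f%% bootstrap CI for QTL position: %g - %g cM (%d resamples, seed %s)\n",
              100 * x$level, x$ci[1], x$ci[2], length(x$peaks),
              format(x$seed)))
  invisible(x)
}

#' Write QTL calls to TSV
#'
#' @param calls A [call_qtl()] result.
#' @param path Output file; `"."` marks not-applicable cells.
#' @export
write_qtl_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}
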