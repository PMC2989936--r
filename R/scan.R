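#' Nested-model F ratio
#'
#' F statistic comparing a full least-squares model against a reduced
#' model nested within it:
#' \eqn{F = ((SSE_r - SSE_f)/df_{num}) / (SSE_f/(n - p_{full}))}.
#' When the full model interpolates exactly (`sse_full = 0`) and the
#' numerator is positive, `Inf` is returned as a sentinel.
#'
#' @param sse_reduced,sse_full Residual sums of squares; the reduced
#'   value must be at least the full value.
#' @param df_num Numerator degrees of freedom (number of tested terms).
#' @param n Number of observations.
#' @param p_full Number of estimated parameters in the full model.
#' @return The F ratio (>= 0, possibly `Inf`).
#' @export
f_statistic <- function(sse_reduced, sse_full, df_num, n, p_full) {
  if (df_num < 1) stop("df_num must be >= 1")
  if (n <= p_full) stop("n must exceed the number of full-model parameters")
  if (sse_full < 0 || sse_reduced < sse_full - 1e-8 * max(1, sse_reduced))
    stop("need sse_reduced >= sse_full >= 0")
  num <- max(sse_reduced - sse_full, 0) / df_num
  if (sse_full == 0) return(if (num > 0) Inf else 0)
  num / (sse_full / (n - p_full))
}

#' Convert an F ratio to -log10 P
#'
#' Upper-tail probability of the F distribution, returned on the
#' -log10 scale (computed on the log scale, so very large F ratios do
#' not underflow).
#'
#' @param f F ratio(s), >= 0.
#' @param df_num,df_den Degrees of freedom, >= 1.
#' @param cap Upper bound applied to the result (default `Inf`).
#' @return -log10 of the upper-tail probability.
#' @export
f_to_neglog10p <- function(f, df_num, df_den, cap = Inf) {
  if (any(f < 0, na.rm = TRUE)) stop("F must be non-negative")
  if (any(df_num < 1) || any(df_den < 1)) stop("degrees of freedom must be >= 1")
  v <- -stats::pf(f, df_num, df_den, lower.tail = FALSE, log.p = TRUE) / log(10)
  pmin(v, cap)
}

#' Build the fixed-effect design for a scan model
#'
#' Expands the fixed factors (default sex and litter) as full-rank
#' indicator contrasts with an intercept, appends any covariates, and
#' for the half-sib (HS) and combined (CB) models appends sire-effect
#' indicators.  Rows with missing factor, covariate or trait values are
#' dropped.
#'
#' @param dataset An [f2_dataset()].
#' @param trait Trait column to use as the response.
#' @param model `"LC"`, `"HS"` or `"CB"`.
#' @param factors Fixed-effect factor columns of the phenotype table.
#' @param covariates Numeric covariate columns (e.g. 10-wk body weight
#'   for average daily gain).
#' @param strict Error on a rank-deficient design (default); otherwise
#'   aliased columns are tolerated and handled by pivoting downstream.
#' @return A list with `ids`, response `y`, design matrix `X`, and
#'   `sire` (factor, or `NULL` for LC).
#' @export
build_design <- function(dataset, trait, model = c("LC", "HS", "CB"),
                         factors = c("sex", "litter"), covariates = NULL,
                         strict = TRUE) {
  model <- match.arg(model)
  ph <- dataset$phenotypes
  if (!trait %in% names(ph)) stop("trait '", trait, "' not in phenotypes")
  bad <- setdiff(c(factors, covariates), names(ph))
  if (length(bad)) stop("phenotype column(s) not found: ",
                        paste(bad, collapse = ", "))
  keep <- stats::complete.cases(ph[c("id", trait, factors, covariates)])
  ph <- ph[keep, , drop = FALSE]
  if (!nrow(ph)) stop("no complete phenotype records for trait ", trait)
  dd <- data.frame(row.names = seq_len(nrow(ph)))
  for (f in factors) {
    fa <- factor(ph[[f]])
    if (any(table(fa) == 1))
      warning("factor '", f, "' has level(s) with a single observation")
    dd[[f]] <- fa
  }
  for (cv in covariates) dd[[cv]] <- as.numeric(ph[[cv]])
  X <- if (ncol(dd)) stats::model.matrix(~ ., dd) else
    matrix(1, nrow(ph), 1, dimnames = list(NULL, "(Intercept)"))
  X_pheno <- X
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    if (strict)
      stop("rank-deficient fixed-effect design; confounded column(s): ",
           paste(aliased, collapse = ", "))
  }
  sire <- NULL
  if (model %in% c("HS", "CB")) {
    ped <- dataset$pedigree
    sire <- factor(ped$sire[match(ph$id, ped$id)])
    small <- names(which(table(sire) < 2))
    if (length(small))
      warning("half-sib famil(ies) with < 2 offspring: ",
              paste(small, collapse = ", "), " (contrast inestimable)")
    # sire main effects may be aliased with litter (one sire per litter);
    # they appear in both the full and the reduced model, so pivoting
    # handles the aliasing without affecting the QTL-term test
    Xs <- stats::model.matrix(~ sire)[, -1, drop = FALSE]
    X <- cbind(X, Xs)
  }
  list(ids = ph$id, y = as.numeric(ph[[trait]]), X = X,
       X_pheno = X_pheno, data = dd, sire = sire)
}

# Rebuild the design matrix for a row subset (bootstrap) or with the
# genetic side (sire indicators) row-permuted (permutation test).
.X_from_data <- function(dd, sire, idx = NULL, sire_perm = NULL) {
  if (!is.null(idx)) {
    dd <- droplevels(dd[idx, , drop = FALSE])
    if (!is.null(sire)) sire <- droplevels(sire[idx])
  }
  if (!is.null(sire_perm) && !is.null(sire)) sire <- sire[sire_perm]
  n <- nrow(dd)
  one <- vapply(dd, function(v) is.factor(v) && nlevels(v) < 2, logical(1))
  dd <- dd[!one]
  X <- if (ncol(dd)) stats::model.matrix(~ ., dd) else
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(sire) && nlevels(sire) > 1)
    X <- cbind(X, stats::model.matrix(~ sire)[, -1, drop = FALSE])
  X
}

# One position: regress residualized response on residualized QTL
# columns (Frisch-Waugh); estimates, SEs, SSEs and the nested-model F
# are identical to refitting the full design.
.fit_qtl_terms <- function(yr, Zr, sse_red, n, p_base, cap = 300) {
  k <- ncol(Zr)
  est <- se <- rep(NA_real_, k)
  names(est) <- names(se) <- colnames(Zr)
  nz <- colSums(Zr^2) > 1e-10 * n
  if (!any(nz)) {
    return(list(F = 0, neglog10P = 0, df_num = 0L, df_den = n - p_base,
                sse_full = sse_red, sse_reduced = sse_red,
                estimates = est, se = se))
  }
  fit <- stats::lm.fit(Zr[, nz, drop = FALSE], yr)
  r <- fit$rank
  sse_full <- sum(fit$residuals^2)
  df_den <- n - p_base - r
  if (df_den < 1) stop("no residual degrees of freedom")
  f <- f_statistic(sse_red, sse_full, r, n, p_base + r)
  sigma2 <- sse_full / df_den
  piv <- fit$qr$pivot[seq_len(r)]
  cu <- chol2inv(fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE])
  est_k <- fit$coefficients
  se_k <- rep(NA_real_, length(est_k))
  se_k[piv] <- sqrt(sigma2 * diag(cu))
  est[nz] <- est_k
  se[nz] <- se_k
  list(F = f, neglog10P = f_to_neglog10p(min(f, .Machine$double.xmax),
                                         r, df_den, cap = cap),
       df_num = r, df_den = df_den, sse_full = sse_full,
       sse_reduced = sse_red, estimates = est, se = se)
}

# QTL-term columns for one position under one model.
.qtl_columns <- function(model, Pa, Pd, Ps, sire) {
  switch(model,
         LC = cbind(a = Pa, d = Pd),
         HS = {
           lv <- levels(sire)
           Z <- vapply(lv, function(s) ifelse(sire == s, Ps, 0),
                       numeric(length(Ps)))
           colnames(Z) <- paste0("alpha_", lv)
           Z
         },
         CB = {
           lv <- levels(sire)
           Z <- vapply(lv, function(s) ifelse(sire == s, Ps, 0),
                       numeric(length(Ps)))
           colnames(Z) <- paste0("alpha_", lv)
           cbind(a = Pa, d = Pd, Z)
         })
}

#' Fit the QTL model at a single position
#'
#' Ordinary least squares of the trait on the fixed-effect design plus
#' the position's QTL terms: `Pa` and `Pd` (line-cross), per-sire `Ps`
#' columns (half-sib), or both (combined).  The reduced model keeps all
#' fixed and sire effects and omits only the QTL terms.
#'
#' @param design A [build_design()] result.
#' @param Pa,Pd,Ps Origin-coefficient vectors at the position, aligned
#'   with `design$ids` (`Pa`, `Pd` used by LC/CB; `Ps` by HS/CB).
#' @param model `"LC"`, `"HS"` or `"CB"`.
#' @return A list with elements `F`, `neglog10P`, `df_num`, `df_den`,
#'   `sse_full`, `sse_reduced`, `estimates`, `se`.
#' @export
fit_at_position <- function(design, Pa = NULL, Pd = NULL, Ps = NULL,
                            model = c("LC", "HS", "CB")) {
  model <- match.arg(model)
  n <- length(design$y)
  Z <- .qtl_columns(model, Pa, Pd, Ps, design$sire)
  qx <- qr(design$X)
  yr <- qr.resid(qx, design$y)
  Zr <- qr.resid(qx, Z)
  .fit_qtl_terms(yr, Zr, sum(yr^2), n, qx$rank)
}

# Flanking markers of a position on one chromosome.
.flanking <- function(map, chrom, pos) {
  mm <- map[map$chrom == chrom, , drop = FALSE]
  lo <- mm$marker[mm$pos_cM <= pos]
  hi <- mm$marker[mm$pos_cM >= pos]
  c(if (length(lo)) lo[length(lo)] else NA_character_,
    if (length(hi)) hi[1] else NA_character_)
}

# Full profile for prepared inputs.  Zlist: per chromosome a list with
# pos and an n x k x npos array of QTL columns.
.profile_engine <- function(y, X, Zlist, cap = 300) {
  qx <- qr(X)
  n <- length(y)
  p_base <- qx$rank
  yr <- qr.resid(qx, y)
  sse_red <- sum(yr^2)
  rows <- list()
  for (ch in names(Zlist)) {
    zz <- Zlist[[ch]]
    k <- dim(zz$arr)[2]
    np <- length(zz$pos)
    Zflat <- matrix(zz$arr, n, k * np)
    Zr <- qr.resid(qx, Zflat)
    for (i in seq_len(np)) {
      Zi <- Zr[, ((i - 1) * k + 1):(i * k), drop = FALSE]
      colnames(Zi) <- zz$colnames
      ft <- .fit_qtl_terms(yr, Zi, sse_red, n, p_base, cap = cap)
      rows[[length(rows) + 1L]] <-
        c(list(chrom = ch, pos_cM = zz$pos[i], F = ft$F,
               neglog10P = ft$neglog10P, df_num = ft$df_num,
               df_den = ft$df_den),
          as.list(ft$estimates), as.list(stats::setNames(
            ft$se, paste0(names(ft$se), "_se"))))
    }
  }
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
}

# Prepared scan context shared by scan_qtl, permutation and bootstrap.
.scan_context <- function(dataset, trait, model, coeffs = NULL,
                          chromosomes = NULL, step = 1, positions = NULL,
                          factors = c("sex", "litter"), covariates = NULL,
                          phase = NULL, strict = TRUE) {
  if (is.null(coeffs))
    coeffs <- origin_coefficients(dataset, phase = phase,
                                  chromosomes = chromosomes, step = step,
                                  positions = positions)
  if (is.null(chromosomes)) chromosomes <- names(coeffs$chromosomes)
  des <- build_design(dataset, trait, model, factors, covariates,
                      strict = strict)
  idx <- match(des$ids, coeffs$ids)
  if (anyNA(idx))
    stop("phenotyped individual(s) lacking origin coefficients: ",
         paste(des$ids[is.na(idx)][1], "..."))
  Zlist <- lapply(coeffs$chromosomes[chromosomes], function(cc) {
    np <- length(cc$pos)
    Z1 <- .qtl_columns(model, cc$Pa[idx, 1], cc$Pd[idx, 1],
                       cc$Ps[idx, 1], des$sire)
    arr <- array(NA_real_, c(length(des$ids), ncol(Z1), np))
    arr[, , 1] <- Z1
    if (np > 1) for (i in 2:np)
      arr[, , i] <- .qtl_columns(model, cc$Pa[idx, i], cc$Pd[idx, i],
                                 cc$Ps[idx, i], des$sire)
    list(pos = cc$pos, arr = arr, colnames = colnames(Z1))
  })
  list(design = des, Zlist = Zlist, model = model, trait = trait,
       map = dataset$map, factors = factors, covariates = covariates)
}

#' Genome scan by least-squares interval mapping
#'
#' Fits the chosen model (line-cross `LC`, half-sib `HS`, or combined
#' `CB`) at every grid position of the requested chromosomes and
#' records the F ratio, \eqn{-\log_{10} P}, and effect estimates with
#' standard errors.  The line-cross model regresses the trait on the
#' breed-origin covariates `Pa` and `Pd`; the half-sib model fits a
#' haplotype substitution effect per F1 sire on `Ps`; the combined
#' model includes both sets of terms.  All models keep sex and litter
#' (and any covariates) as fixed effects, and HS/CB additionally keep
#' sire main effects, in both the full and the reduced model.
#'
#' @inheritParams build_design
#' @param coeffs Optional precomputed [origin_coefficients()].
#' @param chromosomes Chromosomes to scan (default: all with
#'   coefficients).
#' @param step Grid step in cM when coefficients are computed here.
#' @param positions Optional named list of explicit positions per
#'   chromosome.
#' @param phase Optional precomputed [phase_f1()].
#' @param neglog10p_cap Cap applied to \eqn{-\log_{10} P} (default 300),
#'   reached only when the full model interpolates the data exactly.
#' @return An object of class `qtl_scan`: list with `profile` (one row
#'   per grid position), `peaks` (per-chromosome maxima with flanking
#'   markers), and the model metadata.
#' @export
scan_qtl <- function(dataset, trait, model = c("LC", "HS", "CB"),
                     coeffs = NULL, chromosomes = NULL, step = 1,
                     positions = NULL, factors = c("sex", "litter"),
                     covariates = NULL, phase = NULL, neglog10p_cap = 300) {
  model <- match.arg(model)
  ctx <- .scan_context(dataset, trait, model, coeffs, chromosomes, step,
                       positions, factors, covariates, phase)
  prof <- .profile_engine(ctx$design$y, ctx$design$X, ctx$Zlist,
                          cap = neglog10p_cap)
  peaks <- do.call(rbind, lapply(split(prof, prof$chrom), function(pp) {
    i <- which.max(pp$F)
    fl <- .flanking(ctx$map, pp$chrom[i], pp$pos_cM[i])
    data.frame(chrom = pp$chrom[i], pos_cM = pp$pos_cM[i], F = pp$F[i],
               neglog10P = pp$neglog10P[i], flank_lo = fl[1],
               flank_hi = fl[2], stringsAsFactors = FALSE)
  }))
  rownames(peaks) <- NULL
  structure(list(profile = prof, peaks = peaks, model = model,
                 trait = trait, n = length(ctx$design$y),
                 factors = ctx$factors, covariates = ctx$covariates,
                 map = ctx$map),
            class = "qtl_scan")
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("QTL genome scan: model %s, trait '%s', n = %d\n",
              x$model, x$trait, x$n))
  cat(sprintf("  %d grid positions on %d chromosome(s)\n",
              nrow(x$profile), length(unique(x$profile$chrom))))
  i <- which.max(x$profile$F)
  cat(sprintf("  max F = %.2f (-log10P = %.2f) at %s:%g cM\n",
              x$profile$F[i], x$profile$neglog10P[i],
              x$profile$chrom[i], x$profile$pos_cM[i]))
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, ...) {
  i <- which.max(object$profile$F)
  structure(list(model = object$model, trait = object$trait,
                 n = object$n, peaks = object$peaks,
                 top = object$profile[i, , drop = FALSE]),
            class = "summary.qtl_scan")
}

#' @export
print.summary.qtl_scan <- function(x, ...) {
  cat(sprintf("QTL genome scan: model %s, trait '%s', n = %d\n",
              x$model, x$trait, x$n))
  cat("Per-chromosome peaks:\n")
  print(x$peaks, row.names = FALSE)
  cat("Estimates at the genome-wide peak:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.qtl_scan <- function(object, ...) {
  i <- which.max(object$profile$F)
  top <- object$profile[i, , drop = FALSE]
  nm <- setdiff(names(top), c("chrom", "pos_cM", "F", "neglog10P",
                              "df_num", "df_den"))
  nm <- nm[!grepl("_se$", nm)]
  stats::setNames(as.numeric(top[1, nm]), nm)
}

#' Plot a scan profile
#'
#' Draws the \eqn{-\log_{10} P} profile along concatenated chromosomes
#' with marker positions as ticks on the axis.
#'
#' @param x A `qtl_scan`.
#' @param threshold Optional horizontal F-threshold line, drawn after
#'   conversion to \eqn{-\log_{10} P} at the profile's median degrees of
#'   freedom.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.qtl_scan <- function(x, threshold = NULL, ...) {
  prof <- x$profile
  chs <- unique(prof$chrom)
  off <- 0
  xs <- numeric(nrow(prof))
  marks <- numeric(0)
  bounds <- numeric(0)
  for (ch in chs) {
    sel <- prof$chrom == ch
    xs[sel] <- prof$pos_cM[sel] + off
    mm <- x$map[x$map$chrom == ch, "pos_cM"]
    marks <- c(marks, mm + off)
    off <- off + max(prof$pos_cM[sel]) + 10
    bounds <- c(bounds, off - 5)
  }
  graphics::plot(xs, prof$neglog10P, type = "n",
                 xlab = "position (cM, chromosomes concatenated)",
                 ylab = expression(-log[10] * P),
                 main = sprintf("%s scan, %s", x$model, x$trait), ...)
  for (ch in chs) {
    sel <- prof$chrom == ch
    graphics::lines(xs[sel], prof$neglog10P[sel])
  }
  graphics::axis(1, at = marks, labels = FALSE, tcl = -0.2)
  if (length(chs) > 1)
    graphics::abline(v = bounds[-length(bounds)], col = "grey80", lty = 3)
  if (!is.null(threshold)) {
    df1 <- stats::median(prof$df_num[prof$df_num > 0])
    df2 <- stats::median(prof$df_den)
    graphics::abline(h = f_to_neglog10p(threshold, df1, df2), lty = 2)
  }
  invisible(x)
}

#' Write a scan profile to TSV
#'
#' Columns: `chrom`, `pos_cM`, `model`, `trait`, `F`, `neglog10P`,
#' then the effect estimate and standard-error columns of the fitted
#' model, with `"."` where a value does not apply.
#'
#' @param scan A `qtl_scan`.
#' @param path Output file.
#' @export
write_scan <- function(scan, path) {
  out <- cbind(scan$profile[c("chrom", "pos_cM")],
               model = scan$model, trait = scan$trait,
               scan$profile[setdiff(names(scan$profile),
                                    c("chrom", "pos_cM"))])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}
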