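# Two-state transition matrix for one gamete over d cM (Haldane).
.trans2 <- function(d) {
  r <- haldane_cm_to_r(d)
  matrix(c(1 - r, r, r, 1 - r), 2, 2)
}

# Per-parent emission of transmitting allele x, one row per offspring:
# columns are the probabilities under "gamete derives from haplotype 1
# (Duroc-derived)" and "haplotype 2 (Pietrain-derived)".  Ambiguous or
# missing parent phase gives a state-independent emission so the marker
# carries no information about that parent's gamete.
.parent_emission <- function(x, hd, hp, st, pg1, pg2) {
  e1 <- ifelse(st == "phased", as.numeric(x == hd),
               ifelse(st == "ambiguous",
                      0.5 * as.numeric(x == pg1 | x == pg2), 0.5))
  e2 <- ifelse(st == "phased", as.numeric(x == hp),
               ifelse(st == "ambiguous",
                      0.5 * as.numeric(x == pg1 | x == pg2), 0.5))
  cbind(e1, e2)
}

# Joint 4-state emissions for one chromosome: n x 4 x n_markers array.
# States are ordered (paternal, maternal) gamete origin:
# (1,1), (1,2), (2,1), (2,2) with origin 1 = Duroc-derived haplotype.
# The unordered offspring genotype is marginalized over both possible
# paternal/maternal allele assignments.
.joint_emissions <- function(dataset, phase, f2, sires, dams, markers) {
  g <- dataset$genotypes
  n <- length(f2)
  m <- length(markers)
  E <- array(1, c(n, 4L, m))
  pidx_s <- match(sires, phase$ids)
  pidx_d <- match(dams, phase$ids)
  gr <- rownames(g)
  f2r <- match(f2, gr)
  sr <- match(sires, gr)
  dr <- match(dams, gr)
  for (k in seq_len(m)) {
    mk <- markers[k]
    g1 <- g[, mk, 1][f2r]
    g2 <- g[, mk, 2][f2r]
    obs <- !is.na(g1)
    if (!any(obs)) next
    sg1 <- g[, mk, 1][sr]; sg2 <- g[, mk, 2][sr]
    dg1 <- g[, mk, 1][dr]; dg2 <- g[, mk, 2][dr]
    es1 <- .parent_emission(g1, phase$hap_d[pidx_s, mk],
                            phase$hap_p[pidx_s, mk],
                            phase$status[pidx_s, mk], sg1, sg2)
    es2 <- .parent_emission(g2, phase$hap_d[pidx_s, mk],
                            phase$hap_p[pidx_s, mk],
                            phase$status[pidx_s, mk], sg1, sg2)
    ed1 <- .parent_emission(g1, phase$hap_d[pidx_d, mk],
                            phase$hap_p[pidx_d, mk],
                            phase$status[pidx_d, mk], dg1, dg2)
    ed2 <- .parent_emission(g2, phase$hap_d[pidx_d, mk],
                            phase$hap_p[pidx_d, mk],
                            phase$status[pidx_d, mk], dg1, dg2)
    hom <- obs & g1 == g2
    het <- obs & g1 != g2
    for (sp in 1:2) for (sm in 1:2) {
      j <- 2L * (sp - 1L) + sm
      e <- rep(1, n)
      e[hom] <- es1[hom, sp] * ed1[hom, sm]
      e[het] <- es1[het, sp] * ed2[het, sm] + es2[het, sp] * ed1[het, sm]
      E[, j, k] <- e
    }
    bad <- obs & (E[, 1, k] + E[, 2, k] + E[, 3, k] + E[, 4, k]) == 0
    if (any(bad))
      stop("Mendelian inconsistency for individual ", f2[which(bad)[1]],
           " at marker ", mk,
           ": offspring allele incompatible with parental haplotypes")
  }
  E
}

# Forward-backward over the union of marker and grid nodes for one
# chromosome.  Returns an n x 4 x n_nodes posterior array.
.fb_posterior <- function(E, marker_pos, nodes) {
  n <- dim(E)[1]
  Tn <- length(nodes)
  mk_at <- match(marker_pos, nodes)
  emis <- function(t) {
    k <- match(nodes[t], marker_pos)
    if (is.na(k)) NULL else E[, , k, drop = TRUE]
  }
  T4s <- vector("list", Tn)
  if (Tn > 1) {
    for (t in 2:Tn) {
      T2 <- .trans2(nodes[t] - nodes[t - 1])
      T4s[[t]] <- kronecker(T2, T2)
    }
  }
  fwd <- array(NA_real_, c(n, 4L, Tn))
  f <- matrix(0.25, n, 4)
  e <- emis(1)
  if (!is.null(e)) f <- f * e
  f <- f / pmax(rowSums(f), .Machine$double.xmin)
  fwd[, , 1] <- f
  if (Tn > 1) {
    for (t in 2:Tn) {
      f <- f %*% T4s[[t]]
      e <- emis(t)
      if (!is.null(e)) f <- f * e
      f <- f / pmax(rowSums(f), .Machine$double.xmin)
      fwd[, , t] <- f
    }
  }
  post <- array(NA_real_, c(n, 4L, Tn))
  b <- matrix(1, n, 4)
  post[, , Tn] <- fwd[, , Tn]
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      e <- emis(t + 1)
      be <- if (is.null(e)) b else b * e
      b <- be %*% T4s[[t + 1]]
      b <- b / pmax(rowSums(b), .Machine$double.xmin)
      p <- fwd[, , t] * b
      post[, , t] <- p / pmax(rowSums(p), .Machine$double.xmin)
    }
  }
  post
}

.grid_positions <- function(pos, step) {
  last <- max(pos)
  sort(unique(c(seq(0, floor(last / step) * step, by = step), pos)))
}

#' Breed-of-origin and sire-haplotype transmission probabilities
#'
#' Propagates, for every F2 individual, the joint posterior probability
#' of the breed origin of its paternal and maternal gametes along each
#' chromosome by a forward-backward algorithm over a two-state process
#' per gamete with Haldane transition probabilities, conditioning on the
#' phased F1 parental haplotypes and the individual's own marker
#' genotypes.  Yields the regression covariates of the three scan
#' models: `Pa = P11 - P22` and `Pd = P12 + P21` for the line-cross
#' model, and `Ps` (probability that the paternal gamete carries the
#' sire's haplotype 1, the Duroc-derived one) for the half-sib model.
#'
#' @param dataset A validated [f2_dataset()].
#' @param phase Optional [phase_f1()] result; computed if `NULL`.
#' @param chromosomes Chromosomes to cover (default: all on the map).
#' @param step Grid step in cM (default 1); the grid runs from 0 to the
#'   last marker and always includes exact marker positions.
#' @param positions Optional named list (by chromosome) of explicit
#'   evaluation positions overriding the grid.
#' @return A list of class `origin_coeffs`: `ids` (F2 ids), `sire`
#'   (paternal F1 per F2), and `chromosomes`, a named list holding per
#'   chromosome the vector `pos` and n x position matrices `P11`,
#'   `P12`, `P21`, `P22`, `Pa`, `Pd`, `Ps`.
#' @export
origin_coefficients <- function(dataset, phase = NULL, chromosomes = NULL,
                                step = 1, positions = NULL) {
  if (is.null(phase)) phase <- phase_f1(dataset)
  ped <- dataset$pedigree
  rownames(ped) <- ped$id
  f2 <- ped$id[ped$generation == "F2"]
  f2 <- f2[f2 %in% rownames(dataset$genotypes)]
  if (!length(f2)) stop("no genotyped F2 individuals")
  sires <- ped[f2, "sire"]
  dams <- ped[f2, "dam"]
  if (any(!sires %in% phase$ids) || any(!dams %in% phase$ids))
    stop("F2 parent(s) missing from the F1 phase set")
  map <- dataset$map
  if (is.null(chromosomes)) chromosomes <- unique(map$chrom)
  out <- vector("list", length(chromosomes))
  names(out) <- chromosomes
  for (ch in chromosomes) {
    mm <- map[map$chrom == ch, , drop = FALSE]
    if (!nrow(mm)) stop("chromosome ", ch, " not on the map")
    mk <- mm$marker[mm$marker %in% colnames(dataset$genotypes)]
    mp <- mm$pos_cM[match(mk, mm$marker)]
    grid <- if (!is.null(positions) && !is.null(positions[[ch]]))
      sort(unique(positions[[ch]])) else .grid_positions(mm$pos_cM, step)
    nodes <- sort(unique(c(mp, grid)))
    E <- .joint_emissions(dataset, phase, f2, sires, dams, mk)
    post <- .fb_posterior(E, mp, nodes)
    sel <- match(grid, nodes)
    P11 <- post[, 1, sel, drop = TRUE]
    P12 <- post[, 2, sel, drop = TRUE]
    P21 <- post[, 3, sel, drop = TRUE]
    P22 <- post[, 4, sel, drop = TRUE]
    dm <- list(f2, NULL)
    shape <- function(x) matrix(x, length(f2), length(grid), dimnames = dm)
    P11 <- shape(P11); P12 <- shape(P12); P21 <- shape(P21); P22 <- shape(P22)
    clamp <- function(x, lo, hi) {
      x[x < lo] <- lo
      x[x > hi] <- hi
      x
    }
    out[[ch]] <- list(pos = grid, P11 = P11, P12 = P12, P21 = P21,
                      P22 = P22,
                      Pa = clamp(P11 - P22, -1, 1),
                      Pd = clamp(P12 + P21, 0, 1),
                      Ps = clamp(P11 + P12, 0, 1))
  }
  structure(list(ids = f2, sire = stats::setNames(sires, f2),
                 chromosomes = out),
            class = "origin_coeffs")
}

#' @export
print.origin_coeffs <- function(x, ...) {
  np <- sum(vapply(x$chromosomes, function(ch) length(ch$pos), numeric(1)))
  cat("Breed-origin coefficients:", length(x$ids), "F2 x", np,
      "grid positions on", length(x$chromosomes), "chromosome(s)\n")
  invisible(x)
}

#' @export
as.data.frame.origin_coeffs <- function(x, ...) {
  do.call(rbind, lapply(names(x$chromosomes), function(ch) {
    cc <- x$chromosomes[[ch]]
    np <- length(cc$pos)
    data.frame(id = rep(x$ids, np),
               chrom = ch,
               pos_cM = rep(cc$pos, each = length(x$ids)),
               P11 = as.vector(cc$P11), P12 = as.vector(cc$P12),
               P21 = as.vector(cc$P21), P22 = as.vector(cc$P22),
               Pa = as.vector(cc$Pa), Pd = as.vector(cc$Pd),
               sire = rep(unname(x$sire), np),
               Ps = as.vector(cc$Ps),
               stringsAsFactors = FALSE)
  }))
}

#' Single-gamete origin posterior
#'
#' Posterior probability, along one chromosome, that the gamete a parent
#' transmitted derives from its haplotype 1, given the allele the
#' offspring received at each marker.  This is the one-gamete building
#' block of [origin_coefficients()]: a two-state forward-backward pass
#' with Haldane transitions and a uniform 1/2 prior.
#'
#' @param marker_pos Marker positions (cM), increasing.
#' @param hap1,hap2 Parent haplotype alleles per marker (`NA` where the
#'   phase is unresolved; such markers are uninformative).
#' @param gamete Allele received by the offspring at each marker (`NA`
#'   where unobserved).
#' @param at Positions at which to evaluate the posterior (default: the
#'   1-cM grid from 0 to the last marker plus marker positions).
#' @param step Grid step used when `at` is `NULL`.
#' @return `data.frame` with columns `pos_cM` and `p1`.
#' @export
gamete_origin_posterior <- function(marker_pos, hap1, hap2, gamete,
                                    at = NULL, step = 1) {
  stopifnot(length(hap1) == length(marker_pos),
            length(hap2) == length(marker_pos),
            length(gamete) == length(marker_pos))
  if (is.null(at)) at <- .grid_positions(marker_pos, step)
  nodes <- sort(unique(c(marker_pos, at)))
  e1 <- ifelse(is.na(gamete) | is.na(hap1), 0.5, as.numeric(gamete == hap1))
  e2 <- ifelse(is.na(gamete) | is.na(hap2), 0.5, as.numeric(gamete == hap2))
  if (any(e1 + e2 == 0))
    stop("offspring allele incompatible with both parental haplotypes at ",
         "marker position ",
         marker_pos[which(e1 + e2 == 0)[1]], " cM")
  Tn <- length(nodes)
  fwd <- matrix(NA_real_, Tn, 2)
  f <- c(0.5, 0.5)
  k <- match(nodes[1], marker_pos)
  if (!is.na(k)) f <- f * c(e1[k], e2[k])
  fwd[1, ] <- f / sum(f)
  if (Tn > 1) {
    for (t in 2:Tn) {
      T2 <- .trans2(nodes[t] - nodes[t - 1])
      f <- fwd[t - 1, ] %*% T2
      k <- match(nodes[t], marker_pos)
      if (!is.na(k)) f <- f * c(e1[k], e2[k])
      fwd[t, ] <- f / sum(f)
    }
  }
  post <- matrix(NA_real_, Tn, 2)
  b <- c(1, 1)
  post[Tn, ] <- fwd[Tn, ]
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      k <- match(nodes[t + 1], marker_pos)
      be <- if (is.na(k)) b else b * c(e1[k], e2[k])
      T2 <- .trans2(nodes[t + 1] - nodes[t])
      b <- as.vector(T2 %*% be)
      b <- b / sum(b)
      p <- fwd[t, ] * b
      post[t, ] <- p / sum(p)
    }
  }
  sel <- match(at, nodes)
  data.frame(pos_cM = at, p1 = post[sel, 1])
}

#' Information content of the origin coefficients
#'
#' Additive information content at a position is the variance of `Pa`
#' across individuals divided by 0.5, its variance under complete
#' information in an F2 (where `Pa` is -1, 0, +1 with probabilities
#' 1/4, 1/2, 1/4); dominance information content is the variance of
#' `Pd` divided by 0.25.  Both are clipped to [0, 1].
#'
#' @param coeffs An [origin_coefficients()] result.
#' @return `data.frame` of class `information_profile` with columns
#'   `chrom`, `pos_cM`, `ic_add`, `ic_dom`.
#' @export
information_content <- function(coeffs) {
  if (length(coeffs$ids) < 2)
    stop("information content needs at least 2 individuals")
  varp <- function(m) colMeans(m^2) - colMeans(m)^2
  out <- do.call(rbind, lapply(names(coeffs$chromosomes), function(ch) {
    cc <- coeffs$chromosomes[[ch]]
    data.frame(chrom = ch, pos_cM = cc$pos,
               ic_add = pmin(1, pmax(0, varp(cc$Pa) / 0.5)),
               ic_dom = pmin(1, pmax(0, varp(cc$Pd) / 0.25)),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("information_profile", "data.frame")
  out
}
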