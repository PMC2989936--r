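#' Phase F1 parents against their F0 genotypes
#'
#' For every F1 individual, assign its marker alleles to the
#' grandpaternal (Duroc-derived) and grandmaternal (Pietrain-derived)
#' haplotype wherever the F0 genotypes resolve transmission.  A
#' heterozygous F1 marker is phased when exactly one ordering of its two
#' alleles is compatible with the sire's and dam's genotypes; when both
#' orderings are compatible the marker is flagged ambiguous and treated
#' as uninformative downstream.  Homozygous markers are trivially phased.
#'
#' @param dataset A validated [f2_dataset()].
#' @return A list of class `f1_phase`: `ids` (F1 ids), matrices `hap_d`
#'   and `hap_p` (F1 x marker allele matrices for the Duroc- and
#'   Pietrain-derived haplotypes, `NA` where unresolved), and `status`
#'   (`"phased"`, `"ambiguous"` or `"missing"` per F1 x marker).
#' @export
phase_f1 <- function(dataset) {
  ped <- dataset$pedigree
  g <- dataset$genotypes
  rownames(ped) <- ped$id
  f1 <- ped$id[ped$generation == "F1"]
  if (!length(f1)) stop("no F1 individuals in the pedigree")
  mk <- colnames(g)
  hap_d <- hap_p <- matrix(NA_integer_, length(f1), length(mk),
                           dimnames = list(f1, mk))
  status <- matrix("missing", length(f1), length(mk),
                   dimnames = list(f1, mk))
  for (id in f1) {
    s <- ped[id, "sire"]; d <- ped[id, "dam"]
    if (is.na(s) || is.na(d) || !s %in% ped$id || !d %in% ped$id)
      stop("F1 ", id, " has missing F0 parent(s)")
    u <- if (id %in% rownames(g)) g[id, , 1] else rep(NA_integer_, length(mk))
    v <- if (id %in% rownames(g)) g[id, , 2] else rep(NA_integer_, length(mk))
    s1 <- if (s %in% rownames(g)) g[s, , 1] else rep(NA_integer_, length(mk))
    s2 <- if (s %in% rownames(g)) g[s, , 2] else rep(NA_integer_, length(mk))
    d1 <- if (d %in% rownames(g)) g[d, , 1] else rep(NA_integer_, length(mk))
    d2 <- if (d %in% rownames(g)) g[d, , 2] else rep(NA_integer_, length(mk))
    from <- function(x, p1, p2) is.na(p1) | x == p1 | x == p2

    miss <- is.na(u)
    hom <- !miss & u == v
    hap_d[id, hom] <- u[hom]
    hap_p[id, hom] <- u[hom]
    status[id, hom] <- "phased"

    het <- !miss & u != v
    okA <- from(u, s1, s2) & from(v, d1, d2)  # u Duroc-derived
    okB <- from(v, s1, s2) & from(u, d1, d2)  # v Duroc-derived
    a <- het & okA & !okB
    b <- het & okB & !okA
    hap_d[id, a] <- u[a]; hap_p[id, a] <- v[a]
    hap_d[id, b] <- v[b]; hap_p[id, b] <- u[b]
    status[id, a | b] <- "phased"
    status[id, het & !(a | b)] <- "ambiguous"
  }
  structure(list(ids = f1, hap_d = hap_d, hap_p = hap_p, status = status),
            class = "f1_phase")
}

#' @export
print.f1_phase <- function(x, ...) {
  tab <- table(factor(x$status, c("phased", "ambiguous", "missing")))
  cat("F1 phase for", length(x$ids), "parents,", ncol(x$status),
      "markers\n")
  cat(sprintf("  phased %.1f%%, ambiguous %.1f%%, missing %.1f%%\n",
              100 * tab[1] / sum(tab), 100 * tab[2] / sum(tab),
              100 * tab[3] / sum(tab)))
  invisible(x)
}
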