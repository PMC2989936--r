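# Independent oracles used by the tests.  These deliberately avoid the
# package's forward-backward / QR code paths: posteriors are computed by
# exhaustive path enumeration and regressions by explicit normal
# equations.

# Posterior P(source = haplotype 1 at `at`) for a single gamete, by
# enumerating every source path over the marker nodes plus the query
# node (2^k paths).
oracle_gamete <- function(marker_pos, hap1, hap2, gamete, at) {
  emis <- function(x, h1, h2) {
    c(if (is.na(x) || is.na(h1)) 0.5 else as.numeric(x == h1),
      if (is.na(x) || is.na(h2)) 0.5 else as.numeric(x == h2))
  }
  vapply(at, function(pos) {
    nodes <- sort(unique(c(marker_pos, pos)))
    k <- length(nodes)
    qt <- match(pos, nodes)
    num <- den <- 0
    for (code in 0:(2^k - 1)) {
      src <- as.integer(intToBits(code))[1:k] + 1L
      pr <- 0.5
      if (k > 1) for (t in 2:k) {
        r <- haldane_cm_to_r(nodes[t] - nodes[t - 1])
        pr <- pr * if (src[t] == src[t - 1]) 1 - r else r
      }
      for (t in 1:k) {
        m <- match(nodes[t], marker_pos)
        if (!is.na(m)) pr <- pr * emis(gamete[m], hap1[m], hap2[m])[src[t]]
      }
      den <- den + pr
      if (src[qt] == 1L) num <- num + pr
    }
    num / den
  }, numeric(1))
}

# Joint breed-origin posterior (P11, P12, P21, P22) for one F2 at one
# position, enumerating paternal x maternal source paths and summing
# over both allele assignments of each unordered genotype.
oracle_joint <- function(ds, ph, id, chrom, pos) {
  map <- ds$map[ds$map$chrom == chrom, ]
  mk <- map$marker
  mp <- map$pos_cM
  ped <- ds$pedigree
  rownames(ped) <- ped$id
  s <- ped[id, "sire"]
  d <- ped[id, "dam"]
  g <- ds$genotypes
  nodes <- sort(unique(c(mp, pos)))
  k <- length(nodes)
  qt <- match(pos, nodes)
  pe <- function(par, m, x, state) {
    st <- ph$status[par, m]
    if (is.na(x)) return(1)
    if (st == "phased") {
      h <- if (state == 1) ph$hap_d[par, m] else ph$hap_p[par, m]
      return(as.numeric(x == h))
    }
    if (st == "ambiguous") return(0.5 * as.numeric(x %in% g[par, m, ]))
    0.5
  }
  tp <- function(path) {
    pr <- 0.5
    if (k > 1) for (t in 2:k) {
      r <- haldane_cm_to_r(nodes[t] - nodes[t - 1])
      pr <- pr * if (path[t] == path[t - 1]) 1 - r else r
    }
    pr
  }
  paths <- as.matrix(expand.grid(rep(list(1:2), k)))
  res <- numeric(4)
  den <- 0
  for (i in seq_len(nrow(paths))) for (j in seq_len(nrow(paths))) {
    sp <- paths[i, ]
    sm <- paths[j, ]
    pr <- tp(sp) * tp(sm)
    for (t in seq_len(k)) {
      m <- match(nodes[t], mp)
      if (is.na(m)) next
      g1 <- g[id, mk[m], 1]
      g2 <- g[id, mk[m], 2]
      if (is.na(g1)) next
      em <- if (g1 == g2) pe(s, mk[m], g1, sp[t]) * pe(d, mk[m], g1, sm[t])
      else pe(s, mk[m], g1, sp[t]) * pe(d, mk[m], g2, sm[t]) +
        pe(s, mk[m], g2, sp[t]) * pe(d, mk[m], g1, sm[t])
      pr <- pr * em
      if (pr == 0) break
    }
    st4 <- 2 * (sp[qt] - 1) + sm[qt]
    res[st4] <- res[st4] + pr
    den <- den + pr
  }
  res / den
}

# Ordinary least squares solved from the explicit normal equations.
oracle_ols <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% b
  list(coef = drop(b), sse = sum(res^2))
}

# Benjamini-Hochberg step-up, written as the literal definition.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[o[i]] <= i * q / m) k <- i
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  qv_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * p[o][i:m] / (i:m))), numeric(1))
  qv <- numeric(m)
  qv[o] <- qv_sorted
  list(rejected = rej, qvalues = qv,
       p_threshold = if (k > 0) p[o[k]] else NA_real_)
}
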