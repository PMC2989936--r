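test_that("single-gamete posterior matches exhaustive path enumeration", {
  # random-ish configurations with phased, ambiguous and missing markers
  cases <- list(
    list(mp = c(0, 12, 30, 47, 63, 90),
         h1 = c(1L, 2L, NA, 1L, 3L, 2L), h2 = c(2L, 2L, NA, 3L, 1L, 4L),
         g = c(1L, 2L, 2L, 3L, NA, 4L)),
    list(mp = c(0, 10, 20, 35, 55, 70, 85, 100, 120, 140),
         h1 = c(1L, 1L, 2L, NA, 1L, 2L, 1L, NA, 2L, 1L),
         h2 = c(2L, 1L, 1L, NA, 3L, 1L, 2L, NA, 1L, 2L),
         g = c(1L, 1L, 1L, 2L, 3L, NA, 2L, 1L, 1L, 2L)),
    list(mp = c(5, 40), h1 = c(1L, 1L), h2 = c(2L, 2L), g = c(1L, 2L)))
  for (cs in cases) {
    at <- sort(unique(c(cs$mp, pretty(range(cs$mp), 7))))
    at <- at[at >= 0]
    fb <- gamete_origin_posterior(cs$mp, cs$h1, cs$h2, cs$g, at = at)
    expect_equal(fb$p1, oracle_gamete(cs$mp, cs$h1, cs$h2, cs$g, at),
                 tolerance = 1e-9)
  }
})

test_that("gamete posterior honours its boundary behaviour", {
  # no informative marker -> prior 1/2 everywhere
  fb <- gamete_origin_posterior(c(0, 50), c(1L, 1L), c(1L, 1L),
                                c(1L, 1L), at = c(0, 25, 50))
  expect_equal(fb$p1, rep(0.5, 3))
  # fully informative marker indicating haplotype 1 -> posterior 1 there
  fb <- gamete_origin_posterior(c(0, 20), c(1L, 1L), c(2L, 2L),
                                c(1L, 1L), at = c(0, 10, 20))
  expect_equal(fb$p1[c(1, 3)], c(1, 1))
  # midpoint of two agreeing markers 20 cM apart: closed form
  r <- haldane_cm_to_r(10)
  expect_equal(fb$p1[2], (1 - r)^2 / ((1 - r)^2 + r^2), tolerance = 1e-12)
  # recombinant flanking markers -> 1/2 at the midpoint by symmetry
  fb <- gamete_origin_posterior(c(0, 20), c(1L, 1L), c(2L, 2L),
                                c(1L, 2L), at = 10)
  expect_equal(fb$p1, 0.5)
  # incompatible allele -> Mendelian error
  expect_error(gamete_origin_posterior(c(0, 20), c(1L, 1L), c(2L, 2L),
                                       c(3L, 1L), at = 10),
               "incompatible")
})

test_that("joint breed-origin posterior equals the joint enumeration oracle", {
  map <- tiny_map(c(0, 18, 35, 60), prefix = "J")
  cfg <- sim_config(map = map, n_f2 = 15, n_litters = 5, n_groups = 2,
                    missing_rate = 0.1,
                    traits = list(trait_config("y")))
  sim <- simulate_cross(cfg, seed = 5)
  ph <- phase_f1(sim$dataset)
  at <- c(0, 7, 18, 26, 35, 50, 60)
  cf <- origin_coefficients(sim$dataset, phase = ph,
                            positions = list("1" = at))
  cc <- cf$chromosomes[["1"]]
  for (id in cf$ids[c(1, 4, 8, 12, 15)]) {
    i <- match(id, cf$ids)
    for (pp in at) {
      t <- match(pp, cc$pos)
      got <- unname(c(cc$P11[i, t], cc$P12[i, t], cc$P21[i, t],
                      cc$P22[i, t]))
      expect_equal(got, oracle_joint(sim$dataset, ph, id, "1", pp),
                   tolerance = 1e-9)
    }
  }
})

test_that("origin coefficients satisfy their probability invariants", {
  sim <- simulate_cross(quick_cfg(n_f2 = 60, n_litters = 10,
                                  missing_rate = 0.05), seed = 9)
  cf <- origin_coefficients(sim$dataset, step = 5)
  cc <- cf$chromosomes[["1"]]
  expect_lt(max(abs(cc$P11 + cc$P12 + cc$P21 + cc$P22 - 1)), 1e-9)
  expect_true(all(cc$Pa >= -1 & cc$Pa <= 1))
  expect_true(all(cc$Pd >= 0 & cc$Pd <= 1))
  expect_true(all(cc$Ps >= 0 & cc$Ps <= 1))
})

test_that("fully informative markers give exactly 0/1 coefficients that match truth", {
  sim <- simulate_cross(quick_cfg(n_f2 = 80, n_litters = 10,
                                  disjoint = TRUE,
                                  qtl = data.frame(chrom = "1", pos_cM = 50,
                                                   mode = "breed-fixed",
                                                   a = 1, d = 0)),
                        seed = 4)
  cf <- origin_coefficients(sim$dataset, positions = list("1" = 50))
  cc <- cf$chromosomes[["1"]]
  # QTL sits on a marker; with breed-disjoint alleles everything is known
  expect_true(all(abs(cc$Pa - round(cc$Pa)) < 1e-12))
  expect_true(all(abs(cc$Pd - round(cc$Pd)) < 1e-12))
  tr <- sim$truth$codes[[1]]
  expect_equal(as.vector(cc$Pa[tr$id, 1]), tr$w_a)
  expect_equal(as.vector(cc$Pd[tr$id, 1]), tr$w_d)
  # Ps is only determined where the paternal/maternal assignment of the
  # heterozygote is itself resolvable (parents may share haplotype
  # alleles); wherever it is resolved to 0/1 it must match the truth
  ps <- as.vector(cc$Ps[tr$id, 1])
  resolved <- abs(ps - round(ps)) < 1e-12
  expect_gt(mean(resolved), 0.5)
  expect_equal(ps[resolved], tr$ps_true[resolved])
})

test_that("uninformative data give the F2 prior and |Pa| decays from a lone marker", {
  map <- tiny_map(c(0, 30, 60))
  # all offspring genotypes missing -> prior (1/4, 1/2, 1/4) everywhere
  geno <- toy_genotypes(map$marker, list(
    D1 = c("1/1", "1/1", "1/1"), P1 = c("2/2", "2/2", "2/2"),
    S1 = c("1/2", "1/2", "1/2"), M1 = c("1/2", "1/2", "1/2"),
    X1 = c("./.", "./.", "./."), X2 = c("./.", "./.", "./.")))
  cf <- origin_coefficients(toy_dataset(map, geno = geno), step = 10)
  cc <- cf$chromosomes[["1"]]
  expect_equal(as.vector(cc$Pa), rep(0, length(cc$Pa)))
  expect_equal(as.vector(cc$Pd), rep(0.5, length(cc$Pd)))
  expect_equal(as.vector(cc$Ps), rep(0.5, length(cc$Ps)))

  # one informative marker: |Pa| and |Ps - 1/2| non-increasing away from it
  geno2 <- toy_genotypes(map$marker, list(
    D1 = c("1/1", "1/1", "1/1"), P1 = c("2/2", "2/2", "2/2"),
    S1 = c("1/2", "1/2", "1/2"), M1 = c("1/2", "1/2", "1/2"),
    X1 = c("1/1", "./.", "./."), X2 = c("2/2", "./.", "./.")))
  cf2 <- origin_coefficients(toy_dataset(map, geno = geno2), step = 5)
  cc2 <- cf2$chromosomes[["1"]]
  for (i in 1:2) {
    expect_true(all(diff(abs(cc2$Pa[i, ])) <= 1e-12))
    expect_true(all(diff(abs(cc2$Ps[i, ] - 0.5)) <= 1e-12))
  }
})

test_that("sire-uninformative chromosomes give Ps = 1/2 for the family", {
  map <- tiny_map(c(0, 30))
  geno <- toy_genotypes(map$marker, list(
    D1 = c("1/1", "1/1"), P1 = c("1/1", "1/1"),
    S1 = c("1/1", "1/1"), M1 = c("1/1", "1/1"),
    X1 = c("1/1", "1/1"), X2 = c("1/1", "1/1")))
  cf <- origin_coefficients(toy_dataset(map, geno = geno), step = 10)
  expect_equal(as.vector(cf$chromosomes[["1"]]$Ps),
               rep(0.5, 2 * 4))
})

test_that("information content is 1 under complete information and 0 under none", {
  # hand-made coefficients: exact Mendelian 1:2:1 sample
  cfc <- structure(list(
    ids = paste0("X", 1:4),
    sire = setNames(rep("S1", 4), paste0("X", 1:4)),
    chromosomes = list("1" = list(
      pos = c(0, 10),
      P11 = matrix(c(1, 0, 0, 0, 1, 0, 0, 0), 4),
      P12 = matrix(c(0, 1, 0, 0, 0, 1, 0, 0), 4),
      P21 = matrix(c(0, 0, 1, 0, 0, 0, 1, 0), 4),
      P22 = matrix(c(0, 0, 0, 1, 0, 0, 0, 1), 4),
      Pa = matrix(c(1, 0, 0, -1, 1, 0, 0, -1), 4),
      Pd = matrix(c(0, 1, 1, 0, 0, 1, 1, 0), 4),
      Ps = matrix(0.5, 4, 2)))), class = "origin_coeffs")
  ic <- information_content(cfc)
  expect_equal(ic$ic_add, c(1, 1))
  expect_equal(ic$ic_dom, c(1, 1))

  cfc$chromosomes[["1"]]$Pa[] <- 0
  cfc$chromosomes[["1"]]$Pd[] <- 0.5
  ic0 <- information_content(cfc)
  expect_equal(ic0$ic_add, c(0, 0))
  expect_equal(ic0$ic_dom, c(0, 0))

  cfc$ids <- "X1"
  expect_error(information_content(cfc), "2 individuals")
})

test_that("information content peaks at markers and rises when a marker is added", {
  cfg <- quick_cfg(n_f2 = 954, n_litters = 141, pos = c(0, 25, 50))
  sim <- simulate_cross(cfg, seed = 21)
  cf <- origin_coefficients(sim$dataset, positions = list("1" = c(25, 37.5)))
  ic <- information_content(cf)
  expect_gt(ic$ic_add[ic$pos_cM == 25], ic$ic_add[ic$pos_cM == 37.5])

  # denser panel: extra marker at 37.5 raises the information there
  cfg2 <- quick_cfg(n_f2 = 954, n_litters = 141, pos = c(0, 25, 37.5, 50))
  sim2 <- simulate_cross(cfg2, seed = 21)
  cf2 <- origin_coefficients(sim2$dataset, positions = list("1" = 37.5))
  ic2 <- information_content(cf2)
  expect_gt(ic2$ic_add, ic$ic_add[ic$pos_cM == 37.5])
  expect_gt(ic2$ic_dom, ic$ic_dom[ic$pos_cM == 37.5])
})

test_that("Mendelian inconsistencies are reported with individual and marker", {
  map <- tiny_map(c(0, 30))
  geno <- toy_genotypes(map$marker, list(
    D1 = c("1/1", "1/1"), P1 = c("2/2", "2/2"),
    S1 = c("1/2", "1/2"), M1 = c("1/2", "1/2"),
    X1 = c("3/3", "1/2"), X2 = c("1/1", "2/2")))
  expect_error(origin_coefficients(toy_dataset(map, geno = geno)),
               "X1.*M1|M1.*X1")
})
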