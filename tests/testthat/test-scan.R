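test_that("F ratio arithmetic and conventions", {
  expect_equal(f_statistic(120, 100, 2, 56, 6), 5.0)
  expect_equal(f_statistic(100, 100, 2, 56, 6), 0)
  expect_identical(f_statistic(1, 0, 2, 56, 6), Inf)
  expect_identical(f_statistic(0, 0, 2, 56, 6), 0)
  expect_error(f_statistic(100, 120, 2, 56, 6), "sse_reduced")
  expect_error(f_statistic(120, 100, 0, 56, 6), "df_num")
  expect_error(f_statistic(120, 100, 2, 6, 6), "exceed")
})

test_that("F to -log10P conversion matches the F distribution", {
  expect_equal(f_to_neglog10p(0, 2, 100), 0)
  med <- qf(0.5, 2, 100)
  expect_equal(f_to_neglog10p(med, 2, 100), -log10(0.5), tolerance = 1e-9)
  v <- f_to_neglog10p(c(1, 2, 5, 10), 2, 900)
  expect_true(all(diff(v) > 0))
  expect_equal(f_to_neglog10p(Inf, 2, 100, cap = 300), 300)
  expect_error(f_to_neglog10p(-1, 2, 100), "non-negative")
})

test_that("design expansion produces full-rank indicator contrasts", {
  map <- tiny_map(c(0, 20))
  geno <- toy_genotypes(map$marker, list(
    D1 = c("1/1", "1/1"), P1 = c("2/2", "2/2"),
    S1 = c("1/2", "1/2"), M1 = c("1/2", "1/2"),
    X1 = c("1/2", "1/2"), X2 = c("1/1", "2/2"),
    X3 = c("1/2", "1/2"), X4 = c("1/1", "2/2")))
  ped <- toy_pedigree(4)
  pheno <- data.frame(id = paste0("X", 1:4), sex = c("M", "F", "M", "F"),
                      litter = c("L1", "L1", "L2", "L2"),
                      wt10 = c(25, 26, 28, 24), y = c(1, 2, 3, 4))
  ds <- f2_dataset(map, ped, geno, pheno)

  d1 <- build_design(ds, "y", "LC", factors = "sex")
  expect_equal(ncol(d1$X), 2L)  # intercept + one sex indicator
  expect_equal(unname(d1$X[, 1]), rep(1, 4))

  d2 <- build_design(ds, "y", "LC", factors = "sex", covariates = "wt10")
  expect_true("wt10" %in% colnames(d2$X))
  expect_equal(unname(d2$X[, "wt10"]), pheno$wt10)

  # litter completely confounded with sex -> explicit rank error
  pheno2 <- pheno
  pheno2$litter <- ifelse(pheno2$sex == "M", "L1", "L2")
  ds2 <- f2_dataset(map, ped, geno, pheno2)
  expect_error(build_design(ds2, "y", "LC"), "confounded")
})

test_that("exact interpolation recovers the generating effects with zero SSE", {
  sim <- simulate_cross(quick_cfg(n_f2 = 60, n_litters = 6,
                                  disjoint = TRUE), seed = 11)
  cf <- origin_coefficients(sim$dataset, positions = list("1" = 50))
  cc <- cf$chromosomes[["1"]]
  ph <- sim$dataset$phenotypes
  i <- match(ph$id, cf$ids)
  sexe <- ifelse(ph$sex == "M", 0.5, -0.5)
  ph$y <- 10 + sexe + 2.0 * cc$Pa[i, 1] + 1.0 * cc$Pd[i, 1]
  sim$dataset$phenotypes <- ph
  fit <- fit_at_position(build_design(sim$dataset, "y", "LC",
                                      factors = "sex"),
                         Pa = cc$Pa[i, 1], Pd = cc$Pd[i, 1], model = "LC")
  expect_equal(unname(fit$estimates["a"]), 2.0, tolerance = 1e-8)
  expect_equal(unname(fit$estimates["d"]), 1.0, tolerance = 1e-8)
  expect_lt(fit$sse_full, 1e-16)
  expect_gt(fit$F, 1e10)
})

test_that("position fits equal the normal-equations oracle on a toy design", {
  set.seed(42)
  n <- 12
  map <- tiny_map(c(0, 20))
  geno_list <- c(
    list(D1 = c("1/1", "1/1"), P1 = c("2/2", "2/2"),
         S1 = c("1/2", "1/2"), M1 = c("1/2", "1/2")),
    setNames(replicate(n, c(sample(c("1/1", "1/2", "2/2"), 1),
                            sample(c("1/1", "1/2", "2/2"), 1)),
                       simplify = FALSE), paste0("X", 1:n)))
  ped <- toy_pedigree(n)
  pheno <- data.frame(id = paste0("X", 1:n),
                      sex = rep(c("M", "F"), 6),
                      litter = rep(c("L1", "L2"), each = 6),
                      y = rnorm(n, 10, 2))
  ds <- f2_dataset(map, toy_pedigree(n),
                   toy_genotypes(map$marker, geno_list), pheno)
  cf <- origin_coefficients(ds, positions = list("1" = c(0, 10, 20)))
  cc <- cf$chromosomes[["1"]]
  des <- build_design(ds, "y", "LC")
  i <- match(des$ids, cf$ids)
  for (t in 1:3) {
    fit <- fit_at_position(des, Pa = cc$Pa[i, t], Pd = cc$Pd[i, t],
                           model = "LC")
    Xfull <- cbind(des$X, a = cc$Pa[i, t], d = cc$Pd[i, t])
    orc <- oracle_ols(Xfull, des$y)
    expect_equal(unname(fit$estimates), unname(orc$coef[c("a", "d")]),
                 tolerance = 1e-8)
    expect_equal(fit$sse_full, orc$sse, tolerance = 1e-8)
    orc_red <- oracle_ols(des$X, des$y)
    expect_equal(fit$sse_reduced, orc_red$sse, tolerance = 1e-8)
    # SEs from the full-design covariance
    sig2 <- orc$sse / (n - ncol(Xfull))
    covb <- sig2 * solve(crossprod(Xfull))
    expect_equal(unname(fit$se),
                 unname(sqrt(diag(covb))[c("a", "d")]), tolerance = 1e-8)
  }
})

test_that("uninformative positions are reported non-estimable with F = 0", {
  map <- tiny_map(c(0, 30))
  geno <- toy_genotypes(map$marker, list(
    D1 = c("1/1", "1/1"), P1 = c("1/1", "1/1"),
    S1 = c("1/1", "1/1"), M1 = c("1/1", "1/1"),
    X1 = c("1/1", "1/1"), X2 = c("1/1", "1/1"),
    X3 = c("1/1", "1/1"), X4 = c("1/1", "1/1")))
  ped <- toy_pedigree(4)
  pheno <- data.frame(id = paste0("X", 1:4), sex = c("M", "F", "M", "F"),
                      litter = "L1", y = c(1, 3, 2, 4))
  ds <- f2_dataset(map, ped, geno, pheno)
  sc <- scan_qtl(ds, "y", "LC", factors = "sex", step = 10)
  expect_true(all(sc$profile$F == 0))
  expect_true(all(sc$profile$df_num == 0))
  expect_true(all(is.na(sc$profile$a)))
})

test_that("scan grid has floor(length)+1 rows and nested SSEs everywhere", {
  sim <- simulate_cross(quick_cfg(n_f2 = 50, n_litters = 10,
                                  pos = c(0, 20, 40, 60, 83.4)), seed = 6)
  cf <- origin_coefficients(sim$dataset, step = 1)
  sc <- scan_qtl(sim$dataset, "y", "LC", coeffs = cf)
  expect_equal(nrow(sc$profile), floor(83.4) + 1 + 1)  # grid + one marker
  expect_true(all(sc$profile$F >= 0))
  sim2 <- simulate_cross(quick_cfg(n_f2 = 50, n_litters = 10), seed = 6)
  sc2 <- scan_qtl(sim2$dataset, "y", "LC", step = 1)
  expect_equal(nrow(sc2$profile), 101L)
})

test_that("the combined model reduces to line-cross when Ps is constant 1/2", {
  sim <- simulate_cross(quick_cfg(n_f2 = 80, n_litters = 10,
                                  qtl = data.frame(chrom = "1", pos_cM = 40,
                                                   mode = "breed-fixed",
                                                   a = 1, d = 0.5)),
                        seed = 13)
  cf <- origin_coefficients(sim$dataset, step = 10)
  cf$chromosomes[["1"]]$Ps[] <- 0.5
  lc <- scan_qtl(sim$dataset, "y", "LC", coeffs = cf)
  cb <- scan_qtl(sim$dataset, "y", "CB", coeffs = cf)
  expect_equal(cb$profile$F, lc$profile$F, tolerance = 1e-8)
  expect_equal(cb$profile$df_num, lc$profile$df_num)
  expect_equal(cb$profile$a, lc$profile$a, tolerance = 1e-8)
})

test_that("half-sib model detects within-breed QTL that line-cross misses", {
  cfg <- quick_cfg(n_f2 = 600, n_litters = 60,
                   qtl = data.frame(chrom = "1", pos_cM = 50,
                                    mode = "within-breed", a = 1.5, d = 0,
                                    freq_q_duroc = 0.5,
                                    freq_q_pietrain = 0.5),
                   balanced_founders = TRUE)
  sim <- simulate_cross(cfg, seed = 17)
  cf <- origin_coefficients(sim$dataset, step = 5)
  hs <- scan_qtl(sim$dataset, "y", "HS", coeffs = cf)
  lc <- scan_qtl(sim$dataset, "y", "LC", coeffs = cf)
  at_qtl <- function(s) s$profile$neglog10P[s$profile$pos_cM == 50]
  expect_gt(at_qtl(hs), at_qtl(lc))
  thr_hs <- fdr_f_threshold(hs, 0.05)
  expect_false(is.na(thr_hs$f_threshold))
  expect_gte(max(hs$profile$F), thr_hs$f_threshold)
  # line-cross sees no breed contrast at the QTL
  expect_lt(at_qtl(lc), 2)
})

test_that("scan peaks land near a strong simulated QTL with correct flanks", {
  cfg <- quick_cfg(n_f2 = 300, n_litters = 50,
                   qtl = data.frame(chrom = "1", pos_cM = 50,
                                    mode = "breed-fixed", a = 1.0, d = 0))
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_cross(cfg, seed = 100 + s)
    sc <- scan_qtl(sim$dataset, "y", "LC", step = 2)
    if (abs(sc$peaks$pos_cM - 50) <= 10) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
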