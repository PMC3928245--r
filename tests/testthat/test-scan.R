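test_that("GLS reduces to OLS when V is a multiple of the identity", {
  set.seed(61)
  n <- 40
  x <- rbinom(n, 2, 0.4)
  y <- 0.3 * x + rnorm(n)
  fit <- suppressWarnings(
    fit_animal_model(y, diag(n), fixed = c(sigma2_a = 0.5, sigma2_e = 0.5)))
  got <- snp_effect(fit, x, y)
  ols <- lm(y ~ x)
  expect_equal(got$a_hat, unname(coef(ols)[2]), tolerance = 1e-10)
})

test_that("the scan matches a brute-force GLS solve on a toy system", {
  set.seed(62)
  n <- 5
  A <- matrix(rnorm(n * n), n)
  G <- crossprod(A) / n + diag(n) * 0.1
  w <- runif(n, 0.5, 3)
  y <- rnorm(n)
  x <- c(0, 1, 2, 1, 0)
  s2a <- 0.7; s2e <- 1.3
  fit <- fit_animal_model(y, G, weights = w,
                          fixed = c(sigma2_a = s2a, sigma2_e = s2e))
  got <- snp_effect(fit, x, y)
  V <- s2a * G + s2e * diag(1 / w)
  oracle <- gls_oracle(x, y, V)
  expect_equal(got$a_hat, oracle$a_hat, tolerance = 1e-10)
  expect_equal(got$se, oracle$se, tolerance = 1e-10)
})

test_that("monomorphic and all-missing SNPs are skipped, duplicates agree", {
  pop <- small_pop(seed = 63, n = 100, fam = 5, m = 300, missing_rate = 0)
  panel <- pop$panel
  panel$dosage[, 1] <- 2L                 # monomorphic
  panel$dosage[, 2] <- NA_integer_        # all missing
  panel$dosage[, 4] <- panel$dosage[, 3]  # duplicate column
  ps <- deregress(pop$ebv, h2 = 0.4)
  G <- compute_grm(subset_panel(panel, snp = -(1:4)))
  fit <- fit_animal_model(ps$debv, G, weights = ps$weight)
  sc <- snp_scan(panel, ps, fit)
  expect_true(sc$skipped[1] && sc$skipped[2])
  expect_equal(sc$a_hat[1:2], c(0, 0))
  expect_equal(sc$p_value[1:2], c(1, 1))
  expect_equal(sc$a_hat[3], sc$a_hat[4])
  expect_equal(sc$p_value[3], sc$p_value[4])
  # the vectorized scan agrees with the single-SNP path
  one <- snp_effect(fit, panel$dosage[, 5], ps$debv,
                    sigma2_y = attr(sc, "sigma2_y"))
  expect_equal(one$a_hat, sc$a_hat[5], tolerance = 1e-12)
  expect_equal(one$p_value, sc$p_value[5], tolerance = 1e-12)
})

test_that("null responses simulated from the fitted model give uniform p", {
  pop <- small_pop(seed = 64, n = 200, fam = 10, m = 500, h2 = 0.4,
                   missing_rate = 0)
  ps <- deregress(pop$ebv, h2 = 0.4)
  G <- compute_grm(pop$panel)
  fit <- fit_animal_model(ps$debv, G, weights = ps$weight)
  ystar <- simulate(fit, nsim = 1, seed = 99)[[1]]
  sc <- snp_scan(pop$panel, ystar, fit)
  frac <- mean(sc$p_value[!sc$skipped] < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("wald and score statistics agree under weak effects", {
  pop <- small_pop(seed = 65, n = 150, fam = 10, m = 300, h2 = 0.3)
  ps <- deregress(pop$ebv, h2 = 0.3)
  G <- compute_grm(pop$panel)
  fit <- fit_animal_model(ps$debv, G, weights = ps$weight)
  w <- snp_scan(pop$panel, ps, fit, test = "wald")
  s <- snp_scan(pop$panel, ps, fit, test = "score")
  keep <- !w$skipped
  expect_equal(cor(w$stat[keep], s$stat[keep]), 1, tolerance = 0.01)
})

test_that("the strongest scan signal sits at or near a 5% QTL", {
  near <- vapply(1:10, function(s) {
    pop <- small_pop(seed = s + 300, n = 400, fam = 20, m = 1500, nchr = 2,
                     len = 1e7, n_qtl = 1, f = 0.05, h2 = 0.4,
                     n_x_snps = 0, n_y_snps = 0, n_mt_snps = 0,
                     n_unmapped_snps = 0)
    qc <- run_qc(pop$panel, pop$ebv)
    ps <- deregress(qc$ebv, h2 = 0.4)
    fit <- fit_animal_model(ps$debv, compute_grm(qc$panel),
                            weights = ps$weight)
    sc <- snp_scan(qc$panel, ps, fit)
    top <- sc[which.max(sc$pct_var), ]
    q <- pop$truth$qtl
    top$chrom == q$chrom && abs(top$pos - q$pos) <= 2.5e5
  }, logical(1))
  expect_gte(mean(near), 0.8)
})

test_that("LD r2 matches hand-computed correlations", {
  dosage <- cbind(a = c(0L, 1L, 2L, 2L), b = c(0L, 1L, 2L, 2L),
                  c = c(2L, 1L, 0L, 1L), d = c(1L, 1L, 1L, 1L))
  map <- data.frame(snp = colnames(dosage), chrom = "1", pos = 1:4 * 1000)
  panel <- genotype_panel(dosage, map)
  r2 <- ld_r2(panel, snps = 1:4)
  expect_equal(r2["a", "a"], 1)
  expect_equal(r2["a", "b"], 1)  # duplicated column
  expect_equal(r2["a", "c"], cor(c(0, 1, 2, 2), c(2, 1, 0, 1))^2)
  expect_true(all(is.na(r2["d", ])))  # monomorphic: undefined
  # hand value: cor of (0,1,2,2) and (2,1,0,1) = -0.8528029 -> r2 0.7272727
  expect_equal(r2["a", "c"], 0.727272727272727, tolerance = 1e-12)
})
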