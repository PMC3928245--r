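test_that("percent variance explained follows the 2pq a^2 formula", {
  expect_equal(pct_variance_explained(0, 0.3, 5), 0)
  expect_equal(pct_variance_explained(1, 0.5, 10), 5)  # 100*2*.25*1/10
  expect_equal(pct_variance_explained(1.3, 0.2, 4),
               pct_variance_explained(-1.3, 0.8, 4))  # allele relabelling
  expect_error(pct_variance_explained(1, 0.5, 0), "sigma2_y")
  expect_error(pct_variance_explained(1, 0, 1), "frequencies")
})

test_that("sliding windows are 0-anchored, half-open and SNP-count gated", {
  map <- data.frame(chrom = "1", pos = seq(5e4, 9.5e5, by = 1e5))  # 10 SNPs
  w <- build_windows(map, size = 1e6, step = 5e4, min_snps = 10)
  expect_equal(w$start[1], 0)
  expect_equal(w$n_snps[1], 10L)
  # windows exist for every k*step <= max position with >= 10 members
  expect_true(all(w$start <= max(map$pos)))
  expect_true(all(w$end - w$start == 1e6))
  expect_equal(nrow(build_windows(map, 1e6, 5e4, min_snps = 11)), 0L)

  # a SNP exactly at a window's end is excluded (half-open)
  map2 <- data.frame(chrom = "1", pos = c(1, 1e6))
  w2 <- build_windows(map2, size = 1e6, step = 5e5, min_snps = 1)
  expect_equal(w2$n_snps[w2$start == 0], 1L)
  expect_equal(w2$n_snps[w2$start == 5e5], 1L)
  expect_error(build_windows(map2, 1e6, 3e5), "multiple")
})

test_that("window means equal hand-computed averages, independently", {
  # 12 SNPs, two overlapping 1 Mb windows sliding by 0.5 Mb
  pos <- c(1e5, 2e5, 3e5, 4e5, 5e5, 6e5, 7e5, 8e5, 9e5, 1.1e6, 1.2e6, 1.4e6)
  pv <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  sr <- data.frame(chrom = "1", pos = pos, pct_var = pv)
  w <- build_windows(sr, size = 1e6, step = 5e5, min_snps = 3)
  w <- average_windows(sr, w)
  # [0, 1e6): SNPs 1..9 -> mean 5; [5e5, 1.5e6): SNPs 5..12 -> mean 8.5;
  # [1e6, 2e6): SNPs 10..12 -> mean 11
  expect_equal(w$mean_pct_var[w$start == 0], 5)
  expect_equal(w$mean_pct_var[w$start == 5e5], mean(5:12))
  expect_equal(w$mean_pct_var[w$start == 1e6], 11)
  # constant values give the constant
  sr2 <- sr; sr2$pct_var <- 7
  expect_true(all(average_windows(sr2, w)$mean_pct_var == 7))
  # locality: a SNP outside a window does not affect it
  sr3 <- sr; sr3$pct_var[12] <- 1e6
  expect_equal(average_windows(sr3, w)$mean_pct_var[w$start == 0], 5)
  # window means bounded by member extremes
  expect_true(all(w$mean_pct_var >= 1 & w$mean_pct_var <= 12))
})

test_that("the Tukey fence uses interpolated quartiles", {
  x <- 1:8
  thr <- outlier_threshold(x)
  # independent order-statistic oracle
  q1 <- quartile_oracle(x, 0.25); q3 <- quartile_oracle(x, 0.75)
  expect_equal(q1, 2.75)
  expect_equal(q3, 6.25)
  expect_equal(thr, q3 + 1.5 * (q3 - q1))
  expect_equal(thr, 11.5)
  expect_equal(sum(x > thr), 0L)
  # constants: threshold equals the constant, zero strict outliers
  expect_equal(outlier_threshold(rep(3.3, 10)), 3.3)
  expect_equal(sum(rep(3.3, 10) > 3.3), 0L)
  # permutation invariance and translation equivariance
  set.seed(81)
  v <- rexp(50)
  expect_equal(outlier_threshold(sample(v)), outlier_threshold(v))
  expect_equal(outlier_threshold(v + 2.5), outlier_threshold(v) + 2.5)
  expect_error(outlier_threshold(1:3), "at least 4")
})

test_that("outlier windows merge by overlap or abutment into disjoint loci", {
  w <- data.frame(chrom = c("1", "1", "2"),
                  start = c(0, 5e4, 0), end = c(1e6, 1.05e6, 1e6),
                  mean_pct_var = c(1, 2, 3))
  loci <- merge_outlier_windows(w)
  expect_equal(nrow(loci), 2L)
  l1 <- loci[loci$chrom == "1", ]
  expect_equal(c(l1$start, l1$end), c(0, 1.05e6))
  expect_equal(l1$avg_pct_var, 1.5)
  expect_equal(l1$peak_positions[[1]], (5e4 + 1.05e6) / 2)

  # book-ended windows merge under half-open coordinates
  wb <- data.frame(chrom = "1", start = c(0, 1e6), end = c(1e6, 2e6),
                   mean_pct_var = c(1, 1))
  lb <- merge_outlier_windows(wb)
  expect_equal(nrow(lb), 1L)
  expect_equal(c(lb$start, lb$end), c(0, 2e6))
  # tied maxima report every peak midpoint
  expect_equal(lb$peak_positions[[1]], c(5e5, 1.5e6))

  # random fixture against the naive O(n^2) union oracle
  set.seed(82)
  starts <- sample(0:40, 30, replace = TRUE) * 5e4
  rw <- data.frame(chrom = sample(c("1", "2"), 30, replace = TRUE),
                   start = starts, end = starts + 1e6,
                   mean_pct_var = runif(30))
  got <- merge_outlier_windows(rw)
  oracle <- naive_merge(rw)
  expect_equal(got[c("chrom", "start", "end")], oracle, ignore_attr = TRUE)
  # every outlier window is contained in exactly one locus
  for (i in seq_len(nrow(rw))) {
    hits <- sum(got$chrom == rw$chrom[i] & got$start <= rw$start[i] &
                  got$end >= rw$end[i])
    expect_equal(hits, 1L)
  }
})

test_that("window smoothing improves the signal-to-noise coefficient", {
  expect_equal(signal_to_noise_ratio(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(signal_to_noise_ratio(c(1, 2, 3), c(2, 2, 2, 2)), "zero")
  set.seed(83)
  vals <- abs(rnorm(10000)) + 0.5
  wins <- colMeans(matrix(vals, nrow = 25))
  expect_equal(signal_to_noise_ratio(vals, wins), sqrt(25), tolerance = 0.15)
})

test_that("shared window-level signal keeps the SNR ratio above 1", {
  set.seed(85)
  k <- 20
  nw <- 300
  shared <- rep(rexp(nw) + 0.3, each = k)
  vals <- shared + abs(rnorm(nw * k, 0, 0.5))
  wins <- colMeans(matrix(vals, nrow = k))
  expect_gt(signal_to_noise_ratio(vals, wins), 1)
})

test_that("a null polygenic trait maps few spurious loci", {
  # The Tukey fence flags a small fraction of windows on any background,
  # so a pure polygenic trait yields a low -- but not zero -- spurious
  # locus rate: well under one locus per genome on average, with a
  # sizeable fraction of clean runs.
  nloci <- vapply(1:30, function(s) {
    pop <- small_pop(seed = s, n = 500, fam = 25, m = 1200, nchr = 2,
                     len = 4e6, n_qtl = 0, h2 = 0.4, n_x_snps = 0,
                     n_y_snps = 0, n_mt_snps = 0, n_unmapped_snps = 0)
    ps <- deregress(pop$ebv, h2 = 0.4)
    G <- compute_grm(pop$panel)
    fit <- fit_animal_model(ps$debv, G, weights = ps$weight)
    nrow(map_loci(snp_scan(pop$panel, ps, fit))$loci)
  }, numeric(1))
  expect_lt(mean(nloci), 1.5)
  expect_gte(mean(nloci == 0), 0.25)
})

test_that("map_loci is deterministic and degrades gracefully", {
  pop <- small_pop(seed = 84, n = 150, fam = 10, m = 800, nchr = 2,
                   len = 8e6, n_qtl = 1, f = 0.08, h2 = 0.35)
  ps <- deregress(pop$ebv, h2 = 0.35)
  G <- compute_grm(pop$panel)
  fit <- fit_animal_model(ps$debv, G, weights = ps$weight)
  sc <- snp_scan(pop$panel, ps, fit)
  m1 <- map_loci(sc)
  m2 <- map_loci(sc)
  expect_identical(m1$loci, m2$loci)
  expect_identical(m1$summary, m2$summary)
  expect_true(m1$summary$n_windows_outlier <= m1$summary$n_windows_total)
  # outlier windows and loci cover each other exactly
  ow <- m1$windows[m1$windows$mean_pct_var > m1$summary$threshold, ]
  if (nrow(ow) > 0) {
    for (i in seq_len(nrow(ow)))
      expect_equal(sum(m1$loci$chrom == ow$chrom[i] &
                         m1$loci$start <= ow$start[i] &
                         m1$loci$end >= ow$end[i]), 1L)
    expect_true(all(m1$loci$start %in% ow$start))
  }
  # min_snps above any window occupancy: no windows, no loci
  m3 <- map_loci(sc, min_snps = 1e6)
  expect_equal(m3$summary$n_windows_total, 0L)
  expect_equal(nrow(m3$loci), 0L)
  expect_true(is.na(m3$summary$threshold))
})
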