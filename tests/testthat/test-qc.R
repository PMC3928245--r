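make_panel <- function(dosage, chrom = NULL, quality = rep(0.9, ncol(dosage)),
                       sex = NULL) {
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", m)
  map <- data.frame(snp = paste0("s", seq_len(m)), chrom = chrom,
                    pos = stats::ave(seq_len(m), chrom, FUN = seq_along) * 100)
  genotype_panel(dosage, map, quality = quality, sex = sex)
}

test_that("accuracy filter is strict and works on the accuracy scale", {
  ebv <- data.frame(id = c("a", "b", "c"), ebv = 1:3,
                    reliability = c(0.26, 0.25, 0.24))
  kept <- filter_samples_by_accuracy(ebv, 0.5)
  expect_equal(kept$id, "a")  # sqrt(0.26) = 0.5099 > 0.5; sqrt(0.25) = 0.5
  expect_equal(filter_samples_by_accuracy(ebv, 0), ebv)
  expect_error(filter_samples_by_accuracy(ebv, 0.9), "removed all")
  expect_error(filter_samples_by_accuracy(
    data.frame(id = "a", ebv = 1, reliability = 1.2), 0.5), "\\(0, 1\\]")
})

test_that("sample call-rate filter is strict", {
  dosage <- matrix(1L, 4, 10)
  dosage[1, 1] <- NA  # 9/10 = 0.9, not > 0.9
  p <- make_panel(dosage)
  expect_equal(filter_samples_by_call_rate(p, 0.9)$ids, p$ids[-1])
  expect_equal(filter_samples_by_call_rate(p, 0.5)$ids, p$ids)
  # threshold 1 removes any individual with a single missing call
  expect_equal(filter_samples_by_call_rate(p, 1 - 1e-12)$ids, p$ids[-1])
})

test_that("SNP quality filter is inclusive at the threshold", {
  dosage <- matrix(c(0L, 1L, 2L, 1L), 4, 2)
  p <- make_panel(dosage, quality = c(0.70, 0.699))
  expect_equal(filter_snps_by_quality(p, 0.7)$map$snp, "s1")
  expect_equal(n_snp(filter_snps_by_quality(p, 0)), 2L)
  p$quality <- NULL
  expect_error(filter_snps_by_quality(p), "no SNP quality")
})

test_that("MT and unmapped markers are dropped", {
  dosage <- matrix(rep(c(0L, 1L, 2L, 1L), 8), 4, 8)
  p <- make_panel(dosage, chrom = c(rep("1", 5), "MT", "MT", "0"))
  out <- drop_unusable_chromosomes(p)
  expect_equal(n_snp(out), 5L)
  expect_true(all(out$chrom_class == "autosome"))
  expect_identical(drop_unusable_chromosomes(out)$map, out$map)
  allmt <- make_panel(dosage[, 1:2], chrom = c("MT", "MT"))
  expect_error(drop_unusable_chromosomes(allmt), "empty")
})

test_that("heterozygous sex-chromosome calls are masked, autosomes untouched", {
  dosage <- cbind(x = c(0L, 1L, 2L, 1L), a = c(0L, 1L, 2L, 1L))
  p <- make_panel(dosage, chrom = c("X", "1"))
  out <- mask_sex_heterozygotes(p)
  expect_equal(out$n_masked, 2L)
  expect_equal(out$panel$dosage[, 1], c(0L, NA, 2L, NA), ignore_attr = TRUE)
  expect_equal(out$panel$dosage[, 2], dosage[, "a"], ignore_attr = TRUE)

  noxy <- make_panel(dosage, chrom = c("1", "2"))
  out2 <- mask_sex_heterozygotes(noxy)
  expect_equal(out2$n_masked, 0L)
  expect_identical(out2$panel$dosage, noxy$dosage)

  pf <- make_panel(dosage, chrom = c("X", "1"), sex = c(1L, 2L, 1L, 1L))
  expect_error(mask_sex_heterozygotes(pf), "female")
  expect_equal(mask_sex_heterozygotes(pf, force = TRUE)$n_masked, 2L)
})

test_that("MAF/call-rate filter applies both inclusive conditions", {
  n <- 100
  rare <- rep(0L, n); rare[1] <- 1L            # p = 0.005 < 0.02
  boundary <- rep(c(0L, 2L), n / 2); boundary[1:2] <- NA  # cr = 0.98
  mono <- rep(2L, n)
  good <- rep(c(0L, 1L, 2L, 1L), n / 4)
  p <- make_panel(cbind(rare, boundary, mono, good))
  out <- filter_snps_maf_callrate(p, 0.02, 0.98)
  expect_equal(out$map$snp, c("s2", "s4"))
  allna <- p; allna$dosage[, 4] <- NA
  expect_equal(filter_snps_maf_callrate(allna, 0.02, 0.98)$map$snp, "s2")
})

test_that("the full QC chain reproduces the designed survivor set", {
  fx <- qc_fixture()
  res <- run_qc(fx$panel, fx$ebv)
  expect_setequal(res$panel$map$snp, fx$expected_snps)
  expect_setequal(res$panel$ids, fx$expected_ids)
  expect_equal(res$n_masked, fx$expected_masked)
  expect_equal(res$report$n_individuals,
               c(10L, 9L, 8L, 8L, 8L, 8L, 8L))
  expect_equal(res$report$n_snps,
               c(20L, 20L, 20L, 19L, 17L, 17L, 13L))

  # idempotence: a second pass removes nothing
  res2 <- run_qc(res$panel, res$ebv)
  expect_identical(res2$panel$dosage, res$panel$dosage)
  expect_equal(res2$n_masked, 0L)
  expect_true(all(res2$report$n_snps == n_snp(res$panel)))

  # counts reconcile: non-increasing along the chain
  expect_true(all(diff(res$report$n_individuals) <= 0))
  expect_true(all(diff(res$report$n_snps) <= 0))
})

test_that("a clean panel passes QC unchanged", {
  set.seed(31)
  n <- 40
  dosage <- sapply(seq(0.2, 0.5, length.out = 12),
                   function(p) rbinom(n, 2, p))
  storage.mode(dosage) <- "integer"
  # guard against sampling accidents: every column polymorphic and common
  stopifnot(all(colMeans(dosage) / 2 >= 0.1, colMeans(dosage) / 2 <= 0.9))
  p <- make_panel(dosage)
  ebv <- data.frame(id = p$ids, ebv = rnorm(n), reliability = 0.81)
  res <- run_qc(p, ebv)
  expect_identical(res$panel$dosage, p$dosage)
  expect_equal(nrow(res$ebv), n)
})

test_that("MAF is computed after sex-het masking (pipeline order matters)", {
  # X SNP: 94 zeros + 6 hets among 100 males. Before masking p = 0.03
  # (kept); after masking it is monomorphic with call rate 0.94 (removed).
  n <- 100
  x <- rep(0L, n); x[1:6] <- 1L
  good <- rep(c(0L, 1L, 2L, 1L), n / 4)
  p <- make_panel(cbind(x, good), chrom = c("X", "1"))
  ebv <- data.frame(id = p$ids, ebv = rnorm(n), reliability = 0.81)
  res <- run_qc(p, ebv)
  expect_false("s1" %in% res$panel$map$snp)
  # swapped order would keep it:
  swapped <- filter_snps_maf_callrate(p, 0.02, 0.9)
  expect_true("s1" %in% swapped$map$snp)
})

test_that("stricter thresholds yield survivor subsets (monotone chain)", {
  pop <- small_pop(seed = 33, n = 80, fam = 8, m = 300, missing_rate = 0.02)
  loose <- run_qc(pop$panel, pop$ebv,
                  qc_thresholds(min_maf = 0.02, min_quality = 0.5))
  strict <- run_qc(pop$panel, pop$ebv,
                   qc_thresholds(min_maf = 0.1, min_quality = 0.8))
  expect_true(all(strict$panel$map$snp %in% loose$panel$map$snp))
})
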