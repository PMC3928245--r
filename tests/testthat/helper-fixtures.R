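# Hand-built fixtures used across test files.

# Small simulated population with fast defaults.
small_pop <- function(seed = 1, n = 200, fam = 10, m = 600, nchr = 2,
                      len = 5e6, n_qtl = 0, h2 = 0.4, f = 0.05, ...) {
  simulate_population(sim_config(
    n_individuals = n, n_families = fam, n_snps = m, n_chromosomes = nchr,
    chromosome_length = len, n_qtl = n_qtl, qtl_variance_fraction = f,
    heritability = h2, seed = seed, ...))
}

# 10-individual x 20-SNP QC fixture in which every filter has a designed
# violation; the expected survivor set is enumerated by hand:
#   individuals removed: ind01 (reliability 0.25 -> accuracy 0.5, not > 0.5),
#     ind02 (3 missing calls -> call rate 17/20 = 0.85, not > 0.9)
#   SNPs removed: q1 (quality 0.69 < 0.7), mt1 (MT), un1 (unmapped),
#     x1 (het masked -> call rate 7/8 < 0.98), mono1 (MAF 0),
#     miss1 (1 missing among the 8 survivors -> call rate 7/8 < 0.98),
#     y1 (hets masked -> monomorphic)
#   SNPs kept: a01..a10, q2 (quality 0.70, inclusive), a11, x2 -> 13 SNPs
qc_fixture <- function() {
  n <- 10
  clean <- c(0, 1, 2, 1, 0, 2, 0, 1, 2, 1)
  cols <- list()
  for (i in 1:10) cols[[paste0("a", sprintf("%02d", i))]] <- clean
  cols$q1 <- clean                       # fails quality
  cols$q2 <- clean                       # quality exactly 0.70: kept
  cols$mono1 <- rep(0, n)                # monomorphic
  cols$miss1 <- clean; cols$miss1[3] <- NA  # missing on surviving ind03
  cols$a11 <- clean
  cols$mt1 <- clean
  cols$un1 <- clean
  cols$x1 <- c(0, 2, 0, 2, 0, 2, 0, 2, 0, 1)  # one het (ind10)
  cols$x2 <- c(0, 2, 0, 2, 0, 2, 0, 2, 0, 2)  # clean X
  cols$y1 <- c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0)  # two hets (ind04, ind05)
  ord <- c(paste0("a", sprintf("%02d", 1:10)),       # chrom 1
           "q1", "q2", "mono1", "miss1", "a11",      # chrom 2
           "mt1", "un1", "x1", "x2", "y1")
  dosage <- do.call(cbind, cols[ord])
  dosage[2, 1:3] <- NA  # ind02: 3 missing -> sample call rate 0.85
  map <- data.frame(snp = ord,
                    chrom = c(rep("1", 10), rep("2", 5), "MT", "0",
                              "X", "X", "Y"),
                    pos = c(1:10 * 1000, 1:5 * 1000, 500, 100,
                            1000, 2000, 1000))
  quality <- rep(0.9, 20)
  quality[ord == "q1"] <- 0.69
  quality[ord == "q2"] <- 0.70
  ids <- sprintf("ind%02d", 1:n)
  panel <- genotype_panel(dosage, map, quality = quality, ids = ids,
                          sex = rep(1L, n))
  ebv <- data.frame(id = ids, ebv = seq(-1, 1, length.out = n),
                    reliability = c(0.25, rep(0.81, n - 1)))
  list(panel = panel, ebv = ebv,
       expected_snps = c(paste0("a", sprintf("%02d", 1:10)), "q2", "a11", "x2"),
       expected_ids = sprintf("ind%02d", 3:10),
       expected_masked = 3L)
}

# naive O(n^2) interval-union oracle for merge tests (overlap or abut)
naive_merge <- function(w) {
  out <- list()
  for (ch in unique(w$chrom)) {
    x <- w[w$chrom == ch, , drop = FALSE]
    grp <- seq_len(nrow(x))
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(x))) for (j in seq_len(nrow(x))) {
        if (grp[i] != grp[j] &&
            x$start[i] <= x$end[j] && x$start[j] <= x$end[i]) {
          grp[grp == grp[j]] <- grp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (g in unique(grp))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(x$start[grp == g]),
        end = max(x$end[grp == g]))
  }
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), ]
}

# independent interpolated-quartile oracle (type-7 convention, coded
# from the order-statistic definition rather than stats::quantile)
quartile_oracle <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force GLS oracle: full-matrix solve of (X' V^-1 X) b = X' V^-1 y
gls_oracle <- function(x, y, V) {
  X <- cbind(1, x)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  b <- solve(A, t(X) %*% Vi %*% y)
  list(a_hat = b[2], se = sqrt(solve(A)[2, 2]))
}
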