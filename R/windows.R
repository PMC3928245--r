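#' Percent phenotypic variance explained by a SNP
#'
#' \deqn{\%V_p = 100 \cdot \frac{2 p q \hat a^2}{\sigma^2_y}}
#' with \eqn{\hat a} the allele-substitution effect, `p`/`q` the allele
#' frequencies and \eqn{\sigma^2_y} the total trait variance. The value
#' is invariant under allele relabelling `(p, a) -> (1-p, -a)`.
#'
#' @param a_hat allele-substitution effect(s), trait units per allele.
#' @param p counted-allele frequency in (0, 1).
#' @param sigma2_y total trait variance (> 0).
#' @return percent units, `>= 0`.
#' @export
pct_variance_explained <- function(a_hat, p, sigma2_y) {
  if (any(sigma2_y <= 0)) stop("sigma2_y must be positive")
  if (any(p <= 0 | p >= 1)) stop("allele frequencies must lie in (0, 1)")
  100 * 2 * p * (1 - p) * a_hat^2 / sigma2_y
}

#' Build sliding genomic windows
#'
#' Per chromosome, windows are the half-open intervals
#' `[k*step, k*step + size)` for `k = 0, 1, ...` while
#' `k*step <= max SNP position`, anchored at position 0. A window is
#' emitted iff it contains at least `min_snps` markers (position in
#' `[start, end)`).
#'
#' @param map data.frame with columns `chrom` and `pos` (bp,
#'   position-sorted within chromosome).
#' @param size window size in bp (default 1 Mb).
#' @param step slide in bp (default 50 kb); must divide `size`.
#' @param min_snps minimum markers per emitted window (default 10).
#' @return data.frame `chrom`, `start`, `end`, `n_snps`.
#' @export
build_windows <- function(map, size = 1e6, step = 5e4, min_snps = 10) {
  if (size %% step != 0) stop("window size must be a multiple of the step")
  out <- lapply(unique(map$chrom), function(ch) {
    pos <- sort(map$pos[map$chrom == ch])
    if (length(pos) == 0) return(NULL)
    starts <- seq(0, max(pos), by = step)
    n_in <- findInterval(starts + size - 0.5, pos) -
      findInterval(starts - 0.5, pos)
    keep <- n_in >= min_snps
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = starts[keep], end = starts[keep] + size,
               n_snps = n_in[keep])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_snps = integer(0))
  rownames(out) <- NULL
  out
}

#' Average per-SNP variance explained within windows
#'
#' The smoothing step: each window's `mean_pct_var` is the plain
#' arithmetic mean of `pct_var` over its member SNPs (position in
#' `[start, end)`); overlapping windows are averaged independently.
#'
#' @param snp_results data.frame with `chrom`, `pos`, `pct_var` (e.g. a
#'   [snp_scan()]).
#' @param windows data.frame from [build_windows()].
#' @return `windows` with columns `n_snps` (members found in
#'   `snp_results`) and `mean_pct_var` added.
#' @export
average_windows <- function(snp_results, windows) {
  windows$mean_pct_var <- rep(NA_real_, nrow(windows))
  windows$n_snps <- rep(0L, nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    sr <- snp_results[snp_results$chrom == ch, , drop = FALSE]
    sr <- sr[order(sr$pos), , drop = FALSE]
    if (nrow(sr) == 0) next
    cs <- c(0, cumsum(sr$pct_var))
    lo <- findInterval(windows$start[wi] - 0.5, sr$pos)
    hi <- findInterval(windows$end[wi] - 0.5, sr$pos)
    cnt <- hi - lo
    windows$n_snps[wi] <- cnt
    windows$mean_pct_var[wi] <- ifelse(cnt > 0, (cs[hi + 1] - cs[lo + 1]) / cnt,
                                       NA_real_)
  }
  windows
}

#' Tukey-fence outlier threshold
#'
#' Returns `Q3 + 1.5 * IQR` of the window means, with quartiles by the
#' linear-interpolation convention (`stats::quantile` type 7 by
#' default). Windows strictly above the threshold are outliers.
#'
#' @param window_means numeric vector (at least 4 values).
#' @param multiplier fence multiplier (default 1.5).
#' @param qtype quantile type passed to [stats::quantile()].
#' @return the threshold, in the units of the input.
#' @export
outlier_threshold <- function(window_means, multiplier = 1.5, qtype = 7) {
  window_means <- window_means[!is.na(window_means)]
  if (length(window_means) < 4)
    stop("need at least 4 window means to place an outlier fence")
  q <- stats::quantile(window_means, c(0.25, 0.75), type = qtype, names = FALSE)
  q[2] + multiplier * (q[2] - q[1])
}

#' Merge overlapping outlier windows into candidate loci
#'
#' Sweep-line union per chromosome: windows merge iff they overlap or
#' abut (shared endpoint under half-open coordinates). Each locus
#' records the midpoints of the member window(s) attaining the maximal
#' mean (ties all reported), the mean over member-window means, and —
#' when `snp_results` is supplied — the count and average MAF of the
#' distinct SNPs inside the locus.
#'
#' @param outlier_windows data.frame `chrom`, `start`, `end`,
#'   `mean_pct_var` (the outlier subset of [average_windows()] output).
#' @param snp_results optional data.frame with `chrom`, `pos`, `maf`
#'   for SNP-level aggregation.
#' @return data.frame of loci: `chrom`, `start`, `end`, `length_mb`,
#'   `n_windows`, `peak_positions` (list column of bp midpoints),
#'   `peak_mb` (comma-joined, Mb), `avg_pct_var`, `n_snps`, `avg_maf`.
#' @export
merge_outlier_windows <- function(outlier_windows, snp_results = NULL) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length_mb = numeric(0),
                      n_windows = integer(0), peak_mb = character(0),
                      avg_pct_var = numeric(0), n_snps = integer(0),
                      avg_maf = numeric(0))
  empty$peak_positions <- list()
  if (is.null(outlier_windows) || nrow(outlier_windows) == 0)
    return(empty[c("chrom", "start", "end", "length_mb", "n_windows",
                   "peak_positions", "peak_mb", "avg_pct_var", "n_snps",
                   "avg_maf")])
  ow <- outlier_windows[order(outlier_windows$chrom, outlier_windows$start), ]
  loci <- list()
  for (ch in unique(ow$chrom)) {
    w <- ow[ow$chrom == ch, , drop = FALSE]
    cur <- 1L
    groups <- integer(nrow(w))
    groups[1] <- cur
    if (nrow(w) > 1) {
      hi <- w$end[1]
      for (i in 2:nrow(w)) {
        if (w$start[i] > hi) cur <- cur + 1L  # strict gap: no overlap, no abut
        groups[i] <- cur
        hi <- max(hi, w$end[i])
      }
    }
    for (g in unique(groups)) {
      mem <- w[groups == g, , drop = FALSE]
      mx <- max(mem$mean_pct_var)
      peaks <- (mem$start + mem$end)[mem$mean_pct_var >= mx - 1e-12] / 2
      loci[[length(loci) + 1L]] <- list(
        chrom = ch, start = min(mem$start), end = max(mem$end),
        n_windows = nrow(mem), peaks = sort(peaks),
        avg_pct_var = mean(mem$mean_pct_var))
    }
  }
  out <- data.frame(
    chrom = vapply(loci, `[[`, character(1), "chrom"),
    start = vapply(loci, `[[`, numeric(1), "start"),
    end = vapply(loci, `[[`, numeric(1), "end"),
    n_windows = vapply(loci, `[[`, integer(1), "n_windows"),
    avg_pct_var = vapply(loci, `[[`, numeric(1), "avg_pct_var"))
  out$length_mb <- (out$end - out$start) / 1e6
  out$peak_positions <- lapply(loci, `[[`, "peaks")
  out$peak_mb <- vapply(out$peak_positions,
                        function(p) paste(sprintf("%.2f", p / 1e6),
                                          collapse = ","), character(1))
  out$n_snps <- NA_integer_
  out$avg_maf <- NA_real_
  if (!is.null(snp_results)) {
    for (i in seq_len(nrow(out))) {
      inside <- snp_results$chrom == out$chrom[i] &
        snp_results$pos >= out$start[i] & snp_results$pos < out$end[i]
      out$n_snps[i] <- sum(inside)
      out$avg_maf[i] <- if (any(inside)) mean(snp_results$maf[inside]) else NA
    }
  }
  out[c("chrom", "start", "end", "length_mb", "n_windows", "peak_positions",
        "peak_mb", "avg_pct_var", "n_snps", "avg_maf")]
}

#' Signal-to-noise ratio of windows versus single SNPs
#'
#' Each strategy's signal-to-noise coefficient is the reciprocal of its
#' coefficient of variation, mean/sd; the returned ratio is
#' windows over single SNPs. Values above 1 quantify the resolution
#' gain from window smoothing.
#'
#' @param snp_pct_vars per-SNP percent variance explained.
#' @param window_means per-window mean percent variance explained.
#' @return dimensionless ratio.
#' @export
signal_to_noise_ratio <- function(snp_pct_vars, window_means) {
  snp_pct_vars <- snp_pct_vars[!is.na(snp_pct_vars)]
  window_means <- window_means[!is.na(window_means)]
  if (length(snp_pct_vars) < 2 || length(window_means) < 2)
    stop("need at least 2 values per strategy")
  ms <- mean(snp_pct_vars); mw <- mean(window_means)
  if (ms <= 0 || mw <= 0) stop("means must be positive")
  ss <- stats::sd(snp_pct_vars); sw <- stats::sd(window_means)
  if (ss == 0 || sw == 0) stop("zero standard deviation: CV undefined")
  (mw / sw) / (ms / ss)
}

#' Map candidate loci from a SNP scan
#'
#' The full windowed mapping computation: build sliding windows over
#' the tested (non-skipped) SNPs, average their percent variance
#' explained, place the Tukey fence, call outlier windows (strictly
#' above the fence), and merge overlapping/abutting outliers into
#' candidate loci. Deterministic given its inputs.
#'
#' @param scan a [snp_scan()] result (or data.frame with `chrom`,
#'   `pos`, `pct_var`, `maf`, optionally `skipped`).
#' @param size,step,min_snps window geometry, see [build_windows()].
#' @param fence_multiplier Tukey fence multiplier (default 1.5).
#' @param qtype quartile convention, see [outlier_threshold()].
#' @return object of class `"locus_map"`: list with `summary`
#'   (`threshold`, `n_windows_total`, `n_windows_outlier`,
#'   `snr_ratio`), `loci` (see [merge_outlier_windows()]) and
#'   `windows` (all evaluated windows with means).
#' @export
map_loci <- function(scan, size = 1e6, step = 5e4, min_snps = 10,
                     fence_multiplier = 1.5, qtype = 7) {
  sr <- as.data.frame(scan)
  if (!is.null(sr$skipped)) sr <- sr[!sr$skipped, , drop = FALSE]
  windows <- build_windows(sr[c("chrom", "pos")], size = size, step = step,
                           min_snps = min_snps)
  windows <- average_windows(sr, windows)
  if (nrow(windows) >= 4) {
    threshold <- outlier_threshold(windows$mean_pct_var,
                                   multiplier = fence_multiplier, qtype = qtype)
    out_w <- windows[windows$mean_pct_var > threshold, , drop = FALSE]
  } else {
    threshold <- NA_real_
    out_w <- windows[0, , drop = FALSE]
  }
  loci <- merge_outlier_windows(out_w, snp_results = sr)
  snr <- tryCatch(signal_to_noise_ratio(sr$pct_var, windows$mean_pct_var),
                  error = function(e) NA_real_)
  res <- list(summary = list(threshold = threshold,
                             n_windows_total = nrow(windows),
                             n_windows_outlier = nrow(out_w),
                             snr_ratio = snr),
              loci = loci, windows = windows,
              params = list(size = size, step = step, min_snps = min_snps,
                            fence_multiplier = fence_multiplier,
                            qtype = qtype))
  class(res) <- "locus_map"
  res
}

#' @export
print.locus_map <- function(x, ...) {
  s <- x$summary
  cat("Windowed locus map\n")
  cat(sprintf("  windows evaluated: %d; outliers: %d (fence at %s %%Vp)\n",
              s$n_windows_total, s$n_windows_outlier,
              ifelse(is.na(s$threshold), "NA", sprintf("%.4f", s$threshold))))
  cat(sprintf("  signal-to-noise ratio (windows / single SNPs): %s\n",
              ifelse(is.na(s$snr_ratio), "NA", sprintf("%.2f", s$snr_ratio))))
  cat(sprintf("  candidate loci: %d\n", nrow(x$loci)))
  if (nrow(x$loci) > 0)
    print.data.frame(x$loci[c("chrom", "start", "end", "length_mb", "peak_mb",
                              "avg_pct_var", "n_snps", "avg_maf")],
                     row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.locus_map <- function(object, ...) object$summary

#' @export
plot.locus_map <- function(x, ...) {
  w <- x$windows
  manhattan_panel(w$chrom, (w$start + w$end) / 2, w$mean_pct_var,
                  ylab = "% phenotypic variance (window mean)", ...)
  if (!is.na(x$summary$threshold))
    graphics::abline(h = x$summary$threshold, lty = 2, col = "red3")
  invisible(x)
}

# shared Manhattan-style base-graphics panel
manhattan_panel <- function(chrom, pos, value, ylab, ...) {
  chrom_f <- factor(chrom, levels = unique(chrom))
  offs <- c(0, cumsum(tapply(pos, chrom_f, max)))[seq_along(levels(chrom_f))]
  xx <- pos + offs[as.integer(chrom_f)]
  cols <- c("grey25", "steelblue")[(as.integer(chrom_f) %% 2) + 1]
  graphics::plot(xx, value, pch = 16, cex = 0.4, col = cols,
                 xlab = "genome position", ylab = ylab, xaxt = "n", ...)
  mids <- tapply(xx, chrom_f, stats::median)
  graphics::axis(1, at = mids, labels = levels(chrom_f), tick = FALSE)
}

#' Write windows or loci as BED plus extended TSV
#'
#' BED output is 0-based half-open. The TSV mirrors the usual locus
#' table: interval in Mb, peak(s), segment length, SNP count, average
#' MAF and average percent variance explained.
#'
#' @param locus_map a [map_loci()] result.
#' @param prefix output path prefix; writes `<prefix>_loci.bed`,
#'   `<prefix>_loci.tsv`, `<prefix>_windows.bed`,
#'   `<prefix>_windows.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_locus_map <- function(locus_map, prefix) {
  loci <- locus_map$loci
  w <- locus_map$windows
  paths <- character(0)
  bed <- function(df, name) {
    p <- paste0(prefix, "_", name, ".bed")
    utils::write.table(
      data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                 format(df$end, scientific = FALSE, trim = TRUE)),
      p, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    p
  }
  paths <- c(paths, bed(loci, "loci"), bed(w, "windows"))
  ltsv <- loci[c("chrom", "start", "end", "length_mb", "peak_mb",
                 "n_windows", "n_snps", "avg_maf", "avg_pct_var")]
  ltsv$start_mb <- ltsv$start / 1e6
  ltsv$end_mb <- ltsv$end / 1e6
  p <- paste0(prefix, "_loci.tsv")
  utils::write.table(ltsv[c("chrom", "start_mb", "end_mb", "peak_mb",
                            "length_mb", "n_snps", "avg_maf", "avg_pct_var")],
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_windows.tsv")
  wt <- data.frame(chrom = w$chrom, midpoint = (w$start + w$end) / 2,
                   n_snps = w$n_snps, mean_pct_var = w$mean_pct_var)
  utils::write.table(wt, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p))
}
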