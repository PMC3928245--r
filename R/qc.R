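#' Quality-control thresholds
#'
#' Bundle of thresholds for [run_qc()], defaulting to the values used
#' in progeny-test HD genotyping studies: EBV accuracy > 0.5 (strict),
#' sample call rate > 0.9 (strict), assay quality (GenTrain) >= 0.7,
#' MAF >= 0.02 and SNP call rate >= 0.98 (all inclusive).
#'
#' @param min_accuracy minimum EBV accuracy (square root of
#'   reliability), exclusive.
#' @param min_sample_call_rate minimum per-individual call rate,
#'   exclusive.
#' @param min_quality minimum per-SNP quality score, inclusive.
#' @param min_maf minimum minor allele frequency, inclusive.
#' @param min_snp_call_rate minimum per-SNP call rate, inclusive.
#' @return list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(min_accuracy = 0.5, min_sample_call_rate = 0.9,
                          min_quality = 0.7, min_maf = 0.02,
                          min_snp_call_rate = 0.98) {
  out <- list(min_accuracy = min_accuracy,
              min_sample_call_rate = min_sample_call_rate,
              min_quality = min_quality, min_maf = min_maf,
              min_snp_call_rate = min_snp_call_rate)
  if (any(!vapply(out, is.numeric, logical(1))))
    stop("all thresholds must be numeric")
  class(out) <- "qc_thresholds"
  out
}

#' Filter samples by EBV accuracy
#'
#' Keeps records whose accuracy (square root of reliability) is
#' strictly greater than `min_accuracy` for every reliability column
#' supplied (one per trait model).
#'
#' @param ebv data.frame with an `id` column and the reliability
#'   column(s) named in `reliability_cols`.
#' @param min_accuracy accuracy threshold, exclusive.
#' @param reliability_cols names of the reliability columns to test.
#' @return The filtered data.frame.
#' @export
filter_samples_by_accuracy <- function(ebv, min_accuracy = 0.5,
                                       reliability_cols = "reliability") {
  missing_cols <- setdiff(reliability_cols, names(ebv))
  if (length(missing_cols))
    stop("reliability column(s) not found: ", paste(missing_cols, collapse = ", "))
  keep <- rep(TRUE, nrow(ebv))
  for (col in reliability_cols) {
    r2 <- ebv[[col]]
    if (any(r2 <= 0 | r2 > 1, na.rm = TRUE))
      stop("reliabilities must lie in (0, 1]")
    keep <- keep & !is.na(r2) & sqrt(r2) > min_accuracy
  }
  if (!any(keep))
    stop("accuracy filter (accuracy > ", min_accuracy, ") removed all samples")
  ebv[keep, , drop = FALSE]
}

#' Filter samples by genotype call rate
#'
#' An individual is retained iff its fraction of non-missing genotypes
#' over the current marker set is strictly greater than
#' `min_call_rate`.
#'
#' @param panel a [genotype_panel()].
#' @param min_call_rate exclusive threshold.
#' @return The filtered panel.
#' @export
filter_samples_by_call_rate <- function(panel, min_call_rate = 0.9) {
  keep <- sample_call_rate(panel) > min_call_rate
  if (!any(keep))
    stop("sample call-rate filter (> ", min_call_rate, ") removed all samples")
  subset_panel(panel, ind = keep)
}

#' Filter SNPs by assay quality score
#'
#' Keeps SNPs with quality (e.g. GenTrain score) greater than or equal
#' to `min_quality`.
#'
#' @param panel a [genotype_panel()] carrying quality scores.
#' @param min_quality inclusive threshold.
#' @return The filtered panel.
#' @export
filter_snps_by_quality <- function(panel, min_quality = 0.7) {
  if (is.null(panel$quality))
    stop("panel carries no SNP quality scores; cannot apply a quality filter")
  keep <- !is.na(panel$quality) & panel$quality >= min_quality
  if (!any(keep)) stop("quality filter removed all SNPs")
  subset_panel(panel, snp = keep)
}

#' Drop mitochondrial and unmapped markers
#'
#' @param panel a [genotype_panel()].
#' @return The panel without SNPs of class `"MT"` or `"unmapped"`.
#' @export
drop_unusable_chromosomes <- function(panel) {
  keep <- !(panel$chrom_class %in% c("MT", "unmapped"))
  if (!any(keep)) stop("dropping MT/unmapped markers left an empty panel")
  subset_panel(panel, snp = keep)
}

#' Mask heterozygous calls on sex chromosomes
#'
#' Males are hemizygous for X and Y outside the pseudo-autosomal
#' region, so heterozygous X/Y calls are treated as genotyping errors
#' and set missing. Autosomes are untouched.
#'
#' @param panel a [genotype_panel()]; all individuals must be male
#'   unless `force = TRUE`.
#' @param force proceed even if female individuals are present.
#' @return list with `panel` (masked) and `n_masked` (count of calls
#'   set missing).
#' @export
mask_sex_heterozygotes <- function(panel, force = FALSE) {
  if (any(panel$sex == 2L) && !force)
    stop("female individuals present; heterozygous X calls can be genuine. ",
         "Use force = TRUE to mask anyway.")
  sexy <- which(panel$chrom_class %in% c("X", "Y"))
  n_masked <- 0L
  if (length(sexy)) {
    block <- panel$dosage[, sexy, drop = FALSE]
    het <- !is.na(block) & block == 1L
    n_masked <- sum(het)
    block[het] <- NA_integer_
    panel$dosage[, sexy] <- block
  }
  list(panel = panel, n_masked = n_masked)
}

#' Filter SNPs jointly on MAF and call rate
#'
#' A SNP is kept iff its minor allele frequency (computed from
#' non-missing dosages, after any sex-chromosome masking) is at least
#' `min_maf` AND its call rate is at least `min_call_rate`; i.e. it is
#' removed when it fails either condition. SNPs with zero non-missing
#' calls are removed.
#'
#' @param panel a [genotype_panel()].
#' @param min_maf inclusive MAF threshold.
#' @param min_call_rate inclusive call-rate threshold.
#' @return The filtered panel.
#' @export
filter_snps_maf_callrate <- function(panel, min_maf = 0.02,
                                     min_call_rate = 0.98) {
  maf <- snp_maf(panel)
  cr <- snp_call_rate(panel)
  keep <- !is.na(maf) & maf >= min_maf & cr >= min_call_rate
  if (!any(keep)) stop("MAF/call-rate filter removed all SNPs")
  subset_panel(panel, snp = keep)
}

#' Run the full QC chain
#'
#' Applies, in order: EBV-accuracy sample filter; panel/EBV alignment;
#' sample call-rate filter (on the pre-SNP-filter marker set); SNP
#' quality filter; removal of MT/unmapped markers; heterozygous X/Y
#' masking; joint MAF/call-rate SNP filter. MAF is deliberately
#' computed after masking, which alters X/Y frequencies and call
#' rates. The report records individual and SNP counts after every
#' step.
#'
#' @param panel a [genotype_panel()].
#' @param ebv data.frame with `id`, `ebv`, `reliability`.
#' @param thresholds a [qc_thresholds()].
#' @param force_sex_mask passed to [mask_sex_heterozygotes()].
#' @return list with `panel`, `ebv`, `report` (class `"qc_report"`)
#'   and `n_masked`.
#' @export
run_qc <- function(panel, ebv, thresholds = qc_thresholds(),
                   force_sex_mask = FALSE) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  steps <- list()
  note <- function(step) {
    steps[[length(steps) + 1L]] <<-
      data.frame(step = step, n_individuals = n_ind(panel),
                 n_snps = n_snp(panel))
  }
  panel <- subset_panel(panel, ind = panel$ids %in% ebv$id)
  ebv <- ebv[match(panel$ids, ebv$id), , drop = FALSE]
  note("input")
  ebv <- filter_samples_by_accuracy(ebv, thresholds$min_accuracy)
  panel <- subset_panel(panel, ind = panel$ids %in% ebv$id)
  note("ebv_accuracy")
  panel <- filter_samples_by_call_rate(panel, thresholds$min_sample_call_rate)
  ebv <- ebv[match(panel$ids, ebv$id), , drop = FALSE]
  note("sample_call_rate")
  panel <- filter_snps_by_quality(panel, thresholds$min_quality)
  note("snp_quality")
  panel <- drop_unusable_chromosomes(panel)
  note("chromosome_class")
  masked <- mask_sex_heterozygotes(panel, force = force_sex_mask)
  panel <- masked$panel
  note("sex_het_masking")
  panel <- filter_snps_maf_callrate(panel, thresholds$min_maf,
                                    thresholds$min_snp_call_rate)
  note("maf_call_rate")
  report <- do.call(rbind, steps)
  rownames(report) <- NULL
  class(report) <- c("qc_report", "data.frame")
  list(panel = panel, ebv = ebv, report = report, n_masked = masked$n_masked)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (counts surviving each step):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a `"qc_report"`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
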