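#' Genotype panel container
#'
#' Bundles a dosage matrix (individuals x SNPs, allele counts of the A1
#' allele in 0/1/2, `NA` = missing) with its marker map, per-SNP assay
#' quality scores, chromosome classification and individual metadata.
#'
#' @param dosage integer matrix, individuals in rows, SNPs in columns;
#'   entries in \{0, 1, 2, NA\}. Row and column names are used as
#'   individual and SNP ids when `ids`/`map$snp` are absent.
#' @param map data.frame with one row per SNP: columns `snp`, `chrom`
#'   (character label), `pos` (base pairs, non-negative), and optionally
#'   `a1`, `a2` allele codes. Must be position-sorted within chromosome.
#' @param quality numeric vector of per-SNP quality scores in \[0, 1\]
#'   (e.g. GenTrain), or `NULL` if the assay provides none.
#' @param ids character vector of individual ids.
#' @param sex integer vector per individual, 1 = male, 2 = female.
#'
#' @return An object of class `"genotype_panel"`.
#' @export
genotype_panel <- function(dosage, map, quality = NULL, ids = NULL, sex = NULL) {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix")
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(ids)) ids <- rownames(dosage)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (length(ids) != n) stop("length(ids) must equal nrow(dosage)")
  if (!is.data.frame(map) || nrow(map) != m)
    stop("`map` must be a data.frame with one row per SNP column")
  if (!all(c("chrom", "pos") %in% names(map)))
    stop("`map` needs columns chrom and pos")
  if (is.null(map$snp)) map$snp <- colnames(dosage)
  if (is.null(map$snp)) map$snp <- paste0("snp", seq_len(m))
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  map$chrom <- as.character(map$chrom)
  if (any(map$pos < 0, na.rm = TRUE)) stop("marker positions must be non-negative")
  bad <- !is.na(dosage) & (dosage < 0L | dosage > 2L)
  if (any(bad)) stop("dosages must be in {0, 1, 2} or NA")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p)) stop("marker map not position-sorted within chromosome ", ch)
  }
  if (!is.null(quality)) {
    if (length(quality) != m) stop("`quality` must have one entry per SNP")
    if (any(quality < 0 | quality > 1, na.rm = TRUE))
      stop("quality scores must lie in [0, 1]")
  }
  if (is.null(sex)) sex <- rep(1L, n)
  if (length(sex) != n) stop("`sex` must have one entry per individual")
  rownames(dosage) <- ids
  colnames(dosage) <- map$snp
  structure(
    list(dosage = dosage, map = map, quality = quality,
         chrom_class = classify_chromosome(map$chrom),
         ids = ids, sex = as.integer(sex)),
    class = "genotype_panel")
}

#' Classify chromosome labels
#'
#' Maps chromosome labels to the classes the QC chain distinguishes:
#' `"X"`, `"Y"`, `"MT"` (also `"M"`), `"0"`/`""`/`"UN"` = unmapped,
#' everything else autosome.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector with values in
#'   `c("autosome", "X", "Y", "MT", "unmapped")`.
#' @export
classify_chromosome <- function(chrom) {
  chrom <- toupper(as.character(chrom))
  out <- rep("autosome", length(chrom))
  out[chrom == "X"] <- "X"
  out[chrom == "Y"] <- "Y"
  out[chrom %in% c("MT", "M", "MITO")] <- "MT"
  out[chrom %in% c("0", "", "UN", "NA")] <- "unmapped"
  out
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("Genotype panel:", length(x$ids), "individuals x", nrow(x$map), "SNPs\n")
  tab <- table(factor(x$chrom_class,
                      levels = c("autosome", "X", "Y", "MT", "unmapped")))
  cat("  SNP classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.3f%%\n", 100 * miss))
  if (!is.null(x$quality))
    cat(sprintf("  SNP quality: median %.3f, min %.3f\n",
                stats::median(x$quality), min(x$quality)))
  invisible(x)
}

#' Panel dimensions
#'
#' @param panel a `genotype_panel`.
#' @return number of individuals (`n_ind`) or SNPs (`n_snp`).
#' @export
n_ind <- function(panel) length(panel$ids)

#' @rdname n_ind
#' @export
n_snp <- function(panel) nrow(panel$map)

#' Subset a genotype panel
#'
#' @param panel a `genotype_panel`.
#' @param ind logical/integer/character index of individuals to keep.
#' @param snp logical/integer/character index of SNPs to keep.
#' @return The subset `genotype_panel`.
#' @export
subset_panel <- function(panel, ind = NULL, snp = NULL) {
  if (is.null(ind)) ind <- seq_along(panel$ids)
  if (is.null(snp)) snp <- seq_len(nrow(panel$map))
  if (is.character(ind)) ind <- match(ind, panel$ids)
  if (is.character(snp)) snp <- match(snp, panel$map$snp)
  panel$dosage <- panel$dosage[ind, snp, drop = FALSE]
  panel$map <- panel$map[snp, , drop = FALSE]
  rownames(panel$map) <- NULL
  if (!is.null(panel$quality)) panel$quality <- panel$quality[snp]
  panel$chrom_class <- panel$chrom_class[snp]
  panel$ids <- panel$ids[ind]
  panel$sex <- panel$sex[ind]
  if (length(panel$ids) == 0L) stop("panel subset has zero individuals")
  panel
}

#' Per-SNP allele frequency and MAF
#'
#' Frequency of the counted (A1) allele among non-missing genotypes;
#' the minor allele frequency is `pmin(p, 1 - p)`. SNPs with no
#' non-missing calls yield `NA`.
#'
#' @param panel a `genotype_panel`.
#' @return For `snp_freq`, the A1 allele frequency per SNP; for
#'   `snp_maf`, the minor allele frequency.
#' @export
snp_freq <- function(panel) colMeans(panel$dosage, na.rm = TRUE) / 2

#' @rdname snp_freq
#' @export
snp_maf <- function(panel) {
  p <- snp_freq(panel)
  pmin(p, 1 - p)
}

#' Call rates
#'
#' Fraction of non-missing genotypes per SNP or per individual.
#'
#' @param panel a `genotype_panel`.
#' @return numeric vector of call rates in \[0, 1\].
#' @export
snp_call_rate <- function(panel) colMeans(!is.na(panel$dosage))

#' @rdname snp_call_rate
#' @export
sample_call_rate <- function(panel) rowMeans(!is.na(panel$dosage))
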