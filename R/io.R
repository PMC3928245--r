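#' Write a genotype panel as a PLINK fileset
#'
#' Emits the variant-major binary PLINK triplet `<prefix>.bed` /
#' `.bim` / `.fam` (standard magic bytes `6c 1b 01`), plus two TSV
#' side-cars: `<prefix>.ebv.tsv` with columns `id`, `ebv`,
#' `reliability` (and any extra columns of `ebv`), and
#' `<prefix>.snps.tsv` with columns `snp`, `quality`. Dosages count the
#' A1 allele of the `.bim`; missing genotypes use the PLINK missing
#' code.
#'
#' @param panel a [genotype_panel()].
#' @param ebv optional data.frame with at least `id`, `ebv`,
#'   `reliability`; rows must cover the panel's individuals.
#' @param prefix path prefix for the output files.
#' @return Invisibly, the paths written.
#' @export
write_panel <- function(panel, ebv = NULL, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- n_ind(panel); m <- n_snp(panel)
  if (n == 0L) stop("refusing to write a panel with zero individuals")
  if (m == 0L) stop("refusing to write a panel with zero SNPs")
  dir <- dirname(prefix)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)

  # .bed, variant-major: 00=hom A1, 01=missing, 10=het, 11=hom A2
  code <- matrix(1L, 4L * ceiling(n / 4), m)
  code[seq_len(n), ] <- c(3L, 2L, 0L)[panel$dosage + 1L]
  code[seq_len(n), ][is.na(panel$dosage)] <- 1L
  dim(code) <- c(4L, length(code) / 4L)
  bytes <- as.raw(colSums(code * c(1L, 4L, 16L, 64L)))
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), bytes), con)
  close(con)

  bim <- data.frame(chrom = panel$map$chrom, snp = panel$map$snp, cm = 0,
                    pos = panel$map$pos, a1 = panel$map$a1, a2 = panel$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = panel$ids, iid = panel$ids, pid = 0, mid = 0,
                    sex = panel$sex, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  qual <- if (is.null(panel$quality)) rep(NA_real_, m) else panel$quality
  utils::write.table(data.frame(snp = panel$map$snp, quality = qual),
                     paste0(prefix, ".snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- paste0(prefix, c(".bed", ".bim", ".fam", ".snps.tsv"))
  if (!is.null(ebv)) {
    if (!all(c("id", "ebv", "reliability") %in% names(ebv)))
      stop("`ebv` needs columns id, ebv, reliability")
    utils::write.table(ebv, paste0(prefix, ".ebv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, paste0(prefix, ".ebv.tsv"))
  }
  invisible(paths)
}

#' Read a PLINK fileset into a genotype panel
#'
#' Counterpart of [write_panel()]; also accepts filesets written by
#' other tools (the `.snps.tsv` / `.ebv.tsv` side-cars are optional).
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return list with `panel` (a [genotype_panel()]) and `ebv`
#'   (data.frame or `NULL`).
#' @export
read_panel <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  for (f in paste0(prefix, c(".bed", ".bim", ".fam")))
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  names(bim) <- c("chrom", "snp", "cm", "pos", "a1", "a2")
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "character"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01))
    stop("only variant-major .bed files are supported")
  bpv <- ceiling(n / 4)
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bpv * m)
    stop(".bed size does not match .bim/.fam dimensions")
  codes <- matrix(0L, 4L, length(body))
  codes[1L, ] <- body %% 4L
  codes[2L, ] <- (body %/% 4L) %% 4L
  codes[3L, ] <- (body %/% 16L) %% 4L
  codes[4L, ] <- body %/% 64L
  dim(codes) <- c(4L * bpv, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  dosage <- matrix(c(2L, NA_integer_, 1L, 0L)[codes + 1L], n, m)

  qual_path <- paste0(prefix, ".snps.tsv")
  quality <- NULL
  if (file.exists(qual_path)) {
    qt <- utils::read.table(qual_path, header = TRUE, sep = "\t",
                            colClasses = c("character", "numeric"))
    quality <- qt$quality[match(bim$snp, qt$snp)]
    if (all(is.na(quality))) quality <- NULL
  }
  panel <- genotype_panel(dosage, bim[c("snp", "chrom", "pos", "a1", "a2")],
                          quality = quality, ids = fam[[2]], sex = fam[[5]])
  ebv_path <- paste0(prefix, ".ebv.tsv")
  ebv <- if (file.exists(ebv_path))
    utils::read.table(ebv_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  list(panel = panel, ebv = ebv)
}

#' Read a VCF into a genotype panel
#'
#' Converts the GT field to A1 (=ALT) allele dosage. Requires the
#' `vcfR` package. Per-SNP quality is taken from the QUAL column scaled
#' into \[0, 1\] by `quality_scale` when present.
#'
#' @param path a VCF file.
#' @param quality_scale divisor applied to QUAL to map it into \[0, 1\];
#'   `NULL` leaves quality unset.
#' @return a [genotype_panel()].
#' @export
read_vcf_panel <- function(path, quality_scale = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_panel() requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    g[g %in% c(".", "./.", ".|.")] <- NA
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = TRUE)
    vapply(al, function(a) {
      if (length(a) == 0 || anyNA(a) || any(a == "."))
        return(NA_integer_)
      sum(a != "0")
    }, integer(1))
  }
  dosage <- t(apply(gt, 1, count_alt))
  fix <- vcfR::getFIX(v)
  map <- data.frame(snp = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                 paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                 fix[, "ID"]),
                    chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                    a1 = fix[, "ALT"], a2 = fix[, "REF"],
                    stringsAsFactors = FALSE)
  quality <- NULL
  if (!is.null(quality_scale)) {
    q <- suppressWarnings(as.numeric(fix[, "QUAL"]))
    quality <- pmin(pmax(q / quality_scale, 0), 1)
  }
  o <- order(map$chrom, map$pos)
  genotype_panel(t(dosage)[, o, drop = FALSE], map[o, ],
                 quality = quality[o], ids = colnames(gt))
}
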