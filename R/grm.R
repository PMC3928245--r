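#' Genomic relationship matrix (VanRaden method 1)
#'
#' \deqn{G = \frac{(M - 2P)(M - 2P)^\top}{2\sum_j p_j q_j}}
#' with `M` the dosage matrix, `P` the row of observed allele
#' frequencies and the sum over the SNPs used. Missing dosages are
#' imputed to `2p` of their SNP (mean imputation). By default only
#' autosomal SNPs enter; monomorphic SNPs contribute nothing to either
#' numerator or denominator.
#'
#' @param panel a post-QC [genotype_panel()].
#' @param snps which SNPs to use: `"autosome"` (default) or `"all"`,
#'   or an explicit index vector.
#' @return symmetric n x n matrix with individual ids as dimnames.
#' @export
compute_grm <- function(panel, snps = "autosome") {
  if (identical(snps, "autosome")) {
    use <- which(panel$chrom_class == "autosome")
  } else if (identical(snps, "all")) {
    use <- seq_len(n_snp(panel))
  } else use <- snps
  if (length(use) == 0L) stop("no SNPs selected for the GRM")
  M <- panel$dosage[, use, drop = FALSE]
  storage.mode(M) <- "double"
  p <- colMeans(M, na.rm = TRUE) / 2
  ok <- is.finite(p)
  M <- M[, ok, drop = FALSE]
  p <- p[ok]
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all selected SNPs are monomorphic; GRM denominator is zero")
  Z <- sweep(M, 2L, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation: dosage 2p => centred value 0
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(panel$ids, panel$ids)
  G
}
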