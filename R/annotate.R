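#' Read annotation features from a BED-like file
#'
#' BED input is treated as 0-based half-open (the BED standard).
#' GFF-style 1-based inclusive coordinates are converted with
#' `one_based = TRUE` (start is shifted down by 1). Malformed
#' intervals are rejected with their line numbers.
#'
#' @param path BED file (3+ columns: chrom, start, end, optional name).
#' @param one_based set for files with 1-based inclusive coordinates.
#' @param source tag attached to every feature (`"gene"`, `"qtl"`,
#'   `"other"`, ...).
#' @return data.frame `chrom`, `start`, `end`, `name`, `source`.
#' @export
read_features_bed <- function(path, one_based = FALSE, source = "other") {
  if (!file.exists(path)) stop("feature file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = paste0("V", 1:12), fill = TRUE)[, 1:4]
  out <- data.frame(chrom = as.character(raw$V1),
                    start = suppressWarnings(as.numeric(raw$V2)),
                    end = suppressWarnings(as.numeric(raw$V3)),
                    name = if (all(is.na(raw$V4)) || all(raw$V4 == ""))
                      paste0("feature", seq_len(nrow(raw))) else
                        as.character(raw$V4),
                    stringsAsFactors = FALSE)
  if (one_based) out$start <- out$start - 1
  bad <- which(is.na(out$start) | is.na(out$end) | out$start >= out$end |
                 out$start < 0)
  if (length(bad))
    stop("malformed intervals in ", path, " at line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  out$source <- source
  out[order(out$chrom, out$start), ]
}

#' Intersect candidate loci with annotation features
#'
#' Sweep-line intersection of two interval sets (both 0-based
#' half-open): every (locus, feature) pair with positive overlap is
#' reported with its overlap length in bp. Intervals that merely share
#' an endpoint do not overlap. Inputs are sorted internally, so the
#' result is invariant to input order.
#'
#' @param loci data.frame `chrom`, `start`, `end` (e.g.
#'   `map_loci(...)$loci`).
#' @param features data.frame from [read_features_bed()].
#' @return data.frame: `chrom`, `locus_start`, `locus_end`,
#'   `feature_name`, `feature_source`, `feature_start`, `feature_end`,
#'   `overlap_bp`.
#' @export
intersect_loci <- function(loci, features) {
  empty <- data.frame(chrom = character(0), locus_start = numeric(0),
                      locus_end = numeric(0), feature_name = character(0),
                      feature_source = character(0),
                      feature_start = numeric(0), feature_end = numeric(0),
                      overlap_bp = numeric(0))
  if (nrow(loci) == 0 || nrow(features) == 0) return(empty)
  rows <- list()
  for (ch in intersect(unique(loci$chrom), unique(features$chrom))) {
    L <- loci[loci$chrom == ch, , drop = FALSE]
    L <- L[order(L$start), , drop = FALSE]
    FF <- features[features$chrom == ch, , drop = FALSE]
    FF <- FF[order(FF$start), , drop = FALSE]
    ptr <- 1L
    for (i in seq_len(nrow(L))) {
      while (ptr <= nrow(FF) && FF$end[ptr] <= L$start[i]) ptr <- ptr + 1L
      j <- ptr
      while (j <= nrow(FF) && FF$start[j] < L$end[i]) {
        ov <- min(L$end[i], FF$end[j]) - max(L$start[i], FF$start[j])
        if (ov > 0)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ch, locus_start = L$start[i], locus_end = L$end[i],
            feature_name = FF$name[j], feature_source = FF$source[j],
            feature_start = FF$start[j], feature_end = FF$end[j],
            overlap_bp = ov)
        j <- j + 1L
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize locus/feature overlaps
#'
#' Distinct-feature counts per source tag, overall and per locus. A
#' feature overlapping several loci counts once in the overall total.
#'
#' @param pairs output of [intersect_loci()].
#' @return list with `total` (data.frame `source`, `n_features`) and
#'   `per_locus` (data.frame `chrom`, `locus_start`, `locus_end`,
#'   `source`, `n_features`).
#' @export
summarize_overlaps <- function(pairs) {
  if (nrow(pairs) == 0)
    return(list(total = data.frame(source = character(0),
                                   n_features = integer(0)),
                per_locus = data.frame(chrom = character(0),
                                       locus_start = numeric(0),
                                       locus_end = numeric(0),
                                       source = character(0),
                                       n_features = integer(0))))
  tot <- stats::aggregate(feature_name ~ feature_source, data = pairs,
                          FUN = function(x) length(unique(x)))
  names(tot) <- c("source", "n_features")
  per <- stats::aggregate(
    feature_name ~ chrom + locus_start + locus_end + feature_source,
    data = pairs, FUN = function(x) length(unique(x)))
  names(per) <- c("chrom", "locus_start", "locus_end", "source", "n_features")
  list(total = tot, per_locus = per[order(per$chrom, per$locus_start), ])
}
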