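#' Configuration for the synthetic half-sib population generator
#'
#' The defaults emulate a progeny-test genotyping study: several hundred
#' bulls organised in paternal half-sib families, genotyped on a dense
#' SNP panel, with a polygenic trait carrying a handful of medium-effect
#' QTL, and breeding values whose accuracies span the range typical of
#' widely used AI sires.
#'
#' @param n_individuals number of genotyped individuals (default 861).
#' @param n_families number of paternal half-sib families; individuals
#'   are distributed as evenly as possible, the remainder going to the
#'   first families (deterministic).
#' @param n_snps number of autosomal SNPs.
#' @param n_chromosomes number of autosomes.
#' @param chromosome_length autosome length in base pairs.
#' @param n_qtl number of QTL; each is a member SNP of the panel.
#' @param qtl_variance_fraction fraction of phenotypic variance explained
#'   by each QTL. `n_qtl * qtl_variance_fraction` must be below
#'   `heritability` (the remainder is polygenic).
#' @param heritability narrow-sense heritability of the trait in \[0, 1\].
#' @param reliability_range interval in (0, 1\] from which per-animal EBV
#'   reliabilities are drawn uniformly. The default (0.26, 0.96)
#'   corresponds to accuracies of roughly 0.51--0.98.
#' @param missing_rate fraction of genotype calls set missing at random.
#' @param bad_quality_rate fraction of SNPs assigned a quality score
#'   below the usual 0.7 acceptance threshold (drawn U(0, 0.7); the rest
#'   draw U(0.7, 1)).
#' @param n_x_snps,n_y_snps number of X- and Y-flagged SNPs appended to
#'   the panel. Males are hemizygous, so true sex-linked dosages are
#'   homozygous (0/2); `sex_het_error_rate` of them are corrupted to
#'   heterozygous calls, emulating probes that cannot be placed relative
#'   to the pseudo-autosomal region. Y SNPs are monomorphic apart from
#'   these errors.
#' @param n_mt_snps,n_unmapped_snps mitochondrial and unmapped markers
#'   appended to the panel (removed by QC).
#' @param sex_het_error_rate per-genotype probability of a heterozygous
#'   error on X/Y SNPs.
#' @param hide_qtl if `TRUE`, the causal SNPs are removed from the
#'   genotype panel (they remain in the truth record), so mapping must
#'   rely on linked markers.
#' @param seed integer seed; one global seed drives a hierarchical
#'   per-stage stream so stages are individually reproducible.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_individuals = 861, n_families = 43,
                       n_snps = 20000, n_chromosomes = 10,
                       chromosome_length = 5e7,
                       n_qtl = 3, qtl_variance_fraction = 0.05,
                       heritability = 0.4,
                       reliability_range = c(0.26, 0.96),
                       missing_rate = 0.005, bad_quality_rate = 0.1,
                       n_x_snps = 100, n_y_snps = 20,
                       n_mt_snps = 10, n_unmapped_snps = 10,
                       sex_het_error_rate = 0.05,
                       hide_qtl = FALSE, seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_families = as.integer(n_families),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.numeric(chromosome_length),
              n_qtl = as.integer(n_qtl),
              qtl_variance_fraction = qtl_variance_fraction,
              heritability = heritability,
              reliability_range = as.numeric(reliability_range),
              missing_rate = missing_rate,
              bad_quality_rate = bad_quality_rate,
              n_x_snps = as.integer(n_x_snps),
              n_y_snps = as.integer(n_y_snps),
              n_mt_snps = as.integer(n_mt_snps),
              n_unmapped_snps = as.integer(n_unmapped_snps),
              sex_het_error_rate = sex_het_error_rate,
              hide_qtl = isTRUE(hide_qtl), seed = as.integer(seed))
  if (cfg$n_individuals < 1L) stop("n_individuals must be positive")
  if (cfg$n_families < 1L || cfg$n_families > cfg$n_individuals)
    stop("n_families must be in [1, n_individuals]")
  if (cfg$heritability < 0 || cfg$heritability > 1)
    stop("heritability must lie in [0, 1]")
  if (cfg$n_qtl > 0 && cfg$n_qtl * cfg$qtl_variance_fraction >= cfg$heritability)
    stop("impossible variance budget: n_qtl * qtl_variance_fraction must be ",
         "strictly below heritability")
  if (length(cfg$reliability_range) != 2L ||
      cfg$reliability_range[1] <= 0 || cfg$reliability_range[2] > 1 ||
      diff(cfg$reliability_range) < 0)
    stop("reliability_range must be an interval within (0, 1]")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (cfg$bad_quality_rate < 0 || cfg$bad_quality_rate > 1)
    stop("bad_quality_rate must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# Hierarchical seed stream: every stage draws its own seed from a stream
# keyed by the global seed, so a stage re-run in isolation reproduces.
stage_seeds <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  stages <- c("map", "founders", "genotypes", "trait", "ebv",
              "quality", "missing", "sex", "mt")
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

# U-shaped founder frequency spectrum, folded into MAF >= floor.
draw_founder_freqs <- function(m, maf_floor = 0.02) {
  p <- stats::rbeta(m, 0.5, 0.5)
  pmin(pmax(p, maf_floor), 1 - maf_floor)
}

# Even family sizes; remainder assigned to the first families.
family_sizes <- function(n, f) {
  sz <- rep(n %/% f, f)
  r <- n %% f
  if (r > 0) sz[seq_len(r)] <- sz[seq_len(r)] + 1L
  sz
}

#' Simulate a paternal half-sib population with EBVs
#'
#' Generates founder allele frequencies from a U-shaped spectrum folded
#' into \[0.02, 0.98\], draws sire genotypes at those frequencies and
#' offspring genotypes by Mendelian transmission (each offspring's dam is
#' an unobserved founder), builds a phenotype as QTL effects plus a
#' genomic polygenic term (small additive effects on every non-QTL
#' SNP, so the marker-derived relationship matrix is the exact
#' covariance of the polygenic values) plus environmental noise, and
#' emits EBVs as BLUP-style shrunken predictions
#' `EBV = r2 * TBV + e` with `var(e) = r2 (1 - r2) var(TBV)`, so that
#' the squared correlation with the true breeding value equals the
#' drawn reliability `r2`. Per-SNP quality scores, random missingness and
#' heterozygous-error-carrying X/Y markers are layered on top.
#'
#' With `heritability = 0` the true breeding values are identically
#' zero and a shrinkage-based evaluation would return all-zero EBVs; in
#' that degenerate case the generator emits pure prediction-error noise
#' (unit scale) as EBVs so downstream fits remain well defined.
#'
#' @param config a [sim_config()].
#' @return list with elements `panel` (a [genotype_panel()]), `ebv`
#'   (data.frame `id`, `ebv`, `reliability`) and `truth` (list: `qtl`
#'   data.frame, `tbv`, `phenotype`, `true_h2`, `family`, `sire_dosage`
#'   matrix over the autosomal map, `founder_freq`).
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  sds <- stage_seeds(config$seed)
  n <- config$n_individuals
  f <- config$n_families
  m <- config$n_snps
  h2 <- config$heritability

  # marker map
  set.seed(sds[["map"]])
  per_chr <- family_sizes(m, config$n_chromosomes)  # same even split logic
  chrom <- rep(as.character(seq_len(config$n_chromosomes)), per_chr)
  pos <- unlist(lapply(per_chr, function(k)
    sort(sample.int(config$chromosome_length, k))), use.names = FALSE)

  set.seed(sds[["founders"]])
  p <- draw_founder_freqs(m)

  # sires and half-sib offspring
  set.seed(sds[["genotypes"]])
  fam <- rep(seq_len(f), family_sizes(n, f))
  sire <- matrix(stats::rbinom(f * m, 2L, rep(p, each = f)), f, m)
  transmitted <- sire[fam, , drop = FALSE]
  het <- transmitted == 1L
  transmitted[transmitted == 2L] <- 1L
  transmitted[het] <- stats::rbinom(sum(het), 1L, 0.5)
  dam_allele <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
  dos <- transmitted + dam_allele
  storage.mode(dos) <- "integer"

  # trait
  set.seed(sds[["trait"]])
  fq <- config$qtl_variance_fraction
  qtl <- data.frame(snp = character(0), chrom = character(0),
                    pos = numeric(0), effect = numeric(0), freq = numeric(0))
  g_qtl <- numeric(n)
  if (config$n_qtl > 0) {
    maf <- pmin(p, 1 - p)
    eligible <- which(maf >= 0.1)
    if (length(eligible) < config$n_qtl)
      stop("too few common SNPs to place the requested QTL")
    idx <- sort(sample(eligible, config$n_qtl))
    a <- sqrt(fq / (2 * p[idx] * (1 - p[idx]))) *
      sample(c(-1, 1), config$n_qtl, replace = TRUE)
    g_qtl <- drop(dos[, idx, drop = FALSE] %*% a) - sum(2 * p[idx] * a)
    qtl <- data.frame(snp = paste0("snp", idx), chrom = chrom[idx],
                      pos = pos[idx], effect = a, freq = p[idx])
  } else idx <- integer(0)
  # polygenic background: small additive effects on every non-QTL SNP, so
  # the SNP-derived GRM is the exact covariance of the polygenic values
  s2_poly <- h2 - config$n_qtl * fq
  u <- numeric(n)
  if (s2_poly > 0) {
    bg <- setdiff(seq_len(m), idx)
    beta <- stats::rnorm(length(bg), 0,
                         sqrt(s2_poly / (2 * sum(p[bg] * (1 - p[bg])))))
    u <- drop(dos[, bg, drop = FALSE] %*% beta) - sum(2 * p[bg] * beta)
  }
  tbv <- g_qtl + u
  env <- stats::rnorm(n, 0, sqrt(1 - h2))
  phen <- tbv + env

  # EBVs with target reliabilities
  set.seed(sds[["ebv"]])
  r2 <- stats::runif(n, config$reliability_range[1], config$reliability_range[2])
  s2_tbv <- stats::var(tbv)
  if (h2 > 0 && s2_tbv > 0) {
    # BLUP-style shrinkage: EBV = r2 * TBV + e, var(e) = r2 (1 - r2) s2_tbv,
    # so that cor(EBV, TBV)^2 = r2 and dEBV = EBV / r2 = TBV + e' with
    # var(e') = (1 - r2) / r2 * s2_tbv -- the residual variance the
    # deregression weights encode.
    ebv <- r2 * tbv + stats::rnorm(n, 0, sqrt(r2 * (1 - r2) * s2_tbv))
  } else {
    ebv <- stats::rnorm(n)  # pure prediction-error noise, see Details
  }

  # sex-linked / MT / unmapped tails
  set.seed(sds[["sex"]])
  sex_extra <- function(k, label, mono) {
    if (k == 0L) return(NULL)
    pe <- if (mono) rep(0, k) else draw_founder_freqs(k)
    d <- matrix(2L * stats::rbinom(n * k, 1L, rep(pe, each = n)), n, k)
    err <- matrix(stats::runif(n * k) < config$sex_het_error_rate, n, k)
    d[err] <- 1L
    list(d = d, chrom = rep(label, k),
         pos = sort(sample.int(config$chromosome_length, k)), p = pe)
  }
  xs <- sex_extra(config$n_x_snps, "X", mono = FALSE)
  ys <- sex_extra(config$n_y_snps, "Y", mono = TRUE)
  set.seed(sds[["mt"]])
  plain_extra <- function(k, label, maxpos) {
    if (k == 0L) return(NULL)
    pe <- draw_founder_freqs(k)
    d <- matrix(stats::rbinom(n * k, 2L, rep(pe, each = n)), n, k)
    list(d = d, chrom = rep(label, k),
         pos = sort(sample.int(maxpos, k)), p = pe)
  }
  mts <- plain_extra(config$n_mt_snps, "MT", 16000L)
  uns <- plain_extra(config$n_unmapped_snps, "0", 1000L)
  extras <- Filter(Negate(is.null), list(xs, ys, mts, uns))

  dosage <- do.call(cbind, c(list(dos), lapply(extras, `[[`, "d")))
  storage.mode(dosage) <- "integer"
  chrom_all <- c(chrom, unlist(lapply(extras, `[[`, "chrom")))
  pos_all <- c(pos, unlist(lapply(extras, `[[`, "pos")))
  m_all <- length(chrom_all)

  # quality scores
  set.seed(sds[["quality"]])
  qual <- stats::runif(m_all, 0.7, 1)
  nbad <- round(config$bad_quality_rate * m_all)
  if (nbad > 0) {
    bad <- sample.int(m_all, nbad)
    qual[bad] <- stats::runif(nbad, 0, 0.7)
  }

  # missingness
  set.seed(sds[["missing"]])
  if (config$missing_rate > 0) {
    miss <- which(stats::runif(length(dosage)) < config$missing_rate)
    dosage[miss] <- NA_integer_
  }

  map <- data.frame(snp = paste0("snp", seq_len(m_all)),
                    chrom = chrom_all, pos = pos_all,
                    a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  ids <- sprintf("bull%04d", seq_len(n))
  keep <- seq_len(m_all)
  if (config$hide_qtl && length(idx)) keep <- setdiff(keep, idx)
  panel <- genotype_panel(dosage[, keep, drop = FALSE],
                          map[keep, , drop = FALSE],
                          quality = qual[keep], ids = ids,
                          sex = rep(1L, n))
  ebv_tab <- data.frame(id = ids, ebv = ebv, reliability = r2,
                        stringsAsFactors = FALSE)
  colnames(sire) <- paste0("snp", seq_len(m))
  truth <- list(qtl = qtl, tbv = tbv, phenotype = phen, true_h2 = h2,
                family = fam, sire_dosage = sire, founder_freq = p,
                config = config)
  list(panel = panel, ebv = ebv_tab, truth = truth)
}
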