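#' Configuration for a full pipeline run
#'
#' Collects every stage's thresholds (defaulting to the standard
#' progeny-test values), the window-mapping geometry, the trait
#' heritability used for deregression, simulation settings and optional
#' input/feature paths. Unknown keys are rejected.
#'
#' @param sim a [sim_config()] used when no `plink_prefix` is given.
#' @param plink_prefix optional PLINK fileset prefix to analyse instead
#'   of simulating (its `.ebv.tsv` side-car supplies the EBVs).
#' @param features_bed optional named character vector of BED paths to
#'   intersect with the mapped loci; names are used as source tags.
#' @param qc a [qc_thresholds()].
#' @param h2 heritability used for deregression weights; `NULL` uses
#'   the simulation's value (required for file input).
#' @param c_genomic fraction of genetic variance not captured by
#'   markers, for the deregression weight.
#' @param window_size,window_step,min_snps,fence_multiplier window
#'   mapping parameters, see [map_loci()].
#' @param sigma2_y,test passed to [snp_scan()].
#' @param seed integer seed for the simulation stage.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(sim = sim_config(), plink_prefix = NULL,
                       features_bed = NULL, qc = qc_thresholds(),
                       h2 = NULL, c_genomic = 0,
                       window_size = 1e6, window_step = 5e4, min_snps = 10,
                       fence_multiplier = 1.5,
                       sigma2_y = "empirical", test = "wald", seed = NULL) {
  cfg <- list(sim = sim, plink_prefix = plink_prefix,
              features_bed = features_bed, qc = qc, h2 = h2,
              c_genomic = c_genomic, window_size = window_size,
              window_step = window_step, min_snps = min_snps,
              fence_multiplier = fence_multiplier, sigma2_y = sigma2_y,
              test = test, seed = seed)
  if (!inherits(cfg$sim, "sim_config")) stop("`sim` must be a sim_config()")
  if (!inherits(cfg$qc, "qc_thresholds"))
    stop("`qc` must be a qc_thresholds()")
  if (!is.null(cfg$seed)) cfg$sim$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

# small stable FNV-1a hash of a config's JSON form, for the manifest
config_hash <- function(config) {
  s <- jsonlite::toJSON(strip_classes(config),
                        auto_unbox = TRUE, digits = NA, null = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full mapping pipeline
#'
#' Executes simulate (or load) -> QC -> deregression -> GRM -> REML
#' animal model -> GLS genome scan -> windowed locus mapping ->
#' optional feature annotation, writing every artifact into `dir`:
#' `qc_report.tsv`, `pseudo_phenotypes.tsv`, `scan.tsv`,
#' `map_windows.bed/.tsv`, `map_loci.bed/.tsv`, `summary.json`,
#' `overlaps.tsv` (when features are given) and `manifest.json`
#' (config, config hash, seed, package version). Re-running with the
#' same configuration reproduces the artifacts.
#'
#' @param config a [run_config()].
#' @param dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with all stage results (`panel`, `ebv`,
#'   `qc`, `pseudo`, `grm`, `model`, `scan`, `map`, `overlaps`,
#'   `paths`).
#' @export
run_pipeline <- function(config = run_config(), dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[winqtl] ", ...)

  if (is.null(config$plink_prefix)) {
    say("simulating population (seed ", config$sim$seed, ")")
    pop <- simulate_population(config$sim)
    panel <- pop$panel; ebv <- pop$ebv
    h2 <- if (is.null(config$h2)) config$sim$heritability else config$h2
    truth <- pop$truth
  } else {
    say("reading PLINK fileset ", config$plink_prefix)
    if (!file.exists(paste0(config$plink_prefix, ".bed")))
      stop("input not found: ", config$plink_prefix,
           ".bed (check plink_prefix)")
    inp <- read_panel(config$plink_prefix)
    panel <- inp$panel; ebv <- inp$ebv
    if (is.null(ebv)) stop("no .ebv.tsv side-car next to ",
                           config$plink_prefix)
    if (is.null(config$h2))
      stop("h2 must be given in run_config() for file input")
    h2 <- config$h2
    truth <- NULL
  }

  say("QC")
  qc <- run_qc(panel, ebv, thresholds = config$qc)
  write_qc_report(qc$report, file.path(dir, "qc_report.tsv"))

  say("deregression (h2 = ", h2, ")")
  pseudo <- deregress(qc$ebv, h2 = h2, c = config$c_genomic)
  utils::write.table(pseudo, file.path(dir, "pseudo_phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("GRM + REML animal model")
  G <- compute_grm(qc$panel)
  model <- fit_animal_model(pseudo$debv, G, weights = pseudo$weight,
                            ids = pseudo$id)

  say("genome scan (", n_snp(qc$panel), " SNPs)")
  scan <- snp_scan(qc$panel, pseudo, model, sigma2_y = config$sigma2_y,
                   test = config$test)
  write_scan(scan, file.path(dir, "scan.tsv"))

  say("window mapping")
  map <- map_loci(scan, size = config$window_size, step = config$window_step,
                  min_snps = config$min_snps,
                  fence_multiplier = config$fence_multiplier)
  write_locus_map(map, file.path(dir, "map"))

  overlaps <- NULL
  if (!is.null(config$features_bed)) {
    say("annotation overlap")
    feats <- do.call(rbind, lapply(seq_along(config$features_bed), function(i) {
      tag <- names(config$features_bed)[i]
      if (is.null(tag) || tag == "") tag <- "other"
      read_features_bed(config$features_bed[[i]], source = tag)
    }))
    pairs <- intersect_loci(map$loci, feats)
    utils::write.table(pairs, file.path(dir, "overlaps.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    overlaps <- list(pairs = pairs, summary = summarize_overlaps(pairs))
  }

  summary <- list(
    n_individuals = n_ind(qc$panel), n_snps = n_snp(qc$panel),
    h2_deregression = h2,
    h2_reml = model$h2, sigma2_a = model$sigma2_a, sigma2_e = model$sigma2_e,
    threshold = map$summary$threshold,
    n_windows_total = map$summary$n_windows_total,
    n_windows_outlier = map$summary$n_windows_outlier,
    snr_ratio = map$summary$snr_ratio,
    n_loci = nrow(map$loci))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(package = "winqtl",
                   version = as.character(utils::packageVersion("winqtl")),
                   seed = config$sim$seed,
                   config_hash = config_hash(config),
                   config = strip_classes(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done: ", dir)
  invisible(list(panel = panel, ebv = ebv, qc = qc, pseudo = pseudo, grm = G,
                 model = model, scan = scan, map = map, overlaps = overlaps,
                 truth = truth, dir = dir))
}
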