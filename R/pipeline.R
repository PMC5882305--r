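#' Pipeline configuration
#'
#' Flat configuration holding every tunable constant of the analysis:
#' probe/replicate thresholds, window and bin sizes, generator settings,
#' method switches and the seed.  Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    factors = c("PRC", "ERR1", "NRF1", "GABP", "CREB", "YY1"),
    profile = c(PRC = "downstream", ERR1 = "downstream", NRF1 = "proximal",
                GABP = "proximal", CREB = "proximal", YY1 = "proximal"),
    n_genes = 17000L, n_mirna = 0L,
    window_bp = 8000L, probe_spacing_bp = 600L,
    bound_fraction = 0.05, effect = 6, kernel_width_bp = 1000,
    base_mean = 10, base_sd = 1.5, noise = "gaussian",
    n_replicates = 2L,
    n_bins = 20L, pvalue_method = "empirical",
    product_threshold = 1e-3, rep_threshold = 1e-2,
    literal_thresholds = FALSE, strict = FALSE, gm_threshold = 1e-3,
    profile_bin_bp = 250, profile_range = c(-4000, 4000),
    cluster_cap = 10,
    fc_threshold = 2, alpha = 0.05,
    fold_threshold = 3, neglog_threshold = 3, min_hits = 3L,
    background_multiple = 10,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over)
  num <- c("product_threshold", "rep_threshold", "gm_threshold",
           "fc_threshold", "alpha", "fold_threshold", "neglog_threshold",
           "effect", "kernel_width_bp")
  for (k in num) if (any(cfg[[k]] < 0)) stop(sprintf("%s must be positive", k))
  if (cfg$seed != as.integer(cfg$seed)) stop("seed must be an integer")
  structure(cfg, class = "pipeline_config")
}

#' Run the synthetic end-to-end ChIP-chip pipeline
#'
#' Simulates a promoter array with planted truth, then per factor:
#' normalization, reflected-null scale estimation, probe p-values,
#' replicate combination, gene calls; then TSS profiles and the
#' co-occupancy matrix.  All result tables are written as TSV under
#' `outdir` together with a JSON manifest listing the completed stages,
#' stage-level counts, the resolved configuration and its hash.
#'
#' @param config a `pipeline_config`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (annotation,
#'   truth, calls, profiles, occupancy, manifest).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()
  log_counts <- list()

  ann <- make_annotation(config$n_genes, config$n_mirna, config$window_bp,
                         config$probe_spacing_bp, seed = config$seed)
  truth <- make_truth(ann, config$factors, config$bound_fraction,
                      config$effect, profile = config$profile,
                      seed = config$seed + 1L)
  write_bed(ann, file.path(outdir, "annotation.bed"))
  write_tsv(truth, file.path(outdir, "truth.tsv"))
  stages <- c(stages, "simulate")
  log_counts$n_probes <- nrow(ann$probes)

  assignments <- assign_probes(ann, ann$probes)
  calls <- list()
  combined_all <- list()
  for (i in seq_along(config$factors)) {
    f <- config$factors[i]
    sim <- simulate_chip(ann, truth[truth$factor == f],
                         base_mean = config$base_mean,
                         base_sd = config$base_sd,
                         kernel_width_bp = config$kernel_width_bp,
                         n_replicates = config$n_replicates,
                         noise = config$noise,
                         seed = config$seed + 100L * i)
    pv <- lapply(sim$replicates, function(r) {
      pr <- normalize_pairs(r)
      mod <- estimate_null(pr, config$n_bins)
      probe_pvalues(pr, mod, config$pvalue_method)
    })
    comb <- combine_replicates(pv[[1]], pv[[2]],
                               product_threshold = config$product_threshold,
                               rep_threshold = config$rep_threshold,
                               literal = config$literal_thresholds)
    gc <- call_genes(assignments, comb, genes = ann$genes$gene_id,
                     strict = config$strict,
                     gm_threshold = config$gm_threshold)
    calls[[f]] <- gc
    combined_all[[f]] <- comb
    write_tsv(gc, file.path(outdir, sprintf("gene_calls_%s.tsv", f)))
    log_counts[[paste0("positive_", f)]] <- sum(gc$positive)
  }
  stages <- c(stages, "normalize", "estimate_null", "probe_pvalues",
              "combine_replicates", "call_genes")

  profiles <- lapply(config$factors, function(f)
    tss_profile(assignments, combined_all[[f]], config$profile_bin_bp,
                config$profile_range))
  names(profiles) <- config$factors
  prof_dt <- data.table::rbindlist(profiles, idcol = "factor")
  write_tsv(prof_dt, file.path(outdir, "tss_profiles.tsv"))
  stages <- c(stages, "tss_profile")

  om <- build_matrix(calls)
  write_tsv(data.table::data.table(gene_id = rownames(om$scores),
                                   om$scores),
            file.path(outdir, "occupancy_scores.tsv"))
  write_tsv(combination_sizes(om), file.path(outdir, "combination_sizes.tsv"))
  ov <- pairwise_overlap(om, universe_size = config$n_genes)
  write_tsv(ov, file.path(outdir, "pairwise_overlap.tsv"))
  stages <- c(stages, "cooccupancy")

  cfg_plain <- unclass(config)
  manifest <- list(stages = stages, counts = log_counts,
                   config = cfg_plain,
                   config_hash = config_hash(config),
                   seed = config$seed)
  write_json_report(manifest, file.path(outdir, "manifest.json"))

  invisible(list(annotation = ann, truth = truth, assignments = assignments,
                 calls = calls, combined = combined_all,
                 profiles = profiles, occupancy = om, overlap = ov,
                 manifest = manifest))
}

#' Hash of a resolved configuration
#'
#' @param config a `pipeline_config`.
#' @return md5 hex string of the serialized configuration.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Recovery of planted binding truth by the calling pipeline
#'
#' Compares one factor's gene calls with the generator truth and reports
#' sensitivity (recall of truly bound genes) and the empirical false
#' discovery rate among positive calls.
#'
#' @param gene_calls a [call_genes()] table.
#' @param truth truth rows for the same factor (gene_id of bound genes).
#' @return list(sensitivity, fdr, n_called, n_true).
#' @export
recovery_stats <- function(gene_calls, truth) {
  called <- gene_calls$gene_id[gene_calls$positive]
  bound <- unique(truth$gene_id)
  tp <- length(intersect(called, bound))
  list(sensitivity = if (length(bound)) tp / length(bound) else NA_real_,
       fdr = if (length(called)) (length(called) - tp) / length(called)
             else 0,
       n_called = length(called), n_true = length(bound))
}
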