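# Shared small fixtures, built in code.

# annotation with 9 probes/gene (offsets -4000..+4000 by 1000, includes 0)
small_annotation <- function(n_genes = 200, seed = 11) {
  make_annotation(n_genes, window_bp = 8000, probe_spacing_bp = 1000,
                  seed = seed)
}

# one-factor simulated experiment ready for calling
small_experiment <- function(n_genes = 1200, bound_fraction = 0.05,
                             effect = 6, seed = 21) {
  ann <- make_annotation(n_genes, window_bp = 8000, probe_spacing_bp = 600,
                         seed = seed)
  truth <- make_truth(ann, "F1", bound_fraction = bound_fraction,
                      effect = effect, seed = seed + 1)
  sim <- simulate_chip(ann, truth, n_replicates = 2, seed = seed + 2)
  list(ann = ann, truth = truth, sim = sim)
}

# run probe statistics on one replicate table
probe_stats_for <- function(rep_table, method = "empirical", n_bins = 20) {
  pr <- normalize_pairs(rep_table)
  m <- estimate_null(pr, n_bins)
  list(pairs = pr, model = m, pv = probe_pvalues(pr, m, method))
}

# minimal call_genes table from explicit positives
calls_from_sets <- function(universe, positive, gm = 1e-4) {
  data.table::data.table(
    gene_id = universe,
    best_probe_id = paste0(universe, "_p"),
    pVal1 = gm, pVal2 = gm, best_gm = gm,
    tss_distance = 0,
    positive = universe %in% positive,
    bh = gm)
}
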