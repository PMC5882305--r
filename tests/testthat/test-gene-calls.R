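test_that("probe-to-gene distances follow the strand convention", {
  genes <- data.table::data.table(
    gene_id = c("gp", "gm"), chrom = "chr1", tss = c(10000L, 50000L),
    strand = c("+", "-"))
  probes <- data.table::data.table(
    probe_id = c("a", "b", "edge", "out"),
    chrom = "chr1",
    pos = c(9500L, 49500L, 10000L + 4000L, 10000L + 4001L))
  asn <- assign_probes(genes, probes, window_bp = 8000)
  expect_equal(asn[probe_id == "a", tss_distance], -500)   # upstream on +
  expect_equal(asn[probe_id == "b", tss_distance], 500)    # strand flip
  expect_false("edge" %in% asn$probe_id)                   # half-open edge
  expect_false("out" %in% asn$probe_id)
})

test_that("probes on unknown chromosomes are skipped with a count", {
  genes <- data.table::data.table(gene_id = "g", chrom = "chr1",
                                  tss = 10000L, strand = "+")
  probes <- data.table::data.table(probe_id = c("p1", "p2"),
                                   chrom = c("chr1", "chrUn"),
                                   pos = c(10000L, 10000L))
  expect_warning(asn <- assign_probes(genes, probes, window_bp = 8000),
                 "skipped")
  expect_equal(attr(asn, "n_skipped"), 1L)
  expect_equal(asn$probe_id, "p1")
})

test_that("replicate conjunction rule matches a brute-force evaluator", {
  grid <- c(1e-6, 1e-5, 1e-4, 1e-3, 2e-3, 5e-3, 9e-3, 1e-2, 2e-2, 5e-2,
            0.1, 0.2, 0.5)
  g <- expand.grid(p1 = grid, p2 = grid)
  t1 <- data.table::data.table(probe_id = sprintf("p%03d", seq_len(nrow(g))),
                               p = g$p1)
  t2 <- data.table::data.table(probe_id = t1$probe_id, p = g$p2)
  comb <- combine_replicates(t1, t2)
  oracle <- mapply(function(a, b) (a * b < 1e-3) && (a < 1e-2) && (b < 1e-2),
                   g$p1, g$p2)
  expect_identical(comb[match(t1$probe_id, probe_id), pass],
                   unname(oracle))
  expect_equal(comb$gm^2, comb$pVal1 * comb$pVal2, tolerance = 1e-12)
})

test_that("rule examples and literal-reading flag", {
  mk <- function(p1, p2) list(
    data.table::data.table(probe_id = "p", p = p1),
    data.table::data.table(probe_id = "p", p = p2))
  r <- mk(1e-3, 1e-3)
  expect_true(combine_replicates(r[[1]], r[[2]])$pass)
  expect_equal(combine_replicates(r[[1]], r[[2]])$gm, 1e-3)
  r <- mk(0.5, 1e-6)           # product passes, single replicate fails
  expect_false(combine_replicates(r[[1]], r[[2]])$pass)
  r <- mk(0.009, 0.009)
  expect_true(combine_replicates(r[[1]], r[[2]])$pass)
  r <- mk(0.05, 0.05)          # fails strict constants, passes literal ones
  expect_false(combine_replicates(r[[1]], r[[2]])$pass)
  expect_true(combine_replicates(r[[1]], r[[2]], literal = TRUE)$pass)
})

test_that("mismatched replicate probe sets are rejected with a count", {
  t1 <- data.table::data.table(probe_id = c("a", "b"), p = 0.5)
  t2 <- data.table::data.table(probe_id = c("a", "c"), p = 0.5)
  expect_error(combine_replicates(t1, t2), "2 unmatched")
})

test_that("rule is monotone: smaller p-values never revoke a pass", {
  set.seed(5)
  p1 <- runif(200); p2 <- runif(200)
  t1 <- data.table::data.table(probe_id = sprintf("p%d", 1:200), p = p1)
  t2 <- data.table::data.table(probe_id = t1$probe_id, p = p2)
  before <- combine_replicates(t1, t2)
  t1b <- data.table::copy(t1)[, p := p * runif(200)]   # only decreases
  t2b <- data.table::copy(t2)[, p := p * runif(200)]
  after <- combine_replicates(t1b, t2b)
  m <- merge(before[, .(probe_id, pass)], after[, .(probe_id, pass)],
             by = "probe_id")
  expect_true(all(!m$pass.x | m$pass.y))
})

test_that("gene calls pick the best probe and honour tie rules", {
  asn <- data.table::data.table(probe_id = c("p1", "p2", "p3"),
                                gene_id = "g1",
                                tss_distance = c(-500, 200, 900))
  comb <- data.table::data.table(probe_id = c("p1", "p2", "p3"),
                                 pVal1 = c(0.5, 1e-4, 1e-4),
                                 pVal2 = c(0.5, 1e-4, 1e-4))
  comb[, gm := sqrt(pVal1 * pVal2)]
  comb[, pass := pVal1 * pVal2 < 1e-3 & pVal1 < 1e-2 & pVal2 < 1e-2]
  gc <- call_genes(asn, comb)
  expect_true(gc$positive)
  expect_equal(gc$best_gm, 1e-4)
  expect_equal(gc$best_probe_id, "p2")       # gm tie -> pVal1 tie -> lexicographic
  expect_equal(gc$tss_distance, 200)

  # gene whose only probe fails is negative; absent genes emitted negative
  asn2 <- data.table::data.table(probe_id = "q1", gene_id = "g2",
                                 tss_distance = 0)
  comb2 <- data.table::data.table(probe_id = "q1", pVal1 = 0.2, pVal2 = 0.3,
                                  gm = sqrt(0.06), pass = FALSE)
  gc2 <- call_genes(asn2, comb2, genes = c("g2", "g3"))
  expect_false(any(gc2$positive))
  expect_true(is.na(gc2[gene_id == "g3", best_gm]))
})

test_that("strict mode additionally requires best_gm <= 1e-3", {
  asn <- data.table::data.table(probe_id = "p1", gene_id = "g1",
                                tss_distance = 0)
  comb <- data.table::data.table(probe_id = "p1", pVal1 = 0.009,
                                 pVal2 = 0.009, gm = 0.009, pass = TRUE)
  expect_true(call_genes(asn, comb)$positive)
  expect_false(call_genes(asn, comb, strict = TRUE)$positive)
})

test_that("every positive gene has a probe passing both replicates", {
  ex <- small_experiment(n_genes = 600, seed = 51)
  st <- lapply(ex$sim$replicates, probe_stats_for)
  comb <- combine_replicates(st[[1]]$pv, st[[2]]$pv)
  asn <- assign_probes(ex$ann, ex$ann$probes)
  gc <- call_genes(asn, comb, genes = ex$ann$genes$gene_id)
  pos <- gc[positive == TRUE]
  expect_true(all(pos$pVal1 < 0.01 & pos$pVal2 < 0.01))
})

test_that("pure-null positive-gene count stays within the binomial bound", {
  # per-probe pass probability under the rule with uniform p-values is
  # rep_threshold^2 = 1e-4 (the product constraint is then vacuous)
  n_genes <- 4000; n_probes_per_gene <- 14
  n_runs <- 8
  counts <- integer(n_runs)
  for (i in seq_len(n_runs)) {
    ann <- make_annotation(n_genes, window_bp = 8000,
                           probe_spacing_bp = 600, seed = 400 + i)
    sim <- simulate_chip(ann, NULL, n_replicates = 2, seed = 500 + i)
    st <- lapply(sim$replicates, probe_stats_for)
    comb <- combine_replicates(st[[1]]$pv, st[[2]]$pv)
    asn <- assign_probes(ann, ann$probes)
    gc <- call_genes(asn, comb, genes = ann$genes$gene_id)
    counts[i] <- sum(gc$positive)
  }
  p_gene <- 1 - (1 - 1e-4)^n_probes_per_gene
  expected <- n_genes * p_gene
  sd_tot <- sqrt(n_runs * n_genes * p_gene * (1 - p_gene))
  expect_lt(abs(sum(counts) - n_runs * expected), 3 * sd_tot + 3)
})
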