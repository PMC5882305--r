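test_that("total gene signal is (sum of probes) x probe count", {
  expect_equal(total_gene_signal(c(10, 20, 30)), 180)
  expect_equal(total_gene_signal(5), 5)
  expect_equal(total_gene_signal(c(0, 0, 0, 0)), 0)
  expect_error(total_gene_signal(numeric()), "zero probes")
  probe_dt <- data.table::data.table(
    feature_id = rep(c("f1", "f2"), c(3, 1)),
    sample = "s1", signal = c(10, 20, 30, 7))
  m <- tgs_matrix(probe_dt)
  expect_equal(m["f1", "s1"], 180)
  expect_equal(m["f2", "s1"], 7)
})

test_that("QC regression on identical and exactly-linear samples", {
  set.seed(11)
  tgs <- exp(rnorm(200, 8))
  r <- qc_regression(tgs, tgs, background = 1)
  expect_equal(r$slope, 1, tolerance = 1e-9)
  expect_equal(r$rmsd, 0, tolerance = 1e-9)
  # quadratic in linear space is exactly linear in logs
  r2 <- qc_regression(tgs, tgs^2, background = 1e-4)
  expect_equal(r2$slope, 2, tolerance = 1e-9)
  expect_equal(r2$rmsd, 0, tolerance = 1e-9)
  expect_error(qc_regression(tgs[1:5], tgs[1:5], background = 1), "10")
})

test_that("QC regression recovers a planted residual sd", {
  set.seed(12)
  la <- rnorm(1000, 8, 1)
  lb <- la + rnorm(1000, 0, 0.3)
  r <- qc_regression(exp(la), exp(lb), background = 1e-6)
  expect_gt(r$rmsd, 0.27); expect_lt(r$rmsd, 0.33)
})

test_that("background filter keeps features above 10x background", {
  sig <- matrix(c(200, 200, 101, 200, 99, 200), 3, 2, byrow = TRUE,
                dimnames = list(c("hi", "edge", "lo"), c("s1", "s2")))
  expect_equal(unname(background_filter(sig, 10)), c(TRUE, TRUE, FALSE))
  expect_equal(unname(background_filter(sig, 10, all_samples = FALSE)),
               c(TRUE, TRUE, TRUE))
})

test_that("differential calling: trivial cases", {
  set.seed(13)
  e <- simulate_expression(100, de_fraction = 0, sd = 0.2, seed = 14)
  de <- differential(e$signal, e$groups, "ctrl", "kd")
  # equal group means: nothing passes the fold-change gate
  expect_lt(sum(de$is_de), 10)
  # degenerate thresholds flag everything
  de_all <- differential(e$signal, e$groups, "ctrl", "kd",
                         fc_threshold = 1, alpha = 1)
  expect_true(all(de_all$is_de))
  # zero variance with equal means gives p = 1
  sig <- matrix(4, 2, 6, dimnames = list(c("f1", "f2"),
                                         names(e$groups)[1:6]))
  d0 <- differential(sig, e$groups[1:6], "ctrl", "kd")
  expect_equal(d0$p, c(1, 1))
})

test_that("differential calling recovers a planted 4-fold change", {
  e <- simulate_expression(2000, n_reps_per_group = 3, de_fraction = 0.1,
                           lfc = 2, sd = 0.2, low_fraction = 0, seed = 15)
  de <- differential(e$signal, e$groups, "ctrl", "kd")
  m <- merge(de, e$truth, by = "feature_id")
  power <- m[is_de.y == TRUE, mean(is_de.x)]
  expect_gte(power, 0.95)
  # type-I rate among nulls at alpha, fold gate disabled
  de2 <- differential(e$signal, e$groups, "ctrl", "kd", fc_threshold = 1)
  m2 <- merge(de2, e$truth, by = "feature_id")
  t1 <- m2[is_de.y == FALSE, mean(p <= 0.05)]
  n0 <- m2[is_de.y == FALSE, .N]
  expect_lt(abs(t1 - 0.05), 3 * sqrt(0.05 * 0.95 / n0))
})

test_that("ChIP/expression integration percentages", {
  pos <- data.table::data.table(
    factor = rep(c("PRC", "ERR1"), each = 2),
    timepoint = rep(c("24h", "48h"), 2),
    gene_id = "ignore")
  pos <- pos[0]
  add <- function(f, tp, genes) data.table::data.table(
    factor = f, timepoint = tp, gene_id = genes)
  pos <- rbind(add("PRC", "24h", sprintf("g%02d", 1:10)),
               add("PRC", "48h", sprintf("g%02d", 6:10)))
  groups <- list(up24 = sprintf("g%02d", 1:10),
                 down24 = sprintf("g%02d", 90:99))
  rep_ <- integrate_chip_expression(groups, pos)
  expect_equal(rep_[group == "up24" & timepoint == "24h", percent], 100)
  expect_equal(rep_[group == "up24" & timepoint == "48h", percent], 50)
  expect_equal(rep_[group == "down24" & timepoint == "24h", percent], 0)
  expect_true(all(rep_$percent >= 0 & rep_$percent <= 100))
  # permutation invariance in gene order
  groups_p <- lapply(groups, rev)
  expect_equal(integrate_chip_expression(groups_p, pos)$percent,
               rep_$percent)
  expect_warning(integrate_chip_expression(list(empty = character()), pos),
                 "empty")
})

test_that("planted 30% overlap is recovered exactly", {
  grp <- sprintf("g%03d", 1:200)
  pos <- data.table::data.table(factor = "PRC", timepoint = "24h",
                                gene_id = c(grp[1:60], sprintf("o%03d", 1:40)))
  rep_ <- integrate_chip_expression(list(up = grp), pos)
  expect_equal(rep_$percent, 30)
})

test_that("miRNA intersection normalizes ids and partitions the union", {
  r <- intersect_mirna(c("hsa-miR-21", "MIR-15B"), c("mir-21", "hsa-miR-99a"))
  expect_equal(r$both, "mir-21")
  expect_equal(r$chip_only, "mir-15b")
  expect_equal(r$de_only, "mir-99a")
  expect_equal(intersect_mirna(c("m1", "m2"), character())$both, character())
  # planted 13 ChIP-positive promoters, 12 confirmed by expression
  chip <- sprintf("mir-%02d", 1:13)
  de <- c(sprintf("mir-%02d", 1:12), "mir-99")
  expect_length(intersect_mirna(chip, de)$both, 12)
})

test_that("pathway filter matches a brute-force re-filter and is monotone", {
  ex4 <- exp(-4)
  pmat <- matrix(0.5, 5, 4,
                 dimnames = list(sprintf("m%d", 1:5), sprintf("P%d", 1:4)))
  pmat[1:3, "P1"] <- ex4          # 3 hits -> kept
  pmat[1:2, "P2"] <- ex4          # 2 hits -> dropped
  pf <- pathway_filter(pmat)
  expect_equal(pf$kept, "P1")
  expect_equal(unname(pf$neglog["union", "P1"]), 4, tolerance = 1e-12)

  set.seed(16)
  rnd <- matrix(runif(12 * 101), 12, 101,
                dimnames = list(sprintf("m%02d", 1:12),
                                sprintf("P%03d", 1:101)))
  pf2 <- pathway_filter(rnd)
  brute <- colnames(rnd)[vapply(seq_len(ncol(rnd)), function(j) {
    sum(-log(rnd[, j]) > 3) >= 3
  }, TRUE)]
  expect_identical(pf2$kept, brute)
  # monotone: raising the threshold never adds a pathway
  for (thr in c(3.5, 4, 5)) {
    expect_true(all(pathway_filter(rnd, neglog_threshold = thr)$kept
                    %in% pf2$kept))
  }
  expect_error(pathway_filter(rnd * 2), "0, 1")
})
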