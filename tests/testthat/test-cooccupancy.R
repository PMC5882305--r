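test_that("occupancy matrix holds -log10(gm) for positive calls only", {
  calls <- list(
    F1 = calls_from_sets(c("a", "b"), positive = "a", gm = 1e-4),
    F2 = calls_from_sets(c("a", "b"), positive = "b", gm = 1e-5))
  om <- build_matrix(calls)
  expect_equal(rownames(om$scores), c("a", "b"))
  expect_equal(om$scores["a", "F1"], 4)
  expect_equal(om$scores["b", "F2"], 5)
  expect_equal(om$scores["a", "F2"], 0)
  expect_true(all(rowSums(om$positive) >= 1))

  # a gene positive everywhere gives a fully nonzero row
  allpos <- list(F1 = calls_from_sets("g", "g"), F2 = calls_from_sets("g", "g"))
  expect_true(all(build_matrix(allpos)$scores > 0))

  none <- list(F1 = calls_from_sets("g", character()))
  expect_error(build_matrix(none), "no gene is positive")
})

test_that("row clustering is deterministic and merges identical rows at 0", {
  calls <- list(
    F1 = calls_from_sets(letters[1:4], letters[1:2], gm = 1e-4),
    F2 = calls_from_sets(letters[1:4], letters[3:4], gm = 1e-4))
  om <- build_matrix(calls)
  cl <- cluster_rows(om)
  expect_setequal(cl$order, letters[1:4])
  # identical rows (a,b) and (c,d) merge at height 0
  h <- cl$hclust$height
  expect_equal(sort(h)[1:2], c(0, 0))
})

test_that("well-separated planted blocks stay contiguous in leaf order", {
  set.seed(6)
  block1 <- sprintf("a%02d", 1:10)   # positive for F1 only
  block2 <- sprintf("b%02d", 1:10)   # positive for F2 only
  calls <- list(
    F1 = calls_from_sets(c(block1, block2), block1, gm = 1e-6),
    F2 = calls_from_sets(c(block1, block2), block2, gm = 1e-6))
  om <- build_matrix(calls)
  cl <- cluster_rows(om)
  memb <- substr(cl$order, 1, 1)
  expect_equal(sum(memb[-1] != memb[-length(memb)]), 1)  # one block switch
  # permuting input rows leaves the dendrogram topology unchanged
  calls_p <- lapply(calls, function(dt) dt[sample(nrow(dt))])
  expect_equal(cluster_rows(build_matrix(calls_p))$order, cl$order)
})

test_that("single-row matrices cluster trivially", {
  calls <- list(F1 = calls_from_sets("g", "g"))
  cl <- cluster_rows(build_matrix(calls))
  expect_equal(cl$order, "g")
  expect_null(cl$hclust)
})

test_that("exact combination groups partition the positive universe", {
  set.seed(7)
  genes <- sprintf("g%03d", 1:60)
  calls <- list(
    F1 = calls_from_sets(genes, sample(genes, 30)),
    F2 = calls_from_sets(genes, sample(genes, 25)),
    F3 = calls_from_sets(genes, sample(genes, 10)))
  om <- build_matrix(calls)
  sizes <- combination_sizes(om)
  expect_equal(sum(sizes$n_genes), nrow(om$scores))
  # extract_groups(exact) sizes agree with the signature table
  for (k in seq_len(nrow(sizes))) {
    fset <- strsplit(sizes$combination[k], "+", fixed = TRUE)[[1]]
    expect_length(extract_groups(om, fset, exact = TRUE),
                  sizes$n_genes[k])
  }
})

test_that("extract_groups semantics and errors", {
  calls <- list(
    PRC = calls_from_sets(c("solo", "shared"), c("solo", "shared")),
    ERR1 = calls_from_sets(c("solo", "shared"), "shared"))
  om <- build_matrix(calls)
  expect_equal(extract_groups(om, "PRC", exact = TRUE), "solo")
  expect_setequal(extract_groups(om, "PRC", exact = FALSE),
                  c("solo", "shared"))
  expect_setequal(extract_groups(om, character(), exact = FALSE),
                  c("solo", "shared"))
  expect_error(extract_groups(om, "NOPE"), "unknown factor")
})

test_that("planted combination structure is recovered exactly", {
  only1 <- sprintf("x%02d", 1:12)
  both <- sprintf("y%02d", 1:7)
  only2 <- sprintf("z%02d", 1:5)
  u <- c(only1, both, only2)
  calls <- list(A = calls_from_sets(u, c(only1, both)),
                B = calls_from_sets(u, c(both, only2)))
  om <- build_matrix(calls)
  expect_length(extract_groups(om, "A"), 12)
  expect_length(extract_groups(om, c("A", "B")), 7)
  expect_length(extract_groups(om, "B"), 5)
})

test_that("pairwise overlap reproduces hand-computed phi and chi-square", {
  # contingency [[10,20],[20,10]] over a universe of 60 genes
  both <- sprintf("b%02d", 1:10)
  only1 <- sprintf("c%02d", 1:20)
  only2 <- sprintf("d%02d", 1:20)
  u <- c(both, only1, only2)
  calls <- list(A = calls_from_sets(u, c(both, only1)),
                B = calls_from_sets(u, c(both, only2)))
  om <- build_matrix(calls)
  ov <- pairwise_overlap(om, universe_size = 60)
  expect_equal(ov$a, 10); expect_equal(ov$d, 10)
  expect_equal(ov$phi, -1 / 3, tolerance = 1e-6)
  expect_equal(ov$chi2, 60 * (10 * 10 - 20 * 20)^2 / 30^4, tolerance = 1e-6)
  expect_equal(ov$chi2, 6.667, tolerance = 1e-3)
  expect_equal(ov$fisher_p,
               fisher.test(matrix(c(10, 20, 20, 10), 2))$p.value,
               tolerance = 1e-9)
  expect_error(pairwise_overlap(om, universe_size = 10), "universe")
})

test_that("phi equals the Pearson correlation of the call vectors", {
  set.seed(8)
  genes <- sprintf("g%03d", 1:80)
  calls <- list(A = calls_from_sets(genes, sample(genes, 35)),
                B = calls_from_sets(genes, sample(genes, 40)))
  om <- build_matrix(calls)
  ov <- pairwise_overlap(om, universe_size = 100)
  va <- genes %in% calls$A$gene_id[calls$A$positive]
  vb <- genes %in% calls$B$gene_id[calls$B$positive]
  # extend to the full 100-gene universe (20 genes negative for both)
  va <- c(va, rep(FALSE, 20)); vb <- c(vb, rep(FALSE, 20))
  expect_equal(ov$phi, cor(va, vb), tolerance = 1e-12)
})

test_that("identical call vectors give phi = 1; independent calls hover near 0", {
  genes <- sprintf("g%03d", 1:30)
  calls <- list(A = calls_from_sets(genes, genes[1:10]),
                B = calls_from_sets(genes, genes[1:10]))
  expect_equal(pairwise_overlap(build_matrix(calls), 30)$phi, 1)
  set.seed(9)
  phis <- replicate(40, {
    g <- sprintf("g%03d", 1:200)
    cl <- list(A = calls_from_sets(g, sample(g, 60)),
               B = calls_from_sets(g, sample(g, 60)))
    pairwise_overlap(build_matrix(cl), 200)$phi
  })
  expect_lt(abs(mean(phis)), 3 * sd(phis) / sqrt(length(phis)))
})

test_that("time-point comparison proportions behave and sum to one", {
  u <- sprintf("g%02d", 1:20)
  a <- calls_from_sets(u, u[1:10])
  expect_equal(compare_timepoints(a, a)[, .(only_a, both, only_b)],
               data.table::data.table(only_a = 0, both = 1, only_b = 0))
  b <- calls_from_sets(u, u[11:20])
  cmp <- compare_timepoints(a, b)
  expect_equal(unlist(cmp[, .(only_a, both, only_b)]),
               c(only_a = 0.5, both = 0, only_b = 0.5))
  expect_equal(cmp$only_a + cmp$both + cmp$only_b, 1, tolerance = 1e-12)
  none <- calls_from_sets(u, character())
  expect_warning(cmp0 <- compare_timepoints(none, none), "undefined")
  expect_true(is.na(cmp0$both))
})

test_that("planted persistence structure is recovered", {
  # 60 genes positive at both time points, 30 only early, 10 only late
  both <- sprintf("b%02d", 1:60)
  early <- sprintf("e%02d", 1:30)
  late <- sprintf("l%02d", 1:10)
  u <- c(both, early, late)
  cmp <- compare_timepoints(calls_from_sets(u, c(both, early)),
                            calls_from_sets(u, c(both, late)))
  expect_equal(cmp$only_a, 0.3, tolerance = 1e-12)
  expect_equal(cmp$both, 0.6, tolerance = 1e-12)
  expect_equal(cmp$only_b, 0.1, tolerance = 1e-12)
})
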