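test_that("signal-to-noise metric honors the sd floor", {
  expr <- matrix(c(2, 2, 1, 1), nrow = 1,
                 dimnames = list("G1", sprintf("S%d", 1:4)))
  rl <- rank_signal_to_noise(expr, c("A", "A", "B", "B"),
                             contrast = c("A", "B"))
  # sds are 0, floored at 0.2*|mean| = (0.4, 0.2): metric = 1/0.6
  expect_equal(rl$metric, 1 / 0.6, tolerance = 1e-12)
})

test_that("signal-to-noise is zero for identical groups, antisymmetric on swap", {
  set.seed(5)
  expr <- matrix(rnorm(40, 8), 10, 4,
                 dimnames = list(sprintf("G%02d", 1:10), sprintf("S%d", 1:4)))
  expr[, 3:4] <- expr[, 1:2]
  rl <- rank_signal_to_noise(expr, c("A", "A", "B", "B"), c("A", "B"))
  expect_true(all(rl$metric == 0))

  expr2 <- matrix(rnorm(40, 8), 10, 4,
                  dimnames = dimnames(expr))
  r1 <- rank_signal_to_noise(expr2, c("A", "A", "B", "B"), c("A", "B"))
  r2 <- rank_signal_to_noise(expr2, c("A", "A", "B", "B"), c("B", "A"))
  expect_equal(r1$metric[match(r2$gene, r1$gene)], -r2$metric,
               tolerance = 1e-12)
})

test_that("enrichment score matches brute force on small lists", {
  rl <- data.frame(gene = c("A", "B", "C"), metric = c(2, 1, -1),
                   stringsAsFactors = FALSE)
  # set = top gene, weight 0: ES = 1 at position 1
  es <- enrichment_score(rl, "A", weight = 0)
  expect_equal(es$es, 1, tolerance = 1e-12)
  expect_equal(es$leading_edge, "A")

  # random lists: package vs oracle, both weights
  set.seed(9)
  for (i in 1:20) {
    n <- 10
    metric <- sort(rnorm(n), decreasing = TRUE)
    genes <- sprintf("G%02d", 1:n)
    rl <- data.frame(gene = genes, metric = metric, stringsAsFactors = FALSE)
    hit <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(hit) || all(hit)) next
    for (w in c(0, 1)) {
      expect_equal(enrichment_score(rl, genes[hit], weight = w)$es,
                   oracle_es(metric, hit, w), tolerance = 1e-12)
    }
  }
})

test_that("whole-universe sets score zero; reversal negates unweighted ES", {
  rl <- data.frame(gene = c("A", "B", "C"), metric = c(3, 2, 1),
                   stringsAsFactors = FALSE)
  expect_equal(enrichment_score(rl, c("A", "B", "C"), weight = 0)$es, 0)

  set.seed(10)
  for (i in 1:10) {
    n <- 10
    genes <- sprintf("G%02d", 1:n)
    metric <- sort(rnorm(n), decreasing = TRUE)
    hit <- rep(FALSE, n); hit[sample(n, 4)] <- TRUE
    rl <- data.frame(gene = genes, metric = metric, stringsAsFactors = FALSE)
    rl_rev <- data.frame(gene = rev(genes), metric = rev(metric),
                         stringsAsFactors = FALSE)
    e1 <- enrichment_score(rl, genes[hit], weight = 0)$es
    e2 <- enrichment_score(rl_rev, genes[hit], weight = 0)$es
    expect_equal(e1, -e2, tolerance = 1e-12)
  }
})

test_that("|ES| <= 1 and ES ignores genes outside the universe", {
  set.seed(11)
  genes <- sprintf("G%02d", 1:20)
  rl <- data.frame(gene = genes, metric = sort(rnorm(20), decreasing = TRUE),
                   stringsAsFactors = FALSE)
  for (i in 1:10) {
    set_in <- sample(genes, 5)
    e1 <- enrichment_score(rl, set_in)$es
    e2 <- enrichment_score(rl, c(set_in, "NOT_IN_UNIVERSE"))$es
    expect_lte(abs(e1), 1)
    expect_equal(e1, e2)
  }
  expect_error(enrichment_score(rl, "NOT_IN_UNIVERSE"), "no members")
})

test_that("gsea is deterministic under a fixed seed and p is never zero", {
  co <- simulate_counts(sim_config(n_genes = 300, n_TL = 8, n_TNL = 8,
                                   n_PTB_NQ = 0, n_PTB_Q = 0, n_batches = 1,
                                   seed = 12))
  sets <- synthetic_gene_sets(co$gene_truth, n_random = 5, seed = 12)
  lab <- co$sample_truth$true_phenotype
  g1 <- gsea(co$counts, lab, sets, contrast = c("NQ", "Q"), nperm = 99,
             seed = 4)
  g2 <- gsea(co$counts, lab, sets, contrast = c("NQ", "Q"), nperm = 99,
             seed = 4)
  expect_identical(g1, g2)
  expect_true(all(g1$p > 0))
  expect_true(all(abs(g1$es) <= 1))
})

test_that("a coordinately planted set is detected as a positive control", {
  co <- simulate_counts(sim_config(n_genes = 500, n_TL = 8, n_TNL = 8,
                                   n_PTB_NQ = 0, n_PTB_Q = 0, n_batches = 1,
                                   seed = 13))
  tr <- co$gene_truth
  up <- tr$gene[tr$is_de & tr$true_lfc >= 1]
  sets <- structure(list(UP_SET = up[seq_len(min(30, length(up)))]),
                    class = c("gene_sets", "list"))
  g <- gsea(co$counts, co$sample_truth$true_phenotype, sets,
            contrast = c("NQ", "Q"), nperm = 999, size_min = 10, seed = 5)
  expect_lte(g$p[g$set == "UP_SET"], 0.01)
  expect_gt(g$es[g$set == "UP_SET"], 0)
})

test_that("size gates skip sets and nperm is validated", {
  co <- simulate_counts(sim_config(n_genes = 200, n_TL = 3, n_TNL = 3,
                                   n_PTB_NQ = 0, n_PTB_Q = 0, n_batches = 1,
                                   seed = 14))
  sets <- structure(list(TINY = co$gene_truth$gene[1:3],
                         OK = co$gene_truth$gene[1:30]),
                    class = c("gene_sets", "list"))
  expect_message(
    g <- suppressWarnings(gsea(co$counts, co$sample_truth$true_phenotype,
                               sets, contrast = c("NQ", "Q"), nperm = 19,
                               size_min = 15, seed = 1)),
    "skipping")
  expect_equal(g$set, "OK")
  expect_error(gsea(co$counts, co$sample_truth$true_phenotype, sets,
                    contrast = c("NQ", "Q"), nperm = 0), "nperm")
})

test_that("overlap coefficient follows its truth table", {
  expect_equal(overlap_coefficient(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlap_coefficient(c("a", "b"), c("b", "c")), 0.5)
  expect_equal(overlap_coefficient(c("a"), c("a", "b", "c", "d")), 1)
  expect_equal(overlap_coefficient(c("a", "b"), c("c", "d")), 0)
  # symmetry
  set.seed(15)
  for (i in 1:5) {
    a <- sample(letters, sample(3:10, 1))
    b <- sample(letters, sample(3:10, 1))
    expect_equal(overlap_coefficient(a, b), overlap_coefficient(b, a))
  }
  expect_error(overlap_coefficient(character(0), "a"), "non-empty")
})

test_that("enrichment edges apply the significance and overlap gates", {
  sets <- structure(list(S1 = c("A", "B", "C"), S2 = c("B", "C", "D"),
                         S3 = c("X", "Y", "Z")),
                    class = c("gene_sets", "list"))
  res <- data.frame(set = c("S1", "S2", "S3"),
                    size = 3, es = 0.9, nes = 2,
                    p = c(0.001, 0.002, 0.5),
                    fdr = c(0.01, 0.02, 0.9),
                    leading_edge = "", stringsAsFactors = FALSE)
  edges <- enrichment_edges(res, sets)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$overlap, 2 / 3)
  expect_setequal(c(edges$set_a, edges$set_b), c("S1", "S2"))
})
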