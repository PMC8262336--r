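train_fixture <- function(seed = 1, n_genes = 200) {
  cfg <- sim_config(n_genes = n_genes, n_TL = 5, n_TNL = 5, n_PTB_NQ = 3,
                    n_PTB_Q = 8, n_batches = 1, seed = seed)
  co <- simulate_counts(cfg)
  term <- co$sample_truth$group %in% c("TL", "TNL")
  list(co = co,
       train = subset_counts(co$counts,
                             samples = co$sample_truth$sample_id[term]),
       labels = co$sample_truth$true_phenotype[term],
       signature = co$gene_truth$gene[co$gene_truth$is_de])
}

test_that("training samples reproject onto their fit scores", {
  fx <- train_fixture()
  model <- fit_reference_pca(fx$train, fx$signature, fx$labels)
  proj <- project_pca(model, fx$train)
  expect_equal(unname(proj), unname(model$train_scores), tolerance = 1e-10)
})

test_that("2-gene PCA matches the closed-form 2x2 eigenproblem", {
  m <- matrix(c(10, 20, 40, 80, 160, 320,
                320, 160, 80, 40, 20, 10), nrow = 2, byrow = TRUE,
              dimnames = list(c("GUP", "GDN"), sprintf("S%d", 1:6)))
  cm <- count_matrix(m)
  model <- fit_reference_pca(cm, c("GUP", "GDN"),
                             labels = c("NQ", "NQ", "NQ", "Q", "Q", "Q"),
                             factors = rep(1, 6))
  x <- t(log2(m + 1))
  S <- cov(x)
  ev <- eigen(S)$values
  expect_equal(unname(model$explained_variance_ratio),
               ev / sum(ev), tolerance = 1e-10)
  expect_equal(sum(model$explained_variance_ratio), 1, tolerance = 1e-12)
  # loadings columns orthonormal
  expect_equal(crossprod(model$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("orientation puts the NQ centroid below Q; label flip negates PC1", {
  fx <- train_fixture(seed = 2)
  m1 <- fit_reference_pca(fx$train, fx$signature, fx$labels)
  expect_lt(m1$centroids["NQ"], m1$centroids["Q"])
  flipped <- ifelse(fx$labels == "NQ", "Q", "NQ")
  m2 <- fit_reference_pca(fx$train, fx$signature, flipped)
  expect_equal(m1$train_scores[, 1], -m2$train_scores[, 1], tolerance = 1e-10)
})

test_that("a sample at the training mean projects to the origin", {
  fx <- train_fixture(seed = 3)
  model <- fit_reference_pca(fx$train, fx$signature, fx$labels)
  expr <- matrix(model$center, ncol = 1,
                 dimnames = list(model$signature_genes, "MEANSAMPLE"))
  proj <- project_pca(model, expr)
  expect_equal(unname(proj[1, ]), rep(0, ncol(proj)), tolerance = 1e-10)
})

test_that("projection is affine in the expression", {
  fx <- train_fixture(seed = 4)
  model <- fit_reference_pca(fx$train, fx$signature, fx$labels)
  expr <- log_expression(fx$train)[model$signature_genes, 1:2]
  a <- 0.3
  mix <- matrix(a * expr[, 1] + (1 - a) * expr[, 2], ncol = 1,
                dimnames = list(rownames(expr), "MIX"))
  pm <- project_pca(model, mix)
  p12 <- project_pca(model, expr)
  expect_equal(unname(pm[1, ]), unname(a * p12[1, ] + (1 - a) * p12[2, ]),
               tolerance = 1e-10)
})

test_that("missing signature genes abort fitting and projection", {
  fx <- train_fixture(seed = 5)
  expect_error(fit_reference_pca(fx$train, c(fx$signature, "NOSUCHGENE"),
                                 fx$labels), "NOSUCHGENE")
  model <- fit_reference_pca(fx$train, fx$signature, fx$labels)
  small <- subset_counts(fx$train, genes = fx$train$genes[1:5])
  expect_error(project_pca(model, small), "absent")
})

test_that("phenotype calls use the midpoint rule with ties toward NQ", {
  model <- structure(list(centroids = c(Q = 4, NQ = -2)), class = "pca_model")
  mid <- 1
  expect_equal(unname(assign_phenotype(c(mid, mid + 1e-9, -2, 4), model)),
               c("NQ", "Q", "NQ", "Q"))
  # transitional band of total width 0.5 * inter-centroid distance
  calls <- assign_phenotype(c(mid - 1.4, mid, mid + 1.4, mid - 1.6), model,
                            transitional_band = 0.5)
  expect_equal(unname(calls), c("transitional", "transitional",
                                "transitional", "NQ"))
})

test_that("projected synthetic samples land near their planted centroid", {
  cfg <- sim_config(n_genes = 400, n_TL = 5, n_TNL = 5, n_PTB_NQ = 30,
                    n_PTB_Q = 30, n_batches = 1, seed = 6)
  co <- simulate_counts(cfg)
  st <- co$sample_truth
  term <- st$group %in% c("TL", "TNL")
  sig <- co$gene_truth$gene[co$gene_truth$is_de]
  model <- suppressWarnings(fit_reference_pca(
    subset_counts(co$counts, samples = st$sample_id[term]),
    sig, st$true_phenotype[term]))
  proj <- project_pca(model, co$counts)
  calls <- assign_phenotype(proj[, 1], model)
  acc <- mean(calls == st$true_phenotype)
  expect_gte(acc, 0.95)
})

test_that("Spearman correlation matches monotone and degenerate expectations", {
  sc <- data.frame(sample_id = sprintf("S%d", 1:6),
                   contraction = c(5, 4, 3, 2, 1, 0),
                   flat = 1)
  pc1 <- setNames(c(-3, -2.5, -1, 0, 2, 3), sc$sample_id)
  expect_warning(res <- correlate_clinical(pc1, sc), "constant")
  expect_equal(res$rho[res$variable == "contraction"], -1, tolerance = 1e-12)
  expect_true(is.na(res$rho[res$variable == "flat"]))
})

test_that("Spearman rho matches the brute-force midrank oracle with ties", {
  set.seed(13)
  for (i in 1:10) {
    n <- 8
    x <- rnorm(n)
    y <- sample(0:3, n, replace = TRUE)  # heavy ties
    sc <- data.frame(sample_id = sprintf("S%d", 1:n), v = y)
    res <- suppressWarnings(
      correlate_clinical(setNames(x, sc$sample_id), sc))
    expect_equal(res$rho, oracle_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("small-sample permutation p agrees with exhaustive enumeration", {
  set.seed(14)
  n <- 6
  x <- rnorm(n)
  y <- c(0, 1, 1, 2, 2, 2)
  sc <- data.frame(sample_id = sprintf("S%d", 1:n), v = y)
  res <- correlate_clinical(setNames(x, sc$sample_id), sc)
  # independent enumeration over all 6! permutations
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  rho_obs <- oracle_pearson(rx, ry)
  perms <- myoquiesce:::all_permutations(n)
  rhos <- apply(perms, 1, function(idx) oracle_pearson(rx, ry[idx]))
  p_exact <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  expect_equal(res$p, p_exact, tolerance = 1e-12)
  expect_equal(res$method, "exact permutation")
})

test_that("clinical correlation needs at least three pairs", {
  sc <- data.frame(sample_id = c("A", "B"), v = c(1, 2))
  expect_error(correlate_clinical(setNames(c(1, 2), c("A", "B")), sc),
               ">= 3")
})
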