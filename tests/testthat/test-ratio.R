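test_that("count ratio arithmetic and mode equivalence", {
  m <- matrix(c(500, 250, 100, 50, 7, 11), nrow = 3, byrow = TRUE,
              dimnames = list(c("ATP2B4", "ATP2A2", "OTHER"), c("S1", "S2")))
  cm <- count_matrix(m)
  raw <- ratio_from_counts(cm)
  expect_equal(raw$ratio, c(5, 5))
  norm <- ratio_from_counts(cm, mode = "normalized")
  expect_equal(raw$ratio, norm$ratio, tolerance = 1e-12)
})

test_that("zero denominators flag the sample, missing genes abort", {
  m <- matrix(c(500, 400, 100, 0, 5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("ATP2B4", "ATP2A2", "OTHER"), c("S1", "S2")))
  cm <- count_matrix(m)
  expect_warning(r <- ratio_from_counts(cm), "zero denominator")
  expect_true(is.na(r$ratio[2]))
  expect_equal(r$ratio[1], 5)
  expect_error(ratio_from_counts(cm, num = "NOSUCH"), "absent")
})

test_that("comparative-Ct identities hold", {
  mk_ct <- function(b4, a2) {
    data.frame(sample_id = "S1", assay = rep(c("ATP2B4", "ATP2A2"), each = 2),
               well = c(1, 2, 1, 2), ct = c(b4, b4, a2, a2))
  }
  expect_equal(ratio_from_ct(mk_ct(25, 25))$ratio, 1, tolerance = 1e-12)
  expect_equal(ratio_from_ct(mk_ct(26, 24))$ratio, 0.25, tolerance = 1e-12)
  # duplicate wells average on the Ct scale
  dup <- data.frame(sample_id = "S1",
                    assay = rep(c("ATP2B4", "ATP2A2"), each = 2),
                    well = c(1, 2, 1, 2), ct = c(24.8, 25.2, 25, 25))
  expect_equal(ratio_from_ct(dup)$ratio, 1, tolerance = 1e-12)
})

test_that("reference-normalized abundances use the mean reference Ct", {
  ct <- data.frame(sample_id = "S1",
                   assay = c("ATP2B4", "ATP2A2", "B2M", "RPL30"),
                   well = 1, ct = c(26, 24, 20, 22))
  r <- ratio_from_ct(ct)
  expect_equal(r$rel_num, 2^-(26 - 21), tolerance = 1e-12)
  expect_equal(r$rel_den, 2^-(24 - 21), tolerance = 1e-12)
  # ratio identical with or without references
  r2 <- ratio_from_ct(ct[1:2, ])
  expect_equal(r$ratio, r2$ratio, tolerance = 1e-12)
  expect_true(is.na(r2$rel_num))
})

test_that("perfect separation yields AUC 1 and a correct threshold", {
  ratios <- data.frame(sample_id = sprintf("S%d", 1:8),
                       ratio = c(1, 1.5, 2, 2.41, 5.5, 6, 7, 9))
  labels <- setNames(c(rep("NQ", 4), rep("Q", 4)), ratios$sample_id)
  roc <- ratio_roc(ratios, labels)
  expect_equal(roc$auc, 1)
  calls <- classify_ratio(ratios, roc$threshold)
  expect_equal(unname(calls), unname(labels[ratios$sample_id]))
})

test_that("AUC equals the brute-force pairwise concordance with ties", {
  set.seed(20)
  for (i in 1:50) {
    n <- sample(6:20, 1)
    r <- sample(seq(0.5, 8, by = 0.5), n, replace = TRUE)  # forces ties
    lab <- sample(c("Q", "NQ"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    ratios <- data.frame(sample_id = sprintf("S%d", 1:n), ratio = r)
    roc <- ratio_roc(ratios, setNames(lab, ratios$sample_id))
    expect_equal(roc$auc, oracle_auc(r[lab == "NQ"], r[lab == "Q"]),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant to strictly increasing transforms", {
  set.seed(21)
  n <- 20
  r <- rlnorm(n)
  lab <- setNames(sample(c("Q", "NQ"), n, replace = TRUE,
                         prob = c(0.6, 0.4)), sprintf("S%d", 1:n))
  ratios <- data.frame(sample_id = names(lab), ratio = r)
  ratios2 <- data.frame(sample_id = names(lab), ratio = log(r) + 100)
  expect_equal(ratio_roc(ratios, lab)$auc, ratio_roc(ratios2, lab)$auc,
               tolerance = 1e-12)
})

test_that("random labels give null AUC near one half", {
  set.seed(22)
  aucs <- replicate(200, {
    n <- 31
    r <- rlnorm(n, 1, 0.6)
    lab <- setNames(sample(rep(c("NQ", "Q"), c(9, 22))), sprintf("S%d", 1:n))
    ratio_roc(data.frame(sample_id = names(lab), ratio = r), lab)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("single-class inputs are rejected, missing ratios excluded", {
  ratios <- data.frame(sample_id = c("A", "B", "C"), ratio = c(1, 2, NA))
  expect_error(ratio_roc(ratios, setNames(c("Q", "Q", "Q"), ratios$sample_id)),
               "both classes")
  roc <- ratio_roc(ratios, setNames(c("NQ", "Q", "Q"), ratios$sample_id))
  expect_equal(roc$n_excluded, 1)
})

test_that("classification respects the inclusive threshold and band", {
  expect_equal(unname(classify_ratio(2.41, 2.41)), "NQ")
  expect_equal(unname(classify_ratio(2.42, 2.41)), "Q")
  # band arithmetic: 5.0 in (5.12*0.9, 5.12*1.1] = (4.608, 5.632]
  expect_equal(unname(classify_ratio(5.0, 5.12, transitional_band = 0.1)),
               "transitional")
  expect_equal(unname(classify_ratio(4.6, 5.12, transitional_band = 0.1)),
               "NQ")
  expect_equal(unname(classify_ratio(5.7, 5.12, transitional_band = 0.1)),
               "Q")
  # band = 0 recovers the binary partition
  r <- c(1, 2.41, 3, 9)
  expect_equal(unname(classify_ratio(r, 2.41)), c("NQ", "NQ", "Q", "Q"))
  expect_error(classify_ratio(1, 0), "tau")
})

test_that("correlated panel matches the brute-force Pearson oracle", {
  cm <- random_counts(100, 8, seed = 23)
  expr <- log_expression(cm)
  panel <- correlated_panel(cm, cm$genes[1], r_min = -1)
  a <- expr[cm$genes[1], ]
  for (i in sample(nrow(panel), 10)) {
    g <- panel$gene[i]
    expect_lt(abs(panel$r[i] - oracle_pearson(expr[g, ], a)), 1e-10)
  }
  # ordering: r descending
  expect_true(all(diff(panel$r) <= 1e-12))
})

test_that("panel includes exact linear transforms and excludes negations", {
  base <- matrix(rpois(6 * 50, 60) + 1, 6, 50,
                 dimnames = list(sprintf("G%d", 1:6), sprintf("S%02d", 1:50)))
  cm <- count_matrix(base)
  expr <- log_expression(cm, factors = rep(1, 50))
  # craft genes on the log scale, then invert the transform to counts
  anchor <- expr["G1", ]
  lin <- round(2^(2 * anchor + 1) - 1)
  neg <- round(2^(max(anchor) + min(anchor) - anchor) - 1)
  m2 <- rbind(base, POS = pmax(lin, 0), NEG = pmax(neg, 0))
  cm2 <- count_matrix(m2)
  panel <- correlated_panel(cm2, "G1", r_min = 0.95, factors = rep(1, 50))
  expect_true("POS" %in% panel$gene)
  expect_false("NEG" %in% panel$gene)
  expect_false("G1" %in% panel$gene)
  expect_gt(panel$r[panel$gene == "POS"], 0.999)
  # constant anchor is an error
  m3 <- rbind(base, CONST = rep(5, 50))
  expect_error(correlated_panel(count_matrix(m3), "CONST",
                                factors = rep(1, 50)), "constant")
})

test_that("planted fold separation is recovered by the count ratio", {
  set.seed(24)
  seps <- replicate(20, {
    cfg <- sim_config(n_genes = 200, seed = sample.int(1e6, 1))
    co <- simulate_counts(cfg)
    r <- suppressWarnings(ratio_from_counts(co$counts))
    st <- co$sample_truth
    mean(r$ratio[st$true_phenotype == "Q"], na.rm = TRUE) /
      mean(r$ratio[st$true_phenotype == "NQ"], na.rm = TRUE)
  })
  planted <- 2^(0.9 + 1.5)  # anchor effect sizes move the ratio 2^2.4-fold
  expect_lt(abs(mean(seps) - planted) / planted, 0.15)
})
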