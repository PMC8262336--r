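# Independent brute-force oracles, written directly from definitions and kept
# free of the package's own code paths.

# tie-adjusted pairwise concordance: P(ratio_NQ < ratio_Q) + 0.5 P(equal)
oracle_auc <- function(r_nq, r_q) {
  total <- 0
  for (a in r_nq) for (b in r_q)
    total <- total + if (a < b) 1 else if (a == b) 0.5 else 0
  total / (length(r_nq) * length(r_q))
}

# median-of-ratios from the definition, loops only
oracle_size_factors <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  mm <- m[keep, , drop = FALSE]
  geo <- apply(mm, 1, function(r) exp(mean(log(r))))
  s <- numeric(ncol(mm))
  for (j in seq_len(ncol(mm))) s[j] <- median(mm[, j] / geo)
  s / exp(mean(log(s)))
}

# Pearson r from the sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# midranks computed by hand (average position among equal values)
oracle_midrank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# weighted KS enrichment score: full running sum, signed extremum
oracle_es <- function(metric_ordered, is_hit, weight) {
  N <- length(metric_ordered)
  k <- sum(is_hit)
  w <- abs(metric_ordered)^weight
  nr <- sum(w[is_hit])
  running <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    if (is_hit[i]) {
      acc <- acc + (if (nr == 0) 1 / k else w[i] / nr)
    } else {
      acc <- acc - 1 / (N - k)
    }
    running[i] <- acc
  }
  running[which.max(abs(running))]
}

# small deterministic count fixture
tiny_counts <- function() {
  m <- matrix(c(10, 20, 30,
                40, 50, 60,
                5, 15, 25,
                100, 200, 300), nrow = 4, byrow = TRUE,
              dimnames = list(c("ATP2B4", "ATP2A2", "GENEA", "GENEB"),
                              c("S1", "S2", "S3")))
  count_matrix(m)
}

random_counts <- function(n_genes, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, 50) + 1, n_genes, n_samples,
              dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  count_matrix(m)
}

default_record <- function(...) {
  rec <- list(ga_weeks = 40, contractions_raw = "regular_with_cervical_change",
              dilation_cm = 6, membranes = "intact", triple_i = "absent",
              spontaneous_onset = TRUE, provider_initiated = FALSE)
  utils::modifyList(rec, list(...))
}
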