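#' Log-scale expression transform
#'
#' `log2(size-factor-normalized count + 1)`, the variance-stabilizing
#' transform used as input to PCA, ranking and correlation stages.
#'
#' @param counts a [count_matrix()] or matrix.
#' @param factors optional size factors; computed by [size_factors()] when
#'   absent.
#' @return genes x samples matrix of log2 expression.
#' @export
log_expression <- function(counts, factors = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (is.null(factors)) factors <- size_factors(m)
  log2(sweep(m, 2, factors, "/") + 1)
}

#' Fit a reference PCA on the signature genes of labeled samples
#'
#' Principal component analysis on centered (optionally unit-scaled) log2
#' expression restricted to the signature genes, trained on the labeled
#' reference (term) samples. Each component is oriented so that the
#' nonquiescent (NQ) training centroid lies below the quiescent (Q) centroid,
#' making downstream phenotype calls independent of eigen-solver sign
#' conventions.
#'
#' @param counts a [count_matrix()] of the training samples.
#' @param signature character vector of signature gene symbols.
#' @param labels per-sample phenotype labels, "Q" or "NQ".
#' @param scale logical; scale genes to unit variance (default FALSE:
#'   covariance PCA).
#' @param factors optional size factors for the expression transform.
#' @return an object of class `pca_model`: `signature_genes`, `center`,
#'   `scale`, `loadings` (gene x component), `explained_variance_ratio`,
#'   `orientation_sign`, `centroids` (named PC1 means of Q and NQ training
#'   groups) and `train_scores`.
#' @export
fit_reference_pca <- function(counts, signature, labels, scale = FALSE,
                              factors = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  labels <- as.character(labels)
  if (length(labels) != ncol(counts$counts))
    stop("labels must cover every training sample")
  if (!all(labels %in% c("Q", "NQ")))
    stop("labels must be 'Q' or 'NQ'")
  if (any(table(factor(labels, levels = c("Q", "NQ"))) < 2))
    stop("need >= 2 samples per phenotype label")
  signature <- canonicalize_symbols(signature)
  missing <- setdiff(signature, counts$genes)
  if (length(missing))
    stop(sprintf("signature gene(s) absent: %s",
                 paste(utils::head(missing, 10), collapse = ", ")))

  expr <- log_expression(counts, factors)[signature, , drop = FALSE]
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d zero-variance signature gene(s)", sum(v == 0)))
    expr <- expr[v > 0, , drop = FALSE]
  }
  x <- t(expr)  # samples x genes
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  evr <- pc$sdev^2 / sum(pc$sdev^2)

  scores <- pc$x
  sign_flip <- vapply(seq_len(ncol(scores)), function(k) {
    d <- mean(scores[labels == "Q", k]) - mean(scores[labels == "NQ", k])
    if (d < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(scores, 2, sign_flip, "*")
  loadings <- sweep(pc$rotation, 2, sign_flip, "*")

  centroids <- c(Q = mean(scores[labels == "Q", 1]),
                 NQ = mean(scores[labels == "NQ", 1]))
  structure(list(signature_genes = rownames(expr),
                 center = pc$center,
                 scale = if (scale) pc$scale else NULL,
                 loadings = loadings,
                 explained_variance_ratio = evr,
                 orientation_sign = sign_flip,
                 centroids = centroids,
                 train_scores = scores,
                 train_labels = labels),
            class = "pca_model")
}

#' Project samples into a fitted PCA space
#'
#' Transforms new samples with the training center, scale and loadings; no
#' refit. All signature genes must be present (no silent imputation).
#'
#' @param model a `pca_model` from [fit_reference_pca()].
#' @param counts a [count_matrix()] (or a log-expression matrix, genes x
#'   samples, as produced by [log_expression()]).
#' @param factors optional size factors for the expression transform.
#' @return samples x components score matrix.
#' @export
project_pca <- function(model, counts, factors = NULL) {
  stopifnot(inherits(model, "pca_model"))
  if (inherits(counts, "count_matrix")) {
    missing <- setdiff(model$signature_genes, counts$genes)
    if (length(missing))
      stop(sprintf("signature gene(s) absent from projection data: %s",
                   paste(utils::head(missing, 10), collapse = ", ")))
    expr <- log_expression(counts, factors)
  } else {
    expr <- counts
    missing <- setdiff(model$signature_genes, rownames(expr))
    if (length(missing))
      stop(sprintf("signature gene(s) absent from projection data: %s",
                   paste(utils::head(missing, 10), collapse = ", ")))
  }
  x <- t(expr[model$signature_genes, , drop = FALSE])
  x <- sweep(x, 2, model$center, "-")
  if (!is.null(model$scale)) x <- sweep(x, 2, model$scale, "/")
  x %*% model$loadings
}

#' Call Q/NQ phenotypes from oriented PC1 scores
#'
#' Nearest-reference-centroid rule with a midpoint threshold: a sample is
#' called NQ iff its PC1 score is at or below the midpoint between the NQ and
#' Q training centroids (ties go to NQ). An optional transitional band of
#' half-width `band/2` times the inter-centroid distance around the midpoint
#' marks borderline samples "transitional".
#'
#' @param scores numeric PC1 scores (or a score matrix; column 1 is used).
#' @param model a `pca_model`.
#' @param transitional_band fraction of the inter-centroid distance (total
#'   band width); 0 disables the transitional category.
#' @return character vector of "NQ", "Q" or "transitional" calls.
#' @export
assign_phenotype <- function(scores, model, transitional_band = 0) {
  stopifnot(inherits(model, "pca_model"))
  if (is.matrix(scores)) scores <- scores[, 1]
  mid <- mean(model$centroids)
  d <- abs(diff(model$centroids))
  call <- ifelse(scores <= mid, "NQ", "Q")
  if (transitional_band > 0) {
    half <- transitional_band * d / 2
    call[abs(scores - mid) < half] <- "transitional"
  }
  stats::setNames(call, names(scores))
}

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[i, ], n, after = pos - 1)
      row <- row + 1
    }
  }
  out
}

#' Spearman correlation of PC1 with clinical scores
#'
#' Tie-corrected (midrank) Spearman rho for each clinical score column,
#' with a t-approximation p-value for n > 10 and a permutation p-value for
#' n <= 10 (exhaustive enumeration up to n = 7, seeded Monte Carlo with
#' `nperm` draws otherwise). Pairs with missing values are dropped per
#' variable; constant variables return NA with a warning.
#'
#' @param pc1 named numeric vector of PC1 scores.
#' @param clinical_scores data.frame with `sample_id` plus numeric score
#'   columns (as produced by [score_clinical()]).
#' @param nperm Monte Carlo permutations for 8 <= n <= 10.
#' @param seed seed for the Monte Carlo permutation p-value.
#' @return data.frame: variable, n, rho, p, method.
#' @export
correlate_clinical <- function(pc1, clinical_scores, nperm = 20000,
                               seed = 1L) {
  stopifnot(is.data.frame(clinical_scores), "sample_id" %in% names(clinical_scores))
  ids <- clinical_scores$sample_id
  if (is.null(names(pc1))) {
    if (length(pc1) != nrow(clinical_scores))
      stop("unnamed pc1 must align with clinical_scores rows")
    names(pc1) <- ids
  }
  common <- intersect(names(pc1), ids)
  if (length(common) < 3) stop("need >= 3 paired observations")
  vars <- setdiff(names(clinical_scores), "sample_id")
  rows <- lapply(vars, function(v) {
    y <- suppressWarnings(as.numeric(clinical_scores[[v]][match(common, ids)]))
    x <- pc1[common]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3) stop(sprintf("variable '%s': < 3 paired observations", v))
    if (stats::sd(y) == 0 || stats::sd(x) == 0) {
      warning(sprintf("variable '%s' is constant; rho undefined", v))
      return(data.frame(variable = v, n = n, rho = NA_real_, p = NA_real_,
                        method = "undefined", stringsAsFactors = FALSE))
    }
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    if (n > 10) {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
      method <- "t-approximation"
    } else if (n <= 7) {
      perms <- all_permutations(n)
      rhos <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
      p <- mean(abs(rhos) >= abs(rho) - 1e-12)
      method <- "exact permutation"
    } else {
      set_sim_seed(seed, 0L)
      rhos <- replicate(nperm, stats::cor(rx, sample(ry)))
      p <- (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / (nperm + 1)
      method <- "Monte Carlo permutation"
    }
    data.frame(variable = v, n = n, rho = rho, p = p, method = method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
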