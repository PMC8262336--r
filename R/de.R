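#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: each sample's factor is the median, over
#' genes with nonzero counts in every sample, of the ratio of that sample's
#' count to the gene's geometric mean across samples. Factors are rescaled to
#' unit geometric mean, so they are relative library-size estimates.
#'
#' @param counts a [count_matrix()] or numeric matrix (genes x samples).
#' @return numeric vector of positive size factors, one per sample, with unit
#'   geometric mean.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (ncol(m) < 2) stop("size factors need >= 2 samples")
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep))
    stop(paste("no gene has nonzero counts in all samples;",
               "consider a pseudo-reference fallback"))
  lg <- log(m[keep, , drop = FALSE])
  ref <- rowMeans(lg)
  s <- apply(exp(lg - ref), 2, stats::median)
  s <- s / exp(mean(log(s)))
  stats::setNames(s, colnames(m))
}

#' Normalized counts
#'
#' @param counts a [count_matrix()] or matrix.
#' @param factors optional size factors (computed if absent).
#' @return matrix of counts divided by their sample's size factor.
#' @export
normalized_counts <- function(counts, factors = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (is.null(factors)) factors <- size_factors(m)
  sweep(m, 2, factors, "/")
}

#' Per-gene negative binomial dispersion estimates
#'
#' Method-of-moments estimator on size-factor-normalized counts, pooled
#' within groups: `alpha_mom = max((var - mu) / mu^2, alpha_min)` using the
#' pooled within-group variance, optionally blended toward a fitted
#' mean-dispersion trend `alpha(mu) = a0/mu + a1` with weight `trend_weight`.
#' Genes whose groups are all singletons fall back to the pooled trend value
#' with a warning.
#'
#' @param counts a [count_matrix()] or matrix.
#' @param factors size factors (computed if absent).
#' @param groups per-sample group labels used for within-group moments; when
#'   `NULL` all samples form one group.
#' @param trend_weight weight on the fitted trend in the blend (0 = pure
#'   method of moments, 1 = pure trend).
#' @param alpha_min dispersion floor.
#' @return list with `alpha` (per-gene dispersion), `alpha_mom`, `trend`
#'   (function of mean) and `trend_coef` (a0, a1).
#' @export
estimate_dispersions <- function(counts, factors = NULL, groups = NULL,
                                 trend_weight = 0.5, alpha_min = 1e-8) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (is.null(factors)) factors <- size_factors(m)
  y <- sweep(m, 2, factors, "/")
  if (is.null(groups)) groups <- rep("all", ncol(y))
  groups <- as.character(groups)
  glev <- unique(groups)
  n_per <- table(groups)[glev]

  if (all(n_per < 2)) {
    warning("all groups are singletons; dispersion set to trend defaults")
    mu <- rowMeans(y)
    alpha <- pmax(5 / pmax(mu, 1e-8) + 0.05, alpha_min)
    return(list(alpha = alpha, alpha_mom = rep(NA_real_, nrow(y)),
                trend = function(mu) 5 / pmax(mu, 1e-8) + 0.05,
                trend_coef = c(a0 = 5, a1 = 0.05)))
  }

  # pooled within-group moments
  ss <- 0
  mu_g <- matrix(0, nrow(y), length(glev))
  for (i in seq_along(glev)) {
    yg <- y[, groups == glev[i], drop = FALSE]
    mu_g[, i] <- rowMeans(yg)
    if (ncol(yg) > 1)
      ss <- ss + rowSums((yg - mu_g[, i])^2)
  }
  df <- ncol(y) - length(glev)
  v <- ss / max(df, 1)
  mu <- as.vector(mu_g %*% (n_per / sum(n_per)))
  alpha_mom <- pmax((v - mu) / pmax(mu, 1e-8)^2, alpha_min)

  # fit trend alpha(mu) = a0/mu + a1 on informative genes
  ok <- mu > 1 & alpha_mom > alpha_min
  if (sum(ok) >= 10) {
    fit <- stats::lm(alpha_mom[ok] ~ I(1 / mu[ok]))
    a1 <- max(stats::coef(fit)[1], alpha_min)
    a0 <- max(stats::coef(fit)[2], 0)
  } else {
    a0 <- 5; a1 <- 0.05
  }
  trend <- function(mu) a0 / pmax(mu, 1e-8) + a1
  alpha <- pmax(trend_weight * trend(mu) + (1 - trend_weight) * alpha_mom,
                alpha_min)
  list(alpha = alpha, alpha_mom = alpha_mom, trend = trend,
       trend_coef = c(a0 = unname(a0), a1 = unname(a1)))
}

# Vectorized IRLS for per-gene NB log-linear models sharing one design matrix.
# Y: genes x samples counts; X: samples x p design; offset: length-n log
# exposure; alpha: per-gene dispersion. Returns coefficients, their standard
# errors and convergence flags. Fisher-scoring weights w = mu / (1 + alpha*mu).
nb_glm_fit <- function(Y, X, offset, alpha, maxit = 30, tol = 1e-10) {
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  OFF <- matrix(offset, G, n, byrow = TRUE)
  # init from log normalized counts
  L <- log(Y + 0.5) - OFF
  B <- t(solve(crossprod(X), t(X) %*% t(L)))
  XtX_pairs <- utils::combn(seq_len(p), 2, simplify = FALSE)
  conv <- rep(FALSE, G)
  A <- NULL
  for (iter in seq_len(maxit)) {
    ETA <- B %*% t(X)
    ETA[ETA > 30] <- 30
    ETA[ETA < -30] <- -30
    MU <- exp(ETA + OFF)
    W <- MU / (1 + alpha * MU)
    Z <- ETA + (Y - MU) / MU
    # normal equations per gene: A_g beta = r_g
    A <- array(0, c(G, p, p))
    R <- matrix(0, G, p)
    for (a in seq_len(p)) {
      A[, a, a] <- W %*% (X[, a]^2)
      R[, a] <- (W * Z) %*% X[, a]
    }
    for (pr in XtX_pairs) {
      v <- W %*% (X[, pr[1]] * X[, pr[2]])
      A[, pr[1], pr[2]] <- v
      A[, pr[2], pr[1]] <- v
    }
    Bnew <- batch_solve(A, R)
    delta <- abs(Bnew - B)
    conv <- apply(delta, 1, max) < tol
    B <- Bnew
    if (all(conv)) break
  }
  se <- sqrt(batch_inv_diag(A))
  list(coef = B, se = se, converged = conv)
}

# Solve A_g x = r_g for each gene; closed form for p <= 3, loop otherwise.
batch_solve <- function(A, R) {
  p <- dim(A)[2]
  if (p == 1) return(R / A[, 1, 1])
  if (p == 2) {
    a <- A[, 1, 1]; b <- A[, 1, 2]; d <- A[, 2, 2]
    det <- a * d - b^2
    cbind((R[, 1] * d - R[, 2] * b) / det,
          (R[, 2] * a - R[, 1] * b) / det)
  } else if (p == 3) {
    a <- A[, 1, 1]; b <- A[, 1, 2]; c <- A[, 1, 3]
    d <- A[, 2, 2]; e <- A[, 2, 3]; f <- A[, 3, 3]
    det <- a * (d * f - e^2) - b * (b * f - e * c) + c * (b * e - d * c)
    i11 <- (d * f - e^2); i12 <- -(b * f - c * e); i13 <- (b * e - c * d)
    i22 <- (a * f - c^2); i23 <- -(a * e - b * c)
    i33 <- (a * d - b^2)
    cbind((i11 * R[, 1] + i12 * R[, 2] + i13 * R[, 3]) / det,
          (i12 * R[, 1] + i22 * R[, 2] + i23 * R[, 3]) / det,
          (i13 * R[, 1] + i23 * R[, 2] + i33 * R[, 3]) / det)
  } else {
    t(vapply(seq_len(nrow(R)), function(g) solve(A[g, , ], R[g, ]),
             numeric(p)))
  }
}

# Diagonal of A_g^{-1} per gene (for Wald standard errors).
batch_inv_diag <- function(A) {
  p <- dim(A)[2]
  if (p == 1) return(matrix(1 / A[, 1, 1], ncol = 1))
  if (p == 2) {
    a <- A[, 1, 1]; b <- A[, 1, 2]; d <- A[, 2, 2]
    det <- a * d - b^2
    cbind(d / det, a / det)
  } else if (p == 3) {
    a <- A[, 1, 1]; b <- A[, 1, 2]; c <- A[, 1, 3]
    d <- A[, 2, 2]; e <- A[, 2, 3]; f <- A[, 3, 3]
    det <- a * (d * f - e^2) - b * (b * f - e * c) + c * (b * e - d * c)
    cbind((d * f - e^2) / det, (a * f - c^2) / det, (a * d - b^2) / det)
  } else {
    t(vapply(seq_len(dim(A)[1]), function(g) diag(solve(A[g, , ])),
             numeric(p)))
  }
}

#' Negative binomial Wald test for differential expression
#'
#' Fits, per gene, a negative binomial log-linear model with a log
#' size-factor offset and tests the group coefficient with a Wald test
#' (normal approximation). Batch enters as an additive covariate when
#' supplied. P values are adjusted across genes by Benjamini-Hochberg.
#' This is a deliberately simplified pipeline implementing the stated
#' criteria (median-of-ratios normalization, NB model, Wald test, BH FDR);
#' it performs no independent filtering, outlier replacement or fold-change
#' shrinkage.
#'
#' @param counts a [count_matrix()].
#' @param group per-sample labels (character/factor).
#' @param contrast length-2 character vector `c(test, reference)`: positive
#'   log2 fold change means higher in `test`.
#' @param batch optional per-sample batch labels; defaults to the count
#'   matrix's own batch labels when present, none otherwise. Ignored with a
#'   message when constant.
#' @param trend_weight,alpha_min passed to [estimate_dispersions()].
#' @return data.frame of class `de_result`: gene, base_mean, log2fc, se, p,
#'   q, alpha, separated (TRUE when one group is all-zero and the displayed
#'   fold change used a 0.5 pseudo-count).
#' @export
test_de <- function(counts, group, contrast, batch = NULL,
                    trend_weight = 0.5, alpha_min = 1e-8) {
  stopifnot(inherits(counts, "count_matrix"))
  m <- counts$counts
  group <- as.character(group)
  if (length(group) != ncol(m)) stop("group must label every sample")
  if (length(contrast) != 2 || !all(contrast %in% group))
    stop("contrast must name two groups present in 'group'")
  keep <- group %in% contrast
  m <- m[, keep, drop = FALSE]
  group <- group[keep]
  if (is.null(batch) && !is.null(counts$batch)) {
    batch <- counts$batch[keep]
  } else if (!is.null(batch)) {
    batch <- as.character(batch)[keep]
  }
  if (any(table(group)[contrast] < 2))
    stop("each contrast group needs >= 2 samples")

  s <- size_factors(m)
  disp <- estimate_dispersions(m, s, groups = group,
                               trend_weight = trend_weight,
                               alpha_min = alpha_min)
  gf <- factor(group, levels = c(contrast[2], contrast[1]))
  if (!is.null(batch) && length(unique(batch)) > 1) {
    X <- stats::model.matrix(~ gf + factor(batch))
  } else {
    if (!is.null(batch) && length(unique(batch)) == 1)
      message("batch is constant; omitted from the model")
    X <- stats::model.matrix(~ gf)
  }
  coef_idx <- 2L  # group coefficient

  norm <- sweep(m, 2, s, "/")
  base_mean <- rowMeans(norm)
  nonzero <- base_mean > 0
  in_test <- group == contrast[1]
  zero_one_group <- (rowSums(m[, in_test, drop = FALSE]) == 0 |
                     rowSums(m[, !in_test, drop = FALSE]) == 0) & nonzero

  lfc <- se <- p <- rep(NA_real_, nrow(m))
  if (any(nonzero)) {
    fit <- nb_glm_fit(m[nonzero, , drop = FALSE], X, log(s),
                      disp$alpha[nonzero])
    beta <- fit$coef[, coef_idx]
    beta_se <- fit$se[, coef_idx]
    lfc[nonzero] <- beta / log(2)
    se[nonzero] <- beta_se / log(2)
    z <- beta / beta_se
    p[nonzero] <- 2 * stats::pnorm(-abs(z))
  }
  # display fold change with pseudo-count where one group is all zero
  if (any(zero_one_group)) {
    mt <- rowMeans(norm[, in_test, drop = FALSE])
    mr <- rowMeans(norm[, !in_test, drop = FALSE])
    lfc[zero_one_group] <- log2((mt[zero_one_group] + 0.5) /
                                (mr[zero_one_group] + 0.5))
  }
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")

  out <- data.frame(gene = rownames(m), base_mean = base_mean,
                    log2fc = lfc, se = se, p = p, q = q,
                    alpha = disp$alpha, separated = zero_one_group,
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  class(out) <- c("de_result", "data.frame")
  out
}

#' Filter a DE result to the labor signature
#'
#' A gene enters the signature iff `|log2fc| >= log2(min_fc)` and
#' `q < max_fdr` (linear fold-change and FDR gates applied jointly).
#'
#' @param de a `de_result` from [test_de()].
#' @param min_fc minimum linear fold change (default 1.5).
#' @param max_fdr FDR ceiling (default 0.1).
#' @return list with `genes` (all passing genes), `up`, `down`, and the
#'   annotated `table` (adds `passes_filter` and `direction` columns).
#' @export
signature_filter <- function(de, min_fc = 1.5, max_fdr = 0.1) {
  stopifnot(is.data.frame(de))
  pass <- !is.na(de$q) & !is.na(de$log2fc) &
    abs(de$log2fc) >= log2(min_fc) & de$q < max_fdr
  direction <- ifelse(!pass, "",
                      ifelse(de$log2fc > 0, "up", "down"))
  tab <- de
  tab$passes_filter <- pass
  tab$direction <- direction
  list(genes = de$gene[pass],
       up = de$gene[pass & de$log2fc > 0],
       down = de$gene[pass & de$log2fc < 0],
       table = tab)
}
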