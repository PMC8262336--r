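#' ATP2B4/ATP2A2 ratio from RNA-seq counts
#'
#' Per-sample ratio of the numerator gene's feature count to the
#' denominator's. Because both genes are measured in the same sample, any
#' sample-level scaling (library size) cancels, so raw and size-factor
#' normalized modes give identical ratios; both are provided. Samples with a
#' zero denominator are flagged missing rather than failing globally.
#'
#' @param counts a [count_matrix()].
#' @param num numerator gene symbol (default "ATP2B4").
#' @param den denominator gene symbol (default "ATP2A2").
#' @param mode "raw" (default) or "normalized".
#' @return data.frame of class `ratio_result`: sample_id, ratio, numerator,
#'   denominator, source.
#' @export
ratio_from_counts <- function(counts, num = "ATP2B4", den = "ATP2A2",
                              mode = c("raw", "normalized")) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "count_matrix"))
  num <- canonicalize_symbols(num); den <- canonicalize_symbols(den)
  missing <- setdiff(c(num, den), counts$genes)
  if (length(missing))
    stop(sprintf("gene(s) absent from counts: %s",
                 paste(missing, collapse = ", ")))
  m <- counts$counts
  if (mode == "normalized") m <- normalized_counts(m)
  kn <- m[num, ]; kd <- m[den, ]
  ratio <- ifelse(kd > 0, kn / kd, NA_real_)
  if (any(kd == 0))
    warning(sprintf("%d sample(s) with zero denominator flagged missing",
                    sum(kd == 0)))
  out <- data.frame(sample_id = counts$samples, ratio = unname(ratio),
                    numerator = unname(kn), denominator = unname(kd),
                    source = paste0("rnaseq_", mode),
                    stringsAsFactors = FALSE)
  class(out) <- c("ratio_result", "data.frame")
  out
}

#' ATP2B4/ATP2A2 ratio from qPCR Ct values (comparative Ct)
#'
#' Replicate wells are averaged arithmetically on the Ct scale (equivalent to
#' a geometric mean of linear quantities); the ratio is
#' `2^-(Ct_ATP2B4 - Ct_ATP2A2)` on the well-averaged Cts. When both reference
#' genes (B2M, RPL30) are present, reference-normalized relative abundances
#' `2^-(Ct_target - Ct_ref)` are also emitted, with `Ct_ref` the arithmetic
#' mean of the two reference-gene Cts (the log2 of their geometric mean);
#' the reference cancels in the two-gene ratio, so the ratio is computed
#' either way.
#'
#' @param ct a `ct_table` (sample_id, assay, well, ct).
#' @param num,den target gene symbols (defaults ATP2B4 / ATP2A2).
#' @return data.frame of class `ratio_result`: sample_id, ratio, delta_ct,
#'   ct_num, ct_den, rel_num, rel_den (reference-normalized abundances, NA if
#'   references absent), source = "qpcr".
#' @export
ratio_from_ct <- function(ct, num = "ATP2B4", den = "ATP2A2") {
  stopifnot(is.data.frame(ct))
  num <- canonicalize_symbols(num); den <- canonicalize_symbols(den)
  avg <- stats::aggregate(ct ~ sample_id + assay, data = ct, FUN = mean,
                          na.action = stats::na.omit)
  wide <- stats::reshape(avg, idvar = "sample_id", timevar = "assay",
                         direction = "wide")
  names(wide) <- sub("^ct\\.", "", names(wide))
  for (g in c(num, den)) if (!g %in% names(wide)) wide[[g]] <- NA_real_
  delta <- wide[[num]] - wide[[den]]
  ratio <- 2^(-delta)
  n_missing <- sum(is.na(ratio))
  if (n_missing)
    warning(sprintf("%d sample(s) missing a target Ct; ratio flagged missing",
                    n_missing))
  refs <- intersect(REFERENCE_GENES, names(wide))
  if (length(refs) == 2) {
    ct_ref <- rowMeans(wide[, refs, drop = FALSE])
    rel_num <- 2^(-(wide[[num]] - ct_ref))
    rel_den <- 2^(-(wide[[den]] - ct_ref))
  } else {
    rel_num <- rel_den <- rep(NA_real_, nrow(wide))
  }
  out <- data.frame(sample_id = wide$sample_id, ratio = ratio,
                    delta_ct = delta, ct_num = wide[[num]],
                    ct_den = wide[[den]], rel_num = rel_num,
                    rel_den = rel_den, source = "qpcr",
                    stringsAsFactors = FALSE)
  class(out) <- c("ratio_result", "data.frame")
  out
}

#' ROC analysis of the expression ratio
#'
#' Lower ratios indicate the nonquiescent (NQ) phenotype. AUC is the
#' tie-adjusted Mann-Whitney concordance: over all (NQ, Q) pairs, the
#' fraction with `ratio_NQ < ratio_Q`, counting ties 1/2. The full stepwise
#' curve is emitted (one operating point per candidate threshold, rule:
#' call NQ iff ratio <= threshold). The operating threshold maximizes
#' Youden's J = sensitivity + specificity - 1, ties broken toward the higher
#' threshold (favoring NQ sensitivity).
#'
#' @param ratios a `ratio_result` or data.frame with `sample_id` and `ratio`.
#' @param labels named character vector (or data.frame with sample_id /
#'   label columns) of "Q"/"NQ" reference labels.
#' @return list of class `roc_result`: `auc`, `threshold`, `curve`
#'   (data.frame threshold, sensitivity, specificity, youden_j), `n_nq`,
#'   `n_q`, `n_excluded`.
#' @export
ratio_roc <- function(ratios, labels) {
  stopifnot(is.data.frame(ratios), all(c("sample_id", "ratio") %in% names(ratios)))
  if (is.data.frame(labels)) {
    lc <- intersect(c("label", "phenotype_label", "true_phenotype"),
                    names(labels))[1]
    if (is.na(lc)) stop("labels data.frame needs a label column")
    labels <- stats::setNames(as.character(labels[[lc]]), labels$sample_id)
  }
  lab <- labels[ratios$sample_id]
  r <- ratios$ratio
  ok <- !is.na(r) & lab %in% c("Q", "NQ")
  n_excluded <- sum(!ok)
  r <- r[ok]; lab <- lab[ok]
  if (!any(lab == "NQ") || !any(lab == "Q"))
    stop("both classes (Q, NQ) must be present")
  rn <- r[lab == "NQ"]; rq <- r[lab == "Q"]

  # tie-adjusted Mann-Whitney concordance of (lower ratio => NQ)
  cmp <- outer(rn, rq, function(a, b) (a < b) + 0.5 * (a == b))
  auc <- mean(cmp)

  thresholds <- sort(unique(r))
  sens <- vapply(thresholds, function(t) mean(rn <= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(rq > t), numeric(1))
  j <- sens + spec - 1
  best <- max(which(j == max(j)))  # ties toward higher threshold
  curve <- data.frame(threshold = thresholds, sensitivity = sens,
                      specificity = spec, youden_j = j)
  structure(list(auc = auc, threshold = thresholds[best], curve = curve,
                 n_nq = length(rn), n_q = length(rq),
                 n_excluded = n_excluded),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f, NQ threshold <= %.3f (NQ n = %d, Q n = %d)\n",
              x$auc, x$threshold, x$n_nq, x$n_q))
  invisible(x)
}

#' Classify samples by their expression ratio
#'
#' Binary rule: NQ iff `ratio <= tau` (the threshold is inclusive on the NQ
#' side). With a transitional band `b > 0`, samples with ratio in
#' `(tau * (1 - b), tau * (1 + b)]` are called "transitional"; NQ below, Q
#' above.
#'
#' @param ratios a `ratio_result` or numeric vector of ratios.
#' @param tau operating threshold (> 0).
#' @param transitional_band relative band half-width b (default 0, binary).
#' @return character vector of "NQ"/"Q"/"transitional" (NA where the ratio is
#'   missing), named by sample when available.
#' @export
classify_ratio <- function(ratios, tau, transitional_band = 0) {
  if (tau <= 0) stop("tau must be > 0")
  if (is.data.frame(ratios)) {
    r <- stats::setNames(ratios$ratio, ratios$sample_id)
  } else r <- ratios
  call <- ifelse(r <= tau, "NQ", "Q")
  if (transitional_band > 0) {
    lo <- tau * (1 - transitional_band)
    hi <- tau * (1 + transitional_band)
    call[r > lo & r <= hi] <- "transitional"
  }
  call
}

#' Genes correlated with an anchor gene
#'
#' Pearson correlation of every gene's log2-normalized expression with the
#' anchor's across all samples; genes with `r >= r_min` are returned (the
#' anchor itself excluded), ordered by r descending then symbol ascending.
#'
#' @param counts a [count_matrix()] (>= 3 samples).
#' @param anchor anchor gene symbol.
#' @param r_min one-sided correlation threshold (default 0.95).
#' @param factors optional size factors.
#' @return data.frame: gene, r.
#' @export
correlated_panel <- function(counts, anchor, r_min = 0.95, factors = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  anchor <- canonicalize_symbols(anchor)
  if (!anchor %in% counts$genes)
    stop(sprintf("anchor gene '%s' absent from counts", anchor))
  if (ncol(counts$counts) < 3) stop("need >= 3 samples")
  expr <- log_expression(counts, factors)
  a <- expr[anchor, ]
  if (stats::sd(a) == 0) stop("anchor gene is constant across samples")
  keep <- apply(expr, 1, stats::sd) > 0
  r <- as.vector(stats::cor(t(expr[keep, , drop = FALSE]), a))
  names(r) <- rownames(expr)[keep]
  r <- r[names(r) != anchor]
  sel <- r >= r_min
  out <- data.frame(gene = names(r)[sel], r = unname(r[sel]),
                    stringsAsFactors = FALSE)
  out[order(-out$r, out$gene), , drop = FALSE]
}
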