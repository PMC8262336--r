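row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

signal_to_noise_metric <- function(expr, in_test, sd_floor_frac = 0.2,
                                   eps = 1e-8) {
  a <- expr[, in_test, drop = FALSE]
  b <- expr[, !in_test, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  sa <- pmax(row_sds(a), sd_floor_frac * abs(ma), eps)
  sb <- pmax(row_sds(b), sd_floor_frac * abs(mb), eps)
  (ma - mb) / (sa + sb)
}

#' Rank genes by the signal-to-noise metric
#'
#' `(mu_test - mu_ref) / (sd_test + sd_ref)` on log-normalized expression,
#' with each group's sd floored at `max(sd, 0.2 * |mean|, eps)` (the
#' convention of the desktop GSEA tool; configurable). Genes are ordered by
#' metric descending with ties broken by gene symbol ascending, so the
#' ranking is strictly deterministic.
#'
#' @param expr a [count_matrix()] (log-transformed internally via
#'   [log_expression()]) or an already-transformed genes x samples matrix.
#' @param labels per-sample group labels.
#' @param contrast length-2 `c(test, reference)`; positive metric = higher in
#'   test group.
#' @param sd_floor_frac fraction of |mean| used as the sd floor.
#' @return data.frame of class `ranked_list`: gene, metric (ordered).
#' @export
rank_signal_to_noise <- function(expr, labels, contrast = NULL,
                                 sd_floor_frac = 0.2) {
  if (inherits(expr, "count_matrix")) expr <- log_expression(expr)
  labels <- as.character(labels)
  if (length(labels) != ncol(expr)) stop("labels must cover every sample")
  if (is.null(contrast)) contrast <- unique(labels)[1:2]
  if (any(table(labels)[contrast] < 2))
    stop("each group needs >= 2 samples")
  keep <- labels %in% contrast
  expr <- expr[, keep, drop = FALSE]
  metric <- signal_to_noise_metric(expr, labels[keep] == contrast[1],
                                   sd_floor_frac)
  ord <- order(-metric, rownames(expr))
  out <- data.frame(gene = rownames(expr)[ord], metric = metric[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Rank genes by signed FDR
#'
#' Alternative ranking for enrichment against a differential-expression
#' result: `sign(log2fc) * -log10(q)` with `q` floored at 1e-300. Ties broken
#' by gene symbol.
#'
#' @param de a `de_result` from [test_de()].
#' @return a `ranked_list` data.frame.
#' @export
rank_signed_fdr <- function(de) {
  stopifnot(is.data.frame(de))
  ok <- !is.na(de$q) & !is.na(de$log2fc)
  metric <- sign(de$log2fc[ok]) * -log10(pmax(de$q[ok], 1e-300))
  ord <- order(-metric, de$gene[ok])
  out <- data.frame(gene = de$gene[ok][ord], metric = metric[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

# ES from sorted hit positions, weighted KS running-sum extremum.
# wts: |metric|^weight for the hit genes, ordered by position.
es_from_positions <- function(pos, wts, N) {
  k <- length(pos)
  if (k == 0 || k >= N) return(0)
  NR <- sum(wts)
  if (NR == 0) { wts <- rep(1, k); NR <- k }
  miss_step <- 1 / (N - k)
  csw <- cumsum(wts) / NR
  after <- csw - (pos - seq_len(k)) * miss_step
  before <- after - wts / NR
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: set members increment the running sum by
#' `|metric|^weight / sum(|metric|^weight over members)`, non-members
#' decrement by `1 / (N - set size)`. The enrichment score is the signed
#' extremum of the running sum.
#'
#' @param ranked a `ranked_list`.
#' @param gene_set character vector of member symbols.
#' @param weight exponent on |metric| (0 = classic KS, 1 = weighted).
#' @return list: `es`, `running` (length-N profile), `hits` (logical),
#'   `leading_edge` (member genes up to / from the extremum).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  stopifnot(is.data.frame(ranked))
  gene_set <- unique(canonicalize_symbols(gene_set))
  hits <- ranked$gene %in% gene_set
  if (!any(hits)) stop("gene set has no members in the ranked universe")
  N <- nrow(ranked)
  k <- sum(hits)
  if (k == N) {
    return(list(es = 0, running = rep(0, N), hits = hits,
                leading_edge = character(0)))
  }
  w <- abs(ranked$metric)^weight
  NR <- sum(w[hits])
  inc <- if (NR == 0) as.numeric(hits) / k else ifelse(hits, w / NR, 0)
  dec <- ifelse(hits, 0, 1 / (N - k))
  running <- cumsum(inc - dec)
  i <- which.max(abs(running))
  es <- running[i]
  leading_edge <- if (es >= 0) ranked$gene[seq_len(i)][hits[seq_len(i)]]
                  else ranked$gene[i:N][hits[i:N]]
  list(es = es, running = running, hits = hits, leading_edge = leading_edge)
}

#' Gene-set enrichment analysis with a permutation null
#'
#' Signal-to-noise ranking, weighted KS enrichment scores, and a permutation
#' null. Phenotype permutation (relabeling samples and regenerating the
#' ranking each time) is the default; with fewer than 7 samples per group a
#' warning recommends gene-set permutation (`perm_type = "gene_set"`), which
#' draws random sets of matched size instead. The nominal p-value is
#' sign-stratified with an add-one rule, so it is never exactly zero; NES
#' divides each ES by the mean |permuted ES| of the same sign, and FDR q is
#' the sign-stratified ratio of permuted-to-observed tail frequencies.
#'
#' @param expr a [count_matrix()] or log-expression matrix.
#' @param labels per-sample group labels.
#' @param sets a `gene_sets` collection (named list of symbol vectors).
#' @param contrast length-2 `c(test, reference)`.
#' @param nperm number of permutations (>= 1).
#' @param size_min,size_max set-size gates after intersection with the
#'   ranked universe; sets outside are skipped.
#' @param weight KS weight exponent.
#' @param perm_type "phenotype" (default) or "gene_set".
#' @param seed optional integer seed for the permutation stream.
#' @return data.frame of class `gsea_result`: set, size, es, nes, p, fdr,
#'   leading_edge (comma-separated).
#' @export
gsea <- function(expr, labels, sets, contrast = NULL, nperm = 1000,
                 size_min = 15, size_max = 500, weight = 1,
                 perm_type = c("phenotype", "gene_set"), seed = NULL) {
  perm_type <- match.arg(perm_type)
  if (nperm < 1) stop("nperm must be >= 1")
  if (inherits(expr, "count_matrix")) expr <- log_expression(expr)
  labels <- as.character(labels)
  if (is.null(contrast)) contrast <- unique(labels)[1:2]
  keep <- labels %in% contrast
  expr <- expr[, keep, drop = FALSE]
  labels <- labels[keep]
  if (any(table(labels)[contrast] < 2)) stop("each group needs >= 2 samples")
  if (perm_type == "phenotype" && min(table(labels)[contrast]) < 7)
    warning(paste("fewer than 7 samples per group: phenotype permutations",
                  "are coarse; consider perm_type = 'gene_set'"))
  set_sim_seed(seed, 0L)

  genes <- rownames(expr)
  N <- length(genes)
  universe_sets <- lapply(sets, function(s) intersect(canonicalize_symbols(s),
                                                      genes))
  sizes <- lengths(universe_sets)
  use <- sizes >= size_min & sizes <= size_max
  if (!any(use)) stop("no gene set within the size gates")
  skipped <- names(sets)[!use]
  if (length(skipped))
    message(sprintf("skipping %d set(s) outside size gates [%d, %d]",
                    length(skipped), size_min, size_max))
  universe_sets <- universe_sets[use]
  set_idx <- lapply(universe_sets, function(s) match(s, genes))

  in_test <- labels == contrast[1]
  metric <- signal_to_noise_metric(expr, in_test)
  ord <- order(-metric, genes)
  rankpos <- integer(N); rankpos[ord] <- seq_len(N)
  absw <- abs(metric)^weight

  es_for <- function(idx, rankpos, absw) {
    pos <- rankpos[idx]
    o <- order(pos)
    es_from_positions(pos[o], absw[idx][o], N)
  }
  obs <- vapply(set_idx, es_for, numeric(1), rankpos = rankpos, absw = absw)

  n_sets <- length(set_idx)
  perm_es <- matrix(0, nperm, n_sets)
  if (perm_type == "phenotype") {
    for (b in seq_len(nperm)) {
      pl <- sample(in_test)
      pm <- signal_to_noise_metric(expr, pl)
      po <- order(-pm, genes)
      prank <- integer(N); prank[po] <- seq_len(N)
      pw <- abs(pm)^weight
      perm_es[b, ] <- vapply(set_idx, es_for, numeric(1),
                             rankpos = prank, absw = pw)
    }
  } else {
    for (b in seq_len(nperm)) {
      perm_es[b, ] <- vapply(lengths(set_idx), function(k)
        es_for(sample.int(N, k), rankpos, absw), numeric(1))
    }
  }

  p <- nes <- numeric(n_sets)
  perm_nes <- matrix(NA_real_, nperm, n_sets)
  for (j in seq_len(n_sets)) {
    pe <- perm_es[, j]
    if (obs[j] >= 0) {
      same <- pe[pe >= 0]
      p[j] <- (1 + sum(same >= obs[j])) / (1 + length(same))
      denom <- if (length(same)) mean(same) else NA_real_
    } else {
      same <- pe[pe < 0]
      p[j] <- (1 + sum(same <= obs[j])) / (1 + length(same))
      denom <- if (length(same)) abs(mean(same)) else NA_real_
    }
    nes[j] <- if (is.na(denom) || denom == 0) NA_real_ else obs[j] / denom
    pos_mean <- mean(pe[pe >= 0]); neg_mean <- abs(mean(pe[pe < 0]))
    pn <- ifelse(pe >= 0, pe / pos_mean, pe / neg_mean)
    perm_nes[, j] <- pn
  }
  # sign-stratified FDR on the NES scale
  fdr <- rep(NA_real_, n_sets)
  all_pn <- as.vector(perm_nes)
  all_pn <- all_pn[is.finite(all_pn)]
  for (j in seq_len(n_sets)) {
    if (is.na(nes[j])) next
    if (nes[j] >= 0) {
      num <- mean(all_pn[all_pn >= 0] >= nes[j])
      den <- mean(nes[!is.na(nes) & nes >= 0] >= nes[j])
    } else {
      num <- mean(all_pn[all_pn < 0] <= nes[j])
      den <- mean(nes[!is.na(nes) & nes < 0] <= nes[j])
    }
    fdr[j] <- min(1, if (den == 0) 1 else num / den)
  }

  le <- vapply(seq_len(n_sets), function(j) {
    r <- data.frame(gene = genes[ord], metric = metric[ord],
                    stringsAsFactors = FALSE)
    paste(enrichment_score(r, universe_sets[[j]], weight)$leading_edge,
          collapse = ",")
  }, character(1))

  out <- data.frame(set = names(universe_sets), size = lengths(universe_sets),
                    es = obs, nes = nes, p = p, fdr = fdr,
                    leading_edge = le, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Overlap coefficient between two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`: 1 iff one set contains the other.
#'
#' @param a,b character vectors (non-empty).
#' @return numeric in [0, 1].
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(canonicalize_symbols(a))
  b <- unique(canonicalize_symbols(b))
  if (!length(a) || !length(b)) stop("sets must be non-empty")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Enrichment-map edge list
#'
#' Pairwise overlap-coefficient edges between gene sets that pass the
#' enrichment gates (nominal p, FDR) with overlap at or above a threshold.
#'
#' @param result a `gsea_result`.
#' @param sets the `gene_sets` collection used for the analysis.
#' @param overlap_min minimum overlap coefficient for an edge (default 0.1).
#' @param p_max nominal p gate (default 0.005).
#' @param fdr_max FDR gate (default 0.1).
#' @return data.frame: set_a, set_b, overlap.
#' @export
enrichment_edges <- function(result, sets, overlap_min = 0.1,
                             p_max = 0.005, fdr_max = 0.1) {
  stopifnot(is.data.frame(result))
  pass <- result$set[!is.na(result$p) & result$p < p_max &
                     !is.na(result$fdr) & result$fdr < fdr_max]
  pass <- intersect(pass, names(sets))
  edges <- list()
  if (length(pass) >= 2) {
    cmb <- utils::combn(pass, 2)
    for (i in seq_len(ncol(cmb))) {
      oc <- overlap_coefficient(sets[[cmb[1, i]]], sets[[cmb[2, i]]])
      if (oc >= overlap_min)
        edges[[length(edges) + 1]] <- data.frame(
          set_a = cmb[1, i], set_b = cmb[2, i], overlap = oc,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(edges))
    return(data.frame(set_a = character(0), set_b = character(0),
                      overlap = numeric(0)))
  do.call(rbind, edges)
}
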