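ANCHOR_GENES <- c(ATP2B4 = "ATP2B4", ATP2A2 = "ATP2A2")
REFERENCE_GENES <- c("B2M", "RPL30")

#' Simulation configuration for synthetic myometrial cohorts
#'
#' Defines the statistical structure the analysis stages assume: negative
#' binomial counts with a dispersion-mean trend and library-size/batch
#' variation, a planted quiescent (Q) vs nonquiescent (NQ) contrast affecting
#' a configurable fraction of genes, anticorrelated anchor genes ATP2B4
#' (lower in NQ) and ATP2A2 (higher in NQ), qPCR Ct values consistent with
#' the planted expression, and clinical covariates conditionally dependent on
#' the latent phenotype with a configurable clinical/molecular mismatch rate.
#'
#' Cohort defaults mirror the study design the package targets: 5 term-labor
#' (TL, latently NQ) and 5 term-not-in-labor (TNL, latently Q) reference
#' samples plus 21 preterm samples of which 4 are latently NQ, and a planted
#' contrast touching 21% of genes at |linear fold change| >= 1.5.
#'
#' @param n_genes number of genes (anchor and reference genes included).
#' @param n_TL,n_TNL,n_PTB_NQ,n_PTB_Q group sizes.
#' @param de_fraction fraction of genes carrying a planted Q/NQ effect
#'   (anchor genes are always planted and are exempt from this lottery).
#' @param min_planted_lfc minimum |log2 fold change| of planted genes.
#' @param lfc_scale mean excess of |log2FC| above the minimum (exponential).
#' @param lfc_atp2b4,lfc_atp2a2 anchor log2 fold changes, NQ vs Q.
#' @param disp_a0,disp_a1 dispersion trend alpha(mu) = a0/mu + a1.
#' @param libsize_sd sd of log-normal library-size factors.
#' @param n_batches number of sequencing batches. Term samples always sit in
#'   batch 1 (they were sequenced together); preterm samples are spread
#'   across batches.
#' @param batch_sd per-gene, per-batch log2 fold sd of batch effects.
#' @param ct_intercept qPCR calibration constant c0 in Ct = c0 - log2(expr).
#' @param ct_noise_sd per-well Ct measurement noise sd (cycles).
#' @param clinical named list of phenotype-conditional emission parameters;
#'   see Details in the package vignette. Probabilities must lie in [0, 1].
#' @param mismatch_rate probability that a sample's clinical presentation is
#'   emitted from the opposite phenotype's distribution (so that, e.g., a
#'   clinically laboring record carries a molecularly Q phenotype).
#' @param seed optional integer seed; fixed seed gives identical output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20000,
                       n_TL = 5, n_TNL = 5, n_PTB_NQ = 4, n_PTB_Q = 17,
                       de_fraction = 0.21,
                       min_planted_lfc = log2(1.5),
                       lfc_scale = 0.35,
                       lfc_atp2b4 = -1.5,
                       lfc_atp2a2 = 0.9,
                       disp_a0 = 5, disp_a1 = 0.05,
                       libsize_sd = 0.2,
                       n_batches = 2, batch_sd = 0.1,
                       ct_intercept = 34, ct_noise_sd = 0.15,
                       clinical = NULL,
                       mismatch_rate = 0.15,
                       seed = NULL) {
  cfg <- list(n_genes = n_genes, n_TL = n_TL, n_TNL = n_TNL,
              n_PTB_NQ = n_PTB_NQ, n_PTB_Q = n_PTB_Q,
              de_fraction = de_fraction, min_planted_lfc = min_planted_lfc,
              lfc_scale = lfc_scale, lfc_atp2b4 = lfc_atp2b4,
              lfc_atp2a2 = lfc_atp2a2, disp_a0 = disp_a0, disp_a1 = disp_a1,
              libsize_sd = libsize_sd, n_batches = n_batches,
              batch_sd = batch_sd, ct_intercept = ct_intercept,
              ct_noise_sd = ct_noise_sd,
              clinical = clinical %||% default_clinical_emission(),
              mismatch_rate = mismatch_rate, seed = seed,
              rng = "Mersenne-Twister/Inversion/Rejection")
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

default_clinical_emission <- function() {
  list(
    # P(absent, irregular_or_receded, regular_with_cervical_change)
    contraction_probs = list(NQ = c(0.00, 0.05, 0.95),
                             Q  = c(0.70, 0.30, 0.00)),
    # binomial(10, p) cervical dilation
    dilation_p = c(NQ = 0.5, Q = 0.05),
    rupture_p = c(NQ = 0.5, Q = 0.15),
    # preterm cases only: P(absent, suspected_or_confirmed, unknown)
    triple_i_probs = c(0.55, 0.40, 0.05)
  )
}

validate_sim_config <- function(cfg) {
  sizes <- c(cfg$n_TL, cfg$n_TNL, cfg$n_PTB_NQ, cfg$n_PTB_Q)
  if (any(sizes < 0)) stop("group sizes must be >= 0")
  if (sum(sizes) == 0) stop("at least one group must be non-empty")
  if (cfg$de_fraction < 0 || cfg$de_fraction >= 1)
    stop("de_fraction must lie in [0, 1)")
  if (cfg$mismatch_rate < 0 || cfg$mismatch_rate > 1)
    stop("mismatch_rate must lie in [0, 1]")
  probs <- unlist(cfg$clinical)
  if (any(probs < 0 | probs > 1)) stop("clinical probabilities must lie in [0, 1]")
  if (cfg$n_genes < 10) stop("n_genes too small (anchors + references required)")
  invisible(cfg)
}

set_sim_seed <- function(seed, offset = 0L) {
  if (!is.null(seed))
    set.seed(as.integer(seed) + offset, kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Simulate a gene x sample count matrix with planted Q/NQ structure
#'
#' Counts are drawn from a negative binomial model
#' `k_ij ~ NB(mean = s_j * q_i * 2^(lfc_i * z_j) * b_ij, dispersion = a0/q_i + a1)`
#' where `s_j` is a log-normal library-size factor, `q_i` a log-normal
#' baseline mean, `z_j` the latent phenotype indicator (1 = NQ), `lfc_i` the
#' planted log2 fold change and `b_ij` a per-gene batch multiplier. Exactly
#' `round(de_fraction * n_genes)` genes carry `|lfc| >= min_planted_lfc`
#' (anchors included in that count when `de_fraction > 0`; when
#' `de_fraction = 0` the anchors are still planted, a documented exception).
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_counts` with elements `counts`
#'   (a [count_matrix()]), `gene_truth` (gene, true_lfc, is_de),
#'   `sample_truth` (sample_id, group, true_phenotype, size_factor, batch,
#'   true_ratio) and `true_expr` (true linear expression of anchor and
#'   reference genes, genes x samples).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set_sim_seed(config$seed, 0L)
  n_special <- length(ANCHOR_GENES) + length(REFERENCE_GENES)
  n_other <- config$n_genes - n_special
  genes <- c(unname(ANCHOR_GENES), REFERENCE_GENES,
             sprintf("SYNG%05d", seq_len(n_other)))

  # baseline means: anchors and references robustly expressed
  q <- numeric(config$n_genes)
  names(q) <- genes
  q["ATP2B4"] <- 1500
  q["ATP2A2"] <- 300
  q["B2M"] <- 4000
  q["RPL30"] <- 2500
  q[-(1:n_special)] <- stats::rlnorm(n_other, meanlog = log(60), sdlog = 1.5)

  # planted log2 fold changes (NQ vs Q)
  lfc <- numeric(config$n_genes)
  names(lfc) <- genes
  lfc["ATP2B4"] <- config$lfc_atp2b4
  lfc["ATP2A2"] <- config$lfc_atp2a2
  n_de_total <- round(config$de_fraction * config$n_genes)
  n_de_other <- max(0L, n_de_total - length(ANCHOR_GENES))
  if (config$de_fraction > 0 && n_de_other > 0) {
    eligible <- genes[-(1:n_special)]
    de_genes <- sample(eligible, n_de_other)
    magnitude <- config$min_planted_lfc +
      stats::rexp(n_de_other, rate = 1 / config$lfc_scale)
    signs <- sample(c(-1, 1), n_de_other, replace = TRUE)
    lfc[de_genes] <- signs * magnitude
  }
  is_de <- abs(lfc) >= config$min_planted_lfc & lfc != 0

  # samples and latent phenotypes: TL and PTB_NQ are nonquiescent
  groups <- c(rep("TL", config$n_TL), rep("TNL", config$n_TNL),
              rep("PTB", config$n_PTB_NQ + config$n_PTB_Q))
  phen <- c(rep("NQ", config$n_TL), rep("Q", config$n_TNL),
            rep("NQ", config$n_PTB_NQ), rep("Q", config$n_PTB_Q))
  n_s <- length(groups)
  ids <- sprintf("%s%02d", groups, stats::ave(seq_len(n_s), groups,
                                              FUN = seq_along))
  z <- as.numeric(phen == "NQ")

  # library sizes, unit geometric mean
  s <- stats::rlnorm(n_s, 0, config$libsize_sd)
  s <- s / exp(mean(log(s)))

  # batches: term samples sequenced together in batch 1
  batch <- rep("b1", n_s)
  if (config$n_batches > 1) {
    ptb <- which(groups == "PTB")
    batch[ptb] <- sprintf("b%d", 1 + (seq_along(ptb) %% config$n_batches))
  }
  # per-gene batch log2 offsets, batch 1 is reference
  batch_levels <- sort(unique(batch))
  beff <- matrix(0, config$n_genes, length(batch_levels),
                 dimnames = list(genes, batch_levels))
  if (length(batch_levels) > 1 && config$batch_sd > 0)
    beff[, -1] <- stats::rnorm(config$n_genes * (length(batch_levels) - 1),
                               0, config$batch_sd)

  log2mu <- outer(log2(q), rep(1, n_s)) +
    outer(lfc, z) +
    beff[, match(batch, batch_levels), drop = FALSE] +
    matrix(log2(s), config$n_genes, n_s, byrow = TRUE)
  mu <- 2^log2mu
  alpha <- config$disp_a0 / q + config$disp_a1
  k <- matrix(stats::rnbinom(length(mu), mu = mu,
                             size = rep(1 / alpha, n_s)),
              config$n_genes, n_s, dimnames = list(genes, ids))

  ratio_true <- (q["ATP2B4"] * 2^(config$lfc_atp2b4 * z)) /
                (q["ATP2A2"] * 2^(config$lfc_atp2a2 * z))
  assay_genes <- c(unname(ANCHOR_GENES), REFERENCE_GENES)
  true_expr <- outer(q[assay_genes], rep(1, n_s)) * 2^outer(lfc[assay_genes], z)
  colnames(true_expr) <- ids

  structure(list(
    counts = count_matrix(k, batch = batch),
    gene_truth = data.frame(gene = genes, true_lfc = unname(lfc),
                            is_de = unname(is_de), baseline_mean = unname(q),
                            stringsAsFactors = FALSE),
    sample_truth = data.frame(sample_id = ids, group = groups,
                              true_phenotype = phen, size_factor = s,
                              batch = batch, true_ratio = unname(ratio_true),
                              stringsAsFactors = FALSE),
    true_expr = true_expr,
    config = config), class = "sim_counts")
}

#' Simulate qPCR Ct values consistent with planted expression
#'
#' Generates duplicate-well cycle thresholds `Ct = c0 - log2(expr) + noise`
#' for the anchor (ATP2B4, ATP2A2) and reference (B2M, RPL30) genes, so that
#' at zero noise the comparative-Ct ratio `2^-(Ct_ATP2B4 - Ct_ATP2A2)`
#' recovers the planted per-sample expression ratio exactly.
#'
#' @param expr either a `sim_counts` object or a linear expression matrix
#'   (genes x samples) containing at least the anchor genes.
#' @param config a [sim_config()].
#' @return a `ct_table` data.frame (sample_id, assay, well, ct).
#' @export
simulate_ct <- function(expr, config) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(expr, "sim_counts")) expr <- expr$true_expr
  if (!is.matrix(expr)) stop("expr must be a matrix or sim_counts object")
  missing_anchor <- setdiff(unname(ANCHOR_GENES), rownames(expr))
  if (length(missing_anchor))
    stop(sprintf("anchor gene(s) missing from expression: %s",
                 paste(missing_anchor, collapse = ", ")))
  set_sim_seed(config$seed, 1L)
  assays <- intersect(c(unname(ANCHOR_GENES), REFERENCE_GENES), rownames(expr))
  samples <- colnames(expr)
  grid <- expand.grid(well = 1:2, assay = assays, sample_id = samples,
                      stringsAsFactors = FALSE)
  true_ct <- config$ct_intercept -
    log2(expr[cbind(grid$assay, grid$sample_id)])
  grid$ct <- true_ct + stats::rnorm(nrow(grid), 0, config$ct_noise_sd)
  out <- grid[, c("sample_id", "assay", "well", "ct")]
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Simulate clinical covariates conditional on the latent phenotype
#'
#' Each sample's clinical presentation (contractions, cervical dilation,
#' membrane status, Triple I) is emitted from the conditional distribution of
#' its latent molecular phenotype; with probability `mismatch_rate` the
#' opposite phenotype's distribution is used instead, modelling cases whose
#' clinical picture disagrees with the molecular state of the myometrium.
#' Term reference samples keep their definitional labels (TL spontaneous
#' laboring, TNL elective cesarean without labor); preterm samples receive a
#' clinical subgroup (sPTL / PPROM / PI) consistent with the emitted fields.
#'
#' @param sim a `sim_counts` object (provides latent phenotypes).
#' @param config a [sim_config()].
#' @return a `sample_table` data.frame with clinical fields, reference
#'   `phenotype_label` for term samples, and truth columns `true_phenotype`
#'   and `clinical_mismatch`.
#' @export
simulate_clinical <- function(sim, config) {
  stopifnot(inherits(sim, "sim_counts"), inherits(config, "sim_config"))
  set_sim_seed(config$seed, 2L)
  st <- sim$sample_truth
  n <- nrow(st)
  cl <- config$clinical
  mismatch <- stats::runif(n) < config$mismatch_rate
  emit <- ifelse(mismatch, ifelse(st$true_phenotype == "Q", "NQ", "Q"),
                 st$true_phenotype)

  term <- st$group %in% c("TL", "TNL")
  ga <- ifelse(term, stats::runif(n, 38, 41), stats::runif(n, 24, 33))

  contraction_levels <- c("absent", "irregular_or_receded",
                          "regular_with_cervical_change")
  contractions <- vapply(emit, function(e)
    sample(contraction_levels, 1, prob = cl$contraction_probs[[e]]),
    character(1))
  dilation <- stats::rbinom(n, 10, cl$dilation_p[emit])
  membranes <- ifelse(stats::runif(n) < cl$rupture_p[emit],
                      "ruptured", "intact")
  triple_i <- ifelse(term, "absent",
                     vapply(seq_len(n), function(i)
                       sample(c("absent", "suspected_or_confirmed", "unknown"),
                              1, prob = cl$triple_i_probs), character(1)))

  # definitional fields for term reference groups
  contractions[st$group == "TL"] <- "regular_with_cervical_change"
  contractions[st$group == "TNL"] <- "absent"
  dilation[st$group == "TNL"] <- 0L
  membranes[st$group == "TNL"] <- "intact"

  laboring <- contractions != "absent"
  spont <- st$group == "TL" |
    (st$group == "PTB" & (laboring | membranes == "ruptured"))
  provider <- !spont

  group <- st$group
  ptb <- st$group == "PTB"
  group[ptb & membranes == "ruptured"] <- "PTB-PPROM"
  group[ptb & membranes != "ruptured" & laboring] <- "PTB-sPTL"
  group[ptb & membranes != "ruptured" & !laboring] <- "PTB-PI"
  # PI definition excludes dilation
  dilation[group == "PTB-PI"] <- 0L

  out <- data.frame(
    sample_id = st$sample_id,
    group = group,
    phenotype_label = ifelse(st$group == "TL", "NQ",
                             ifelse(st$group == "TNL", "Q", NA_character_)),
    batch = st$batch,
    incision = ifelse(term, "low-transverse",
                      sample(c("low-transverse", "classical"), n, replace = TRUE)),
    ga_weeks = round(ga, 1),
    contractions_raw = contractions,
    dilation_cm = as.integer(dilation),
    membranes = membranes,
    triple_i = triple_i,
    spontaneous_onset = spont,
    provider_initiated = provider,
    true_phenotype = st$true_phenotype,
    clinical_mismatch = mismatch,
    stringsAsFactors = FALSE)
  class(out) <- c("sample_table", "data.frame")
  out
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates [simulate_counts()], [simulate_clinical()] and
#' [simulate_ct()] under a single seed. With a fixed seed the output is
#' byte-identical across runs (Mersenne-Twister RNG, inversion normals).
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed overriding `config$seed`.
#' @return a list of class `synthetic_cohort` with elements `counts`
#'   ([count_matrix()]), `samples` (`sample_table` with truth columns), `ct`
#'   (`ct_table`), `gene_truth`, `sample_truth` and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  sim <- simulate_counts(config)
  samples <- simulate_clinical(sim, config)
  ct <- simulate_ct(sim, config)
  structure(list(counts = sim$counts, samples = samples, ct = ct,
                 gene_truth = sim$gene_truth, sample_truth = sim$sample_truth,
                 true_expr = sim$true_expr, config = config),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to a directory
#'
#' Emits counts.tsv, samples.tsv, ct.tsv and truth.tsv.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(cohort$counts, file.path(dir, "counts.tsv"))
  write_table(cohort$samples, file.path(dir, "samples.tsv"))
  write_table(cohort$ct, file.path(dir, "ct.tsv"))
  write_table(cohort$gene_truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
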