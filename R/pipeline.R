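PIPELINE_KEYS <- c("counts", "samples", "ct", "gmt", "simulate", "sim",
                   "seed", "out_dir", "min_fc", "max_fdr", "scale_pca",
                   "transitional_band", "nperm", "size_min", "size_max",
                   "gsea_weight", "r_min", "anchor_num", "anchor_den",
                   "log_level")

pipeline_defaults <- function() {
  list(simulate = FALSE, seed = 1L, min_fc = 1.5, max_fdr = 0.1,
       scale_pca = FALSE, transitional_band = 0, nperm = 1000,
       size_min = 15, size_max = 500, gsea_weight = 1, r_min = 0.95,
       anchor_num = "ATP2B4", anchor_den = "ATP2A2", log_level = "info")
}

#' Validate a pipeline configuration
#'
#' Checks a configuration (a YAML file path or an R list) against the
#' pipeline schema, reporting all violations at once rather than stopping at
#' the first.
#'
#' @param config a path to a YAML config file, or a named list.
#' @return character vector of problems; `character(0)` means valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(sprintf("config file not found: %s", config))
    if (file.size(config) == 0) return("config file is empty")
    config <- tryCatch(yaml::read_yaml(config), error = function(e)
      sprintf("unreadable config: %s", conditionMessage(e)))
    if (is.character(config)) return(config)
    if (is.null(config)) return("config file is empty")
  }
  if (!is.list(config)) return("config must be a mapping of keys to values")
  probs <- character(0)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown))
    probs <- c(probs, sprintf("unknown key(s): %s",
                              paste(unknown, collapse = ", ")))
  num_pos <- c(min_fc = 1, nperm = 1, size_min = 1, size_max = 1, r_min = -1)
  for (k in names(num_pos)) {
    if (!is.null(config[[k]]) &&
        (!is.numeric(config[[k]]) || config[[k]] < num_pos[[k]]))
      probs <- c(probs, sprintf("'%s' must be numeric >= %s", k, num_pos[[k]]))
  }
  if (!is.null(config$max_fdr) &&
      (!is.numeric(config$max_fdr) || config$max_fdr <= 0 || config$max_fdr > 1))
    probs <- c(probs, "'max_fdr' must lie in (0, 1]")
  if (!is.null(config$transitional_band) &&
      (!is.numeric(config$transitional_band) || config$transitional_band < 0))
    probs <- c(probs, "'transitional_band' must be >= 0")
  if (!isTRUE(config$simulate)) {
    for (k in c("counts", "samples")) {
      if (is.null(config[[k]])) {
        probs <- c(probs, sprintf("'%s' path required unless simulate: true", k))
      } else if (!file.exists(config[[k]])) {
        probs <- c(probs, sprintf("'%s' file not found: %s", k, config[[k]]))
      }
    }
    for (k in c("ct", "gmt")) {
      if (!is.null(config[[k]]) && !file.exists(config[[k]]))
        probs <- c(probs, sprintf("'%s' file not found: %s", k, config[[k]]))
    }
  }
  probs
}

#' Synthetic gene-set collection from simulation truth
#'
#' Builds a gene-set collection for exercising the enrichment stage on a
#' synthetic cohort: one set of planted up-regulated genes, one of planted
#' down-regulated genes, and `n_random` sets drawn uniformly from the gene
#' universe (null sets).
#'
#' @param gene_truth the `gene_truth` table of a [simulate_cohort()] result.
#' @param n_random number of random null sets.
#' @param planted_size size of each planted set.
#' @param size_range size range of the random sets.
#' @param seed optional integer seed.
#' @return a `gene_sets` collection.
#' @export
synthetic_gene_sets <- function(gene_truth, n_random = 30, planted_size = 50,
                                size_range = c(15, 100), seed = NULL) {
  set_sim_seed(seed, 0L)
  up <- gene_truth$gene[gene_truth$is_de & gene_truth$true_lfc > 0]
  dn <- gene_truth$gene[gene_truth$is_de & gene_truth$true_lfc < 0]
  sets <- list()
  if (length(up) >= 5)
    sets$PLANTED_UP <- sample(up, min(planted_size, length(up)))
  if (length(dn) >= 5)
    sets$PLANTED_DOWN <- sample(dn, min(planted_size, length(dn)))
  for (i in seq_len(n_random)) {
    k <- sample(seq(size_range[1], size_range[2]), 1)
    sets[[sprintf("RANDOM_%03d", i)]] <- sample(gene_truth$gene, k)
  }
  structure(sets, description = stats::setNames(rep("synthetic", length(sets)),
                                                names(sets)),
            class = c("gene_sets", "list"))
}

#' Run the end-to-end phenotyping pipeline
#'
#' Stage order: clinical scoring, TL-vs-TNL differential expression and
#' signature filtering, reference PCA with projection of the remaining
#' samples and Q/NQ phenotype calling, clinical correlation, gene-set
#' enrichment (NQ vs Q), ATP2B4/ATP2A2 ratio computation (RNA-seq and, when
#' Ct data are present, qPCR) with ROC threshold selection and
#' classification, and anchor-correlated gene panels. Writes de.tsv,
#' scores.tsv, phenotypes.tsv, gsea.tsv, ratios.tsv, roc.tsv, panel.tsv and
#' a run manifest to the output directory; the manifest is written even when
#' a stage fails (recording the failure point) before the error propagates.
#'
#' @param config a named list or YAML path (see [validate_config()]). With
#'   `simulate: TRUE` a synthetic cohort is generated under `seed` instead of
#'   reading input files.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    probs <- validate_config(config)
    if (length(probs)) stop(paste(probs, collapse = "; "))
    config <- yaml::read_yaml(config)
  } else {
    probs <- validate_config(config)
    if (length(probs)) stop(paste(probs, collapse = "; "))
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  out_dir <- out_dir %||% cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(package = "myoquiesce",
                   version = as.character(utils::packageVersion("myoquiesce")),
                   seed = cfg$seed, rng = "Mersenne-Twister/Inversion/Rejection",
                   config = config, started = format(Sys.time(), tz = "UTC"),
                   stages = list(), status = "running")
  write_manifest <- function() {
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$status <<- sprintf("failed at stage '%s': %s", name,
                                  conditionMessage(e))
      write_manifest()
      stop(e)
    })
    manifest$stages[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  results <- list()
  # inputs
  inputs <- stage("load", {
    if (isTRUE(cfg$simulate)) {
      sim_args <- cfg[["sim"]] %||% list()
      sim_args$seed <- cfg$seed
      sc <- do.call(sim_config, sim_args)
      cohort <- simulate_cohort(sc)
      sets <- synthetic_gene_sets(cohort$gene_truth, seed = cfg$seed)
      list(counts = cohort$counts, samples = cohort$samples, ct = cohort$ct,
           sets = sets, cohort = cohort)
    } else {
      counts <- read_counts(cfg$counts)
      samples <- read_sample_table(cfg$samples)
      ct <- if (!is.null(cfg$ct)) read_ct_table(cfg$ct) else NULL
      sets <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL
      list(counts = counts, samples = samples, ct = ct, sets = sets)
    }
  })
  counts <- inputs$counts
  samples <- inputs$samples
  samples <- samples[match(counts$samples, samples$sample_id), ]

  scores <- stage("clinical_scoring", {
    sc <- score_clinical(samples)
    write_table(sc, file.path(out_dir, "scores.tsv"))
    sc
  })

  de <- stage("de_signature", {
    term <- samples$group %in% c("TL", "TNL")
    if (sum(samples$group == "TL") < 2 || sum(samples$group == "TNL") < 2)
      stop("need >= 2 TL and >= 2 TNL samples for the reference contrast")
    term_counts <- subset_counts(counts, samples = samples$sample_id[term])
    d <- test_de(term_counts, group = samples$group[term],
                 contrast = c("TL", "TNL"))
    sig <- signature_filter(d, min_fc = cfg$min_fc, max_fdr = cfg$max_fdr)
    write_table(sig$table, file.path(out_dir, "de.tsv"))
    list(de = d, signature = sig)
  })
  if (length(de$signature$genes) < 2)
    stop("signature is empty; cannot fit the reference PCA")

  phen <- stage("phenotype_pca", {
    sf_all <- size_factors(counts)
    term <- samples$group %in% c("TL", "TNL")
    term_ids <- samples$sample_id[term]
    labels <- ifelse(samples$group[term] == "TL", "NQ", "Q")
    model <- fit_reference_pca(
      subset_counts(counts, samples = term_ids),
      signature = de$signature$genes, labels = labels,
      scale = isTRUE(cfg$scale_pca), factors = sf_all[term_ids])
    proj <- project_pca(model, counts, factors = sf_all)
    calls <- assign_phenotype(proj[, 1], model,
                              transitional_band = cfg$transitional_band)
    tab <- data.frame(sample_id = rownames(proj),
                      round(proj[, seq_len(min(5, ncol(proj))), drop = FALSE], 6),
                      phenotype_call = calls,
                      dist_to_NQ = abs(proj[, 1] - model$centroids["NQ"]),
                      dist_to_Q = abs(proj[, 1] - model$centroids["Q"]),
                      stringsAsFactors = FALSE, row.names = NULL)
    write_table(tab, file.path(out_dir, "phenotypes.tsv"))
    corr <- correlate_clinical(
      stats::setNames(proj[, 1], rownames(proj)),
      scores[, c("sample_id", "contraction_score", "dilation_score",
                 "membrane_score", "triple_i_score")],
      seed = cfg$seed)
    list(model = model, scores = proj, calls = calls, clinical_corr = corr)
  })

  gsea_res <- stage("enrichment", {
    if (is.null(inputs$sets)) {
      out <- data.frame(set = character(0), size = integer(0),
                        es = numeric(0), nes = numeric(0), p = numeric(0),
                        fdr = numeric(0), leading_edge = character(0))
      message("no gene sets supplied; enrichment stage skipped")
    } else {
      lab <- phen$calls
      if (sum(lab == "NQ") < 2 || sum(lab == "Q") < 2) {
        message("called phenotypes too unbalanced for enrichment; skipped")
        out <- data.frame(set = character(0), size = integer(0),
                          es = numeric(0), nes = numeric(0), p = numeric(0),
                          fdr = numeric(0), leading_edge = character(0))
      } else {
        out <- suppressWarnings(gsea(counts, labels = lab, sets = inputs$sets,
                                     contrast = c("NQ", "Q"),
                                     nperm = cfg$nperm,
                                     size_min = cfg$size_min,
                                     size_max = cfg$size_max,
                                     weight = cfg$gsea_weight,
                                     seed = cfg$seed))
      }
    }
    write_table(as.data.frame(out), file.path(out_dir, "gsea.tsv"))
    out
  })

  ratio_res <- stage("ratio_classifier", {
    rr <- ratio_from_counts(counts, num = cfg$anchor_num, den = cfg$anchor_den)
    rr_all <- rr
    if (!is.null(inputs$ct)) {
      rq <- ratio_from_ct(inputs$ct, num = cfg$anchor_num, den = cfg$anchor_den)
      rr_all <- rbind(rr[, c("sample_id", "ratio", "source")],
                      rq[, c("sample_id", "ratio", "source")])
    } else rq <- NULL
    write_table(rr_all, file.path(out_dir, "ratios.tsv"))
    roc <- ratio_roc(rr, stats::setNames(phen$calls, counts$samples))
    curve <- roc$curve
    curve$auc <- roc$auc
    curve$chosen <- curve$threshold == roc$threshold
    write_table(curve, file.path(out_dir, "roc.tsv"))
    calls <- classify_ratio(rr, roc$threshold,
                            transitional_band = cfg$transitional_band)
    list(rnaseq = rr, qpcr = rq, roc = roc, calls = calls)
  })

  panel <- stage("correlated_panel", {
    p1 <- correlated_panel(counts, cfg$anchor_num, r_min = cfg$r_min)
    p2 <- correlated_panel(counts, cfg$anchor_den, r_min = cfg$r_min)
    p1$anchor <- rep(cfg$anchor_num, nrow(p1))
    p2$anchor <- rep(cfg$anchor_den, nrow(p2))
    out <- rbind(p1, p2)
    write_table(out, file.path(out_dir, "panel.tsv"))
    out
  })

  manifest$status <- "ok"
  manifest$finished <- format(Sys.time(), tz = "UTC")
  write_manifest()
  invisible(list(inputs = inputs, scores = scores, de = de, phenotype = phen,
                 gsea = gsea_res, ratio = ratio_res, panel = panel,
                 out_dir = out_dir))
}
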