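#' Semiquantitative clinical phenotype scoring
#'
#' Encodes the clinical phenotyping scheme used to characterize the likelihood
#' that a pregnancy was progressing toward spontaneous labor at the time of
#' cesarean delivery:
#'
#' * gestational age, dichotomized into term (score 1, delivery > 37 weeks)
#'   and preterm (score 0, delivery < 34 weeks); deliveries at 34-37 weeks
#'   fall outside the dichotomy and are flagged `"indeterminate"` rather than
#'   silently coerced;
#' * uterine contractions on a 0-2 scale (0, absent; 1, irregular without
#'   cervical change or contractions that receded after tocolysis; 2, regular
#'   and followed by cervical change);
#' * cervical dilation, 0-10 cm as recorded at the last exam;
#' * membrane status, 0 (intact) or 1 (ruptured);
#' * Triple I (intraamniotic infection/inflammation), 0 (absent) or
#'   1 (suspected or confirmed); unknown status propagates as `NA`.
#'
#' @param record a list or one-row data.frame with fields `ga_weeks` (real),
#'   `contractions_raw` (one of "absent", "irregular_or_receded",
#'   "regular_with_cervical_change"), `dilation_cm` (integer 0-10),
#'   `membranes` ("intact"/"ruptured"), `triple_i` ("absent",
#'   "suspected_or_confirmed", "unknown").
#' @return a list with components `ga_score` (0, 1 or "indeterminate"),
#'   `contraction_score` (0/1/2), `dilation_score` (0-10), `membrane_score`
#'   (0/1) and `triple_i_score` (0/1/NA).
#' @export
score_case <- function(record) {
  ga <- as.numeric(record$ga_weeks)
  if (is.na(ga) || ga <= 15 || ga >= 45)
    stop("ga_weeks must lie in (15, 45)")
  dil <- as.integer(record$dilation_cm)
  if (is.na(dil) || dil < 0 || dil > 10)
    stop("dilation_cm must be an integer in [0, 10]")

  ga_score <- if (ga > 37) 1L else if (ga < 34) 0L else "indeterminate"
  contraction_score <- switch(as.character(record$contractions_raw),
    absent = 0L,
    irregular_or_receded = 1L,
    regular_with_cervical_change = 2L,
    stop(sprintf("unknown contractions_raw value: %s",
                 record$contractions_raw)))
  membrane_score <- switch(as.character(record$membranes),
    intact = 0L, ruptured = 1L,
    stop(sprintf("unknown membranes value: %s", record$membranes)))
  triple_i_score <- switch(as.character(record$triple_i),
    absent = 0L,
    suspected_or_confirmed = 1L,
    unknown = NA_integer_,
    stop(sprintf("unknown triple_i value: %s", record$triple_i)))

  list(ga_score = ga_score,
       contraction_score = contraction_score,
       dilation_score = dil,
       membrane_score = membrane_score,
       triple_i_score = triple_i_score)
}

#' Score all cases in a sample table
#'
#' Applies [score_case()] row-wise and returns a score table mirroring the
#' clinical heatmap layout (one row per sample, one column per score).
#'
#' @param samples a `sample_table` (or data.frame) carrying the clinical
#'   fields named in [score_case()].
#' @return data.frame with columns sample_id, ga_score, contraction_score,
#'   dilation_score, membrane_score, triple_i_score. `ga_score` is character
#'   ("0", "1" or "indeterminate").
#' @export
score_clinical <- function(samples) {
  stopifnot(is.data.frame(samples))
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    s <- score_case(as.list(samples[i, ]))
    data.frame(sample_id = samples$sample_id[i],
               ga_score = as.character(s$ga_score),
               contraction_score = s$contraction_score,
               dilation_score = s$dilation_score,
               membrane_score = s$membrane_score,
               triple_i_score = s$triple_i_score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign a case to a clinical delivery group
#'
#' Group definitions:
#' * `Gr1_TL`: term birth following spontaneous onset of term labor;
#' * `Gr2_TNL`: term birth by cesarean, not in labor;
#' * `Gr3_PTB_sPTL`: preterm birth following spontaneous preterm labor with
#'   intact membranes;
#' * `Gr4_PTB_PPROM`: preterm birth following prelabor rupture of membranes;
#' * `Gr5_PTB_PI`: provider-initiated preterm birth in the absence of active
#'   labor contractions, cervical dilation, or membrane rupture.
#'
#' Records with contradictory flags (e.g., a provider-initiated preterm case
#' with regular contractions, violating the Group 5 definition) return
#' `"unclassified"`. Deliveries in the 34-37-week band fall outside the
#' term/preterm dichotomy and are also unclassified.
#'
#' @param record as for [score_case()], additionally requiring
#'   `spontaneous_onset` and `provider_initiated` logical fields.
#' @return one of "Gr1_TL", "Gr2_TNL", "Gr3_PTB_sPTL", "Gr4_PTB_PPROM",
#'   "Gr5_PTB_PI", "unclassified".
#' @export
assign_group <- function(record) {
  sc <- score_case(record)
  spont <- isTRUE(as.logical(record$spontaneous_onset))
  provider <- isTRUE(as.logical(record$provider_initiated))
  laboring <- sc$contraction_score == 2L
  any_labor <- sc$contraction_score > 0L
  ruptured <- sc$membrane_score == 1L
  dilated <- sc$dilation_score > 0L

  if (identical(sc$ga_score, "indeterminate")) return("unclassified")
  if (sc$ga_score == 1L) {
    if (spont && laboring) return("Gr1_TL")
    if (!spont && !any_labor) return("Gr2_TNL")
    return("unclassified")
  }
  # preterm
  if (provider) {
    # provider-initiated PTB requires absence of labor, dilation and rupture
    if (!any_labor && !dilated && !ruptured && !spont) return("Gr5_PTB_PI")
    return("unclassified")
  }
  if (spont && ruptured) return("Gr4_PTB_PPROM")
  if (spont && !ruptured) return("Gr3_PTB_sPTL")
  "unclassified"
}
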