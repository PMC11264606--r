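# Back-pain impact instrument scoring. Each scorer accepts a numeric
# vector of one respondent's items or an n-by-k matrix / data frame; any
# missing item yields a missing score (no imputation), and out-of-range
# items are a validation error.

.items_matrix <- function(items, k, lo, hi, what, integer_only = TRUE) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.numeric(items) && is.null(dim(items))) items <- matrix(items, nrow = 1)
  if (!is.matrix(items) || ncol(items) != k)
    stop(sprintf("validation error: %s requires %d items", what, k), call. = FALSE)
  v <- items[is.finite(items)]
  if (any(v < lo) || any(v > hi) || (integer_only && any(v != round(v))))
    stop(sprintf("validation error: %s items must be %s in %g..%g", what,
                 if (integer_only) "integers" else "values", lo, hi), call. = FALSE)
  items
}

.na_if_incomplete <- function(score, items) {
  score[rowSums(!is.finite(items)) > 0] <- NA_real_
  score
}

#' Score the Oswestry Disability Index (ODI)
#'
#' Ten items scored 0-5; the item sum is rescaled to 0-100
#' (`sum / 50 * 100`), higher = worse disability.
#'
#' @param items numeric vector of 10 items, or n-by-10 matrix/data frame.
#' @return Score(s) on 0-100; `NA` where any item is missing.
#' @export
score_odi <- function(items) {
  m <- .items_matrix(items, 10, 0, 5, "ODI")
  .na_if_incomplete(rowSums(m) / 50 * 100, m)
}

#' Score the Roland-Morris Disability Questionnaire (RMDQ)
#'
#' Sum of 24 dichotomous items, range 0-24, higher = worse impact.
#' @param items numeric vector of 24 binary items, or n-by-24 matrix.
#' @return Integer score(s) 0-24; `NA` where any item is missing.
#' @export
score_rmdq <- function(items) {
  m <- .items_matrix(items, 24, 0, 1, "RMDQ")
  .na_if_incomplete(rowSums(m), m)
}

#' Score the PEG scale
#'
#' Mean of the 3 items (pain intensity, interference with enjoyment of
#' life, interference with general activity), each 0-10.
#' @param items numeric vector of 3 items, or n-by-3 matrix.
#' @return Score(s) on 0-10; `NA` where any item is missing.
#' @export
score_peg <- function(items) {
  m <- .items_matrix(items, 3, 0, 10, "PEG")
  .na_if_incomplete(rowMeans(m), m)
}

#' Score the STarT Back screening tool
#'
#' Sum of 9 dichotomous items, range 0-9, higher = worse symptoms.
#' @param items numeric vector of 9 binary items, or n-by-9 matrix.
#' @return Integer score(s) 0-9; `NA` where any item is missing.
#' @export
score_startback <- function(items) {
  m <- .items_matrix(items, 9, 0, 1, "STarT Back")
  .na_if_incomplete(rowSums(m), m)
}

#' Score the Graded Chronic Pain Scale (GCPS)
#'
#' Two 3-item subscores (pain intensity; disability), each the item mean
#' rescaled to 0-100 (mean of the 0-10 items times 10, the instrument's
#' standard convention).
#'
#' @param intensity_items numeric vector of 3 items (0-10), or n-by-3 matrix.
#' @param disability_items numeric vector of 3 items (0-10), or n-by-3 matrix.
#' @return Data frame with columns `intensity` and `disability` (0-100).
#' @export
score_gcps <- function(intensity_items, disability_items) {
  mi <- .items_matrix(intensity_items, 3, 0, 10, "GCPS intensity")
  md <- .items_matrix(disability_items, 3, 0, 10, "GCPS disability")
  if (nrow(mi) != nrow(md))
    stop("validation error: intensity and disability must cover the same persons",
         call. = FALSE)
  data.frame(intensity = .na_if_incomplete(rowMeans(mi) * 10, mi),
             disability = .na_if_incomplete(rowMeans(md) * 10, md))
}

#' Chronic-pain classification (NIH task-force definition)
#'
#' A person is classified as having chronic pain when both flags hold: pain
#' persisting at least 3 months AND pain on at least half the days of the
#' past six months.
#'
#' @param duration_flag binary, pain persisted >= 3 months.
#' @param frequency_flag binary, pain on >= half the days in past 6 months.
#' @return Binary vector (`NA` where either flag is missing).
#' @export
classify_chronic_pain <- function(duration_flag, frequency_flag) {
  for (v in list(duration_flag, frequency_flag))
    if (any(!v[is.finite(v)] %in% c(0, 1)))
      stop("validation error: flags must be coded 0/1", call. = FALSE)
  as.integer(duration_flag == 1 & frequency_flag == 1)
}

#' Score all pain instruments from item-level columns
#'
#' Expects the conventional column layout `odi_1..odi_10`,
#' `rmdq_1..rmdq_24`, `peg_1..peg_3`, `sb_1..sb_9`, `gcps_i1..gcps_i3`,
#' `gcps_d1..gcps_d3`, and optionally `pain_duration_ge_3mo`,
#' `pain_half_days_6mo`. Instruments whose columns are absent are skipped.
#'
#' @param data person-level data frame.
#' @return `data` with score columns `odi`, `rmdq`, `peg`, `startback`,
#'   `gcps_intensity`, `gcps_disability`, `chronic_pain` appended (where
#'   computable).
#' @export
score_pain_instruments <- function(data) {
  grab <- function(prefix, k) {
    cols <- paste0(prefix, seq_len(k))
    if (all(cols %in% names(data))) as.matrix(data[, cols]) else NULL
  }
  if (!is.null(m <- grab("odi_", 10))) data$odi <- score_odi(m)
  if (!is.null(m <- grab("rmdq_", 24))) data$rmdq <- score_rmdq(m)
  if (!is.null(m <- grab("peg_", 3))) data$peg <- score_peg(m)
  if (!is.null(m <- grab("sb_", 9))) data$startback <- score_startback(m)
  mi <- grab("gcps_i", 3); md <- grab("gcps_d", 3)
  if (!is.null(mi) && !is.null(md)) {
    g <- score_gcps(mi, md)
    data$gcps_intensity <- g$intensity
    data$gcps_disability <- g$disability
  }
  if (all(c("pain_duration_ge_3mo", "pain_half_days_6mo") %in% names(data)))
    data$chronic_pain <- classify_chronic_pain(data$pain_duration_ge_3mo,
                                               data$pain_half_days_6mo)
  data
}
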