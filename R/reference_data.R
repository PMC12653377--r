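#' Reference data from a large-scale English reading comprehension assessment
#'
#' The package ships the published summaries of a provincial college
#' entrance English reading comprehension assessment (20 items, ~362k
#' examinees) whose raw responses are confidential. These summaries serve
#' as calibration targets for the synthetic-cohort generator and as
#' worked-example inputs; none of them is a substitute for raw data.
#'
#' * `reading_qmatrix()` — the expert-calibrated preliminary Q-matrix:
#'   20 items by 8 attributes (A1 difficult vocabulary, A2 complex
#'   sentences, A3 inter-sentence relationships, A4 rhetorical and
#'   organizational structure, A5 inference, A6 information matching,
#'   A7 option processing, A8 main idea). A8 is measured by only two
#'   items and is removed by the three-item rule, leaving the 7-attribute
#'   matrix used for diagnosis (`prune_attributes`).
#' * `reading_attribute_mastery()` — population mastery probabilities of
#'   the seven retained attributes.
#' * `reading_attribute_reliability()` — simulation-based attribute
#'   classification reliabilities reported for the assessment.
#' * `reading_cohort_counts()` — head counts of the cohort: total
#'   examinees, examinees in the 17 most frequent knowledge states,
#'   examinees in the remaining rare states, and the numbers of observed
#'   and rare states.
#' * `reading_dominant_path()` — the dominant learning trajectory
#'   reported for the cohort, as a chain of 7-attribute state strings
#'   from no mastery to full mastery (acquisition order
#'   A6, A2, A7, A3, A5, A4, A1).
#'
#' @return See each description; vectors are named by attribute.
#' @name reading_reference
NULL

#' @rdname reading_reference
#' @export
reading_qmatrix <- function() {
  read_qmatrix(system.file("extdata", "reading_qmatrix.csv",
                           package = "cdmpath", mustWork = TRUE))
}

#' @rdname reading_reference
#' @export
reading_attribute_mastery <- function() {
  c(A1 = 0.333, A2 = 0.582, A3 = 0.394, A4 = 0.364, A5 = 0.363,
    A6 = 0.858, A7 = 0.587)
}

#' @rdname reading_reference
#' @export
reading_attribute_reliability <- function() {
  c(A1 = 0.882, A2 = 0.823, A3 = 0.973, A4 = 0.820, A5 = 0.759,
    A6 = 0.947, A7 = 0.903)
}

#' @rdname reading_reference
#' @export
reading_cohort_counts <- function() {
  list(total_n = 361967L,
       retained_n = 351332L,
       excluded_n = 10635L,
       states_observed = 79L,
       states_retained = 17L,
       states_rare = 62L)
}

#' @rdname reading_reference
#' @export
reading_dominant_path <- function() {
  c("0000000", "0000010", "0100010", "0100011",
    "0110011", "0110111", "0111111", "1111111")
}
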