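#' Count distinct patients in a fixture table
#'
#' Patients appearing in several rows or sections (flagged "same
#' patient" in the curated tables) are counted once; idempotent under
#' row duplication.
#'
#' @param rows A fixture table from [load_fixture_table()] (or any data
#'   frame with a `patient_id` column).
#' @return Integer count of unique patient identifiers.
#' @export
distinct_patients <- function(rows) {
  if (is.null(rows$patient_id)) stop("rows must carry a patient_id column")
  length(unique(rows$patient_id))
}

#' Tally distinct patients matching a predicate
#'
#' @param rows A fixture table.
#' @param predicate Logical vector parallel to `rows`, or a function of
#'   the table returning one; default selects all rows.
#' @param denominator Positive integer denominator for the proportion.
#' @return A list with `numerator` (distinct matching patients),
#'   `denominator` and `proportion`.
#' @export
tally_patients <- function(rows, predicate = NULL, denominator) {
  if (denominator <= 0) stop("denominator must be positive")
  keep <- if (is.null(predicate)) rep(TRUE, nrow(rows))
          else if (is.function(predicate)) predicate(rows)
          else predicate
  stopifnot(is.logical(keep), length(keep) == nrow(rows))
  num <- distinct_patients(rows[keep, , drop = FALSE])
  list(numerator = num, denominator = denominator,
       proportion = num / denominator)
}

#' Cohort summary counts from the curated finding tables
#'
#' Recomputes the headline cohort metrics by de-duplicated
#' distinct-patient counting over the bundled targetable-alteration and
#' germline-finding tables: patients with at least one potentially
#' targetable alteration (overall and by disease group), patients who
#' received matched therapy, patients with clinically impactful
#' germline findings (overall and by disease group), and patients with
#' secondary findings.
#'
#' @return A list of [tally_patients()] results keyed by metric name.
#' @export
cohort_summary <- function() {
  den <- cohort_denominators()
  t2 <- load_fixture_table("table2")
  t4 <- load_fixture_table("table4")
  list(
    targetable = tally_patients(t2, denominator = den[["all"]]),
    targetable_solid = tally_patients(
      t2, t2$disease_group == "solid", den[["solid"]]),
    targetable_hematologic = tally_patients(
      t2, t2$disease_group == "hematologic", den[["hematologic"]]),
    matched_therapy = tally_patients(
      t2, t2$therapy_received, distinct_patients(t2)),
    germline_impactful = tally_patients(
      t4, denominator = den[["germline_tested"]]),
    germline_solid = tally_patients(
      t4, t4$disease_group == "solid", den[["solid_germline"]]),
    germline_hematologic = tally_patients(
      t4, t4$disease_group == "hematologic", den[["hematologic_germline"]]),
    acmg_secondary = tally_patients(
      t4, t4$section == "acmg", den[["germline_tested"]]))
}
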