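MATCH_THRESHOLD <- 0.5  # a drug is "recommended" when its score is strictly above

matching_result_row <- function(patient_id, courses, scores,
                                include_unscored = TRUE) {
  drug_scores <- scores[match(courses$drug, names(scores))]
  unscored <- is.na(drug_scores)
  n_unscored <- sum(unscored)
  if (!include_unscored) {
    courses <- courses[!unscored, , drop = FALSE]
    drug_scores <- drug_scores[!unscored]
    unscored <- unscored[!unscored]
  }
  n_courses <- nrow(courses)
  matched <- !is.na(drug_scores) & drug_scores > MATCH_THRESHOLD
  n_matched <- sum(matched)
  modified <- if (n_courses > 0L) 100 * n_matched / n_courses else NA_real_

  actionable <- names(scores)[scores > MATCH_THRESHOLD]
  n_recommended <- length(actionable)
  n_matched_drugs <- length(intersect(unique(courses$drug), actionable))
  standard <- if (n_recommended > 0L) 100 * n_matched_drugs / n_recommended else NA_real_

  data.frame(patient_id = patient_id,
             n_courses = n_courses,
             n_matched_courses = n_matched,
             modified_score = modified,
             n_recommended_drugs = n_recommended,
             n_matched_drugs = n_matched_drugs,
             standard_score = standard,
             n_unscored_courses = n_unscored,
             stringsAsFactors = FALSE)
}

#' Modified (course-weighted) matching score
#'
#' The percentage of all administered treatment courses whose drug carries a
#' prediction score strictly greater than 0.5. Putting *all* administered
#' courses in the denominator — rather than the number of recommended drugs —
#' removes the survivorship bias of the literature-standard score: a patient
#' who lives longer and accumulates more empirical drug trials is not
#' rewarded for volume alone. Courses of drugs absent from the report count
#' in the denominator and never in the numerator (they are tallied in
#' `n_unscored_courses`); set `include_unscored = FALSE` to drop them for
#' sensitivity analysis.
#'
#' @param courses `data.frame` of post-report treatment courses for one
#'   patient, from [aggregate_treatments()].
#' @param report The patient's [prediction_report()].
#' @param include_unscored Keep courses of unscored drugs in the denominator
#'   (default `TRUE`).
#' @return One-row `data.frame` (a matching result) with course and drug
#'   counts and both score variants; `modified_score` is `NA` when the
#'   patient has no courses (flagged for exclusion downstream).
#' @examples
#' rep <- prediction_report("d1", as.Date("2021-01-01"),
#'                          c(prednisone = 0.3, rabacfosadine = 0.7))
#' ev <- data.frame(
#'   patient_id = "d1",
#'   drug = c(rep("prednisone", 12), "rabacfosadine", "rabacfosadine"),
#'   date = as.Date("2021-01-02") +
#'     c(rep(7 * 0:5, each = 2) + c(0, 3), 0, 21))
#' cs <- aggregate_treatments(ev, rep$delivery_date)
#' modified_matching_score(cs, rep)$modified_score  # 100 * 2/8 = 25
#' @export
modified_matching_score <- function(courses, report, include_unscored = TRUE) {
  matching_result_row(report$patient_id, courses, report$scores,
                      include_unscored = include_unscored)
}

#' Standard (drug-level) matching score
#'
#' The literature definition: the number of distinct administered drugs that
#' belong to the actionable set (report drugs scored strictly above 0.5)
#' divided by the size of the actionable set, as a percentage. This score is
#' biased upward for longer-lived patients, who accumulate more distinct
#' drugs through empirical therapy; see [bias_experiment()].
#'
#' @inheritParams modified_matching_score
#' @return One-row `data.frame` as in [modified_matching_score()];
#'   `standard_score` is `NA` when the actionable set is empty.
#' @export
standard_matching_score <- function(courses, report) {
  matching_result_row(report$patient_id, courses, report$scores)
}

#' Matching-score table for a whole cohort
#'
#' Aggregates each patient's post-report administrations into courses and
#' computes both matching-score variants.
#'
#' @param patients List of [patient_record()] objects.
#' @param include_unscored Passed to [modified_matching_score()].
#' @return `data.frame` with one row per patient, the schema of
#'   `matching_scores.csv`.
#' @export
cohort_matching_scores <- function(patients, include_unscored = TRUE) {
  rows <- lapply(patients, function(p) {
    cs <- aggregate_treatments(p$administrations, p$report$delivery_date,
                               post_report_only = TRUE)
    matching_result_row(p$patient_id, cs, p$report$scores,
                        include_unscored = include_unscored)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- matching_result_row("x", empty_administrations()[0, ],
                                               numeric())[0, ]
  out
}

#' Shuffle prediction reports to build a null cohort
#'
#' Permuting the drug recommendations destroys any true correspondence
#' between a patient and their report: a matching score free of survivorship
#' bias should then show no outcome difference between high- and
#' low-matching groups. `across_patients` (the default) reassigns whole
#' score mappings between patients by a uniform random permutation (each
#' patient keeps their own delivery date); `within_patient` permutes the
#' score values across each patient's own report drugs.
#'
#' @param patients Nonempty list of [patient_record()] objects.
#' @param seed Integer seed; the permutation is deterministic given the seed.
#' @param mode `"across_patients"` or `"within_patient"`.
#' @return A copy of `patients` with permuted prediction scores.
#' @export
shuffle_predictions <- function(patients, seed = NULL,
                                mode = c("across_patients", "within_patient")) {
  mode <- match.arg(mode)
  if (length(patients) == 0L)
    stop_validation("shuffle_predictions requires a nonempty cohort")
  with_local_seed(seed, {
    if (mode == "across_patients") {
      perm <- sample.int(length(patients))
      mapply(function(p, j) {
        p$report$scores <- patients[[j]]$report$scores
        p
      }, patients, perm, SIMPLIFY = FALSE)
    } else {
      lapply(patients, function(p) {
        s <- p$report$scores
        p$report$scores <- stats::setNames(s[sample.int(length(s))], names(s))
        p
      })
    }
  })
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. With seed = NULL the global stream is
# used (and advanced) as usual.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
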