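#' @keywords internal
"_PACKAGE"

RESPONSE_LEVELS <- c("PD", "SD", "PR", "CR")

stop_validation <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c("oncomatch_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

parse_iso_date <- function(x, file = "<memory>", field = "date") {
  x <- as.character(x)
  out <- as.Date(rep(NA_character_, length(x)))
  nonblank <- !is.na(x) & nzchar(trimws(x))
  if (any(nonblank)) {
    parsed <- as.Date(trimws(x[nonblank]), format = "%Y-%m-%d")
    bad <- which(is.na(parsed))
    if (length(bad) > 0L) {
      row <- which(nonblank)[bad[1L]]
      stop_validation("%s row %d: field '%s' is not an ISO 8601 date: '%s'",
                      file, row, field, x[row])
    }
    out[nonblank] <- parsed
  }
  out
}

#' Construct a prediction report
#'
#' A prediction report holds the per-drug response-likelihood scores (scale
#' 0 to 1, higher means a positive clinical response is more likely) that a
#' decision-support model delivered to the treating oncologist on a given
#' date. Drugs with a score strictly above 0.5 are considered recommended.
#'
#' @param patient_id Opaque patient identifier.
#' @param delivery_date `Date` the report reached the oncologist.
#' @param scores Named numeric vector, drug name -> score in `[0, 1]`.
#' @return An object of class `prediction_report`.
#' @export
prediction_report <- function(patient_id, delivery_date, scores) {
  if (length(delivery_date) != 1L || is.na(delivery_date))
    stop_validation("prediction report for '%s': delivery_date is required", patient_id)
  delivery_date <- as.Date(delivery_date)
  scores <- unlist(scores)
  if (length(scores) > 0L) {
    if (is.null(names(scores)) || any(!nzchar(names(scores))))
      stop_validation("prediction report for '%s': scores must be named by drug", patient_id)
    if (anyDuplicated(names(scores)))
      stop_validation("prediction report for '%s': duplicate drug '%s'",
                      patient_id, names(scores)[duplicated(names(scores))][1L])
    if (any(is.na(scores)) || any(scores < 0) || any(scores > 1))
      stop_validation("prediction report for '%s': scores must lie in [0, 1]", patient_id)
  }
  structure(
    list(patient_id = as.character(patient_id),
         delivery_date = delivery_date,
         scores = scores),
    class = "prediction_report"
  )
}

#' Construct a patient record
#'
#' Bundles one patient's baseline covariates, prediction report, raw drug
#' administrations, tumor response assessments, and survival follow-up.
#' Survival time is the number of days from report delivery to death (event)
#' or to the last follow-up (censored).
#'
#' @param patient_id Opaque identifier.
#' @param grade Tumor grade, `"low"` or `"high"`.
#' @param stage Clinical stage, integer 1-5.
#' @param substage `"a"` (no clinical signs) or `"b"`.
#' @param report A [prediction_report()].
#' @param administrations `data.frame` with columns `patient_id`, `drug`,
#'   `date` — one row per drug administration.
#' @param responses `data.frame` with columns `patient_id`, `date`,
#'   `category` (one of PD, SD, PR, CR).
#' @param last_followup_date Last date the patient was known alive, or the
#'   death date for deceased patients.
#' @param death_date `Date` or `NA` while alive.
#' @param event Logical; `TRUE` iff death/euthanasia was observed. Defaults
#'   to whether `death_date` is present.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, grade, stage, substage, report,
                           administrations = empty_administrations(),
                           responses = empty_responses(),
                           last_followup_date, death_date = as.Date(NA),
                           event = !is.na(death_date)) {
  patient_id <- as.character(patient_id)
  grade <- match.arg(as.character(grade), c("low", "high"))
  substage <- match.arg(as.character(substage), c("a", "b"))
  stage <- as.integer(stage)
  if (is.na(stage) || stage < 1L || stage > 5L)
    stop_validation("patient '%s': stage must be an integer in 1..5", patient_id)
  if (!inherits(report, "prediction_report"))
    stop_validation("patient '%s': report must be a prediction_report", patient_id)
  last_followup_date <- as.Date(last_followup_date)
  death_date <- as.Date(death_date)
  event <- isTRUE(as.logical(event))
  if (event != !is.na(death_date))
    stop_validation("patient '%s': event must be TRUE iff death_date is present", patient_id)
  if (!is.na(death_date) && death_date < report$delivery_date)
    stop_validation("patient '%s': death_date precedes report delivery", patient_id)
  if (is.na(last_followup_date) || last_followup_date < report$delivery_date)
    stop_validation("patient '%s': last_followup_date must be on/after report delivery",
                    patient_id)
  bad_cat <- setdiff(unique(toupper(responses$category)), RESPONSE_LEVELS)
  if (length(bad_cat) > 0L)
    stop_validation("patient '%s': unknown response category '%s'", patient_id, bad_cat[1L])
  responses$category <- toupper(responses$category)
  responses <- responses[order(responses$date), , drop = FALSE]
  rownames(responses) <- NULL
  rownames(administrations) <- NULL
  structure(
    list(patient_id = patient_id, grade = grade, stage = stage,
         substage = substage, report = report,
         administrations = administrations, responses = responses,
         last_followup_date = last_followup_date, death_date = death_date,
         event = event),
    class = "patient_record"
  )
}

empty_administrations <- function() {
  data.frame(patient_id = character(), drug = character(),
             date = as.Date(character()), stringsAsFactors = FALSE)
}

empty_responses <- function() {
  data.frame(patient_id = character(), date = as.Date(character()),
             category = character(), stringsAsFactors = FALSE)
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s> grade=%s stage=%d substage=%s\n",
              x$patient_id, x$grade, x$stage, x$substage))
  cat(sprintf("  report: %d drugs, delivered %s\n",
              length(x$report$scores), format(x$report$delivery_date)))
  cat(sprintf("  %d administrations, %d assessments, survival %d days (%s)\n",
              nrow(x$administrations), nrow(x$responses),
              survival_days(x), if (x$event) "event" else "censored"))
  invisible(x)
}

#' Days from report delivery to death or last follow-up
#'
#' @param patient A [patient_record()].
#' @return Nonnegative integer number of days.
#' @export
survival_days <- function(patient) {
  end <- if (patient$event) patient$death_date else patient$last_followup_date
  as.integer(end - patient$report$delivery_date)
}

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", strip.white = TRUE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L)
    stop_validation("%s: missing required column(s): %s",
                    path, paste(missing, collapse = ", "))
  df
}

#' Read a cohort from its four CSV tables
#'
#' Assembles one [patient_record()] per patient from the four flat files the
#' pipeline exchanges: prediction reports (one row per patient-drug),
#' administration events, tumor response assessments, and baseline/outcome
#' records. Dates must be ISO 8601 (`YYYY-MM-DD`); scores must lie in
#' `[0, 1]`. Rows in the reports, administrations or responses tables whose
#' patient id does not appear in the patients table are rejected (dropped
#' with a warning).
#'
#' @param reports_path CSV with columns `patient_id,drug,score,delivery_date`.
#' @param administrations_path CSV with columns `patient_id,drug,date`.
#' @param responses_path CSV with columns `patient_id,date,category`.
#' @param patients_path CSV with columns
#'   `patient_id,grade,stage,substage,last_followup_date,death_date,event`.
#' @return List of [patient_record()] objects, ordered as in the patients
#'   table.
#' @seealso [write_cohort()] for the inverse operation.
#' @export
read_cohort <- function(reports_path, administrations_path, responses_path,
                        patients_path) {
  pat <- read_csv_checked(patients_path,
                          c("patient_id", "grade", "stage", "substage",
                            "last_followup_date", "death_date", "event"))
  if (anyDuplicated(pat$patient_id))
    stop_validation("%s: duplicate patient_id '%s'", patients_path,
                    pat$patient_id[duplicated(pat$patient_id)][1L])
  known <- pat$patient_id

  rep_df <- read_csv_checked(reports_path,
                             c("patient_id", "drug", "score", "delivery_date"))
  score <- suppressWarnings(as.numeric(rep_df$score))
  bad <- which(is.na(score) | score < 0 | score > 1)
  if (length(bad) > 0L)
    stop_validation("%s row %d: field 'score' must be a number in [0, 1], got '%s'",
                    reports_path, bad[1L], rep_df$score[bad[1L]])
  rep_df$score <- score
  rep_df$delivery_date <- parse_iso_date(rep_df$delivery_date, reports_path,
                                         "delivery_date")
  if (anyNA(rep_df$delivery_date))
    stop_validation("%s row %d: field 'delivery_date' is required",
                    reports_path, which(is.na(rep_df$delivery_date))[1L])
  dup <- duplicated(rep_df[c("patient_id", "drug")])
  if (any(dup))
    stop_validation("%s row %d: duplicate (patient, drug) pair ('%s', '%s')",
                    reports_path, which(dup)[1L],
                    rep_df$patient_id[which(dup)[1L]], rep_df$drug[which(dup)[1L]])

  adm_df <- read_csv_checked(administrations_path, c("patient_id", "drug", "date"))
  adm_df$date <- parse_iso_date(adm_df$date, administrations_path, "date")
  if (anyNA(adm_df$date))
    stop_validation("%s row %d: field 'date' is required", administrations_path,
                    which(is.na(adm_df$date))[1L])

  res_df <- read_csv_checked(responses_path, c("patient_id", "date", "category"))
  res_df$date <- parse_iso_date(res_df$date, responses_path, "date")
  res_df$category <- toupper(trimws(res_df$category))
  bad <- which(!res_df$category %in% RESPONSE_LEVELS)
  if (length(bad) > 0L)
    stop_validation("%s row %d: field 'category' must be one of PD, SD, PR, CR, got '%s'",
                    responses_path, bad[1L], res_df$category[bad[1L]])

  drop_unknown <- function(df, what) {
    stray <- !df$patient_id %in% known
    if (any(stray)) {
      warning(sprintf("%d %s row(s) with unknown patient id rejected (e.g. '%s')",
                      sum(stray), what, df$patient_id[stray][1L]), call. = FALSE)
      df <- df[!stray, , drop = FALSE]
    }
    df
  }
  rep_df <- drop_unknown(rep_df, "report")
  adm_df <- drop_unknown(adm_df, "administration")
  res_df <- drop_unknown(res_df, "response")

  pat$death_date <- parse_iso_date(pat$death_date, patients_path, "death_date")
  pat$last_followup_date <- parse_iso_date(pat$last_followup_date, patients_path,
                                           "last_followup_date")
  pat$event <- as.integer(pat$event) == 1L

  lapply(seq_len(nrow(pat)), function(i) {
    pid <- pat$patient_id[i]
    r <- rep_df[rep_df$patient_id == pid, , drop = FALSE]
    if (nrow(r) == 0L)
      stop_validation("%s: patient '%s' has no prediction report", reports_path, pid)
    report <- prediction_report(pid, r$delivery_date[1L],
                                stats::setNames(r$score, r$drug))
    patient_record(
      patient_id = pid, grade = pat$grade[i], stage = pat$stage[i],
      substage = pat$substage[i], report = report,
      administrations = adm_df[adm_df$patient_id == pid,
                               c("patient_id", "drug", "date"), drop = FALSE],
      responses = res_df[res_df$patient_id == pid,
                         c("patient_id", "date", "category"), drop = FALSE],
      last_followup_date = pat$last_followup_date[i],
      death_date = pat$death_date[i], event = pat$event[i]
    )
  })
}

#' Aggregate raw drug administrations into treatment courses
#'
#' The counting unit of the matching-score analysis is a treatment course:
#' one 7-day course of a drug administered more than once per week, or one
#' administration of a drug given weekly or less often. Per drug, if any two
#' administrations fall within 7 days of each other (a sliding-window test:
#' consecutive gap of 6 days or less), the drug is counted in
#' `weekly_window` mode — administrations are binned into consecutive 7-day
#' half-open windows anchored at the drug's first retained administration,
#' each nonempty window contributing one course. Otherwise every
#' administration is its own course (`per_administration` mode).
#'
#' @param events `data.frame` with columns `patient_id`, `drug`, `date`
#'   for a single patient.
#' @param report_delivery_date `Date`; required when `post_report_only`.
#' @param post_report_only Drop events on or before the report delivery date
#'   before counting (the default, as only post-report treatments enter the
#'   matching score).
#' @return `data.frame` with one row per course: `patient_id`, `drug`,
#'   `start_date`, `n_administrations`, `counting_mode`.
#' @examples
#' # twice-weekly prednisone for 6 weeks + 2 rabacfosadine infusions
#' ev <- data.frame(
#'   patient_id = "d1",
#'   drug = c(rep("prednisone", 12), "rabacfosadine", "rabacfosadine"),
#'   date = as.Date("2021-01-01") +
#'     c(rep(7 * 0:5, each = 2) + c(0, 3), 0, 21)
#' )
#' courses <- aggregate_treatments(ev, as.Date("2020-12-31"))
#' nrow(courses)  # 8 courses: 6 prednisone + 2 rabacfosadine
#' @export
aggregate_treatments <- function(events, report_delivery_date = NULL,
                                 post_report_only = TRUE) {
  out <- data.frame(patient_id = character(), drug = character(),
                    start_date = as.Date(character()),
                    n_administrations = integer(),
                    counting_mode = character(), stringsAsFactors = FALSE)
  if (is.null(events) || nrow(events) == 0L) return(out)
  if (length(unique(events$patient_id)) > 1L)
    stop_validation("aggregate_treatments expects events for a single patient")
  if (post_report_only) {
    if (is.null(report_delivery_date))
      stop_validation("post_report_only requires report_delivery_date")
    events <- events[events$date > as.Date(report_delivery_date), , drop = FALSE]
    if (nrow(events) == 0L) return(out)
  }
  pid <- events$patient_id[1L]
  all_dates <- as.integer(events$date)
  acc_drug <- character(0); acc_start <- integer(0)
  acc_n <- integer(0); acc_mode <- character(0)
  for (dr in unique(events$drug)) {
    d <- sort(all_dates[events$drug == dr])
    if (length(d) >= 2L && any(diff(d) <= 6L)) {
      win <- (d - d[1L]) %/% 7L
      wlev <- sort(unique(win))
      starts <- vapply(wlev, function(w) d[match(w, win)], integer(1L))
      counts <- tabulate(match(win, wlev))
      acc_drug <- c(acc_drug, rep(dr, length(wlev)))
      acc_start <- c(acc_start, starts)
      acc_n <- c(acc_n, counts)
      acc_mode <- c(acc_mode, rep("weekly_window", length(wlev)))
    } else {
      acc_drug <- c(acc_drug, rep(dr, length(d)))
      acc_start <- c(acc_start, d)
      acc_n <- c(acc_n, rep(1L, length(d)))
      acc_mode <- c(acc_mode, rep("per_administration", length(d)))
    }
  }
  ord <- order(acc_start, acc_drug)
  data.frame(patient_id = pid, drug = acc_drug[ord],
             start_date = as.Date(acc_start[ord], origin = "1970-01-01"),
             n_administrations = acc_n[ord],
             counting_mode = acc_mode[ord], stringsAsFactors = FALSE)
}

#' Pair treatment courses with the tumor response that followed them
#'
#' Each course is labelled by the first response assessment dated on or
#' after the course start: CR/PR map to 1 (positive response), SD/PD map to
#' 0. Courses with no subsequent assessment are left out of the result.
#'
#' @param responses `data.frame` with columns `date`, `category`, sorted or
#'   not (sorted internally).
#' @param courses `data.frame` as returned by [aggregate_treatments()].
#' @return `data.frame`: the labelled subset of `courses` plus columns
#'   `response_date`, `response_category` and binary `label`.
#' @export
derive_response_labels <- function(responses, courses) {
  if (nrow(courses) == 0L) {
    out <- courses
    out$response_date <- as.Date(character())
    out$response_category <- character()
    out$label <- integer()
    return(out)
  }
  responses <- responses[order(responses$date), , drop = FALSE]
  idx <- vapply(courses$start_date, function(s) {
    k <- which(responses$date >= s)
    if (length(k) == 0L) NA_integer_ else k[1L]
  }, integer(1L))
  keep <- !is.na(idx)
  out <- courses[keep, , drop = FALSE]
  out$response_date <- responses$date[idx[keep]]
  out$response_category <- toupper(responses$category[idx[keep]])
  out$label <- as.integer(out$response_category %in% c("CR", "PR"))
  rownames(out) <- NULL
  out
}

#' Best post-report tumor response for one patient
#'
#' The maximum response category observed strictly after report delivery,
#' under the ordering CR > PR > SD > PD.
#'
#' @param patient A [patient_record()].
#' @return One of `"CR"`, `"PR"`, `"SD"`, `"PD"`, or `NA_character_` when no
#'   post-report assessment exists.
#' @export
best_response <- function(patient) {
  res <- patient$responses
  res <- res[res$date > patient$report$delivery_date, , drop = FALSE]
  if (nrow(res) == 0L) return(NA_character_)
  RESPONSE_LEVELS[max(match(toupper(res$category), RESPONSE_LEVELS))]
}

#' Apply the minimum-administration inclusion criterion
#'
#' Patients must have received at least `min_administrations` anticancer
#' drug administrations after the prediction report was delivered; the
#' threshold guarantees a minimal sample size for the matching-score
#' denominator. All recorded anticancer drugs, including prednisone, count.
#'
#' @param patients List of [patient_record()] objects.
#' @param min_administrations Minimum number of post-report administration
#'   events (default 3).
#' @return List with elements `included` (list of patient records) and
#'   `exclusions` (`data.frame` of `patient_id`, `reason`).
#' @export
inclusion_filter <- function(patients, min_administrations = 3L) {
  excl <- data.frame(patient_id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  keep <- logical(length(patients))
  for (i in seq_along(patients)) {
    p <- patients[[i]]
    n_post <- sum(p$administrations$date > p$report$delivery_date)
    if (n_post >= min_administrations) {
      keep[i] <- TRUE
    } else {
      excl <- rbind(excl, data.frame(
        patient_id = p$patient_id,
        reason = sprintf("%d post-report administration(s), need >= %d",
                         n_post, min_administrations),
        stringsAsFactors = FALSE))
    }
  }
  list(included = patients[keep], exclusions = excl)
}

#' Survival data frame for a cohort
#'
#' @param patients List of [patient_record()] objects.
#' @return `data.frame` with `patient_id`, `time` (days from report delivery
#'   to death or last follow-up), `event` (0/1), and the Cox covariate
#'   codings `grade` (high = 1), `substage` (b = 1), `stage` (numeric 1-5).
#' @export
cohort_survival <- function(patients) {
  data.frame(
    patient_id = vapply(patients, `[[`, character(1L), "patient_id"),
    time = vapply(patients, survival_days, integer(1L)),
    event = vapply(patients, function(p) as.integer(p$event), integer(1L)),
    grade = vapply(patients, function(p) as.integer(p$grade == "high"), integer(1L)),
    substage = vapply(patients, function(p) as.integer(p$substage == "b"), integer(1L)),
    stage = vapply(patients, function(p) p$stage, integer(1L)),
    stringsAsFactors = FALSE
  )
}
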