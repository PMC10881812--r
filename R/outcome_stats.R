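#' Kaplan-Meier product-limit survival curve
#'
#' Wraps [survival::survfit()] and returns the step function as a plain
#' object. The median is the smallest time at which the survival
#' probability reaches 0.5 or below (within floating-point tolerance), `NA`
#' if the curve never gets there.
#'
#' @param durations Nonnegative follow-up times in days.
#' @param events Logical/0-1 vector; `TRUE` for death, `FALSE` for censoring.
#' @return An object of class `survival_curve`: list with `time`,
#'   `survival`, `at_risk`, `n_events`, `median`, `n`.
#' @export
kaplan_meier <- function(durations, events) {
  if (length(durations) == 0L) stop_validation("kaplan_meier: empty input")
  if (length(durations) != length(events))
    stop_validation("kaplan_meier: durations and events differ in length")
  if (any(durations < 0)) stop_validation("kaplan_meier: negative duration")
  fit <- survival::survfit(survival::Surv(durations, as.integer(events)) ~ 1)
  med <- km_median(fit$time, fit$surv)
  structure(list(time = fit$time, survival = fit$surv, at_risk = fit$n.risk,
                 n_events = fit$n.event, median = med, n = length(durations)),
            class = "survival_curve")
}

km_median <- function(time, surv) {
  hit <- which(surv <= 0.5 + 1e-9)
  if (length(hit) == 0L) NA_real_ else time[hit[1L]]
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> n=%d, %d event time(s), median=%s days\n",
              x$n, sum(x$n_events > 0),
              if (is.na(x$median)) "NA" else format(x$median)))
  invisible(x)
}

#' Two-group logrank test
#'
#' @param durations_a,events_a Follow-up times and event indicators, group A.
#' @param durations_b,events_b Same for group B.
#' @return An object of class `htest` with the chi-squared statistic
#'   (1 degree of freedom) and two-sided p-value.
#' @export
logrank_test <- function(durations_a, events_a, durations_b, events_b) {
  if (length(durations_a) == 0L || length(durations_b) == 0L)
    stop_validation("logrank_test: both groups must be nonempty")
  time <- c(durations_a, durations_b)
  event <- as.integer(c(events_a, events_b))
  grp <- rep(c("A", "B"), c(length(durations_a), length(durations_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- sd$chisq
  structure(list(statistic = c(chisq = stat), parameter = c(df = 1),
                 p.value = stats::pchisq(stat, 1, lower.tail = FALSE),
                 method = "Two-group logrank test",
                 data.name = "survival by group"),
            class = "htest")
}

#' Complete and overall response rates by group
#'
#' Computes per-group response category counts, the complete response rate
#' (CRR = CR / n) and overall response rate (ORR = (CR + PR) / n), and
#' Fisher's exact two-sided p-values comparing the two groups on each rate.
#' Patients with no post-report assessment stay in the denominator as
#' non-responders.
#'
#' @param groups Named character vector mapping patient id to `"low"` or
#'   `"high"`.
#' @param best_responses Named character vector mapping patient id to one of
#'   `"CR"`, `"PR"`, `"SD"`, `"PD"`, or `NA` when never assessed.
#' @return An object of class `response_summary`: list with `table` (one row
#'   per group: n, per-category counts, `n_no_assessment`, `crr`, `orr`,
#'   rates in percent) and `fisher_p` (named vector, `crr` and `orr`).
#' @export
response_rates <- function(groups, best_responses) {
  lv <- sort(unique(groups))
  if (length(lv) != 2L)
    stop_validation("response_rates requires exactly two groups, got %d", length(lv))
  rows <- lapply(lv, function(g) {
    ids <- names(groups)[groups == g]
    if (length(ids) == 0L) stop_validation("empty group '%s'", g)
    br <- best_responses[ids]
    counts <- vapply(RESPONSE_LEVELS, function(k) sum(br == k, na.rm = TRUE),
                     integer(1L))
    n <- length(ids)
    data.frame(group = g, n = n,
               n_CR = counts[["CR"]], n_PR = counts[["PR"]],
               n_SD = counts[["SD"]], n_PD = counts[["PD"]],
               n_no_assessment = sum(is.na(br)),
               crr = 100 * counts[["CR"]] / n,
               orr = 100 * (counts[["CR"]] + counts[["PR"]]) / n,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  fisher_2x2 <- function(resp_counts) {
    m <- rbind(resp_counts, tab$n - resp_counts)
    stats::fisher.test(m, alternative = "two.sided")$p.value
  }
  fisher_p <- c(crr = fisher_2x2(tab$n_CR),
                orr = fisher_2x2(tab$n_CR + tab$n_PR))
  structure(list(table = tab, fisher_p = fisher_p), class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("Fisher exact (two-sided): CRR p=%.4g, ORR p=%.4g\n",
              x$fisher_p[["crr"]], x$fisher_p[["orr"]]))
  invisible(x)
}

#' Duration of complete response, per group
#'
#' For every patient whose best post-report response is CR, the duration
#' runs from the first post-report CR assessment to the first later PD
#' assessment (event) or to the last follow-up date (censored). With
#' `event_rule = "pd_or_pr"` a PR after CR also counts as relapse.
#'
#' @param patients List of [patient_record()] objects.
#' @param groups Named character vector, patient id -> group label.
#' @param event_rule `"pd_only"` (default) or `"pd_or_pr"`.
#' @return List with `durations` (`data.frame`: `patient_id`, `group`,
#'   `time`, `event`) and `curves` (named list of [kaplan_meier()] curves;
#'   groups with no CR patient are omitted with a warning).
#' @export
cr_durations <- function(patients, groups, event_rule = c("pd_only", "pd_or_pr")) {
  event_rule <- match.arg(event_rule)
  relapse_cats <- if (event_rule == "pd_only") "PD" else c("PD", "PR")
  rows <- lapply(patients, function(p) {
    if (!identical(best_response(p), "CR")) return(NULL)
    res <- p$responses[p$responses$date > p$report$delivery_date, , drop = FALSE]
    cr_date <- res$date[match("CR", res$category)]
    later <- res[res$date > cr_date & res$category %in% relapse_cats, , drop = FALSE]
    if (nrow(later) > 0L) {
      data.frame(patient_id = p$patient_id,
                 time = as.integer(later$date[1L] - cr_date), event = 1L,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = p$patient_id,
                 time = as.integer(p$last_followup_date - cr_date), event = 0L,
                 stringsAsFactors = FALSE)
    }
  })
  dur <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(dur))
    dur <- data.frame(patient_id = character(), time = integer(),
                      event = integer(), stringsAsFactors = FALSE)
  dur$group <- unname(groups[dur$patient_id])
  curves <- list()
  for (g in sort(unique(unname(groups)))) {
    sub <- dur[!is.na(dur$group) & dur$group == g, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning(sprintf("no CR patients in group '%s'; curve omitted", g),
              call. = FALSE)
    } else {
      curves[[g]] <- kaplan_meier(sub$time, sub$event)
    }
  }
  list(durations = dur[, c("patient_id", "group", "time", "event")],
       curves = curves)
}

#' Compare per-drug recommendation frequencies between groups
#'
#' For each drug, the recommendation frequency in a group is the fraction of
#' that group's patients whose report scores the drug strictly above 0.5.
#' Frequencies are compared with the pooled two-sample proportion Z-test and
#' the p-values are Benjamini-Hochberg adjusted across the drug panel.
#'
#' @param patients List of [patient_record()] objects.
#' @param groups Named character vector, patient id -> group (two groups).
#' @param drugs Drug panel to test; defaults to the union of all report
#'   drugs. Drugs present in no report are excluded with a warning.
#' @return `data.frame`: `drug`, `freq_low`, `freq_high`, `z`, `p`, `p_adjusted`.
#' @export
prediction_frequency_comparison <- function(patients, groups, drugs = NULL) {
  lv <- sort(unique(unname(groups)))
  if (length(lv) != 2L)
    stop_validation("prediction_frequency_comparison requires exactly two groups")
  if (setequal(lv, c("low", "high"))) lv <- c("low", "high")  # z = high - low
  all_report_drugs <- unique(unlist(lapply(patients, function(p) names(p$report$scores))))
  if (is.null(drugs)) {
    drugs <- sort(all_report_drugs)
  } else {
    absent <- setdiff(drugs, all_report_drugs)
    if (length(absent) > 0L) {
      warning(sprintf("drug(s) present in no report excluded: %s",
                      paste(absent, collapse = ", ")), call. = FALSE)
      drugs <- setdiff(drugs, absent)
    }
  }
  ids <- vapply(patients, `[[`, character(1L), "patient_id")
  recommended <- function(p, d) {
    s <- p$report$scores
    d %in% names(s) && s[[d]] > MATCH_THRESHOLD
  }
  rows <- lapply(drugs, function(d) {
    hit <- vapply(patients, recommended, logical(1L), d)
    g <- unname(groups[ids])
    x <- vapply(lv, function(l) sum(hit & !is.na(g) & g == l), integer(1L))
    n <- vapply(lv, function(l) sum(!is.na(g) & g == l), integer(1L))
    p1 <- x / n
    pool <- sum(x) / sum(n)
    se <- sqrt(pool * (1 - pool) * sum(1 / n))
    z <- if (se == 0) 0 else (p1[2L] - p1[1L]) / se
    data.frame(drug = d, freq_low = p1[1L], freq_high = p1[2L], z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adjusted <- bh_adjust(out$p)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values controlling the false discovery rate: with raw
#' p-values sorted ascending, `p_adj(i) = min_{j >= i} min(1, n/j * p(j))`.
#' Adjusted values are monotone in the raw ranking and never smaller than
#' the raw p-value.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Vector of adjusted p-values, in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_validation("bh_adjust: p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric(0))
  desc <- order(p, decreasing = TRUE)
  pmin(1, cummin(n / seq(n, 1) * p[desc]))[order(desc)]
}

#' Cox proportional-hazards models of survival
#'
#' Fits univariate models (one per covariate) or a single multivariate
#' model by partial likelihood with Breslow tie handling and no
#' penalization. Covariates are expected pre-coded numerically (see
#' [cohort_survival()]: grade high = 1, substage b = 1, stage 1-5, matching
#' group high = 1). Rows with missing values are dropped with a message.
#' The proportional-hazards assumption is checked per covariate by the
#' scaled Schoenfeld residual time-correlation test ([survival::cox.zph()])
#' at alpha = 0.05.
#'
#' @param data `data.frame` with columns `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return `data.frame` of class `cox_result`, one row per covariate:
#'   `covariate`, `mode`, `coef`, `hr`, `ci_low`, `ci_high`, `p`,
#'   `concordance`, `ph_pass`. A degenerate covariate (e.g. constant)
#'   yields `NA` estimates with a warning; detected separation is an error
#'   suggesting penalized refitting outside this package's scope.
#' @export
cox_model <- function(data, covariates, mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  missing_cols <- setdiff(c("time", "event", covariates), names(data))
  if (length(missing_cols) > 0L)
    stop_validation("cox_model: missing column(s): %s",
                    paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(data[, c("time", "event", covariates), drop = FALSE])
  if (any(!keep)) {
    message(sprintf("cox_model: dropped %d row(s) with missing values", sum(!keep)))
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) == 0L) stop_validation("cox_model: no complete rows")

  fit_one <- function(cvs) {
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(cvs, collapse = " + ")))
    warned <- character()
    fit <- withCallingHandlers(
      survival::coxph(fml, data = data, ties = "breslow"),
      warning = function(w) {
        warned <<- c(warned, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    cf <- stats::coef(fit)
    if (any(!is.na(cf) & abs(cf) > 15) ||
        any(grepl("converged before", warned)))
      stop_validation(paste("cox_model: monotone likelihood/separation detected",
                            "for '%s'; consider a penalized model"),
                      paste(cvs[!is.na(cf) & abs(cf) > 15], collapse = ", "))
    singular <- names(cf)[is.na(cf)]
    if (length(singular) > 0L)
      warning(sprintf("cox_model: covariate(s) %s dropped as singular; estimates set NA",
                      paste(singular, collapse = ", ")), call. = FALSE)
    zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
    rows <- lapply(cvs, function(v) {
      if (v %in% singular || !v %in% rownames(s$coefficients)) {
        return(data.frame(covariate = v, mode = mode, coef = NA_real_,
                          hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          p = NA_real_, concordance = unname(s$concordance[1L]),
                          ph_pass = NA, stringsAsFactors = FALSE))
      }
      ph <- if (!is.null(zph) && v %in% rownames(zph$table))
        unname(zph$table[v, "p"] > 0.05) else NA
      data.frame(covariate = v, mode = mode,
                 coef = unname(s$coefficients[v, "coef"]),
                 hr = unname(s$conf.int[v, "exp(coef)"]),
                 ci_low = unname(s$conf.int[v, "lower .95"]),
                 ci_high = unname(s$conf.int[v, "upper .95"]),
                 p = unname(s$coefficients[v, "Pr(>|z|)"]),
                 concordance = unname(s$concordance[1L]),
                 ph_pass = ph, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }

  out <- if (mode == "univariate") {
    do.call(rbind, c(lapply(covariates, fit_one), list(make.row.names = FALSE)))
  } else {
    fit_one(covariates)
  }
  class(out) <- c("cox_result", class(out))
  out
}

#' Historical median survival after relapse
#'
#' Estimated by subtracting the median time to relapse from the median
#' overall survival time, both taken from published first-line therapy
#' studies.
#'
#' @param median_os Median overall survival, days (> 0).
#' @param median_time_to_relapse Median time to relapse, days (> 0, less
#'   than `median_os`).
#' @return Difference in days.
#' @export
historical_survival_after_relapse <- function(median_os, median_time_to_relapse) {
  if (median_os <= 0 || median_time_to_relapse <= 0)
    stop_validation("both inputs must be positive")
  if (median_os <= median_time_to_relapse)
    stop_validation("median_os (%g) must exceed median_time_to_relapse (%g)",
                    median_os, median_time_to_relapse)
  median_os - median_time_to_relapse
}
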