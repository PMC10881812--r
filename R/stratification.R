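stop_degenerate <- function(fmt, ...) {
  cond <- structure(
    class = c("oncomatch_degenerate_stratification", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  )
  stop(cond)
}

#' Dichotomize a cohort into low- and high-matching groups
#'
#' Splits patients at a threshold chosen by one of the three methods found
#' in the precision-oncology literature:
#' \describe{
#'   \item{`median`}{Threshold is the sample median of the scores. Scores
#'     strictly above go to `high`, strictly below to `low`; patients tied
#'     exactly at the median are allocated deterministically (ascending
#'     patient id, each to the currently smaller group, ties to `low`) so
#'     group sizes are as equal as possible. This method involves no
#'     hypothesis-shopping over candidate thresholds.}
#'   \item{`fixed`}{An arbitrary threshold (default 50); `score >= threshold`
#'     is `high`.}
#'   \item{`optimized`}{Scans distinct score values as candidate thresholds
#'     (`score > c` is `high`) and picks the cut maximizing the logrank
#'     statistic against the supplied survival data; ties break toward the
#'     more balanced split. Following maximally-selected-statistics
#'     practice, candidates leaving less than a fraction `minprop` of the
#'     cohort in either group are not scanned — the logrank chi-square
#'     approximation is anti-conservative for extreme splits. Because the
#'     scan tests one hypothesis per candidate, the raw logrank p-value is
#'     reported alongside a Bonferroni adjustment over the number of
#'     candidates actually scanned.}
#' }
#'
#' @param scores Named numeric vector of matching scores (names are patient
#'   ids); all values must be defined (drop undefined-score patients first).
#' @param method `"median"`, `"fixed"` or `"optimized"`.
#' @param fixed_threshold Threshold for the fixed method (default 50,
#'   percent scale).
#' @param outcome_data For the optimized method: `data.frame` with columns
#'   `patient_id`, `time`, `event`.
#' @param minprop Optimized method only: minimum fraction of patients each
#'   group must retain for a candidate threshold to be scanned (default
#'   0.1).
#' @return An object of class `group_assignment`: list with `method`,
#'   `threshold`, `assignment` (named character vector, `"low"`/`"high"`),
#'   `n_low`, `n_high`, and for the optimized method `statistic`, `p_raw`,
#'   `p_adjusted`, `n_candidates`.
#' @export
dichotomize <- function(scores, method = c("median", "fixed", "optimized"),
                        fixed_threshold = 50, outcome_data = NULL,
                        minprop = 0.1) {
  method <- match.arg(method)
  if (length(scores) == 0L || is.null(names(scores)))
    stop_validation("dichotomize requires a named, nonempty score vector")
  if (anyNA(scores))
    stop_validation("all scores must be defined; %d are NA", sum(is.na(scores)))

  res <- switch(method,
    median = {
      if (length(unique(scores)) < 2L)
        stop_degenerate("all %d scores identical (%.3g); median split impossible",
                        length(scores), scores[1L])
      thr <- stats::median(scores)
      grp <- ifelse(scores > thr, "high", ifelse(scores < thr, "low", NA))
      ties <- names(scores)[is.na(grp)]
      names(grp) <- names(scores)
      for (id in sort(ties)) {  # deterministic: ascending id, to smaller group
        n_low <- sum(grp == "low", na.rm = TRUE)
        n_high <- sum(grp == "high", na.rm = TRUE)
        grp[id] <- if (n_low <= n_high) "low" else "high"
      }
      list(threshold = thr, assignment = grp)
    },
    fixed = {
      grp <- ifelse(scores >= fixed_threshold, "high", "low")
      names(grp) <- names(scores)
      list(threshold = fixed_threshold, assignment = grp)
    },
    optimized = {
      if (is.null(outcome_data))
        stop_validation("optimized dichotomization requires outcome_data")
      if (length(unique(scores)) < 2L)
        stop_degenerate("fewer than 2 distinct scores; no threshold to optimize")
      od <- outcome_data[match(names(scores), outcome_data$patient_id), , drop = FALSE]
      if (anyNA(od$time))
        stop_validation("outcome_data lacks rows for some scored patients")
      cand <- sort(unique(scores))
      cand <- cand[-length(cand)]  # score > max would empty the high group
      min_group <- max(1L, ceiling(minprop * length(scores)))
      cand <- cand[vapply(cand, function(c0) {
        k <- sum(scores > c0)
        k >= min_group && length(scores) - k >= min_group
      }, logical(1L))]
      if (length(cand) == 0L)
        stop_degenerate("no candidate threshold keeps %d patients per group",
                        min_group)
      best <- NULL
      for (c0 in cand) {
        g <- scores > c0
        chi <- tryCatch(
          survival::survdiff(survival::Surv(od$time, od$event) ~ g)$chisq,
          error = function(e) NA_real_)
        if (is.na(chi)) next
        balance <- -abs(sum(g) - sum(!g))
        if (is.null(best) || chi > best$chisq + 1e-12 ||
            (abs(chi - best$chisq) <= 1e-12 && balance > best$balance)) {
          best <- list(threshold = c0, chisq = chi, balance = balance)
        }
      }
      if (is.null(best))
        stop_degenerate("no candidate threshold produced a valid split")
      grp <- ifelse(scores > best$threshold, "high", "low")
      names(grp) <- names(scores)
      p_raw <- stats::pchisq(best$chisq, df = 1L, lower.tail = FALSE)
      list(threshold = best$threshold, assignment = grp,
           statistic = best$chisq, p_raw = p_raw,
           p_adjusted = min(1, p_raw * length(cand)),
           n_candidates = length(cand))
    })

  out <- c(list(method = method), res,
           list(n_low = sum(res$assignment == "low"),
                n_high = sum(res$assignment == "high")))
  class(out) <- "group_assignment"
  out
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> method=%s threshold=%.4g  low=%d high=%d\n",
              x$method, x$threshold, x$n_low, x$n_high))
  if (!is.null(x$p_adjusted))
    cat(sprintf("  optimized scan: %d candidates, logrank chi2=%.3g, raw p=%.3g, adjusted p=%.3g\n",
                x$n_candidates, x$statistic, x$p_raw, x$p_adjusted))
  invisible(x)
}

#' Compare dichotomization methods on the same cohort
#'
#' Runs each requested threshold method, fits a univariate Cox model on the
#' resulting group indicator (high = 1), and reports the hazard ratio and
#' logrank p per method. A method that fails (e.g. degenerate scores)
#' yields a row with `NA` estimates and the failure message, never a
#' dropped row.
#'
#' @param scores Named numeric vector of matching scores.
#' @param outcome_data `data.frame` with `patient_id`, `time`, `event`.
#' @param methods Subset of `c("median", "fixed", "optimized")`.
#' @param fixed_threshold Threshold for the fixed method.
#' @return `data.frame` with one row per method: `method`, `threshold`,
#'   `hr`, `ci_low`, `ci_high`, `logrank_p`, `error`.
#' @export
stratification_sensitivity <- function(scores, outcome_data,
                                       methods = c("median", "fixed", "optimized"),
                                       fixed_threshold = 50) {
  rows <- lapply(methods, function(m) {
    tryCatch({
      ga <- dichotomize(scores, m, fixed_threshold = fixed_threshold,
                        outcome_data = outcome_data)
      od <- outcome_data[match(names(ga$assignment), outcome_data$patient_id), ]
      grp <- as.integer(ga$assignment == "high")
      if (length(unique(grp)) < 2L)
        stop_degenerate("method '%s' put every patient in one group", m)
      fit <- survival::coxph(survival::Surv(od$time, od$event) ~ grp,
                             ties = "breslow")
      ci <- summary(fit)$conf.int
      lr <- survival::survdiff(survival::Surv(od$time, od$event) ~ grp)
      data.frame(method = m, threshold = ga$threshold,
                 hr = unname(ci[1, "exp(coef)"]),
                 ci_low = unname(ci[1, "lower .95"]),
                 ci_high = unname(ci[1, "upper .95"]),
                 logrank_p = stats::pchisq(lr$chisq, 1, lower.tail = FALSE),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(method = m, threshold = NA_real_, hr = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, logrank_p = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
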