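#' Configuration for a full analysis run
#'
#' Exactly one of `input_dir` (a directory containing the four cohort CSV
#' files) or `sim_config` (a [cohort_config()], to simulate the cohort)
#' must be supplied.
#'
#' @param outdir Output directory for the result bundle.
#' @param input_dir Directory with `reports.csv`, `administrations.csv`,
#'   `responses.csv`, `patients.csv`.
#' @param sim_config A [cohort_config()] to generate the cohort instead.
#' @param method Dichotomization method (see [dichotomize()]).
#' @param fixed_threshold Threshold for `method = "fixed"`.
#' @param variant Matching-score variant used for grouping, `"modified"`
#'   (default) or `"standard"`.
#' @param include_unscored Keep courses of unscored drugs in the modified
#'   denominator (default `TRUE`).
#' @param cr_event_rule Relapse rule for CR-duration curves (see
#'   [cr_durations()]).
#' @param min_administrations Inclusion threshold on post-report
#'   administrations (default 3).
#' @param seed Seed for simulation (ignored when reading files).
#' @return A validated list of class `analysis_config`.
#' @export
analysis_config <- function(outdir, input_dir = NULL, sim_config = NULL,
                            method = c("median", "fixed", "optimized"),
                            fixed_threshold = 50,
                            variant = c("modified", "standard"),
                            include_unscored = TRUE,
                            cr_event_rule = c("pd_only", "pd_or_pr"),
                            min_administrations = 3L, seed = NULL) {
  if (is.null(input_dir) == is.null(sim_config))
    stop_validation("supply exactly one of input_dir or sim_config")
  if (!is.null(sim_config) && !inherits(sim_config, "cohort_config"))
    stop_validation("sim_config must be a cohort_config")
  structure(list(
    outdir = outdir, input_dir = input_dir, sim_config = sim_config,
    method = match.arg(method), fixed_threshold = fixed_threshold,
    variant = match.arg(variant), include_unscored = isTRUE(include_unscored),
    cr_event_rule = match.arg(cr_event_rule),
    min_administrations = as.integer(min_administrations),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "analysis_config")
}

stage <- function(name, code) {
  withCallingHandlers(
    tryCatch(code, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    }),
    warning = function(w) {
      message(sprintf("[stage %s] warning: %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
}

#' Run the full matching-score study
#'
#' Executes read/generate -> course aggregation -> matching score ->
#' dichotomization -> outcome analysis and writes the result bundle:
#' `matching_scores.csv`, `groups.csv`, `km_curves.csv`, `cox_table.csv`,
#' `summary.json` and `run_log.json` (seed, decision flags, per-patient
#' exclusions). Any stage failure removes partial outputs before
#' propagating, so the output directory never holds a half-written bundle.
#'
#' @param config An [analysis_config()].
#' @return Invisibly, a list with every intermediate object (`patients`,
#'   `exclusions`, `matching`, `assignment`, `survival`, `km`, `logrank`,
#'   `responses`, `cr`, `prediction_freq`, `cox`, `summary`, `paths`).
#' @export
run_study <- function(config) {
  if (!inherits(config, "analysis_config"))
    stop_validation("run_study expects an analysis_config")
  outdir <- config$outdir
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop_validation("cannot create output directory '%s'", outdir)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  cohort <- stage("input", {
    if (!is.null(config$sim_config)) {
      gen <- generate_cohort(config$sim_config, seed = config$seed)
      write_cohort(gen$patients, file.path(outdir, "cohort"))
      gen$patients
    } else {
      read_cohort(file.path(config$input_dir, "reports.csv"),
                  file.path(config$input_dir, "administrations.csv"),
                  file.path(config$input_dir, "responses.csv"),
                  file.path(config$input_dir, "patients.csv"))
    }
  })

  incl <- stage("inclusion", inclusion_filter(cohort, config$min_administrations))
  exclusions <- incl$exclusions

  matching <- stage("matching_score",
                    cohort_matching_scores(incl$included,
                                           include_unscored = config$include_unscored))
  score_col <- if (config$variant == "modified") "modified_score" else "standard_score"
  svec <- stats::setNames(matching[[score_col]], matching$patient_id)
  undefined <- names(svec)[is.na(svec)]
  if (length(undefined) > 0L) {
    exclusions <- rbind(exclusions, data.frame(
      patient_id = undefined,
      reason = sprintf("undefined %s matching score", config$variant),
      stringsAsFactors = FALSE))
    svec <- svec[!is.na(svec)]
  }
  scored <- incl$included[vapply(incl$included, `[[`, character(1L),
                                 "patient_id") %in% names(svec)]

  od <- stage("survival_data", cohort_survival(scored))
  ga <- tryCatch(
    dichotomize(svec, config$method,
                fixed_threshold = config$fixed_threshold,
                outcome_data = od),
    oncomatch_degenerate_stratification = function(e) e)
  if (inherits(ga, "condition")) {
    # Cohort cannot be stratified (e.g. a single patient, or identical
    # scores): emit the matching scores plus a log marked incomplete
    # rather than a half-written outcome bundle.
    p <- c(matching_scores = file.path(outdir, "matching_scores.csv"),
           run_log = file.path(outdir, "run_log.json"))
    utils::write.csv(matching, p[["matching_scores"]], row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(
      list(status = "incomplete", error = conditionMessage(ga),
           seed = config$seed, n_input = length(cohort),
           n_included = length(scored), exclusions = exclusions),
      p[["run_log"]], auto_unbox = TRUE, digits = 10, dataframe = "rows",
      null = "null", pretty = TRUE)
    ok <- TRUE
    warning(sprintf("stratification degenerate (%s); bundle marked incomplete",
                    conditionMessage(ga)), call. = FALSE)
    return(invisible(list(patients = cohort, included = scored,
                          exclusions = exclusions, matching = matching,
                          assignment = NULL, paths = p)))
  }
  groups <- ga$assignment
  od$group <- as.integer(groups[od$patient_id] == "high")

  km <- stage("kaplan_meier", {
    lapply(stats::setNames(nm = c("low", "high")), function(g) {
      sub <- od[groups[od$patient_id] == g, , drop = FALSE]
      if (nrow(sub) == 0L) NULL else kaplan_meier(sub$time, sub$event)
    })
  })
  lr <- stage("logrank", {
    a <- od[od$group == 0L, ]; b <- od[od$group == 1L, ]
    if (nrow(a) > 0L && nrow(b) > 0L)
      logrank_test(a$time, a$event, b$time, b$event) else NULL
  })
  best <- stage("best_response", {
    stats::setNames(vapply(scored, best_response, character(1L)),
                    vapply(scored, `[[`, character(1L), "patient_id"))
  })
  resp <- stage("response_rates", response_rates(groups, best))
  cr <- stage("cr_durations", cr_durations(scored, groups,
                                           event_rule = config$cr_event_rule))
  pfc <- stage("prediction_frequency", prediction_frequency_comparison(scored, groups))
  cox <- stage("cox", {
    covs <- c("grade", "substage", "stage", "group")
    usable <- covs[vapply(covs, function(v) length(unique(od[[v]])) > 1L, logical(1L))]
    rbind(cox_model(od, usable, "univariate"),
          cox_model(od, usable, "multivariate"))
  })

  paths <- stage("write_outputs", {
    p <- c(matching_scores = file.path(outdir, "matching_scores.csv"),
           groups = file.path(outdir, "groups.csv"),
           km_curves = file.path(outdir, "km_curves.csv"),
           cox_table = file.path(outdir, "cox_table.csv"),
           summary = file.path(outdir, "summary.json"),
           run_log = file.path(outdir, "run_log.json"))
    written <- p

    utils::write.csv(matching, p[["matching_scores"]], row.names = FALSE,
                     quote = FALSE)
    groups_df <- data.frame(patient_id = names(groups),
                            matching_score = unname(svec[names(groups)]),
                            group = unname(groups), method = ga$method,
                            threshold = ga$threshold, stringsAsFactors = FALSE)
    utils::write.csv(groups_df, p[["groups"]], row.names = FALSE, quote = FALSE)

    km_df <- do.call(rbind, lapply(names(km), function(g) {
      cv <- km[[g]]
      if (is.null(cv)) return(NULL)
      data.frame(group = g, time = cv$time, survival = cv$survival,
                 at_risk = cv$at_risk, median = cv$median,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(km_df, p[["km_curves"]], row.names = FALSE, quote = FALSE)
    cox_out <- as.data.frame(cox)
    names(cox_out) <- sub("^hr$", "HR", names(cox_out))
    utils::write.csv(cox_out, p[["cox_table"]], row.names = FALSE, quote = FALSE)

    smry <- list(
      n_patients = length(cohort),
      n_included = length(scored),
      n_excluded = nrow(exclusions),
      variant = config$variant,
      dichotomization = list(method = ga$method, threshold = ga$threshold,
                             n_low = ga$n_low, n_high = ga$n_high),
      survival = list(
        median_days = lapply(km, function(cv) if (is.null(cv)) NULL else cv$median),
        logrank_p = if (is.null(lr)) NULL else lr$p.value),
      response = list(
        per_group = resp$table,
        fisher_p = as.list(resp$fisher_p)),
      cr_duration_median_days = lapply(cr$curves, `[[`, "median"),
      cox_group_hr = {
        g <- cox[cox$covariate == "group", , drop = FALSE]
        lapply(split(g, g$mode), function(r)
          list(hr = r$hr, ci_low = r$ci_low, ci_high = r$ci_high, p = r$p))
      },
      seed = config$seed
    )
    jsonlite::write_json(smry, p[["summary"]], auto_unbox = TRUE, digits = 10,
                         dataframe = "rows", null = "null", pretty = TRUE)

    log <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("oncomatch")),
      flags = list(method = config$method, variant = config$variant,
                   fixed_threshold = config$fixed_threshold,
                   include_unscored = config$include_unscored,
                   cr_event_rule = config$cr_event_rule,
                   min_administrations = config$min_administrations,
                   post_report_only = TRUE),
      n_input = length(cohort), n_included = length(scored),
      exclusions = exclusions
    )
    jsonlite::write_json(log, p[["run_log"]], auto_unbox = TRUE, digits = 10,
                         dataframe = "rows", null = "null", pretty = TRUE)
    p
  })

  ok <- TRUE
  invisible(list(patients = cohort, included = scored, exclusions = exclusions,
                 matching = matching, assignment = ga, survival = od, km = km,
                 logrank = lr, responses = resp, cr = cr,
                 prediction_freq = pfc, cox = cox, paths = paths))
}

#' Grouped baseline characteristics table
#'
#' Per-group summaries of the baseline covariates: counts (with percent)
#' for categorical variables, median and interquartile range for numeric
#' ones, and an explicit missing-value count per variable — missing values
#' are never silently dropped. No hypothesis tests are attached unless
#' requested.
#'
#' @param patients Nonempty list of [patient_record()] objects.
#' @param groups Optional named character vector patient id -> group; when
#'   `NULL` the whole cohort is summarized as one column.
#' @param test Attach a comparison p-value per variable (chi-squared for
#'   categorical, Wilcoxon for numeric); default `FALSE`.
#' @return `data.frame`: `variable`, `level`, one column per group, and
#'   `n_missing` (plus `p` when `test`).
#' @export
make_baseline_table <- function(patients, groups = NULL, test = FALSE) {
  if (length(patients) == 0L) stop_validation("make_baseline_table: empty cohort")
  ids <- vapply(patients, `[[`, character(1L), "patient_id")
  if (is.null(groups)) groups <- stats::setNames(rep("all", length(ids)), ids)
  lv <- sort(unique(unname(groups)))
  if (setequal(lv, c("low", "high"))) lv <- c("low", "high")
  df <- data.frame(
    grade = vapply(patients, `[[`, character(1L), "grade"),
    substage = vapply(patients, `[[`, character(1L), "substage"),
    stage = vapply(patients, `[[`, integer(1L), "stage"),
    group = unname(groups[ids]), stringsAsFactors = FALSE)

  summarize_cat <- function(var) {
    levels_ <- sort(unique(stats::na.omit(df[[var]])))
    rows <- lapply(levels_, function(l) {
      cells <- vapply(lv, function(g) {
        sub <- df[[var]][!is.na(df$group) & df$group == g]
        sprintf("%d (%.1f%%)", sum(sub == l, na.rm = TRUE),
                100 * mean(sub == l, na.rm = TRUE))
      }, character(1L))
      out <- data.frame(variable = var, level = as.character(l),
                        stringsAsFactors = FALSE)
      out[lv] <- as.list(cells)
      out$n_missing <- sum(is.na(df[[var]]))
      out
    })
    do.call(rbind, rows)
  }
  summarize_num <- function(var) {
    cells <- vapply(lv, function(g) {
      sub <- df[[var]][!is.na(df$group) & df$group == g]
      q <- stats::quantile(sub, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
      sprintf("%.1f [%.1f-%.1f]", q[2L], q[1L], q[3L])
    }, character(1L))
    out <- data.frame(variable = var, level = "median [IQR]",
                      stringsAsFactors = FALSE)
    out[lv] <- as.list(cells)
    out$n_missing <- sum(is.na(df[[var]]))
    out
  }
  out <- rbind(summarize_cat("grade"), summarize_cat("substage"),
               summarize_num("stage"))
  n_row <- data.frame(variable = "n", level = "", stringsAsFactors = FALSE)
  n_row[lv] <- as.list(vapply(lv, function(g)
    as.character(sum(df$group == g, na.rm = TRUE)), character(1L)))
  n_row$n_missing <- sum(is.na(df$group))
  out <- rbind(n_row, out)
  if (test && length(lv) == 2L) {
    out$p <- NA_real_
    for (v in c("grade", "substage")) {
      tb <- table(df[[v]], df$group)
      out$p[out$variable == v] <- tryCatch(
        stats::fisher.test(tb)$p.value, error = function(e) NA_real_)
    }
    out$p[out$variable == "stage"] <- tryCatch(
      stats::wilcox.test(df$stage ~ df$group, exact = FALSE)$p.value,
      error = function(e) NA_real_)
  }
  rownames(out) <- NULL
  out
}
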