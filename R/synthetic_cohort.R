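DEFAULT_DRUG_PANEL <- c(
  "doxorubicin", "cyclophosphamide", "vincristine", "prednisone",
  "lomustine", "rabacfosadine", "mitoxantrone", "vinblastine",
  "chlorambucil", "asparaginase"
)

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a relapsed canine B-cell lymphoma cohort under
#' model-guided rescue therapy: 60 dogs, a 10-drug panel, prediction scores
#' calibrated so a score of 0.5 corresponds to a 50% response probability,
#' oncologists following high-score recommendations most of the time,
#' drug switching on progression (so longer-lived patients accumulate more
#' distinct drugs), a baseline hazard giving an 83-day median survival for
#' fully unmatched treatment, a matching-effect hazard ratio of 0.3, and
#' administrative censoring at two years.
#'
#' @param n_patients Number of patients (>= 2; default 60).
#' @param drug_panel Character vector of drug names (default: 10 drugs
#'   commonly used against canine lymphoid malignancies).
#' @param score_noise_sd SD of the Gaussian noise separating the reported
#'   prediction score from the drug's true response probability (default 0.1).
#' @param adherence Mean probability in `[0, 1]` that the oncologist draws
#'   the next drug from the recommended set (score > 0.5) rather than from
#'   the whole panel (default 0.75, which together with the default panel
#'   puts the cohort's median matching score near the high-80s percent
#'   range typical of decision-support cohorts).
#' @param adherence_concentration Concentration `k > 0` of the per-patient
#'   adherence draw `a_i ~ Beta(k * adherence, k * (1 - adherence))`
#'   (default 1). Different treating clinicians follow recommendations to
#'   very different degrees; this between-patient heterogeneity is what
#'   spreads matching scores across the cohort. Use `Inf` for a
#'   homogeneous cohort.
#' @param baseline_hazard Per-day death hazard of a patient whose treatment
#'   never matches (default `log(2) / 83`).
#' @param beta_match Log hazard ratio applied to the fraction of effective
#'   treatment; `log(0.3)` means a fully matched patient has 0.3 times the
#'   baseline hazard. Set 0 for a null cohort.
#' @param switch_on_progression Change drug after a PD assessment
#'   (default `TRUE`).
#' @param assessment_interval_days Days between response assessments; also
#'   the treatment decision-epoch length (default 21, a common
#'   chemotherapy cycle).
#' @param study_horizon_days Administrative censoring horizon (default 730).
#' @param cr_fraction Fraction of positive responses recorded as CR rather
#'   than PR (default 0.5).
#' @param backbone_prednisone_prob Probability that a patient receives
#'   continuous twice-weekly backbone prednisone for the whole observation
#'   period, independent of its prediction score (default 0.8) — the
#'   standard corticosteroid backbone of rescue protocols. Backbone
#'   patients do not additionally draw prednisone as an epoch drug. Set 0
#'   to disable; ignored when prednisone is not on the panel.
#' @param weekly_drugs Panel drugs administered weekly within an epoch;
#'   prednisone is given twice weekly (so it aggregates in weekly-window
#'   mode) and all other drugs once per epoch (defaults follow common
#'   canine lymphoma dosing: vincristine, vinblastine, asparaginase).
#' @param seed Integer seed making generation deterministic.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 60L,
                          drug_panel = DEFAULT_DRUG_PANEL,
                          score_noise_sd = 0.1,
                          adherence = 0.75,
                          adherence_concentration = 1,
                          baseline_hazard = log(2) / 83,
                          beta_match = log(0.3),
                          switch_on_progression = TRUE,
                          assessment_interval_days = 21L,
                          study_horizon_days = 730L,
                          cr_fraction = 0.5,
                          backbone_prednisone_prob = 0.8,
                          weekly_drugs = c("vincristine", "vinblastine",
                                           "asparaginase"),
                          seed = NULL) {
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 2L)
    stop_validation("n_patients must be an integer >= 2")
  if (length(drug_panel) < 1L || anyDuplicated(drug_panel))
    stop_validation("drug_panel must be a nonempty set of unique drug names")
  if (!is.numeric(score_noise_sd) || score_noise_sd <= 0)
    stop_validation("score_noise_sd must be positive")
  if (!is.numeric(adherence) || adherence < 0 || adherence > 1)
    stop_validation("adherence must lie in [0, 1]")
  if (!is.numeric(adherence_concentration) || adherence_concentration <= 0)
    stop_validation("adherence_concentration must be positive (Inf allowed)")
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0)
    stop_validation("baseline_hazard must be positive")
  if (!is.numeric(beta_match) || is.na(beta_match))
    stop_validation("beta_match must be a finite number")
  if (as.integer(assessment_interval_days) < 1L)
    stop_validation("assessment_interval_days must be >= 1")
  if (as.integer(study_horizon_days) < as.integer(assessment_interval_days))
    stop_validation("study_horizon_days must cover at least one epoch")
  if (cr_fraction < 0 || cr_fraction > 1)
    stop_validation("cr_fraction must lie in [0, 1]")
  if (backbone_prednisone_prob < 0 || backbone_prednisone_prob > 1)
    stop_validation("backbone_prednisone_prob must lie in [0, 1]")
  structure(list(
    n_patients = n_patients, drug_panel = as.character(drug_panel),
    score_noise_sd = score_noise_sd, adherence = adherence,
    adherence_concentration = adherence_concentration,
    baseline_hazard = baseline_hazard, beta_match = beta_match,
    switch_on_progression = isTRUE(switch_on_progression),
    assessment_interval_days = as.integer(assessment_interval_days),
    study_horizon_days = as.integer(study_horizon_days),
    cr_fraction = cr_fraction,
    backbone_prednisone_prob = backbone_prednisone_prob,
    weekly_drugs = as.character(weekly_drugs),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Simulates, per patient: (1) true per-drug response probabilities
#' `p_d ~ Beta(2, 2)` and reported scores `s_d = clip(p_d + N(0, sd), 0, 1)`,
#' so the empirical response rate among score-0.5 drugs is about 50%;
#' (2) treatment in decision epochs — each epoch the oncologist keeps the
#' current drug, or (at start, or after a PD when `switch_on_progression`)
#' draws a new one from the recommended set with probability `adherence`
#' and uniformly from the panel otherwise; prednisone is administered twice
#' weekly (aggregating to weekly-window courses), all other drugs once per
#' epoch; each epoch ends in an assessment whose category is drawn from the
#' drug's true response probability; (3) a death time from an exponential
#' hazard `baseline_hazard * exp(beta_match * f)`, where `f` is the
#' patient's fraction of planned treatment courses whose drug has true
#' response probability above 0.5, with administrative censoring at the
#' study horizon. Records are truncated at death/censoring, which is what
#' couples survival to the number of distinct drugs accumulated.
#'
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed`.
#' @return List with `patients` (list of [patient_record()]) and `reports`
#'   (list of [prediction_report()], same order). Deterministic given seed.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, as.list(config))
  with_local_seed(seed, generate_cohort_impl(config))
}

patient_adherence <- function(m, k) {
  if (!is.finite(k) || m <= 0 || m >= 1) return(m)
  stats::rbeta(1L, k * m, k * (1 - m))
}

generate_cohort_impl <- function(config) {
  K <- length(config$drug_panel)
  interval <- config$assessment_interval_days
  horizon <- config$study_horizon_days
  n_epochs <- horizon %/% interval
  base_date <- as.Date("2020-06-26")
  weekly_off <- seq(0L, interval - 1L, by = 7L)
  # twice-weekly dosing (days 0 and 3 of each week of the epoch)
  twice_weekly_off <- sort(c(weekly_off, weekly_off + 3L))
  twice_weekly_off <- twice_weekly_off[twice_weekly_off < interval]

  # Number of courses one epoch of a drug aggregates to: twice-weekly
  # dosing collapses into 7-day windows, weekly/once dosing is counted per
  # administration.
  epoch_offsets <- function(drug) {
    if (drug == "prednisone") twice_weekly_off
    else if (drug %in% config$weekly_drugs) weekly_off
    else 0L
  }
  epoch_course_weight <- function(drug) {
    offs <- epoch_offsets(drug)
    if (drug == "prednisone") length(unique(offs %/% 7L)) else length(offs)
  }

  patients <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", i)
    delivery <- base_date + (sample.int(860L, 1L) - 1L)
    p_true <- stats::setNames(stats::rbeta(K, 2, 2), config$drug_panel)
    s <- pmin(pmax(p_true + stats::rnorm(K, 0, config$score_noise_sd), 0), 1)
    report <- prediction_report(pid, delivery, stats::setNames(s, config$drug_panel))
    recommended <- config$drug_panel[s > MATCH_THRESHOLD]
    a_i <- patient_adherence(config$adherence, config$adherence_concentration)
    backbone <- "prednisone" %in% config$drug_panel &&
      stats::runif(1) < config$backbone_prednisone_prob
    pick_panel <- if (backbone)
      setdiff(config$drug_panel, "prednisone") else config$drug_panel
    if (length(pick_panel) == 0L) pick_panel <- config$drug_panel
    pick_recommended <- intersect(recommended, pick_panel)

    pick_drug <- function(exclude = NULL) {
      pool <- if (stats::runif(1) < a_i && length(pick_recommended) > 0L)
        pick_recommended else pick_panel
      pool2 <- setdiff(pool, exclude)
      if (length(pool2) == 0L) pool2 <- setdiff(pick_panel, exclude)
      if (length(pool2) == 0L) pool2 <- pool
      pool2[sample.int(length(pool2), 1L)]
    }

    # One drug per decision epoch, redrawn every epoch so the per-course
    # match probability is stationary in time; a PD assessment additionally
    # forces a change of drug (switch-on-progression).
    adm_drug <- character(); adm_day <- integer()
    if (backbone) {
      pred_days <- 1L + sort(as.integer(outer(c(0L, 3L),
                                              7L * (seq_len(horizon %/% 7L) - 1L),
                                              `+`)))
      pred_days <- pred_days[pred_days <= horizon]
      adm_drug <- rep("prednisone", length(pred_days))
      adm_day <- pred_days
    }
    res_day <- integer(); res_cat <- character()
    epoch_drug <- character(n_epochs)
    drug <- pick_drug()
    for (e in seq_len(n_epochs)) {
      epoch_drug[e] <- drug
      start <- 1L + (e - 1L) * interval
      offs <- epoch_offsets(drug)
      adm_drug <- c(adm_drug, rep(drug, length(offs)))
      adm_day <- c(adm_day, start + offs)
      success <- stats::runif(1) < p_true[[drug]]
      cat_e <- if (success) {
        if (stats::runif(1) < config$cr_fraction) "CR" else "PR"
      } else {
        if (stats::runif(1) < 0.5) "PD" else "SD"
      }
      res_day <- c(res_day, e * interval)
      res_cat <- c(res_cat, cat_e)
      drug <- if (config$switch_on_progression && cat_e == "PD")
        pick_drug(exclude = drug) else pick_drug()
    }

    # Planned course-weighted fraction of effective treatment: each epoch
    # contributes its drug once per course it aggregates to; backbone
    # prednisone adds one weekly-window course per week on treatment.
    w <- vapply(epoch_drug, epoch_course_weight, integer(1L))
    num <- sum(w * (p_true[epoch_drug] > MATCH_THRESHOLD))
    den <- sum(w)
    if (backbone) {
      w_pred <- horizon %/% 7L
      num <- num + w_pred * (p_true[["prednisone"]] > MATCH_THRESHOLD)
      den <- den + w_pred
    }
    f <- num / den
    t_death <- stats::rexp(1L, config$baseline_hazard *
                               exp(config$beta_match * f))
    event <- t_death <= horizon
    obs_day <- if (event) max(1L, as.integer(ceiling(t_death))) else horizon

    keep_a <- adm_day <= obs_day
    keep_r <- res_day <= obs_day
    administrations <- if (any(keep_a)) {
      data.frame(patient_id = pid, drug = adm_drug[keep_a],
                 date = delivery + adm_day[keep_a], stringsAsFactors = FALSE)
    } else {
      empty_administrations()
    }
    responses <- if (any(keep_r)) {
      data.frame(patient_id = pid, date = delivery + res_day[keep_r],
                 category = res_cat[keep_r], stringsAsFactors = FALSE)
    } else {
      empty_responses()
    }

    patients[[i]] <- patient_record(
      patient_id = pid,
      grade = if (stats::runif(1) < 0.85) "high" else "low",
      stage = sample(1:5, 1L, prob = c(0.05, 0.10, 0.20, 0.35, 0.30)),
      substage = if (stats::runif(1) < 0.5) "a" else "b",
      report = report,
      administrations = administrations,
      responses = responses,
      last_followup_date = delivery + obs_day,
      death_date = if (event) delivery + obs_day else as.Date(NA),
      event = event
    )
  }
  list(patients = patients,
       reports = lapply(patients, `[[`, "report"))
}

#' Write a cohort to the four pipeline CSV files
#'
#' Emits `reports.csv`, `administrations.csv`, `responses.csv` and
#' `patients.csv` in the dialects read by [read_cohort()]; the round trip
#' reproduces the records exactly.
#'
#' @param patients List of [patient_record()] objects.
#' @param directory Output directory, created (recursively) on demand.
#' @return Invisibly, the four file paths (named character vector).
#' @export
write_cohort <- function(patients, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop_validation("cannot create directory '%s'", directory)
  paths <- file.path(directory, c(reports = "reports.csv",
                                  administrations = "administrations.csv",
                                  responses = "responses.csv",
                                  patients = "patients.csv"))
  names(paths) <- c("reports", "administrations", "responses", "patients")

  reports <- do.call(rbind, lapply(patients, function(p) {
    s <- p$report$scores
    data.frame(patient_id = p$patient_id, drug = names(s), score = unname(s),
               delivery_date = format(p$report$delivery_date),
               stringsAsFactors = FALSE)
  }))
  adm <- do.call(rbind, lapply(patients, function(p) {
    a <- p$administrations
    if (nrow(a) == 0L) return(NULL)
    data.frame(patient_id = a$patient_id, drug = a$drug,
               date = format(a$date), stringsAsFactors = FALSE)
  }))
  if (is.null(adm))
    adm <- data.frame(patient_id = character(), drug = character(),
                      date = character(), stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(patients, function(p) {
    r <- p$responses
    if (nrow(r) == 0L) return(NULL)
    data.frame(patient_id = r$patient_id, date = format(r$date),
               category = toupper(r$category), stringsAsFactors = FALSE)
  }))
  if (is.null(res))
    res <- data.frame(patient_id = character(), date = character(),
                      category = character(), stringsAsFactors = FALSE)
  pat <- do.call(rbind, lapply(patients, function(p) {
    data.frame(patient_id = p$patient_id, grade = p$grade, stage = p$stage,
               substage = p$substage,
               last_followup_date = format(p$last_followup_date),
               death_date = if (is.na(p$death_date)) "" else format(p$death_date),
               event = as.integer(p$event), stringsAsFactors = FALSE)
  }))

  utils::write.csv(reports, paths[["reports"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(adm, paths[["administrations"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(res, paths[["responses"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(pat, paths[["patients"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

# One replicate of the generate -> score -> dichotomize -> Cox chain.
# Returns one row per requested score variant.
replicate_group_hr <- function(config, rep_seed, shuffle,
                               variants = c("modified", "standard")) {
  cohort <- generate_cohort(config, seed = rep_seed)
  incl <- inclusion_filter(cohort$patients)
  pats <- incl$included
  if (length(pats) < 4L)
    return(NULL)
  if (shuffle)
    pats <- shuffle_predictions(pats, seed = rep_seed + 500000L)
  tab <- cohort_matching_scores(pats)
  od <- cohort_survival(pats)
  rows <- lapply(variants, function(v) {
    col <- if (v == "modified") "modified_score" else "standard_score"
    svec <- stats::setNames(tab[[col]], tab$patient_id)
    svec <- svec[!is.na(svec)]
    row <- data.frame(score_variant = v, hr = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, n_patients = length(svec),
                      stringsAsFactors = FALSE)
    est <- tryCatch({
      ga <- dichotomize(svec, "median")
      sub <- od[match(names(ga$assignment), od$patient_id), ]
      grp <- as.integer(ga$assignment == "high")
      fit <- survival::coxph(survival::Surv(sub$time, sub$event) ~ grp,
                             ties = "breslow")
      ci <- summary(fit)$conf.int
      c(ci[1, "exp(coef)"], ci[1, "lower .95"], ci[1, "upper .95"])
    }, error = function(e) rep(NA_real_, 3L))
    row$hr <- est[[1L]]
    row$ci_low <- est[[2L]]
    row$ci_high <- est[[3L]]
    row
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Replicated hazard-ratio experiments on synthetic cohorts
#'
#' Repeatedly generates a cohort, optionally shuffles the prediction
#' reports across patients, computes matching scores, median-dichotomizes,
#' and fits a univariate Cox model on the group indicator (high = 1).
#'
#' @param config A [cohort_config()].
#' @param n_reps Number of replicates.
#' @param shuffle Shuffle reports across patients before scoring.
#' @param variants Score variants to evaluate, subset of
#'   `c("modified", "standard")`.
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @return `data.frame`: `replicate`, `score_variant`, `hr`, `ci_low`,
#'   `ci_high`, `n_patients`. Replicates where the fit failed (degenerate
#'   scores) carry `NA` estimates.
#' @export
hr_replicates <- function(config, n_reps, shuffle = FALSE,
                          variants = c("modified", "standard"),
                          seed = if (is.null(config$seed)) 1L else config$seed) {
  rows <- lapply(seq_len(n_reps), function(r) {
    out <- replicate_group_hr(config, seed + r, shuffle, variants)
    if (is.null(out)) return(NULL)
    cbind(data.frame(replicate = r), out)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Shuffled-recommendation bias experiment
#'
#' The diagnostic behind the modified matching score: under shuffled
#' recommendations no score should separate outcomes, yet the standard
#' (drug-level) score still produces hazard ratios below 1 because
#' longer-lived patients accumulate more distinct drugs and therefore hit
#' more of the (arbitrary) actionable set. The modified score, with all
#' administered courses in its denominator, does not reward volume and
#' stays null. Requires `switch_on_progression` dynamics, the mechanism
#' that couples survival time to drug accumulation.
#'
#' @inheritParams hr_replicates
#' @return `data.frame` as in [hr_replicates()], both score variants per
#'   replicate under the shuffled null.
#' @export
bias_experiment <- function(config, n_reps,
                            seed = if (is.null(config$seed)) 1L else config$seed) {
  if (!config$switch_on_progression)
    stop_validation("bias_experiment requires switch_on_progression dynamics")
  hr_replicates(config, n_reps, shuffle = TRUE,
                variants = c("modified", "standard"), seed = seed)
}
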