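# Independent oracle: empirical survival function S(t) = mean(durations > t),
# evaluated at the curve's time points. Equals the product-limit estimate
# whenever there is no censoring.
empirical_surv <- function(durations, times) {
  vapply(times, function(t) mean(durations > t), numeric(1))
}

test_that("Kaplan-Meier equals the empirical survival function without censoring (exhaustive n <= 8)", {
  values <- c(1, 2, 5)
  for (n in 1:8) {
    combos <- utils::combn(length(values) + n - 1, n)  # multisets via stars and bars
    for (j in seq_len(ncol(combos))) {
      durations <- values[combos[, j] - seq_len(n) + 1]
      km <- kaplan_meier(durations, rep(TRUE, n))
      expect_equal(km$survival, empirical_surv(durations, km$time),
                   tolerance = 1e-12)
    }
  }
})

test_that("Kaplan-Meier basics: steps, censoring, median", {
  km <- kaplan_meier(c(3, 1, 4, 2), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$at_risk, c(4L, 3L, 2L, 1L))
  expect_equal(km$median, 2)  # smallest time with S <= 0.5
  flat <- kaplan_meier(c(10, 20, 30), c(FALSE, FALSE, FALSE))
  expect_true(all(flat$survival == 1))
  expect_true(is.na(flat$median))
  # censored subjects shrink risk sets without steps
  mix <- kaplan_meier(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(mix$survival, c(2 / 3, 2 / 3, 0), tolerance = 1e-12)
  expect_error(kaplan_meier(numeric(0), logical(0)),
               class = "oncomatch_validation_error")
  expect_error(kaplan_meier(c(-1, 2), c(TRUE, TRUE)),
               class = "oncomatch_validation_error")
})

test_that("KM median of exponential survival matches ln(2)/lambda within 5%", {
  set.seed(41)
  lambda <- 0.01
  km <- kaplan_meier(rexp(1000, lambda), rep(TRUE, 1000))
  expect_lt(abs(km$median - log(2) / lambda) / (log(2) / lambda), 0.05)
})

test_that("logrank test: identity, symmetry, and separation", {
  a <- c(10, 20, 30, 40)
  e <- c(TRUE, TRUE, FALSE, TRUE)
  ident <- logrank_test(a, e, a, e)
  expect_equal(unname(ident$statistic), 0, tolerance = 1e-12)
  expect_equal(ident$p.value, 1, tolerance = 1e-12)
  set.seed(42)
  b <- rexp(20, 0.05); eb <- runif(20) > 0.3
  a2 <- rexp(25, 0.02); ea <- runif(25) > 0.3
  expect_equal(logrank_test(a2, ea, b, eb)$statistic,
               logrank_test(b, eb, a2, ea)$statistic, tolerance = 1e-12)
  expect_error(logrank_test(numeric(0), logical(0), b, eb),
               class = "oncomatch_validation_error")
  # strongly separated exponentials: p < 0.001 in >= 95% of simulations
  hits <- 0L
  for (r in 1:200) {
    ga <- rexp(50, 0.04); gb <- rexp(50, 0.01)
    hits <- hits + (logrank_test(ga, rep(TRUE, 50), gb, rep(TRUE, 50))$p.value < 0.001)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("logrank p-values are uniform under label permutation", {
  set.seed(43)
  time <- rexp(30, 0.02)
  event <- runif(30) > 0.2
  pvals <- vapply(1:500, function(r) {
    lab <- sample(rep(c(TRUE, FALSE), each = 15))
    logrank_test(time[lab], event[lab], time[!lab], event[!lab])$p.value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

# Oracle: two-sided Fisher p by full hypergeometric enumeration, summing the
# probabilities of all tables no more likely than the observed one.
fisher_enum <- function(m) {
  k <- m[1, 1]; r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  sum(probs[probs <= stats::dhyper(k, r1, r2, c1) * (1 + 1e-7)])
}

test_that("response rates and Fisher tests match the enumeration oracle", {
  groups <- stats::setNames(rep(c("high", "low"), each = 30),
                            sprintf("p%02d", 1:60))
  # 16/30 CR in high vs 4/30 in low (the 53.3% vs 13.3% CRR pattern)
  best <- stats::setNames(
    c(rep("CR", 16), rep("SD", 14), rep("CR", 4), rep("PD", 26)),
    names(groups))
  rs <- response_rates(groups, best)
  high <- rs$table[rs$table$group == "high", ]
  low <- rs$table[rs$table$group == "low", ]
  expect_equal(high$crr, 100 * 16 / 30, tolerance = 1e-9)
  expect_equal(low$crr, 100 * 4 / 30, tolerance = 1e-9)
  expect_equal(rs$fisher_p[["crr"]],
               fisher_enum(matrix(c(16, 14, 4, 26), 2, byrow = TRUE)),
               tolerance = 1e-9)
  expect_equal(round(rs$fisher_p[["crr"]], 3), 0.002)
  # counts always sum to the group size and CRR <= ORR
  expect_equal(high$n_CR + high$n_PR + high$n_SD + high$n_PD +
                 high$n_no_assessment, high$n)
  expect_lte(high$crr, high$orr)
})

test_that("response rates: rates, unassessed patients, and degenerate groups", {
  groups <- stats::setNames(rep(c("high", "low"), each = 3), paste0("p", 1:6))
  best <- stats::setNames(c("CR", "PR", "SD", "CR", "PR", "SD"), names(groups))
  rs <- response_rates(groups, best)
  expect_equal(rs$table$crr, c(100 / 3, 100 / 3), tolerance = 1e-9)
  expect_equal(rs$table$orr, c(200 / 3, 200 / 3), tolerance = 1e-9)
  expect_equal(unname(rs$fisher_p), c(1, 1))
  # a patient never assessed stays in the denominator as a non-responder
  best2 <- best; best2[["p1"]] <- NA_character_
  rs2 <- response_rates(groups, best2)
  expect_equal(rs2$table$n_no_assessment, c(1L, 0L))
  expect_equal(rs2$table$n[1], 3L)
  expect_error(response_rates(stats::setNames("high", "p1"), best),
               class = "oncomatch_validation_error")
  # symmetry under simultaneous row/column swap
  m <- matrix(c(16, 14, 4, 26), 2, byrow = TRUE)
  expect_equal(fisher_enum(m), fisher_enum(m[2:1, 2:1]), tolerance = 1e-12)
})

test_that("BH adjustment matches the step-up oracle and its properties", {
  # the textbook example: (0.01, 0.02, 0.03, 0.04) all adjust to 0.04
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(44)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # monotone in rank
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "oncomatch_validation_error")
})

test_that("prediction frequency comparison: identical groups are all null", {
  gen <- generate_cohort(cohort_config(n_patients = 10, seed = 8))
  pats <- gen$patients
  ids <- vapply(pats, `[[`, character(1), "patient_id")
  # mirrored groups: same patients counted in both -> identical frequencies
  doubled <- c(pats, pats)
  groups <- stats::setNames(rep(c("low", "high"), each = 10),
                            c(ids, paste0(ids, "x")))
  for (i in 11:20) doubled[[i]]$patient_id <- paste0(ids[i - 10], "x")
  tab <- prediction_frequency_comparison(doubled, groups)
  expect_true(all(tab$z == 0))
  expect_true(all(tab$p == 1))
  expect_true(all(tab$p_adjusted == 1))
  expect_equal(tab$freq_low, tab$freq_high)
  # requesting an unknown drug warns and drops it
  expect_warning(
    tab2 <- prediction_frequency_comparison(doubled, groups,
                                            drugs = c("doxorubicin", "nosuchdrug")),
    "no report")
  expect_equal(tab2$drug, "doxorubicin")
  expect_true(all(tab2$p_adjusted >= tab2$p - 1e-12))
})

test_that("CR durations: event on first PD after CR, censoring at follow-up", {
  p_event <- make_patient(id = "e", response_days = c(10, 210),
                          response_cats = c("CR", "PD"), followup_days = 400)
  p_cens <- make_patient(id = "c", response_days = 10,
                         response_cats = "CR", followup_days = 100)
  # PR after CR is not an event under the default rule, but is under pd_or_pr
  p_pr <- make_patient(id = "r", response_days = c(10, 150),
                       response_cats = c("CR", "PR"), followup_days = 300)
  groups <- c(e = "high", c = "high", r = "low")
  out <- cr_durations(list(p_event, p_cens, p_pr), groups)
  expect_equal(out$durations$time[out$durations$patient_id == "e"], 200L)
  expect_equal(out$durations$event[out$durations$patient_id == "e"], 1L)
  expect_equal(out$durations$time[out$durations$patient_id == "c"], 90L)
  expect_equal(out$durations$event[out$durations$patient_id == "c"], 0L)
  expect_equal(out$durations$event[out$durations$patient_id == "r"], 0L)
  expect_equal(out$curves$high$n, 2L)
  out2 <- cr_durations(list(p_event, p_cens, p_pr), groups,
                       event_rule = "pd_or_pr")
  expect_equal(out2$durations$event[out2$durations$patient_id == "r"], 1L)
  # a group with no CR patients is omitted with a warning
  groups_na <- c(e = "high", c = "high", r = "high")
  p_nocr <- make_patient(id = "n", response_days = 10, response_cats = "PR")
  expect_warning(out3 <- cr_durations(list(p_event, p_nocr),
                                      c(e = "high", n = "low")),
                 "no CR")
  expect_null(out3$curves$low)
})

test_that("Cox model recovers a known hazard ratio and covers the null", {
  set.seed(45)
  reps <- 200
  n <- 200
  covered_effect <- 0L
  covered_null <- 0L
  for (r in seq_len(reps)) {
    x <- rbinom(n, 1, 0.5)
    t_true <- rexp(n, 0.01 * exp(log(0.3) * x))
    cens <- quantile(t_true, 0.8)  # administrative, ~20% censored
    d <- data.frame(time = pmin(t_true, cens), event = as.integer(t_true <= cens),
                    x = x, z = rbinom(n, 1, 0.5))
    fit <- cox_model(d, c("x"), "univariate")
    covered_effect <- covered_effect + (fit$ci_low <= 0.3 && 0.3 <= fit$ci_high)
    fitz <- cox_model(d, c("z"), "univariate")
    covered_null <- covered_null + (fitz$ci_low <= 1 && 1 <= fitz$ci_high)
  }
  expect_gte(covered_effect / reps, 0.93)
  expect_gte(covered_null / reps, 0.90)
  expect_lte(covered_null / reps, 0.99)
})

test_that("Cox model output structure, degenerate covariates, PH check", {
  set.seed(46)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  t_true <- rexp(n, 0.02 * exp(-0.8 * x))
  d <- data.frame(time = t_true, event = 1L, x = x, flat = 0L)
  res <- cox_model(d, "x", "univariate")
  expect_s3_class(res, "cox_result")
  expect_equal(res$hr, exp(res$coef), tolerance = 1e-9)
  expect_true(res$ci_low > 0 && res$ci_low < res$hr && res$hr < res$ci_high)
  expect_true(res$concordance >= 0 && res$concordance <= 1)
  expect_true(res$ph_pass %in% c(TRUE, FALSE))
  # HR direction agrees with group event-time comparison
  expect_lt(res$hr, 1)
  expect_gt(median(t_true[x == 1]), median(t_true[x == 0]))
  # an all-zero covariate yields NA estimates with a warning, never silence
  expect_warning(flat <- cox_model(d, "flat", "univariate"), "singular")
  expect_true(is.na(flat$coef))
  # multivariate mode returns one row per covariate with shared concordance
  d$z <- rbinom(n, 1, 0.5)
  mv <- cox_model(d, c("x", "z"), "multivariate")
  expect_equal(nrow(mv), 2L)
  expect_equal(length(unique(mv$concordance)), 1L)
  # missing values dropped with a message
  d2 <- d; d2$x[1] <- NA
  expect_message(cox_model(d2, "x", "univariate"), "dropped 1")
})

test_that("Cox coefficient of a symmetric design is zero with concordance 1/2", {
  # mirror pairs (t, x) / (t, 1 - x): the partial-likelihood score at
  # beta = 0 vanishes by symmetry
  t0 <- c(5, 9, 13, 17)
  d <- data.frame(time = rep(t0, each = 2), event = 1L,
                  x = rep(c(0L, 1L), times = 4))
  res <- cox_model(d, "x", "univariate")
  expect_equal(res$coef, 0, tolerance = 1e-8)
  expect_equal(res$concordance, 0.5, tolerance = 1e-9)
})

test_that("historical survival after relapse is a guarded difference", {
  expect_equal(historical_survival_after_relapse(250, 140), 110)
  expect_equal(historical_survival_after_relapse(100, 99), 1)
  expect_error(historical_survival_after_relapse(100, 120),
               class = "oncomatch_validation_error")
  expect_error(historical_survival_after_relapse(-5, 3),
               class = "oncomatch_validation_error")
})
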