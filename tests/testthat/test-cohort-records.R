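test_that("read_cohort assembles records from the four CSV files", {
  dir <- write_cohort_csvs(
    withr::local_tempdir(),
    reports = c("p1,doxorubicin,0.8,2021-01-01", "p1,lomustine,0.4,2021-01-01"),
    administrations = c("p1,doxorubicin,2021-01-10", "p1,lomustine,2021-02-01"),
    responses = "p1,2021-01-20,pr",
    patients = "p1,high,4,b,2021-06-01,,0")
  cohort <- read_cohort_dir(dir)
  expect_length(cohort, 1L)
  p <- cohort[[1L]]
  expect_s3_class(p, "patient_record")
  expect_equal(nrow(p$administrations), 2L)
  expect_equal(p$report$scores, c(doxorubicin = 0.8, lomustine = 0.4))
  expect_equal(p$responses$category, "PR")  # canonical uppercase
  expect_false(p$event)
  expect_equal(survival_days(p), as.integer(as.Date("2021-06-01") - as.Date("2021-01-01")))
})

test_that("read_cohort validation: bad scores, dates, duplicates, strays", {
  base <- list(
    reports = "p1,doxorubicin,0.8,2021-01-01",
    administrations = "p1,doxorubicin,2021-01-10",
    responses = "p1,2021-01-20,PR",
    patients = "p1,high,4,b,2021-06-01,,0")
  run_with <- function(...) {
    args <- utils::modifyList(base, list(...))
    dir <- do.call(write_cohort_csvs, c(list(withr::local_tempdir()), args))
    read_cohort_dir(dir)
  }
  # score out of [0, 1] names file, row and field
  expect_error(run_with(reports = "p1,doxorubicin,1.2,2021-01-01"),
               "row 1.*score", class = "oncomatch_validation_error")
  # malformed date
  expect_error(run_with(administrations = "p1,doxorubicin,10/01/2021"),
               "ISO 8601", class = "oncomatch_validation_error")
  # duplicate (patient, drug) in a report
  expect_error(run_with(reports = c("p1,doxorubicin,0.8,2021-01-01",
                                    "p1,doxorubicin,0.5,2021-01-01")),
               "duplicate", class = "oncomatch_validation_error")
  # unknown response category
  expect_error(run_with(responses = "p1,2021-01-20,XX"),
               "category", class = "oncomatch_validation_error")
  # rows for unknown patients are rejected with a warning, not kept
  expect_warning(cohort <- run_with(
    administrations = c("p1,doxorubicin,2021-01-10", "ghost,lomustine,2021-01-11")),
    "unknown patient")
  expect_equal(nrow(cohort[[1L]]$administrations), 1L)
})

test_that("patients with an empty administrations table read cleanly", {
  dir <- write_cohort_csvs(
    withr::local_tempdir(),
    reports = "p1,doxorubicin,0.8,2021-01-01",
    administrations = character(),
    responses = character(),
    patients = "p1,high,4,b,2021-06-01,,0")
  cohort <- read_cohort_dir(dir)
  expect_equal(nrow(cohort[[1L]]$administrations), 0L)
  flt <- inclusion_filter(cohort)
  expect_length(flt$included, 0L)
  expect_equal(flt$exclusions$patient_id, "p1")
})

test_that("aggregate_treatments reproduces the worked example: 6 + 2 = 8 courses", {
  courses <- aggregate_treatments(worked_example_events(),
                                  as.Date("2020-12-31"))
  expect_equal(nrow(courses), 8L)
  expect_equal(sum(courses$drug == "prednisone"), 6L)
  expect_equal(sum(courses$drug == "rabacfosadine"), 2L)
  expect_setequal(courses$counting_mode[courses$drug == "prednisone"],
                  "weekly_window")
  expect_setequal(courses$counting_mode[courses$drug == "rabacfosadine"],
                  "per_administration")
  expect_true(all(courses$n_administrations[courses$drug == "prednisone"] == 2L))
})

test_that("aggregation frequency rule: weekly binning vs per administration", {
  day0 <- as.Date("2021-03-01")
  one <- data.frame(patient_id = "p", drug = "lomustine", date = day0)
  expect_equal(nrow(aggregate_treatments(one, day0 - 1)), 1L)
  expect_equal(aggregate_treatments(one, day0 - 1)$counting_mode,
               "per_administration")
  # daily for 14 consecutive days -> two 7-day windows
  daily <- data.frame(patient_id = "p", drug = "prednisone",
                      date = day0 + 0:13)
  agg <- aggregate_treatments(daily, day0 - 1)
  expect_equal(nrow(agg), 2L)
  expect_equal(agg$n_administrations, c(7L, 7L))
  expect_equal(agg$start_date, day0 + c(0, 7))
  # post-report filtering drops events on or before the delivery date
  mixed <- data.frame(patient_id = "p", drug = "vincristine",
                      date = day0 + c(-7, 0, 7, 14))
  expect_equal(nrow(aggregate_treatments(mixed, day0)), 2L)
  expect_equal(nrow(aggregate_treatments(mixed, day0, post_report_only = FALSE)), 4L)
  # empty input
  expect_equal(nrow(aggregate_treatments(mixed[0, ], day0)), 0L)
})

test_that("aggregation properties: order invariance and course-count bound", {
  day0 <- as.Date("2021-01-01")
  set.seed(11)
  for (i in 1:25) {
    n <- sample(1:25, 1)
    ev <- data.frame(
      patient_id = "p",
      drug = sample(c("a", "b", "c"), n, replace = TRUE),
      date = day0 + sample(0:60, n, replace = TRUE),
      stringsAsFactors = FALSE)
    ref <- aggregate_treatments(ev, day0 - 1)
    shuf <- aggregate_treatments(ev[sample(n), , drop = FALSE], day0 - 1)
    expect_identical(ref, shuf)
    # courses never exceed administrations; per-administration counting
    # preserves the count exactly, weekly binning only when a window holds
    # several administrations
    expect_lte(nrow(ref), nrow(ev))
    if (all(ref$counting_mode == "per_administration"))
      expect_equal(nrow(ref), nrow(ev))
    expect_equal(nrow(ref) == nrow(ev), all(ref$n_administrations == 1L))
    expect_equal(sum(ref$n_administrations), nrow(ev))
  }
})

test_that("derive_response_labels pairs courses with the next assessment", {
  day0 <- as.Date("2021-01-01")
  courses <- aggregate_treatments(
    data.frame(patient_id = "p", drug = "doxorubicin", date = day0 + c(5, 40, 90)),
    day0)
  responses <- data.frame(patient_id = "p", date = day0 + c(20, 60),
                          category = c("PR", "SD"), stringsAsFactors = FALSE)
  lab <- derive_response_labels(responses, courses)
  expect_equal(nrow(lab), 2L)  # day-90 course has no later assessment
  expect_equal(lab$label, c(1L, 0L))
  expect_equal(lab$response_category, c("PR", "SD"))
  # an assessment on the course start date counts ("on/after")
  same_day <- derive_response_labels(
    data.frame(patient_id = "p", date = day0 + 5, category = "CR"),
    courses[1, , drop = FALSE])
  expect_equal(same_day$label, 1L)
  expect_equal(nrow(derive_response_labels(responses, courses[0, ])), 0L)
})

test_that("best_response takes the post-report maximum of CR > PR > SD > PD", {
  p <- make_patient(response_days = c(10, 30, 50),
                    response_cats = c("SD", "PR", "SD"))
  expect_equal(best_response(p), "PR")
  expect_equal(best_response(make_patient(response_days = 10,
                                          response_cats = "PD")), "PD")
  expect_true(is.na(best_response(make_patient())))
  # assessments on or before delivery are ignored
  pre <- make_patient(response_days = 0, response_cats = "CR")
  expect_true(is.na(best_response(pre)))
})

test_that("inclusion filter applies the >= 3 post-report administration rule", {
  two <- make_patient(id = "two", admin_days = c(1, 8),
                      admin_drugs = rep("doxorubicin", 2))
  three <- make_patient(id = "three", admin_days = c(1, 8, 15),
                        admin_drugs = rep("doxorubicin", 3))
  # pre-report administrations never count
  padded <- make_patient(id = "padded", admin_days = c(-10, -5, 1, 8),
                         admin_drugs = rep("doxorubicin", 4))
  flt <- inclusion_filter(list(two, three, padded))
  expect_equal(vapply(flt$included, `[[`, character(1), "patient_id"), "three")
  expect_setequal(flt$exclusions$patient_id, c("two", "padded"))
  expect_match(flt$exclusions$reason[1], "need >= 3")
  empty <- inclusion_filter(list())
  expect_length(empty$included, 0L)
  expect_equal(nrow(empty$exclusions), 0L)
})

test_that("record invariants are enforced at construction", {
  expect_error(prediction_report("p", as.Date("2021-01-01"), c(a = 1.2)),
               class = "oncomatch_validation_error")
  expect_error(prediction_report("p", as.Date(NA), c(a = 0.5)),
               class = "oncomatch_validation_error")
  expect_error(make_patient(death_day = -3),
               class = "oncomatch_validation_error")
  expect_error(
    patient_record("p", "high", 3, "a",
                   prediction_report("p", as.Date("2021-01-01"), c(a = 0.5)),
                   last_followup_date = as.Date("2021-06-01"),
                   death_date = as.Date(NA), event = TRUE),
    class = "oncomatch_validation_error")
})
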