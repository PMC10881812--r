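# Shared fixtures, built in code.

# The worked-example dog: 6 weeks of twice-weekly prednisone (score 0.3)
# and two rabacfosadine infusions 21 days apart (score 0.7), all after the
# report. Expected: 6 + 2 = 8 treatment courses, matching score 25%.
worked_example_report <- function(delivery = as.Date("2020-12-31")) {
  prediction_report("dog1", delivery,
                    c(prednisone = 0.3, rabacfosadine = 0.7))
}

worked_example_events <- function(first_day = as.Date("2021-01-01")) {
  data.frame(
    patient_id = "dog1",
    drug = c(rep("prednisone", 12), "rabacfosadine", "rabacfosadine"),
    date = first_day + c(rep(7 * 0:5, each = 2) + c(0, 3), 0, 21),
    stringsAsFactors = FALSE
  )
}

# Minimal patient with explicit parts; sensible defaults for the rest.
make_patient <- function(id = "p1", scores = c(drugA = 0.8, drugB = 0.2),
                         delivery = as.Date("2021-01-01"),
                         admin_days = integer(), admin_drugs = character(),
                         response_days = integer(), response_cats = character(),
                         followup_days = 365L, death_day = NA_integer_,
                         grade = "high", stage = 3L, substage = "a") {
  adm <- if (length(admin_days) > 0L) {
    data.frame(patient_id = id, drug = admin_drugs,
               date = delivery + admin_days, stringsAsFactors = FALSE)
  } else {
    data.frame(patient_id = character(), drug = character(),
               date = as.Date(character()), stringsAsFactors = FALSE)
  }
  res <- if (length(response_days) > 0L) {
    data.frame(patient_id = id, date = delivery + response_days,
               category = response_cats, stringsAsFactors = FALSE)
  } else {
    data.frame(patient_id = character(), date = as.Date(character()),
               category = character(), stringsAsFactors = FALSE)
  }
  dead <- !is.na(death_day)
  patient_record(
    patient_id = id, grade = grade, stage = stage, substage = substage,
    report = prediction_report(id, delivery, scores),
    administrations = adm, responses = res,
    last_followup_date = delivery + if (dead) death_day else followup_days,
    death_date = if (dead) delivery + death_day else as.Date(NA),
    event = dead
  )
}

# Write the four cohort CSVs for read_cohort tests; fields given as strings
# so malformed values can be injected.
write_cohort_csvs <- function(dir, reports, administrations, responses, patients) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("patient_id,drug,score,delivery_date", reports),
             file.path(dir, "reports.csv"))
  writeLines(c("patient_id,drug,date", administrations),
             file.path(dir, "administrations.csv"))
  writeLines(c("patient_id,date,category", responses),
             file.path(dir, "responses.csv"))
  writeLines(c(paste0("patient_id,grade,stage,substage,",
                      "last_followup_date,death_date,event"), patients),
             file.path(dir, "patients.csv"))
  dir
}

read_cohort_dir <- function(dir) {
  read_cohort(file.path(dir, "reports.csv"),
              file.path(dir, "administrations.csv"),
              file.path(dir, "responses.csv"),
              file.path(dir, "patients.csv"))
}

# Field-by-field record comparison (object identity modulo attributes that
# don't matter, e.g. row names).
expect_same_patient <- function(a, b) {
  expect_equal(a$patient_id, b$patient_id)
  expect_equal(a$grade, b$grade)
  expect_equal(a$stage, b$stage)
  expect_equal(a$substage, b$substage)
  expect_equal(a$report$delivery_date, b$report$delivery_date)
  expect_equal(sort(names(a$report$scores)), sort(names(b$report$scores)))
  expect_equal(a$report$scores[sort(names(a$report$scores))],
               b$report$scores[sort(names(b$report$scores))],
               tolerance = 1e-12)
  ord <- function(df) {
    df <- df[do.call(order, df), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  expect_equal(ord(a$administrations), ord(b$administrations))
  expect_equal(ord(a$responses), ord(b$responses))
  expect_equal(a$last_followup_date, b$last_followup_date)
  expect_equal(a$death_date, b$death_date)
  expect_equal(a$event, b$event)
}
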