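## four-patient toy universe exercising each selection filter
toy_tables <- function() {
  d <- as.Date
  EmrTables(
    person = data.frame(
      patient_id = c("A", "B", "C", "D"), sex = c("F", "M", "F", "M"),
      birth_date = d(c("1950-01-01", "1950-01-01", "1950-01-01",
                       "1950-01-01")), stringsAsFactors = FALSE),
    diagnosis = data.frame(
      patient_id = c("A", "B", "C", "D"),
      icd10_code = c("I20", "I20", "I25", "I20"),
      diagnosis_name = c("angina pectoris", "angina pectoris",
                         "chronic ischaemic heart disease",
                         "angina pectoris"),
      diagnosis_date = d(c("2005-05-01", "2005-05-01", "2005-05-01",
                           "2005-05-01")),
      encounter_type = c("inpatient", "outpatient", "inpatient",
                         "inpatient"), stringsAsFactors = FALSE),
    visit = data.frame(
      patient_id = c("A", "B", "C", "D"),
      visit_date = d(rep("2005-05-01", 4)),
      encounter_type = c("inpatient", "outpatient", "inpatient",
                         "inpatient"),
      age_at_visit = rep(55.3, 4), stringsAsFactors = FALSE),
    events = data.frame(
      patient_id = "D", event_type = "MI",
      event_date = d("2003-02-01"), stringsAsFactors = FALSE))
}

test_that("inclusion/exclusion flow keeps exactly the qualifying patient", {
  co <- selectCohort(toy_tables())
  expect_identical(co$patient_id, "A")
  expect_identical(co$index_date, as.Date("2005-05-01"))
})

test_that("index admission is the earliest qualifying one inside the window", {
  tb <- toy_tables()
  dx <- data.frame(
    patient_id = "A", icd10_code = "I20",
    diagnosis_name = "angina pectoris",
    diagnosis_date = as.Date(c("1999-06-01", "2001-03-01")),
    encounter_type = "inpatient", stringsAsFactors = FALSE)
  tb@diagnosis <- rbind(tb@diagnosis, dx)
  co <- selectCohort(tb)
  expect_identical(co$index_date[co$patient_id == "A"],
                   as.Date("2001-03-01"))
})

test_that("outcome labelling follows the five-year horizon strictly after index", {
  tb <- toy_tables()
  co <- selectCohort(tb)
  mk <- function(days) data.frame(patient_id = "A", event_type = "MI",
                                  event_date = co$index_date + days,
                                  stringsAsFactors = FALSE)
  expect_identical(labelOutcome(co, mk(3 * 365))$outcome, 1)    # +3 years
  expect_identical(labelOutcome(co, mk(6 * 365.25))$outcome, 0) # beyond
  expect_identical(labelOutcome(co, mk(0))$outcome, 0)          # index day
  expect_identical(labelOutcome(co, mk(1826))$outcome, 1)       # boundary
  expect_identical(labelOutcome(co, mk(1827))$outcome, 0)
  no_events <- data.frame(patient_id = character(0),
                          event_type = character(0),
                          event_date = as.Date(character(0)))
  expect_identical(labelOutcome(co, no_events)$outcome, 0)
  expect_error(labelOutcome(co, mk(-100)), "consistency")
})

test_that("cohort membership equals an independent predicate scan", {
  emr <- generateEmr(generatorConfig(n_patients = 2000, seed = 17,
                                     fraction_prior_event = 0.2))
  crit <- cohortCriteria()
  co <- selectCohort(emr, crit)
  ## brute-force per-patient scan over the raw tables
  dx <- emrTable(emr, "diagnosis")
  ev <- emrTable(emr, "events")
  keep <- character(0)
  for (pid in personTable(emr)$patient_id) {
    rows <- dx[dx$patient_id == pid, ]
    ok <- startsWith(rows$icd10_code, crit$index_code) &
      rows$encounter_type %in% crit$allowed_encounters &
      rows$diagnosis_date >= crit$window[1] &
      rows$diagnosis_date <= crit$window[2]
    if (!any(ok)) next
    idx <- min(rows$diagnosis_date[ok])
    pe <- ev[ev$patient_id == pid &
               ev$event_type %in% crit$exclusion_history, ]
    if (nrow(pe) && any(pe$event_date < idx)) next
    keep <- c(keep, pid)
  }
  expect_identical(co$patient_id, sort(keep))
})

test_that("cohort and labels are insensitive to input row order", {
  emr <- generateEmr(generatorConfig(n_patients = 150, seed = 23))
  co1 <- labelOutcome(selectCohort(emr), emr)
  set.seed(1)
  for (tb in c("diagnosis", "laboratory", "events", "visit")) {
    df <- slot(emr, tb)
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    rownames(df) <- NULL
    slot(emr, tb) <- df
  }
  co2 <- labelOutcome(selectCohort(emr), emr)
  rownames(co1) <- rownames(co2) <- NULL
  expect_equal(co1, co2)
})

test_that("labelling is idempotent and an empty person table gives an empty cohort", {
  st <- small_study(80, seed = 2)
  again <- labelOutcome(st$cohort, st$tables)
  expect_identical(again$outcome, st$cohort$outcome)
  expect_identical(nrow(selectCohort(EmrTables())), 0L)
})

test_that("per-patient summaries take the latest value at or before index", {
  tb <- toy_tables()
  tb@laboratory <- data.frame(
    patient_id = "A", test_name = "blood", value = c(80, 99, 120),
    date = as.Date(c("2004-01-01", "2005-04-30", "2005-06-01")),
    stringsAsFactors = FALSE)
  co <- selectCohort(tb)
  expect_identical(co$lab_blood, 99)  # post-index 120 ignored
})
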