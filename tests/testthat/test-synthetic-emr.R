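test_that("empty universe keeps the canonical column sets", {
  emr <- generateEmr(generatorConfig(n_patients = 0, seed = 1))
  expect_s4_class(emr, "EmrTables")
  for (tb in c("person", "diagnosis", "laboratory", "events")) {
    df <- emrTable(emr, tb)
    expect_identical(nrow(df), 0L)
  }
  expect_named(emrTable(emr, "person"),
               c("patient_id", "sex", "birth_date"))
  expect_named(emrTable(emr, "visit"),
               c("patient_id", "visit_date", "encounter_type",
                 "age_at_visit"))
})

test_that("generation is deterministic given the seed, down to the CSVs", {
  a <- generateEmr(generatorConfig(n_patients = 100, seed = 7))
  b <- generateEmr(generatorConfig(n_patients = 100, seed = 7))
  for (tb in c("person", "diagnosis", "laboratory", "medication", "events"))
    expect_identical(emrTable(a, tb), emrTable(b, tb))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeEmrCsv(a, d1); writeEmrCsv(b, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  c2 <- generateEmr(generatorConfig(n_patients = 100, seed = 8))
  expect_false(identical(emrTable(a, "person"), emrTable(c2, "person")))
})

test_that("generated tables are referentially intact and every patient visits", {
  emr <- generateEmr(generatorConfig(n_patients = 200, seed = 3))
  expect_true(validObject(emr))
  pids <- personTable(emr)$patient_id
  expect_true(all(pids %in% emrTable(emr, "visit")$patient_id))
  dx <- emrTable(emr, "diagnosis")
  i20 <- dx[dx$icd10_code == "I20", ]
  expect_true(all(pids %in% i20$patient_id))
})

test_that("invalid configurations are rejected", {
  expect_error(generatorConfig(10, event_prevalence = 0), "prevalence")
  expect_error(generatorConfig(10, event_prevalence = 1.2), "prevalence")
  expect_error(generatorConfig(10, admission_window =
                                 as.Date(c("2016-01-01", "2000-01-01"))),
               "window")
  expect_error(generatorConfig(-1), "n_patients")
  expect_error(generatorConfig(10, fraction_prior_event = 1), "fraction")
})

test_that("risk score is logistic and strictly increasing in age", {
  par0 <- list(intercept = 0, age_effect = 0.05, age_center = 60)
  expect_identical(riskScore(60, params = par0), 0.5)
  expect_gt(riskScore(70, params = par0), riskScore(50, params = par0))
  ages <- seq(30, 90, by = 5)
  expect_true(all(diff(riskScore(ages, params = par0)) > 0))
  parb <- c(par0, list(beta = c(0.5, -0.5)))
  expect_equal(riskScore(60, c(0, 0), parb), 0.5)
  expect_gt(riskScore(60, c(1, 0), parb), riskScore(60, c(0, 0), parb))
})

test_that("outcome-positive patients are older on average", {
  st <- small_study(4000, seed = 5)
  co <- st$cohort
  expect_gt(mean(co$age_at_index[co$outcome == 1]),
            mean(co$age_at_index[co$outcome == 0]))
})

test_that("CSV round trip preserves tables, rejecting malformed dates", {
  emr <- generateEmr(generatorConfig(n_patients = 40, seed = 11))
  d <- withr::local_tempdir()
  writeEmrCsv(emr, d)
  back <- readEmrCsv(d)
  for (tb in c("person", "diagnosis", "laboratory", "smoke", "events"))
    expect_equal(emrTable(back, tb), emrTable(emr, tb))
  ## corrupt one diagnosis date: that record alone is dropped, with a note
  p <- file.path(d, "diagnosis.csv")
  lines <- readLines(p)
  lines[2] <- sub("[0-9]{4}-[0-9]{2}-[0-9]{2}", "not-a-date", lines[2])
  writeLines(lines, p)
  expect_message(back2 <- readEmrCsv(d), "malformed")
  expect_identical(nrow(emrTable(back2, "diagnosis")),
                   nrow(emrTable(emr, "diagnosis")) - 1L)
})

test_that("YAML configuration round-trips through the constructor", {
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_patients: 25", "seed: 3", "event_prevalence: 0.1"), p)
  cfg <- generatorConfigFromYaml(p)
  expect_identical(cfg$n_patients, 25L)
  expect_identical(cfg$event_prevalence, 0.1)
  expect_identical(generateEmr(cfg)@person,
                   generateEmr(generatorConfig(25, seed = 3,
                                               event_prevalence = 0.1))@person)
})
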