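#' Small synthetic worked example: a five-patient EMR bundle
#'
#' A hand-built [EmrTables] universe used throughout the tests and
#' documentation.  Patient `107411` carries a characteristic journey: a
#' hypertension diagnosis alongside the index angina admission, a
#' laboratory blood value of 94.0, an echocardiography value of -1.0, a
#' physical measurement of 53.55, smoking level 1, statin medication, a
#' diagnostic ultrasound, and a composite event at age 67.  Cohort
#' selection keeps four of the five patients (one is outpatient-only),
#' three of whom are on statin.
#'
#' @return An [EmrTables] bundle.
#' @examples
#' emr <- journeyFixture()
#' coh <- labelOutcome(selectCohort(emr), emr)
#' table(coh$outcome)
#' @export
journeyFixture <- function() {
  d <- as.Date
  EmrTables(
    person = data.frame(
      patient_id = c("107411", "200001", "200002", "200003", "200005"),
      sex = c("M", "F", "M", "F", "M"),
      birth_date = d(c("1945-03-10", "1950-06-01", "1938-11-20",
                       "1960-02-02", "1955-08-15")),
      stringsAsFactors = FALSE),
    diagnosis = data.frame(
      patient_id = c("107411", "107411", "200001", "200002", "200003",
                     "200005"),
      icd10_code = c("I20", "I10", "I20", "I20", "I20", "I20"),
      diagnosis_name = c("angina pectoris", "hypertension",
                         "angina pectoris", "angina pectoris",
                         "angina pectoris", "angina pectoris"),
      diagnosis_date = d(c("2010-06-15", "2009-01-10", "2005-03-01",
                           "2008-07-01", "2007-04-01", "2006-05-05")),
      encounter_type = c("inpatient", "outpatient", "inpatient",
                         "emergency", "outpatient", "inpatient"),
      stringsAsFactors = FALSE),
    laboratory = data.frame(
      patient_id = c("107411", "200001", "200002", "200005"),
      test_name = "blood",
      value = c(94.0, 101.5, 88.2, 95.0),
      date = d(c("2010-05-01", "2005-02-14", "2008-06-20", "2006-05-01")),
      stringsAsFactors = FALSE),
    echocardiography = data.frame(
      patient_id = c("107411", "200001", "200002"),
      measure_name = "EF",
      value = c(-1.0, 0.4, -0.2),
      date = d(c("2010-04-20", "2005-02-15", "2008-06-21")),
      stringsAsFactors = FALSE),
    physical = data.frame(
      patient_id = c("107411", "200001", "200002", "200005"),
      measure_name = "weight",
      value = c(53.55, 64.2, 71.0, 80.5),
      date = d(c("2010-05-02", "2005-02-14", "2008-06-20", "2006-05-01")),
      stringsAsFactors = FALSE),
    medication = data.frame(
      patient_id = c("107411", "200001", "200002", "200002"),
      drug_name = c("statin", "statin", "statin", "aspirin"),
      start_date = d(c("2010-05-20", "2005-03-02", "2008-06-25",
                       "2008-06-25")),
      stringsAsFactors = FALSE),
    surgery = data.frame(
      patient_id = c("107411", "200002"),
      procedure_name = c("diagnostic ultrasound",
                         "percutaneous coronary intervention"),
      date = d(c("2010-06-16", "2008-07-03")),
      stringsAsFactors = FALSE),
    visit = data.frame(
      patient_id = c("107411", "107411", "200001", "200002", "200003",
                     "200005"),
      visit_date = d(c("2010-06-15", "2009-01-10", "2005-03-01",
                       "2008-07-01", "2007-04-01", "2006-05-05")),
      encounter_type = c("inpatient", "outpatient", "inpatient",
                         "emergency", "outpatient", "inpatient"),
      age_at_visit = c(65.3, 63.8, 54.7, 69.6, 47.2, 50.7),
      stringsAsFactors = FALSE),
    smoke = data.frame(
      patient_id = c("107411", "200001", "200002", "200003", "200005"),
      smoking_level = c(1L, 0L, 2L, 0L, 3L),
      stringsAsFactors = FALSE),
    events = data.frame(
      patient_id = c("107411", "200002"),
      event_type = c("MI", "heart_failure"),
      event_date = d(c("2012-09-01", "2009-01-01")),
      stringsAsFactors = FALSE)
  )
}
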