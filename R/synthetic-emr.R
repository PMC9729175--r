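#' Fixed ICD-10 code pool used by the synthetic generator
#'
#' A deterministic pool of three-character ICD-10 codes with readable names
#' for a handful of common cardiometabolic conditions.  Sampling weights in
#' the generator follow a Zipf profile over this fixed order, so a stable
#' "top" code set exists for the diagnosis feature schema.
#'
#' @return data.frame with columns `code`, `name` and sampling `weight`.
#' @examples
#' head(icd10Pool())
#' @export
icd10Pool <- function() {
  named <- c(I10 = "hypertension",
             I20 = "angina pectoris",
             I25 = "chronic ischaemic heart disease",
             I48 = "atrial fibrillation",
             E11 = "type 2 diabetes mellitus",
             E78 = "hyperlipidaemia",
             J44 = "chronic obstructive pulmonary disease",
             J45 = "asthma",
             N18 = "chronic kidney disease",
             K21 = "gastro-oesophageal reflux disease",
             M54 = "dorsalgia",
             G47 = "sleep disorder")
  chapters <- c("I", "E", "J", "K", "N", "M", "G", "C", "D", "F")
  codes <- as.vector(t(outer(chapters, sprintf("%02d", 0:19), paste0)))
  nm <- ifelse(codes %in% names(named), named[codes],
               paste("disorder", codes))
  data.frame(code = codes, name = unname(nm),
             weight = 1 / seq_along(codes), stringsAsFactors = FALSE)
}

## latent per-patient feature distributions (population mean, sd, noise sd,
## lower clip) used both to draw records and to standardize the risk score
.latent_specs <- list(
  lab_blood  = c(mean = 90,  sd = 15,  noise = 3,    lo = 20),
  lab_creatinine = c(mean = 1.0, sd = 0.25, noise = 0.05, lo = 0.3),
  lab_glucose = c(mean = 105, sd = 25, noise = 5,    lo = 40),
  echo_EF    = c(mean = 58,  sd = 8,   noise = 2,    lo = 15),
  echo_LVEDD = c(mean = 50,  sd = 6,   noise = 1.5,  lo = 25),
  phys_weight = c(mean = 68, sd = 12,  noise = 0.8,  lo = 35),
  phys_SBP   = c(mean = 128, sd = 18,  noise = 4,    lo = 70)
)

#' Configuration of the synthetic EMR generator
#'
#' Defines the study conditions the generator emulates: an angina (ICD-10
#' I20) admission cohort with inpatient/emergency index encounters inside a
#' 2000--2016 admission window, a binary five-year composite event outcome
#' with roughly one positive per eleven negatives, and event risk that
#' increases with age.
#'
#' @param n_patients number of patients to generate (>= 0).
#' @param seed integer RNG seed; identical config + seed is byte-identical.
#' @param admission_window two dates bounding index admissions.
#' @param event_prevalence target probability of the composite event within
#'   five years of index among patients that survive cohort filters; the
#'   logistic intercept is calibrated so the population mean matches it.
#' @param age_effect log-odds of the composite event per year of age.
#' @param feature_effects named log-odds per standard deviation of the
#'   latent `lab_blood`, `echo_EF` and `phys_SBP` values.
#' @param records_per_table named list of mean record counts (Poisson) per
#'   patient for each auxiliary table (`laboratory` is per test).
#' @param fraction_outpatient_only fraction of patients whose I20 encounters
#'   are all outpatient (removed by cohort selection).
#' @param fraction_prior_event fraction of patients given an MI/stroke/heart
#'   failure event before index (removed by cohort selection).
#' @param late_event_rate probability of a first composite event between 5
#'   and 8 years after index (labelled 0 at the five-year horizon).
#' @return A validated list of class `generatorConfig`.
#' @examples
#' cfg <- generatorConfig(n_patients = 100, seed = 7)
#' @export
generatorConfig <- function(n_patients,
                            seed = 1L,
                            admission_window = as.Date(c("2000-01-01",
                                                         "2016-12-31")),
                            event_prevalence = 1 / 12,
                            age_effect = 0.05,
                            feature_effects = c(lab_blood = 0.5,
                                                echo_EF = -0.5,
                                                phys_SBP = 0.4),
                            records_per_table = list(diagnosis = 4,
                                                     laboratory = 2,
                                                     echocardiography = 1,
                                                     physical = 1.5,
                                                     medication = 2,
                                                     surgery = 0.6,
                                                     visit = 3),
                            fraction_outpatient_only = 0.15,
                            fraction_prior_event = 0.10,
                            late_event_rate = 0.05) {
  admission_window <- as.Date(admission_window)
  if (length(n_patients) != 1 || is.na(n_patients) || n_patients < 0)
    stop("n_patients must be a single non-negative integer")
  if (!is.finite(event_prevalence) || event_prevalence <= 0 ||
      event_prevalence >= 1)
    stop("event_prevalence must lie in (0, 1)")
  if (length(admission_window) != 2 || any(is.na(admission_window)) ||
      admission_window[1] >= admission_window[2])
    stop("admission_window must be an interval with start < end")
  fr <- c(fraction_outpatient_only, fraction_prior_event)
  if (any(fr < 0) || any(fr >= 1) || sum(fr) >= 1)
    stop("filter fractions must lie in [0, 1) and sum below 1")
  if (any(unlist(records_per_table) <= 0))
    stop("records_per_table means must be positive")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 admission_window = admission_window,
                 event_prevalence = event_prevalence,
                 age_effect = age_effect,
                 feature_effects = feature_effects,
                 records_per_table = records_per_table,
                 fraction_outpatient_only = fraction_outpatient_only,
                 fraction_prior_event = fraction_prior_event,
                 late_event_rate = late_event_rate),
            class = "generatorConfig")
}

#' Read a generator configuration from a YAML file
#'
#' @param path YAML file whose keys match the [generatorConfig()] arguments.
#' @return A `generatorConfig`.
#' @export
generatorConfigFromYaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$feature_effects))
    vals$feature_effects <- unlist(vals$feature_effects)
  do.call(generatorConfig, vals)
}

#' Logistic event-risk model of the generator
#'
#' Probability of the five-year composite event as a logistic function of a
#' linear predictor in age and standardized covariates; strictly increasing
#' in age whenever `age_effect > 0`.
#'
#' @param age age in years (vectorized).
#' @param covariates numeric vector (one observation) or matrix (rows are
#'   observations) of standardized covariates, or `NULL`.
#' @param params list with `intercept`, `age_effect`, `age_center` and, if
#'   covariates are supplied, a coefficient vector `beta`.
#' @return event probability in (0, 1).
#' @examples
#' riskScore(60, params = list(intercept = 0, age_effect = 0.05,
#'                             age_center = 60))  # 0.5
#' @export
riskScore <- function(age, covariates = NULL, params) {
  lp <- params$intercept + params$age_effect * (age - params$age_center)
  if (!is.null(covariates)) {
    contrib <- if (is.matrix(covariates)) drop(covariates %*% params$beta)
               else sum(params$beta * covariates)
    lp <- lp + contrib
  }
  plogis(lp)
}

#' Generate a synthetic EMR table bundle
#'
#' Draws an angina-admission universe under the conditions of
#' [generatorConfig()]: every patient has at least one visit; all but a
#' configurable outpatient-only subset carry an I20 inpatient/emergency
#' diagnosis inside the admission window; a configurable subset carries a
#' disqualifying pre-index event; and among patients that survive the
#' cohort filters the five-year composite event follows a logistic model in
#' age and selected latent features, with the intercept calibrated so the
#' population event probability equals `event_prevalence`.
#'
#' @param config a [generatorConfig()].
#' @return An [EmrTables] bundle (referentially intact, ISO dates).
#' @examples
#' emr <- generateEmr(generatorConfig(n_patients = 50, seed = 1))
#' emr
#' @export
generateEmr <- function(config) {
  stopifnot(inherits(config, "generatorConfig"))
  n <- config$n_patients
  if (n == 0) return(EmrTables())
  set.seed(config$seed)
  rpt <- config$records_per_table

  pid <- as.character(seq_len(n) + 200000L)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.45, 0.55))
  age <- pmin(92, pmax(25, rnorm(n, 61, 11)))
  win <- config$admission_window
  span <- as.numeric(win[2] - win[1])
  index_date <- win[1] + floor(runif(n) * (span + 1))
  birth_date <- index_date - round(age * 365.25)

  u <- runif(n)
  outpatient_only <- u < config$fraction_outpatient_only
  prior_event <- !outpatient_only &
    u < config$fraction_outpatient_only + config$fraction_prior_event
  eligible <- !outpatient_only & !prior_event

  ## latent per-patient values feeding both the record draws and the risk
  latent <- sapply(names(.latent_specs), function(f) {
    sp <- .latent_specs[[f]]
    pmax(sp["lo"], rnorm(n, sp["mean"], sp["sd"]))
  })
  if (!is.matrix(latent))
    latent <- matrix(latent, nrow = n,
                     dimnames = list(NULL, names(.latent_specs)))
  smoking_level <- sample(0:3, n, replace = TRUE,
                          prob = c(0.5, 0.2, 0.2, 0.1))

  zs <- sapply(names(config$feature_effects), function(f) {
    sp <- .latent_specs[[f]]
    (latent[, f] - sp["mean"]) / sp["sd"]
  })
  if (!is.matrix(zs))
    zs <- matrix(zs, nrow = n,
                 dimnames = list(NULL, names(config$feature_effects)))
  lp <- config$age_effect * (age - 60) +
    drop(zs %*% config$feature_effects)
  lp_cal <- if (any(eligible)) lp[eligible] else lp
  intercept <- uniroot(function(b0)
    mean(plogis(b0 + lp_cal)) - config$event_prevalence,
    c(-20, 10))$root
  p_event <- plogis(intercept + lp)

  has_event5 <- rbinom(n, 1, p_event) == 1
  has_late <- !has_event5 & rbinom(n, 1, config$late_event_rate) == 1

  ## --- diagnosis --------------------------------------------------------
  pool <- icd10Pool()
  other <- pool[pool$code != "I20", ]
  idx_enc <- ifelse(outpatient_only, "outpatient",
                    ifelse(runif(n) < 0.7, "inpatient", "emergency"))
  dx_index <- data.frame(patient_id = pid, icd10_code = "I20",
                         diagnosis_name = "angina pectoris",
                         diagnosis_date = index_date,
                         encounter_type = idx_enc,
                         stringsAsFactors = FALSE)
  n_extra <- rpois(n, rpt$diagnosis)
  rep_i <- rep.int(seq_len(n), n_extra)
  pick <- sample.int(nrow(other), sum(n_extra), replace = TRUE,
                     prob = other$weight)
  dx_extra <- data.frame(
    patient_id = pid[rep_i],
    icd10_code = other$code[pick],
    diagnosis_name = other$name[pick],
    diagnosis_date = index_date[rep_i] - floor(runif(sum(n_extra)) * 730),
    encounter_type = sample(c("outpatient", "inpatient", "emergency"),
                            sum(n_extra), replace = TRUE,
                            prob = c(0.6, 0.3, 0.1)),
    stringsAsFactors = FALSE)
  diagnosis <- rbind(dx_index, dx_extra)

  ## --- long numeric tables ---------------------------------------------
  draw_long <- function(features, name_col, mean_records) {
    parts <- lapply(features, function(f) {
      sp <- .latent_specs[[f]]
      k <- rpois(n, mean_records)
      ri <- rep.int(seq_len(n), k)
      if (!length(ri)) return(NULL)
      data.frame(patient_id = pid[ri],
                 name = sub("^[a-z]+_", "", f),
                 value = pmax(sp["lo"],
                              latent[ri, f] + rnorm(length(ri), 0,
                                                    sp["noise"])),
                 date = index_date[ri] - floor(runif(length(ri)) * 1095),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, parts)
    if (is.null(out)) out <- data.frame(patient_id = character(0),
                                        name = character(0),
                                        value = numeric(0),
                                        date = as.Date(character(0)))
    names(out)[names(out) == "name"] <- name_col
    rownames(out) <- NULL
    out
  }
  laboratory <- draw_long(c("lab_blood", "lab_creatinine", "lab_glucose"),
                          "test_name", rpt$laboratory)
  echocardiography <- draw_long(c("echo_EF", "echo_LVEDD"), "measure_name",
                                rpt$echocardiography)
  physical <- draw_long(c("phys_weight", "phys_SBP"), "measure_name",
                        rpt$physical)

  ## --- medication / surgery --------------------------------------------
  drugs <- c("statin", "aspirin", "beta blocker", "ACE inhibitor",
             "nitrate", "clopidogrel", "diuretic")
  k_med <- pmin(rpois(n, rpt$medication), length(drugs))
  med_i <- rep.int(seq_len(n), k_med)
  medication <- data.frame(
    patient_id = pid[med_i],
    drug_name = unlist(lapply(k_med[k_med > 0], function(k)
      drugs[sample.int(length(drugs), k)])),
    start_date = index_date[med_i] - floor(runif(length(med_i)) * 365),
    stringsAsFactors = FALSE)

  procedures <- c("diagnostic ultrasound",
                  "percutaneous coronary intervention",
                  "coronary artery bypass graft", "stent insertion")
  k_surg <- rpois(n, rpt$surgery)
  surg_i <- rep.int(seq_len(n), k_surg)
  surgery <- data.frame(
    patient_id = pid[surg_i],
    procedure_name = procedures[sample.int(length(procedures),
                                           length(surg_i), replace = TRUE)],
    date = index_date[surg_i] - floor(runif(length(surg_i)) * 365),
    stringsAsFactors = FALSE)

  ## --- visits (every patient keeps the index visit) ---------------------
  k_vis <- rpois(n, rpt$visit)
  vis_i <- rep.int(seq_len(n), k_vis)
  extra_dates <- win[1] + floor(runif(length(vis_i)) * (span + 1))
  visit <- rbind(
    data.frame(patient_id = pid, visit_date = index_date,
               encounter_type = idx_enc,
               age_at_visit = round(as.numeric(index_date - birth_date) /
                                      365.25, 1),
               stringsAsFactors = FALSE),
    data.frame(patient_id = pid[vis_i], visit_date = extra_dates,
               encounter_type = sample(c("outpatient", "inpatient",
                                         "emergency"), length(vis_i),
                                       replace = TRUE,
                                       prob = c(0.7, 0.2, 0.1)),
               age_at_visit = round(as.numeric(extra_dates -
                                                 birth_date[vis_i]) /
                                      365.25, 1),
               stringsAsFactors = FALSE))

  smoke <- data.frame(patient_id = pid, smoking_level = smoking_level,
                      stringsAsFactors = FALSE)

  ## --- events -----------------------------------------------------------
  types <- c("death", "MI", "stroke", "heart_failure")
  prior_types <- c("MI", "stroke", "heart_failure")
  ev <- list()
  if (any(prior_event)) {
    m <- sum(prior_event)
    ev$prior <- data.frame(
      patient_id = pid[prior_event],
      event_type = prior_types[sample.int(3, m, replace = TRUE)],
      event_date = index_date[prior_event] -
        (30 + floor(runif(m) * 1470)),
      stringsAsFactors = FALSE)
  }
  if (any(has_event5)) {
    m <- sum(has_event5)
    ev$in5 <- data.frame(
      patient_id = pid[has_event5],
      event_type = types[sample.int(4, m, replace = TRUE)],
      event_date = index_date[has_event5] + ceiling(runif(m) * 1826),
      stringsAsFactors = FALSE)
  }
  if (any(has_late)) {
    m <- sum(has_late)
    ev$late <- data.frame(
      patient_id = pid[has_late],
      event_type = types[sample.int(4, m, replace = TRUE)],
      event_date = index_date[has_late] + 1826 + ceiling(runif(m) * 1096),
      stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    .empty_emr_table("events")
  rownames(events) <- NULL

  EmrTables(
    person = data.frame(patient_id = pid, sex = sex,
                        birth_date = birth_date, stringsAsFactors = FALSE),
    diagnosis = diagnosis, laboratory = laboratory,
    echocardiography = echocardiography, physical = physical,
    medication = medication, surgery = surgery, visit = visit,
    smoke = smoke, events = events)
}

#' Write / read an EMR bundle as CSV files
#'
#' One UTF-8 comma-separated file with a header row per table
#' (`person.csv`, `diagnosis.csv`, ...), dates in ISO-8601.  `readEmrCsv`
#' parses them back; rows whose dates fail to parse are rejected
#' record-wise with a message.
#'
#' @param tables an [EmrTables] bundle.
#' @param dir directory to write to / read from (created if needed).
#' @return `writeEmrCsv` returns `dir` invisibly; `readEmrCsv` an
#'   [EmrTables].
#' @export
writeEmrCsv <- function(tables, dir) {
  stopifnot(is(tables, "EmrTables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in names(.emr_columns)) {
    df <- slot(tables, tb)
    for (cl in names(df)) if (inherits(df[[cl]], "Date"))
      df[[cl]] <- format(df[[cl]], "%Y-%m-%d")
    write.csv(df, file.path(dir, paste0(tb, ".csv")), row.names = FALSE,
              fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' @rdname writeEmrCsv
#' @export
readEmrCsv <- function(dir) {
  date_cols <- c("birth_date", "diagnosis_date", "date", "start_date",
                 "visit_date", "event_date")
  out <- list()
  for (tb in names(.emr_columns)) {
    path <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(path)) stop("missing table file: ", path)
    df <- read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
    for (cl in intersect(names(df), date_cols)) {
      parsed <- as.Date(df[[cl]], format = "%Y-%m-%d")
      bad <- is.na(parsed) & nzchar(df[[cl]])
      if (any(bad)) {
        message(sprintf("%s: rejected %d record(s) with malformed %s",
                        tb, sum(bad), cl))
        df <- df[!bad, , drop = FALSE]
        parsed <- parsed[!bad]
      }
      df[[cl]] <- parsed
    }
    for (cl in intersect(names(df), c("value", "age_at_visit")))
      df[[cl]] <- as.numeric(df[[cl]])
    if ("smoking_level" %in% names(df))
      df$smoking_level <- as.integer(df$smoking_level)
    rownames(df) <- NULL
    out[[tb]] <- df
  }
  do.call(EmrTables, out)
}
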