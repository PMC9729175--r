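#' Cohort inclusion/exclusion criteria
#'
#' Selection rules for the index admission: an ICD-10 prefix on an allowed
#' encounter type inside the admission window, no disqualifying event
#' history before index, and the follow-up horizon of the composite
#' outcome.
#'
#' @param index_code ICD-10 prefix of the index diagnosis (angina = "I20").
#' @param allowed_encounters encounter types that can anchor the index
#'   admission; outpatient encounters are excluded by default.
#' @param window two dates bounding index admissions.
#' @param exclusion_history event types whose occurrence before index
#'   removes the patient.
#' @param horizon_days follow-up horizon; 1826 days is five years at 365.25
#'   days per year.
#' @param event_types event types forming the composite outcome.
#' @return A validated list of class `cohortCriteria`.
#' @examples
#' cohortCriteria()
#' @export
cohortCriteria <- function(index_code = "I20",
                           allowed_encounters = c("inpatient", "emergency"),
                           window = as.Date(c("2000-01-01", "2016-12-31")),
                           exclusion_history = c("MI", "stroke",
                                                 "heart_failure"),
                           horizon_days = 1826L,
                           event_types = c("death", "MI", "stroke",
                                           "heart_failure")) {
  window <- as.Date(window)
  if (!nzchar(index_code)) stop("index_code must be non-empty")
  if (horizon_days <= 0) stop("horizon_days must be positive")
  if (length(window) != 2 || any(is.na(window)) || window[1] >= window[2])
    stop("window must be an interval with start < end")
  structure(list(index_code = index_code,
                 allowed_encounters = allowed_encounters,
                 window = window,
                 exclusion_history = exclusion_history,
                 horizon_days = as.integer(horizon_days),
                 event_types = event_types),
            class = "cohortCriteria")
}

## Latest value at or before the per-patient index date, one column per
## distinct measure name.  Ties on date resolve by value order so the
## result is independent of input row order.
.latest_before_index <- function(df, name_col, index) {
  measures <- sort(unique(df[[name_col]]))
  wide <- data.frame(patient_id = index$patient_id,
                     stringsAsFactors = FALSE)
  for (msr in measures) wide[[msr]] <- rep(NA_real_, nrow(wide))
  if (!nrow(df) || !nrow(index)) return(wide)
  m <- merge(df[, c("patient_id", name_col, "value", "date")], index,
             by = "patient_id")
  m <- m[!is.na(m$date) & m$date <= m$index_date, , drop = FALSE]
  if (!nrow(m)) return(wide)
  m <- m[order(m$patient_id, m[[name_col]], m$date, m$value), ]
  m <- m[!duplicated(m[, c("patient_id", name_col)], fromLast = TRUE), ]
  for (msr in measures) {
    sub <- m[m[[name_col]] == msr, ]
    wide[[msr]][match(sub$patient_id, wide$patient_id)] <- sub$value
  }
  wide
}

#' Select the study cohort from an EMR bundle
#'
#' Applies the inclusion/exclusion flow: keep patients with at least one
#' index-code diagnosis on an allowed encounter type inside the window
#' (outpatient-only patients drop out), anchor each patient at the earliest
#' qualifying admission, and remove patients with a disqualifying event
#' strictly before index.  Per-patient summaries (latest-at-or-before-index
#' value per named measure, visit and medication counts, smoking level) are
#' attached for downstream feature building.
#'
#' @param tables an [EmrTables] bundle.
#' @param criteria a [cohortCriteria()].
#' @return Unlabelled cohort: a data.frame with one row per included
#'   patient (`patient_id`, `index_date`, `age_at_index`, `sex`, summary
#'   columns, `outcome = NA`), sorted by `patient_id`.
#' @seealso [labelOutcome()] to fill in the outcome.
#' @export
selectCohort <- function(tables, criteria = cohortCriteria()) {
  stopifnot(is(tables, "EmrTables"), inherits(criteria, "cohortCriteria"))
  dx <- tables@diagnosis
  bad <- is.na(dx$diagnosis_date)
  if (any(bad)) {
    message(sprintf("diagnosis: rejected %d record(s) with missing date",
                    sum(bad)))
    dx <- dx[!bad, , drop = FALSE]
  }
  qual <- dx[startsWith(dx$icd10_code, criteria$index_code) &
               dx$encounter_type %in% criteria$allowed_encounters &
               dx$diagnosis_date >= criteria$window[1] &
               dx$diagnosis_date <= criteria$window[2], , drop = FALSE]
  if (!nrow(qual)) {
    out <- data.frame(patient_id = character(0),
                      index_date = as.Date(character(0)),
                      age_at_index = numeric(0), sex = character(0),
                      outcome = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }
  index_date <- tapply(qual$diagnosis_date, qual$patient_id, min)
  index <- data.frame(patient_id = names(index_date),
                      index_date = as.Date(index_date,
                                           origin = "1970-01-01"),
                      stringsAsFactors = FALSE)

  ev <- tables@events
  if (nrow(ev)) {
    prior <- merge(ev[ev$event_type %in% criteria$exclusion_history, ],
                   index, by = "patient_id")
    excl <- unique(prior$patient_id[!is.na(prior$event_date) &
                                      prior$event_date < prior$index_date])
    index <- index[!index$patient_id %in% excl, , drop = FALSE]
  }
  index <- index[order(index$patient_id), , drop = FALSE]

  person <- tables@person
  mp <- match(index$patient_id, person$patient_id)
  if (anyNA(mp)) stop("cohort patient absent from person table")
  cohort <- data.frame(
    patient_id = index$patient_id,
    index_date = index$index_date,
    age_at_index = as.numeric(index$index_date - person$birth_date[mp]) /
      365.25,
    sex = person$sex[mp],
    stringsAsFactors = FALSE)

  add_wide <- function(cohort, df, name_col, prefix) {
    wide <- .latest_before_index(df, name_col, cohort)
    for (msr in setdiff(names(wide), "patient_id"))
      cohort[[paste0(prefix, msr)]] <- wide[[msr]]
    cohort
  }
  cohort <- add_wide(cohort, tables@laboratory, "test_name", "lab_")
  cohort <- add_wide(cohort, tables@echocardiography, "measure_name",
                     "echo_")
  cohort <- add_wide(cohort, tables@physical, "measure_name", "phys_")

  sm <- tables@smoke
  cohort$smoking_level <-
    as.numeric(sm$smoking_level[match(cohort$patient_id, sm$patient_id)])

  vis <- tables@visit
  vis <- merge(vis[, c("patient_id", "visit_date")], cohort[,
               c("patient_id", "index_date")], by = "patient_id")
  nv <- table(vis$patient_id[!is.na(vis$visit_date) &
                               vis$visit_date <= vis$index_date])
  cohort$n_visits <- as.numeric(nv[cohort$patient_id])
  cohort$n_visits[is.na(cohort$n_visits)] <- 0

  med <- merge(unique(tables@medication[, c("patient_id", "drug_name",
                                            "start_date")]),
               cohort[, c("patient_id", "index_date")], by = "patient_id")
  med <- med[!is.na(med$start_date) & med$start_date <= med$index_date, ]
  nm <- table(unique(med[, c("patient_id", "drug_name")])$patient_id)
  cohort$n_medications <- as.numeric(nm[cohort$patient_id])
  cohort$n_medications[is.na(cohort$n_medications)] <- 0

  cohort$outcome <- rep(NA_real_, nrow(cohort))
  rownames(cohort) <- NULL
  cohort
}

#' Label the five-year composite outcome
#'
#' `outcome` is 1 iff any composite event (death, MI, stroke, heart
#' failure by default) falls strictly after the index date and within
#' `horizon_days` of it, else 0.  An event on the index day does not count
#' as follow-up; a composite exclusion-type event strictly before index
#' signals a cohort inconsistency and raises an error.
#'
#' @param cohort unlabelled cohort from [selectCohort()].
#' @param events an [EmrTables] bundle or its `events` data.frame.
#' @param horizon_days follow-up horizon in days (default 1826, five
#'   years).
#' @param event_types event types counted in the composite outcome.
#' @return The cohort data.frame with `outcome` filled in (0/1).
#' @export
labelOutcome <- function(cohort, events, horizon_days = 1826L,
                         event_types = c("death", "MI", "stroke",
                                         "heart_failure")) {
  if (is(events, "EmrTables")) events <- events@events
  stopifnot(all(c("patient_id", "index_date") %in% names(cohort)))
  cohort$outcome <- rep(0, nrow(cohort))
  if (!nrow(cohort) || !nrow(events)) return(cohort)
  ev <- merge(events[events$event_type %in% event_types, , drop = FALSE],
              cohort[, c("patient_id", "index_date")], by = "patient_id")
  if (!nrow(ev)) return(cohort)
  off <- as.numeric(ev$event_date - ev$index_date)
  if (any(off < 0 & ev$event_type %in% c("MI", "stroke", "heart_failure")))
    stop("consistency error: included patient has a composite event ",
         "before index")
  hit <- unique(ev$patient_id[off > 0 & off <= horizon_days])
  cohort$outcome[cohort$patient_id %in% hit] <- 1
  cohort
}
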