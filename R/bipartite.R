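## default 12 patient features, drawn from the cohort summary columns
.default_patient_features <- c(
  "age_at_index", "sex", "smoking_level",
  "lab_blood", "lab_creatinine", "lab_glucose",
  "echo_EF", "echo_LVEDD",
  "phys_weight", "phys_SBP",
  "n_visits", "n_medications")

#' Feature schema of the bipartite graph
#'
#' Fixed-length node feature definitions: 12 patient features (demographic,
#' laboratory, echocardiography, physical and utilisation summaries) and
#' 147 diagnosis features (indicators for the most frequent three-character
#' ICD-10 codes plus one residual count column).
#'
#' @param patient_features ordered character vector of cohort summary
#'   columns to use as patient features.
#' @param diagnosis_codes fixed character vector of three-character codes
#'   for the indicator columns, or `NULL` to take the `n_codes` most
#'   frequent codes from the data (ties broken by code order).
#' @param n_codes number of indicator codes when `diagnosis_codes` is
#'   `NULL`; the residual "other" column brings the default length to 147.
#' @param normalization `"zscore"` (train-split statistics) or `"none"`.
#' @param missing_indicator append a 0/1 missingness indicator column per
#'   imputed patient feature (off by default, keeping length 12).
#' @return list of class `featureSchema`.
#' @export
featureSchema <- function(patient_features = .default_patient_features,
                          diagnosis_codes = NULL,
                          n_codes = 146L,
                          normalization = c("zscore", "none"),
                          missing_indicator = FALSE) {
  normalization <- match.arg(normalization)
  if (anyDuplicated(patient_features))
    stop("patient feature names must be unique")
  structure(list(patient_features = patient_features,
                 diagnosis_codes = diagnosis_codes,
                 n_codes = as.integer(n_codes),
                 normalization = normalization,
                 missing_indicator = missing_indicator),
            class = "featureSchema")
}

#' Build the fixed-length node feature matrices
#'
#' One row per cohort patient in each matrix.  Patient features come from
#' the cohort summary columns; missing continuous values are median-imputed
#' (with optional missingness indicators) and, under `zscore`
#' normalization, standardized with train-split statistics.  Diagnosis
#' features are 0/1 indicators of the schema's three-character ICD-10
#' codes over each patient's distinct pre-index codes, plus a residual
#' column counting distinct unmapped codes.
#'
#' @param cohort labelled cohort from [labelOutcome()].
#' @param tables the [EmrTables] bundle the cohort came from.
#' @param schema a [featureSchema()].
#' @param stats statistics of a previous (training) call — medians,
#'   centers, scales and the code list — to reuse on new data; `NULL`
#'   computes them from this cohort.
#' @return list of class `emrFeatures`: `patient` and `diagnosis` matrices
#'   (rownames are patient ids), the `stats` used, and the `schema`.
#' @export
buildFeatures <- function(cohort, tables, schema = featureSchema(),
                          stats = NULL) {
  stopifnot(is(tables, "EmrTables"), inherits(schema, "featureSchema"))
  cohort <- cohort[order(cohort$patient_id), , drop = FALSE]
  miss_col <- setdiff(schema$patient_features, names(cohort))
  if (length(miss_col))
    stop("schema references absent cohort column(s): ",
         paste(miss_col, collapse = ", "))

  x <- cohort[, schema$patient_features, drop = FALSE]
  if ("sex" %in% names(x)) x$sex <- as.numeric(x$sex == "M")
  x <- as.matrix(as.data.frame(lapply(x, as.numeric)))
  rownames(x) <- cohort$patient_id

  med <- stats$median %||%
    apply(x, 2, function(v) {
      m <- median(v, na.rm = TRUE)
      if (is.na(m)) 0 else m
    })
  ind <- NULL
  if (schema$missing_indicator) {
    ind <- 0 + is.na(x)
    colnames(ind) <- paste0(colnames(x), "_missing")
  }
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]

  if (schema$normalization == "zscore") {
    center <- stats$center %||% colMeans(x)
    scale_ <- stats$scale %||% apply(x, 2, sd)
    scale_[!is.finite(scale_) | scale_ == 0] <- 1
    x <- sweep(sweep(x, 2, center, "-"), 2, scale_, "/")
  } else {
    center <- NULL; scale_ <- NULL
  }
  if (!is.null(ind)) x <- cbind(x, ind)

  ## diagnosis indicators over distinct pre-index 3-character codes
  dx <- tables@diagnosis[tables@diagnosis$patient_id %in% cohort$patient_id,
                         , drop = FALSE]
  if (nrow(dx)) {
    dx <- merge(dx[, c("patient_id", "icd10_code", "diagnosis_date")],
                cohort[, c("patient_id", "index_date")], by = "patient_id")
    dx <- dx[!is.na(dx$diagnosis_date) & dx$diagnosis_date <= dx$index_date, ]
    dx$code3 <- substr(dx$icd10_code, 1, 3)
    dx <- unique(dx[, c("patient_id", "code3")])
  } else dx$code3 <- character(0)

  codes <- stats$codes %||% schema$diagnosis_codes
  if (is.null(codes)) {
    freq <- table(dx$code3)
    ord <- order(-as.integer(freq), names(freq))
    codes <- head(names(freq)[ord], schema$n_codes)
    if (length(codes) < schema$n_codes) {
      ## pad from the fixed pool so the feature length stays constant
      pad <- setdiff(icd10Pool()$code, codes)
      codes <- c(codes, head(pad, schema$n_codes - length(codes)))
    }
  }
  d <- matrix(0, nrow(cohort), length(codes) + 1L,
              dimnames = list(cohort$patient_id, c(codes, "other")))
  if (nrow(dx)) {
    ri <- match(dx$patient_id, cohort$patient_id)
    ci <- match(dx$code3, codes)
    mapped <- !is.na(ci)
    d[cbind(ri[mapped], ci[mapped])] <- 1
    if (any(!mapped)) {
      cnt <- table(ri[!mapped])
      d[as.integer(names(cnt)), length(codes) + 1L] <- as.integer(cnt)
    }
  }

  structure(list(patient = x, diagnosis = d,
                 stats = list(median = med, center = center,
                              scale = scale_, codes = codes),
                 schema = schema),
            class = "emrFeatures")
}

#' Assemble the bipartite attributed graph
#'
#' In the default `per_patient` mode each patient receives one
#' diagnosis-profile node and exactly one edge carrying that patient's
#' outcome, so a cohort of N patients yields 2N nodes and N edges.  In
#' `shared_diagnosis` mode identical diagnosis profiles collapse into
#' shared nodes (the multigraph view).  Node ids receive `p_`/`d_`
#' prefixes so raw id collisions across partitions are impossible.
#'
#' @param cohort labelled cohort (supplies the edge outcomes).
#' @param features an `emrFeatures` object from [buildFeatures()],
#'   row-aligned with the cohort.
#' @param mode `"per_patient"` or `"shared_diagnosis"`.
#' @return A [BipartiteGraph].
#' @export
buildBipartite <- function(cohort, features,
                           mode = c("per_patient", "shared_diagnosis")) {
  mode <- match.arg(mode)
  stopifnot(inherits(features, "emrFeatures"))
  cohort <- cohort[order(cohort$patient_id), , drop = FALSE]
  if (anyNA(cohort$outcome)) stop("cohort must be labelled")
  if (!identical(rownames(features$patient), cohort$patient_id))
    stop("feature matrices are not row-aligned with the cohort")

  pf <- features$patient
  rownames(pf) <- paste0("p_", cohort$patient_id)
  if (mode == "per_patient") {
    df <- features$diagnosis
    rownames(df) <- paste0("d_", cohort$patient_id)
    edges <- data.frame(source = rownames(pf), target = rownames(df),
                        outcome = cohort$outcome, stringsAsFactors = FALSE)
  } else {
    key <- apply(features$diagnosis, 1, paste, collapse = ",")
    uk <- sort(unique(key))
    df <- features$diagnosis[match(uk, key), , drop = FALSE]
    rownames(df) <- paste0("d_", seq_along(uk))
    edges <- data.frame(source = rownames(pf),
                        target = rownames(df)[match(key, uk)],
                        outcome = cohort$outcome, stringsAsFactors = FALSE)
  }
  rownames(edges) <- NULL
  new("BipartiteGraph", patientFeatures = pf, diagnosisFeatures = df,
      edges = edges, mode = mode)
}

#' Flatten the bipartite graph for tabular baselines
#'
#' Concatenates each patient's feature vector with its linked diagnosis
#' node's features (default widths 12 + 147 = 159) and returns the edge
#' outcomes as the label vector.
#'
#' @param graph a [BipartiteGraph]; each patient must have exactly one
#'   edge, otherwise the flattening is ambiguous and an error is raised.
#' @return list with `features` (numeric matrix, rownames are patient ids)
#'   and `labels` (0/1 vector).
#' @export
flattenForBaselines <- function(graph) {
  stopifnot(is(graph, "BipartiteGraph"))
  ed <- graph@edges
  if (anyDuplicated(ed$source))
    stop("ambiguous flattening: a patient has more than one edge")
  ed <- ed[match(rownames(graph@patientFeatures), ed$source), , drop = FALSE]
  if (anyNA(ed$source)) stop("patient node without an edge")
  x <- cbind(graph@patientFeatures,
             graph@diagnosisFeatures[ed$target, , drop = FALSE])
  rownames(x) <- sub("^p_", "", rownames(graph@patientFeatures))
  list(features = x, labels = ed$outcome)
}

#' Write the bipartite graph as CSV tables
#'
#' `nodes_patient.csv` and `nodes_diagnosis.csv` (id + feature columns)
#' and `edges.csv` with exactly the `source`, `target`, `outcome` headers.
#'
#' @param graph a [BipartiteGraph].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeBipartiteCsv <- function(graph, dir) {
  stopifnot(is(graph, "BipartiteGraph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, path) {
    df <- data.frame(id = rownames(m), as.data.frame(m, optional = TRUE),
                     check.names = FALSE)
    write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(graph@patientFeatures, file.path(dir, "nodes_patient.csv"))
  wr(graph@diagnosisFeatures, file.path(dir, "nodes_diagnosis.csv"))
  write.csv(graph@edges, file.path(dir, "edges.csv"), row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(dir)
}
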