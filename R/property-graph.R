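#' Relation labels of the patient-centric schema
#'
#' The nine relation labels, one per non-person node label; the relation
#' label of an edge is determined by its tail node's label.
#'
#' @return Named character vector (names are tail node labels).
#' @export
relationLabels <- function() .pg_relations

.join_vals <- function(x) paste(x, collapse = ";")

#' Build the patient-centric heterogeneous property graph
#'
#' Converts a labelled cohort plus its EMR tables into the ten-node-type /
#' nine-edge-type star schema: one `Person` node per patient, one node per
#' populated auxiliary record group (records aggregated to the
#' latest-at-or-before-index value per measure, or joined code/name lists),
#' and one `Event` node carrying the binary outcome.  Every node holds
#' both the patient-ID property and a graph-internal integer id; every
#' edge starts at the person (star shape).
#'
#' @param tables an [EmrTables] bundle.
#' @param cohort labelled cohort from [labelOutcome()]; the graph is
#'   restricted to its patients.
#' @return A [PropertyGraph].
#' @examples
#' emr <- journeyFixture()
#' coh <- labelOutcome(selectCohort(emr), emr)
#' g <- buildPropertyGraph(emr, coh)
#' nodeTypes(g)
#' @export
buildPropertyGraph <- function(tables, cohort) {
  stopifnot(is(tables, "EmrTables"))
  if (anyNA(cohort$outcome)) stop("cohort must be labelled (see labelOutcome)")
  cohort <- cohort[order(cohort$patient_id), , drop = FALSE]
  if (!nrow(cohort))
    return(new("PropertyGraph",
               nodes = data.frame(node_id = integer(0),
                                  label = character(0),
                                  patient_id = character(0),
                                  stringsAsFactors = FALSE),
               props = list(),
               edges = data.frame(head = integer(0), tail = integer(0),
                                  label = character(0),
                                  stringsAsFactors = FALSE)))
  pids <- cohort$patient_id
  person <- tables@person
  mp <- match(pids, person$patient_id)
  if (anyNA(mp)) stop("cohort patient absent from person table")

  sub <- function(df) df[df$patient_id %in% pids, , drop = FALSE]
  idx <- cohort[, c("patient_id", "index_date")]

  props <- list()
  props$Person <- data.frame(patient_id = pids, sex = person$sex[mp],
                             birth_date = format(person$birth_date[mp],
                                                 "%Y-%m-%d"),
                             stringsAsFactors = FALSE)

  dx <- sub(tables@diagnosis)
  if (nrow(dx)) {
    dx <- merge(dx, idx, by = "patient_id")
    dx <- dx[!is.na(dx$diagnosis_date) & dx$diagnosis_date <= dx$index_date, ]
  }
  if (nrow(dx)) {
    dx <- unique(dx[, c("patient_id", "icd10_code", "diagnosis_name")])
    dx <- dx[order(dx$patient_id, dx$icd10_code), ]
    props$Diagnosis <- data.frame(
      patient_id = unique(dx$patient_id),
      codes = as.character(tapply(dx$icd10_code, dx$patient_id, .join_vals)),
      names = as.character(tapply(dx$diagnosis_name, dx$patient_id,
                                  .join_vals)),
      n_codes = as.integer(table(dx$patient_id)),
      stringsAsFactors = FALSE)
  }

  wide_group <- function(df, name_col) {
    df <- sub(df)
    if (!nrow(df)) return(NULL)
    present <- sort(unique(df$patient_id))
    wide <- .latest_before_index(df, name_col,
                                 idx[idx$patient_id %in% present, ])
    wide
  }
  props$Laboratory <- wide_group(tables@laboratory, "test_name")
  props$Echocardiography <- wide_group(tables@echocardiography,
                                       "measure_name")
  props$Physical <- wide_group(tables@physical, "measure_name")

  med <- unique(sub(tables@medication)[, c("patient_id", "drug_name")])
  if (nrow(med)) {
    med <- med[order(med$patient_id, med$drug_name), ]
    props$Medication <- data.frame(
      patient_id = unique(med$patient_id),
      drugs = as.character(tapply(med$drug_name, med$patient_id,
                                  .join_vals)),
      n_drugs = as.integer(table(med$patient_id)),
      stringsAsFactors = FALSE)
  }

  surg <- unique(sub(tables@surgery)[, c("patient_id", "procedure_name")])
  if (nrow(surg)) {
    surg <- surg[order(surg$patient_id, surg$procedure_name), ]
    props$Surgery <- data.frame(
      patient_id = unique(surg$patient_id),
      procedures = as.character(tapply(surg$procedure_name,
                                       surg$patient_id, .join_vals)),
      n_procedures = as.integer(table(surg$patient_id)),
      stringsAsFactors = FALSE)
  }

  vis <- sub(tables@visit)
  if (nrow(vis)) {
    vis <- vis[order(vis$patient_id, vis$visit_date), ]
    props$Visit <- data.frame(
      patient_id = unique(vis$patient_id),
      n_visits = as.integer(table(vis$patient_id)),
      first_visit = format(as.Date(tapply(vis$visit_date, vis$patient_id,
                                          min), origin = "1970-01-01"),
                           "%Y-%m-%d"),
      last_visit = format(as.Date(tapply(vis$visit_date, vis$patient_id,
                                         max), origin = "1970-01-01"),
                          "%Y-%m-%d"),
      stringsAsFactors = FALSE)
  }

  sm <- sub(tables@smoke)
  if (nrow(sm)) {
    sm <- sm[!duplicated(sm$patient_id), ]
    props$Smoke <- data.frame(patient_id = sm$patient_id,
                              smoking_level = as.integer(sm$smoking_level),
                              stringsAsFactors = FALSE)
  }

  ## Event node: one per cohort patient, carrying the outcome and, when an
  ## event occurred, the age at the first composite event.
  ev <- sub(tables@events)
  event_prop <- data.frame(patient_id = pids,
                           outcome = as.integer(cohort$outcome),
                           age_at_event = rep(NA_real_, length(pids)),
                           event_type = rep(NA_character_, length(pids)),
                           stringsAsFactors = FALSE)
  if (nrow(ev)) {
    ev <- merge(ev, cohort[, c("patient_id", "index_date")],
                by = "patient_id")
    ev <- ev[!is.na(ev$event_date) & ev$event_date > ev$index_date, ]
    if (nrow(ev)) {
      ev <- ev[order(ev$patient_id, ev$event_date, ev$event_type), ]
      first <- ev[!duplicated(ev$patient_id), ]
      i <- match(first$patient_id, event_prop$patient_id)
      born <- person$birth_date[match(first$patient_id, person$patient_id)]
      event_prop$age_at_event[i] <-
        floor(as.numeric(first$event_date - born) / 365.25)
      event_prop$event_type[i] <- first$event_type
    }
  }
  props$Event <- event_prop

  props <- props[!vapply(props, is.null, logical(1))]

  ## deterministic internal ids: label order within patient order
  nodes_parts <- lapply(.pg_node_labels, function(lbl) {
    if (is.null(props[[lbl]])) return(NULL)
    data.frame(label = rep(lbl, nrow(props[[lbl]])),
               patient_id = props[[lbl]]$patient_id,
               stringsAsFactors = FALSE)
  })
  nodes <- do.call(rbind, nodes_parts)
  nodes <- nodes[order(nodes$patient_id,
                       match(nodes$label, .pg_node_labels)), ]
  nodes$node_id <- seq_len(nrow(nodes))
  nodes <- nodes[, c("node_id", "label", "patient_id")]
  rownames(nodes) <- NULL

  for (lbl in names(props)) {
    key <- paste(lbl, props[[lbl]]$patient_id)
    props[[lbl]]$node_id <-
      nodes$node_id[match(key, paste(nodes$label, nodes$patient_id))]
    props[[lbl]] <-
      props[[lbl]][order(props[[lbl]]$node_id),
                   c("node_id", setdiff(names(props[[lbl]]),
                                        c("node_id", "patient_id"))),
                   drop = FALSE]
    rownames(props[[lbl]]) <- NULL
  }

  persons <- nodes[nodes$label == "Person", ]
  np <- nodes[nodes$label != "Person", ]
  edges <- data.frame(
    head = persons$node_id[match(np$patient_id, persons$patient_id)],
    tail = np$node_id,
    label = unname(.pg_relations[np$label]),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL

  new("PropertyGraph", nodes = nodes, props = props, edges = edges)
}

#' Extract a patient's journey subgraph
#'
#' The star centred on one person: the person node, all of its neighbours
#' and their properties, unchanged.
#'
#' @param graph a [PropertyGraph].
#' @param patient_id the patient to extract.
#' @return A [PropertyGraph] restricted to that patient.
#' @export
patientJourney <- function(graph, patient_id) {
  stopifnot(is(graph, "PropertyGraph"))
  keep <- graph@nodes$patient_id == patient_id
  if (!any(keep)) stop("patient not found: ", patient_id)
  nodes <- graph@nodes[keep, , drop = FALSE]
  props <- lapply(graph@props, function(p)
    p[p$node_id %in% nodes$node_id, , drop = FALSE])
  props <- props[vapply(props, nrow, integer(1)) > 0]
  edges <- graph@edges[graph@edges$tail %in% nodes$node_id, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  new("PropertyGraph", nodes = nodes, props = props, edges = edges)
}

#' Look up a node property for a patient
#'
#' Convenience read of one property value from a patient's star, e.g. the
#' latest laboratory `blood` value.
#'
#' @param graph a [PropertyGraph].
#' @param patient_id patient to inspect.
#' @param label node label holding the property.
#' @param property property (column) name.
#' @return The property value, or `NA` if the node is absent.
#' @export
nodeProperty <- function(graph, patient_id, label, property) {
  stopifnot(is(graph, "PropertyGraph"))
  if (!label %in% .pg_node_labels) stop("unknown node label: ", label)
  tab <- graph@props[[label]]
  if (is.null(tab)) return(NA)
  if (!property %in% names(tab)) stop("unknown property: ", label, ".",
                                      property)
  nid <- graph@nodes$node_id[graph@nodes$patient_id == patient_id &
                               graph@nodes$label == label]
  if (!length(nid)) return(NA)
  tab[[property]][match(nid, tab$node_id)]
}

#' Query patients across the star
#'
#' Conjunctive filtering over the per-patient stars: medication membership,
#' outcome value and diagnosis-name membership, plus arbitrary equality
#' predicates via `where`.  With `distinct = TRUE` duplicated patient
#' results are excluded.
#'
#' @param graph a [PropertyGraph].
#' @param medication_name keep patients whose medication list contains
#'   this drug.
#' @param outcome keep patients whose `Event` outcome equals this value.
#' @param diagnosis_name keep patients whose diagnosis names contain this
#'   condition.
#' @param where optional named list `list(Label = list(property = value))`
#'   of extra equality predicates; unknown labels or properties raise a
#'   query error.
#' @param distinct deduplicate patient ids (default `TRUE`).
#' @return list with `patient_ids` (sorted) and `count`.
#' @examples
#' emr <- journeyFixture()
#' coh <- labelOutcome(selectCohort(emr), emr)
#' g <- buildPropertyGraph(emr, coh)
#' queryPatients(g, medication_name = "statin")$count
#' @export
queryPatients <- function(graph, medication_name = NULL, outcome = NULL,
                          diagnosis_name = NULL, where = NULL,
                          distinct = TRUE) {
  stopifnot(is(graph, "PropertyGraph"))
  sets <- list()

  member_set <- function(label, column, value) {
    tab <- graph@props[[label]]
    if (is.null(tab)) return(character(0))
    hit <- vapply(strsplit(tab[[column]], ";", fixed = TRUE),
                  function(v) value %in% v, logical(1))
    .pg_patients(graph, tab$node_id[hit])
  }
  if (!is.null(medication_name))
    sets$medication <- member_set("Medication", "drugs", medication_name)
  if (!is.null(diagnosis_name))
    sets$diagnosis <- member_set("Diagnosis", "names", diagnosis_name)
  if (!is.null(outcome)) {
    tab <- graph@props$Event
    sets$outcome <- if (is.null(tab)) character(0) else
      .pg_patients(graph, tab$node_id[tab$outcome == outcome])
  }
  if (!is.null(where)) {
    for (lbl in names(where)) {
      if (!lbl %in% .pg_node_labels) stop("unknown node label: ", lbl)
      tab <- graph@props[[lbl]]
      for (prop in names(where[[lbl]])) {
        if (!is.null(tab) && !prop %in% names(tab))
          stop("unknown property: ", lbl, ".", prop)
        sets[[paste(lbl, prop)]] <- if (is.null(tab)) character(0) else
          .pg_patients(graph,
                       tab$node_id[!is.na(tab[[prop]]) &
                                     tab[[prop]] == where[[lbl]][[prop]]])
      }
    }
  }
  res <- if (!length(sets)) patientIds(graph) else Reduce(intersect, sets)
  res <- sort(res)
  if (distinct) res <- unique(res)
  list(patient_ids = res, count = length(res))
}

.pg_patients <- function(graph, node_ids)
  graph@nodes$patient_id[match(node_ids, graph@nodes$node_id)]
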