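#' emrgraph: heterogeneous patient graphs and HinSAGE link prediction
#'
#' Builds a patient-centric heterogeneous property graph and a bipartite
#' patient--diagnosis graph from EMR-style tables, and predicts a binary
#' five-year composite cardiovascular event outcome attached to the
#' patient--diagnosis edges with a from-scratch heterogeneous GraphSAGE
#' (HinSAGE) model.
#'
#' @import methods
#' @importFrom stats rnorm runif rbinom rpois plogis uniroot median sd
#'   quantile predict aggregate setNames
#' @importFrom utils read.csv write.csv head tail
#' @keywords internal
"_PACKAGE"

## Canonical column sets of the EMR table bundle.  All dates are Date,
## values double, everything else character/integer.
.emr_columns <- list(
  person           = c("patient_id", "sex", "birth_date"),
  diagnosis        = c("patient_id", "icd10_code", "diagnosis_name",
                       "diagnosis_date", "encounter_type"),
  laboratory       = c("patient_id", "test_name", "value", "date"),
  echocardiography = c("patient_id", "measure_name", "value", "date"),
  physical         = c("patient_id", "measure_name", "value", "date"),
  medication       = c("patient_id", "drug_name", "start_date"),
  surgery          = c("patient_id", "procedure_name", "date"),
  visit            = c("patient_id", "visit_date", "encounter_type",
                       "age_at_visit"),
  smoke            = c("patient_id", "smoking_level"),
  events           = c("patient_id", "event_type", "event_date")
)

.aux_tables <- setdiff(names(.emr_columns), "person")

.empty_emr_table <- function(table) {
  cols <- .emr_columns[[table]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  date_cols <- intersect(cols, c("birth_date", "diagnosis_date", "date",
                                 "start_date", "visit_date", "event_date"))
  for (dc in date_cols) df[[dc]] <- as.Date(character(0))
  num_cols <- intersect(cols, c("value", "age_at_visit"))
  for (nc in num_cols) df[[nc]] <- numeric(0)
  if ("smoking_level" %in% cols) df$smoking_level <- integer(0)
  df
}

#' Bundle of EMR-style record tables
#'
#' Container for the raw input universe: a `person` table plus eight
#' auxiliary record tables (diagnosis, laboratory, echocardiography,
#' physical, medication, surgery, visit, smoke) and an `events` table,
#' all keyed by an anonymized `patient_id`.
#'
#' @slot person data.frame with columns `patient_id`, `sex`, `birth_date`.
#' @slot diagnosis data.frame of ICD-10 coded diagnoses with encounter type.
#' @slot laboratory,echocardiography,physical long-format numeric
#'   measurements (`*_name`, `value`, `date`).
#' @slot medication,surgery named treatments with dates.
#' @slot visit encounter dates with type and age at visit.
#' @slot smoke one smoking-level record per patient.
#' @slot events composite-outcome events (`death`, `MI`, `stroke`,
#'   `heart_failure`) with dates.
#'
#' @exportClass EmrTables
setClass("EmrTables",
  representation(
    person = "data.frame",
    diagnosis = "data.frame",
    laboratory = "data.frame",
    echocardiography = "data.frame",
    physical = "data.frame",
    medication = "data.frame",
    surgery = "data.frame",
    visit = "data.frame",
    smoke = "data.frame",
    events = "data.frame"
  )
)

setValidity("EmrTables", function(object) {
  msgs <- character(0)
  for (tb in names(.emr_columns)) {
    df <- slot(object, tb)
    missing_cols <- setdiff(.emr_columns[[tb]], names(df))
    if (length(missing_cols))
      msgs <- c(msgs, sprintf("table '%s' lacks column(s): %s", tb,
                              paste(missing_cols, collapse = ", ")))
  }
  if (!length(msgs)) {
    pids <- object@person$patient_id
    if (anyDuplicated(pids))
      msgs <- c(msgs, "duplicated patient_id in person table")
    for (tb in .aux_tables) {
      df <- slot(object, tb)
      if (nrow(df) && !all(df$patient_id %in% pids))
        msgs <- c(msgs, sprintf(
          "table '%s' references patient_id absent from person", tb))
    }
    for (tb in c("laboratory", "echocardiography", "physical")) {
      v <- slot(object, tb)$value
      if (length(v) && any(!is.finite(v)))
        msgs <- c(msgs, sprintf("non-finite value in table '%s'", tb))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an [EmrTables] bundle
#'
#' Missing tables default to empty tables with the canonical column sets,
#' so `EmrTables()` is the valid empty universe.
#'
#' @param person,diagnosis,laboratory,echocardiography,physical,medication,surgery,visit,smoke,events
#'   data.frames with the canonical columns (extra columns are kept).
#' @return An [EmrTables] object.
#' @examples
#' emr <- EmrTables()
#' nrow(personTable(emr))
#' @export
EmrTables <- function(person = .empty_emr_table("person"),
                      diagnosis = .empty_emr_table("diagnosis"),
                      laboratory = .empty_emr_table("laboratory"),
                      echocardiography = .empty_emr_table("echocardiography"),
                      physical = .empty_emr_table("physical"),
                      medication = .empty_emr_table("medication"),
                      surgery = .empty_emr_table("surgery"),
                      visit = .empty_emr_table("visit"),
                      smoke = .empty_emr_table("smoke"),
                      events = .empty_emr_table("events")) {
  new("EmrTables", person = person, diagnosis = diagnosis,
      laboratory = laboratory, echocardiography = echocardiography,
      physical = physical, medication = medication, surgery = surgery,
      visit = visit, smoke = smoke, events = events)
}

setMethod("show", "EmrTables", function(object) {
  cat("EmrTables bundle\n")
  cat(sprintf("  %d patients\n", nrow(object@person)))
  for (tb in .aux_tables)
    cat(sprintf("  %-16s %6d records\n", tb, nrow(slot(object, tb))))
})

## The canonical node labels of the property graph and the relation label
## determined by each tail node's label (relation label follows the tail).
.pg_node_labels <- c("Person", "Diagnosis", "Laboratory", "Echocardiography",
                     "Physical", "Medication", "Surgery", "Visit", "Smoke",
                     "Event")

.pg_relations <- c(
  Diagnosis        = "HAS_DIAGNOSIS",
  Laboratory       = "HAS_LAB",
  Echocardiography = "HAS_ECHO",
  Physical         = "HAS_PHYSICAL",
  Medication       = "TAKES_MEDICATION",
  Surgery          = "UNDERWENT_SURGERY",
  Visit            = "HAS_VISIT",
  Smoke            = "HAS_SMOKING_STATUS",
  Event            = "EXPERIENCED_EVENT"
)

#' Patient-centric heterogeneous property graph
#'
#' A Neo4j-style attributed multigraph: typed nodes with per-label property
#' tables, and typed directed edges.  The graph is patient-centric: every
#' non-person node hangs off exactly one `Person` node (a star per patient),
#' and the relation label is determined by the tail node's label.
#'
#' @slot nodes data.frame with `node_id` (internal integer id), `label`
#'   (one of the ten canonical node labels) and `patient_id`.
#' @slot props named list, one data.frame per node label present, keyed by
#'   `node_id`, holding that label's property columns.
#' @slot edges data.frame with `head` (Person `node_id`), `tail`
#'   (non-person `node_id`) and `label` (relation label).
#'
#' @exportClass PropertyGraph
setClass("PropertyGraph",
  representation(nodes = "data.frame", props = "list", edges = "data.frame")
)

setValidity("PropertyGraph", function(object) {
  msgs <- character(0)
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("node_id", "label", "patient_id") %in% names(nd)))
    return("nodes must have node_id, label, patient_id")
  if (!all(c("head", "tail", "label") %in% names(ed)))
    return("edges must have head, tail, label")
  if (anyDuplicated(nd$node_id))
    msgs <- c(msgs, "duplicated node_id")
  if (!all(nd$label %in% .pg_node_labels))
    msgs <- c(msgs, "unknown node label")
  persons <- nd$node_id[nd$label == "Person"]
  if (anyDuplicated(nd$patient_id[nd$label == "Person"]))
    msgs <- c(msgs, "patient_id not unique among Person nodes")
  if (nrow(ed)) {
    if (!all(ed$head %in% persons))
      msgs <- c(msgs, "edge head is not a Person node (star invariant)")
    if (!all(ed$tail %in% nd$node_id))
      msgs <- c(msgs, "edge tail references unknown node")
    tail_label <- nd$label[match(ed$tail, nd$node_id)]
    if (any(tail_label == "Person"))
      msgs <- c(msgs, "edge tail must be a non-person node")
    else if (!all(ed$label == .pg_relations[tail_label]))
      msgs <- c(msgs, "relation label inconsistent with tail node label")
    if (anyDuplicated(ed$tail))
      msgs <- c(msgs, "non-person node attached to more than one person")
  }
  np <- nd$node_id[nd$label != "Person"]
  if (length(np) && !all(np %in% ed$tail))
    msgs <- c(msgs, "non-person node not reachable from a person")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PropertyGraph", function(object) {
  cat("PropertyGraph\n")
  cat(sprintf("  %d nodes (%d types), %d edges (%d types)\n",
              nrow(object@nodes), length(unique(object@nodes$label)),
              nrow(object@edges), length(unique(object@edges$label))))
  cat(sprintf("  %d patients\n",
              sum(object@nodes$label == "Person")))
})

#' Bipartite attributed patient--diagnosis graph
#'
#' The learning-ready graph: a patient partition and a diagnosis partition,
#' each with fixed-length feature vectors, joined by edges whose single
#' attribute is the binary five-year composite event outcome.  Node ids are
#' prefixed (`p_`, `d_`) so the two partitions can never collide.
#'
#' @slot patientFeatures numeric matrix, one row per patient node, rownames
#'   are prefixed patient ids.
#' @slot diagnosisFeatures numeric matrix, one row per diagnosis node,
#'   rownames are prefixed diagnosis ids.
#' @slot edges data.frame with `source` (patient id), `target` (diagnosis
#'   id) and `outcome` (0/1).
#' @slot mode `"per_patient"` (one diagnosis-profile node and one edge per
#'   patient) or `"shared_diagnosis"` (identical profiles shared).
#'
#' @exportClass BipartiteGraph
setClass("BipartiteGraph",
  representation(patientFeatures = "matrix", diagnosisFeatures = "matrix",
                 edges = "data.frame", mode = "character")
)

setValidity("BipartiteGraph", function(object) {
  msgs <- character(0)
  pf <- object@patientFeatures
  df <- object@diagnosisFeatures
  ed <- object@edges
  if (!all(c("source", "target", "outcome") %in% names(ed)))
    return("edges must have source, target, outcome")
  if (length(object@mode) != 1 ||
      !object@mode %in% c("per_patient", "shared_diagnosis"))
    msgs <- c(msgs, "mode must be per_patient or shared_diagnosis")
  if (nrow(pf) && !all(startsWith(rownames(pf), "p_")))
    msgs <- c(msgs, "patient node ids must carry the p_ prefix")
  if (nrow(df) && !all(startsWith(rownames(df), "d_")))
    msgs <- c(msgs, "diagnosis node ids must carry the d_ prefix")
  if (anyDuplicated(c(rownames(pf), rownames(df))))
    msgs <- c(msgs, "node ids not globally unique")
  if (nrow(ed)) {
    if (!all(ed$source %in% rownames(pf)))
      msgs <- c(msgs, "edge source must be a patient node")
    if (!all(ed$target %in% rownames(df)))
      msgs <- c(msgs, "edge target must be a diagnosis node (bipartite)")
    if (!all(ed$outcome %in% c(0, 1)))
      msgs <- c(msgs, "edge outcome must be binary 0/1")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BipartiteGraph", function(object) {
  cat("BipartiteGraph (undirected multigraph, mode:", object@mode, ")\n")
  cat(sprintf("  %d patient nodes x %d features\n",
              nrow(object@patientFeatures), ncol(object@patientFeatures)))
  cat(sprintf("  %d diagnosis nodes x %d features\n",
              nrow(object@diagnosisFeatures), ncol(object@diagnosisFeatures)))
  cat(sprintf("  %d edges, edge feature length 1 (outcome), %d positive\n",
              nrow(object@edges), sum(object@edges$outcome == 1)))
})

#' Trained HinSAGE link-attribute model
#'
#' Per-layer, per-node-type weight sets of the heterogeneous GraphSAGE
#' model, the sampler and training configuration it was fitted with, and
#' the per-epoch training history.
#'
#' @slot params nested list of weight matrices (`W_self`, `W_neigh`, bias
#'   per layer and node type) plus the logistic link head.
#' @slot sampler the [samplerConfig()] used during training.
#' @slot train the [trainConfig()] used during training.
#' @slot history data.frame with one row per epoch: training loss and
#'   accuracy, validation loss and accuracy.
#'
#' @exportClass HinsageModel
setClass("HinsageModel",
  representation(params = "list", sampler = "list", train = "list",
                 history = "data.frame")
)

setMethod("show", "HinsageModel", function(object) {
  cat("HinsageModel\n")
  cat(sprintf("  layers: %d, hidden sizes: %s, link operator: %s\n",
              length(object@params$layers),
              paste(object@params$hidden, collapse = ", "),
              object@params$head$operator))
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  trained %d epochs; final loss %.4f acc %.3f / val loss %.4f acc %.3f\n",
                nrow(object@history), last$loss, last$accuracy,
                last$val_loss, last$val_accuracy))
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
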