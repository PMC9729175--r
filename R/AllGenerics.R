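#' Accessors for emrgraph containers
#'
#' Small accessor generics in place of direct slot access: node/edge type
#' inventories, node and edge counts, patient ids and edge tables.
#'
#' @param x an [EmrTables], [PropertyGraph], [BipartiteGraph] or
#'   [HinsageModel] object.
#' @return `nodeTypes`/`edgeTypes` return character vectors; `nNodes` and
#'   `nEdges` integers; `patientIds` a character vector; `edgeTable` a
#'   data.frame; `trainHistory` the per-epoch history data.frame.
#' @name accessors
#' @examples
#' g <- buildBipartite(labelOutcome(selectCohort(journeyFixture())),
#'                     journeyFixture())
#' nNodes(g); nEdges(g)
NULL

#' @rdname accessors
#' @export
setGeneric("nodeTypes", function(x) standardGeneric("nodeTypes"))
#' @rdname accessors
#' @export
setGeneric("edgeTypes", function(x) standardGeneric("edgeTypes"))
#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))
#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("trainHistory", function(x) standardGeneric("trainHistory"))

#' @rdname accessors
#' @export
setMethod("nodeTypes", "PropertyGraph",
          function(x) sort(unique(x@nodes$label)))
#' @rdname accessors
#' @export
setMethod("edgeTypes", "PropertyGraph",
          function(x) sort(unique(x@edges$label)))
#' @rdname accessors
#' @export
setMethod("nNodes", "PropertyGraph", function(x) nrow(x@nodes))
#' @rdname accessors
#' @export
setMethod("nEdges", "PropertyGraph", function(x) nrow(x@edges))
#' @rdname accessors
#' @export
setMethod("patientIds", "PropertyGraph",
          function(x) x@nodes$patient_id[x@nodes$label == "Person"])

#' @rdname accessors
#' @export
setMethod("nNodes", "BipartiteGraph",
          function(x) nrow(x@patientFeatures) + nrow(x@diagnosisFeatures))
#' @rdname accessors
#' @export
setMethod("nEdges", "BipartiteGraph", function(x) nrow(x@edges))
#' @rdname accessors
#' @export
setMethod("edgeTable", "BipartiteGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("patientIds", "BipartiteGraph",
          function(x) sub("^p_", "", rownames(x@patientFeatures)))
#' @rdname accessors
#' @export
setMethod("nodeTypes", "BipartiteGraph",
          function(x) c("patient", "diagnosis"))

#' @rdname accessors
#' @export
setMethod("trainHistory", "HinsageModel", function(x) x@history)

#' @rdname accessors
#' @param partition `"patient"` or `"diagnosis"`.
#' @export
nodeFeatures <- function(x, partition = c("patient", "diagnosis")) {
  stopifnot(is(x, "BipartiteGraph"))
  partition <- match.arg(partition)
  if (partition == "patient") x@patientFeatures else x@diagnosisFeatures
}

#' @rdname accessors
#' @export
personTable <- function(x) {
  stopifnot(is(x, "EmrTables"))
  x@person
}

#' @rdname accessors
#' @param table name of one of the ten EMR tables.
#' @export
emrTable <- function(x, table) {
  stopifnot(is(x, "EmrTables"))
  table <- match.arg(table, names(.emr_columns))
  slot(x, table)
}
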