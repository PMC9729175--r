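## ---- typed CSV helpers (Neo4j bulk-import style `name:type` headers) ----

.col_type <- function(x) {
  if (is.integer(x)) "int"
  else if (is.numeric(x)) "double"
  else "string"
}

.csv_quote <- function(x) {
  x[is.na(x)] <- ""
  need <- grepl('[",\n]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

.format_col <- function(x) {
  out <- if (is.double(x)) sprintf("%.17g", x) else as.character(x)
  out[is.na(x)] <- NA_character_
  out
}

.write_typed_csv <- function(df, path) {
  types <- vapply(df, .col_type, character(1))
  header <- paste(paste0(names(df), ":", types), collapse = ",")
  cols <- lapply(df, function(x) .csv_quote(.format_col(x)))
  body <- if (nrow(df)) do.call(paste, c(cols, sep = ",")) else character(0)
  writeLines(c(header, body), path, useBytes = TRUE)
}

.read_typed_csv <- function(path) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  out <- list()
  for (h in names(df)) {
    type <- sub("^.*:", "", h)
    nm <- sub(":[a-z]+$", "", h)
    v <- df[[h]]
    v[v == ""] <- NA
    out[[nm]] <- switch(type,
                        int = as.integer(v),
                        double = as.numeric(v),
                        v)
  }
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Export a property graph as Cypher bulk-import scripts
#'
#' Writes a directory of deterministic, re-parseable import artifacts:
#' `constraints.cypher` with one uniqueness constraint per canonical node
#' label and look-up indexes on the patient-ID attribute;
#' `nodes_<Label>.csv` / `edges_<REL>.csv` data files with typed
#' (`name:type`) headers; and `import.cypher` with `LOAD CSV`-style
#' creation statements batched so that no transaction exceeds
#' `batch_size` rows.  Output is sorted by label, then by internal id.
#'
#' @param graph a [PropertyGraph].
#' @param dir output directory (created if needed).
#' @param batch_size maximum rows per import transaction (>= 1).
#' @return `dir`, invisibly.
#' @seealso [parseCypherExport()] for the lossless inverse.
#' @export
exportCypher <- function(graph, dir, batch_size = 1000L) {
  stopifnot(is(graph, "PropertyGraph"))
  if (batch_size < 1) stop("batch_size must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  cons <- c(
    sprintf(paste0("CREATE CONSTRAINT %s_patient_id IF NOT EXISTS FOR ",
                   "(n:%s) REQUIRE n.patient_id IS UNIQUE;"),
            tolower(.pg_node_labels), .pg_node_labels),
    sprintf(paste0("CREATE INDEX %s_patient_id_idx IF NOT EXISTS FOR ",
                   "(n:%s) ON (n.patient_id);"),
            tolower(.pg_node_labels), .pg_node_labels))
  writeLines(cons, file.path(dir, "constraints.cypher"), useBytes = TRUE)

  stmts <- character(0)
  batch_stmt <- function(n_rows, template, file) {
    starts <- seq(0L, max(n_rows - 1L, 0L), by = batch_size)
    sprintf(template, file, starts, batch_size)
  }
  for (lbl in sort(unique(graph@nodes$label))) {
    tab <- graph@props[[lbl]]
    nd <- graph@nodes[graph@nodes$label == lbl, c("node_id", "patient_id")]
    tab <- if (is.null(tab)) nd else merge(nd, tab, by = "node_id")
    tab <- tab[order(tab$node_id), , drop = FALSE]
    file <- sprintf("nodes_%s.csv", lbl)
    .write_typed_csv(tab, file.path(dir, file))
    stmts <- c(stmts, batch_stmt(nrow(tab), paste0(
      "LOAD CSV WITH HEADERS FROM 'file:///%s' AS row WITH row ",
      "SKIP %d LIMIT %d CREATE (n:", lbl, ") SET n = row;"), file))
  }
  for (rel in sort(unique(graph@edges$label))) {
    ed <- graph@edges[graph@edges$label == rel, c("head", "tail")]
    ed <- ed[order(ed$head, ed$tail), , drop = FALSE]
    ed$head <- as.integer(ed$head)
    ed$tail <- as.integer(ed$tail)
    file <- sprintf("edges_%s.csv", rel)
    .write_typed_csv(ed, file.path(dir, file))
    stmts <- c(stmts, batch_stmt(nrow(ed), paste0(
      "LOAD CSV WITH HEADERS FROM 'file:///%s' AS row WITH row ",
      "SKIP %d LIMIT %d ",
      "MATCH (h:Person {node_id: toInteger(row.head)}) ",
      "MATCH (t {node_id: toInteger(row.tail)}) ",
      "CREATE (h)-[:", rel, "]->(t);"), file))
  }
  writeLines(stmts, file.path(dir, "import.cypher"), useBytes = TRUE)
  invisible(dir)
}

#' Parse a Cypher bulk-import directory back into a property graph
#'
#' Reads the dialect written by [exportCypher()] (constraint/index
#' statements plus batched `LOAD CSV` creation statements with typed CSV
#' data files) and reconstructs the nodes, properties and edges exactly.
#' Any statement outside that dialect raises a parse error naming the
#' offending line.
#'
#' @param dir directory written by [exportCypher()].
#' @return A [PropertyGraph].
#' @export
parseCypherExport <- function(dir) {
  cons_path <- file.path(dir, "constraints.cypher")
  imp_path <- file.path(dir, "import.cypher")
  for (p in c(cons_path, imp_path))
    if (!file.exists(p)) stop("missing script file: ", p)
  cons <- readLines(cons_path)
  bad <- which(!grepl("^CREATE (CONSTRAINT|INDEX) ", cons) & nzchar(cons))
  if (length(bad))
    stop(sprintf("unsupported statement at constraints.cypher line %d: %s",
                 bad[1], cons[bad[1]]))

  node_re <- paste0("^LOAD CSV WITH HEADERS FROM 'file:///([^']+)' AS row ",
                    "WITH row SKIP ([0-9]+) LIMIT ([0-9]+) ",
                    "CREATE \\(n:([A-Za-z]+)\\) SET n = row;$")
  edge_re <- paste0("^LOAD CSV WITH HEADERS FROM 'file:///([^']+)' AS row ",
                    "WITH row SKIP ([0-9]+) LIMIT ([0-9]+) ",
                    "MATCH \\(h:Person \\{node_id: toInteger\\(row.head\\)\\}\\) ",
                    "MATCH \\(t \\{node_id: toInteger\\(row.tail\\)\\}\\) ",
                    "CREATE \\(h\\)-\\[:([A-Z_]+)\\]->\\(t\\);$")
  stmts <- readLines(imp_path)
  nodes <- data.frame()
  props <- list()
  edges <- list()
  seen <- character(0)
  for (i in seq_along(stmts)) {
    line <- stmts[i]
    if (!nzchar(line)) next
    if (grepl(node_re, line)) {
      m <- regmatches(line, regexec(node_re, line))[[1]]
      file <- m[2]; skip <- as.integer(m[3]); lim <- as.integer(m[4])
      lbl <- m[5]
      tab <- .read_typed_csv(file.path(dir, file))
      rows <- tab[seq_len(nrow(tab)) > skip &
                    seq_len(nrow(tab)) <= skip + lim, , drop = FALSE]
      if (!nrow(rows)) next
      nodes <- rbind(nodes, data.frame(node_id = rows$node_id, label = lbl,
                                       patient_id = rows$patient_id,
                                       stringsAsFactors = FALSE))
      extra <- rows[, setdiff(names(rows), "patient_id"), drop = FALSE]
      props[[lbl]] <- if (is.null(props[[lbl]])) extra else
        rbind(props[[lbl]], extra)
    } else if (grepl(edge_re, line)) {
      m <- regmatches(line, regexec(edge_re, line))[[1]]
      file <- m[2]; skip <- as.integer(m[3]); lim <- as.integer(m[4])
      rel <- m[5]
      tab <- .read_typed_csv(file.path(dir, file))
      rows <- tab[seq_len(nrow(tab)) > skip &
                    seq_len(nrow(tab)) <= skip + lim, , drop = FALSE]
      if (!nrow(rows)) next
      edges[[length(edges) + 1L]] <-
        data.frame(head = rows$head, tail = rows$tail, label = rel,
                   stringsAsFactors = FALSE)
    } else {
      stop(sprintf("unsupported statement at import.cypher line %d: %s",
                   i, line))
    }
  }
  if (!nrow(nodes))
    nodes <- data.frame(node_id = integer(0), label = character(0),
                        patient_id = character(0), stringsAsFactors = FALSE)
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(head = integer(0), tail = integer(0), label = character(0),
               stringsAsFactors = FALSE)
  ## drop all-NA property tables reduced to the id column only
  props <- lapply(props, function(p) {
    p <- p[order(p$node_id), , drop = FALSE]
    rownames(p) <- NULL
    p
  })
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  new("PropertyGraph", nodes = nodes, props = props, edges = edges)
}

#' Property-wise equality of two property graphs
#'
#' Compares node sets, per-label property tables (rows matched by internal
#' id, numeric values to a tolerance, `NA`s equal) and edge sets.
#'
#' @param a,b [PropertyGraph] objects.
#' @param tol numeric tolerance.
#' @return `TRUE`, or a character description of the first difference.
#' @export
graphsEqual <- function(a, b, tol = 1e-9) {
  na <- a@nodes[order(a@nodes$node_id), ]
  nb <- b@nodes[order(b@nodes$node_id), ]
  if (!identical(unname(as.list(na)), unname(as.list(nb))))
    return("node tables differ")
  ea <- a@edges[order(a@edges$head, a@edges$tail, a@edges$label), ]
  eb <- b@edges[order(b@edges$head, b@edges$tail, b@edges$label), ]
  if (nrow(ea) != nrow(eb) ||
      (nrow(ea) && !all(ea$head == eb$head & ea$tail == eb$tail &
                          ea$label == eb$label)))
    return("edge tables differ")
  labs_a <- names(a@props)[vapply(a@props, nrow, integer(1)) > 0]
  labs_b <- names(b@props)[vapply(b@props, nrow, integer(1)) > 0]
  if (!setequal(labs_a, labs_b)) return("property label sets differ")
  for (lbl in labs_a) {
    pa <- a@props[[lbl]]; pb <- b@props[[lbl]]
    pb <- pb[match(pa$node_id, pb$node_id), , drop = FALSE]
    if (!setequal(names(pa), names(pb)))
      return(paste("property columns differ for", lbl))
    for (cl in names(pa)) {
      va <- pa[[cl]]; vb <- pb[[cl]]
      same_na <- identical(is.na(va), is.na(vb))
      ok <- if (is.numeric(va) && is.numeric(vb))
        same_na && all(abs(va - vb) <= tol, na.rm = TRUE)
      else same_na && all(as.character(va) == as.character(vb),
                          na.rm = TRUE)
      if (!isTRUE(ok))
        return(sprintf("property %s.%s differs", lbl, cl))
    }
  }
  TRUE
}

#' Export a property graph to GraphML
#'
#' Standard GraphML via igraph: node label, patient id and all node
#' properties become vertex attributes (union across labels, `NA` where a
#' property does not apply); the relation label becomes an edge attribute.
#'
#' @param graph a [PropertyGraph].
#' @param path output `.graphml` file.
#' @return `path`, invisibly.
#' @export
exportGraphML <- function(graph, path) {
  stopifnot(is(graph, "PropertyGraph"))
  nd <- graph@nodes
  vdf <- data.frame(name = as.character(nd$node_id), label = nd$label,
                    patient_id = nd$patient_id, stringsAsFactors = FALSE)
  for (lbl in names(graph@props)) {
    tab <- graph@props[[lbl]]
    for (cl in setdiff(names(tab), "node_id")) {
      if (is.null(vdf[[cl]]))
        vdf[[cl]] <- if (is.numeric(tab[[cl]])) NA_real_ else NA_character_
      vdf[[cl]][match(tab$node_id, nd$node_id)] <- tab[[cl]]
    }
  }
  edf <- data.frame(from = as.character(graph@edges$head),
                    to = as.character(graph@edges$tail),
                    label = graph@edges$label, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    if (nrow(edf)) edf else data.frame(from = character(0),
                                       to = character(0)),
    directed = TRUE, vertices = vdf)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
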