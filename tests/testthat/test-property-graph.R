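journey_graph <- function() {
  emr <- journeyFixture()
  co <- labelOutcome(selectCohort(emr), emr)
  list(tables = emr, cohort = co, graph = buildPropertyGraph(emr, co))
}

test_that("a fully populated patient yields the 10-node, 9-edge star", {
  jg <- journey_graph()
  star <- patientJourney(jg$graph, "107411")
  expect_identical(nNodes(star), 10L)
  expect_identical(nEdges(star), 9L)
  expect_setequal(nodeTypes(star),
                  c("Person", "Diagnosis", "Laboratory", "Echocardiography",
                    "Physical", "Medication", "Surgery", "Visit", "Smoke",
                    "Event"))
  expect_setequal(edgeTypes(star), unname(relationLabels()))
})

test_that("journey properties round-trip the printed patient record", {
  g <- journey_graph()$graph
  expect_identical(nodeProperty(g, "107411", "Laboratory", "blood"), 94.0)
  expect_identical(nodeProperty(g, "107411", "Echocardiography", "EF"),
                   -1.0)
  expect_identical(nodeProperty(g, "107411", "Physical", "weight"), 53.55)
  expect_identical(nodeProperty(g, "107411", "Smoke", "smoking_level"), 1L)
  expect_match(nodeProperty(g, "107411", "Diagnosis", "names"),
               "hypertension")
  expect_match(nodeProperty(g, "107411", "Medication", "drugs"), "statin")
  expect_match(nodeProperty(g, "107411", "Surgery", "procedures"),
               "diagnostic ultrasound")
  expect_identical(nodeProperty(g, "107411", "Event", "age_at_event"), 67)
  expect_identical(nodeProperty(g, "107411", "Event", "outcome"), 1L)
})

test_that("patients without records in a group get no node of that type", {
  g <- journey_graph()$graph
  star <- patientJourney(g, "200005")  # no medication/surgery/echo records
  expect_false(any(c("Medication", "Surgery", "Echocardiography") %in%
                     nodeTypes(star)))
  expect_true(all(c("Person", "Event", "Visit") %in% nodeTypes(star)))
  expect_error(patientJourney(g, "nobody"), "not found")
})

test_that("node and edge counts match an independent row-count oracle", {
  st <- small_study(300, seed = 6)
  g <- buildPropertyGraph(st$tables, st$cohort)
  pids <- st$cohort$patient_id
  expected_nodes <- length(pids) + length(pids)  # Person + Event
  expected_edges <- length(pids)                 # Event edges
  for (tb in c("diagnosis", "laboratory", "echocardiography", "physical",
               "medication", "surgery", "visit", "smoke")) {
    df <- emrTable(st$tables, tb)
    pop <- length(unique(df$patient_id[df$patient_id %in% pids]))
    expected_nodes <- expected_nodes + pop
    expected_edges <- expected_edges + pop
  }
  expect_identical(nNodes(g), expected_nodes)
  expect_identical(nEdges(g), expected_edges)
  expect_true(validObject(g))
})

test_that("the union of all patient journeys partitions the graph", {
  st <- small_study(60, seed = 8)
  g <- buildPropertyGraph(st$tables, st$cohort)
  ids <- unlist(lapply(patientIds(g), function(p)
    patientJourney(g, p)@nodes$node_id))
  expect_identical(sort(ids), sort(g@nodes$node_id))
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("star invariant: every edge starts at a person node", {
  st <- small_study(50, seed = 12)
  g <- buildPropertyGraph(st$tables, st$cohort)
  persons <- g@nodes$node_id[g@nodes$label == "Person"]
  expect_true(all(g@edges$head %in% persons))
  expect_false(any(g@edges$tail %in% persons))
})

test_that("queries filter conjunctively and deduplicate patients", {
  jg <- journey_graph()
  q_statin <- queryPatients(jg$graph, medication_name = "statin")
  expect_identical(q_statin$count, 3L)
  expect_setequal(q_statin$patient_ids, c("107411", "200001", "200002"))

  q_pos <- queryPatients(jg$graph, outcome = 1)
  q_both <- queryPatients(jg$graph, medication_name = "statin", outcome = 1)
  expect_setequal(q_both$patient_ids,
                  intersect(q_statin$patient_ids, q_pos$patient_ids))
  q_dx <- queryPatients(jg$graph, diagnosis_name = "hypertension",
                        outcome = 1)
  expect_identical(q_dx$patient_ids, "107411")
  expect_error(queryPatients(jg$graph,
                             where = list(Laboratory = list(nope = 1))),
               "unknown property")
  expect_error(queryPatients(jg$graph, where = list(Foo = list(x = 1))),
               "unknown node label")
})

test_that("query counts equal brute-force scans of the source tables", {
  for (seed in c(4, 9, 14)) {
    st <- small_study(50, seed = seed)
    g <- buildPropertyGraph(st$tables, st$cohort)
    med <- emrTable(st$tables, "medication")
    expected <- sort(unique(med$patient_id[
      med$drug_name == "statin" &
        med$patient_id %in% st$cohort$patient_id]))
    got <- queryPatients(g, medication_name = "statin")
    expect_identical(got$patient_ids, expected)
    expect_identical(got$count, length(expected))
    pos <- sort(st$cohort$patient_id[st$cohort$outcome == 1])
    expect_identical(queryPatients(g, outcome = 1)$patient_ids, pos)
  }
})
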