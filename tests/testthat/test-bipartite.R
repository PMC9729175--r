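study_features <- function(n = 200, seed = 5, ...) {
  st <- small_study(n, seed = seed)
  st$features <- buildFeatures(st$cohort, st$tables, ...)
  st
}

test_that("default schema gives 12 patient and 147 diagnosis features", {
  st <- study_features()
  expect_identical(ncol(st$features$patient), 12L)
  expect_identical(ncol(st$features$diagnosis), 147L)
  expect_identical(nrow(st$features$patient), nrow(st$cohort))
  bg <- buildBipartite(st$cohort, st$features)
  expect_identical(ncol(edgeTable(bg)) - 2L, 1L)  # outcome only
})

test_that("z-scored training columns have mean 0 and unit sd", {
  st <- study_features()
  x <- st$features$patient
  expect_true(all(abs(colMeans(x)) < 1e-9))
  sds <- apply(x, 2, sd)
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-9))
  raw <- buildFeatures(st$cohort, st$tables,
                       featureSchema(normalization = "none"))
  expect_gt(max(abs(colMeans(raw$patient))), 1)
})

test_that("train statistics are reusable on held-out patients", {
  st <- study_features()
  tr <- st$cohort[1:120, ]; te <- st$cohort[121:nrow(st$cohort), ]
  ftr <- buildFeatures(tr, st$tables)
  fte <- buildFeatures(te, st$tables, stats = ftr$stats)
  expect_identical(colnames(fte$diagnosis), colnames(ftr$diagnosis))
  ## held-out columns are standardized with the training centers
  expect_gt(max(abs(colMeans(fte$patient))), 1e-9)
})

test_that("an all-missing measure imputes to a constant with all-one indicator", {
  st <- small_study(50, seed = 31)
  ## push every echo record after index so the summary is missing for all
  st$tables@echocardiography$date <-
    max(st$cohort$index_date) + 1000
  co <- labelOutcome(selectCohort(st$tables), st$tables)
  f <- buildFeatures(co, st$tables, featureSchema(missing_indicator = TRUE,
                                                  normalization = "none"))
  expect_true(all(is.na(co$echo_EF)))
  expect_identical(unname(unique(f$patient[, "echo_EF"])), 0)  # median fallback
  expect_true(all(f$patient[, "echo_EF_missing"] == 1))
})

test_that("diagnosis indicator row sums equal a distinct-code table scan", {
  st <- study_features(n = 150, seed = 19)
  d <- st$features$diagnosis
  dx <- emrTable(st$tables, "diagnosis")
  for (pid in sample(st$cohort$patient_id, 20)) {
    idx <- st$cohort$index_date[st$cohort$patient_id == pid]
    rows <- dx[dx$patient_id == pid & dx$diagnosis_date <= idx, ]
    expect_identical(unname(sum(d[pid, ])),
                     as.numeric(length(unique(substr(rows$icd10_code,
                                                     1, 3)))))
  }
})

test_that("per-patient mode yields 2N nodes, N edges, outcomes conserved", {
  st <- study_features(n = 60, seed = 3)
  bg <- buildBipartite(st$cohort, st$features)
  n <- nrow(st$cohort)
  expect_identical(nNodes(bg), 2L * n)
  expect_identical(nEdges(bg), n)
  expect_identical(sort(edgeTable(bg)$outcome), sort(st$cohort$outcome))
  expect_true(validObject(bg))
  ## raw patient and diagnosis ids coincide; prefixes keep them distinct
  expect_identical(sub("^p_", "", edgeTable(bg)$source),
                   sub("^d_", "", edgeTable(bg)$target))
})

test_that("shared mode collapses identical profiles and stays bipartite", {
  st <- study_features(n = 80, seed = 13)
  bg <- buildBipartite(st$cohort, st$features, mode = "shared_diagnosis")
  expect_lte(nrow(nodeFeatures(bg, "diagnosis")),
             nrow(nodeFeatures(bg, "patient")))
  expect_identical(nEdges(bg), nrow(st$cohort))
  expect_true(validObject(bg))
})

test_that("flattening concatenates to width 159 in aligned patient order", {
  st <- study_features(n = 40, seed = 21)
  bg <- buildBipartite(st$cohort, st$features)
  flat <- flattenForBaselines(bg)
  expect_identical(ncol(flat$features), 159L)
  expect_identical(rownames(flat$features), st$cohort$patient_id)
  expect_identical(flat$labels, st$cohort$outcome)
  one <- buildBipartite(st$cohort[1, , drop = FALSE],
                        local({
                          f <- st$features
                          f$patient <- f$patient[1, , drop = FALSE]
                          f$diagnosis <- f$diagnosis[1, , drop = FALSE]
                          f
                        }))
  expect_identical(dim(flattenForBaselines(one)$features), c(1L, 159L))
})

test_that("construction is deterministic and row-order independent", {
  st <- study_features(n = 70, seed = 29)
  bg1 <- buildBipartite(st$cohort, st$features)
  shuffled <- st$tables
  set.seed(2)
  for (tb in c("diagnosis", "laboratory")) {
    df <- slot(shuffled, tb)
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    rownames(df) <- NULL
    slot(shuffled, tb) <- df
  }
  co2 <- labelOutcome(selectCohort(shuffled), shuffled)
  bg2 <- buildBipartite(co2, buildFeatures(co2, shuffled))
  expect_equal(nodeFeatures(bg1, "patient"), nodeFeatures(bg2, "patient"))
  expect_equal(nodeFeatures(bg1, "diagnosis"),
               nodeFeatures(bg2, "diagnosis"))
  expect_identical(edgeTable(bg1), edgeTable(bg2))
})

test_that("schema errors name the missing source column", {
  st <- small_study(30, seed = 1)
  expect_error(buildFeatures(st$cohort, st$tables,
                             featureSchema(patient_features = c(
                               "age_at_index", "no_such_column"))),
               "no_such_column")
})
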