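## two patients sharing one diagnosis node, plus a spare, for sampler tests
tiny_bg <- function() {
  pf <- matrix(c(1, 0, 0, 1, 2, 2), 3, 2, byrow = TRUE,
               dimnames = list(c("p_a", "p_b", "p_c"), NULL))
  df <- matrix(c(2, 5, -1, 0, 0, 3), 3, 2, byrow = TRUE,
               dimnames = list(c("d_x", "d_y", "d_z"), NULL))
  edges <- data.frame(
    source = c("p_a", "p_a", "p_a", "p_a", "p_a", "p_b"),
    target = c("d_x", "d_y", "d_z", "d_x", "d_y", "d_x"),
    outcome = c(1, 0, 1, 0, 1, 0), stringsAsFactors = FALSE)
  new("BipartiteGraph", patientFeatures = pf, diagnosisFeatures = df,
      edges = edges, mode = "shared_diagnosis")
}

test_that("sampling respects degree, replacement and exhaustive mode", {
  bg <- tiny_bg()
  s <- sampleNeighbors(bg, "p_a", samplerConfig(c(2L, 1L), seed = 1))
  expect_length(s[[1]][["p_a"]], 2)
  expect_true(all(s[[1]][["p_a"]] %in% c("d_x", "d_y", "d_z")))

  s1 <- sampleNeighbors(bg, "p_b", samplerConfig(c(3L, 1L), seed = 1))
  expect_identical(s1[[1]][["p_b"]], rep("d_x", 3))  # with replacement

  ex <- sampleNeighbors(bg, "p_a", samplerConfig(c(2L, 2L), seed = 1,
                                                 exhaustive = TRUE))
  expect_setequal(ex[[1]][["p_a"]], c("d_x", "d_y", "d_z"))

  iso <- sampleNeighbors(bg, "p_c", samplerConfig(c(2L, 1L), seed = 1))
  expect_length(iso[[1]][["p_c"]], 0)  # zero-feature sentinel, no error

  expect_error(sampleNeighbors(bg, "p_nope"), "unknown seed node")
  same1 <- sampleNeighbors(bg, "p_a", samplerConfig(c(2L, 2L), seed = 9))
  same2 <- sampleNeighbors(bg, "p_a", samplerConfig(c(2L, 2L), seed = 9))
  expect_identical(same1, same2)
})

test_that("a hand-computed two-layer forward pass matches", {
  ## one patient (x_p = [1, 0]) linked to one diagnosis (x_d = [2, 5]):
  ## with every weight matrix the 1x2 ones-row and zero biases each layer
  ## halves are sums, so the arithmetic is checkable by hand
  pf <- matrix(c(1, 0), 1, 2, dimnames = list("p_a", NULL))
  df <- matrix(c(2, 5), 1, 2, dimnames = list("d_x", NULL))
  bg <- new("BipartiteGraph", patientFeatures = pf, diagnosisFeatures = df,
            edges = data.frame(source = "p_a", target = "d_x", outcome = 1),
            mode = "per_patient")
  ones <- matrix(1, 1, 2)
  par <- list(layers = list(
    list(patient = list(W_self = ones, W_neigh = ones, b = c(0, 0)),
         diagnosis = list(W_self = ones, W_neigh = ones, b = c(0, 0))),
    list(patient = list(W_self = ones, W_neigh = ones, b = c(0, 0)),
         diagnosis = list(W_self = ones, W_neigh = ones, b = c(0, 0)))),
    head = list(w = matrix(1, 4, 1), b = 0, operator = "concat"),
    dims = list(patient = 2, diagnosis = 2), hidden = c(2L, 2L))
  ## layer 1: h1(p) = relu([1+0, 2+5]) = [1, 7]; h1(d) = [7, 1]
  ## layer 2: z(p) = [1+7, 7+1] = [8, 8] -> normalized [1, 1]/sqrt(2)
  z <- hinsageForward(par, bg, c("p_a", "d_x"))
  expect_equal(unname(z["p_a", ]), c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(z["d_x", ]), c(1, 1) / sqrt(2), tolerance = 1e-12)

  ## zero weights: all embeddings zero before (and after) normalization
  zpar <- par
  for (k in 1:2) for (t in c("patient", "diagnosis"))
    zpar$layers[[k]][[t]] <- list(W_self = 0 * ones, W_neigh = 0 * ones,
                                  b = c(0, 0))
  expect_true(all(hinsageForward(zpar, bg, c("p_a", "d_x")) == 0))
})

test_that("exhaustive forward equals the dense full-neighborhood oracle", {
  worst <- 0
  for (seed in 1:100) {
    bg <- random_bipartite(seed)
    view <- emrgraph:::.bg_view(bg)
    set.seed(seed + 1000)
    par <- initHinsageParams(list(patient = ncol(view$Xp),
                                  diagnosis = ncol(view$Xd)),
                             hidden = c(4L, 6L))
    nodes <- c(rownames(view$Xp), rownames(view$Xd))
    z <- hinsageForward(par, bg, nodes)
    zo <- rbind(
      dense_hinsage(par, view$Xp, view$Xd, view$p2d, view$d2p,
                    seq_len(nrow(view$Xp)), "patient"),
      dense_hinsage(par, view$Xp, view$Xd, view$p2d, view$d2p,
                    seq_len(nrow(view$Xd)), "diagnosis"))
    worst <- max(worst, max(abs(unname(z) - unname(zo))))
  }
  expect_lt(worst, 1e-6)
})

test_that("link head is logistic with the documented identities", {
  h <- list(w = rep(0, 6), b = 0)
  expect_equal(linkScore(rnorm(3), rnorm(3), h, "concat"), 0.5)
  h2 <- list(w = rep(1, 3), b = 0.7)
  expect_equal(linkScore(rep(0, 3), rnorm(3), h2, "hadamard"),
               plogis(0.7))
  ## monotone: scaling the aligned embedding up raises the score
  z <- c(1, 2, 3)
  s1 <- linkScore(z, z, h2, "hadamard")
  s2 <- linkScore(2 * z, z, h2, "hadamard")
  expect_gt(s2, s1)
  expect_error(linkScore(rnorm(3), rnorm(4), h2, "hadamard"), "shape")
})

test_that("training records a full history and is seed-deterministic", {
  st <- small_study(250, seed = 15)
  bg <- buildBipartite(st$cohort, buildFeatures(st$cohort, st$tables))
  m1 <- trainLinkModel(bg, config = trainConfig(epochs = 4, seed = 7))
  h <- trainHistory(m1)
  expect_identical(nrow(h), 4L)
  expect_named(h, c("epoch", "loss", "accuracy", "val_loss",
                    "val_accuracy"))
  expect_true(all(is.finite(as.matrix(h))))
  m2 <- trainLinkModel(bg, config = trainConfig(epochs = 4, seed = 7))
  expect_identical(trainHistory(m1), trainHistory(m2))
  ## disjoint split enforced, single-class labels warn
  expect_error(trainLinkModel(bg, train_idx = 1:10, val_idx = 5:20),
               "disjoint")
  ones <- which(edgeTable(bg)$outcome == 0)[1:30]
  expect_warning(trainLinkModel(bg, train_idx = ones[1:20],
                                val_idx = ones[21:30],
                                config = trainConfig(epochs = 1)),
                 "single-class")
})

test_that("loss is non-increasing over the first steps at a small rate", {
  st <- small_study(150, seed = 33)
  bg <- buildBipartite(st$cohort, buildFeatures(st$cohort, st$tables))
  view <- emrgraph:::.bg_view(bg)
  set.seed(4)
  par <- initHinsageParams(list(patient = 12, diagnosis = 147))
  trainable <- list(layers = par$layers,
                    head = list(w = par$head$w, b = par$head$b))
  m <- emrgraph:::.zero_like(trainable)
  v <- emrgraph:::.zero_like(trainable)
  batch <- seq_len(min(32, nEdges(bg)))
  losses <- numeric(10)
  for (s in 1:10) {
    res <- emrgraph:::.hs_batch(par, view, batch, c(8L, 4L), TRUE)
    losses[s] <- res$loss
    g <- list(layers = res$grads$layers,
              head = list(w = res$grads$head$w, b = res$grads$head$b))
    upd <- emrgraph:::.adam_rec(trainable, g, m, v, 1e-4, s)
    trainable <- upd$p; m <- upd$m; v <- upd$v
    par$layers <- trainable$layers
    par$head$w <- trainable$head$w
    par$head$b <- trainable$head$b
  }
  expect_true(all(diff(losses) <= 1e-10))
})

test_that("a linearly separable outcome is learned to high accuracy", {
  st <- small_study(2500, seed = 41)
  f <- buildFeatures(st$cohort, st$tables)
  co <- st$cohort
  co$outcome <- as.integer(f$patient[, "age_at_index"] > 0)  # z-scored
  bg <- buildBipartite(co, f)
  ## logistic-regression oracle confirms separability on the same data
  lr <- glmnet::glmnet(f$patient, co$outcome, family = "binomial",
                       alpha = 0, lambda = 1e-4)
  p_lr <- drop(predict(lr, f$patient, type = "response"))
  expect_gte(auroc(co$outcome, p_lr), 0.99)
  ## the L2-normalized embedding bounds the attainable logit sharpness, so
  ## the separable rule is recovered as a strong ranking rather than a
  ## near-perfect 0.5-threshold classification
  m <- trainLinkModel(bg, config = trainConfig(epochs = 40, seed = 2,
                                               learning_rate = 1e-2))
  expect_gte(tail(trainHistory(m)$accuracy, 1), 0.85)
  tr <- m@train$train_idx
  p_tr <- predictLinks(m, bg, tr)
  expect_gte(auroc(edgeTable(bg)$outcome[tr], p_tr), 0.90)
})

test_that("predictions are probabilities, deterministic, oracle-consistent", {
  bg <- tiny_bg()
  view <- emrgraph:::.bg_view(bg)
  set.seed(6)
  par <- initHinsageParams(list(patient = 2, diagnosis = 2),
                           hidden = c(4L, 4L))
  ex <- samplerConfig(c(2L, 2L), seed = 3, exhaustive = TRUE)
  p1 <- predictLinks(par, bg, sampler = ex)
  p2 <- predictLinks(par, bg, sampler = ex)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  ## dense oracle forward + link head reproduces the probabilities
  zs <- dense_hinsage(par, view$Xp, view$Xd, view$p2d, view$d2p,
                      view$src, "patient")
  zd <- dense_hinsage(par, view$Xp, view$Xd, view$p2d, view$d2p,
                      view$dst, "diagnosis")
  oracle <- plogis(drop(cbind(zs, zd) %*% par$head$w) + par$head$b)
  expect_lt(max(abs(p1 - oracle)), 1e-6)
  ## zero-weight head scores 0.5 everywhere
  par0 <- par
  par0$head$w[] <- 0; par0$head$b <- 0
  expect_equal(predictLinks(par0, bg, sampler = ex), rep(0.5, nEdges(bg)))
})

test_that("a model survives the portable text archive round trip", {
  st <- small_study(120, seed = 51)
  bg <- buildBipartite(st$cohort, buildFeatures(st$cohort, st$tables))
  m <- trainLinkModel(bg, config = trainConfig(epochs = 2, seed = 5))
  p <- withr::local_tempfile(fileext = ".json")
  saveHinsageModel(m, p)
  m2 <- readHinsageModel(p)
  pr1 <- predictLinks(m, bg)
  pr2 <- predictLinks(m2, bg)
  expect_equal(pr1, pr2, tolerance = 1e-12)
  expect_equal(trainHistory(m)$loss, trainHistory(m2)$loss)
})
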