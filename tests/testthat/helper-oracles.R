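## Independent oracles, coded with plain loops so they share nothing with
## the implementation paths they check.

## AUROC by enumerating all positive-negative pairs
pairwise_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## average precision by walking the ranked list threshold by threshold
stepwise_ap <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  ap <- 0
  prev_rec <- 0
  for (t in ths) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / npos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

## dense recursive full-neighborhood HinSAGE aggregator (no sampling)
dense_hinsage <- function(params, Xp, Xd, p2d, d2p, targets, type) {
  relu <- function(x) pmax(x, 0)
  h1 <- function(i, ty) {
    if (ty == "patient") {
      x <- Xp[i, ]; nb <- p2d[[i]]; Xn <- Xd
      W <- params$layers[[1]]$patient
    } else {
      x <- Xd[i, ]; nb <- d2p[[i]]; Xn <- Xp
      W <- params$layers[[1]]$diagnosis
    }
    mn <- if (length(nb)) colMeans(Xn[nb, , drop = FALSE]) else
      rep(0, ncol(Xn))
    relu(c(drop(W$W_self %*% x), drop(W$W_neigh %*% mn)) + W$b)
  }
  other <- if (type == "patient") "diagnosis" else "patient"
  out <- NULL
  for (i in targets) {
    nb <- if (type == "patient") p2d[[i]] else d2p[[i]]
    W <- params$layers[[2]][[type]]
    h_self <- h1(i, type)
    mh <- if (length(nb)) {
      acc <- 0
      for (j in nb) acc <- acc + h1(j, other)
      acc / length(nb)
    } else rep(0, length(h_self))
    z <- c(drop(W$W_self %*% h_self), drop(W$W_neigh %*% mh)) + W$b
    nr <- sqrt(sum(z * z))
    if (nr == 0) nr <- 1
    out <- rbind(out, z / nr)
  }
  out
}

## random small attributed bipartite graph (may contain isolated nodes)
random_bipartite <- function(seed, max_n = 12) {
  set.seed(seed)
  np <- sample(2:max_n, 1)
  nd <- sample(2:max_n, 1)
  dp <- sample(2:4, 1)
  dd <- sample(2:5, 1)
  pf <- matrix(rnorm(np * dp), np,
               dimnames = list(paste0("p_", seq_len(np)), NULL))
  df <- matrix(rnorm(nd * dd), nd,
               dimnames = list(paste0("d_", seq_len(nd)), NULL))
  ne <- sample(1:(2 * max_n), 1)
  edges <- unique(data.frame(
    source = rownames(pf)[sample.int(np, ne, replace = TRUE)],
    target = rownames(df)[sample.int(nd, ne, replace = TRUE)],
    stringsAsFactors = FALSE))
  edges$outcome <- sample(0:1, nrow(edges), replace = TRUE)
  new("BipartiteGraph", patientFeatures = pf, diagnosisFeatures = df,
      edges = edges, mode = "shared_diagnosis")
}

## small labelled cohort + tables from the generator, shared across tests
small_study <- function(n = 300, seed = 42, ...) {
  emr <- generateEmr(generatorConfig(n_patients = n, seed = seed, ...))
  cohort <- labelOutcome(selectCohort(emr), emr)
  list(tables = emr, cohort = cohort)
}

## generator configuration with a deliberately strong, recoverable feature
## signal (the injected-signal study condition)
signal_config <- function(n, seed) {
  generatorConfig(n_patients = n, seed = seed, age_effect = 0.12,
                  feature_effects = c(lab_blood = 2.5, echo_EF = -2.5,
                                      phys_SBP = 1.5))
}
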