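#' Neighbor sampler configuration
#'
#' @param num_samples per-layer neighbor sample counts (two layers).
#' @param seed integer seed making the sampling deterministic.
#' @param exhaustive if `TRUE`, return the full neighbor multiset of every
#'   node instead of sampling (used by the dense-oracle tests).
#' @return list of class `samplerConfig`.
#' @export
samplerConfig <- function(num_samples = c(8L, 4L), seed = 42L,
                          exhaustive = FALSE) {
  if (length(num_samples) != 2 || any(num_samples < 1))
    stop("num_samples must give two per-layer counts >= 1")
  structure(list(num_samples = as.integer(num_samples),
                 seed = as.integer(seed), exhaustive = exhaustive),
            class = "samplerConfig")
}

#' Training configuration of the link-attribute model
#'
#' @param epochs number of training epochs (>= 1).
#' @param batch_size minibatch size in edges.
#' @param learning_rate Adam step size.
#' @param split train fraction of the stratified edge split, in (0, 1).
#' @param hidden two hidden layer sizes (even, default 32 and 32).
#' @param operator link head combination, `"concat"` or `"hadamard"`.
#' @param seed seed controlling init, shuffling and sampling.
#' @return list of class `trainConfig`.
#' @export
trainConfig <- function(epochs = 30L, batch_size = 200L,
                        learning_rate = 5e-3, split = 0.8,
                        hidden = c(32L, 32L),
                        operator = c("concat", "hadamard"), seed = 42L) {
  operator <- match.arg(operator)
  if (epochs < 1) stop("epochs must be >= 1")
  if (split <= 0 || split >= 1) stop("split must lie in (0, 1)")
  if (length(hidden) != 2 || any(hidden %% 2 != 0))
    stop("hidden must give two even layer sizes")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, split = split,
                 hidden = as.integer(hidden), operator = operator,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

## ---- internal graph view ------------------------------------------------

.bg_view <- function(graph) {
  pf <- graph@patientFeatures
  df <- graph@diagnosisFeatures
  src <- match(graph@edges$source, rownames(pf))
  dst <- match(graph@edges$target, rownames(df))
  p2d <- split(dst, factor(src, levels = seq_len(nrow(pf))))
  d2p <- split(src, factor(dst, levels = seq_len(nrow(df))))
  list(Xp = pf, Xd = df, src = src, dst = dst,
       p2d = unname(p2d), d2p = unname(d2p),
       y = graph@edges$outcome)
}

.sample_nbrs <- function(adj, nodes, s, exhaustive) {
  lapply(adj[nodes], function(nb) {
    k <- length(nb)
    if (k == 0L) integer(0)
    else if (exhaustive) nb
    else if (k >= s) nb[sample.int(k, s)]
    else nb[sample.int(k, s, replace = TRUE)]
  })
}

## two-hop sampled tree for targets of one partition
.build_tree <- function(view, targets, self = c("patient", "diagnosis"),
                        ns, exhaustive) {
  self <- match.arg(self)
  a1 <- if (self == "patient") view$p2d else view$d2p
  a2 <- if (self == "patient") view$d2p else view$p2d
  n1 <- .sample_nbrs(a1, targets, ns[1], exhaustive)
  n2 <- .sample_nbrs(a2, unlist(n1, use.names = FALSE), ns[2], exhaustive)
  list(targets = targets, n1 = n1, n2 = n2, self = self)
}

.group_mean <- function(X, g, n) {
  out <- matrix(0, n, ncol(X))
  if (length(g)) {
    cnt <- tabulate(g, n)
    s <- rowsum(X, g)
    ug <- sort(unique(g))
    out[ug, ] <- s / cnt[ug]
  }
  out
}

.relu <- function(x) x * (x > 0)

.l2norm_rows <- function(z) {
  nr <- sqrt(rowSums(z * z))
  nr[nr == 0] <- 1
  nr
}

## forward pass over one tree; returns embeddings + cache for backprop
.hs_forward_tree <- function(params, view, tree) {
  self <- tree$self
  other <- if (self == "patient") "diagnosis" else "patient"
  Xs <- if (self == "patient") view$Xp else view$Xd
  Xo <- if (self == "patient") view$Xd else view$Xp
  B <- length(tree$targets)
  l1 <- lengths(tree$n1)
  g1 <- rep.int(seq_len(B), l1)
  i1 <- unlist(tree$n1, use.names = FALSE)
  n1tot <- length(i1)
  g2 <- rep.int(seq_len(n1tot), lengths(tree$n2))
  i2 <- unlist(tree$n2, use.names = FALSE)

  X0t <- Xs[tree$targets, , drop = FALSE]
  X01 <- Xo[i1, , drop = FALSE]
  X02 <- if (length(i2)) Xs[i2, , drop = FALSE] else
    matrix(0, 0, ncol(Xs))

  W1o <- params$layers[[1]][[other]]
  M2 <- .group_mean(X02, g2, n1tot)
  A1o <- cbind(X01 %*% t(W1o$W_self), M2 %*% t(W1o$W_neigh))
  A1o <- sweep(A1o, 2, W1o$b, "+")
  H1o <- .relu(A1o)

  W1s <- params$layers[[1]][[self]]
  M1x <- .group_mean(X01, g1, B)
  A1s <- cbind(X0t %*% t(W1s$W_self), M1x %*% t(W1s$W_neigh))
  A1s <- sweep(A1s, 2, W1s$b, "+")
  H1s <- .relu(A1s)

  W2 <- params$layers[[2]][[self]]
  M1h <- .group_mean(H1o, g1, B)
  Z <- cbind(H1s %*% t(W2$W_self), M1h %*% t(W2$W_neigh))
  Z <- sweep(Z, 2, W2$b, "+")
  nr <- .l2norm_rows(Z)
  list(z = Z / nr, cache = list(self = self, other = other, B = B,
                                g1 = g1, g2 = g2, cnt1 = tabulate(g1, B),
                                X0t = X0t, X01 = X01, M2 = M2, M1x = M1x,
                                A1o = A1o, H1o = H1o, A1s = A1s, H1s = H1s,
                                M1h = M1h, Z = Z, nr = nr))
}

## gradient of one tree given dL/dz (normalized embedding); accumulates
## into a grads structure shaped like params$layers
.hs_backward_tree <- function(params, grads, cache, dz) {
  self <- cache$self; other <- cache$other
  h2h <- ncol(params$layers[[2]][[self]]$W_self)  # = hidden1
  h2a <- nrow(params$layers[[2]][[self]]$W_self)
  ## through row L2 normalization
  zn <- cache$Z / cache$nr
  dZ <- (dz - zn * rowSums(zn * dz)) / cache$nr

  W2 <- params$layers[[2]][[self]]
  dSelf <- dZ[, seq_len(h2a), drop = FALSE]
  dNeigh <- dZ[, h2a + seq_len(h2a), drop = FALSE]
  grads$layers[[2]][[self]]$W_self <-
    grads$layers[[2]][[self]]$W_self + t(dSelf) %*% cache$H1s
  grads$layers[[2]][[self]]$W_neigh <-
    grads$layers[[2]][[self]]$W_neigh + t(dNeigh) %*% cache$M1h
  grads$layers[[2]][[self]]$b <-
    grads$layers[[2]][[self]]$b + colSums(dZ)
  dH1s <- dSelf %*% W2$W_self
  dM1h <- dNeigh %*% W2$W_neigh

  ## layer-1 target-type block
  dA1s <- dH1s * (cache$A1s > 0)
  h1a <- nrow(params$layers[[1]][[self]]$W_self)
  grads$layers[[1]][[self]]$W_self <-
    grads$layers[[1]][[self]]$W_self +
    t(dA1s[, seq_len(h1a), drop = FALSE]) %*% cache$X0t
  grads$layers[[1]][[self]]$W_neigh <-
    grads$layers[[1]][[self]]$W_neigh +
    t(dA1s[, h1a + seq_len(h1a), drop = FALSE]) %*% cache$M1x
  grads$layers[[1]][[self]]$b <-
    grads$layers[[1]][[self]]$b + colSums(dA1s)

  ## layer-1 neighbor-type block, reached through the hop-1 mean
  if (length(cache$g1)) {
    cnt <- cache$cnt1[cache$g1]
    dH1o <- dM1h[cache$g1, , drop = FALSE] / cnt
    dA1o <- dH1o * (cache$A1o > 0)
    h1b <- nrow(params$layers[[1]][[other]]$W_self)
    grads$layers[[1]][[other]]$W_self <-
      grads$layers[[1]][[other]]$W_self +
      t(dA1o[, seq_len(h1b), drop = FALSE]) %*% cache$X01
    grads$layers[[1]][[other]]$W_neigh <-
      grads$layers[[1]][[other]]$W_neigh +
      t(dA1o[, h1b + seq_len(h1b), drop = FALSE]) %*% cache$M2
    grads$layers[[1]][[other]]$b <-
      grads$layers[[1]][[other]]$b + colSums(dA1o)
  }
  grads
}

## ---- parameters ---------------------------------------------------------

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize HinSAGE parameters
#'
#' Glorot-uniform per-layer, per-node-type self and neighbor weight
#' matrices with zero biases, plus the logistic link head.  Each layer's
#' output is the concatenation of the self and neighbor halves, so hidden
#' sizes must be even; both partitions map to a common final embedding
#' size.
#'
#' @param dims named list/vector with input feature widths `patient` and
#'   `diagnosis`.
#' @param hidden two even hidden sizes (default 32, 32).
#' @param operator link head combination (`"concat"` or `"hadamard"`).
#' @return nested parameter list (layers, head, dims, hidden).
#' @export
initHinsageParams <- function(dims, hidden = c(32L, 32L),
                              operator = c("concat", "hadamard")) {
  operator <- match.arg(operator)
  if (any(hidden %% 2 != 0)) stop("hidden sizes must be even")
  dp <- dims[["patient"]]; dd <- dims[["diagnosis"]]
  h1 <- hidden[1]; h2 <- hidden[2]
  layers <- list(
    list(patient = list(W_self = .glorot(h1 / 2, dp),
                        W_neigh = .glorot(h1 / 2, dd),
                        b = numeric(h1)),
         diagnosis = list(W_self = .glorot(h1 / 2, dd),
                          W_neigh = .glorot(h1 / 2, dp),
                          b = numeric(h1))),
    list(patient = list(W_self = .glorot(h2 / 2, h1),
                        W_neigh = .glorot(h2 / 2, h1),
                        b = numeric(h2)),
         diagnosis = list(W_self = .glorot(h2 / 2, h1),
                          W_neigh = .glorot(h2 / 2, h1),
                          b = numeric(h2))))
  we <- if (operator == "concat") 2L * h2 else h2
  list(layers = layers,
       head = list(w = .glorot(we, 1), b = 0, operator = operator),
       dims = list(patient = dp, diagnosis = dd), hidden = hidden)
}

#' Sample layered neighborhoods
#'
#' For each layer, every frontier node contributes exactly
#' `num_samples[k]` neighbor ids: uniformly without replacement when its
#' degree allows, with replacement when the degree is smaller, or the full
#' neighbor multiset in exhaustive mode.  An isolated node yields the
#' zero-feature sentinel (an empty sample), never an error.
#'
#' @param graph a [BipartiteGraph].
#' @param seed_nodes character vector of prefixed node ids.
#' @param config a [samplerConfig()].
#' @return list with one element per layer; each element is a list, one
#'   character vector of sampled neighbor ids per parent node in the
#'   flattened order of the previous layer.
#' @export
sampleNeighbors <- function(graph, seed_nodes, config = samplerConfig()) {
  stopifnot(is(graph, "BipartiteGraph"))
  view <- .bg_view(graph)
  ids <- c(rownames(view$Xp), rownames(view$Xd))
  if (!all(seed_nodes %in% ids)) stop("unknown seed node")
  set.seed(config$seed)
  adj_ids <- function(nodes) {
    lapply(nodes, function(nd) {
      if (startsWith(nd, "p_")) {
        i <- match(nd, rownames(view$Xp))
        rownames(view$Xd)[view$p2d[[i]]]
      } else {
        i <- match(nd, rownames(view$Xd))
        rownames(view$Xp)[view$d2p[[i]]]
      }
    })
  }
  frontier <- seed_nodes
  out <- vector("list", length(config$num_samples))
  for (k in seq_along(config$num_samples)) {
    nb <- adj_ids(frontier)
    s <- config$num_samples[k]
    out[[k]] <- lapply(nb, function(v) {
      m <- length(v)
      if (m == 0L) character(0)
      else if (config$exhaustive) v
      else if (m >= s) v[sample.int(m, s)]
      else v[sample.int(m, s, replace = TRUE)]
    })
    names(out[[k]]) <- frontier
    frontier <- unlist(out[[k]], use.names = FALSE)
  }
  out
}

#' HinSAGE forward pass
#'
#' Layer rule: the new representation of a node is the concatenation of a
#' self term and a neighbor term,
#' `h_v = act(W_self h_v^(k-1) || W_neigh mean(h_u^(k-1)) + b)` with
#' type-specific weights, ReLU on the hidden layer, a linear final layer,
#' and row-wise L2 normalization of the final embeddings.  `h^(0)` are the
#' raw node features; an empty neighborhood contributes a zero vector.
#'
#' @param params parameters from [initHinsageParams()] or a trained
#'   [HinsageModel]'s `params`.
#' @param graph a [BipartiteGraph].
#' @param nodes prefixed node ids to embed.
#' @param sampler a [samplerConfig()]; the default embeds over the full
#'   neighborhood (exhaustive).
#' @return numeric matrix of L2-normalized embeddings, rownames `nodes`.
#' @export
hinsageForward <- function(params, graph, nodes,
                           sampler = samplerConfig(exhaustive = TRUE)) {
  stopifnot(is(graph, "BipartiteGraph"))
  view <- .bg_view(graph)
  set.seed(sampler$seed)
  is_p <- startsWith(nodes, "p_")
  h2 <- params$hidden[2]
  out <- matrix(0, length(nodes), h2, dimnames = list(nodes, NULL))
  if (any(is_p)) {
    idx <- match(nodes[is_p], rownames(view$Xp))
    if (anyNA(idx)) stop("unknown patient node")
    tr <- .build_tree(view, idx, "patient", sampler$num_samples,
                      sampler$exhaustive)
    out[is_p, ] <- .hs_forward_tree(params, view, tr)$z
  }
  if (any(!is_p)) {
    idx <- match(nodes[!is_p], rownames(view$Xd))
    if (anyNA(idx)) stop("unknown diagnosis node")
    tr <- .build_tree(view, idx, "diagnosis", sampler$num_samples,
                      sampler$exhaustive)
    out[!is_p, ] <- .hs_forward_tree(params, view, tr)$z
  }
  out
}

#' Logistic link head
#'
#' Combines two endpoint embeddings with concatenation or the Hadamard
#' product and maps the result through a logistic unit.
#'
#' @param z_src,z_dst embedding vectors or row-aligned matrices.
#' @param head list with weight vector `w` and bias `b` (and optionally
#'   `operator`, overridden by the argument).
#' @param operator `"concat"` or `"hadamard"`.
#' @return probabilities in (0, 1).
#' @export
linkScore <- function(z_src, z_dst, head,
                      operator = head$operator %||% "concat") {
  if (is.null(dim(z_src))) z_src <- matrix(z_src, 1)
  if (is.null(dim(z_dst))) z_dst <- matrix(z_dst, 1)
  if (!identical(dim(z_src), dim(z_dst)))
    stop("embedding shapes differ")
  e <- switch(operator,
              concat = cbind(z_src, z_dst),
              hadamard = z_src * z_dst,
              stop("unknown operator: ", operator))
  drop(plogis(e %*% matrix(head$w, ncol = 1) + head$b))
}

## ---- loss / optimizer ---------------------------------------------------

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

.zero_like <- function(x) {
  if (is.numeric(x)) x * 0
  else if (is.list(x)) lapply(x, .zero_like)
  else x
}

.adam_rec <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  if (is.numeric(p)) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  } else if (is.list(p)) {
    for (nm in names(p)) {
      r <- .adam_rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    list(p = p, m = m, v = v)
  } else list(p = p, m = m, v = v)
}

## forward + (optionally) backward over a batch of edges; returns scores,
## loss and parameter gradients
.hs_batch <- function(params, view, edge_idx, ns, exhaustive,
                      with_grads = TRUE) {
  y <- view$y[edge_idx]
  tp <- .build_tree(view, view$src[edge_idx], "patient", ns, exhaustive)
  td <- .build_tree(view, view$dst[edge_idx], "diagnosis", ns, exhaustive)
  fp <- .hs_forward_tree(params, view, tp)
  fd <- .hs_forward_tree(params, view, td)
  zp <- fp$z; zd <- fd$z
  op <- params$head$operator
  e <- if (op == "concat") cbind(zp, zd) else zp * zd
  logit <- drop(e %*% params$head$w) + params$head$b
  p <- plogis(logit)
  loss <- .bce(p, y)
  if (!with_grads)
    return(list(p = p, loss = loss, y = y))
  B <- length(y)
  dlogit <- (p - y) / B
  grads <- list(layers = .zero_like(params$layers),
                head = list(w = t(e) %*% dlogit, b = sum(dlogit),
                            operator = NULL))
  de <- outer(dlogit, drop(params$head$w))
  h2 <- ncol(zp)
  if (op == "concat") {
    dzp <- de[, seq_len(h2), drop = FALSE]
    dzd <- de[, h2 + seq_len(h2), drop = FALSE]
  } else {
    dzp <- de * zd
    dzd <- de * zp
  }
  grads <- .hs_backward_tree(params, grads, fp$cache, dzp)
  grads <- .hs_backward_tree(params, grads, fd$cache, dzd)
  list(p = p, loss = loss, y = y, grads = grads)
}

.stratified_split <- function(y, split) {
  train <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    k <- max(1L, round(split * length(idx)))
    if (k >= length(idx) && length(idx) > 1) k <- length(idx) - 1L
    train <- c(train, idx[seq_len(k)])
  }
  sort(train)
}

#' Train the HinSAGE link-attribute model
#'
#' Minimizes the binary cross-entropy of [linkScore()] applied to the
#' two-layer HinSAGE embeddings of each edge's endpoints against the edge
#' outcomes, by minibatch Adam over a stratified train/validation edge
#' split.  Fully seeded: initialization, shuffling and neighbor sampling
#' all derive from `config$seed`.
#'
#' @param graph a [BipartiteGraph] with outcome-labelled edges.
#' @param train_idx,val_idx optional disjoint integer indices into the
#'   edge table; `NULL` draws a stratified split with fraction
#'   `config$split`.
#' @param sampler a [samplerConfig()].
#' @param config a [trainConfig()].
#' @return A [HinsageModel] with per-epoch history (training and
#'   validation loss and accuracy at the 0.5 threshold).
#' @export
trainLinkModel <- function(graph, train_idx = NULL, val_idx = NULL,
                           sampler = samplerConfig(),
                           config = trainConfig()) {
  stopifnot(is(graph, "BipartiteGraph"))
  view <- .bg_view(graph)
  n <- length(view$y)
  if (n < 2) stop("need at least two edges to train")
  set.seed(config$seed)
  if (is.null(train_idx)) {
    train_idx <- .stratified_split(view$y, config$split)
    val_idx <- setdiff(seq_len(n), train_idx)
  } else if (is.null(val_idx)) {
    val_idx <- setdiff(seq_len(n), train_idx)
  }
  if (length(intersect(train_idx, val_idx)))
    stop("train and validation edge sets must be disjoint")
  if (length(unique(view$y[train_idx])) < 2)
    warning("training labels are single-class; proceeding")

  params <- initHinsageParams(
    dims = list(patient = ncol(view$Xp), diagnosis = ncol(view$Xd)),
    hidden = config$hidden, operator = config$operator)
  trainable <- list(layers = params$layers,
                    head = list(w = params$head$w, b = params$head$b))
  m <- .zero_like(trainable); v <- .zero_like(trainable)
  step <- 0L
  ns <- sampler$num_samples

  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- train_idx[sample.int(length(train_idx))]
    starts <- seq(1L, length(ord), by = config$batch_size)
    ep_loss <- 0; ep_acc <- 0; nb <- 0L
    for (st in starts) {
      batch <- ord[st:min(st + config$batch_size - 1L, length(ord))]
      res <- .hs_batch(params, view, batch, ns, sampler$exhaustive)
      step <- step + 1L
      g <- list(layers = res$grads$layers,
                head = list(w = res$grads$head$w, b = res$grads$head$b))
      upd <- .adam_rec(trainable, g, m, v, config$learning_rate, step)
      trainable <- upd$p; m <- upd$m; v <- upd$v
      params$layers <- trainable$layers
      params$head$w <- trainable$head$w
      params$head$b <- trainable$head$b
      w <- length(batch)
      ep_loss <- ep_loss + res$loss * w
      ep_acc <- ep_acc + sum((res$p > 0.5) == res$y)
      nb <- nb + w
    }
    if (length(val_idx)) {
      vres <- .hs_batch(params, view, val_idx, ns, sampler$exhaustive,
                        with_grads = FALSE)
      vl <- vres$loss; va <- mean((vres$p > 0.5) == vres$y)
    } else {
      vl <- NA_real_; va <- NA_real_
    }
    hist[[ep]] <- data.frame(epoch = ep, loss = ep_loss / nb,
                             accuracy = ep_acc / nb, val_loss = vl,
                             val_accuracy = va)
  }
  new("HinsageModel", params = params, sampler = unclass(sampler),
      train = c(unclass(config),
                list(train_idx = train_idx, val_idx = val_idx)),
      history = do.call(rbind, hist))
}

#' Predict link-attribute probabilities
#'
#' One probability per requested edge, deterministic given the sampler
#' seed.
#'
#' @param model a trained [HinsageModel] (or its bare parameter list).
#' @param graph the [BipartiteGraph] to predict on.
#' @param edge_idx integer indices into the edge table (default all).
#' @param sampler a [samplerConfig()]; defaults to the model's.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictLinks <- function(model, graph, edge_idx = NULL, sampler = NULL) {
  params <- if (is(model, "HinsageModel")) model@params else model
  if (is.null(sampler))
    sampler <- if (is(model, "HinsageModel"))
      do.call(samplerConfig, model@sampler[c("num_samples", "seed",
                                             "exhaustive")])
    else samplerConfig()
  view <- .bg_view(graph)
  if (is.null(edge_idx)) edge_idx <- seq_along(view$y)
  if (any(edge_idx < 1 | edge_idx > length(view$y)))
    stop("edge index out of range")
  set.seed(sampler$seed)
  out <- numeric(length(edge_idx))
  starts <- seq(1L, length(edge_idx), by = 2000L)
  for (st in starts) {
    sel <- edge_idx[st:min(st + 1999L, length(edge_idx))]
    out[st:(st + length(sel) - 1L)] <-
      .hs_batch(params, view, sel, sampler$num_samples,
                sampler$exhaustive, with_grads = FALSE)$p
  }
  out
}

#' Save / load a trained model as a portable text archive
#'
#' Weight arrays are stored flattened with their shapes in a single JSON
#' manifest together with the sampler/training configuration and history.
#'
#' @param model a [HinsageModel].
#' @param path JSON file path.
#' @return `saveHinsageModel` returns `path` invisibly;
#'   `readHinsageModel` the restored [HinsageModel].
#' @export
saveHinsageModel <- function(model, path) {
  stopifnot(is(model, "HinsageModel"))
  enc <- function(x) {
    if (is.matrix(x)) list(.dim = dim(x), .data = as.vector(x))
    else if (is.list(x)) lapply(x, enc)
    else x
  }
  obj <- list(params = enc(model@params), sampler = model@sampler,
              train = model@train, history = model@history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname saveHinsageModel
#' @export
readHinsageModel <- function(path) {
  obj <- jsonlite::read_json(path)
  dec <- function(x) {
    if (!is.list(x)) return(x)
    if (!is.null(x[[".dim"]]))
      return(matrix(as.numeric(unlist(x$.data)),
                    unlist(x$.dim)[1], unlist(x$.dim)[2]))
    if (length(x) && is.null(names(x)) &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1,
                   logical(1))))
      return(unlist(x))
    lapply(x, dec)
  }
  params <- dec(obj$params)
  hist <- do.call(rbind, lapply(obj$history, as.data.frame))
  new("HinsageModel", params = params, sampler = dec(obj$sampler),
      train = dec(obj$train), history = hist)
}
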