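#' Area under the ROC curve
#'
#' Mann--Whitney formulation: the probability that a random positive
#' outscores a random negative, with ties counted one half.
#'
#' @param labels 0/1 vector with at least one positive and one negative.
#' @param scores finite numeric scores, same length.
#' @return value in \[0, 1\].
#' @examples
#' auroc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))  # 0.75
#' @export
auroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0)
    stop("AUROC undefined for single-class labels")
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision--recall curve (average precision)
#'
#' Step-wise integral of precision over recall across the distinct score
#' thresholds.
#'
#' @inheritParams auroc
#' @return value in (0, 1].
#' @export
auprc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  npos <- sum(labels == 1)
  if (npos == 0) stop("AUPRC undefined without positives")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)  # threshold boundaries
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples positives and negatives separately with replacement (so no
#' resample can lose a class) and returns the percentile interval of the
#' metric; deterministic given the seed.
#'
#' @param metric function of `(labels, scores)`, e.g. [auroc()].
#' @param labels,scores as in [auroc()].
#' @param n_boot number of bootstrap resamples.
#' @param alpha two-sided miscoverage (0.05 gives a 95% interval).
#' @param seed RNG seed.
#' @return numeric `c(lower, upper)`.
#' @export
bootstrapCI <- function(metric, labels, scores, n_boot = 1000L,
                        alpha = 0.05, seed = 1L) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  set.seed(seed)
  vals <- vapply(seq_len(n_boot), function(i) {
    idx <- c(pos[sample.int(length(pos), replace = TRUE)],
             neg[sample.int(length(neg), replace = TRUE)])
    metric(labels[idx], scores[idx])
  }, numeric(1))
  unname(quantile(vals, c(alpha / 2, 1 - alpha / 2)))
}

#' ROC curve points
#'
#' @inheritParams auroc
#' @return data.frame with `fpr`, `tpr`, starting at (0,0) and ending at
#'   (1,1).
#' @export
rocCurve <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(s, fromLast = TRUE)
  data.frame(fpr = c(0, fp[last] / max(sum(y == 0), 1), 1),
             tpr = c(0, tp[last] / max(sum(y == 1), 1), 1))
}

## ---- plain two-hidden-layer MLP (ANN baseline), Adam + BCE -------------

.mlp_train <- function(x, y, hidden = c(32L, 32L), epochs = 30L,
                       batch_size = 200L, lr = 1e-3, seed = 1L) {
  set.seed(seed)
  d <- ncol(x)
  W1 <- .glorot(hidden[1], d);  b1 <- numeric(hidden[1])
  W2 <- .glorot(hidden[2], hidden[1]); b2 <- numeric(hidden[2])
  W3 <- .glorot(1, hidden[2]); b3 <- 0
  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, W3 = W3, b3 = b3)
  m <- .zero_like(pars); v <- .zero_like(pars); step <- 0L
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (st in seq(1L, n, by = batch_size)) {
      sel <- ord[st:min(st + batch_size - 1L, n)]
      xb <- x[sel, , drop = FALSE]; yb <- y[sel]
      a1 <- sweep(xb %*% t(pars$W1), 2, pars$b1, "+"); h1 <- .relu(a1)
      a2 <- sweep(h1 %*% t(pars$W2), 2, pars$b2, "+"); h2 <- .relu(a2)
      p <- plogis(drop(h2 %*% t(pars$W3)) + pars$b3)
      dlg <- (p - yb) / length(yb)
      g <- list(W3 = t(dlg) %*% h2, b3 = sum(dlg))
      dh2 <- outer(dlg, drop(pars$W3)) * (a2 > 0)
      g$W2 <- t(dh2) %*% h1; g$b2 <- colSums(dh2)
      dh1 <- dh2 %*% pars$W2 * (a1 > 0)
      g$W1 <- t(dh1) %*% xb; g$b1 <- colSums(dh1)
      step <- step + 1L
      upd <- .adam_rec(pars, g[names(pars)], m, v, lr, step)
      pars <- upd$p; m <- upd$m; v <- upd$v
    }
  }
  structure(pars, class = "emrMlp")
}

.mlp_predict <- function(pars, x) {
  h1 <- .relu(sweep(x %*% t(pars$W1), 2, pars$b1, "+"))
  h2 <- .relu(sweep(h1 %*% t(pars$W2), 2, pars$b2, "+"))
  plogis(drop(h2 %*% t(pars$W3)) + pars$b3)
}

#' Tabular baseline models on the flattened features
#'
#' Fits a random forest (500 trees), an L2-regularized logistic regression
#' and a two-hidden-layer (32, 32, ReLU) neural network on identical
#' features, split and seed, and returns their held-out probability
#' scores.
#'
#' @param features numeric matrix (e.g. from [flattenForBaselines()]).
#' @param labels 0/1 vector.
#' @param train_idx,test_idx row indices of the split (the same split used
#'   for the graph model).
#' @param seed RNG seed shared by all three fits.
#' @param rf_trees number of random-forest trees.
#' @param ann_epochs training epochs of the neural-network baseline.
#' @return list with per-model held-out `scores` (named list `RF`, `LR`,
#'   `ANN`) and the held-out `labels`.
#' @export
runBaselines <- function(features, labels, train_idx, test_idx,
                         seed = 42L, rf_trees = 500L, ann_epochs = 30L) {
  if (length(unique(labels[train_idx])) < 2)
    stop("degenerate single-class training split")
  xtr <- features[train_idx, , drop = FALSE]
  ytr <- labels[train_idx]
  xte <- features[test_idx, , drop = FALSE]

  set.seed(seed)
  rf <- randomForest::randomForest(x = xtr, y = factor(ytr,
                                                       levels = c(0, 1)),
                                   ntree = rf_trees)
  rf_scores <- predict(rf, xte, type = "prob")[, "1"]

  set.seed(seed)
  lrfit <- glmnet::glmnet(xtr, ytr, family = "binomial", alpha = 0,
                          lambda = 1e-4)
  lr_scores <- drop(predict(lrfit, xte, type = "response"))

  ann <- .mlp_train(xtr, ytr, epochs = ann_epochs, seed = seed)
  ann_scores <- .mlp_predict(ann, xte)

  list(scores = list(RF = unname(rf_scores), LR = unname(lr_scores),
                     ANN = unname(ann_scores)),
       labels = labels[test_idx])
}

#' Model comparison report
#'
#' Computes AUROC and AUPRC with stratified bootstrap 95% confidence
#' intervals for every model's held-out scores, renders the comparison
#' table (CSV + Markdown), and draws the ROC curves and the true/predicted
#' outcome distribution (0.5 threshold) to files.
#'
#' @param scores named list of held-out probability vectors, one per
#'   model.
#' @param labels held-out 0/1 labels shared by all models.
#' @param out_dir output directory for `report.csv`, `report.md`,
#'   `roc_curves.png` and `outcome_distribution.png`; `NULL` skips files.
#' @param n_boot bootstrap resamples for the intervals.
#' @param seed bootstrap seed.
#' @return invisibly, a list with the metrics `table` (data.frame), the
#'   ROC `curves`, and per-model outcome distribution `counts`.
#' @export
compareReport <- function(scores, labels, out_dir = NULL, n_boot = 1000L,
                          seed = 1L) {
  stopifnot(is.list(scores), length(scores) >= 1)
  rows <- lapply(names(scores), function(mod) {
    s <- scores[[mod]]
    ci_roc <- bootstrapCI(auroc, labels, s, n_boot, seed = seed)
    ci_prc <- bootstrapCI(auprc, labels, s, n_boot, seed = seed)
    data.frame(model = mod,
               auroc = auroc(labels, s),
               auroc_lo = ci_roc[1], auroc_hi = ci_roc[2],
               auprc = auprc(labels, s),
               auprc_lo = ci_prc[1], auprc_hi = ci_prc[2],
               n_test = length(s), positives = sum(labels == 1),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  curves <- lapply(scores, function(s) rocCurve(labels, s))
  counts <- lapply(scores, function(s)
    c(pred_0 = sum(s <= 0.5), pred_1 = sum(s > 0.5),
      true_0 = sum(labels == 0), true_1 = sum(labels == 1)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(tab, file.path(out_dir, "report.csv"), row.names = FALSE)
    md <- c("| Model | AUROC (95% CI) | AUPRC (95% CI) |",
            "|---|---|---|",
            sprintf("| %s | %.2f [%.2f, %.2f] | %.2f [%.2f, %.2f] |",
                    tab$model, tab$auroc, tab$auroc_lo, tab$auroc_hi,
                    tab$auprc, tab$auprc_lo, tab$auprc_hi))
    writeLines(md, file.path(out_dir, "report.md"))

    grDevices::png(file.path(out_dir, "roc_curves.png"), width = 640,
                   height = 640)
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                   xlab = "False positive rate (1 - specificity)",
                   ylab = "True positive rate (sensitivity)",
                   main = "ROC curves of comparison models")
    for (i in seq_along(curves))
      graphics::lines(curves[[i]]$fpr, curves[[i]]$tpr, col = i + 1,
                      lwd = 2)
    graphics::legend("bottomright", legend = names(curves),
                     col = seq_along(curves) + 1, lwd = 2)
    grDevices::dev.off()

    grDevices::png(file.path(out_dir, "outcome_distribution.png"),
                   width = 640, height = 480)
    first <- counts[[1]]
    graphics::barplot(matrix(first, 2, byrow = TRUE,
                             dimnames = list(c("predicted", "true"),
                                             c("0", "1"))),
                      beside = TRUE, legend.text = TRUE,
                      main = sprintf(
                        "True and predicted outcome distribution (%s)",
                        names(counts)[1]),
                      xlab = "outcome", ylab = "count")
    grDevices::dev.off()
  }
  invisible(list(table = tab, curves = curves, counts = counts))
}
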