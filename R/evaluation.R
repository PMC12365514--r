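## Evaluation module: masked 5-fold ranking AUC for link prediction,
## classification metric bundles, cross-validated biomarker screening by
## fold frequency, the final weighted model, and the shared-protein
## sensitivity protocol.

#' Masked k-fold ranking AUC for link prediction
#'
#' Splits the known associations into `k` near-equal folds.  Per fold,
#' the test positives are masked to zero in the association matrix, the
#' GIP kernels are recomputed on the masked matrix (sequence similarity
#' does not depend on it), the heterogeneous network is rebuilt, the
#' layer-attention GCN is retrained, and the held-out positives are
#' ranked among all candidate pairs (every pair that is not a training
#' positive).  The ROC over rank thresholds gives the fold AUC, computed
#' as the Mann-Whitney statistic of test-positive scores against
#' unknown-pair scores.
#'
#' @param assoc binary association matrix.
#' @param sequences named amino-acid sequences covering the proteins of
#'   `assoc` (same order not required; matched by name).
#' @param k number of folds (default 5).
#' @param seed integer seed driving the fold split and model training.
#' @param alpha1,alpha2 similarity fusion weights.
#' @param rho_prime initial GIP bandwidth.
#' @param psi similarity penalty factor.
#' @param ... further arguments to [lagcn()] (preset, epochs, ...).
#' @return list with `mean_auc`, `fold_auc`, and the fold assignment of
#'   the positive pairs.
#' @export
kfold_link_auc <- function(assoc, sequences, k = 5, seed = 1,
                           alpha1 = 1, alpha2 = 1, rho_prime = 1,
                           psi = 6, ...) {
  assoc <- as_association(assoc)
  if (!all(rownames(assoc) %in% names(sequences)))
    stop("sequences missing for some association proteins", call. = FALSE)
  pos <- which(assoc == 1)
  if (length(pos) < k)
    stop("fewer positive pairs than folds", call. = FALSE)
  ssp <- sequence_similarity(sequences[rownames(assoc)])
  fold <- plain_folds(length(pos), k, seed)
  if (any(tabulate(fold, k) == 0))
    stop("a fold received no test positives; reduce k", call. = FALSE)

  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    test_pos <- pos[fold == f]
    a_tr <- assoc
    a_tr[test_pos] <- 0
    sgp <- gip_kernel(a_tr, rho_prime)
    sgd <- gip_kernel(t(a_tr), rho_prime)
    sp <- fuse_similarity(ssp, sgp, alpha1, alpha2)
    hg <- build_input_graph(build_hetero_network(a_tr, sp, sgd), psi)
    fit <- lagcn(hg, a_tr, seed = derive_seed(seed, f), ...)
    unknown <- which(assoc != 1)
    fold_auc[f] <- rank_auc(fit$scores[test_pos], fit$scores[unknown])
  }
  list(mean_auc = mean(fold_auc), fold_auc = fold_auc, fold = fold)
}

#' Classification metric bundle
#'
#' For two classes: accuracy, F1 of the positive class (the second
#' factor level), and the AUC of the positive-class probability.  For
#' three or more classes: accuracy, support-weighted mean F1, and
#' macro-averaged F1.  With a single-class truth vector the AUC is
#' undefined and reported as `NA`.
#'
#' @param y_true true labels (factor or coercible).
#' @param y_prob probability matrix with one column per class (columns
#'   named by level), or for binary problems optionally a vector of
#'   positive-class probabilities.
#' @return named list of metrics.
#' @export
classification_metrics <- function(y_true, y_prob) {
  y_true <- factor(y_true)
  lev <- levels(y_true)
  if (is.null(dim(y_prob))) {
    stopifnot(length(lev) <= 2)
    y_prob <- cbind(1 - y_prob, y_prob)
    colnames(y_prob) <- lev[seq_len(ncol(y_prob))]
  }
  if (!is.null(colnames(y_prob)) && all(lev %in% colnames(y_prob)))
    y_prob <- y_prob[, lev, drop = FALSE]
  pred <- lev[max.col(as.matrix(y_prob), ties.method = "first")]
  acc <- mean(pred == as.character(y_true))
  f1s <- vapply(lev, function(cl) {
    tp <- sum(pred == cl & y_true == cl)
    fp <- sum(pred == cl & y_true != cl)
    fn <- sum(pred != cl & y_true == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  support <- as.numeric(table(y_true)[lev])
  if (length(lev) <= 2) {
    posl <- lev[length(lev)]
    auc <- if (length(unique(y_true)) < 2) NA_real_ else
      rank_auc(y_prob[y_true == posl, posl],
               y_prob[y_true != posl, posl])
    list(acc = acc, f1 = unname(f1s[posl]), auc = auc)
  } else {
    list(acc = acc,
         f1_weighted = sum(f1s * support) / sum(support),
         f1_macro = mean(f1s))
  }
}

#' Stratified cross-validated accuracy of the GCN classifier
#'
#' Convenience wrapper running the transductive GCN over stratified
#' folds of an expression dataset (weight the dataset first with
#' [feature_weight()] for the weighted pipeline) and pooling test
#' predictions.
#'
#' @param expr an [expression_dataset()].
#' @param k folds (default 5).
#' @param seed integer seed.
#' @param gamma,hidden,lr,epochs GCN settings.
#' @param mode transductive extension mode (`"batch"` or `"single"`).
#' @return list with per-fold `acc`, `mean_acc`, pooled probability
#'   matrix `prob`, pooled `pred`, and the fold assignment.
#' @export
fwgcn_cv <- function(expr, k = 5, seed = 1, gamma = 2, hidden = 64,
                     lr = 0.001, epochs = 400, mode = "batch") {
  stopifnot(inherits(expr, "expression_dataset"))
  y <- expr$labels
  fold <- stratified_folds(y, k, seed)
  prob <- matrix(NA_real_, length(y), nlevels(y),
                 dimnames = list(expr$sample_ids, levels(y)))
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- fwgcn(expr$values[tr, , drop = FALSE], y[tr], gamma = gamma,
                 hidden = hidden, lr = lr, epochs = epochs,
                 seed = derive_seed(seed, f))
    p <- predict(fit, expr$values[!tr, , drop = FALSE], mode = mode)
    prob[!tr, colnames(p)] <- p
    acc[f] <- mean(fit$levels[max.col(p, ties.method = "first")] == as.character(y[!tr]))
  }
  list(acc = acc, mean_acc = mean(acc), prob = prob,
       pred = factor(levels(y)[max.col(prob, ties.method = "first")], levels = levels(y)),
       fold = fold)
}

#' Screen PTM biomarkers by cross-validation frequency
#'
#' Per stratified fold, an unweighted GCN fixes the baseline validation
#' accuracy; then each shared protein in turn has its expression column
#' score-weighted (alone) and the model is retrained with the same seed.
#' A protein whose weighting strictly improves the fold's validation
#' accuracy is recorded for that fold.  Counts are aggregated over the
#' `k` folds and proteins ranked by frequency, ties broken by mean
#' improvement and then ID.
#'
#' @param expr an [expression_dataset()] (unweighted).
#' @param scores potentiality score matrix.
#' @param k,seed CV controls.
#' @param delta,mode weighting parameters.
#' @param gamma,hidden,lr,epochs GCN settings.
#' @return object of class `biomarker_report`: a ranked data frame with
#'   columns `protein`, `count`, `mean_improvement`, plus the per-fold
#'   improvement matrix as attribute `"improvements"`.
#' @export
screen_biomarkers <- function(expr, scores, k = 5, seed = 1,
                              delta = 0.01, mode = "literal",
                              gamma = 2, hidden = 64, lr = 0.001,
                              epochs = 400) {
  stopifnot(inherits(expr, "expression_dataset"))
  shared <- expr$shared_index
  if (length(shared) == 0) {
    rep0 <- structure(data.frame(protein = character(), count = integer(),
                                 mean_improvement = numeric()),
                      class = c("biomarker_report", "data.frame"),
                      empty = TRUE, k = k)
    warning("no shared proteins: screening is empty; the pipeline degrades to the plain GCN")
    return(rep0)
  }
  y <- expr$labels
  fold <- stratified_folds(y, k, seed)
  prot <- expr$protein_ids[shared]
  imp <- matrix(0, length(shared), k, dimnames = list(prot, NULL))
  for (f in seq_len(k)) {
    tr <- fold != f
    sfit <- derive_seed(seed, f)
    val_acc <- function(values) {
      fit <- fwgcn(values[tr, , drop = FALSE], y[tr], gamma = gamma,
                   hidden = hidden, lr = lr, epochs = epochs, seed = sfit)
      p <- predict(fit, values[!tr, , drop = FALSE])
      mean(fit$levels[max.col(p, ties.method = "first")] == as.character(y[!tr]))
    }
    base <- val_acc(expr$values)
    for (j in seq_along(shared)) {
      w <- feature_weight(expr, scores, delta = delta, mode = mode,
                          columns = shared[j])
      imp[j, f] <- val_acc(w$values) - base
    }
  }
  rep <- data.frame(protein = prot,
                    count = as.integer(rowSums(imp > 0)),
                    mean_improvement = rowMeans(imp))
  rep <- rep[order(-rep$count, -rep$mean_improvement, rep$protein), ]
  rownames(rep) <- NULL
  structure(rep, class = c("biomarker_report", "data.frame"),
            improvements = imp, empty = FALSE, k = k)
}

#' @export
print.biomarker_report <- function(x, n = 10, ...) {
  cat(sprintf("Biomarker screen over %d folds: %d shared protein(s), %d with count > 0\n",
              attr(x, "k"), nrow(x), sum(x$count > 0)))
  if (nrow(x)) print.data.frame(utils::head(x, n))
  invisible(x)
}

#' Train the final model weighted by the screened biomarkers
#'
#' Applies score weighting only to the proteins the screen recorded at
#' least `min_count` times, then fits the GCN classifier on the full
#' weighted dataset.
#'
#' @param expr an [expression_dataset()].
#' @param scores potentiality score matrix.
#' @param report a [screen_biomarkers()] result.
#' @param min_count minimum fold frequency for weighting (default 1).
#' @param delta,mode weighting parameters.
#' @param ... further arguments to [fwgcn()].
#' @return a fitted `fwgcn` model; the weighted protein IDs are attached
#'   as attribute `"weighted_proteins"`.
#' @export
final_weighted_model <- function(expr, scores, report, min_count = 1,
                                 delta = 0.01, mode = "literal", ...) {
  stopifnot(inherits(report, "biomarker_report"))
  keep <- report$protein[report$count >= min_count]
  w <- if (length(keep))
    feature_weight(expr, scores, delta = delta, mode = mode, columns = keep)
  else expr
  fit <- fwgcn(w$values, w$labels, ...)
  attr(fit, "weighted_proteins") <- keep
  fit
}

#' Sensitivity of the weighted pipeline to the shared-protein count
#'
#' For each requested size, draws that many shared proteins at random,
#' applies score weighting to them only, and records the mean stratified
#' CV accuracy; size 0 is the unweighted baseline.  A warning is issued
#' when the dataset has 10 or fewer shared proteins, the regime in which
#' weighting gains are unreliable.
#'
#' @param expr an [expression_dataset()].
#' @param scores potentiality score matrix.
#' @param sizes integer vector of shared-subset sizes to test.
#' @param k,seed CV controls.
#' @param delta,mode weighting parameters.
#' @param ... further arguments to the internal GCN.
#' @return data frame with columns `size` and `accuracy`; the unweighted
#'   baseline is attached as attribute `"baseline"`.
#' @export
shared_protein_sensitivity <- function(expr, scores, sizes, k = 5,
                                       seed = 1, delta = 0.01,
                                       mode = "literal", ...) {
  stopifnot(inherits(expr, "expression_dataset"),
            all(sizes >= 0), all(sizes <= length(expr$shared_index)))
  if (length(expr$shared_index) <= 10)
    warning("10 or fewer shared proteins: weighting gains may be unreliable")
  baseline <- mean(.cv_accuracy(expr$values, expr$labels, k = k,
                                seed = seed, ...))
  acc <- vapply(seq_along(sizes), function(i) {
    s <- sizes[i]
    if (s == 0) return(baseline)
    cols <- with_seed(derive_seed(seed, 100 + i),
                      sample(expr$shared_index, s))
    w <- feature_weight(expr, scores, delta = delta, mode = mode,
                        columns = cols)
    mean(.cv_accuracy(w$values, w$labels, k = k, seed = seed, ...))
  }, numeric(1))
  structure(data.frame(size = sizes, accuracy = acc), baseline = baseline)
}
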