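## Feature-weighted GCN classification: potentiality-score weighting of
## shared protein-expression features, a thresholded cosine-similarity
## sample graph, and a transductive GCN subtype classifier trained by
## full-batch Adam on softmax cross-entropy.

#' Construct an expression dataset
#'
#' Bundles a sample x protein abundance matrix with subtype labels, the
#' index of "shared" proteins (those also present in the association
#' data, the only ones eligible for score weighting), and the disease
#' term of the association table this dataset maps to.
#'
#' @param values numeric matrix, samples in rows, proteins in columns,
#'   with dimnames.
#' @param labels subtype label per sample (factor or coercible).
#' @param shared character vector of shared protein IDs (or integer
#'   column indices).
#' @param disease_key disease ID in the association vocabulary.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, labels, shared = character(),
                               disease_key = NA_character_) {
  values <- as.matrix(values)
  check_finite(values, "expression values")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("P", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  labels <- factor(labels)
  stopifnot(length(labels) == nrow(values))
  shared_index <- if (is.numeric(shared)) as.integer(shared)
                  else match(shared, colnames(values))
  if (anyNA(shared_index) || any(shared_index < 1) ||
      any(shared_index > ncol(values)))
    stop("shared proteins must be columns of the expression matrix",
         call. = FALSE)
  structure(list(values = values, labels = labels,
                 sample_ids = rownames(values),
                 protein_ids = colnames(values),
                 shared_index = sort(unique(shared_index)),
                 disease_key = disease_key),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d samples x %d proteins, %d subtypes\n",
              nrow(x$values), ncol(x$values), nlevels(x$labels)))
  cat(sprintf("  shared proteins: %d (disease key: %s)\n",
              length(x$shared_index), x$disease_key))
  print(table(x$labels))
  invisible(x)
}

#' Weight expression features by PTM potentiality scores
#'
#' For each shared protein `i` with score `a_i` for the mapped disease,
#' every abundance value `p` becomes `2 * p * a_i * exp(delta * |p|)`
#' (mode `"literal"`), so a score above 0.5 amplifies the protein and a
#' score below 0.5 attenuates it; at `a = 0.5, delta = 0` the map is the
#' identity.  Mode `"shrink"` uses `exp(-delta * |p|)` instead.
#' Non-shared columns pass through unchanged.
#'
#' @param expr an [expression_dataset()].
#' @param scores protein x disease score matrix with dimnames covering
#'   the shared proteins and `expr$disease_key`.
#' @param delta non-negative regularization coefficient.
#' @param mode `"literal"` (default) or `"shrink"`.
#' @param columns protein IDs (or column indices) to weight; defaults to
#'   all shared proteins.  Must be a subset of the shared set.
#' @return the weighted `expression_dataset`.
#' @export
feature_weight <- function(expr, scores, delta = 0.01,
                           mode = c("literal", "shrink"),
                           columns = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expression_dataset"))
  if (delta < 0) stop("delta must be non-negative", call. = FALSE)
  cols <- if (is.null(columns)) expr$shared_index
          else if (is.numeric(columns)) as.integer(columns)
          else match(columns, expr$protein_ids)
  if (anyNA(cols) || !all(cols %in% expr$shared_index))
    stop("columns to weight must be shared proteins", call. = FALSE)
  if (length(cols) == 0) return(expr)
  if (is.na(expr$disease_key) || !(expr$disease_key %in% colnames(scores)))
    stop(sprintf("disease key '%s' not present in the score matrix",
                 expr$disease_key), call. = FALSE)
  prot <- expr$protein_ids[cols]
  if (!all(prot %in% rownames(scores)))
    stop("missing potentiality scores for shared protein(s): ",
         paste(setdiff(prot, rownames(scores)), collapse = ", "),
         call. = FALSE)
  a <- scores[prot, expr$disease_key]
  p <- expr$values[, cols, drop = FALSE]
  sgn <- if (mode == "literal") 1 else -1
  expr$values[, cols] <- 2 * p * rep(a, each = nrow(p)) *
    exp(sgn * delta * abs(p))
  expr
}

#' The regularization-coefficient search grid
#'
#' The ten candidate values of `delta` scanned by cross-validation.
#' @return numeric vector of length 10.
#' @export
delta_grid <- function() {
  c(0.0001, 0.0003, 0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 1, 3)
}

#' Thresholded cosine-similarity sample graph
#'
#' Computes all pairwise cosine similarities between sample feature
#' vectors, keeps off-diagonal edges whose similarity reaches a
#' threshold `epsilon`, and adds unit self-loops.  `epsilon` is chosen
#' as the largest value among the observed similarities such that the
#' mean number of retained edges per node, counting the self-loop,
#' is at least `gamma`; ties break toward the larger threshold.  If even
#' the smallest observed similarity cannot reach `gamma` (possible when
#' some rows are all-zero), the smallest is used and the achieved mean
#' degree is reported.
#'
#' @param features numeric sample x feature matrix.
#' @param gamma target mean degree, an integer in `[1, n]`.
#' @return object of class `sample_graph`: list with the weighted
#'   adjacency `g_pp`, `epsilon`, `gamma`, and `mean_degree` achieved.
#' @export
cosine_adjacency <- function(features, gamma) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (gamma < 1 || gamma > n)
    stop("gamma must lie in [1, n]", call. = FALSE)
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm == 0
  if (any(zero))
    warning(sum(zero), " all-zero sample row(s): self-loop only")
  xs <- x / ifelse(zero, 1, nrm)
  cosm <- tcrossprod(xs)
  cosm[zero, ] <- 0; cosm[, zero] <- 0
  cosm <- pmin(pmax(cosm, -1), 1)
  diag(cosm) <- 0

  off <- cosm[upper.tri(cosm)]
  # descending scan over the unique cosines via cumulative run counts:
  # mean degree at threshold v[i] is (2 * cum[i] + n) / n
  runs <- rle(sort(off, decreasing = TRUE))
  cum <- cumsum(runs$lengths)
  hit <- which((2 * cum + n) / n >= gamma)
  eps <- if (length(hit)) runs$values[hit[1]]
         else if (length(runs$values)) runs$values[length(runs$values)]
         else Inf
  g <- ifelse(cosm >= eps & cosm != 0, cosm, 0)
  # edges exactly at 0 similarity carry no weight either way
  diag(g) <- 1
  structure(list(g_pp = g, epsilon = eps, gamma = gamma,
                 mean_degree = mean(rowSums(g != 0))),
            class = "sample_graph")
}

#' @export
print.sample_graph <- function(x, ...) {
  cat(sprintf("Cosine sample graph: %d nodes, epsilon = %.4f (gamma = %d), mean degree %.2f\n",
              nrow(x$g_pp), x$epsilon, x$gamma, x$mean_degree))
  invisible(x)
}

#' Fit the GCN subtype classifier
#'
#' Trains a graph convolutional network over the cosine sample graph of
#' the (typically score-weighted) training expression matrix, minimizing
#' the softmax cross-entropy of the training labels by full-batch Adam.
#' Each layer follows the symmetric-normalized propagation rule; hidden
#' layers use ReLU, the output layer a row-wise softmax.
#'
#' @param x numeric sample x feature training matrix.
#' @param y subtype labels (factor or coercible), at least two classes.
#' @param gamma target mean degree of the sample graph (default 2).
#' @param graph optional precomputed [cosine_adjacency()] result for
#'   `x`; built from `x` and `gamma` when missing.
#' @param hidden integer vector of hidden-layer widths (default 64, one
#'   hidden layer before the softmax layer gives the default 2-layer
#'   GCN).
#' @param lr,epochs Adam settings (defaults 0.001, 400).
#' @param seed integer seed for initialization.
#' @param verbose print the loss every 100 steps.
#' @return an object of class `fwgcn` with the trained `weights`, the
#'   training data and graph, `loss_trace`, and `config`.
#' @seealso [predict.fwgcn()] for transductive prediction.
#' @export
fwgcn <- function(x, y, gamma = 2, graph = NULL, hidden = 64,
                  lr = 0.001, epochs = 400, seed = 1, verbose = FALSE) {
  x <- as.matrix(x)
  y <- factor(y)
  check_finite(x, "features")
  if (nlevels(y) < 2)
    stop("training labels contain a single class", call. = FALSE)
  stopifnot(length(y) == nrow(x), lr > 0, epochs >= 1)
  if (is.null(graph)) graph <- cosine_adjacency(x, gamma)
  stopifnot(inherits(graph, "sample_graph"),
            nrow(graph$g_pp) == nrow(x))
  ahat <- normalize_graph(graph$g_pp)
  yi <- as.integer(y)
  C <- nlevels(y)
  dims <- c(ncol(x), hidden, C)

  with_seed(seed, {
    w <- lapply(seq_len(length(dims) - 1), function(l) {
      lim <- sqrt(6 / (dims[l] + dims[l + 1]))
      matrix(stats::runif(dims[l] * dims[l + 1], -lim, lim),
             dims[l], dims[l + 1])
    })
    opt <- .adam_init(list(w = w), lr)
    loss_trace <- numeric(epochs)
    onehot <- diag(C)[yi, , drop = FALSE]
    p1 <- ahat %*% x
    for (ep in seq_len(epochs)) {
      fw <- .gcn_forward(w, x, ahat, p1)
      probs <- fw$probs
      loss <- -mean(log(pmax(probs[cbind(seq_along(yi), yi)], 1e-12)))
      if (!is.finite(loss))
        stop(sprintf("loss diverged at step %d (try a lower lr)", ep),
             call. = FALSE)
      loss_trace[ep] <- loss
      grads <- .gcn_backward(w, fw, ahat, probs, onehot)
      upd <- .adam_update(opt, list(w = w), list(w = grads))
      w <- upd$params$w; opt <- upd$opt
      if (verbose && ep %% 100 == 0)
        cat(sprintf("step %4d  loss %.5f\n", ep, loss))
    }
  })
  fit <- .gcn_forward(w, x, ahat)
  structure(list(weights = w, x_tr = x, y_tr = y, graph = graph,
                 levels = levels(y), loss_trace = loss_trace,
                 fitted_probs = fit$probs,
                 config = list(gamma = graph$gamma, hidden = hidden,
                               lr = lr, epochs = epochs, seed = seed)),
            class = "fwgcn")
}

# Forward through all layers: ReLU hidden, softmax output.  `p1` caches
# ahat %*% x, which is constant across training epochs.
.gcn_forward <- function(w, x, ahat, p1 = NULL) {
  L <- length(w)
  ps <- zs <- hs <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    ps[[l]] <- if (l == 1 && !is.null(p1)) p1 else ahat %*% h
    zs[[l]] <- ps[[l]] %*% w[[l]]
    h <- if (l < L) pmax(zs[[l]], 0) else zs[[l]]
    hs[[l]] <- h
  }
  logits <- zs[[L]]
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  list(ps = ps, zs = zs, hs = hs, probs = e / rowSums(e))
}

.gcn_backward <- function(w, fw, ahat, probs, onehot) {
  L <- length(w)
  n <- nrow(probs)
  d_z <- (probs - onehot) / n
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    grads[[l]] <- crossprod(fw$ps[[l]], d_z)
    if (l > 1) {
      d_h <- ahat %*% (d_z %*% t(w[[l]]))
      d_z <- d_h * (fw$zs[[l - 1]] > 0)
    }
  }
  grads
}

#' Transductive prediction for new samples
#'
#' Inserts the test samples into the sample graph: the cosine adjacency
#' is rebuilt over the union of training and test rows with the same
#' `gamma`, the trained network propagates once with frozen weights, and
#' the softmax rows of the test samples are returned.  Mode `"batch"`
#' (default) extends the graph with all test samples jointly; mode
#' `"single"` inserts them one at a time.
#'
#' @param object a fitted `fwgcn` model.
#' @param newdata numeric matrix of test samples over the same features
#'   (already weighted with the same scores and `delta` as training).
#' @param mode `"batch"` or `"single"`.
#' @param ... unused.
#' @return matrix of class probabilities, one row per test sample,
#'   rows summing to 1, columns named by subtype level.
#' @export
predict.fwgcn <- function(object, newdata, mode = c("batch", "single"), ...) {
  mode <- match.arg(mode)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x_tr))
    stop("feature dimension mismatch between training and test data",
         call. = FALSE)
  one <- function(xte) {
    xall <- rbind(object$x_tr, xte)
    g <- cosine_adjacency(xall, object$graph$gamma)
    ahat <- normalize_graph(g$g_pp)
    probs <- .gcn_forward(object$weights, xall, ahat)$probs
    probs[nrow(object$x_tr) + seq_len(nrow(xte)), , drop = FALSE]
  }
  out <- if (mode == "batch") one(newdata)
         else do.call(rbind, lapply(seq_len(nrow(newdata)),
                                    function(i) one(newdata[i, , drop = FALSE])))
  colnames(out) <- object$levels
  rownames(out) <- rownames(newdata)
  out
}

#' @export
print.fwgcn <- function(x, ...) {
  cat(sprintf("GCN subtype classifier: %d samples x %d features, %d classes\n",
              nrow(x$x_tr), ncol(x$x_tr), length(x$levels)))
  cat(sprintf("  gamma = %d (epsilon %.4f), hidden: %s, lr %g, %d steps\n",
              x$graph$gamma, x$graph$epsilon,
              paste(x$config$hidden, collapse = "-"),
              x$config$lr, x$config$epochs))
  acc <- mean(x$levels[max.col(x$fitted_probs, ties.method = "first")] == as.character(x$y_tr))
  cat(sprintf("  final loss %.5f, training accuracy %.3f\n",
              x$loss_trace[length(x$loss_trace)], acc))
  invisible(x)
}

#' @export
summary.fwgcn <- function(object, ...) {
  print(object)
  cat("\nTraining confusion matrix:\n")
  print(table(truth = object$y_tr,
              predicted = object$levels[max.col(object$fitted_probs, ties.method = "first")]))
  invisible(object)
}

#' @export
plot.fwgcn <- function(x, ...) {
  graphics::plot(x$loss_trace, type = "l", xlab = "training step",
                 ylab = "cross-entropy", ...)
  invisible(x)
}

# Stratified k-fold CV accuracy of the (optionally pre-weighted)
# expression matrix under the transductive GCN; shared engine for delta
# and gamma selection, the ablation property, and biomarker screening.
.cv_accuracy <- function(values, labels, k = 5, seed = 1, gamma = 2,
                         hidden = 64, lr = 0.001, epochs = 400,
                         mode = "batch") {
  fold <- stratified_folds(labels, k, seed)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- fwgcn(values[tr, , drop = FALSE], labels[tr], gamma = gamma,
                 hidden = hidden, lr = lr, epochs = epochs,
                 seed = derive_seed(seed, f))
    probs <- predict(fit, values[!tr, , drop = FALSE], mode = mode)
    pred <- fit$levels[max.col(probs, ties.method = "first")]
    acc[f] <- mean(pred == as.character(labels[!tr]))
  }
  acc
}

#' Select the regularization coefficient by cross-validation
#'
#' Scans the `delta` grid, scoring each value by the mean stratified
#' 5-fold accuracy of the weighted pipeline on the training data, and
#' returns the maximizer (ties break toward the smaller `delta`).
#'
#' @param expr an [expression_dataset()].
#' @param scores potentiality score matrix.
#' @param grid candidate values (default [delta_grid()]).
#' @param folds number of internal folds (default 5).
#' @param seed integer seed.
#' @param mode weighting mode passed to [feature_weight()].
#' @param ... further arguments to the internal GCN (gamma, hidden, lr,
#'   epochs).
#' @return the selected `delta` (with the accuracy profile as attribute
#'   `"profile"`).
#' @export
select_delta <- function(expr, scores, grid = delta_grid(), folds = 5,
                         seed = 1, mode = "literal", ...) {
  stopifnot(length(grid) >= 1)
  prof <- vapply(grid, function(d) {
    w <- feature_weight(expr, scores, delta = d, mode = mode)
    mean(.cv_accuracy(w$values, w$labels, k = folds, seed = seed, ...))
  }, numeric(1))
  structure(grid[which.max(prof)], profile = stats::setNames(prof, grid))
}

#' Select the sample-graph mean degree by cross-validation
#'
#' Evaluates each candidate `gamma` by internal stratified CV accuracy
#' on the training data and returns the best (ties toward smaller).
#'
#' @param x feature matrix (already weighted if weighting is used).
#' @param y labels.
#' @param candidates candidate mean degrees (default `c(2, 5, 10)`).
#' @param folds,seed CV controls.
#' @param ... further arguments to the internal GCN.
#' @return the selected `gamma` with the accuracy profile attached.
#' @export
select_gamma <- function(x, y, candidates = c(2, 5, 10), folds = 5,
                         seed = 1, ...) {
  prof <- vapply(candidates, function(g)
    mean(.cv_accuracy(as.matrix(x), factor(y), k = folds, seed = seed,
                      gamma = g, ...)), numeric(1))
  structure(candidates[which.max(prof)],
            profile = stats::setNames(prof, candidates))
}
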