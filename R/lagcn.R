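## Layer-attention GCN link predictor: graph convolution over the
## penalized heterogeneous network, learned attention over layer
## outputs, bilinear decoding to PTM potentiality scores, and training
## by full-batch Adam on a class-weighted cross-entropy.  Gradients are
## derived analytically; the graphs involved are small and dense.

#' Single graph-convolution layer
#'
#' Propagation rule `H' = act(D^{-1/2} G D^{-1/2} H W)` with
#' `D = diag(rowSums(G))`.
#'
#' @param h node embedding matrix (nodes x features).
#' @param g non-negative graph matrix (nodes square).
#' @param w weight matrix (features x out-features).
#' @param activation `"relu"` (default) or `"identity"`.
#' @return the propagated embedding matrix.
#' @export
gcn_layer <- function(h, g, w, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  check_finite(h, "embeddings"); check_finite(g, "graph")
  check_finite(w, "weights")
  if (any(g < 0)) stop("graph matrix must be non-negative", call. = FALSE)
  z <- normalize_graph(g) %*% h %*% w
  if (activation == "relu") pmax(z, 0) else z
}

#' Attention-weighted combination of layer outputs
#'
#' Weighted sum `sum_l theta_l H^(l)` over the hidden-layer embeddings,
#' split into the protein rows and the disease rows.  In a fresh model
#' the weights are initialized to `1/(l+1)` for layers `l = 1..L`.
#'
#' @param embeddings list of L node-embedding matrices, all the same
#'   shape.
#' @param theta numeric vector of L attention scalars.
#' @param n_p number of protein nodes (the leading rows).
#' @return list with elements `h_p` and `h_d`.
#' @export
layer_attention <- function(embeddings, theta, n_p) {
  if (length(embeddings) != length(theta))
    stop("number of embeddings and attention weights differ", call. = FALSE)
  h <- Reduce(`+`, Map(`*`, theta, embeddings))
  list(h_p = h[seq_len(n_p), , drop = FALSE],
       h_d = h[-seq_len(n_p), , drop = FALSE])
}

#' Bilinear decoder
#'
#' Reconstructs the score matrix `sigmoid(H_p W' H_d^T)`; every entry is
#' a probability-like PTM potentiality score strictly inside (0, 1).
#'
#' @param h_p,h_d protein and disease embeddings (rows) in a common
#'   latent dimension.
#' @param w_prime square decoder matrix in that dimension.
#' @return `n_p x n_d` score matrix.
#' @export
bilinear_decode <- function(h_p, h_d, w_prime) {
  stopifnot(ncol(h_p) == nrow(w_prime), ncol(h_d) == ncol(w_prime))
  plogis(h_p %*% w_prime %*% t(h_d))
}

#' Class-weighted cross-entropy over all protein-disease pairs
#'
#' `L = -(1/(P*D)) * ((|T-|/|T+|) * sum_{T+} log s + sum_{T-} log(1-s))`,
#' the imbalance-weighted loss used to train the link predictor.  Scores
#' exactly at 0 or 1 are clamped to `[eps, 1-eps]` (reported via
#' `message()`).
#'
#' @param scores score matrix in (0, 1).
#' @param positives,negatives integer vectors of linear indices into
#'   `scores`; together they must cover every pair exactly once.
#' @param eps clamp bound, default 1e-7.
#' @return non-negative scalar loss.
#' @export
weighted_ce_loss <- function(scores, positives, negatives, eps = 1e-7) {
  npair <- length(scores)
  if (length(positives) == 0) stop("empty positive set", call. = FALSE)
  if (length(positives) + length(negatives) != npair ||
      anyDuplicated(c(positives, negatives)))
    stop("positives and negatives must partition all pairs", call. = FALSE)
  s <- scores[c(positives, negatives)]
  if (any(s <= 0 | s >= 1)) {
    message("clamping ", sum(s <= 0 | s >= 1), " boundary score(s)")
    s <- pmin(pmax(s, eps), 1 - eps)
  }
  w <- length(negatives) / length(positives)
  sp <- s[seq_along(positives)]
  sn <- s[-seq_along(positives)]
  -(w * sum(log(sp)) + sum(log1p(-sn))) / npair
}

#' Fit the layer-attention GCN link predictor
#'
#' Trains the full model (layer weights, attention scalars, bilinear
#' decoder) by full-batch Adam on the weighted cross-entropy, with the
#' known associations as positives and every other pair as negative.
#' During training, node embeddings undergo dropout at rate
#' `dropout_node` after each layer and graph edges are dropped at rate
#' `dropout_edge` (both disabled at evaluation time).  The decoded score
#' matrix is computed once more without dropout after the final step.
#'
#' Two named presets carry the learning-rate / step-count profiles used
#' for link-prediction experiments: `"grid"` (lr 0.01, 800 steps, the
#' cross-validated optimum) and `"text"` (lr 0.001, 400 steps).  Explicit
#' `lr` / `epochs` arguments override the preset.
#'
#' @param hetero a `hetero_graph` with the input graph built (see
#'   [build_input_graph()]); if `g_pd` is absent it is built with
#'   `psi`.
#' @param assoc the binary association matrix aligned with `hetero`.
#' @param embed_dim latent dimension k (default 64).
#' @param n_layers number of graph-convolution layers L (default 3).
#' @param preset `"grid"` (default) or `"text"`.
#' @param lr,epochs optimizer settings; default from `preset`.
#' @param dropout_node,dropout_edge dropout rates (defaults 0.6, 0.4).
#' @param psi similarity penalty factor used only when the input graph
#'   still has to be built (default 6).
#' @param activation hidden activation, `"relu"` (default).
#' @param seed integer seed controlling initialization and dropout.
#' @param verbose print the loss every 100 steps.
#' @return an object of class `lagcn` with components `scores` (the
#'   decoded potentiality matrix with protein/disease dimnames),
#'   `theta`, `weights`, `w_prime`, `loss_trace`, and `config`.
#' @seealso [predict.lagcn()], [kfold_link_auc()]
#' @export
lagcn <- function(hetero, assoc, embed_dim = 64, n_layers = 3,
                  preset = c("grid", "text"), lr = NULL, epochs = NULL,
                  dropout_node = 0.6, dropout_edge = 0.4, psi = 6,
                  activation = "relu", seed = 1, verbose = FALSE) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
                     grid = list(lr = 0.01, epochs = 800),
                     text = list(lr = 0.001, epochs = 400))
  lr <- lr %||% defaults$lr
  epochs <- as.integer(epochs %||% defaults$epochs)
  stopifnot(embed_dim >= 1, n_layers >= 1, lr > 0, epochs >= 1,
            dropout_node >= 0, dropout_node < 1,
            dropout_edge >= 0, dropout_edge < 1)
  assoc <- as_association(assoc)
  stopifnot(inherits(hetero, "hetero_graph"),
            nrow(assoc) == hetero$n_p, ncol(assoc) == hetero$n_d)
  if (is.null(hetero$g_pd)) hetero <- build_input_graph(hetero, psi)

  n_p <- hetero$n_p; n_d <- hetero$n_d; n <- n_p + n_d
  h0 <- initial_embedding(hetero)
  g <- hetero$g_pd
  positives <- which(assoc == 1)
  negatives <- which(assoc != 1)
  if (length(positives) == 0) stop("no positive associations", call. = FALSE)

  with_seed(seed, {
    params <- .lagcn_init(n, embed_dim, n_layers)
    opt <- .adam_init(params, lr)
    loss_trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      step <- .lagcn_step(params, h0, g, n_p, positives, negatives,
                          dropout_node, dropout_edge, activation)
      if (!is.finite(step$loss))
        stop(sprintf("loss diverged at step %d (try a lower lr)", ep),
             call. = FALSE)
      loss_trace[ep] <- step$loss
      upd <- .adam_update(opt, params, step$grads)
      params <- upd$params; opt <- upd$opt
      if (verbose && ep %% 100 == 0)
        cat(sprintf("step %4d  loss %.5f\n", ep, step$loss))
    }
    scores <- .lagcn_forward(params, h0, g, n_p, activation)$scores
  })
  dimnames(scores) <- dimnames(assoc)

  structure(list(scores = scores, theta = params$theta,
                 weights = params$w, w_prime = params$w_prime,
                 loss_trace = loss_trace,
                 n_p = n_p, n_d = n_d,
                 protein_ids = hetero$protein_ids,
                 disease_ids = hetero$disease_ids,
                 n_positive = length(positives),
                 config = list(embed_dim = embed_dim, n_layers = n_layers,
                               preset = preset, lr = lr, epochs = epochs,
                               dropout_node = dropout_node,
                               dropout_edge = dropout_edge,
                               psi = hetero$psi, activation = activation,
                               seed = seed)),
            class = "lagcn")
}

# Glorot-uniform initialization for the trainable matrices; attention
# scalars start at 1/(l+1).
.lagcn_init <- function(n, k, L) {
  glorot <- function(fi, fo) {
    lim <- sqrt(6 / (fi + fo))
    matrix(stats::runif(fi * fo, -lim, lim), fi, fo)
  }
  w <- vector("list", L)
  w[[1]] <- glorot(n, k)
  if (L > 1) for (l in 2:L) w[[l]] <- glorot(k, k)
  list(w = w, theta = 1 / (seq_len(L) + 1), w_prime = glorot(k, k))
}

# Forward pass without dropout (evaluation mode).
.lagcn_forward <- function(params, h0, g, n_p, activation) {
  ahat <- normalize_graph(g)
  hs <- vector("list", length(params$w))
  h <- h0
  for (l in seq_along(params$w)) {
    z <- ahat %*% h %*% params$w[[l]]
    h <- if (activation == "relu") pmax(z, 0) else z
    hs[[l]] <- h
  }
  att <- layer_attention(hs, params$theta, n_p)
  list(scores = bilinear_decode(att$h_p, att$h_d, params$w_prime),
       hs = hs, att = att)
}

# One training step: stochastic forward (node + edge dropout) and
# analytic gradients of the weighted cross-entropy.
.lagcn_step <- function(params, h0, g, n_p, positives, negatives,
                        phi, omega, activation) {
  n <- nrow(g); L <- length(params$w)
  # symmetric edge dropout (diagonal kept), inverted scaling
  if (omega > 0) {
    keep <- matrix(0, n, n)
    up <- upper.tri(g)
    keep[up] <- stats::rbinom(sum(up), 1, 1 - omega)
    keep <- keep + t(keep); diag(keep) <- 1
    gd <- g * keep / (1 - omega)
    diag(gd) <- diag(g)
  } else gd <- g
  ahat <- normalize_graph(gd)

  zs <- ps <- hs <- masks <- vector("list", L)
  h <- h0
  for (l in seq_len(L)) {
    ps[[l]] <- ahat %*% h                       # cached for the backward pass
    zs[[l]] <- ps[[l]] %*% params$w[[l]]
    a <- if (activation == "relu") pmax(zs[[l]], 0) else zs[[l]]
    if (phi > 0) {
      masks[[l]] <- matrix(stats::rbinom(length(a), 1, 1 - phi),
                           nrow(a), ncol(a)) / (1 - phi)
      h <- a * masks[[l]]
    } else h <- a
    hs[[l]] <- h
  }
  att <- layer_attention(hs, params$theta, n_p)
  m <- att$h_p %*% params$w_prime %*% t(att$h_d)
  s <- plogis(m)
  loss <- weighted_ce_loss(s, positives, negatives)

  npair <- length(s)
  w_pos <- length(negatives) / length(positives)
  gm <- matrix(0, nrow(s), ncol(s))
  gm[positives] <- w_pos * (s[positives] - 1) / npair
  gm[negatives] <- s[negatives] / npair

  g_wp <- crossprod(att$h_p, gm %*% att$h_d)
  d_hp <- gm %*% att$h_d %*% t(params$w_prime)
  d_hd <- crossprod(gm, att$h_p) %*% params$w_prime
  d_hfin <- rbind(d_hp, d_hd)

  g_theta <- numeric(L)
  g_w <- vector("list", L)
  d_h <- vector("list", L)
  for (l in seq_len(L)) {
    g_theta[l] <- sum(d_hfin * hs[[l]])
    d_h[[l]] <- params$theta[l] * d_hfin
  }
  for (l in rev(seq_len(L))) {
    d_a <- if (phi > 0) d_h[[l]] * masks[[l]] else d_h[[l]]
    d_z <- if (activation == "relu") d_a * (zs[[l]] > 0) else d_a
    g_w[[l]] <- crossprod(ps[[l]], d_z)
    if (l > 1)
      d_h[[l - 1]] <- d_h[[l - 1]] + ahat %*% (d_z %*% t(params$w[[l]]))
  }
  list(loss = loss,
       grads = list(w = g_w, theta = g_theta, w_prime = g_wp))
}

## --- Adam over the flat parameter list -------------------------------

.adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- rapply(params, function(p) p * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L, lr = lr,
       beta1 = beta1, beta2 = beta2, eps = eps)
}

.adam_update <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  upd1 <- function(p, g, m, v) {
    m <- opt$beta1 * m + (1 - opt$beta1) * g
    v <- opt$beta2 * v + (1 - opt$beta2) * g^2
    mh <- m / (1 - opt$beta1^opt$t)
    vh <- v / (1 - opt$beta2^opt$t)
    list(p = p - opt$lr * mh / (sqrt(vh) + opt$eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else upd1(p, g, m, v)
  }
  out <- walk(params, grads, opt$m, opt$v)
  opt$m <- out$m; opt$v <- out$v
  list(params = out$p, opt = opt)
}

## --- S3 methods ------------------------------------------------------

#' @export
print.lagcn <- function(x, ...) {
  cat(sprintf("Layer-attention GCN link predictor (%d proteins x %d diseases)\n",
              x$n_p, x$n_d))
  cat(sprintf("  k = %d, L = %d, preset '%s' (lr %g, %d steps), psi = %g\n",
              x$config$embed_dim, x$config$n_layers, x$config$preset,
              x$config$lr, x$config$epochs, x$config$psi))
  cat(sprintf("  final loss %.5f; attention theta: %s\n",
              x$loss_trace[length(x$loss_trace)],
              paste(sprintf("%.3f", x$theta), collapse = ", ")))
  invisible(x)
}

#' @export
summary.lagcn <- function(object, ...) {
  s <- object$scores
  cat("PTM potentiality scores\n")
  print(stats::quantile(s, c(0, 0.25, 0.5, 0.75, 1)))
  cat(sprintf("known positives: %d of %d pairs (density %.4f)\n",
              object$n_positive, length(s), object$n_positive / length(s)))
  invisible(object)
}

#' Decoded PTM potentiality scores
#'
#' Returns the full decoded score matrix, or the scores of specific
#' protein-disease pairs.
#'
#' @param object a fitted `lagcn` model.
#' @param proteins,diseases optional equal-length ID vectors selecting
#'   individual pairs.
#' @param ... unused.
#' @return the score matrix, or a numeric vector of pair scores.
#' @export
predict.lagcn <- function(object, proteins = NULL, diseases = NULL, ...) {
  if (is.null(proteins)) return(object$scores)
  stopifnot(length(proteins) == length(diseases))
  object$scores[cbind(match(proteins, object$protein_ids),
                      match(diseases, object$disease_ids))]
}

#' @export
coef.lagcn <- function(object, ...) {
  list(theta = object$theta, w_prime = object$w_prime)
}

#' @export
plot.lagcn <- function(x, ...) {
  graphics::plot(x$loss_trace, type = "l", xlab = "training step",
                 ylab = "weighted cross-entropy", ...)
  invisible(x)
}
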