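## Heterogeneous network assembly: the block matrix joining
## degree-normalized protein similarity, the association matrix, and
## degree-normalized disease similarity; its penalized input form; and
## the initial node embedding for the layer-attention GCN.

#' Assemble the protein-disease heterogeneous network
#'
#' Builds the `(n_p + n_d)`-node block matrix whose diagonal blocks are
#' the symmetrically degree-normalized similarity matrices
#' `D^{-1/2} S D^{-1/2}` (with `D = diag(rowSums(S))`) and whose
#' off-diagonal blocks are the association matrix and its transpose.
#'
#' @param assoc binary protein x disease association matrix (see
#'   [as_association()]).
#' @param sp fused protein similarity matrix, `n_p` square.
#' @param sd_ disease similarity matrix, `n_d` square (named `sd_` to
#'   avoid masking [stats::sd()]).
#' @return an object of class `hetero_graph`: a list with the block
#'   matrix `a_h`, counts `n_p`, `n_d`, and the ID vocabularies.
#' @export
build_hetero_network <- function(assoc, sp, sd_) {
  assoc <- as_association(assoc)
  n_p <- nrow(assoc); n_d <- ncol(assoc)
  if (!identical(dim(sp), c(n_p, n_p)))
    stop("protein similarity dimension does not match association rows",
         call. = FALSE)
  if (!identical(dim(sd_), c(n_d, n_d)))
    stop("disease similarity dimension does not match association columns",
         call. = FALSE)
  np_block <- .norm_sim_block(sp, rownames(assoc), "protein")
  nd_block <- .norm_sim_block(sd_, colnames(assoc), "disease")
  a_h <- rbind(cbind(np_block, assoc),
               cbind(t(assoc), nd_block))
  ids <- c(rownames(assoc), colnames(assoc))
  dimnames(a_h) <- list(ids, ids)
  structure(list(a_h = a_h, g_pd = NULL, psi = NULL,
                 n_p = n_p, n_d = n_d,
                 protein_ids = rownames(assoc),
                 disease_ids = colnames(assoc)),
            class = "hetero_graph")
}

.norm_sim_block <- function(s, ids, what) {
  s <- unclass_sim(as.matrix(s))
  deg <- rowSums(s)
  if (any(deg <= 0)) {
    bad <- if (!is.null(ids)) ids[which(deg <= 0)] else which(deg <= 0)
    stop(sprintf("zero row sum in %s similarity for: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  d <- 1 / sqrt(deg)
  s * outer(d, d)
}

#' Apply the similarity penalty factor to form the GCN input graph
#'
#' Multiplies both normalized similarity blocks of the heterogeneous
#' network by the factor `psi`, leaving the association blocks
#' untouched.  `psi = 1` returns the network unchanged; the default 6
#' up-weights within-type similarity edges relative to association
#' edges.
#'
#' @param hetero a `hetero_graph` from [build_hetero_network()].
#' @param psi positive penalty factor (default 6).
#' @return the `hetero_graph` with `g_pd` filled in.  Calling this on a
#'   graph whose `g_pd` is already built is an error (the factor must
#'   not compound).
#' @export
build_input_graph <- function(hetero, psi = 6) {
  stopifnot(inherits(hetero, "hetero_graph"))
  if (!is.null(hetero$g_pd))
    stop("input graph already built; penalty factor must not be applied twice",
         call. = FALSE)
  if (psi <= 0) stop("psi must be positive", call. = FALSE)
  n_p <- hetero$n_p; n_d <- hetero$n_d
  g <- hetero$a_h
  ip <- seq_len(n_p); id <- n_p + seq_len(n_d)
  g[ip, ip] <- psi * g[ip, ip]
  g[id, id] <- psi * g[id, id]
  hetero$g_pd <- g
  hetero$psi <- psi
  hetero
}

#' Initial node embedding for the layer-attention GCN
#'
#' Each node's initial feature vector is its row of the heterogeneous
#' block matrix, so the embedding is the `(n_p+n_d)` square matrix `a_h`
#' itself: proteins are described by their similarity and association
#' pattern, diseases symmetrically.
#'
#' @param hetero a `hetero_graph`.
#' @return numeric matrix, one row per node.
#' @export
initial_embedding <- function(hetero) {
  stopifnot(inherits(hetero, "hetero_graph"))
  hetero$a_h
}

# Symmetric degree normalization D^{-1/2} G D^{-1/2} used by every GCN
# layer; row sums are floored to keep isolated nodes finite.
normalize_graph <- function(g, floor = 1e-12) {
  deg <- pmax(rowSums(g), floor)
  d <- 1 / sqrt(deg)
  g * outer(d, d)
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("Protein-disease heterogeneous network: %d proteins + %d diseases\n",
              x$n_p, x$n_d))
  cat(sprintf("  association density: %.4f\n",
              mean(x$a_h[seq_len(x$n_p), x$n_p + seq_len(x$n_d)])))
  if (is.null(x$g_pd)) cat("  input graph: not built\n")
  else cat(sprintf("  input graph: built with psi = %g\n", x$psi))
  invisible(x)
}
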