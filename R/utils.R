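#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Run `code` under `seed`, restoring the caller's RNG state afterwards so
# package functions never clobber user-level reproducibility.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-module sub-seed derived from one top-level seed.
# Keeps every stream below 2^31 - 1.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Probability that a randomly chosen positive score exceeds a randomly
#' chosen negative score, with ties counted 1/2.  This is the area under
#' the ROC curve traced by sweeping a rank threshold, used both for
#' ranking held-out associations among candidate pairs and for binary
#' classification probabilities.
#'
#' @param pos numeric scores of the positive items.
#' @param neg numeric scores of the negative (candidate) items.
#' @return a single number in \[0, 1\].
#' @export
rank_auc <- function(pos, neg) {
  stopifnot(length(pos) > 0, length(neg) > 0)
  r <- rank(c(pos, neg), ties.method = "average")
  np <- length(pos)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

#' Robust feature scaling
#'
#' Centers each column by its median and scales by its interquartile
#' range, the standard preprocessing for reverse-phase protein-array
#' style abundance tables.  Columns with zero IQR are scaled by 1.
#'
#' @param x numeric matrix (samples in rows, features in columns).
#' @return matrix of the same shape.
#' @export
robust_scale <- function(x) {
  x <- as.matrix(x)
  med <- apply(x, 2, stats::median)
  iqr <- apply(x, 2, stats::IQR)
  iqr[iqr < .Machine$double.eps] <- 1
  sweep(sweep(x, 2, med, "-"), 2, iqr, "/")
}

# Stratified k-fold assignment: returns an integer vector of fold ids,
# with class proportions preserved as far as divisibility allows.
stratified_folds <- function(y, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
    fold
  })
}

# Plain k-fold over n items (near-equal parts, sizes differ by <= 1).
plain_folds <- function(n, k, seed = NULL) {
  with_seed(seed, {
    fold <- rep_len(seq_len(k), n)
    fold[sample.int(n)]
  })
}

check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
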