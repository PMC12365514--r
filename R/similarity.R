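## Similarity module: local-alignment sequence similarity, Gaussian
## interaction profile (GIP) kernels, and their additive fusion.

#' Pairwise local-alignment sequence similarity
#'
#' Computes Smith-Waterman local alignments with affine gap penalties for
#' every pair of protein sequences and normalizes the resulting score
#' matrix by its global maximum, so entries lie in \[0, 1\] and the best
#' self-alignment of the highest-scoring sequence equals 1.
#'
#' Gap penalties follow the convention in which the first gapped position
#' costs `gap_open` and each further position `gap_extend` (a gap of
#' length L costs `|gap_open| + (L-1)*|gap_extend|`).  Alignment scores
#' are computed by [Biostrings::pairwiseAlignment()]; only the optimal
#' score per pair is recorded.  Non-standard residues simply never match
#' (the substitution matrix scores them as mismatches, including against
#' themselves).
#'
#' @param sequences named character vector of amino-acid strings (names
#'   are the protein IDs; unnamed input gets `seq1..seqN`).
#' @param match,mismatch,gap_open,gap_extend alignment scoring
#'   parameters; penalties are negative.  Defaults: 2, -1, -0.5, -0.1.
#' @param normalize divide all scores by the global matrix maximum
#'   (default `TRUE`); self-scores are included when locating the
#'   maximum.
#' @return a symmetric similarity matrix with `kind` attribute
#'   `"sequence"` and the sequence names as dimnames.
#' @examples
#' s <- sequence_similarity(c(a = "ACGT", b = "ACGA"), normalize = FALSE)
#' s["a", "a"]  # 8: four matches at +2
#' @export
sequence_similarity <- function(sequences, match = 2, mismatch = -1,
                                gap_open = -0.5, gap_extend = -0.1,
                                normalize = TRUE) {
  sequences <- unlist(sequences)
  n <- length(sequences)
  if (n < 2) stop("need at least two sequences", call. = FALSE)
  ids <- names(sequences) %||% paste0("seq", seq_len(n))
  if (anyDuplicated(ids)) stop("duplicate sequence IDs", call. = FALSE)
  empty <- !nzchar(sequences)
  if (any(empty))
    stop("empty sequence(s): ", paste(ids[empty], collapse = ", "),
         call. = FALSE)
  if (gap_open > 0 || gap_extend > 0 || mismatch > 0)
    stop("mismatch and gap parameters must be penalties (<= 0)",
         call. = FALSE)

  sub <- .substitution_matrix(sequences, match, mismatch)
  # Biostrings charges open + L*extend for a gap of length L; the
  # open + (L-1)*extend convention is reproduced by shifting the open cost.
  g_open <- abs(gap_open) - abs(gap_extend)
  g_ext <- abs(gap_extend)
  if (g_open < 0)
    stop("|gap_open| must be >= |gap_extend|", call. = FALSE)

  aa <- Biostrings::AAStringSet(sequences)
  s <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      aa[i:n], aa[[i]], type = "local", substitutionMatrix = sub,
      gapOpening = g_open, gapExtension = g_ext, scoreOnly = TRUE)
    s[i, i:n] <- sc
    s[i:n, i] <- sc
  }
  if (normalize) {
    mx <- max(s)
    if (mx <= 0)
      stop("all alignment scores are zero; normalization undefined",
           call. = FALSE)
    s <- s / mx
  }
  structure(s, kind = "sequence")
}

# Substitution matrix over every character observed in the input:
# standard residues score `match` against themselves, everything else
# (including a non-standard character against itself) scores `mismatch`.
.substitution_matrix <- function(sequences, match, mismatch) {
  letters_seen <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  alphabet <- union(letters_seen, standard)
  sub <- matrix(mismatch, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(sub)[alphabet %in% standard] <- match
  sub
}

#' Gaussian interaction profile kernel
#'
#' Kernel similarity between interaction profiles: rows of the binary
#' association matrix for proteins, columns for diseases.  The kernel is
#' `K(i, j) = exp(-rho * ||I(i) - I(j)||^2)` with the bandwidth
#' normalized by the mean squared profile norm,
#' `rho = rho_prime / mean(||I(i)||^2)`.
#'
#' @param profiles numeric 0/1 matrix, one profile per row.
#' @param rho_prime initial bandwidth before normalization (default 1).
#' @return symmetric similarity matrix with unit diagonal and `kind`
#'   attribute `"gip"`.
#' @export
gip_kernel <- function(profiles, rho_prime = 1) {
  profiles <- as.matrix(profiles)
  stopifnot(rho_prime > 0)
  check_finite(profiles, "profiles")
  sq <- rowSums(profiles^2)
  mean_norm <- mean(sq)
  if (mean_norm == 0)
    stop("all interaction profiles are zero; GIP bandwidth undefined",
         call. = FALSE)
  rho <- rho_prime / mean_norm
  # ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  k <- exp(-rho * d2)
  k <- (k + t(k)) / 2
  diag(k) <- 1
  dimnames(k) <- list(rownames(profiles), rownames(profiles))
  structure(k, kind = "gip", rho = rho, rho_prime = rho_prime)
}

#' Fuse sequence and GIP protein similarity
#'
#' Elementwise weighted sum `alpha1 * ssp + alpha2 * sgp`; both weights
#' default to 1 so fused entries are bounded by 2.
#'
#' @param ssp,sgp square similarity matrices with identical dimnames.
#' @param alpha1,alpha2 non-negative fusion weights.
#' @return fused similarity matrix, `kind` attribute `"fused"`.
#' @export
fuse_similarity <- function(ssp, sgp, alpha1 = 1, alpha2 = 1) {
  if (!identical(dim(ssp), dim(sgp)))
    stop("similarity matrices have different dimensions", call. = FALSE)
  if (!is.null(rownames(ssp)) && !is.null(rownames(sgp)) &&
      !identical(rownames(ssp), rownames(sgp)))
    stop("similarity matrices have different ID orderings", call. = FALSE)
  structure(alpha1 * unclass_sim(ssp) + alpha2 * unclass_sim(sgp),
            kind = "fused", dimnames = dimnames(ssp))
}

unclass_sim <- function(x) {
  attr(x, "kind") <- NULL
  attr(x, "rho") <- NULL
  attr(x, "rho_prime") <- NULL
  x
}

#' Validate a binary protein-disease association matrix
#'
#' Checks the incidence-matrix invariants (0/1 entries, matching dimname
#' vocabularies, no duplicated IDs) and returns the matrix unchanged.
#'
#' @param a numeric matrix, proteins in rows and diseases in columns,
#'   with dimnames.
#' @return `a`, invisibly validated.
#' @export
as_association <- function(a) {
  a <- as.matrix(a)
  if (!all(a %in% c(0, 1)))
    stop("association matrix entries must be 0/1", call. = FALSE)
  if (is.null(rownames(a)) || is.null(colnames(a)))
    stop("association matrix needs protein and disease IDs as dimnames",
         call. = FALSE)
  if (anyDuplicated(rownames(a)) || anyDuplicated(colnames(a)))
    stop("duplicate protein or disease IDs", call. = FALSE)
  storage.mode(a) <- "double"
  a
}
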