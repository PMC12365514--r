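## Synthetic-data generator: block-structured association matrices,
## motif-sharing sequences, and expression tables with planted subtype
## signal on a designated shared-protein subset.  Every generator is
## bit-reproducible from the spec seed.

#' Specification of a synthetic PTM-disease study
#'
#' Collects all sizes and signal parameters of the generators.  The
#' defaults describe a desk-scale study: a 100 x 40 association matrix
#' with 5 latent protein/disease blocks (within-block density 0.6,
#' background noise 0.02), and an expression cohort of 300 samples over
#' 200 proteins of which 30 are shared with the association data and 15
#' carry subtype signal of 1.5 feature-SD units.
#'
#' @param n_proteins,n_diseases association matrix dimensions.
#' @param n_blocks number of latent co-association blocks.
#' @param within_block_density,noise_density edge probabilities inside /
#'   outside blocks.
#' @param n_samples,n_subtypes expression cohort size and class count.
#' @param n_expr_proteins number of expression features.
#' @param n_shared shared proteins (present in both datasets).
#' @param n_shared_informative shared proteins carrying subtype signal.
#' @param effect_size class mean shift in units of the unit feature SD.
#' @param seq_length length range of the simulated sequences.
#' @param motif_length length of the conserved per-block motif.
#' @param seed integer master seed.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 100, n_diseases = 40, n_blocks = 5,
                           within_block_density = 0.6, noise_density = 0.02,
                           n_samples = 300, n_subtypes = 2,
                           n_expr_proteins = 200, n_shared = 30,
                           n_shared_informative = 15, effect_size = 1.5,
                           seq_length = c(50, 80), motif_length = 12,
                           seed = 1) {
  spec <- list(n_proteins = n_proteins, n_diseases = n_diseases,
               n_blocks = n_blocks,
               within_block_density = within_block_density,
               noise_density = noise_density,
               n_samples = n_samples, n_subtypes = n_subtypes,
               n_expr_proteins = n_expr_proteins, n_shared = n_shared,
               n_shared_informative = n_shared_informative,
               effect_size = effect_size, seq_length = seq_length,
               motif_length = motif_length, seed = seed)
  stopifnot(within_block_density >= 0, within_block_density <= 1,
            noise_density >= 0, noise_density <= 1,
            n_shared_informative <= n_shared,
            n_shared <= min(n_proteins, n_expr_proteins),
            n_blocks >= 1, n_subtypes >= 2)
  structure(spec, class = "synthetic_spec")
}

#' Simulate a block-structured association matrix
#'
#' Proteins and diseases are assigned round-robin to latent blocks;
#' within-block pairs become associations with probability
#' `within_block_density`, all other pairs with `noise_density`.  A draw
#' with zero positives is regenerated with the within-block density
#' doubled (reported via `message()`).
#'
#' @param spec a [synthetic_spec()].
#' @return binary association matrix with protein/disease dimnames and
#'   the block assignments attached as attributes `protein_block` and
#'   `disease_block`.
#' @export
simulate_associations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(derive_seed(spec$seed, 1), {
    pb <- rep_len(seq_len(spec$n_blocks), spec$n_proteins)
    db <- rep_len(seq_len(spec$n_blocks), spec$n_diseases)
    dens <- spec$within_block_density
    repeat {
      within <- outer(pb, db, "==")
      prob <- ifelse(within, dens, spec$noise_density)
      a <- matrix(stats::rbinom(length(prob), 1, prob),
                  spec$n_proteins, spec$n_diseases)
      if (sum(a) > 0) break
      dens <- min(1, max(2 * dens, 0.1))
      message("association draw had zero positives; raising within-block density to ", dens)
    }
    dimnames(a) <- list(paste0("PROT", seq_len(spec$n_proteins)),
                        paste0("DIS", seq_len(spec$n_diseases)))
    structure(a, protein_block = pb, disease_block = db)
  })
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate protein sequences with conserved block motifs
#'
#' Each latent block gets a random conserved motif; each protein's
#' sequence is a uniform random residue string with its block's motif
#' embedded at a random position, so within-block sequence similarity
#' exceeds between-block similarity.
#'
#' @param spec a [synthetic_spec()].
#' @param assoc a [simulate_associations()] matrix (provides the block
#'   assignment and protein IDs).
#' @return named character vector of sequences, with the block motifs
#'   attached as attribute `motifs`.
#' @export
simulate_sequences <- function(spec, assoc) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pb <- attr(assoc, "protein_block")
  stopifnot(!is.null(pb), length(pb) == nrow(assoc))
  with_seed(derive_seed(spec$seed, 2), {
    motifs <- vapply(seq_len(spec$n_blocks), function(b)
      paste(sample(AA20, spec$motif_length, replace = TRUE), collapse = ""),
      character(1))
    seqs <- vapply(seq_len(nrow(assoc)), function(i) {
      len <- sample(spec$seq_length[1]:spec$seq_length[2], 1)
      s <- sample(AA20, len, replace = TRUE)
      pos <- sample.int(len - spec$motif_length + 1, 1)
      s[pos:(pos + spec$motif_length - 1)] <-
        strsplit(motifs[pb[i]], "")[[1]]
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- rownames(assoc)
    structure(seqs, motifs = motifs)
  })
}

#' Simulate ground-truth potentiality scores
#'
#' A realistic score profile for the expression-side disease: the
#' planted informative proteins draw Beta(8, 2) scores (mean 0.8) at the
#' mapped disease, every other protein-disease pair draws Beta(2, 8)
#' (mean 0.2).
#'
#' @param spec a [synthetic_spec()].
#' @param assoc association matrix (provides vocabularies).
#' @param informative protein IDs that carry subtype signal.
#' @param disease_key the mapped disease ID.
#' @return score matrix over the association vocabularies.
#' @export
simulate_truth_scores <- function(spec, assoc, informative,
                                  disease_key = colnames(assoc)[1]) {
  with_seed(derive_seed(spec$seed, 3), {
    s <- matrix(stats::rbeta(length(assoc), 2, 8),
                nrow(assoc), ncol(assoc), dimnames = dimnames(assoc))
    s[informative, disease_key] <- stats::rbeta(length(informative), 8, 2)
    s
  })
}

#' Simulate a subtype-labeled expression dataset
#'
#' Draws `n_samples` samples over `n_expr_proteins` features with
#' near-balanced subtype labels.  A random subset of `n_shared`
#' association proteins appears among the expression columns; the first
#' `n_shared_informative` of them receive subtype-dependent mean shifts
#' of `effect_size` (per-protein random class pattern, unit Gaussian
#' noise), all other features are pure noise.  The matrix is
#' robust-scaled (median/IQR per feature).
#'
#' @param spec a [synthetic_spec()].
#' @param assoc association matrix supplying the shared-protein
#'   vocabulary.
#' @param scores_truth optional score matrix to attach as the truth
#'   (defaults to [simulate_truth_scores()]).
#' @param disease_key mapped disease (default: first disease ID).
#' @return an [expression_dataset()] with attribute `truth`: a list with
#'   `informative`, `shared`, `scores`, and `disease_key`.
#' @export
simulate_expression <- function(spec, assoc, scores_truth = NULL,
                                disease_key = colnames(assoc)[1]) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_samples / spec$n_subtypes < 5)
    stop("a subtype would receive fewer than 5 samples", call. = FALSE)
  with_seed(derive_seed(spec$seed, 4), {
    shared <- sort(sample(rownames(assoc), spec$n_shared))
    informative <- sort(sample(shared, spec$n_shared_informative))
    n_other <- spec$n_expr_proteins - spec$n_shared
    prot <- c(shared, paste0("EXPR", seq_len(n_other)))
    prot <- prot[sample.int(length(prot))]

    C <- spec$n_subtypes
    labels <- sample(rep_len(seq_len(C), spec$n_samples))
    x <- matrix(stats::rnorm(spec$n_samples * length(prot)),
                spec$n_samples, length(prot), dimnames = list(
                  paste0("S", seq_len(spec$n_samples)), prot))
    if (spec$effect_size != 0 && length(informative)) {
      base <- seq_len(C) - (C + 1) / 2
      base <- base / max(abs(base)) / 2        # range +-0.5
      for (p in informative) {
        mu <- spec$effect_size * sample(base)  # random class pattern
        x[, p] <- x[, p] + mu[labels]
      }
    }
    x <- robust_scale(x)
    expr <- expression_dataset(x, paste0("subtype", labels),
                               shared = shared, disease_key = disease_key)
  })
  scores <- scores_truth %||%
    simulate_truth_scores(spec, assoc, informative, disease_key)
  attr(expr, "truth") <- list(informative = informative, shared = shared,
                              scores = scores, disease_key = disease_key)
  expr
}

#' Generate a complete synthetic study
#'
#' Runs all three generators and returns the association matrix, the
#' sequences, the expression dataset, and the truth list in one call.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `assoc`, `sequences`, `expr`, `truth`.
#' @export
simulate_ptm_study <- function(spec = synthetic_spec()) {
  assoc <- simulate_associations(spec)
  sequences <- simulate_sequences(spec, assoc)
  expr <- simulate_expression(spec, assoc)
  list(assoc = assoc, sequences = sequences, expr = expr,
       truth = attr(expr, "truth"))
}
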