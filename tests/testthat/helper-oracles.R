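# Independent oracles used to check the package's numerics.  Each is a
# deliberately naive implementation (loops, enumeration) kept free of
# any package internals.

# Smith-Waterman local alignment with affine gaps, brute-force dynamic
# programming over the three-state recurrence (match/insert-x/insert-y,
# with gap-to-gap transitions allowed at opening cost).  The first
# gapped position costs `open`, each further position `ext`.
sw_oracle <- function(a, b, match = 2, mismatch = -1,
                      open = -0.5, ext = -0.1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1, m + 1)
  Ix <- Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1) for (j in seq_len(m) + 1) {
    s <- if (x[i - 1] == y[j - 1] && x[i - 1] %in% std) match else mismatch
    M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                              Iy[i - 1, j - 1]))
    Ix[i, j] <- max(M[i - 1, j] + open, Ix[i - 1, j] + ext,
                    Iy[i - 1, j] + open)
    Iy[i, j] <- max(M[i, j - 1] + open, Iy[i, j - 1] + ext,
                    Ix[i, j - 1] + open)
    best <- max(best, M[i, j])
  }
  best
}

# Naive double-loop Gaussian interaction profile kernel.
gip_oracle <- function(profiles, rho_prime = 1) {
  n <- nrow(profiles)
  rho <- rho_prime / mean(sapply(seq_len(n),
                                 function(i) sum(profiles[i, ]^2)))
  k <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    k[i, j] <- exp(-rho * sum((profiles[i, ] - profiles[j, ])^2))
  k
}

# Exhaustive threshold scan for the cosine sample graph: tries every
# observed off-diagonal cosine as epsilon, keeps the largest whose mean
# degree (self-loops included) reaches gamma, and materializes the
# resulting adjacency.
cosine_oracle <- function(x, gamma) {
  n <- nrow(x)
  cosm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ni <- sqrt(sum(x[i, ]^2)); nj <- sqrt(sum(x[j, ]^2))
    cosm[i, j] <- if (i == j || ni == 0 || nj == 0) 0 else
      sum(x[i, ] * x[j, ]) / (ni * nj)
  }
  cand <- sort(unique(cosm[row(cosm) != col(cosm)]), decreasing = TRUE)
  eps <- cand[length(cand)]
  for (e in cand) {
    deg <- mean(sapply(seq_len(n), function(i)
      sum(cosm[i, ] >= e & cosm[i, ] != 0) + 1))
    if (deg >= gamma) { eps <- e; break }
  }
  g <- ifelse(cosm >= eps & cosm != 0, cosm, 0)
  diag(g) <- 1
  list(epsilon = eps, g_pp = g)
}

# Mann-Whitney AUC by exhaustive pair comparison.
auc_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Small block fixture shared by several tests.
toy_study <- function(seed = 7, ...) {
  spec <- synthetic_spec(n_proteins = 20, n_diseases = 10, n_blocks = 2,
                         n_samples = 60, n_expr_proteins = 30,
                         n_shared = 8, n_shared_informative = 4,
                         seed = seed, ...)
  simulate_ptm_study(spec)
}

# Evaluate `code` under a temporary seed (restores RNG state).
with_seed_local <- function(seed, code) ptmnet:::with_seed(seed, code)

# Strip similarity attributes so matrices compare structurally.
unclass_attr <- function(x) {
  attributes(x)[setdiff(names(attributes(x)), "dim")] <- NULL
  x
}

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}
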