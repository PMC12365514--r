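make_expr <- function(n = 40, p = 10, shared = c("A1", "A2"), seed = 1,
                      sep = 0) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- c(shared, paste0("N", seq_len(p - length(shared))))
  y <- rep(c("a", "b"), length.out = n)
  x[, 1] <- x[, 1] + ifelse(y == "a", sep / 2, -sep / 2)
  expression_dataset(x, y, shared = shared, disease_key = "D1")
}

toy_scores <- function(vals, diseases = "D1") {
  matrix(vals, length(vals), length(diseases),
         dimnames = list(names(vals), diseases))
}

test_that("feature weighting follows the exponential score map", {
  expr <- make_expr()
  # identity at a = 0.5, delta = 0
  s <- toy_scores(c(A1 = 0.5, A2 = 0.5))
  w <- feature_weight(expr, s, delta = 0)
  expect_equal(w$values, expr$values)
  # worked scalar: p = 1, a = 0.8, delta = 0 -> 1.6
  expr$values[1, "A1"] <- 1
  w2 <- feature_weight(expr, toy_scores(c(A1 = 0.8, A2 = 0.5)), delta = 0)
  expect_equal(w2$values[1, "A1"], 1.6)
  # p = 0 stays 0; non-shared columns untouched
  expr$values[2, "A1"] <- 0
  w3 <- feature_weight(expr, toy_scores(c(A1 = 0.9, A2 = 0.1)), delta = 1)
  expect_equal(w3$values[2, "A1"], 0)
  expect_equal(w3$values[, -(1:2)], expr$values[, -(1:2)])
  # strictly monotone in the score for positive p
  f <- function(a) 2 * 1 * a * exp(0.3 * 1)
  expect_true(f(0.9) > f(0.5))
  w_lo <- feature_weight(expr, toy_scores(c(A1 = 0.2, A2 = 0.5)), delta = 0.3)
  w_hi <- feature_weight(expr, toy_scores(c(A1 = 0.7, A2 = 0.5)), delta = 0.3)
  pos <- expr$values[, "A1"] > 0
  expect_true(all(w_hi$values[pos, "A1"] > w_lo$values[pos, "A1"]))
})

test_that("weighting validates its inputs", {
  expr <- make_expr()
  s <- toy_scores(c(A1 = 0.5, A2 = 0.5))
  expect_error(feature_weight(expr, s, delta = -1), "non-negative")
  bad <- s; colnames(bad) <- "OTHER"
  expect_error(feature_weight(expr, bad), "disease key")
  expect_error(feature_weight(expr, s, columns = "N1"), "shared")
  expect_error(feature_weight(expr, toy_scores(c(A1 = 0.5))), "A2")
})

test_that("shrink mode inverts the exponent sign", {
  expr <- make_expr()
  s <- toy_scores(c(A1 = 0.5, A2 = 0.5))
  w <- feature_weight(expr, s, delta = 0.7, mode = "shrink")
  expect_equal(w$values[, "A1"],
               expr$values[, "A1"] * exp(-0.7 * abs(expr$values[, "A1"])))
})

test_that("the delta grid holds the ten canonical candidates", {
  expect_equal(delta_grid(),
               c(0.0001, 0.0003, 0.001, 0.003, 0.01, 0.03, 0.1, 0.3, 1, 3))
})

test_that("cosine graph handles the degenerate extremes", {
  # orthogonal samples, gamma 1 -> self-loops only
  g <- cosine_adjacency(diag(4), gamma = 1)
  expect_equal(g$g_pp, diag(4))
  expect_equal(g$mean_degree, 1)
  # identical samples -> complete graph of ones at any gamma
  x <- matrix(1, 5, 3)
  g2 <- cosine_adjacency(x, gamma = 3)
  expect_equal(g2$g_pp, matrix(1, 5, 5))
  expect_error(cosine_adjacency(x, gamma = 0), "gamma")
  expect_error(cosine_adjacency(x, gamma = 9), "gamma")
  expect_warning(cosine_adjacency(rbind(diag(3), 0), gamma = 1), "all-zero")
})

test_that("cosine graph equals the exhaustive threshold-scan oracle", {
  set.seed(77)
  for (r in 1:8) {
    n <- sample(4:12, 1)
    x <- matrix(rnorm(n * 5), n, 5)
    gamma <- sample(seq_len(n), 1)
    impl <- cosine_adjacency(x, gamma)
    orc <- cosine_oracle(x, gamma)
    expect_equal(impl$epsilon, orc$epsilon)
    expect_equal(unname(impl$g_pp), orc$g_pp)
    # achieved mean degree admissible unless even the smallest
    # threshold cannot reach gamma
    all_deg <- (2 * sum(impl$g_pp[upper.tri(impl$g_pp)] != 0) + n) / n
    expect_true(impl$mean_degree >= gamma || impl$mean_degree == all_deg)
  }
})

test_that("the classifier separates linearly separable clusters", {
  set.seed(12)
  n <- 60
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 6, sd = 0.3), n, 6)
  x[y == "a", 1] <- x[y == "a", 1] + 3
  fit <- fwgcn(x, y, gamma = 2, epochs = 500, seed = 3)
  acc <- mean(fit$levels[max.col(fit$fitted_probs, ties.method = "first")] == y)
  expect_gte(acc, 0.98)
  # initial loss is close to ln C for balanced classes
  expect_equal(fit$loss_trace[1], log(2), tolerance = 0.2)
  expect_error(fwgcn(x, rep("a", n)), "single class")
})

test_that("training is reproducible from the seed", {
  set.seed(30)
  x <- matrix(rnorm(40 * 5), 40, 5)
  y <- rep(c("a", "b"), 20)
  f1 <- fwgcn(x, y, epochs = 50, seed = 4)
  f2 <- fwgcn(x, y, epochs = 50, seed = 4)
  expect_identical(f1$weights, f2$weights)
})

test_that("transductive prediction propagates probabilities", {
  set.seed(13)
  n <- 50
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 5, sd = 0.4), n, 5)
  x[y == "a", 1] <- x[y == "a", 1] + 2.5
  fit <- fwgcn(x, y, gamma = 2, epochs = 200, seed = 5)
  # rows sum to one
  p <- predict(fit, x[1:6, , drop = FALSE] + rnorm(30, sd = 0.01))
  expect_equal(unname(rowSums(p)), rep(1, 6))
  # a duplicate of a training sample inherits that sample's probability
  # vector within the extended graph (exact by symmetry)
  dup <- x[7, , drop = FALSE]
  xall <- rbind(x, dup)
  g_all <- cosine_adjacency(xall, fit$graph$gamma)
  probs <- ptmnet:::.gcn_forward(fit$weights, xall,
                                 ptmnet:::normalize_graph(g_all$g_pp))$probs
  expect_equal(unname(probs[nrow(xall), ]), unname(probs[7, ]),
               tolerance = 1e-3)
  expect_equal(unname(predict(fit, dup)[1, ]), unname(probs[nrow(xall), ]))
  expect_error(predict(fit, x[, 1:3]), "mismatch")
})

test_that("batched and one-at-a-time extension agree on separable data", {
  set.seed(14)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 5, sd = 0.4), n, 5)
  x[y == "a", 1] <- x[y == "a", 1] + 2.5
  te <- matrix(rnorm(10 * 5, sd = 0.4), 10, 5)
  te[1:5, 1] <- te[1:5, 1] + 2.5
  fit <- fwgcn(x, y, gamma = 2, epochs = 150, seed = 6)
  pb <- predict(fit, te, mode = "batch")
  ps <- predict(fit, te, mode = "single")
  agree <- mean(max.col(pb, ties.method = "first") ==
                max.col(ps, ties.method = "first"))
  expect_gte(agree, 0.95)
})

test_that("delta selection returns the grid maximizer deterministically", {
  expr <- make_expr(n = 50, sep = 2.5, seed = 21)
  s <- toy_scores(c(A1 = 0.9, A2 = 0.5))
  expect_equal(as.numeric(select_delta(expr, s, grid = 0.03, folds = 2,
                                       epochs = 30)), 0.03)
  d1 <- select_delta(expr, s, grid = c(0.001, 3), folds = 2, seed = 2,
                     epochs = 60)
  d2 <- select_delta(expr, s, grid = c(0.001, 3), folds = 2, seed = 2,
                     epochs = 60)
  expect_identical(d1, d2)
  # a huge delta blows up the planted scale and loses to the small one
  expect_equal(as.numeric(d1), 0.001)
})
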