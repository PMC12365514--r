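test_that("gcn_layer follows the normalized propagation rule", {
  # identity graph and weights pass the embedding through
  h <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_layer(h, diag(4), diag(3), "identity"), h)
  # 2-node swap toy: G = antidiagonal, D = I, so rows swap
  g <- matrix(c(0, 1, 1, 0), 2, 2)
  h2 <- diag(2)
  expect_equal(gcn_layer(h2, g, diag(2), "identity"),
               matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(gcn_layer(h * NA, diag(4), diag(3)), "non-finite")
  expect_error(gcn_layer(h, -diag(4), diag(3)), "non-negative")
})

test_that("layer attention is a split weighted sum with 1/(l+1) init", {
  init <- ptmnet:::.lagcn_init(6, 4, 3)
  expect_equal(init$theta, c(1/2, 1/3, 1/4))
  h <- matrix(rnorm(24), 6, 4)
  same <- list(h, h, h)
  att <- layer_attention(same, init$theta, n_p = 4)
  expect_equal(rbind(att$h_p, att$h_d), sum(init$theta) * h)
  one_hot <- layer_attention(same, c(0, 1, 0), n_p = 4)
  expect_equal(rbind(one_hot$h_p, one_hot$h_d), h)
  expect_error(layer_attention(same, c(1, 2)), "differ")
})

test_that("bilinear decoder produces sigmoid scores", {
  h_p <- matrix(c(1, 0), 1, 2)
  h_d <- matrix(c(0, 1), 1, 2)
  w <- matrix(c(0, 0, 2, 0), 2, 2)   # logit = h_p W h_d' = 2
  expect_equal(bilinear_decode(h_p, h_d, w)[1, 1], plogis(2))
  expect_equal(bilinear_decode(h_p, h_d, 0 * w)[1, 1], 0.5)
  s <- bilinear_decode(matrix(rnorm(8), 4, 2), matrix(rnorm(6), 3, 2),
                       matrix(rnorm(4), 2, 2))
  expect_true(all(s > 0 & s < 1))
})

test_that("weighted cross-entropy matches hand evaluation", {
  s <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(weighted_ce_loss(s, positives = 1, negatives = 2), log(2))
  # perfect fit drives the loss to ~0
  s2 <- matrix(c(1 - 1e-9, 1e-9), 1, 2)
  expect_lt(suppressMessages(weighted_ce_loss(s2, 1, 2)), 1e-6)
  # balanced sets reduce to unweighted CE / (P*D)
  s3 <- matrix(c(0.8, 0.7, 0.3, 0.4), 2, 2)
  expect_equal(weighted_ce_loss(s3, c(1, 2), c(3, 4)),
               -(log(0.8) + log(0.7) + log(0.7) + log(0.6)) / 4)
  expect_error(weighted_ce_loss(s3, c(1, 2), c(3)), "partition")
  expect_error(weighted_ce_loss(s3, integer(0), 1:4), "empty positive")
  expect_message(weighted_ce_loss(matrix(c(0, 0.5), 1), 2, 1), "clamping")
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  a <- matrix(rbinom(20, 1, 0.4), 5, 4,
              dimnames = list(paste0("P", 1:5), paste0("D", 1:4)))
  hg <- build_input_graph(build_hetero_network(a, diag(5) + 0.1,
                                               diag(4) + 0.1), 2)
  h0 <- initial_embedding(hg)
  pos <- which(a == 1); neg <- which(a != 1)
  set.seed(9)
  params <- ptmnet:::.lagcn_init(9, 3, 2)
  res <- ptmnet:::.lagcn_step(params, h0, hg$g_pd, 5, pos, neg, 0, 0, "relu")
  lossfun <- function(p)
    ptmnet:::.lagcn_step(p, h0, hg$g_pd, 5, pos, neg, 0, 0, "relu")$loss
  eps <- 1e-6
  fd <- function(get, set, analytic) {
    p0 <- get(params)
    for (i in seq_along(p0)) {
      pp <- params; v <- get(pp); v[i] <- v[i] + eps; pp <- set(pp, v)
      pm <- params; v <- get(pm); v[i] <- v[i] - eps; pm <- set(pm, v)
      expect_equal(analytic[i], (lossfun(pp) - lossfun(pm)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
  fd(function(p) p$w[[1]], function(p, v) { p$w[[1]][] <- v; p },
     res$grads$w[[1]])
  fd(function(p) p$w[[2]], function(p, v) { p$w[[2]][] <- v; p },
     res$grads$w[[2]])
  fd(function(p) p$theta, function(p, v) { p$theta <- v; p },
     res$grads$theta)
  fd(function(p) p$w_prime, function(p, v) { p$w_prime[] <- v; p },
     res$grads$w_prime)
})

test_that("training reduces the loss on block-structured data", {
  spec <- synthetic_spec(n_proteins = 20, n_diseases = 10, n_blocks = 2,
                         n_shared = 8, n_shared_informative = 4, seed = 5)
  a <- simulate_associations(spec)
  sgp <- gip_kernel(a); sgd <- gip_kernel(t(a))
  hg <- build_hetero_network(a, unclass_attr(sgp), unclass_attr(sgd))
  windows <- sapply(1:3, function(s) {
    tr <- lagcn(hg, a, epochs = 150, seed = s)$loss_trace
    expect_true(all(is.finite(tr)))
    tapply(tr, (seq_along(tr) - 1) %/% 50, mean)  # 50-step window means
  })
  # averaged across seeds, the windowed loss is decreasing
  expect_true(all(diff(rowMeans(windows)) < 0))
})

test_that("fitting is reproducible from the seed and scores lie in (0,1)", {
  spec <- synthetic_spec(n_proteins = 12, n_diseases = 8, n_blocks = 2,
                         n_shared = 6, n_shared_informative = 3, seed = 6)
  a <- simulate_associations(spec)
  hg <- build_hetero_network(a, unclass_attr(gip_kernel(a)),
                             unclass_attr(gip_kernel(t(a))))
  f1 <- lagcn(hg, a, epochs = 60, seed = 11)
  f2 <- lagcn(hg, a, epochs = 60, seed = 11)
  expect_identical(f1$scores, f2$scores)
  expect_true(all(f1$scores > 0 & f1$scores < 1))
  f3 <- lagcn(hg, a, epochs = 60, seed = 12)
  expect_false(identical(f1$scores, f3$scores))
  # presets carry the documented profiles
  expect_equal(f1$config$lr, 0.01)     # grid preset default
  expect_equal(f1$config$embed_dim, 64)
  expect_equal(f1$config$n_layers, 3)
  f4 <- lagcn(hg, a, preset = "text", epochs = 5, seed = 1)
  expect_equal(f4$config$lr, 0.001)
})
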