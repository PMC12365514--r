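test_that("rank AUC equals exhaustive pair counting", {
  set.seed(50)
  for (r in 1:10) {
    pos <- sample(0:10, sample(2:10, 1), replace = TRUE) / 10
    neg <- sample(0:10, sample(2:30, 1), replace = TRUE) / 10
    expect_equal(rank_auc(pos, neg), auc_oracle(pos, neg))
  }
  expect_equal(rank_auc(c(0.9, 0.8), c(0.1, 0.2, 0.3)), 1)  # perfect
  set.seed(51)
  null_auc <- rank_auc(runif(3000), runif(3000))
  expect_equal(null_auc, 0.5, tolerance = 0.05)              # null ranking
})

test_that("classification metrics match hand confusion counts", {
  perfect <- classification_metrics(c("a", "b"), c(0.1, 0.9))
  expect_equal(perfect, list(acc = 1, f1 = 1, auc = 1))
  # truth (1,1,0,0) vs predictions (1,0,0,0): ACC 3/4, F1 2/3
  m <- classification_metrics(factor(c(1, 1, 0, 0), levels = c(0, 1)),
                              c(0.9, 0.2, 0.1, 0.3))
  expect_equal(m$acc, 0.75)
  expect_equal(m$f1, 2 / 3)
  # three classes all correct
  probs <- diag(3)[c(1, 2, 3, 1), ]
  colnames(probs) <- c("x", "y", "z")
  m3 <- classification_metrics(c("x", "y", "z", "x"), probs)
  expect_equal(m3, list(acc = 1, f1_weighted = 1, f1_macro = 1))
  # single-class truth: AUC undefined
  expect_true(is.na(classification_metrics(factor(c("a", "a"),
                                                  levels = c("a", "b")),
                                           c(0.2, 0.4))$auc))
})

test_that("binary AUC agrees with an external ROC implementation", {
  set.seed(52)
  y <- rep(c(0, 1), each = 25)
  p <- runif(50) + y * 0.4
  ours <- classification_metrics(y, p)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE)))
  expect_equal(ours, ref)
})

test_that("fold partitions are exhaustive, disjoint and reproducible", {
  y <- rep(c("a", "b", "c"), times = c(20, 12, 9))
  f1 <- ptmnet:::stratified_folds(y, 5, seed = 3)
  f2 <- ptmnet:::stratified_folds(y, 5, seed = 3)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:5)
  expect_lte(diff(range(table(f1))), 3)       # near-equal given 3 strata
  for (cl in unique(y))                        # strata spread across folds
    expect_lte(diff(range(tabulate(f1[y == cl], 5))), 1)
  p <- ptmnet:::plain_folds(23, 5, seed = 9)
  expect_lte(diff(range(table(p))), 1)
  expect_identical(p, ptmnet:::plain_folds(23, 5, seed = 9))
})

test_that("masked-fold link AUC separates block structure from noise scores", {
  st <- toy_study(seed = 17)
  res <- kfold_link_auc(st$assoc, st$sequences, k = 3, seed = 17,
                        epochs = 120)
  expect_length(res$fold_auc, 3)
  expect_true(all(res$fold_auc > 0 & res$fold_auc < 1))
  expect_gt(res$mean_auc, 0.6)   # block structure is learnable even briefly
  expect_error(kfold_link_auc(st$assoc[, 1:2] * 0 + diag(1, 20, 2),
                              st$sequences, k = 50), "fewer positive")
})

test_that("identity weighting yields an all-zero biomarker screen", {
  st <- toy_study(seed = 19)
  s05 <- st$truth$scores
  s05[] <- 0.5
  rep <- screen_biomarkers(st$expr, s05, k = 3, seed = 19, delta = 0,
                           hidden = 16, epochs = 60)
  expect_true(all(rep$count == 0))
  expect_true(all(abs(rep$mean_improvement) < 1e-12))
  expect_lte(max(rep$count), 3)   # counts bounded by the fold number
})

test_that("an empty shared set degrades the screen gracefully", {
  st <- toy_study(seed = 23)
  expr0 <- expression_dataset(st$expr$values, st$expr$labels,
                              shared = character(), disease_key = "DIS1")
  expect_warning(rep0 <- screen_biomarkers(expr0, st$truth$scores, k = 2,
                                           epochs = 20),
                 "no shared proteins")
  expect_true(attr(rep0, "empty"))
  expect_equal(nrow(rep0), 0)
})

test_that("the final model weights exactly the screened columns", {
  st <- toy_study(seed = 29)
  prot <- st$expr$protein_ids[st$expr$shared_index]
  full <- structure(data.frame(protein = prot,
                               count = rep(2L, length(prot)),
                               mean_improvement = 0),
                    class = c("biomarker_report", "data.frame"), k = 3)
  m_all <- final_weighted_model(st$expr, st$truth$scores, full,
                                delta = 0.01, epochs = 40, seed = 2)
  w <- feature_weight(st$expr, st$truth$scores, delta = 0.01)
  m_ref <- fwgcn(w$values, w$labels, epochs = 40, seed = 2)
  expect_identical(m_all$weights, m_ref$weights)
  empty <- structure(data.frame(protein = character(), count = integer(),
                                mean_improvement = numeric()),
                     class = c("biomarker_report", "data.frame"), k = 3)
  m_none <- final_weighted_model(st$expr, st$truth$scores, empty,
                                 epochs = 40, seed = 2)
  m_unw <- fwgcn(st$expr$values, st$expr$labels, epochs = 40, seed = 2)
  expect_identical(m_none$weights, m_unw$weights)
})

test_that("shared-protein sensitivity anchors size 0 at the baseline", {
  st <- toy_study(seed = 31)
  expect_warning(
    curve <- shared_protein_sensitivity(st$expr, st$truth$scores,
                                        sizes = c(0, 4), k = 2, seed = 31,
                                        hidden = 16, epochs = 60),
    "10 or fewer")
  expect_equal(curve$accuracy[curve$size == 0], attr(curve, "baseline"))
  expect_equal(nrow(curve), 2)
})
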