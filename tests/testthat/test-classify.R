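# well-separated Gaussian blobs: 2-D, `classes` centers on a circle
blob_data <- function(n_per = 20, classes = 3, sd = 0.15, seed = 71) {
  set.seed(seed)
  ang <- 2 * pi * (seq_len(classes) - 1) / classes
  x <- do.call(rbind, lapply(seq_len(classes), function(c) {
    cbind(cos(ang[c]) + rnorm(n_per, sd = sd),
          sin(ang[c]) + rnorm(n_per, sd = sd))
  }))
  colnames(x) <- c("u", "v")
  list(x = x, y = factor(rep(paste0("c", seq_len(classes)), each = n_per)))
}

test_that("stratified folds partition every class evenly and reproducibly", {
  y <- factor(rep(c("a", "b"), each = 50))
  f <- make_folds(y, k = 10, seed = 5)
  expect_equal(sort(unique(f$assignments)), 1:10)
  expect_true(all(table(f$assignments) == 10))
  expect_true(all(table(f$assignments, y) == 5))
  expect_identical(make_folds(y, k = 10, seed = 5)$assignments,
                   f$assignments)
  expect_false(identical(make_folds(y, k = 10, seed = 6)$assignments,
                         f$assignments))
  expect_warning(make_folds(factor(c("a", rep("b", 20))), k = 5, seed = 1),
                 "fewer samples than folds")
})

test_that("metric formulas agree with hand computation on 2x2 tables", {
  y_true <- factor(c(rep("pos", 10), rep("neg", 10)),
                   levels = c("neg", "pos"))
  y_pred <- factor(c(rep("pos", 8), "neg", "neg",
                     rep("neg", 6), rep("pos", 4)),
                   levels = c("neg", "pos"))
  m <- compute_metrics(y_true, y_pred, positive = "pos")
  expect_equal(unname(m$acc), 14 / 20)
  expect_equal(unname(m$sen), 8 / 10)          # TP = 8, FN = 2
  expect_equal(unname(m$prec), 8 / 12)         # FP = 4
  expect_equal(sum(m$confusion), 20)
  expect_equal(as.vector(rowSums(m$confusion)), c(10, 10))

  # perfect prediction with well-ordered scores
  sc <- cbind(neg = c(rep(0, 10), rep(1, 10)),
              pos = c(rep(1, 10), rep(0, 10)))
  mp <- compute_metrics(y_true, y_true, scores = sc, positive = "pos")
  expect_equal(unname(mp$acc), 1)
  expect_equal(unname(mp$auc), 1)
})

test_that("random scores on balanced labels give chance-level AUC", {
  set.seed(72)
  n <- 10000
  y <- factor(rep(c("a", "b"), each = n / 2))
  sc <- cbind(a = runif(n), b = runif(n))
  m <- compute_metrics(y, factor(sample(y), levels = levels(y)), scores = sc,
                       positive = "b")
  expect_lt(abs(m$auc - 0.5), 0.02)
})

test_that("classifiers separate easy data and expose usable scores", {
  d <- blob_data(sd = 0.05)
  svm <- train_svm(d$x, d$y)
  pr <- predict_scores(svm, d$x)
  expect_equal(mean(pr$class == d$y), 1)
  expect_equal(dim(pr$scores), c(60, 3))
  # the true class should receive the top aggregated decision value
  expect_equal(unname(apply(pr$scores, 1, which.max)),
               as.integer(d$y))

  dtb <- train_dtb(d$x, d$y, n_trees = 25, seed = 3)
  pr2 <- predict_scores(dtb, d$x)
  expect_gt(mean(pr2$class == d$y), 0.95)
  dtb_again <- train_dtb(d$x, d$y, n_trees = 25, seed = 3)
  expect_identical(predict_scores(dtb_again, d$x)$class, pr2$class)

  expect_error(train_svm(d$x, factor(rep("c1", 60))), "single class")
})

test_that("cross-validation aggregates fold metrics without leakage", {
  d <- blob_data(n_per = 30, sd = 0.1, seed = 73)
  r <- cross_validate(d$x, d$y, k = 5, seed = 2)
  expect_equal(nrow(r$per_fold), 5)
  expect_gt(unname(r$acc), 0.95)
  expect_equal(sum(r$confusion), 90)
  expect_equal(as.vector(rowSums(r$confusion)), rep(30, 3))
  # reproducible end to end
  r2 <- cross_validate(d$x, d$y, k = 5, seed = 2)
  expect_equal(r2$per_fold, r$per_fold)
  # dtb path and per-fold PCA path run through the same machinery
  r3 <- cross_validate(d$x, d$y, k = 3, seed = 2, classifier = "dtb",
                       n_trees = 25)
  expect_gt(unname(r3$acc), 0.9)
  r4 <- cross_validate(d$x, d$y, k = 3, seed = 2, n_components = 2)
  expect_gt(unname(r4$acc), 0.9)
})

test_that("the component sweep evaluates the documented grid", {
  d <- blob_data(n_per = 25, classes = 2, sd = 0.1, seed = 74)
  x <- cbind(d$x, matrix(rnorm(50 * 8, sd = 0.05), 50))
  colnames(x) <- paste0("f", 1:10)
  sw <- pc_sweep(x, d$y, step = 4, k = 5, seed = 3)
  expect_equal(sw$curve$n_pcs, c(4, 8, 10))
  expect_equal(nrow(sw$curve), 3)
  expect_true(sw$best_n_pcs %in% sw$curve$n_pcs)
  expect_true(all(sw$curve$acc >= 0 & sw$curve$acc <= 1))
})
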