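#' Stratified k-fold assignment
#'
#' Assigns every sample to exactly one of `k` folds.  Under stratification
#' (the default) samples are shuffled and dealt round-robin within each
#' class, so per-class fold sizes differ by at most one; a class with fewer
#' samples than folds triggers a warning and a best-effort assignment.
#' The assignment is deterministic for a fixed seed.
#'
#' @param labels Factor (or coercible) of class labels.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @param stratified Stratify by class (default TRUE).
#' @return Object of class `fold_plan`: list with integer `assignments`
#'   (length of `labels`, values in `1..k`) and the parameters.
#' @export
make_folds <- function(labels, k = 10, seed = 1, stratified = TRUE) {
  labels <- as.factor(labels)
  n <- length(labels)
  stopifnot(k >= 2, n >= k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  assignments <- integer(n)
  if (stratified) {
    if (any(table(labels) < k)) {
      warning("some class has fewer samples than folds; ",
              "those folds will lack that class")
    }
    offset <- 0
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assignments[idx] <- (offset + seq_along(idx) - 1) %% k + 1
      offset <- offset + length(idx)
    }
  } else {
    assignments <- (sample.int(n) - 1) %% k + 1
  }
  structure(list(assignments = assignments, k = as.integer(k),
                 seed = seed, stratified = stratified),
            class = "fold_plan")
}

#' Train a support vector machine
#'
#' Radial-basis-function SVM with one-versus-one multiclass decisions,
#' trained with the sequential-minimal-optimization-style dual solver of
#' libsvm.  Features are expected to be standardized already; no internal
#' scaling is applied.  The default regularization is `C = 5` and the
#' default kernel width is `gamma = 1 / n_features`.
#'
#' @param x Standardized numeric feature matrix.
#' @param y Factor of class labels (at least two classes present).
#' @param cost Regularization parameter C (default 5).
#' @param gamma RBF kernel width (default `1 / ncol(x)`).
#' @return Object of class `svm_model` wrapping the fitted classifier.
#' @export
train_svm <- function(x, y, cost = 5, gamma = 1 / ncol(x)) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training labels contain a single class")
  stopifnot(cost > 0)
  fit <- e1071::svm(x, y, scale = FALSE, kernel = "radial",
                    cost = cost, gamma = gamma)
  structure(list(fit = fit, levels = levels(y)), class = "svm_model")
}

#' Train a bagged decision tree ensemble
#'
#' Bootstrap-aggregated classification trees with random attribute
#' selection at each split.  Defaults: 100 trees and
#' `floor(sqrt(n_features))` candidate attributes per split.
#'
#' @param x Numeric feature matrix.
#' @param y Factor of class labels (at least two classes present).
#' @param n_trees Number of bootstrap trees (default 100).
#' @param mtry Attributes tried per split (default `floor(sqrt(ncol(x)))`).
#' @param seed Integer seed making the ensemble reproducible.
#' @return Object of class `dtb_model`.
#' @export
train_dtb <- function(x, y, n_trees = 100, mtry = max(1, floor(sqrt(ncol(x)))),
                      seed = 1) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training labels contain a single class")
  stopifnot(n_trees >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fit <- randomForest::randomForest(x, y, ntree = n_trees, mtry = mtry)
  structure(list(fit = fit, levels = levels(y)), class = "dtb_model")
}

#' Predict classes and per-class scores
#'
#' For the SVM, per-class scores aggregate the signed one-versus-one
#' decision values (each pairwise decision adds its value to the first
#' class of the pair and subtracts it from the second), which is
#' deterministic; for the bagged trees, scores are the ensemble vote
#' fractions.
#'
#' @param model An `svm_model` or `dtb_model`.
#' @param x Feature matrix prepared the same way as the training data.
#' @return List with `class` (factor) and `scores` (matrix, one column per
#'   class, higher = more confident).
#' @export
predict_scores <- function(model, x) {
  if (inherits(model, "svm_model")) {
    pr <- stats::predict(model$fit, x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    scores <- matrix(0, nrow(x), length(model$levels),
                     dimnames = list(NULL, model$levels))
    for (cn in colnames(dv)) {
      pair <- strsplit(cn, "/", fixed = TRUE)[[1]]
      scores[, pair[1]] <- scores[, pair[1]] + dv[, cn]
      scores[, pair[2]] <- scores[, pair[2]] - dv[, cn]
    }
    list(class = factor(as.character(pr), levels = model$levels),
         scores = scores)
  } else if (inherits(model, "dtb_model")) {
    cls <- stats::predict(model$fit, x)
    scores <- stats::predict(model$fit, x, type = "prob")
    list(class = factor(as.character(cls), levels = model$levels),
         scores = scores[, model$levels, drop = FALSE])
  } else {
    stop("unsupported model class")
  }
}

auc_binary <- function(truth, score) {
  if (length(unique(truth)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = score,
    levels = c(FALSE, TRUE), direction = "<", quiet = TRUE
  )))
}

#' Classification metrics: accuracy, AUC, sensitivity, precision
#'
#' Binary problems use the designated positive class: sensitivity is
#' TP/(TP+FN), precision TP/(TP+FP), and the AUC is the area under the ROC
#' curve of the positive-class score.  Multiclass problems report
#' macro-averaged one-versus-rest sensitivity, precision and AUC; accuracy
#' is always the fraction of correct predictions.  Degenerate ratios (an
#' empty denominator) contribute 0.
#'
#' @param y_true,y_pred Factors with identical level sets.
#' @param scores Optional per-class score matrix (columns named by class);
#'   without it the AUC is reported as `NA`.
#' @param positive Positive class name for binary problems (default: the
#'   second factor level).
#' @return Object of class `metrics_report` with fields `acc`, `auc`,
#'   `sen`, `prec` and the `confusion` matrix (true classes in rows).
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL, positive = NULL) {
  y_true <- as.factor(y_true)
  y_pred <- factor(as.character(y_pred), levels = levels(y_true))
  stopifnot(length(y_true) == length(y_pred))
  lev <- levels(y_true)
  confusion <- table(true = y_true, predicted = y_pred)
  acc <- mean(y_true == y_pred)
  safe_ratio <- function(num, den) if (den > 0) num / den else 0
  if (length(lev) == 2) {
    positive <- positive %||% lev[2]
    stopifnot(positive %in% lev)
    tp <- sum(y_true == positive & y_pred == positive)
    fn <- sum(y_true == positive & y_pred != positive)
    fp <- sum(y_true != positive & y_pred == positive)
    sen <- safe_ratio(tp, tp + fn)
    prec <- safe_ratio(tp, tp + fp)
    auc <- if (!is.null(scores)) {
      auc_binary(y_true == positive, scores[, positive])
    } else NA_real_
  } else {
    per <- vapply(lev, function(cls) {
      tp <- confusion[cls, cls]
      fn <- sum(confusion[cls, ]) - tp
      fp <- sum(confusion[, cls]) - tp
      c(sen = safe_ratio(tp, tp + fn), prec = safe_ratio(tp, tp + fp),
        auc = if (!is.null(scores)) {
          auc_binary(y_true == cls, scores[, cls])
        } else NA_real_)
    }, numeric(3))
    sen <- mean(per["sen", ])
    prec <- mean(per["prec", ])
    auc <- mean(per["auc", ])
  }
  structure(list(acc = acc, auc = auc, sen = sen, prec = prec,
                 confusion = confusion, positive = positive),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf("ACC %s  AUC %s  Sen %s  Prec %s\n",
              fmt(x$acc), fmt(x$auc), fmt(x$sen), fmt(x$prec)))
  if (!is.null(x$per_fold)) {
    cat(sprintf("(mean over %d folds; sd: ACC %.4f, AUC %.4f, Sen %.4f, Prec %.4f)\n",
                nrow(x$per_fold), x$sd["acc"], x$sd["auc"], x$sd["sen"],
                x$sd["prec"]))
  }
  cat("Confusion matrix (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Cross-validated classification of a feature matrix
#'
#' For every fold: fits the standardizer (and, when `n_components` is
#' given, the varimax-rotated PCA) on the training split only, trains the
#' classifier, and evaluates on the held-out fold.  No statistic of the
#' test split enters any fitted transformation.  Metrics are aggregated as
#' mean and standard deviation over folds; the confusion matrix is pooled
#' over all held-out predictions.
#'
#' @param x Numeric feature matrix (samples x features).
#' @param y Class labels.
#' @param k Number of folds (default 10); ignored when `folds` is given.
#' @param seed Seed for the fold assignment and the tree ensemble.
#' @param classifier `"svm"` (default) or `"dtb"`.
#' @param n_components Optional number of rotated principal components to
#'   project onto before classification (capped per fold at the training
#'   rank).
#' @param pca_scope `"fold"` (default, leakage-free) fits the PCA inside
#'   each training fold; `"global"` fits it once on the full dataset
#'   before cross-validation, matching pipelines that reduce first and
#'   validate later.
#' @param folds Optional precomputed [make_folds()] plan.
#' @param stratified Stratify the fold assignment (default TRUE).
#' @param positive Positive class for binary metrics.
#' @param cost,gamma SVM parameters (see [train_svm()]).
#' @param n_trees,mtry Bagged-tree parameters (see [train_dtb()]).
#' @return A `metrics_report` whose `acc`/`auc`/`sen`/`prec` are fold
#'   means, with `per_fold` metrics, fold standard deviations `sd`, and
#'   the pooled confusion matrix.
#' @export
cross_validate <- function(x, y, k = 10, seed = 1,
                           classifier = c("svm", "dtb"),
                           n_components = NULL,
                           pca_scope = c("fold", "global"),
                           folds = NULL, stratified = TRUE, positive = NULL,
                           cost = 5, gamma = NULL,
                           n_trees = 100, mtry = NULL) {
  classifier <- match.arg(classifier)
  pca_scope <- match.arg(pca_scope)
  y <- as.factor(y)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (is.null(folds)) {
    folds <- make_folds(y, k = k, seed = seed, stratified = stratified)
  }
  stopifnot(inherits(folds, "fold_plan"))
  k <- folds$k
  global_model <- NULL
  if (!is.null(n_components) && pca_scope == "global") {
    std_all <- suppressWarnings(standardize_fit(x))
    global_model <- pca_fit(standardize_apply(x, std_all),
                            min(n_components, nrow(x) - 1))
  }
  per_fold <- data.frame(fold = seq_len(k), acc = NA_real_, auc = NA_real_,
                         sen = NA_real_, prec = NA_real_)
  confusion <- NULL
  for (f in seq_len(k)) {
    tr <- folds$assignments != f
    te <- !tr
    std <- suppressWarnings(standardize_fit(x[tr, , drop = FALSE]))
    xtr <- standardize_apply(x[tr, , drop = FALSE], std)
    xte <- standardize_apply(x[te, , drop = FALSE], std)
    if (!is.null(n_components)) {
      if (pca_scope == "global") {
        xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
        xtr <- pca_project(standardize_apply(xtr, std_all), global_model)
        xte <- pca_project(standardize_apply(xte, std_all), global_model)
      } else {
        nc <- min(n_components, sum(tr) - 1, ncol(xtr))
        model <- pca_fit(xtr, nc)
        xtr <- pca_project(xtr, model)
        xte <- pca_project(xte, model)
      }
    }
    fit <- if (classifier == "svm") {
      train_svm(xtr, y[tr], cost = cost,
                gamma = gamma %||% (1 / ncol(xtr)))
    } else {
      train_dtb(xtr, y[tr], n_trees = n_trees,
                mtry = mtry %||% max(1, floor(sqrt(ncol(xtr)))),
                seed = seed + f)
    }
    pr <- predict_scores(fit, xte)
    m <- compute_metrics(y[te], pr$class, pr$scores, positive = positive)
    per_fold[f, c("acc", "auc", "sen", "prec")] <-
      c(m$acc, m$auc, m$sen, m$prec)
    confusion <- if (is.null(confusion)) m$confusion else confusion + m$confusion
  }
  means <- colMeans(per_fold[, c("acc", "auc", "sen", "prec")])
  sds <- apply(per_fold[, c("acc", "auc", "sen", "prec")], 2, stats::sd)
  structure(list(acc = means["acc"], auc = means["auc"], sen = means["sen"],
                 prec = means["prec"], sd = sds, per_fold = per_fold,
                 confusion = confusion, positive = positive,
                 classifier = classifier, k = k),
            class = "metrics_report")
}

#' Accuracy-versus-components sweep
#'
#' Cross-validates the pipeline at an increasing number of rotated
#' principal components -- `step`, `2 step`, ... up to the maximum usable
#' count (which is always included as the final grid point) -- and reports
#' the full curve with the best-accuracy point.
#'
#' @inheritParams cross_validate
#' @param step Component-grid increment (default 50).
#' @param max_pcs Largest component count to evaluate; defaults to the
#'   usable maximum `min(n_features, smallest training-fold size - 1)`.
#' @param ... Further arguments passed to [cross_validate()].
#' @return Object of class `pc_sweep`: data frame `curve` (n_pcs, acc,
#'   auc, sen, prec) plus `best_n_pcs` and `reports`.
#' @export
pc_sweep <- function(x, y, step = 50, max_pcs = NULL, k = 10, seed = 1, ...) {
  stopifnot(step >= 1)
  folds <- make_folds(y, k = k, seed = seed)
  min_train <- min(vapply(seq_len(k), function(f) {
    sum(folds$assignments != f)
  }, numeric(1)))
  limit <- min(ncol(x), min_train - 1)
  max_pcs <- min(max_pcs %||% limit, limit)
  grid <- unique(c(seq(step, max_pcs, by = step), max_pcs))
  reports <- lapply(grid, function(nc) {
    cross_validate(x, y, folds = folds, seed = seed, n_components = nc, ...)
  })
  curve <- data.frame(
    n_pcs = grid,
    acc = vapply(reports, function(r) unname(r$acc), numeric(1)),
    auc = vapply(reports, function(r) unname(r$auc), numeric(1)),
    sen = vapply(reports, function(r) unname(r$sen), numeric(1)),
    prec = vapply(reports, function(r) unname(r$prec), numeric(1))
  )
  structure(list(curve = curve,
                 best_n_pcs = grid[which.max(curve$acc)],
                 reports = reports),
            class = "pc_sweep")
}

#' @export
print.pc_sweep <- function(x, ...) {
  cat("Accuracy vs number of rotated principal components:\n")
  print(x$curve, row.names = FALSE)
  cat(sprintf("Best accuracy at %d components\n", x$best_n_pcs))
  invisible(x)
}
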