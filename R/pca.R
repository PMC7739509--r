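# Varimax rotation of an orthonormal loading matrix (orthomax with
# gamma = 1).  Raw loadings are rotated (no Kaiser row normalization) so
# the returned basis stays exactly orthonormal.
varimax_rotate <- function(L, eps = 1e-6) {
  nc <- ncol(L)
  if (nc < 2) return(list(loadings = L, rotmat = diag(nc)))
  v <- stats::varimax(L, normalize = FALSE, eps = eps)
  list(loadings = L %*% v$rotmat, rotmat = v$rotmat)
}

#' Fit a varimax-rotated PCA model
#'
#' Extracts the leading principal axes of the (column-centered) training
#' matrix and rotates them to maximize the varimax criterion (orthomax with
#' \eqn{\gamma = 1}), yielding an orthonormal basis with simple structure.
#' Because the rotation is orthogonal, projections before and after
#' rotation differ only by a rigid rotation of the component space;
#' pairwise distances between projected samples are unchanged.  Each basis
#' column's sign is fixed so its largest-magnitude loading is positive,
#' making the fitted model deterministic.
#'
#' @param train Numeric training matrix (samples x features).
#' @param n_components Number of components to retain; at most
#'   `min(n_features, n_train - 1)`.
#' @param eps Varimax convergence tolerance (default 1e-6).
#' @return Object of class `pca_model` with the orthonormal rotated
#'   `basis` (features x components), the training column means, and the
#'   component count.
#' @export
pca_fit <- function(train, n_components, eps = 1e-6) {
  stopifnot(is.matrix(train), nrow(train) >= 2)
  limit <- min(ncol(train), nrow(train) - 1)
  if (n_components < 1 || n_components > limit) {
    stop(sprintf(
      "n_components = %d out of range: must be between 1 and min(n_features, n_train - 1) = %d",
      n_components, limit
    ))
  }
  pc <- stats::prcomp(train, center = TRUE, scale. = FALSE)
  basis <- pc$rotation[, seq_len(n_components), drop = FALSE]
  basis <- varimax_rotate(basis, eps = eps)$loadings
  for (j in seq_len(ncol(basis))) {
    i <- which.max(abs(basis[, j]))
    if (basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(list(basis = basis, center = pc$center,
                 n_components = as.integer(n_components),
                 feature_names = colnames(train)),
            class = "pca_model")
}

#' Project data onto a fitted varimax-rotated PCA basis
#'
#' Centers by the training column means and projects onto the rotated
#' orthonormal basis.
#'
#' @param x Numeric matrix with the same columns the model was fitted on.
#' @param model A `pca_model` from [pca_fit()].
#' @return Matrix with `n_components` columns.
#' @export
pca_project <- function(x, model) {
  stopifnot(inherits(model, "pca_model"), is.matrix(x))
  if (ncol(x) != nrow(model$basis)) {
    stop(sprintf("data has %d columns but the model was fitted on %d",
                 ncol(x), nrow(model$basis)))
  }
  sweep(x, 2, model$center, "-") %*% model$basis
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("Varimax-rotated PCA model: %d features -> %d components\n",
              nrow(x$basis), x$n_components))
  invisible(x)
}
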