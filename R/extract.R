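#' Extract texture descriptor blocks for a whole image set
#'
#' Builds (or reuses) the shearlet system for the common image shape,
#' decomposes every image, and computes the requested descriptor blocks.
#' All images must share one shape.
#'
#' @param images List of grayscale matrices (values in [0, 1]).
#' @param descriptors,components,ng,nt See [texture_blocks()].
#' @param system Optional prebuilt [shearlet_system()] matching the image
#'   shape; built automatically when `NULL`.
#' @param scales,directions_per_scale System parameters used when building.
#' @param baselines Optional character vector of baseline method names to
#'   compute alongside (see [baseline_features()]).
#' @param progress Print a dot every 25 images (default FALSE).
#' @return List with `samples` (per-image named lists of `feature_block`s)
#'   and the `system` used.
#' @export
extract_dataset <- function(images,
                            descriptors = c("cm", "lbp", "losib", "sfta"),
                            components = c("magnitude", "rp"),
                            ng = 8, nt = 4, system = NULL,
                            scales = 4, directions_per_scale = 8,
                            baselines = NULL, progress = FALSE) {
  stopifnot(is.list(images), length(images) >= 1)
  dims <- dim(images[[1]])
  if (is.null(system)) {
    system <- shearlet_system(dims[1], dims[2], scales = scales,
                              directions_per_scale = directions_per_scale)
  }
  samples <- vector("list", length(images))
  for (i in seq_along(images)) {
    co <- shearlet_transform(images[[i]], system)
    blocks <- texture_blocks(co, descriptors = descriptors,
                             components = components, ng = ng, nt = nt)
    for (m in baselines) {
      blocks[[paste(m, "baseline", sep = ".")]] <- baseline_features(co, m)
    }
    samples[[i]] <- blocks
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  list(samples = samples, system = system)
}

#' Baseline feature matrix for a whole image set
#'
#' Convenience wrapper computing one baseline descriptor per image and
#' stacking the vectors into a matrix, so baselines run through the same
#' fusion-free evaluation path as the main descriptors.
#'
#' @param images List of grayscale matrices sharing one shape.
#' @param method Baseline method name (see [baseline_features()]).
#' @param system Optional prebuilt system.
#' @return Numeric matrix (samples x features) with column names.
#' @export
baseline_matrix <- function(images, method, system = NULL) {
  dims <- dim(images[[1]])
  if (is.null(system)) system <- shearlet_system(dims[1], dims[2])
  rows <- lapply(images, function(img) {
    baseline_features(shearlet_transform(img, system), method)$values
  })
  x <- do.call(rbind, rows)
  rownames(x) <- NULL
  x
}
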