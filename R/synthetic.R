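#' Generate one oriented synthetic texture
#'
#' Produces a sinusoidal grating at the requested orientation and spatial
#' frequency plus seeded Gaussian pixel noise, clipped to [0, 1].  The
#' orientation is the direction along which intensity varies (the stripes
#' run perpendicular to it), so gratings at different orientations
#' concentrate their shearlet energy in different directional sub-bands.
#'
#' @param orientation Orientation in degrees in [0, 180).
#' @param frequency Spatial frequency in cycles per image width; must be
#'   below the Nyquist limit `size / 2`.
#' @param size Image side length in pixels (square image).
#' @param contrast Peak-to-peak amplitude of the grating in [0, 1].
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer seed; the same arguments always return the same
#'   image.
#' @return `size` x `size` numeric matrix with values in [0, 1].
#' @export
generate_texture <- function(orientation, frequency, size = 128,
                             contrast = 1, noise_sd = 0.3, seed = 1) {
  stopifnot(size >= 8, contrast >= 0, noise_sd >= 0)
  if (frequency <= 0 || frequency >= size / 2) {
    stop(sprintf(
      "frequency %.1f cycles/image exceeds the Nyquist limit %.1f for size %d",
      frequency, size / 2, size
    ))
  }
  theta <- orientation * pi / 180
  xs <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  ys <- matrix(seq_len(size) - 1, size, size)
  phase <- 2 * pi * frequency * (xs * cos(theta) + ys * sin(theta)) / size
  img <- 0.5 + contrast / 2 * cos(phase)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    img <- img + matrix(stats::rnorm(size^2, sd = noise_sd), size, size)
  }
  pmin(pmax(img, 0), 1)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a multi-class synthetic texture dataset
#'
#' Class identity is carried by grating orientation: class c of
#' `n_classes` uses orientation `(c - 1) * 180 / n_classes` degrees, so the
#' classes are separable by construction through the orientation
#' selectivity of the shearlet sub-bands.  Per-image seeds are derived from
#' the master seed with a fixed counter scheme (class index and image index
#' enter separately), so enlarging `n_per_class` never changes images that
#' were already generated.
#'
#' @param n_classes Number of texture classes (default 4).
#' @param n_per_class Images per class (default 50).
#' @param size Image side length in pixels (default 128).
#' @param seed Master integer seed.
#' @param frequency Grating frequency in cycles per image (default 16).
#' @param contrast Grating amplitude (default 1).
#' @param noise_sd Additive Gaussian noise level (default 0.3).
#' @return Object of class `synthetic_dataset`: list with `images`,
#'   `labels` (factor `class1..classN`), `class_specs` (data frame) and the
#'   generation parameters.
#' @export
synthetic_textures <- function(n_classes = 4, n_per_class = 50, size = 128,
                               seed = 7, frequency = 16, contrast = 1,
                               noise_sd = 0.3) {
  stopifnot(n_classes >= 2, n_per_class >= 1)
  orientations <- (seq_len(n_classes) - 1) * 180 / n_classes
  specs <- data.frame(
    class = paste0("class", seq_len(n_classes)),
    orientation = orientations,
    frequency = frequency, contrast = contrast, noise_sd = noise_sd
  )
  images <- vector("list", n_classes * n_per_class)
  labels <- character(length(images))
  i <- 0
  for (c in seq_len(n_classes)) {
    for (m in seq_len(n_per_class)) {
      i <- i + 1
      img_seed <- (seed + 7919 * c + 104729 * m) %% 2147483647
      images[[i]] <- generate_texture(
        orientation = orientations[c], frequency = frequency, size = size,
        contrast = contrast, noise_sd = noise_sd, seed = img_seed
      )
      labels[i] <- specs$class[c]
    }
  }
  structure(list(
    images = images, labels = factor(labels, levels = specs$class),
    class_specs = specs, size = size, seed = seed
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic texture dataset: %d images (%d classes x %d), %d x %d px, noise sd %.2f\n",
    length(x$images), nlevels(x$labels), length(x$images) / nlevels(x$labels),
    x$size, x$size, x$class_specs$noise_sd[1]
  ))
  invisible(x)
}

#' Write a synthetic dataset as a folder-per-class PNG corpus
#'
#' @param dataset A `synthetic_dataset`.
#' @param out Output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
write_dataset_folder <- function(dataset, out) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  paths <- character(length(dataset$images))
  counts <- integer(nlevels(dataset$labels))
  names(counts) <- levels(dataset$labels)
  for (i in seq_along(dataset$images)) {
    cls <- as.character(dataset$labels[i])
    counts[cls] <- counts[cls] + 1
    dir.create(file.path(out, cls), recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(out, cls, sprintf("img%04d.png", counts[cls]))
    png::writePNG(dataset$images[[i]], paths[i])
  }
  invisible(paths)
}
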