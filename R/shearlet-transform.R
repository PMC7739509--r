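fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Complex shearlet decomposition of an image
#'
#' Applies every directional filter of the system to the image in the
#' frequency domain and returns the complex coefficient stack together with
#' the derived magnitude (\eqn{\rho = \sqrt{x^2 + y^2}}) and phase
#' (\eqn{\theta = \mathrm{atan2}(y, x)}, in \eqn{(-\pi, \pi]}) stacks.  The
#' transform is linear; the low-pass residual is kept separately so the
#' decomposition is invertible.
#'
#' @param image Numeric matrix (single-channel image) whose dimensions match
#'   the system's image shape.
#' @param system A [shearlet_system()].
#' @return An object of class `shearlet_coeffs`: lists `coeffs` (complex),
#'   `magnitude` and `phase` (real), one matrix per (scale, direction)
#'   sub-band in the system's canonical order, plus the real `lowpass` band
#'   and the sub-band `index`.
#' @seealso [inverse_shearlet_transform()], [relative_phase()]
#' @export
shearlet_transform <- function(image, system) {
  stopifnot(inherits(system, "shearlet_system"), is.matrix(image))
  if (!all(is.finite(image))) stop("image contains non-finite values")
  if (nrow(image) != system$rows || ncol(image) != system$cols) {
    stop(sprintf(
      "image is %d x %d but system was built for %d x %d",
      nrow(image), ncol(image), system$rows, system$cols
    ))
  }
  fhat <- fft2(image)
  coeffs <- lapply(system$filters, function(filt) ifft2(fhat * filt))
  structure(list(
    coeffs = coeffs,
    magnitude = lapply(coeffs, Mod),
    phase = lapply(coeffs, Arg),
    lowpass = Re(ifft2(fhat * system$lowpass)),
    index = system$index,
    rows = system$rows, cols = system$cols,
    scales = system$scales,
    directions_per_scale = system$directions_per_scale
  ), class = "shearlet_coeffs")
}

#' @export
print.shearlet_coeffs <- function(x, ...) {
  cat(sprintf(
    "Shearlet coefficients: %d sub-bands of %d x %d (%d scales x %d directions)\n",
    length(x$coeffs), x$rows, x$cols, x$scales, x$directions_per_scale
  ))
  invisible(x)
}

#' Reconstruct an image from its shearlet coefficients
#'
#' Uses the tight-frame property of the system: the frequency responses of
#' all sub-band filters plus the low-pass filter square-sum to one, so
#' summing the refiltered sub-bands and taking the real part recovers the
#' original image to numerical tolerance.
#'
#' @param coeffs A `shearlet_coeffs` object produced by
#'   [shearlet_transform()] with the same system (the low-pass band must be
#'   present).
#' @param system The [shearlet_system()] used for the forward transform.
#' @return The reconstructed image matrix.
#' @export
inverse_shearlet_transform <- function(coeffs, system) {
  stopifnot(inherits(coeffs, "shearlet_coeffs"),
            inherits(system, "shearlet_system"))
  if (length(coeffs$coeffs) != length(system$filters)) {
    stop(sprintf(
      "coefficient stack has %d sub-bands but the system defines %d",
      length(coeffs$coeffs), length(system$filters)
    ))
  }
  if (is.null(coeffs$lowpass)) {
    stop("coefficient stack is missing the low-pass band; cannot reconstruct")
  }
  acc <- fft2(coeffs$lowpass) * system$lowpass
  for (b in seq_along(system$filters)) {
    acc <- acc + fft2(coeffs$coeffs[[b]]) * system$filters[[b]]
  }
  Re(ifft2(acc))
}

# wrap angles to (-pi, pi]
wrap_angle <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Relative phase of a shearlet phase stack
#'
#' The relative phase (RP) at position (i, j) is the wrapped difference
#' between the phase and that of its neighbor along the direction matched to
#' the sub-band's frequency cone: for directions `k <= K/2` (horizontal
#' cone) the neighbor is the next column (i, j+1); for `k > K/2` (vertical
#' cone) the next row (i+1, j).  The neighbor at the last column (row) is
#' taken circularly so the RP sub-band keeps the full image shape.  Raw
#' differences in \eqn{(-2\pi, 2\pi)} are wrapped to \eqn{(-\pi, \pi]}, so
#' RP is a proper angle and is invariant under a global phase shift.
#'
#' @param phase_stack List of phase matrices (values in \eqn{(-\pi, \pi]}),
#'   one per sub-band in canonical order, e.g. the `phase` element of a
#'   `shearlet_coeffs` object, or the object itself.
#' @param directions_per_scale Directions per scale K used to assign each
#'   sub-band to a cone (taken from the object when one is supplied).
#' @return List of RP matrices with the same shapes and ordering.
#' @export
relative_phase <- function(phase_stack, directions_per_scale = NULL) {
  if (inherits(phase_stack, "shearlet_coeffs")) {
    directions_per_scale <- phase_stack$directions_per_scale
    phase_stack <- phase_stack$phase
  }
  stopifnot(is.list(phase_stack), !is.null(directions_per_scale))
  K <- directions_per_scale
  stopifnot(length(phase_stack) %% K == 0)
  lapply(seq_along(phase_stack), function(b) {
    theta <- phase_stack[[b]]
    k <- (b - 1) %% K + 1
    neighbor <- if (k <= K / 2) {
      theta[, c(seq_len(ncol(theta))[-1], 1), drop = FALSE]
    } else {
      theta[c(seq_len(nrow(theta))[-1], 1), , drop = FALSE]
    }
    wrap_angle(theta - neighbor)
  })
}

#' Magnitude and relative-phase component stacks
#'
#' Convenience accessor returning the two real-valued stacks descriptors are
#' computed from: the coefficient magnitudes and the relative phase.
#'
#' @param coeffs A `shearlet_coeffs` object.
#' @return Named list with elements `magnitude` and `rp`, each a list of
#'   real matrices in canonical sub-band order.
#' @export
component_stacks <- function(coeffs) {
  stopifnot(inherits(coeffs, "shearlet_coeffs"))
  list(magnitude = coeffs$magnitude, rp = relative_phase(coeffs))
}
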