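#' @keywords internal
"_PACKAGE"

# Meyer auxiliary polynomial: smooth 0->1 ramp with nu(x) + nu(1-x) = 1,
# so cos(pi/2*nu)^2 + sin(pi/2*nu)^2 partitions of unity are exact.
meyer_ramp <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
}

# DFT frequency axis in cycles/pixel, in [-0.5, 0.5)
fft_freqs <- function(n) {
  f <- (seq_len(n) - 1) / n
  f[f >= 0.5] <- f[f >= 0.5] - 1
  f
}

#' Build a cone-adapted complex shearlet system
#'
#' Constructs a band-limited directional filter bank in the frequency domain:
#' Meyer-type radial windows split the spectrum into `scales` dyadic bands
#' (plus a residual low-pass), and Meyer-type angular windows split each band
#' into `directions_per_scale` orientation wedges grouped into a horizontal
#' and a vertical frequency cone.  Each directional filter is restricted to a
#' single frequency half-plane, so the spatial-domain coefficients are
#' complex-valued with a meaningful magnitude and phase (an analytic-signal
#' construction).  The squared windows are normalized to sum to one at every
#' frequency, which makes the system a tight frame: the inverse transform
#' reconstructs any image to floating-point accuracy.
#'
#' Sub-bands are ordered coarse-to-fine in scale; within a scale, directions
#' run through the horizontal cone first (orientation angles in
#' \eqn{[-45, 45)} degrees, ascending shear) and then the vertical cone
#' (\eqn{[45, 135)} degrees), so directions `1..K/2` belong to the horizontal
#' cone and `K/2+1..K` to the vertical cone.  This ordering is fixed: every
#' concatenated feature vector downstream depends on it.
#'
#' @param rows,cols Image dimensions in pixels; both must be at least 32 and
#'   at least `2^(scales+1)` so the coarsest radial band is resolvable.
#' @param scales Number of radial scales S (default 4).
#' @param directions_per_scale Number of orientation wedges K per scale
#'   (default 8); must be even so the two cones get K/2 wedges each.
#' @return An object of class `shearlet_system`: a list with the directional
#'   frequency-domain `filters` (length `scales * directions_per_scale`), the
#'   real `lowpass` filter, the `index` data frame (scale, direction,
#'   orientation in degrees, cone), and the image shape.
#' @examples
#' sys <- shearlet_system(64, 64)
#' nrow(sys$index)  # 32 directional sub-bands
#' @export
shearlet_system <- function(rows, cols, scales = 4, directions_per_scale = 8) {
  stopifnot(length(rows) == 1, length(cols) == 1, length(scales) == 1)
  if (scales < 1) stop("`scales` must be at least 1")
  K <- as.integer(directions_per_scale)
  if (K < 2 || K %% 2 != 0) {
    stop("`directions_per_scale` must be even and at least 2")
  }
  min_dim <- 2^(scales + 1)
  if (rows < 32 || cols < 32 || min(rows, cols) < min_dim) {
    stop(sprintf(
      "image of %d x %d too small for %d scales: need at least %d x %d",
      rows, cols, scales, max(32, min_dim), max(32, min_dim)
    ))
  }

  fx <- matrix(fft_freqs(cols), nrow = rows, ncol = cols, byrow = TRUE)
  fy <- matrix(fft_freqs(rows), nrow = rows, ncol = cols)
  r <- sqrt(fx^2 + fy^2)
  beta <- atan2(fy, fx) %% pi   # orientation angle folded to [0, pi)

  # radial Meyer partition: knots t_s = 0.5 * 2^(s - S)
  knots <- 0.5 * 2^(seq(0, scales) - scales)
  edge_up <- function(r, a, b) sin(pi / 2 * meyer_ramp((r - a) / (b - a)))
  edge_dn <- function(r, a, b) cos(pi / 2 * meyer_ramp((r - a) / (b - a)))
  w_low <- ifelse(r <= knots[1], 1, edge_dn(r, knots[1], knots[2]))
  w_band <- vector("list", scales)
  for (s in seq_len(scales)) {
    up <- edge_up(r, knots[s], knots[s + 1])
    up[r < knots[s]] <- 0
    if (s < scales) {
      dn <- edge_dn(r, knots[s + 1], knots[s + 2])
      dn[r < knots[s + 1]] <- 1
      dn[r > knots[s + 2]] <- 0
      w_band[[s]] <- up * dn
    } else {
      up[r >= knots[s + 1]] <- 1   # finest band covers spectrum corners
      w_band[[s]] <- up
    }
  }

  # angular Meyer windows, period pi; centers laid out so directions 1..K/2
  # tile the horizontal cone and K/2+1..K the vertical cone
  centers <- (-pi / 4 + (seq_len(K) - 0.5) * pi / K) %% pi
  delta <- pi / K
  v_ang <- vector("list", K)
  for (k in seq_len(K)) {
    d <- (beta - centers[k] + pi / 2) %% pi - pi / 2
    v <- cos(pi / 2 * meyer_ramp(abs(d) / delta))
    v[abs(d) >= delta] <- 0
    v_ang[[k]] <- v
  }

  # half-plane mask: 1 on one member of each conjugate frequency pair,
  # 1/2 on self-conjugate frequencies, so Re() reconstruction is exact
  selfx <- fx == 0 | (cols %% 2 == 0 & fx == -0.5)
  selfy <- fy == 0 | (rows %% 2 == 0 & fy == -0.5)
  hmask <- ifelse(!selfx, as.numeric(fx > 0),
                  ifelse(!selfy, as.numeric(fy > 0), 0.5))

  idx <- expand.grid(direction = seq_len(K), scale = seq_len(scales))
  idx <- idx[, c("scale", "direction")]
  filters <- vector("list", nrow(idx))
  total <- w_low^2
  for (b in seq_len(nrow(idx))) {
    phi <- w_band[[idx$scale[b]]] * v_ang[[idx$direction[b]]]
    filters[[b]] <- phi
    total <- total + phi^2
  }
  norm <- sqrt(total)            # force exact tightness numerically
  w_low <- w_low / norm
  analytic <- sqrt(2 * hmask)
  for (b in seq_len(nrow(idx))) {
    filters[[b]] <- filters[[b]] / norm * analytic
  }

  ang <- centers[idx$direction]
  ang[ang >= 3 * pi / 4] <- ang[ang >= 3 * pi / 4] - pi
  idx$orientation_deg <- ang * 180 / pi
  idx$cone <- ifelse(idx$direction <= K / 2, "horizontal", "vertical")

  structure(list(
    filters = filters,
    lowpass = w_low,
    rows = as.integer(rows), cols = as.integer(cols),
    scales = as.integer(scales),
    directions_per_scale = K,
    index = idx
  ), class = "shearlet_system")
}

#' @export
print.shearlet_system <- function(x, ...) {
  cat(sprintf(
    "Complex shearlet system: %d x %d image, %d scales x %d directions = %d sub-bands (+ low-pass)\n",
    x$rows, x$cols, x$scales, x$directions_per_scale, length(x$filters)
  ))
  invisible(x)
}

#' Number of directional sub-bands of a shearlet system
#' @param system A `shearlet_system`.
#' @return Integer count `scales * directions_per_scale`.
#' @export
n_subbands <- function(system) {
  stopifnot(inherits(system, "shearlet_system"))
  length(system$filters)
}
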