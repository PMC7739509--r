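# shifted view of x at (dr, dc) relative to the interior window
shift_view <- function(x, dr, dc, margin) {
  nr <- nrow(x); nc <- ncol(x)
  x[(1 + margin + dr):(nr - margin + dr),
    (1 + margin + dc):(nc - margin + dc), drop = FALSE]
}

# neighbor values at radius r, angle a, bilinear interpolation on the
# interior window (margin = ceiling(r))
lbp_neighbor <- function(x, r, a, margin) {
  dc <- r * cos(a); dr <- -r * sin(a)
  if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
  if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
  fr <- floor(dr); fc <- floor(dc)
  wr <- dr - fr; wc <- dc - fc
  if (abs(wr) < 1e-9 && abs(wc) < 1e-9) {
    return(shift_view(x, round(dr), round(dc), margin))
  }
  (1 - wr) * (1 - wc) * shift_view(x, fr, fc, margin) +
    (1 - wr) * wc * shift_view(x, fr, fc + 1, margin) +
    wr * (1 - wc) * shift_view(x, fr + 1, fc, margin) +
    wr * wc * shift_view(x, fr + 1, fc + 1, margin)
}

#' Rotation-invariant uniform local binary pattern histogram
#'
#' For every interior pixel, thresholds the `p` circular neighbors at radius
#' `r` (bilinear interpolation at non-integer positions) against the center
#' value with the step rule `s(x) = 1` iff `x >= 0`, maps the code to the
#' rotation-invariant uniform (riu2) label -- the number of set bits for
#' uniform codes (at most two 0/1 transitions around the circle), a single
#' catch-all label otherwise -- and accumulates the labels into a normalized
#' histogram of length `p + 2`.
#'
#' A relative tolerance of 1e-10 is applied to the `>= 0` comparison so
#' interpolation round-off on locally constant neighborhoods cannot flip a
#' bit; exact ties still take the 1 branch.
#'
#' Statistics are computed over interior pixels only (a border of width
#' `ceiling(r)` is excluded), so no padding values are invented.
#'
#' @param band Numeric matrix; both dimensions must exceed `2 r + 1`.
#' @param p Number of circular neighbors (default 8).
#' @param r Neighborhood radius in pixels (default 2).
#' @return Numeric vector of length `p + 2` summing to 1: bins for riu2
#'   labels `0..p` followed by the non-uniform bin.
#' @export
lbp_riu2 <- function(band, p = 8, r = 2) {
  stopifnot(is.matrix(band), p >= 4, r >= 1)
  margin <- ceiling(r)
  if (nrow(band) <= 2 * r + 1 || ncol(band) <= 2 * r + 1) {
    stop(sprintf("sub-band %d x %d too small for LBP radius %g",
                 nrow(band), ncol(band), r))
  }
  center <- shift_view(band, 0, 0, margin)
  tol <- 1e-10 * (1 + abs(center))
  bits <- vector("list", p)
  for (q in seq_len(p)) {
    nb <- lbp_neighbor(band, r, 2 * pi * (q - 1) / p, margin)
    bits[[q]] <- (nb - center) >= -tol
  }
  ones <- Reduce(`+`, bits)
  trans <- matrix(0, nrow(center), ncol(center))
  for (q in seq_len(p)) {
    trans <- trans + (bits[[q]] != bits[[q %% p + 1]])
  }
  label <- ifelse(trans <= 2, ones, p + 1)
  h <- tabulate(as.vector(label) + 1L, nbins = p + 2)
  h / sum(h)
}
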