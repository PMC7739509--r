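#' Local oriented statistics information booster (LOSIB)
#'
#' For each of the `p` neighbor directions at radius `r`, computes the mean
#' over all interior center pixels of the absolute difference between the
#' center coefficient and its neighbor, \eqn{\mu_p = \sum |SH_c - SH_p| /
#' (M N)}, giving one oriented roughness statistic per direction.
#'
#' With the defaults `r = 1, p = 8`, the neighbors are the eight integer
#' grid offsets (east, north-east, north, ... counter-clockwise), so no
#' interpolation is involved.  Centers are interior pixels only (border of
#' width `ceiling(r)` excluded).
#'
#' @param band Numeric matrix at least 3 x 3.
#' @param p Number of neighbor directions (default 8).
#' @param r Neighborhood radius in pixels (default 1).
#' @return Numeric vector of length `p`; entries are non-negative and scale
#'   linearly with the input.
#' @export
losib <- function(band, p = 8, r = 1) {
  stopifnot(is.matrix(band), p >= 1, r >= 1)
  margin <- ceiling(r)
  if (nrow(band) < 2 * margin + 1 || ncol(band) < 2 * margin + 1) {
    stop(sprintf("sub-band %d x %d too small for LOSIB radius %g",
                 nrow(band), ncol(band), r))
  }
  center <- shift_view(band, 0, 0, margin)
  out <- numeric(p)
  for (q in seq_len(p)) {
    a <- 2 * pi * (q - 1) / p
    dc <- round(r * cos(a)); dr <- round(-r * sin(a))
    out[q] <- mean(abs(center - shift_view(band, dr, dc, margin)))
  }
  out
}
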