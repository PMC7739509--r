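# Otsu threshold restricted to histogram bins lo..hi (0-based levels).
# Returns the level t (lo <= t < hi) maximizing between-class variance of
# the split (<= t vs > t), or NA when the restricted histogram is empty or
# concentrated in one bin.
otsu_range <- function(hist256, lo, hi) {
  if (hi <= lo) return(NA_integer_)
  h <- as.numeric(hist256[(lo + 1):(hi + 1)])
  tot <- sum(h)
  if (tot == 0) return(NA_integer_)
  lv <- lo:hi
  w0 <- cumsum(h)[-length(h)]
  w1 <- tot - w0
  m0 <- cumsum(h * lv)[-length(h)]
  mt <- sum(h * lv)
  valid <- w0 > 0 & w1 > 0
  if (!any(valid)) return(NA_integer_)
  bc <- rep(-Inf, length(w0))
  bc[valid] <- (mt * w0[valid] - tot * m0[valid])^2 /
    (w0[valid] * w1[valid])
  lv[which.max(bc)]
}

# Multi-level Otsu via recursive splitting: pick the Otsu threshold of the
# current level range, then recurse into the two halves with the remaining
# threshold budget split evenly.  Returns a sorted vector of `n` levels;
# degenerate ranges are padded with 255 (producing empty binary sets).
otsu_multilevel <- function(hist256, n) {
  rec <- function(lo, hi, k) {
    if (k < 1 || hi <= lo) return(integer(0))
    t <- otsu_range(hist256, lo, hi)
    if (is.na(t)) return(integer(0))
    nl <- (k - 1) %/% 2
    nr <- k - 1 - nl
    c(rec(lo, t, nl), t, rec(t + 1, hi, nr))
  }
  th <- rec(0L, 255L, n)
  if (length(th) < n) th <- c(th, rep(255L, n - length(th)))
  sort(th)
}

#' Two-threshold binary decomposition (TTBD)
#'
#' Rescales the sub-band to 256 integer gray levels, finds `nt` thresholds
#' with multi-level Otsu, and forms `2 nt - 1` binary images: one upper set
#' `{band > t_i}` per threshold and one band-pass set `{t_i < band <=
#' t_{i+1}}` per consecutive threshold pair.  A constant sub-band has no
#' meaningful thresholds and falls back to all-empty binaries rather than
#' failing.
#'
#' @param band Numeric matrix.
#' @param nt Number of thresholds (default 4, giving 7 binary images).
#' @return List with `binaries` (list of logical matrices, upper sets then
#'   band-pass sets), `gray` (the 0..255 rescaled integer image) and
#'   `thresholds`.
#' @export
ttbd <- function(band, nt = 4) {
  stopifnot(is.matrix(band), nt >= 2)
  if (!all(is.finite(band))) stop("sub-band contains non-finite values")
  rng <- max(band) - min(band)
  if (rng == 0) {
    gray <- matrix(0L, nrow(band), ncol(band))
    empty <- matrix(FALSE, nrow(band), ncol(band))
    return(list(binaries = rep(list(empty), 2 * nt - 1),
                gray = gray, thresholds = rep(255L, nt)))
  }
  gray <- matrix(as.integer(round((band - min(band)) / rng * 255)),
                 nrow(band), ncol(band))
  th <- otsu_multilevel(tabulate(gray + 1L, nbins = 256), nt)
  upper <- lapply(th, function(t) gray > t)
  bandpass <- lapply(seq_len(nt - 1), function(i) {
    gray > th[i] & gray <= th[i + 1]
  })
  list(binaries = c(upper, bandpass), gray = gray, thresholds = th)
}

# border of a binary region: set pixels with at least one unset 4-neighbor
# (out-of-image neighbors count as unset)
region_border <- function(b) {
  nr <- nrow(b); nc <- ncol(b)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- b
  interior <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  b & !interior
}

#' Box-counting fractal dimension of a binary image
#'
#' Counts occupied boxes on dyadic grids of side 1, 2, 4, ... up to half
#' the smaller image dimension and returns the least-squares slope of
#' `log(count)` against `log(1/size)`.  An empty image has dimension 0.
#'
#' @param b Logical matrix.
#' @return Estimated box-counting dimension (non-negative scalar).
#' @export
box_counting_dimension <- function(b) {
  stopifnot(is.matrix(b))
  idx <- which(b)
  if (length(idx) == 0) return(0)
  nr <- nrow(b)
  rr <- (idx - 1L) %% nr
  cc <- (idx - 1L) %/% nr
  emax <- min(nr, ncol(b)) %/% 2
  sizes <- 1L
  while (tail(sizes, 1) * 2L <= emax) sizes <- c(sizes, tail(sizes, 1) * 2L)
  if (length(sizes) < 2) return(0)
  counts <- vapply(sizes, function(e) {
    length(unique((rr %/% e) * 1e6 + (cc %/% e)))
  }, numeric(1))
  x <- log(1 / sizes)
  y <- log(counts)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# the three SFTA attributes of one binary region
sfta_region_features <- function(binary, gray) {
  stopifnot(all(dim(binary) == dim(gray)))
  if (!any(binary)) return(c(0, 0, 0))
  c(box_counting_dimension(region_border(binary)),
    mean(gray[binary]),
    sum(binary))
}

#' Segmentation-based fractal texture analysis (SFTA) of one sub-band
#'
#' Decomposes the sub-band into `2 nt - 1` binary images via [ttbd()] and
#' summarizes each by three attributes: the box-counting fractal dimension
#' of the region border, the mean gray level (on the 0..255 rescaled scale)
#' over the region, and the region pixel count.  With the default `nt = 4`
#' this yields a 21-element vector per sub-band.
#'
#' @param band Numeric matrix.
#' @param nt Number of TTBD thresholds (default 4).
#' @return Numeric vector of length `3 (2 nt - 1)`, ordered per binary
#'   image as (fractal dimension, mean level, pixel count).
#' @export
sfta <- function(band, nt = 4) {
  dec <- ttbd(band, nt)
  unlist(lapply(dec$binaries, sfta_region_features, gray = dec$gray),
         use.names = FALSE)
}
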