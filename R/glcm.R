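#' Quantize a sub-band into discrete gray levels
#'
#' Min-max rescales the sub-band and bins it uniformly into `1..ng`.  A
#' constant sub-band (zero range) maps entirely to level 1.
#'
#' @param band Numeric matrix (one magnitude or relative-phase sub-band).
#' @param ng Number of levels (default 8).
#' @return Integer matrix with entries in `1..ng`.
#' @export
quantize_subband <- function(band, ng = 8) {
  stopifnot(is.matrix(band), ng >= 2)
  if (!all(is.finite(band))) stop("sub-band contains non-finite values")
  rng <- max(band) - min(band)
  if (rng == 0) {
    return(matrix(1L, nrow(band), ncol(band)))
  }
  lev <- floor((band - min(band)) / rng * ng) + 1
  mode(lev) <- "integer"
  pmin(lev, as.integer(ng))
}

# co-occurrence counts for one (dr, dc) offset, symmetrized
glcm_offset <- function(q, ng, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  rows <- seq_len(nr - abs(dr)); cols <- seq_len(nc - abs(dc))
  r1 <- if (dr < 0) rows - dr else rows
  c1 <- if (dc < 0) cols - dc else cols
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(0, ng, ng)
  tab <- tabulate((a - 1L) * ng + b, nbins = ng * ng)
  counts[] <- matrix(tab, ng, ng, byrow = TRUE)
  counts + t(counts)
}

#' Orientation-averaged gray-level co-occurrence matrix
#'
#' Computes four symmetric co-occurrence matrices at orientations 0, 45, 90
#' and 135 degrees with a fixed pixel distance, normalizes each, and
#' averages them entrywise.  Averaging over the four orientations makes the
#' derived statistics rotation invariant.
#'
#' @param q Integer matrix from [quantize_subband()].
#' @param ng Number of gray levels (defaults to `max(q)` coverage, i.e. the
#'   quantizer's level count; pass explicitly when the top level is empty).
#' @param pd Pixel distance of the co-occurrence offset (default 1).
#' @return Object of class `cooc_matrix`: the `ng` x `ng` relative-frequency
#'   matrix `p` (entries sum to 1, symmetric) plus the offset parameters.
#' @export
cooccurrence_mean <- function(q, ng = max(q), pd = 1) {
  stopifnot(is.matrix(q), min(q) >= 1, pd >= 1)
  if (nrow(q) <= pd || ncol(q) <= pd) {
    stop(sprintf("sub-band %d x %d too small for co-occurrence distance %d",
                 nrow(q), ncol(q), pd))
  }
  ng <- as.integer(ng)
  offsets <- list(c(0, pd), c(-pd, pd), c(-pd, 0), c(-pd, -pd))
  acc <- matrix(0, ng, ng)
  for (off in offsets) {
    counts <- glcm_offset(q, ng, off[1], off[2])
    acc <- acc + counts / sum(counts)
  }
  p <- acc / sum(acc)
  structure(list(p = p, ng = ng, distance = pd,
                 orientations = c(0, 45, 90, 135)),
            class = "cooc_matrix")
}

haralick_stat_names <- c(
  "contrast", "correlation", "energy", "autocorrelation",
  "cluster_prominence", "cluster_shade", "dissimilarity", "entropy",
  "homogeneity", "max_probability", "sum_of_squares", "variance",
  "sum_average", "sum_variance", "sum_entropy", "difference_variance",
  "difference_entropy", "imc", "idn", "idmn"
)

#' Twenty Haralick-style statistics of a co-occurrence matrix
#'
#' Returns, in fixed order: contrast, correlation, energy, autocorrelation,
#' cluster prominence, cluster shade, dissimilarity, entropy, homogeneity,
#' maximum probability, sum of squares, variance, sum average, sum variance,
#' sum entropy, difference variance, difference entropy, information measure
#' of correlation, inverse difference normalized, and inverse difference
#' moment normalized.  Natural logarithms are used and `0 log 0 = 0`.
#' Statistics with a variance or entropy denominator (correlation, the
#' information measure) return 0 when the denominator vanishes, so the
#' output is always finite -- a constant sub-band is a legitimate input.
#'
#' Sum of squares is taken about the co-occurrence mean level
#' \eqn{\mu = (\mu_x + \mu_y)/2} and variance is the marginal row-level
#' variance; on symmetric matrices (the only kind produced here) the two
#' coincide, but both are kept as separate named entries of the
#' twenty-statistic contract.
#'
#' @param cm A `cooc_matrix` from [cooccurrence_mean()], or a plain
#'   normalized matrix.
#' @return Named numeric vector of length 20; all values finite.
#' @export
haralick20 <- function(cm) {
  p <- if (inherits(cm, "cooc_matrix")) cm$p else cm
  stopifnot(is.matrix(p), nrow(p) == ncol(p))
  if (abs(sum(p) - 1) > 1e-8) {
    stop("co-occurrence matrix must be normalized to sum 1")
  }
  ng <- nrow(p)
  lev <- seq_len(ng)
  II <- matrix(lev, ng, ng)
  JJ <- matrix(lev, ng, ng, byrow = TRUE)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sdx <- sqrt(sum((lev - mux)^2 * px)); sdy <- sqrt(sum((lev - muy)^2 * py))
  plogp <- function(v) { v <- v[v > 0]; -sum(v * log(v)) }

  # index-sum and index-difference marginals
  psum <- tapply(as.vector(p), as.vector(II + JJ), sum)   # k = 2..2*ng
  ks <- as.numeric(names(psum))
  pdiff <- tapply(as.vector(p), as.vector(abs(II - JJ)), sum)  # k = 0..ng-1
  kd <- as.numeric(names(pdiff))

  entropy <- plogp(p)
  hx <- plogp(px); hy <- plogp(py)
  pos <- p > 0
  hxy1 <- -sum(p[pos] * log((px[II])[pos] * (py[JJ])[pos]))
  mu_cm <- (mux + muy) / 2
  sum_avg <- sum(ks * psum)
  diff_avg <- sum(kd * pdiff)

  out <- c(
    contrast = sum((II - JJ)^2 * p),
    correlation = if (sdx * sdy > 0)
      sum((II - mux) * (JJ - muy) * p) / (sdx * sdy) else 0,
    energy = sum(p^2),
    autocorrelation = sum(II * JJ * p),
    cluster_prominence = sum((II + JJ - mux - muy)^4 * p),
    cluster_shade = sum((II + JJ - mux - muy)^3 * p),
    dissimilarity = sum(abs(II - JJ) * p),
    entropy = entropy,
    homogeneity = sum(p / (1 + abs(II - JJ))),
    max_probability = max(p),
    sum_of_squares = sum((II - mu_cm)^2 * p),
    variance = sum((lev - mux)^2 * px),
    sum_average = sum_avg,
    sum_variance = sum((ks - sum_avg)^2 * psum),
    sum_entropy = plogp(psum),
    difference_variance = sum((kd - diff_avg)^2 * pdiff),
    difference_entropy = plogp(pdiff),
    imc = if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0,
    idn = sum(p / (1 + abs(II - JJ) / ng)),
    idmn = sum(p / (1 + (II - JJ)^2 / ng^2))
  )
  out
}
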