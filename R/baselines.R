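# Baseline shearlet-domain descriptor sets from the comparison literature,
# computed on the same coefficient stacks as the main descriptors so all
# methods share the transform and evaluation machinery.

#' Circular-statistics baseline (Vo-style)
#'
#' Per sub-band: the circular mean and circular variance of the
#' relative-phase values plus the mean of the magnitude values,
#' concatenated over sub-bands (3 x 32 = 96 features for the default
#' system).  The circular variance is one minus the mean resultant length,
#' so it lies in [0, 1].
#'
#' @param coeffs A `shearlet_coeffs` object.
#' @return A `feature_block` with descriptor tag `"vo"`.
#' @export
vo_features <- function(coeffs) {
  stopifnot(inherits(coeffs, "shearlet_coeffs"))
  stacks <- component_stacks(coeffs)
  vals <- unlist(lapply(seq_along(stacks$rp), function(b) {
    z <- mean(exp(1i * stacks$rp[[b]]))
    c(Arg(z), 1 - Mod(z), mean(stacks$magnitude[[b]]))
  }), use.names = FALSE)
  names(vals) <- block_names("vo", "both", coeffs$index,
                             c("circmean", "circvar", "magmean"))
  new_feature_block("vo", "both", vals)
}

#' Co-occurrence/magnitude product baseline (Meshkini-style)
#'
#' The entrywise product of each magnitude sub-band's co-occurrence matrix
#' with a matched reduction of the magnitude coefficients, sharing the
#' [cmdot_features()] construction.
#'
#' @param coeffs A `shearlet_coeffs` object.
#' @param ng Quantization levels (default 8).
#' @return A `feature_block` with descriptor tag `"meshkini"`.
#' @export
meshkini_features <- function(coeffs, ng = 8) {
  stopifnot(inherits(coeffs, "shearlet_coeffs"))
  blk <- cmdot_features(coeffs$magnitude, "magnitude", coeffs$index, ng = ng)
  names(blk$values) <- sub("^cmdot\\.", "meshkini.", names(blk$values))
  new_feature_block("meshkini", "magnitude", blk$values)
}

#' Layer-selective co-occurrence/statistics baseline (Zhou-style)
#'
#' Three concatenated parts computed from the magnitude stack only:
#' (1) entropy, correlation, contrast and energy of the co-occurrence
#' matrix of every first-scale sub-band in the horizontal cone; (2) mean,
#' variance and energy (mean square) of every sub-band in scales 1 and 3
#' of both cones; (3) the per-column maxima of every finest-scale
#' (high-frequency) sub-band.
#'
#' @param coeffs A `shearlet_coeffs` object.
#' @param ng Quantization levels for part (1) (default 8).
#' @return A `feature_block` with descriptor tag `"zhou"`.
#' @export
zhou_features <- function(coeffs, ng = 8) {
  stopifnot(inherits(coeffs, "shearlet_coeffs"))
  idx <- coeffs$index
  mag <- coeffs$magnitude
  K <- coeffs$directions_per_scale

  part1 <- lapply(which(idx$scale == 1 & idx$direction <= K / 2), function(b) {
    h <- haralick20(cooccurrence_mean(quantize_subband(mag[[b]], ng), ng = ng))
    v <- h[c("entropy", "correlation", "contrast", "energy")]
    names(v) <- paste("zhou.cm", paste0("s1.k", idx$direction[b]),
                      names(v), sep = ".")
    v
  })
  sel2 <- which(idx$scale %in% c(1, 3))
  part2 <- lapply(sel2, function(b) {
    x <- mag[[b]]
    v <- c(mean = mean(x), variance = stats::var(as.vector(x)),
           energy = mean(x^2))
    names(v) <- paste("zhou.stat",
                      paste0("s", idx$scale[b], ".k", idx$direction[b]),
                      names(v), sep = ".")
    v
  })
  sel3 <- which(idx$scale == coeffs$scales)
  part3 <- lapply(sel3, function(b) {
    v <- apply(mag[[b]], 2, max)
    names(v) <- paste("zhou.colmax",
                      paste0("s", idx$scale[b], ".k", idx$direction[b]),
                      paste0("c", seq_along(v)), sep = ".")
    v
  })
  vals <- c(unlist(part1), unlist(part2), unlist(part3))
  new_feature_block("zhou", "magnitude", vals)
}

#' First- and second-moment baseline (Dong-style)
#'
#' The mean and standard deviation of every magnitude sub-band,
#' concatenated (2 x 32 = 64 features for the default system).
#'
#' @param coeffs A `shearlet_coeffs` object.
#' @return A `feature_block` with descriptor tag `"dong"`.
#' @export
dong_features <- function(coeffs) {
  stopifnot(inherits(coeffs, "shearlet_coeffs"))
  vals <- unlist(lapply(coeffs$magnitude, function(x) {
    c(mean(x), stats::sd(as.vector(x)))
  }), use.names = FALSE)
  names(vals) <- block_names("dong", "magnitude", coeffs$index,
                             c("mean", "sd"))
  new_feature_block("dong", "magnitude", vals)
}

#' Baseline descriptor block by method name
#'
#' @param coeffs A `shearlet_coeffs` object.
#' @param method One of `"vo"`, `"meshkini"`, `"zhou"`, `"dong"`.
#' @param ... Passed to the method-specific function.
#' @return A `feature_block`.
#' @export
baseline_features <- function(coeffs,
                              method = c("vo", "meshkini", "zhou", "dong"),
                              ...) {
  method <- match.arg(method)
  switch(method,
         vo = vo_features(coeffs, ...),
         meshkini = meshkini_features(coeffs, ...),
         zhou = zhou_features(coeffs, ...),
         dong = dong_features(coeffs, ...))
}
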