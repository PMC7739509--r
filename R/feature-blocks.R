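new_feature_block <- function(descriptor, component, values) {
  structure(list(descriptor = descriptor, component = component,
                 values = values),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("Feature block %s.%s: %d features\n",
              x$descriptor, x$component, length(x$values)))
  invisible(x)
}

#' @export
length.feature_block <- function(x) length(x$values)

# names like "cm.magnitude.s2.k5.contrast" in canonical sub-band order
block_names <- function(descriptor, component, index, stats) {
  unlist(lapply(seq_len(nrow(index)), function(b) {
    paste(descriptor, component,
          paste0("s", index$scale[b]), paste0("k", index$direction[b]),
          stats, sep = ".")
  }))
}

stack_index <- function(stack, index) {
  if (nrow(index) != length(stack)) {
    stop(sprintf("stack has %d sub-bands but index describes %d",
                 length(stack), nrow(index)))
  }
  index
}

#' Co-occurrence (Haralick) features of a component stack
#'
#' Quantizes every sub-band, computes its orientation-averaged
#' co-occurrence matrix and extracts the 20 Haralick-style statistics,
#' concatenated in canonical sub-band order: 20 x 32 = 640 features per
#' component for the default 4 scales x 8 directions system.
#'
#' @param stack List of real sub-band matrices (magnitude or RP component)
#'   in canonical order.
#' @param component Component tag, `"magnitude"` or `"rp"`.
#' @param index Sub-band index data frame from the system or coefficients.
#' @param ng Number of quantization levels (default 8).
#' @param pd Co-occurrence pixel distance (default 1).
#' @return A `feature_block` with named values.
#' @export
cm_features <- function(stack, component, index, ng = 8, pd = 1) {
  index <- stack_index(stack, index)
  vals <- unlist(lapply(stack, function(band) {
    haralick20(cooccurrence_mean(quantize_subband(band, ng), ng = ng, pd = pd))
  }), use.names = FALSE)
  names(vals) <- block_names("cm", component, index, haralick_stat_names)
  new_feature_block("cm", component, vals)
}

#' Rotation-invariant uniform LBP features of a component stack
#'
#' One normalized (p+2)-bin riu2 histogram per sub-band, concatenated:
#' 10 x 32 = 320 features per component at the defaults.
#'
#' @inheritParams cm_features
#' @param p,r LBP neighborhood size and radius (defaults 8 and 2).
#' @return A `feature_block`.
#' @export
lbp_features <- function(stack, component, index, p = 8, r = 2) {
  index <- stack_index(stack, index)
  vals <- unlist(lapply(stack, lbp_riu2, p = p, r = r), use.names = FALSE)
  names(vals) <- block_names("lbp", component, index,
                             c(paste0("riu", 0:p), "nonuniform"))
  new_feature_block("lbp", component, vals)
}

#' LOSIB features of a component stack
#'
#' One p-vector of oriented mean absolute differences per sub-band,
#' concatenated: 8 x 32 = 256 features per component at the defaults.
#'
#' @inheritParams cm_features
#' @param p,r LOSIB neighborhood size and radius (defaults 8 and 1).
#' @return A `feature_block`.
#' @export
losib_features <- function(stack, component, index, p = 8, r = 1) {
  index <- stack_index(stack, index)
  vals <- unlist(lapply(stack, losib, p = p, r = r), use.names = FALSE)
  names(vals) <- block_names("losib", component, index, paste0("dir", 0:(p - 1)))
  new_feature_block("losib", component, vals)
}

#' SFTA features of a component stack
#'
#' 21 segmentation-based fractal texture attributes per sub-band at the
#' default `nt = 4`, concatenated: 21 x 32 = 672 features per component.
#'
#' @inheritParams cm_features
#' @param nt Number of TTBD thresholds (default 4).
#' @return A `feature_block`.
#' @export
sfta_features <- function(stack, component, index, nt = 4) {
  index <- stack_index(stack, index)
  vals <- unlist(lapply(stack, sfta, nt = nt), use.names = FALSE)
  stats <- paste0(rep(paste0("b", seq_len(2 * nt - 1)), each = 3),
                  c(".fractal", ".meanlevel", ".count"))
  names(vals) <- block_names("sfta", component, index, stats)
  new_feature_block("sfta", component, vals)
}

# block-mean reduction of a matrix to ng x ng
block_pool <- function(x, ng) {
  gr <- ceiling(seq_len(nrow(x)) * ng / nrow(x))
  gc <- ceiling(seq_len(ncol(x)) * ng / ncol(x))
  sums <- rowsum(t(rowsum(x, gr)), gc)
  cnts <- tabulate(gr, ng) %o% tabulate(gc, ng)
  t(sums) / cnts
}

# Hadamard product of a sub-band's co-occurrence matrix with the ng x ng
# block-mean reduction of its magnitude, summarized by column maxima.
cmdot_subband <- function(band, ng, pd) {
  cm <- cooccurrence_mean(quantize_subband(band, ng), ng = ng, pd = pd)
  had <- cm$p * block_pool(band, ng)
  unname(apply(had, 2, max))
}

#' Co-occurrence/magnitude inner-product (CM-dot) features
#'
#' Auxiliary descriptor pairing each magnitude sub-band's co-occurrence
#' matrix with the sub-band itself: the co-occurrence matrix is multiplied
#' entrywise with an `ng` x `ng` block-mean reduction of the magnitude
#' coefficients, and the product matrix is summarized by its column maxima,
#' giving `ng` deterministic features per sub-band (256 over 32 sub-bands
#' at the defaults).  The published description of this construction fixes
#' only the "inner product" idea; the block-mean reduction and column-max
#' summary are this package's documented concrete choice (see the methods
#' vignette).  Defined for the magnitude component only.
#'
#' @inheritParams cm_features
#' @param ng Quantization levels and output length per sub-band (default 8).
#' @param pd Co-occurrence distance (default 1).
#' @return A `feature_block` with `ng` features per sub-band.
#' @export
cmdot_features <- function(stack, component = "magnitude", index,
                           ng = 8, pd = 1) {
  if (!identical(component, "magnitude")) {
    stop("cmdot features are defined for the magnitude component only")
  }
  index <- stack_index(stack, index)
  vals <- unlist(lapply(stack, cmdot_subband, ng = ng, pd = pd),
                 use.names = FALSE)
  names(vals) <- block_names("cmdot", component, index,
                             paste0("colmax", seq_len(ng)))
  new_feature_block("cmdot", component, vals)
}

#' All requested texture descriptor blocks of one coefficient stack
#'
#' Computes the selected descriptor families on the selected components of
#' a shearlet decomposition.  The CM-dot descriptor is magnitude-only and
#' is added when requested regardless of the component selection.
#'
#' @param coeffs A `shearlet_coeffs` object.
#' @param descriptors Character subset of
#'   `c("cm", "lbp", "losib", "sfta", "cmdot")`.
#' @param components Character subset of `c("magnitude", "rp")`.
#' @param ng Quantization levels for CM and CM-dot (default 8).
#' @param nt SFTA threshold count (default 4).
#' @return Named list of `feature_block`s keyed `descriptor.component`.
#' @export
texture_blocks <- function(coeffs,
                           descriptors = c("cm", "lbp", "losib", "sfta"),
                           components = c("magnitude", "rp"),
                           ng = 8, nt = 4) {
  stopifnot(inherits(coeffs, "shearlet_coeffs"))
  descriptors <- match.arg(descriptors,
                           c("cm", "lbp", "losib", "sfta", "cmdot"),
                           several.ok = TRUE)
  components <- match.arg(components, c("magnitude", "rp"),
                          several.ok = TRUE)
  stacks <- component_stacks(coeffs)
  out <- list()
  for (comp in components) {
    stack <- stacks[[comp]]
    for (d in setdiff(descriptors, "cmdot")) {
      blk <- switch(d,
        cm = cm_features(stack, comp, coeffs$index, ng = ng),
        lbp = lbp_features(stack, comp, coeffs$index),
        losib = losib_features(stack, comp, coeffs$index),
        sfta = sfta_features(stack, comp, coeffs$index, nt = nt)
      )
      out[[paste(d, comp, sep = ".")]] <- blk
    }
  }
  if ("cmdot" %in% descriptors) {
    out[["cmdot.magnitude"]] <- cmdot_features(
      stacks$magnitude, "magnitude", coeffs$index, ng = ng
    )
  }
  out
}
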