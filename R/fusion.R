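fusion_block_order <- c("cm", "lbp", "losib", "sfta", "cmdot")

#' Declare a descriptor fusion recipe
#'
#' A fusion specification names which descriptor blocks from the
#' relative-phase component and which from the magnitude component are
#' concatenated into one feature vector.  Three recipes are predefined:
#'
#' * `fusion1`: CM + LBP + LOSIB + SFTA from both components (3776 columns
#'   at the default system configuration),
#' * `fusion2`: CM + LOSIB from both components (1792 columns),
#' * `fusion3`: CM + LBP + LOSIB from RP plus CM + LBP + SFTA + CM-dot from
#'   magnitude.
#'
#' @param name `"fusion1"`, `"fusion2"`, `"fusion3"` or `"custom"`.
#' @param components For `fusion1`/`fusion2`, which components to draw from
#'   (default both).
#' @param rp_blocks,mag_blocks For `"custom"`: descriptor tags drawn from
#'   the RP and magnitude components.
#' @return Object of class `fusion_spec`.
#' @export
fusion_spec <- function(name = c("fusion1", "fusion2", "fusion3", "custom"),
                        components = c("rp", "magnitude"),
                        rp_blocks = NULL, mag_blocks = NULL) {
  name <- match.arg(name)
  components <- match.arg(components, c("rp", "magnitude"), several.ok = TRUE)
  if (name == "fusion1") {
    fams <- c("cm", "lbp", "losib", "sfta")
    rp_blocks <- if ("rp" %in% components) fams else character()
    mag_blocks <- if ("magnitude" %in% components) fams else character()
  } else if (name == "fusion2") {
    fams <- c("cm", "losib")
    rp_blocks <- if ("rp" %in% components) fams else character()
    mag_blocks <- if ("magnitude" %in% components) fams else character()
  } else if (name == "fusion3") {
    rp_blocks <- c("cm", "lbp", "losib")
    mag_blocks <- c("cm", "lbp", "sfta", "cmdot")
  } else {
    rp_blocks <- as.character(rp_blocks %||% character())
    mag_blocks <- as.character(mag_blocks %||% character())
  }
  if (length(rp_blocks) + length(mag_blocks) == 0) {
    stop("fusion spec selects no blocks")
  }
  bad <- setdiff(c(rp_blocks, mag_blocks), fusion_block_order)
  if (length(bad)) stop("unknown descriptor tags: ", paste(bad, collapse = ", "))
  structure(list(name = name,
                 rp_blocks = intersect(fusion_block_order, rp_blocks),
                 mag_blocks = intersect(fusion_block_order, mag_blocks)),
            class = "fusion_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fusion_spec <- function(x, ...) {
  cat(sprintf("Fusion spec '%s': RP blocks [%s], magnitude blocks [%s]\n",
              x$name, paste(x$rp_blocks, collapse = ", "),
              paste(x$mag_blocks, collapse = ", ")))
  invisible(x)
}

#' Concatenate per-sample descriptor blocks into a feature matrix
#'
#' Pure concatenation in a deterministic column order: RP blocks first,
#' then magnitude blocks, each component's blocks in CM, LBP, LOSIB, SFTA,
#' CM-dot order.  Every value is copied bit-for-bit from its source block.
#'
#' @param samples List with one element per sample; each element is a named
#'   list of `feature_block`s as returned by [texture_blocks()].
#' @param spec A [fusion_spec()].
#' @return Numeric matrix (samples x features) with unique column names.
#' @export
fuse <- function(samples, spec) {
  stopifnot(inherits(spec, "fusion_spec"), length(samples) >= 1)
  keys <- c(
    if (length(spec$rp_blocks)) paste(spec$rp_blocks, "rp", sep = "."),
    if (length(spec$mag_blocks)) paste(spec$mag_blocks, "magnitude", sep = ".")
  )
  rows <- lapply(seq_along(samples), function(i) {
    blocks <- samples[[i]]
    missing <- setdiff(keys, names(blocks))
    if (length(missing)) {
      stop(sprintf("sample %d is missing block(s): %s",
                   i, paste(missing, collapse = ", ")))
    }
    unlist(lapply(unname(blocks[keys]), function(b) b$values),
           use.names = TRUE)
  })
  x <- do.call(rbind, rows)
  rownames(x) <- NULL
  x
}

#' Fit a feature standardizer on training data
#'
#' Estimates per-column mean and standard deviation; zero-variance columns
#' are dropped (their names are kept in the fitted object and a warning is
#' raised).  Applying the fitted standardizer to any data uses the training
#' statistics only.
#'
#' @param train Numeric training matrix with column names.
#' @return Object of class `standardizer`.
#' @export
standardize_fit <- function(train) {
  stopifnot(is.matrix(train), nrow(train) >= 2)
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  drop <- sd == 0
  if (any(drop)) {
    warning(sprintf("dropping %d zero-variance feature column(s)", sum(drop)))
  }
  structure(list(mean = mu[!drop], sd = sd[!drop],
                 keep = colnames(train)[!drop],
                 dropped = colnames(train)[drop]),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param x Numeric matrix whose columns include the standardizer's kept
#'   columns.
#' @param s A `standardizer` from [standardize_fit()].
#' @return Matrix restricted to the kept columns, centered and scaled by
#'   the training statistics.
#' @export
standardize_apply <- function(x, s) {
  stopifnot(inherits(s, "standardizer"), is.matrix(x))
  if (!all(s$keep %in% colnames(x))) {
    stop("data is missing columns the standardizer was fitted on")
  }
  x <- x[, s$keep, drop = FALSE]
  sweep(sweep(x, 2, s$mean, "-"), 2, s$sd, "/")
}
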