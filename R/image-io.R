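#' Convert a raster to a single-channel image in [0, 1]
#'
#' RGB input is converted with Rec. 601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B); grayscale input is passed through.
#' Integer-coded input (0..255 or 0..65535) is rescaled to [0, 1].
#'
#' @param image Numeric matrix (grayscale) or 3-D array with 1 or 3 channels
#'   in the third dimension.  Values either already in [0, 1] or integer
#'   codes on an 8- or 16-bit scale.
#' @return Numeric matrix with values in [0, 1].
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) {
    gray <- image
  } else if (is.array(image) && length(dim(image)) == 3) {
    nc <- dim(image)[3]
    if (nc == 1) {
      gray <- image[, , 1]
    } else if (nc == 3) {
      gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    } else {
      stop(sprintf("unsupported channel count: %d (expected 1 or 3)", nc))
    }
  } else {
    stop("image must be a matrix or a 3-D array")
  }
  if (!all(is.finite(gray))) stop("image contains non-finite values")
  mx <- max(gray)
  if (mx > 1) {
    scale <- if (mx <= 255) 255 else 65535
    gray <- gray / scale
  }
  pmin(pmax(gray, 0), 1)
}

#' Read an image file as a grayscale matrix
#'
#' PNG and TIFF are read natively; JPEG is read through EBImage when that
#' package is available.  The result is converted with [to_grayscale()].
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return Numeric matrix with values in [0, 1].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE)) {
        stop("reading JPEG requires the EBImage package: ", path)
      }
      img <- EBImage::imageData(EBImage::readImage(path))
      # EBImage stores x as the first dimension; transpose to row = y
      if (length(dim(img)) == 3) aperm(img, c(2, 1, 3)) else t(img)
    },
    stop("unsupported image format '", ext, "': ", path)
  )
  # drop an alpha channel if present
  if (is.array(raw) && !is.matrix(raw) && dim(raw)[3] %in% c(2L, 4L)) {
    raw <- raw[, , seq_len(dim(raw)[3] - 1), drop = FALSE]
    if (dim(raw)[3] == 1) raw <- raw[, , 1]
  }
  to_grayscale(raw)
}

#' Load a folder-per-class image corpus
#'
#' Every subfolder of `root` is one class; its name is the class label.
#' Files and folders are visited in lexicographic order so repeated runs
#' produce the same sample ordering.
#'
#' @param root Directory containing one subfolder per class.
#' @param pattern Regular expression selecting image files (default: PNG,
#'   TIFF and JPEG extensions).
#' @return List with `images` (list of grayscale matrices), `labels`
#'   (factor) and `paths` (character).
#' @export
load_image_folder <- function(root,
                              pattern = "\\.(png|tiff?|jpe?g)$") {
  if (!dir.exists(root)) stop("no such directory: ", root)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop("no class subfolders under: ", root)
  paths <- character()
  labels <- character()
  for (cls in classes) {
    files <- sort(list.files(file.path(root, cls), pattern = pattern,
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("class folder contains no images: ", cls)
    paths <- c(paths, files)
    labels <- c(labels, rep(cls, length(files)))
  }
  images <- lapply(paths, function(p) {
    tryCatch(read_image(p), error = function(e) {
      stop("failed to read '", p, "': ", conditionMessage(e), call. = FALSE)
    })
  })
  list(images = images, labels = factor(labels, levels = classes),
       paths = paths)
}
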