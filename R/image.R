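#' Grayscale OCT B-scan image
#'
#' An `oct_image` is an `m x n` numeric matrix of intensities on a fixed
#' `[0, 255]` scale (rows = depth, increasing downward; columns = lateral
#' position). Inputs of any bit depth are rescaled to this range on load so
#' that intensity thresholds carry one fixed meaning across sources.
#'
#' @param x numeric matrix of intensities. Values must be finite and within
#'   `[0, 255]`; use [read_oct_image()] to load and rescale image files.
#' @return An `oct_image` object (a numeric matrix with class attribute).
#' @examples
#' img <- oct_image(matrix(120, 20, 30))
#' dim(img)
#' @export
oct_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix", call. = FALSE)
  }
  storage.mode(x) <- "double"
  if (nrow(x) < 7L || ncol(x) < 7L) {
    stop("image must be at least 7 x 7 (got ", nrow(x), " x ", ncol(x), ")",
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("image intensities must all be finite", call. = FALSE)
  }
  if (min(x) < 0 || max(x) > 255) {
    stop("image intensities must lie within [0, 255]; rescale on load",
         call. = FALSE)
  }
  structure(x, class = c("oct_image", class(matrix())))
}

#' @export
print.oct_image <- function(x, ...) {
  cat(sprintf("<oct_image> %d x %d, intensity range [%.1f, %.1f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Read a grayscale B-scan from a PNG or TIFF file
#'
#' Reads an 8- or 16-bit grayscale image and rescales intensities linearly to
#' `[0, 255]`. Multi-channel images are converted to grayscale by averaging
#' the channels (luminance average), with a warning.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return An [oct_image()].
#' @export
read_oct_image <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read image: file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (PNG and TIFF only)",
         call. = FALSE)
  )
  if (length(dim(x)) == 3L) {
    nc <- dim(x)[3]
    if (nc > 1L) {
      warning("multi-channel image converted to grayscale by channel average")
    }
    x <- apply(x[, , seq_len(min(nc, 3L)), drop = FALSE], c(1, 2), mean)
  }
  # readPNG/readTIFF return values in [0, 1] regardless of bit depth
  oct_image(x * 255)
}

#' Write an image matrix as an 8-bit grayscale PNG
#'
#' @param img an [oct_image()] or numeric matrix with values in `[0, 255]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_oct_png <- function(img, path) {
  png::writePNG(pmin(pmax(unclass(img) / 255, 0), 1), target = path)
  invisible(path)
}
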