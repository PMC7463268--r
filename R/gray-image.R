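#' Grayscale image container
#'
#' A `gray_image` is a 2-D matrix of integer intensities together with a
#' declared bit depth. All pipeline stages operate on this container so that
#' the intensity range (`0 .. 2^bit_depth - 1`) is known at every step.
#'
#' @param pixels numeric matrix of intensities; values must lie in
#'   `[0, 2^bit_depth - 1]` and are stored rounded to integers.
#' @param bit_depth integer, 8 or 16.
#' @return An object of class `gray_image`: the pixel matrix with attribute
#'   `bit_depth`. Matrix rows index image rows (y), columns index x.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16), bit_depth = 8)
#' max_intensity(img)
#' @export
gray_image <- function(pixels, bit_depth = 8L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one pixel")
  }
  top <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > top)) {
    stop("pixel intensities outside [0, ", top, "]")
  }
  structure(round(pixels), bit_depth = as.integer(bit_depth),
            class = c("gray_image", "matrix", "array"))
}

#' @rdname gray_image
#' @param x object to test or query.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

#' @rdname gray_image
#' @export
max_intensity <- function(x) {
  2^attr(x, "bit_depth") - 1
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, %d-bit, intensity range [%d, %d]\n",
              nrow(x), ncol(x), attr(x, "bit_depth"),
              as.integer(min(x)), as.integer(max(x))))
  invisible(x)
}

# Clamp raw numeric pixels into the declared range and rebuild the container.
clip_gray <- function(pixels, bit_depth) {
  top <- 2^bit_depth - 1
  px <- round(pixels)
  px[px < 0] <- 0
  px[px > top] <- top
  gray_image(px, bit_depth)
}

#' Read and write grayscale images
#'
#' Single-channel PNG (8-bit) and TIFF (8- or 16-bit) input/output. Color
#' (multi-channel) files are rejected: IR-SLO reflectance scans are
#' single-channel and silent channel collapsing would change texture.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`).
#' @param bit_depth declared bit depth of the stored intensities.
#' @return `read_gray_image()` returns a [gray_image()];
#'   `write_gray_image()` returns `path` invisibly.
#' @export
read_gray_image <- function(path, bit_depth = 8L) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] > 1L) {
      stop("image is not single-channel: ", path)
    }
    arr <- arr[, , 1L]
  }
  gray_image(round(arr * (2^bit_depth - 1)), bit_depth)
}

#' @rdname read_gray_image
#' @param img a [gray_image()].
#' @export
write_gray_image <- function(img, path) {
  stopifnot(is_gray_image(img))
  ext <- tolower(tools::file_ext(path))
  norm <- unclass(img) / max_intensity(img)
  attr(norm, "bit_depth") <- NULL
  if (ext == "png") {
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path,
                    bits.per.sample = attr(img, "bit_depth"))
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}
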