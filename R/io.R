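#' Read an RGB image
#'
#' Reads a PNG image and returns an `H x W x 3` double array with values in
#' `[0, 1]`. Grayscale inputs are replicated across channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a PNG file.
#' @return Numeric array of dimension `c(height, width, 3)`.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) {
    x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  } else if (dim(x)[3] == 4L) {
    x <- x[, , 1:3, drop = FALSE]
  } else if (dim(x)[3] == 2L) {            # gray + alpha
    x <- array(rep(x[, , 1L], 3L), dim = c(dim(x)[1:2], 3L))
  }
  x
}

#' Write an RGB image as 8-bit PNG
#'
#' @param image `H x W x 3` array with values in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read a mask image as an 8-bit integer matrix
#'
#' Returns the stored 8-bit values (0-255) as an integer matrix, reducing
#' RGB via luminance first when necessary. Use [binarize_mask()] to obtain a
#' logical foreground grid and [read_label_mask()] for combined label masks.
#'
#' @param path Path to a PNG mask.
#' @return Integer matrix of 8-bit values.
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- luminance(x[, , 1:min(3L, dim(x)[3]), drop = FALSE])
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Write a binary mask as 8-bit grayscale PNG (foreground 255)
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_binary_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write a combined label mask as single-channel PNG
#'
#' Pixel values are stored verbatim (0 = background, 1 = RBC, 2 = WBC,
#' 3 = platelet), so the file round-trips exactly through
#' [read_label_mask()].
#'
#' @param label Integer matrix with values in `0:3`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(label, path) {
  check_label_mask(label)
  png::writePNG(label / 255, path)
  invisible(path)
}

#' Read a combined label mask
#'
#' @param path Path to a PNG written by [write_label_mask()].
#' @return Integer matrix with values in `0:3`.
#' @export
read_label_mask <- function(path) {
  m <- read_mask(path)
  check_label_mask(m)
  m
}

check_label_mask <- function(label) {
  if (!is.matrix(label)) {
    stop_hemaseg("hemaseg_format_error", "label mask must be a matrix")
  }
  bad <- setdiff(unique(as.vector(label)), 0:3)
  if (length(bad)) {
    stop_hemaseg("hemaseg_format_error",
                 "label mask contains values outside {0,1,2,3}: %s",
                 paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(label)
}

# Rec.601 luma weighting, the conventional grayscale reduction.
luminance <- function(x) {
  if (length(dim(x)) == 2L) return(x)
  0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
}
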