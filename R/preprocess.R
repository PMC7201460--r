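#' Binarize a mask image
#'
#' Reduces a 3-channel mask to a single channel (Rec.601 luminance) when
#' needed, then thresholds. With `polarity = "light_on_dark"` (default)
#' foreground is any value > 0; with `"dark_on_light"` (black cells on a
#' white sheet) foreground is any value below the representable maximum.
#'
#' @param mask Matrix or `H x W x 3` array; values in `[0,1]` or `0-255`.
#' @param polarity `"light_on_dark"` or `"dark_on_light"`.
#' @return Logical matrix, `TRUE` on foreground.
#' @export
binarize_mask <- function(mask, polarity = c("light_on_dark", "dark_on_light")) {
  polarity <- match.arg(polarity)
  if (is.logical(mask) && is.matrix(mask)) return(mask)
  d <- dim(mask)
  if (length(d) == 3L) {
    if (d[3] != 3L) {
      stop_hemaseg("hemaseg_format_error",
                   "mask must have 1 or 3 channels, got %d", d[3])
    }
    mask <- luminance(mask)
  } else if (length(d) != 2L) {
    stop_hemaseg("hemaseg_format_error", "mask must be 2-D or H x W x 3")
  }
  if (polarity == "light_on_dark") {
    mask > 0
  } else {
    vmax <- if (max(mask) <= 1) 1 else 255
    mask < vmax
  }
}

#' Fuse per-class binary masks into a combined label mask
#'
#' Starts from an all-zero grid and assigns pixel IDs in order RBC = 1,
#' WBC = 2, platelet = 3; later assignments overwrite earlier ones, so on
#' overlap the priority is PLT > WBC > RBC.
#'
#' @param rbc,wbc,plt Logical (or 0/1) matrices of one common shape.
#' @return Integer label matrix with values in `0:3`.
#' @export
fuse_labels <- function(rbc, wbc, plt) {
  if (!identical(dim(rbc), dim(wbc)) || !identical(dim(rbc), dim(plt))) {
    stop_hemaseg("hemaseg_dimension_error",
                 "the three masks must share one shape")
  }
  out <- matrix(0L, nrow(rbc), ncol(rbc))
  out[rbc != 0] <- 1L
  out[wbc != 0] <- 2L
  out[plt != 0] <- 3L
  out
}

#' Background (unity-mask) complement of a label mask
#'
#' @param label Integer label matrix (values `0:3`).
#' @return Logical matrix, `TRUE` exactly where `label == 0`.
#' @export
background_complement <- function(label) {
  check_label_mask(label)
  label == 0L
}

#' Resize an image / label-mask pair
#'
#' The image is resized with bilinear interpolation; the label mask with
#' nearest-neighbor so class IDs are never interpolated into fractional
#' values.
#'
#' @param image `H x W x 3` array (or `NULL` to resize a label alone).
#' @param label Integer label matrix, or `NULL`.
#' @param target_h,target_w Output dimensions, >= 1.
#' @return List with resized `image` and `label`.
#' @export
resize_pair <- function(image, label, target_h, target_w) {
  if (target_h < 1 || target_w < 1) {
    stop_hemaseg("hemaseg_invalid_argument",
                 "resize targets must be >= 1, got %sx%s", target_h, target_w)
  }
  out <- list(image = NULL, label = NULL)
  if (!is.null(image)) out$image <- resize_bilinear(image, target_h, target_w)
  if (!is.null(label)) {
    check_label_mask(label)
    out$label <- resize_nearest(label, target_h, target_w)
  }
  out
}

resize_nearest <- function(mat, th, tw) {
  H <- nrow(mat); W <- ncol(mat)
  ri <- pmin(H, pmax(1L, as.integer(ceiling((seq_len(th) - 0.5) * H / th))))
  ci <- pmin(W, pmax(1L, as.integer(ceiling((seq_len(tw) - 0.5) * W / tw))))
  mat[ri, ci, drop = FALSE]
}

resize_bilinear <- function(img, th, tw) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  # map output pixel centers into source pixel-center coordinates
  sr <- (seq_len(th) - 0.5) * H / th
  sc <- (seq_len(tw) - 0.5) * W / tw
  r0 <- pmin(H, pmax(1, floor(sr + 0.5)))
  r1 <- pmin(H, r0 + 1)
  c0 <- pmin(W, pmax(1, floor(sc + 0.5)))
  c1 <- pmin(W, c0 + 1)
  fr <- pmin(1, pmax(0, sr + 0.5 - r0))
  fc <- pmin(1, pmax(0, sc + 0.5 - c0))
  FR <- matrix(fr, th, tw); FC <- matrix(fc, th, tw, byrow = TRUE)
  resize_plane <- function(p) {
    a <- p[r0, c0, drop = FALSE]; b <- p[r1, c0, drop = FALSE]
    cc <- p[r0, c1, drop = FALSE]; dd <- p[r1, c1, drop = FALSE]
    a * (1 - FR) * (1 - FC) + b * FR * (1 - FC) +
      cc * (1 - FR) * FC + dd * FR * FC
  }
  if (length(d) == 2L) return(resize_plane(img))
  out <- array(0, dim = c(th, tw, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- resize_plane(img[, , k])
  out
}

#' Read a datastore index from disk
#'
#' @param path Path to an `index.csv` written by [write_dataset()] (or the
#'   directory containing it).
#' @return Datastore index data frame with a `root` attribute.
#' @export
read_datastore <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "index.csv")
  if (!file.exists(path)) {
    stop_hemaseg("hemaseg_io_error", "no datastore index at '%s'", path)
  }
  index <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  attr(index, "root") <- normalizePath(dirname(path))
  index
}

datastore_path <- function(index, column, i) {
  file.path(attr(index, "root") %||% ".", index[[column]][i])
}

#' Split a datastore into train and test sets
#'
#' Uniform random split without replacement, deterministic for a fixed
#' seed. Records not drawn into either split are dropped.
#'
#' @param index Datastore index (see [read_datastore()]).
#' @param n_train,n_test Split sizes; their sum must not exceed the number
#'   of records.
#' @param seed Integer seed.
#' @return The index restricted to the sampled records, with the `split`
#'   column set to `"train"` / `"test"`.
#' @export
split_datastore <- function(index, n_train, n_test, seed) {
  n <- nrow(index)
  if (n_train < 0 || n_test < 0 || n_train + n_test > n) {
    stop_hemaseg("hemaseg_invalid_split",
                 "cannot split %d records into %d train + %d test",
                 n, n_train, n_test)
  }
  pick <- with_seed(seed, sample.int(n, n_train + n_test))
  out <- index[pick, , drop = FALSE]
  out$split <- rep(c("train", "test"), c(n_train, n_test))
  rownames(out) <- NULL
  attr(out, "root") <- attr(index, "root")
  out
}

# Load (image, label) pairs for one split, resized to the network input.
load_split <- function(index, split, input_size) {
  rows <- which(index$split == split)
  lapply(rows, function(i) {
    img <- read_image(datastore_path(index, "image", i))
    lab <- read_label_mask(datastore_path(index, "combined", i))
    p <- resize_pair(img, lab, input_size[1], input_size[2])
    list(image = p$image, label = p$label)
  })
}
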