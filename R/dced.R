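#' Specification of the encoder-decoder segmentation network
#'
#' A VGG-style encoder (stacked 3x3 conv + ReLU blocks, each stage followed
#' by 2x2 max pooling) mirrored by a decoder (2x nearest-neighbor upsampling
#' followed by conv blocks) that restores full resolution, ending in a
#' per-pixel score map over `n_classes`.
#'
#' Spatial dims must be divisible by `2^depth`; inputs that are not (such
#' as the conventional 300x300) are padded internally by [predict_image()]
#' and the scores cropped back.
#'
#' @param input_size `c(height, width)` of the RGB input. Default 300x300.
#' @param n_classes Number of classes including background; default 4
#'   (background + RBC + WBC + platelet).
#' @param widths Encoder stage channel counts; `c(64,128,256,512,512)`
#'   reproduces the VGG16 stage pattern. Smaller widths give desk-scale
#'   models.
#' @param convs_per_stage Number of conv layers per encoder stage.
#' @param use_pretrained_encoder Optional hook: if `TRUE`, encoder weights
#'   may later be overwritten via [load_encoder_weights()]; nothing is
#'   downloaded.
#' @param decoder_upsampling `"unpool"` (default) reuses the max-pool
#'   argmax indices of the mirrored encoder stage, which carries
#'   pixel-accurate boundary positions into the decoder; `"nearest"` is
#'   plain nearest-neighbor upsampling.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(input_size = c(300L, 300L),
                         n_classes = 4L,
                         widths = c(64L, 128L, 256L, 512L, 512L),
                         convs_per_stage = 2L,
                         use_pretrained_encoder = FALSE,
                         decoder_upsampling = c("unpool", "nearest")) {
  decoder_upsampling <- match.arg(decoder_upsampling)
  if (n_classes < 2) {
    stop_hemaseg("hemaseg_invalid_spec", "n_classes must be >= 2")
  }
  if (length(widths) < 1 || any(widths < 1)) {
    stop_hemaseg("hemaseg_invalid_spec", "widths must be positive")
  }
  depth <- length(widths)
  structure(list(
    input_size = as.integer(input_size),
    n_classes = as.integer(n_classes),
    widths = as.integer(widths),
    depth = depth,
    convs_per_stage = as.integer(convs_per_stage),
    use_pretrained_encoder = isTRUE(use_pretrained_encoder),
    decoder_upsampling = decoder_upsampling
  ), class = "network_spec")
}

# Smallest multiple of 2^depth that fits each spatial dim.
padded_size <- function(spec) {
  m <- 2L^spec$depth
  as.integer(ceiling(spec$input_size / m) * m)
}

conv_layer <- function(cin, cout, relu = TRUE, gain = sqrt(2)) {
  n <- 9L * cin * cout
  w <- stats::rnorm(n, 0, gain / sqrt(9 * cin))
  list(type = "conv", W = array(w, dim = c(3L, 3L, cin * cout)),
       b = numeric(cout), relu = relu, cin = cin, cout = cout)
}

#' Build an encoder-decoder segmentation model
#'
#' Parameter initialization (He-scaled Gaussian) is deterministic for a
#' fixed `(spec, seed)`. If the input size is not divisible by `2^depth`
#' the network operates on the padded size; [predict_image()] hides this.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `dced_model` with fields `spec`, `layers`,
#'   `seed` and `work_size` (the internal, padded spatial size).
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  work <- padded_size(spec)
  layers <- with_seed(seed, {
    ls <- list()
    cin <- 3L
    for (w in spec$widths) {                      # encoder
      for (k in seq_len(spec$convs_per_stage)) {
        ls[[length(ls) + 1L]] <- conv_layer(cin, w)
        cin <- w
      }
      ls[[length(ls) + 1L]] <- list(type = "pool")
    }
    rw <- rev(spec$widths)
    for (s in seq_along(rw)) {                    # mirrored decoder
      ls[[length(ls) + 1L]] <- list(type = "upsample",
                                    method = spec$decoder_upsampling)
      cout_stage <- if (s < length(rw)) rw[s + 1L] else rw[length(rw)]
      for (k in seq_len(spec$convs_per_stage)) {
        cout <- if (k == spec$convs_per_stage) cout_stage else cin
        ls[[length(ls) + 1L]] <- conv_layer(cin, cout)
        cin <- cout
      }
    }
    ls[[length(ls) + 1L]] <- conv_layer(cin, spec$n_classes, relu = FALSE,
                                        gain = 1)
    ls
  })
  structure(list(spec = spec, layers = layers, seed = as.integer(seed),
                 work_size = work), class = "dced_model")
}

pad_to_work <- function(image, work) {
  d <- dim(image)
  if (d[1] == work[1] && d[2] == work[2]) return(image)
  out <- array(0, dim = c(work[1], work[2], d[3]))
  ri <- pmin(d[1], seq_len(work[1]))   # replicate bottom/right edge
  ci <- pmin(d[2], seq_len(work[2]))
  out[, , ] <- image[ri, ci, , drop = FALSE]
  out
}

#' Per-pixel class scores and labels for one image
#'
#' Runs the network forward and returns softmax score maps (per-pixel
#' probabilities summing to 1 across classes) plus the argmax label mask
#' in the pixel-ID convention (class index - 1, so background = 0).
#'
#' @param model A `dced_model`.
#' @param image `H x W x 3` array in `[0,1]` matching `spec$input_size`.
#' @return List with `scores` (`H x W x n_classes`) and `label` (integer
#'   matrix).
#' @export
predict_image <- function(model, image) {
  stopifnot(inherits(model, "dced_model"))
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L ||
      d[1] != model$spec$input_size[1] || d[2] != model$spec$input_size[2]) {
    stop_hemaseg("hemaseg_dimension_error",
                 "image must be %dx%dx3", model$spec$input_size[1],
                 model$spec$input_size[2])
  }
  x <- pad_to_work(image, model$work_size)
  res <- cpp_dced_run(x, model$layers)
  scores <- res$scores[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  label <- apply(scores, c(1, 2), which.max) - 1L
  list(scores = scores, label = matrix(as.integer(label), d[1], d[2]))
}

#' @export
predict.dced_model <- function(object, image, ...) predict_image(object, image)

# Loss/accuracy/gradients for one (image, label) pair at working resolution.
model_grad <- function(model, image, label, class_weights = NULL) {
  x <- pad_to_work(image, model$work_size)
  y <- label
  if (any(dim(y) != model$work_size)) {
    ri <- pmin(nrow(y), seq_len(model$work_size[1]))
    ci <- pmin(ncol(y), seq_len(model$work_size[2]))
    y <- y[ri, ci, drop = FALSE]
  }
  cpp_dced_run(x, model$layers, target = y, class_weights = class_weights,
               want_grads = TRUE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding the spec, seed and all
#' parameters.
#'
#' @param model A `dced_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `dced_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dced_model")) {
    stop_hemaseg("hemaseg_format_error", "'%s' is not a model checkpoint", path)
  }
  model
}

#' Load external encoder weights (optional hook)
#'
#' Overwrites encoder conv parameters from an RDS file holding a list of
#' `list(W=, b=)` in encoder layer order. Provided so a VGG16-derived
#' encoder can be injected when available; the package never downloads one.
#'
#' @param model A `dced_model` built with `use_pretrained_encoder = TRUE`.
#' @param path RDS file with the weight list.
#' @return The model with encoder weights replaced.
#' @export
load_encoder_weights <- function(model, path) {
  wts <- readRDS(path)
  enc <- which(vapply(model$layers, function(l) l$type == "conv", logical(1)))
  enc <- enc[seq_len(min(length(enc), length(wts)))]
  for (i in seq_along(enc)) {
    l <- model$layers[[enc[i]]]
    if (!identical(dim(l$W), dim(wts[[i]]$W))) {
      stop_hemaseg("hemaseg_invalid_spec",
                   "encoder weight %d has shape mismatch", i)
    }
    model$layers[[enc[i]]]$W <- wts[[i]]$W
    model$layers[[enc[i]]]$b <- wts[[i]]$b
  }
  model
}
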