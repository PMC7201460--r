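# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive pointwise/set computations, independent of the package internals
# they check.

# Demo synthetic world used for desk-scale training tests: a 64x64 field
# crop holding a dozen erythrocytes, one leukocyte and two platelets.
demo_smear_config <- function(n_images = 16L) {
  smear_config(canvas = c(64L, 64L),
               counts = c(RBC = 12, WBC = 1, PLT = 2),
               n_images = n_images)
}

# Build a smear_scene by hand (no RNG) from a data.frame of cells.
manual_scene <- function(canvas, cells, noise_sd = 0) {
  base <- data.frame(cell_class = character(), row = numeric(),
                     col = numeric(), a = numeric(), b = numeric(),
                     rot = numeric(), r = numeric(), g = numeric(),
                     b_col = numeric(), pallor = logical(),
                     nucleus_frac = numeric(), stringsAsFactors = FALSE)
  if (nrow(cells)) {
    defaults <- data.frame(r = 0.8, g = 0.5, b_col = 0.5, pallor = FALSE,
                           nucleus_frac = 0)
    for (nm in names(defaults)) {
      if (is.null(cells[[nm]])) cells[[nm]] <- defaults[[nm]]
    }
    base <- cells[, names(base)]
  }
  structure(list(canvas = as.integer(canvas),
                 background = c(0.92, 0.90, 0.95),
                 cells = base, noise_sd = noise_sd, seed = 0L),
            class = "smear_scene")
}

# Oracle: pointwise ellipse-inclusion rasterization over every pixel.
brute_force_ellipse_mask <- function(H, W, cr, cc, a, b, rot) {
  m <- matrix(FALSE, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      x <- i - 0.5 - cr
      y <- j - 0.5 - cc
      u <- (x * cos(rot) + y * sin(rot)) / a
      v <- (-x * sin(rot) + y * cos(rot)) / b
      m[i, j] <- u * u + v * v <= 1
    }
  }
  m
}

# Oracle: confusion entries by direct set counting.
oracle_confusion_entry <- function(pred, truth, t, p) {
  sum(truth == t & pred == p)
}

# Oracle: per-class recall and IoU by direct set operations on masks.
oracle_recall <- function(pred, truth, c) {
  sum(pred == c & truth == c) / sum(truth == c)
}
oracle_iou <- function(pred, truth, c) {
  sum(pred == c & truth == c) / sum(pred == c | truth == c)
}

# Oracle: boundary-F by exhaustive all-pairs distance matching.
oracle_boundary <- function(mask) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  out <- NULL
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (!mask[i, j]) next
      edge <- i == 1 || i == H || j == 1 || j == W ||
        !mask[i - 1, j] || !mask[i + 1, j] || !mask[i, j - 1] || !mask[i, j + 1]
      if (edge) out <- rbind(out, c(i, j))
    }
  }
  out
}
oracle_bf <- function(pred, truth, tol) {
  bp <- oracle_boundary(pred)
  bt <- oracle_boundary(truth)
  if (is.null(bp) && is.null(bt)) return(1)
  if (is.null(bp) || is.null(bt)) return(0)
  near <- function(A, B) {
    mean(apply(A, 1, function(p) {
      any(sqrt((B[, 1] - p[1])^2 + (B[, 2] - p[2])^2) <= tol)
    }))
  }
  P <- near(bp, bt)
  R <- near(bt, bp)
  if (P + R == 0) return(0)
  2 * P * R / (P + R)
}

random_label_mask <- function(H, W, classes = 0:3) {
  matrix(sample(classes, H * W, replace = TRUE), H, W)
}

random_confusion <- function(K = 4L) {
  cm <- matrix(sample(0:40, K * K, replace = TRUE), K, K,
               dimnames = list(truth = as.character(seq_len(K) - 1L),
                               pred = as.character(seq_len(K) - 1L)))
  diag(cm) <- diag(cm) + 5L   # keep every class populated
  structure(cm, class = c("confusion_matrix", class(cm)))
}
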