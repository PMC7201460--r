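#' Configuration for the synthetic smear generator
#'
#' Describes a family of synthetic whole-slide blood smear images: canvas
#' size, expected number of cells per class (derived from the pixel
#' frequency targets when not given), stain noise and overlap policy.
#'
#' Default pixel-frequency targets are 93.55 / 6.09 / 0.34 % for RBC / WBC /
#' platelet, the classwise shares typical of a stained smear field; cell
#' counts are derived from these targets, the mean ellipse areas and a
#' Poisson coverage model (see the methods vignette).
#'
#' @param canvas Integer vector `c(height, width)`; each must be >= 64.
#' @param counts Optional named vector `c(RBC=, WBC=, PLT=)` of expected
#'   cell counts per image; `NULL` derives them from `freq_targets`.
#' @param freq_targets Foreground pixel-frequency targets in percent, named
#'   `RBC`, `WBC`, `PLT`; positive, summing to at most 100.
#' @param coverage Fraction of the canvas covered by cells (foreground),
#'   used when deriving counts. Default 0.55, a moderately dense smear.
#' @param noise_sd Standard deviation of additive Gaussian color jitter on
#'   the rendered image (intensity scale `[0,1]`); never applied to masks.
#' @param allow_overlap If `FALSE`, same-class cell centers are
#'   rejection-sampled to avoid overlap (best effort, 100 tries per cell).
#' @param n_images Number of images a dataset built from this config holds.
#' @param geometry Per-class ellipse semi-axis means/sds in pixels; see
#'   `default_cell_geometry()`.
#' @return An object of class `smear_config`.
#' @export
smear_config <- function(canvas = c(512L, 512L),
                         counts = NULL,
                         freq_targets = c(RBC = 93.55, WBC = 6.09, PLT = 0.34),
                         coverage = 0.55,
                         noise_sd = 0.02,
                         allow_overlap = TRUE,
                         n_images = 108L,
                         geometry = default_cell_geometry()) {
  canvas <- unlist(canvas)
  if (length(canvas) != 2L || any(!is.finite(canvas)) || any(canvas <= 0)) {
    stop_hemaseg("hemaseg_invalid_config", "canvas must be two positive dims")
  }
  if (any(canvas < 64)) {
    stop_hemaseg("hemaseg_invalid_config",
                 "canvas must be at least 64x64, got %dx%d",
                 canvas[1], canvas[2])
  }
  freq_targets <- unlist(freq_targets)[c("RBC", "WBC", "PLT")]
  if (any(is.na(freq_targets)) || any(freq_targets <= 0) ||
      sum(freq_targets) > 100 + 1e-9) {
    stop_hemaseg("hemaseg_invalid_config",
                 "freq_targets must be positive percentages summing to <= 100")
  }
  cfg <- structure(list(
    canvas = as.integer(canvas),
    counts = counts,
    freq_targets = freq_targets,
    coverage = coverage,
    noise_sd = noise_sd,
    allow_overlap = isTRUE(allow_overlap),
    n_images = as.integer(n_images),
    geometry = geometry
  ), class = "smear_config")
  if (is.null(cfg$counts)) {
    cfg$counts <- derive_cell_counts(cfg)
  } else {
    cts <- unlist(cfg$counts)
    if (is.null(names(cts)) && length(cts) == 3L) {
      names(cts) <- c("RBC", "WBC", "PLT")   # positional (e.g. from YAML)
    }
    cfg$counts <- round(cts[c("RBC", "WBC", "PLT")])
    if (any(is.na(cfg$counts)) || any(cfg$counts < 0)) {
      stop_hemaseg("hemaseg_invalid_config",
                   "counts must be named non-negative RBC/WBC/PLT values")
    }
  }
  cfg
}

#' Default cell geometry (pixels, desk-scale 512x512 canvas)
#'
#' Ellipse semi-axis means and spreads per class. Relative scale follows
#' smear morphology: leukocytes are the largest elements, erythrocytes
#' intermediate, platelets small fragments.
#'
#' @return Named list of per-class geometry parameters.
#' @export
default_cell_geometry <- function() {
  list(
    RBC = list(a = 9,    b = 7.5, sd = 1.0, min = 5),
    WBC = list(a = 16,   b = 14,  sd = 2.0, min = 10),
    PLT = list(a = 3.5,  b = 3,   sd = 0.5, min = 2)
  )
}

mean_cell_area <- function(g) pi * g$a * g$b

# Invert the frequency targets into expected per-class cell counts using a
# Poisson coverage model: n cells of mean area a on canvas A cover
# A * (1 - exp(-n a / A)) after same-class union. Cross-class overlap is
# resolved by label priority PLT > WBC > RBC, so lower-priority targets are
# inflated by the area the higher classes will overwrite.
derive_cell_counts <- function(config) {
  A <- prod(config$canvas)
  fg <- config$coverage * A
  want <- config$freq_targets / 100 * fg        # fused pixels per class
  areas <- vapply(config$geometry, mean_cell_area, numeric(1))

  union_for <- function(target_px) min(target_px, 0.95 * A)
  n_from_union <- function(u, area) -A / area * log(1 - u / A)

  u_plt <- union_for(want[["PLT"]])
  u_wbc <- union_for(want[["WBC"]] / (1 - u_plt / A))
  u_rbc <- union_for(want[["RBC"]] / (1 - (u_wbc + u_plt) / A))

  counts <- c(
    RBC = n_from_union(u_rbc, areas[["RBC"]]),
    WBC = n_from_union(u_wbc, areas[["WBC"]]),
    PLT = n_from_union(u_plt, areas[["PLT"]])
  )
  round(counts)
}

#' Generate one synthetic smear scene
#'
#' Draws cell positions, sizes, orientations and stain parameters for one
#' slide. Deterministic: the same `(config, seed)` always yields an
#' identical scene, and the caller's RNG state is left untouched.
#'
#' @param config A [smear_config()].
#' @param seed Integer seed for this scene.
#' @return An object of class `smear_scene` with fields `canvas`,
#'   `background`, `cells` (one row per cell), `noise_sd` and `seed`.
#' @export
generate_scene <- function(config, seed) {
  if (!inherits(config, "smear_config")) config <- do.call(smear_config, config)
  H <- config$canvas[1]; W <- config$canvas[2]

  cells <- with_seed(seed, {
    recs <- lapply(c("RBC", "WBC", "PLT"), function(cl) {
      n <- config$counts[[cl]]
      if (n == 0L) return(NULL)
      g <- config$geometry[[cl]]
      a <- pmax(g$min, stats::rnorm(n, g$a, g$sd))
      b <- pmax(g$min * g$b / g$a, stats::rnorm(n, g$b, g$sd))
      pos <- sample_centers(n, H, W, pmax(a, b), config$allow_overlap)
      col <- cell_base_color(cl, n)
      data.frame(
        cell_class = cl, row = pos$row, col = pos$col, a = a, b = b,
        rot = stats::runif(n, 0, pi),
        r = col[, 1], g = col[, 2], b_col = col[, 3],
        pallor = cl == "RBC" & stats::runif(n) < 0.9,
        nucleus_frac = ifelse(cl == "WBC", stats::runif(n, 0.55, 0.8), 0),
        stringsAsFactors = FALSE
      )
    })
    recs <- Filter(Negate(is.null), recs)
    if (length(recs) == 0L) NULL else {
      out <- do.call(rbind, recs)
      rownames(out) <- NULL
      out
    }
  })
  if (is.null(cells)) {
    cells <- data.frame(cell_class = character(), row = numeric(),
                        col = numeric(), a = numeric(), b = numeric(),
                        rot = numeric(), r = numeric(), g = numeric(),
                        b_col = numeric(), pallor = logical(),
                        nucleus_frac = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(
    canvas = c(H, W),
    background = c(0.92, 0.90, 0.95),
    cells = cells,
    noise_sd = config$noise_sd,
    seed = as.integer(seed)
  ), class = "smear_scene")
}

sample_centers <- function(n, H, W, radius, allow_overlap) {
  if (allow_overlap || n == 0L) {
    return(list(row = stats::runif(n, 0, H), col = stats::runif(n, 0, W)))
  }
  rows <- numeric(n); cols <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      r <- stats::runif(1, 0, H); c <- stats::runif(1, 0, W)
      if (i == 1L) break
      d2 <- (rows[seq_len(i - 1)] - r)^2 + (cols[seq_len(i - 1)] - c)^2
      if (all(d2 > (radius[i] + radius[seq_len(i - 1)])^2)) break
    }
    rows[i] <- r; cols[i] <- c
  }
  list(row = rows, col = cols)
}

cell_base_color <- function(cl, n) {
  base <- switch(cl,
    RBC = c(0.84, 0.47, 0.47),   # eosin pink-red
    WBC = c(0.62, 0.46, 0.74),   # basophilic purple cytoplasm
    PLT = c(0.52, 0.38, 0.66)    # small purple fragments
  )
  jit <- matrix(stats::rnorm(3 * n, 0, 0.03), n, 3)
  pmin(pmax(matrix(base, n, 3, byrow = TRUE) + jit, 0), 1)
}

#' Generate a list of scenes
#'
#' @param config A [smear_config()]; `config$n_images` scenes are produced.
#' @param seed Base seed; scene `i` uses `seed + i - 1`.
#' @return List of `smear_scene` objects.
#' @export
generate_scenes <- function(config, seed) {
  lapply(seq_len(config$n_images), function(i) {
    generate_scene(config, seed + i - 1L)
  })
}

# Bounding box + inside test for one rotated ellipse on an H x W grid.
# Pixel (i, j) (1-based) has center (i - 0.5, j - 0.5); the pixel belongs
# to the cell iff its center satisfies the ellipse inequality.
ellipse_pixels <- function(H, W, cr, cc, a, b, rot) {
  er <- sqrt((a * cos(rot))^2 + (b * sin(rot))^2)
  ec <- sqrt((a * sin(rot))^2 + (b * cos(rot))^2)
  r0 <- max(1L, as.integer(floor(cr - er + 0.5)))
  r1 <- min(H, as.integer(ceiling(cr + er + 0.5)))
  c0 <- max(1L, as.integer(floor(cc - ec + 0.5)))
  c1 <- min(W, as.integer(ceiling(cc + ec + 0.5)))
  if (r0 > r1 || c0 > c1) return(NULL)
  dx <- (r0:r1) - 0.5 - cr
  dy <- (c0:c1) - 0.5 - cc
  X <- matrix(dx, length(dx), length(dy))
  Y <- matrix(dy, length(dx), length(dy), byrow = TRUE)
  u <- (X * cos(rot) + Y * sin(rot)) / a
  v <- (-X * sin(rot) + Y * cos(rot)) / b
  list(rows = r0:r1, cols = c0:c1, q = u * u + v * v)
}

#' Render a scene into an image and per-class masks
#'
#' Rasterizes each cell by the pixel-center inclusion rule and paints the
#' image in class order RBC, WBC, PLT (so later classes sit on top, as
#' platelets and leukocytes do over the erythrocyte carpet). Masks are
#' binary unions per class and are never affected by image noise.
#'
#' @param scene A `smear_scene`.
#' @return List with `image` (`H x W x 3`, values in `[0,1]`) and logical
#'   matrices `rbc_mask`, `wbc_mask`, `plt_mask`.
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "smear_scene"))
  H <- scene$canvas[1]; W <- scene$canvas[2]
  planes <- list(matrix(scene$background[1], H, W),
                 matrix(scene$background[2], H, W),
                 matrix(scene$background[3], H, W))
  masks <- list(RBC = matrix(FALSE, H, W), WBC = matrix(FALSE, H, W),
                PLT = matrix(FALSE, H, W))

  cells <- scene$cells
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    px <- ellipse_pixels(H, W, cell$row, cell$col, cell$a, cell$b, cell$rot)
    if (is.null(px)) next
    w <- which(px$q <= 1)
    if (!length(w)) next
    nbr <- length(px$rows)
    gr <- px$rows[(w - 1L) %% nbr + 1L]
    gc <- px$cols[(w - 1L) %/% nbr + 1L]
    lin <- (gc - 1L) * H + gr                 # column-major linear indices
    masks[[cell$cell_class]][lin] <- TRUE

    color <- matrix(c(cell$r, cell$g, cell$b_col), length(w), 3, byrow = TRUE)
    if (cell$cell_class == "RBC" && isTRUE(cell$pallor)) {
      pal <- px$q[w] <= 0.45^2
      color[pal, ] <- rep(pmin(1, c(cell$r, cell$g, cell$b_col) * 0.5 +
                                  0.5 * c(0.95, 0.80, 0.80)), each = sum(pal))
    } else if (cell$cell_class == "WBC") {
      nuc <- px$q[w] <= cell$nucleus_frac^2
      color[nuc, ] <- rep(c(0.38, 0.22, 0.55), each = sum(nuc))
    }
    for (ch in 1:3) planes[[ch]][lin] <- color[, ch]
  }
  img <- array(c(planes[[1]], planes[[2]], planes[[3]]), dim = c(H, W, 3))

  if (scene$noise_sd > 0) {
    noise <- with_seed(scene$seed %% 1000000L + 7L,
                       stats::rnorm(length(img), 0, scene$noise_sd))
    img <- pmin(pmax(img + noise, 0), 1)
  }
  list(image = img, rbc_mask = masks$RBC, wbc_mask = masks$WBC,
       plt_mask = masks$PLT)
}

#' Write a rendered dataset to disk
#'
#' For each scene writes the RGB image, the three individual binary masks
#' (8-bit grayscale, foreground 255) and the combined label mask produced by
#' [fuse_labels()] (values 0-3), i.e. four mask files per image, plus a CSV
#' index with columns `image, rbc_mask, wbc_mask, plt_mask, combined,
#' split`. Paths in the index are relative to `out_dir`.
#'
#' @param scenes List of `smear_scene` objects.
#' @param out_dir Output directory, created if needed.
#' @return The datastore index, invisibly (also written to
#'   `out_dir/index.csv`); see [read_datastore()].
#' @export
write_dataset <- function(scenes, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop_hemaseg("hemaseg_io_error", "cannot create output dir '%s'", out_dir)
  }
  rows <- vector("list", length(scenes))
  for (i in seq_along(scenes)) {
    stem <- sprintf("img_%04d", i)
    r <- render_scene(scenes[[i]])
    paths <- c(image = paste0(stem, ".png"),
               rbc_mask = paste0(stem, "_rbc.png"),
               wbc_mask = paste0(stem, "_wbc.png"),
               plt_mask = paste0(stem, "_plt.png"),
               combined = paste0(stem, "_labels.png"))
    write_image(r$image, file.path(out_dir, paths["image"]))
    write_binary_mask(r$rbc_mask, file.path(out_dir, paths["rbc_mask"]))
    write_binary_mask(r$wbc_mask, file.path(out_dir, paths["wbc_mask"]))
    write_binary_mask(r$plt_mask, file.path(out_dir, paths["plt_mask"]))
    label <- fuse_labels(r$rbc_mask, r$wbc_mask, r$plt_mask)
    write_label_mask(label, file.path(out_dir, paths["combined"]))
    rows[[i]] <- c(paths, split = "")
  }
  index <- if (length(rows)) {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else {
    data.frame(image = character(), rbc_mask = character(),
               wbc_mask = character(), plt_mask = character(),
               combined = character(), split = character(),
               stringsAsFactors = FALSE)
  }
  utils::write.csv(index, file.path(out_dir, "index.csv"), row.names = FALSE)
  attr(index, "root") <- normalizePath(out_dir)
  invisible(index)
}
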