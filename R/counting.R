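#' Classwise pixel counting
#'
#' Counts pixels per class over one label mask or a set of masks and
#' reports class frequencies as percentages of the counted total. By
#' default only the three foreground classes are counted, matching the
#' usual three-way RBC/WBC/platelet frequency split; background can be
#' included with a flag.
#'
#' @param labels One integer label matrix or a list of them.
#' @param include_background Count class 0 as well.
#' @return Object of class `pixel_count_report`: `counts` (named integer),
#'   `frequencies` (named percentages), `scope` (`"single_image"` or
#'   `"image_set"`), `n_images`.
#' @export
pixel_counts <- function(labels, include_background = FALSE) {
  if (is.matrix(labels)) {
    scope <- "single_image"
    labels <- list(labels)
  } else {
    scope <- "image_set"
  }
  if (length(labels) == 0L) {
    stop_hemaseg("hemaseg_no_data", "no label masks supplied")
  }
  counts <- c(background = 0, RBC = 0, WBC = 0, PLT = 0)
  for (m in labels) {
    check_label_mask(m)
    counts <- counts + tabulate(as.vector(m) + 1L, nbins = 4L)
  }
  if (!include_background) counts <- counts[c("RBC", "WBC", "PLT")]
  freqs <- if (sum(counts) == 0) {
    warning("all class counts are zero; frequencies undefined, reported as 0")
    counts * 0
  } else {
    frequencies_from_counts(counts)
  }
  structure(list(counts = counts, frequencies = freqs, scope = scope,
                 n_images = length(labels)),
            class = "pixel_count_report")
}

#' Percent frequencies from class pixel counts
#'
#' @param counts Named non-negative counts with at least one positive
#'   entry.
#' @return Percentages summing to 100.
#' @export
frequencies_from_counts <- function(counts) {
  if (length(counts) == 0L || any(counts < 0) || sum(counts) <= 0) {
    stop_hemaseg("hemaseg_invalid_input",
                 "counts must be non-negative with a positive total")
  }
  100 * counts / sum(counts)
}

#' Write a pixel-count report
#'
#' CSV and JSON (exact integer counts plus percent frequencies) and an
#' optional bar chart.
#'
#' @param report A [pixel_counts()] report.
#' @param dir Output directory.
#' @param plot Also write `counts.png`.
#' @return Paths written, invisibly.
#' @export
write_count_report <- function(report, dir, plot = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(class = names(report$counts),
                   pixel_count = as.numeric(report$counts),
                   frequency_pct = as.numeric(report$frequencies))
  csv <- file.path(dir, "counts.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  js <- file.path(dir, "counts.json")
  jsonlite::write_json(list(scope = report$scope, n_images = report$n_images,
                            counts = as.list(report$counts),
                            frequencies = as.list(report$frequencies)),
                       js, auto_unbox = TRUE, digits = NA)
  paths <- c(csv, js)
  if (plot) {
    p <- file.path(dir, "counts.png")
    grDevices::png(p, width = 600, height = 420)
    graphics::barplot(report$counts, col = c("#c0392b", "#8e44ad", "#2980b9"),
                      ylab = "pixels", main = "Classwise pixel counts")
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}
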