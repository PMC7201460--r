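#' Pixel confusion matrix
#'
#' Entry `(t, p)` counts pixels whose true class is `t` and predicted class
#' is `p`. By default the full label set `0:3` (background included) is
#' tabulated; summaries then restrict to the foreground classes.
#'
#' @param pred,truth Integer label matrices of one shape.
#' @param classes Integer class IDs to tabulate (default `0:3`).
#' @return Object of class `confusion_matrix`: a K x K integer matrix with
#'   dimnames `truth` x `pred`.
#' @export
confusion <- function(pred, truth, classes = 0:3) {
  if (!identical(dim(pred), dim(truth))) {
    stop_hemaseg("hemaseg_dimension_error",
                 "pred and truth must share one shape")
  }
  f <- factor(as.vector(truth), levels = classes)
  g <- factor(as.vector(pred), levels = classes)
  keep <- !is.na(f) & !is.na(g)
  cm <- table(truth = f[keep], pred = g[keep])
  cm <- matrix(as.integer(cm), length(classes), length(classes),
               dimnames = list(truth = as.character(classes),
                               pred = as.character(classes)))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Add confusion matrices
#' @param ... `confusion_matrix` objects over identical class sets.
#' @return Their elementwise sum.
#' @export
add_confusion <- function(...) {
  ms <- list(...)
  out <- Reduce(`+`, lapply(ms, unclass))
  structure(out, class = c("confusion_matrix", class(out)))
}

cm_parts <- function(cm, c) {
  key <- as.character(c)
  if (!key %in% rownames(cm)) {
    stop_hemaseg("hemaseg_invalid_argument", "class %s not in matrix", key)
  }
  tp <- cm[key, key]
  fn <- sum(cm[key, ]) - tp
  fp <- sum(cm[, key]) - tp
  tn <- sum(cm) - tp - fn - fp
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Per-class accuracy
#'
#' Default mode is per-class recall `TP / (TP + FN)` — the fraction of a
#' class's true pixels that were labeled correctly, the convention
#' consistent with aggregate reporting under heavy class imbalance. Mode
#' `"eq1"` is the textbook `(TP + TN) / (TP + TN + FP + FN)`, which is
#' dominated by true negatives for rare classes.
#'
#' @param cm A [confusion()] matrix.
#' @param c Class ID.
#' @param mode `"recall"` (default) or `"eq1"`.
#' @return Fraction in `[0, 1]`; `NaN` with a warning for a class with no
#'   true pixels.
#' @export
class_accuracy <- function(cm, c, mode = c("recall", "eq1")) {
  mode <- match.arg(mode)
  p <- cm_parts(cm, c)
  if (mode == "eq1") {
    return((p$tp + p$tn) / (p$tp + p$tn + p$fp + p$fn))
  }
  if (p$tp + p$fn == 0) {
    warning("class ", c, " has no true pixels; accuracy undefined")
    return(NaN)
  }
  p$tp / (p$tp + p$fn)
}

#' Per-class intersection over union
#'
#' `TP / (TP + FP + FN)`, i.e. |target ∩ prediction| / |target ∪ prediction|.
#'
#' @inheritParams class_accuracy
#' @return Fraction in `[0, 1]`; `NaN` with a warning when the union is
#'   empty.
#' @export
iou <- function(cm, c) {
  p <- cm_parts(cm, c)
  denom <- p$tp + p$fp + p$fn
  if (denom == 0) {
    warning("class ", c, " has empty target/prediction union; IoU undefined")
    return(NaN)
  }
  p$tp / denom
}

boundary_pixels <- function(mask) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  up    <- rbind(TRUE, !mask[-H, , drop = FALSE])
  down  <- rbind(!mask[-1, , drop = FALSE], TRUE)
  left  <- cbind(TRUE, !mask[, -W, drop = FALSE])
  right <- cbind(!mask[, -1, drop = FALSE], TRUE)
  which(mask & (up | down | left | right), arr.ind = TRUE)
}

#' Boundary-F (BF) contour matching score
#'
#' Extracts the boundary pixels of both masks (foreground pixels 4-adjacent
#' to background or to the image edge), computes boundary precision (the
#' fraction of predicted boundary pixels within `tolerance` of some true
#' boundary pixel, Euclidean distance) and boundary recall (vice versa) and
#' returns their harmonic mean `2PR / (P + R)`, or 0 when `P + R = 0`.
#'
#' @param pred_mask,truth_mask Binary (logical or 0/1) matrices of one
#'   shape.
#' @param tolerance Match distance in pixels, > 0. Default 0.75% of the
#'   image diagonal, the established convention.
#' @return Score in `[0, 1]`.
#' @export
bf_score <- function(pred_mask, truth_mask, tolerance = NULL) {
  if (!identical(dim(pred_mask), dim(truth_mask))) {
    stop_hemaseg("hemaseg_dimension_error", "masks must share one shape")
  }
  if (is.null(tolerance)) {
    tolerance <- 0.0075 * sqrt(nrow(pred_mask)^2 + ncol(pred_mask)^2)
  }
  if (!is.finite(tolerance) || tolerance <= 0) {
    stop_hemaseg("hemaseg_invalid_argument", "tolerance must be > 0")
  }
  bp <- boundary_pixels(pred_mask)
  bt <- boundary_pixels(truth_mask)
  if (nrow(bp) == 0L && nrow(bt) == 0L) return(1)
  if (nrow(bp) == 0L || nrow(bt) == 0L) return(0)
  precision <- cpp_count_matched(bp, bt, tolerance) / nrow(bp)
  recall <- cpp_count_matched(bt, bp, tolerance) / nrow(bt)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Aggregate printed classwise metrics into summary metrics
#'
#' Computes the summary-row aggregations directly from per-class values:
#' `MeanAccuracy` and `MeanIoU` are unweighted class means; `WeightedIoU`
#' is the true-pixel-frequency weighted mean; `MeanBFScore` the unweighted
#' mean of class BF scores.
#'
#' @param accuracy,iou,bf Per-class values (any may be `NULL`).
#' @param freq Per-class true-pixel fractions (needed for `WeightedIoU`).
#' @return Named list with the computable summary entries.
#' @export
summary_from_classwise <- function(accuracy = NULL, iou = NULL, freq = NULL,
                                   bf = NULL) {
  out <- list()
  if (!is.null(accuracy)) out$MeanAccuracy <- mean(accuracy)
  if (!is.null(iou)) {
    out$MeanIoU <- mean(iou)
    if (!is.null(freq)) out$WeightedIoU <- sum(freq / sum(freq) * iou)
  }
  if (!is.null(bf)) out$MeanBFScore <- mean(bf)
  out
}

#' Summary metrics from a confusion matrix
#'
#' Restricted to the foreground classes (1 = RBC, 2 = WBC, 3 = platelet) by
#' default; background-truth pixels then contribute only through false
#' positives. `GlobalAccuracy` is the correctly-labeled fraction of
#' evaluated true pixels; `MeanAccuracy`/`MeanIoU` are unweighted class
#' means; `WeightedIoU` weights IoU by true-pixel frequency.
#'
#' @param cm A [confusion()] matrix over all classes.
#' @param bf_by_class Optional per-class BF scores (aggregated upstream,
#'   see [evaluate_model()]).
#' @param include_background Include class 0 in the evaluated set.
#' @return Object of class `summary_metrics` (named list).
#' @export
summarize_metrics <- function(cm, bf_by_class = NULL,
                              include_background = FALSE) {
  if (sum(cm) == 0) {
    stop_hemaseg("hemaseg_no_data", "confusion matrix is empty")
  }
  classes <- as.integer(rownames(cm))
  if (!include_background) classes <- setdiff(classes, 0L)
  keys <- as.character(classes)
  row_tot <- rowSums(cm)[keys]
  tp <- unclass(cm)[cbind(keys, keys)]
  if (sum(row_tot) == 0) {
    stop_hemaseg("hemaseg_no_data", "no true pixels in evaluated classes")
  }
  freq <- row_tot / sum(row_tot)
  acc <- vapply(classes, function(c) class_accuracy(cm, c), numeric(1))
  ious <- vapply(classes, function(c) iou(cm, c), numeric(1))
  out <- list(
    GlobalAccuracy = sum(tp) / sum(row_tot),
    MeanAccuracy = mean(acc),
    MeanIoU = mean(ious),
    WeightedIoU = sum(freq * ious),
    MeanBFScore = if (is.null(bf_by_class)) NA_real_ else mean(bf_by_class)
  )
  structure(out, class = "summary_metrics",
            classes = classes, class_accuracy = acc, class_iou = ious,
            freq = freq)
}

#' Evaluate a model on a datastore split
#'
#' Accumulates the pixel confusion matrix over the split and computes
#' per-class BF scores per image. `MeanBFScore` defaults to the mean over
#' test images of the image-level mean BF score
#' (`bf_aggregation = "images"`); `"classes"` instead averages the pooled
#' per-class scores.
#'
#' @param model A `dced_model`.
#' @param datastore Split datastore index, or list of pairs as in
#'   [train_model()].
#' @param split Which split to evaluate (default `"test"`).
#' @param bf_tolerance BF match tolerance in pixels (`NULL` = 0.75% of the
#'   image diagonal).
#' @param include_background Include background in summary metrics.
#' @param bf_aggregation `"images"` or `"classes"`.
#' @return Object of class `hemaseg_evaluation`: `classwise` data frame
#'   (accuracy, IoU, mean BF per foreground class), `summary`, `confusion`.
#' @export
evaluate_model <- function(model, datastore, split = "test",
                           bf_tolerance = NULL, include_background = FALSE,
                           bf_aggregation = c("images", "classes")) {
  bf_aggregation <- match.arg(bf_aggregation)
  pairs <- if (is.data.frame(datastore)) {
    load_split(datastore, split, model$spec$input_size)
  } else {
    datastore
  }
  if (length(pairs) == 0L) {
    stop_hemaseg("hemaseg_no_data", "no records in split '%s'", split)
  }
  fg <- CLASS_IDS[c("RBC", "WBC", "PLT")]
  cm <- NULL
  bf_img <- matrix(NA_real_, length(pairs), length(fg),
                   dimnames = list(NULL, names(fg)))
  for (i in seq_along(pairs)) {
    pred <- predict_image(model, pairs[[i]]$image)$label
    truth <- pairs[[i]]$label
    cmi <- confusion(pred, truth)
    cm <- if (is.null(cm)) cmi else add_confusion(cm, cmi)
    for (k in seq_along(fg)) {
      tm <- truth == fg[k]
      pm <- pred == fg[k]
      if (!any(tm) && !any(pm)) next       # class absent from this image
      bf_img[i, k] <- bf_score(pm, tm, bf_tolerance)
    }
  }
  class_bf <- colMeans(bf_img, na.rm = TRUE)
  bf_for_summary <- if (bf_aggregation == "images") {
    rowMeans(bf_img, na.rm = TRUE)
  } else {
    class_bf
  }
  summary <- summarize_metrics(cm, bf_by_class = bf_for_summary,
                               include_background = include_background)
  classwise <- data.frame(
    class = names(fg),
    accuracy = vapply(fg, function(c) class_accuracy(cm, c), numeric(1)),
    iou = vapply(fg, function(c) iou(cm, c), numeric(1)),
    mean_bf_score = as.numeric(class_bf),
    row.names = NULL
  )
  structure(list(classwise = classwise, summary = summary, confusion = cm),
            class = "hemaseg_evaluation")
}

#' Write an evaluation report
#'
#' One CSV row per foreground class plus a summary block, and a JSON
#' mirror.
#'
#' @param evaluation A `hemaseg_evaluation`.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_evaluation_report <- function(evaluation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "evaluation_classwise.csv")
  utils::write.csv(evaluation$classwise, csv, row.names = FALSE)
  sj <- file.path(dir, "evaluation_summary.json")
  jsonlite::write_json(
    list(summary = evaluation$summary[!vapply(evaluation$summary, is.na,
                                              logical(1))],
         classwise = evaluation$classwise,
         confusion = unclass(evaluation$confusion)),
    sj, auto_unbox = TRUE, digits = NA)
  scsv <- file.path(dir, "evaluation_summary.csv")
  utils::write.csv(
    data.frame(metric = names(evaluation$summary),
               value = unlist(evaluation$summary)),
    scsv, row.names = FALSE)
  invisible(c(csv, scsv, sj))
}
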