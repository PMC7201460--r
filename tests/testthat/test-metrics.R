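test_that("confusion matrix counts pixels by (truth, pred)", {
  truth <- matrix(c(1L, 2L, 1L, 3L), 2, 2)
  pred <- matrix(c(1L, 2L, 2L, 3L), 2, 2)
  cm <- confusion(pred, truth)
  expect_equal(cm["1", "1"], 1L)             # TP of class 1
  expect_equal(cm["1", "2"], 1L)             # the mislabeled RBC pixel
  expect_equal(cm["2", "2"], 1L)
  expect_equal(cm["3", "3"], 1L)
  expect_equal(sum(cm), 4L)

  same <- random_label_mask(6, 6)
  cm2 <- confusion(same, same)
  expect_true(all(cm2[upper.tri(cm2) | lower.tri(cm2)] == 0))

  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               class = "hemaseg_dimension_error")
})

test_that("class accuracy supports recall (default) and eq1 modes", {
  cm <- matrix(0L, 4, 4, dimnames = list(truth = as.character(0:3),
                                         pred = as.character(0:3)))
  cm["1", "1"] <- 3L; cm["1", "0"] <- 1L     # TP=3, FN=1
  cm <- structure(cm, class = c("confusion_matrix", class(cm)))
  expect_equal(class_accuracy(cm, 1), 0.75)
  expect_equal(class_accuracy(cm, 1, mode = "eq1"), (3 + 0) / 4)

  truth <- random_label_mask(8, 8)
  perfect <- confusion(truth, truth)
  for (c in 0:3) {
    expect_equal(class_accuracy(perfect, c), 1)
    expect_equal(class_accuracy(perfect, c, mode = "eq1"), 1)
    expect_equal(iou(perfect, c), 1)
  }
  expect_warning(class_accuracy(confusion(matrix(1L, 2, 2), matrix(1L, 2, 2)), 3),
                 "no true pixels")
})

test_that("accuracy and IoU match pointwise set-based oracles", {
  set.seed(17)
  for (k in 1:25) {
    truth <- random_label_mask(8, 8)
    pred <- random_label_mask(8, 8)
    cm <- confusion(pred, truth)
    for (c in 0:3) {
      for (p in 0:3) {
        expect_identical(cm[as.character(c), as.character(p)],
                         oracle_confusion_entry(pred, truth, c, p))
      }
      if (any(truth == c)) {
        expect_equal(class_accuracy(cm, c), oracle_recall(pred, truth, c))
      }
      if (any(truth == c | pred == c)) {
        expect_equal(iou(cm, c), oracle_iou(pred, truth, c))
      }
    }
  }
})

test_that("iou handles the worked TP/FP/FN example", {
  cm <- matrix(0L, 2, 2, dimnames = list(truth = c("0", "1"),
                                         pred = c("0", "1")))
  cm["1", "1"] <- 1L; cm["0", "1"] <- 1L; cm["1", "0"] <- 2L
  cm <- structure(cm, class = c("confusion_matrix", class(cm)))
  expect_equal(iou(cm, 1), 0.25)             # TP=1, FP=1, FN=2
})

test_that("bf_score identity, disjoint and oracle equivalence", {
  sq <- function(H, W, r0, c0, s) {
    m <- matrix(FALSE, H, W); m[r0:(r0 + s - 1), c0:(c0 + s - 1)] <- TRUE; m
  }
  a <- sq(64, 64, 10, 10, 10)
  expect_equal(bf_score(a, a, tolerance = 2), 1)

  # two 3x3 squares 20 px apart: disjoint beyond tolerance
  expect_equal(bf_score(sq(64, 64, 5, 5, 3), sq(64, 64, 5, 25, 3),
                        tolerance = 2), 0)

  # 10x10 square vs the same square shifted by 1 px
  b <- sq(64, 64, 11, 10, 10)
  expect_equal(bf_score(a, b, tolerance = 2), oracle_bf(a, b, 2),
               tolerance = 1e-12)

  set.seed(23)
  for (k in 1:10) {
    p <- matrix(runif(144) < 0.35, 12, 12)
    t <- matrix(runif(144) < 0.35, 12, 12)
    tol <- runif(1, 1, 3)
    expect_equal(bf_score(p, t, tol), oracle_bf(p, t, tol), tolerance = 1e-12)
    # symmetry under swapping prediction and truth
    expect_equal(bf_score(p, t, tol), bf_score(t, p, tol), tolerance = 1e-12)
  }
  expect_equal(bf_score(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4), 1), 1)
  expect_equal(bf_score(matrix(FALSE, 4, 4), matrix(TRUE, 4, 4), 1), 0)
  expect_error(bf_score(a, a, tolerance = 0), class = "hemaseg_invalid_argument")
})

test_that("summary identities hold on random confusion matrices", {
  set.seed(29)
  for (k in 1:20) {
    cm <- random_confusion()
    s <- summarize_metrics(cm)
    classes <- attr(s, "classes")
    freq <- attr(s, "freq")
    acc <- attr(s, "class_accuracy")
    ious <- attr(s, "class_iou")
    expect_equal(s$GlobalAccuracy, sum(freq * acc))
    expect_equal(s$WeightedIoU, sum(freq * ious))
    expect_true(all(ious <= acc + 1e-12))    # IoU_c <= recall_c
    # permutation invariance of the label set
    perm <- sample(4)
    cmp <- unclass(cm)[perm, perm]
    dimnames(cmp) <- dimnames(cm)
    sp <- summarize_metrics(structure(cmp, class = class(cm)),
                            include_background = TRUE)
    s_all <- summarize_metrics(cm, include_background = TRUE)
    expect_equal(sp$GlobalAccuracy, s_all$GlobalAccuracy)
    expect_equal(sort(attr(sp, "class_iou")), sort(attr(s_all, "class_iou")))
  }
})

test_that("classwise aggregation reproduces summary conventions", {
  s <- summary_from_classwise(accuracy = c(0.9, 0.8, 0.7),
                              iou = c(0.5, 0.4, 0.3),
                              freq = c(0.90, 0.08, 0.02))
  expect_equal(s$MeanAccuracy, 0.8)
  expect_equal(s$MeanIoU, 0.4)
  expect_equal(s$WeightedIoU, 0.9 * 0.5 + 0.08 * 0.4 + 0.02 * 0.3)
})

test_that("perfect and disjoint predictions bracket the metrics", {
  truth <- fuse_labels(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2),
                       matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2),
                       matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2))
  cm <- confusion(truth, truth)
  s <- summarize_metrics(cm, bf_by_class = c(1, 1, 1))
  expect_equal(unname(unlist(s)), rep(1, 5))

  disjoint <- matrix(0L, 2, 2)               # predicts background everywhere
  cmd <- confusion(disjoint, truth)
  expect_equal(class_accuracy(cmd, 1), 0)
  expect_equal(iou(cmd, 1), 0)
})

test_that("evaluate_model produces a coherent report", {
  cfg <- demo_smear_config(3L)
  pairs <- lapply(generate_scenes(cfg, 3), function(sc) {
    r <- render_scene(sc)
    list(image = r$image,
         label = fuse_labels(r$rbc_mask, r$wbc_mask, r$plt_mask))
  })
  spec <- network_spec(input_size = c(64L, 64L), widths = c(4L))
  model <- build_network(spec, seed = 2)
  suppressWarnings(ev <- evaluate_model(model, pairs))
  expect_s3_class(ev, "hemaseg_evaluation")
  expect_equal(ev$classwise$class, c("RBC", "WBC", "PLT"))
  expect_true(all(ev$classwise$iou >= 0 & ev$classwise$iou <= 1, na.rm = TRUE))
  expect_equal(sum(ev$confusion), 3L * 64L * 64L)
  dir <- withr::local_tempdir()
  files <- write_evaluation_report(ev, dir)
  expect_true(all(file.exists(file.path(dir, c("evaluation_classwise.csv",
                                               "evaluation_summary.json")))))
})
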