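test_that("forward output matches input resolution over a grid of specs", {
  set.seed(21)
  grid <- list(
    list(size = c(16L, 16L), widths = c(4L)),
    list(size = c(16L, 24L), widths = c(4L, 8L)),
    list(size = c(32L, 32L), widths = c(3L, 5L, 7L)),
    list(size = c(16L, 16L), widths = c(4L, 8L), up = "nearest")
  )
  for (g in grid) {
    spec <- network_spec(input_size = g$size, widths = g$widths,
                         decoder_upsampling = if (is.null(g$up)) "unpool" else g$up)
    m <- build_network(spec, seed = 2)
    img <- array(runif(prod(g$size) * 3), dim = c(g$size, 3))
    p <- predict_image(m, img)
    expect_equal(dim(p$scores), c(g$size, 4L))
    expect_equal(dim(p$label), g$size)
    # per-pixel scores are a probability distribution
    sums <- apply(p$scores, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-6))
    # label is an argmax of the scores at every pixel
    for (k in 1:20) {
      i <- sample(g$size[1], 1); j <- sample(g$size[2], 1)
      expect_equal(p$scores[i, j, p$label[i, j] + 1L], max(p$scores[i, j, ]))
    }
  }
})

test_that("inputs not divisible by 2^depth are padded and cropped back", {
  spec <- network_spec(input_size = c(30L, 30L), widths = c(4L, 8L))
  m <- build_network(spec, seed = 5)
  expect_equal(m$work_size, c(32L, 32L))
  img <- array(runif(30 * 30 * 3), dim = c(30, 30, 3))
  p <- predict_image(m, img)
  expect_equal(dim(p$scores), c(30L, 30L, 4L))
  expect_error(predict_image(m, array(0, dim = c(32, 32, 3))),
               class = "hemaseg_dimension_error")
})

test_that("initialization and prediction are deterministic in the seed", {
  spec <- network_spec(input_size = c(16L, 16L), widths = c(4L, 8L))
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  m1 <- build_network(spec, seed = 77)
  m2 <- build_network(spec, seed = 77)
  expect_identical(m1$layers, m2$layers)
  p1 <- predict_image(m1, img)
  p2 <- predict_image(m2, img)
  expect_identical(p1$label, p2$label)
  expect_identical(p1$scores, p2$scores)
  expect_false(identical(build_network(spec, seed = 78)$layers, m1$layers))
})

test_that("analytic gradients match finite differences", {
  set.seed(13)
  spec <- network_spec(input_size = c(8L, 8L), widths = c(3L, 4L))
  m <- build_network(spec, seed = 4)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  lab <- random_label_mask(8, 8)
  res <- hemaseg:::model_grad(m, img, lab)
  convs <- which(vapply(m$layers, function(l) l$type == "conv", logical(1)))
  eps <- 1e-5
  for (l in convs) {
    for (idx in sample(length(m$layers[[l]]$W), 2)) {
      m2 <- m
      m2$layers[[l]]$W[idx] <- m2$layers[[l]]$W[idx] + eps
      lp <- hemaseg:::model_grad(m2, img, lab)$loss
      m2$layers[[l]]$W[idx] <- m2$layers[[l]]$W[idx] - 2 * eps
      lm <- hemaseg:::model_grad(m2, img, lab)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- res$grads[[l]]$W[idx]
      expect_lt(abs(num - ana), 1e-6 + 1e-4 * (abs(num) + abs(ana)))
    }
  }
})

test_that("invalid specs are rejected", {
  expect_error(network_spec(n_classes = 1L), class = "hemaseg_invalid_spec")
  expect_error(network_spec(widths = integer(0)), class = "hemaseg_invalid_spec")
})

test_that("checkpoints round-trip through disk", {
  dir <- withr::local_tempdir()
  spec <- network_spec(input_size = c(16L, 16L), widths = c(4L))
  m <- build_network(spec, seed = 3)
  p <- file.path(dir, "ckpt.rds")
  save_checkpoint(m, p)
  m2 <- load_checkpoint(p)
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  expect_identical(predict_image(m, img), predict_image(m2, img))
})

test_that("the small spec can fit one synthetic slide", {
  # capacity sanity: >= 99% pixel accuracy within 200 gradient steps on a
  # one-image dataset drawn from the default generator world at 64x64
  cfg <- smear_config(canvas = c(64L, 64L), n_images = 1L)
  r <- render_scene(generate_scene(cfg, 5))
  lab <- fuse_labels(r$rbc_mask, r$wbc_mask, r$plt_mask)
  spec <- network_spec(input_size = c(64L, 64L), widths = c(16L, 32L))
  model <- build_network(spec, seed = 11)
  tc <- train_config(epochs = 200L, batch_size = 1L, initial_lr = 0.01,
                     momentum = 0.9, seed = 2)
  res <- train_model(model, list(list(image = r$image, label = lab)), tc)
  final <- predict_image(res$model, r$image)$label
  expect_gte(mean(final == lab), 0.99)
})
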