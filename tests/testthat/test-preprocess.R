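test_that("binarize_mask thresholds, reduces channels and is idempotent", {
  expect_identical(binarize_mask(matrix(0, 4, 4)), matrix(FALSE, 4, 4))

  # RGB mask with a single stained pixel
  rgb <- array(0, dim = c(3, 3, 3))
  rgb[2, 2, ] <- c(200, 180, 190) / 255
  b <- binarize_mask(rgb)
  expect_equal(sum(b), 1L)
  expect_true(b[2, 2])

  m <- matrix(runif(25) > 0.5, 5, 5) * 37
  expect_identical(binarize_mask(binarize_mask(m)), binarize_mask(m))

  # dark-on-light polarity: black cells on a white sheet
  dl <- matrix(255, 4, 4); dl[1, 2] <- 0
  expect_identical(binarize_mask(dl, polarity = "dark_on_light"), dl == 0)

  expect_error(binarize_mask(array(0, dim = c(2, 2, 4))),
               class = "hemaseg_format_error")
})

test_that("fuse_labels assigns pixel IDs with PLT > WBC > RBC priority", {
  z <- matrix(FALSE, 2, 2)
  rbc <- z; rbc[1, 1] <- TRUE
  expect_equal(fuse_labels(rbc, z, z)[1, 1], 1L)
  wbc <- z; wbc[2, 2] <- TRUE
  plt <- z; plt[1, 1] <- TRUE               # overlaps the RBC pixel
  fused <- fuse_labels(rbc, wbc, plt)
  expect_equal(fused[1, 1], 3L)             # overwrite order wins
  expect_equal(fused[2, 2], 2L)
  expect_equal(fused[1, 2], 0L)
  expect_identical(fuse_labels(z, z, z), matrix(0L, 2, 2))
  expect_error(fuse_labels(z, z, matrix(FALSE, 3, 2)),
               class = "hemaseg_dimension_error")
})

test_that("fuse_labels is pointwise and conserves the foreground union", {
  set.seed(5)
  for (k in 1:20) {
    rbc <- matrix(runif(64) < 0.4, 8, 8)
    wbc <- matrix(runif(64) < 0.2, 8, 8)
    plt <- matrix(runif(64) < 0.1, 8, 8)
    fused <- fuse_labels(rbc, wbc, plt)
    # pointwise recomputation
    for (i in 1:8) for (j in 1:8) {
      want <- if (plt[i, j]) 3L else if (wbc[i, j]) 2L else if (rbc[i, j]) 1L else 0L
      expect_identical(fused[i, j], want)
    }
    expect_equal(sum(fused > 0), sum(rbc | wbc | plt))
    # complement is the pointwise negation of the foreground
    expect_identical(background_complement(fused), !(rbc | wbc | plt))
  }
})

test_that("background_complement covers the degenerate masks", {
  expect_identical(background_complement(matrix(0L, 3, 3)), matrix(TRUE, 3, 3))
  expect_identical(background_complement(matrix(1L, 3, 3)), matrix(FALSE, 3, 3))
})

test_that("resize_pair keeps label values categorical and hits target shape", {
  # full-scale slide dimensions down to the network input
  big <- matrix(sample(0:3, 2592 * 1944, replace = TRUE), 2592, 1944)
  small <- resize_pair(NULL, big, 300, 300)$label
  expect_equal(dim(small), c(300L, 300L))
  expect_true(all(small %in% 0:3))

  set.seed(8)
  img <- array(runif(20 * 30 * 3), dim = c(20, 30, 3))
  lab <- random_label_mask(20, 30)
  same <- resize_pair(img, lab, 20, 30)
  expect_identical(same$label, lab)                   # identity resize
  expect_equal(same$image, img, tolerance = 1e-12)

  for (k in 1:10) {
    th <- sample(1:40, 1); tw <- sample(1:40, 1)
    out <- resize_pair(img, lab, th, tw)
    expect_equal(dim(out$label), c(th, tw))
    expect_equal(dim(out$image), c(th, tw, 3L))
    expect_true(all(out$label %in% 0:3))
  }
  expect_error(resize_pair(img, lab, 0, 10),
               class = "hemaseg_invalid_argument")
})

test_that("split_datastore partitions deterministically", {
  index <- data.frame(image = sprintf("i%03d.png", 1:108),
                      rbc_mask = "r", wbc_mask = "w", plt_mask = "p",
                      combined = "c", split = "",
                      stringsAsFactors = FALSE)
  s1 <- split_datastore(index, 103, 5, seed = 9)
  expect_equal(sum(s1$split == "train"), 103L)
  expect_equal(sum(s1$split == "test"), 5L)
  expect_identical(s1, split_datastore(index, 103, 5, seed = 9))
  expect_false(identical(s1$image, split_datastore(index, 103, 5, 10)$image))

  s0 <- split_datastore(index, 10, 0, seed = 1)
  expect_equal(unique(s0$split), "train")
  expect_equal(nrow(s0), 10L)

  expect_error(split_datastore(index, 108, 1, 1),
               class = "hemaseg_invalid_split")
})

test_that("label mask PNG write/read round-trip is the identity", {
  dir <- withr::local_tempdir()
  set.seed(3)
  for (k in 1:5) {
    lab <- random_label_mask(17, 23)
    p <- file.path(dir, sprintf("lab%d.png", k))
    write_label_mask(lab, p)
    expect_identical(read_label_mask(p), lab)
  }
})
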