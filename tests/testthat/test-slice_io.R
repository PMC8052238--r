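test_that("labeled_slice validates labels and derives z", {
  sl <- labeled_slice(matrix(0L, 5, 5), pixel_pitch = 2, slice_index = 3,
                      slice_distance = 100)
  expect_equal(sl$z, 300)
  expect_error(labeled_slice(matrix(12L, 2, 2), 1, 0), "label")
  expect_error(labeled_slice(matrix(0L, 2, 2), -1, 0), "pixel_pitch")
  expect_error(labeled_slice(matrix(0L, 2, 2), 1, -1), "slice_index")
})

test_that("PNG label images round-trip losslessly in both modes", {
  set.seed(7)
  lab <- matrix(sample(c(0:9, 10L), 30 * 20, replace = TRUE), 30, 20)
  sl <- labeled_slice(lab, 12, 2)
  cfg <- stack_config(pixel_pitch = 12)
  path <- withr::local_tempfile(fileext = ".png")
  write_label_slice(sl, path, mode = "rgb")
  expect_identical(read_label_slice(path, class_palette(), cfg, 2)$labels,
                   lab)
  write_label_slice(sl, path, mode = "gray")
  expect_identical(read_label_slice(path, class_palette(), cfg, 2)$labels,
                   lab)
})

test_that("an all-background image reads as zeros", {
  sl <- labeled_slice(matrix(0L, 8, 8), 10, 0)
  path <- withr::local_tempfile(fileext = ".png")
  write_label_slice(sl, path)
  got <- read_label_slice(path, class_palette(), stack_config(10), 0)
  expect_true(all(got$labels == 0L))
})

test_that("unknown colors are reported with color and pixel count", {
  arr <- array(0, c(4, 4, 3))
  arr[1, 1:2, ] <- rep(c(12, 34, 56) / 255, each = 2)
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr, path)
  expect_error(
    read_label_slice(path, class_palette(), stack_config(10), 0),
    "2 pixel\\(s\\).*rgb\\(12,34,56\\)"
  )
  expect_error(read_label_slice(file.path(tempdir(), "nope.png"),
                                class_palette(), stack_config(10), 0),
               "does not exist")
})

test_that("downsampling keeps 15% of the resolution by default", {
  big <- labeled_slice(matrix(0L, 1000, 600), 1, 0)
  d <- downsample_labels(big, 0.15)
  expect_identical(dim(d$labels), c(150L, 90L))
  # physical extent preserved within one output pixel per axis
  expect_lt(abs(nrow(d$labels) * d$pixel_pitch - 1000 * 1),
            d$pixel_pitch + 1e-9)
  expect_error(downsample_labels(big, 0), "keep_fraction")
  expect_error(downsample_labels(big, 1.2), "keep_fraction")
})

test_that("keep_fraction 1 is the identity", {
  sl <- labeled_slice(matrix(sample(0:9, 400, TRUE), 20, 20), 3, 0)
  expect_identical(downsample_labels(sl, 1), sl)
})

test_that("downsampling preserves area and creates no new labels", {
  m <- matrix(0L, 500, 500)
  idx <- as.matrix(expand.grid(1:500, 1:500))
  m[idx[(idx[, 1] - 250)^2 + (idx[, 2] - 250)^2 <= 200^2, ]] <- 9L
  d <- downsample_labels(labeled_slice(m, 1, 0), 0.15)
  area_ratio <- sum(d$labels == 9L) / (0.15^2 * sum(m == 9L))
  expect_lt(abs(area_ratio - 1), 0.05)
  expect_true(all(unique(as.vector(d$labels)) %in% unique(as.vector(m))))
})

test_that("stacks read in lexicographic slice order", {
  dir <- withr::local_tempdir()
  cfg <- stack_config(pixel_pitch = 10)
  for (i in 0:2) {
    lab <- matrix(0L, 6, 6); lab[i + 1, 1] <- 9L
    write_label_slice(labeled_slice(lab, 10, i),
                      file.path(dir, sprintf("slice_%03d.png", i)))
  }
  stack <- read_label_stack(dir, cfg)
  expect_length(stack, 3)
  for (i in 0:2) {
    expect_equal(stack[[i + 1]]$slice_index, i)
    expect_equal(stack[[i + 1]]$z, i * 100)
    expect_equal(which(stack[[i + 1]]$labels == 9L, arr.ind = TRUE)[1],
                 i + 1)
  }
})
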