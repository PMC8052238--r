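test_that("an empty raster yields no contours", {
  sl <- labeled_slice(matrix(0L, 10, 10), 1, 0)
  expect_identical(extract_contours(sl), list())
})

test_that("Moore tracing of a 3x3 square visits exactly the 8 border pixels", {
  m <- matrix(0L, 7, 7)
  m[3:5, 3:5] <- 4L
  sl <- labeled_slice(m, 1, 0)
  cts <- extract_contours(sl, min_pixels = 1)
  expect_length(cts, 1)
  expect_identical(cts[[1]]$tissue_class, 4L)
  # hand enumeration: border pixel centers of rows/cols 3..5 excluding the
  # center pixel, in um with pitch 1 (pixel (i,j) -> (j-1, i-1))
  expected <- expand.grid(x = 2:4, y = 2:4)
  expected <- expected[!(expected$x == 3 & expected$y == 3), ]
  got <- unique(round(cts[[1]]$points, 9))
  expect_equal(nrow(got), 8)
  expect_setequal(paste(got[, 1], got[, 2]),
                  paste(expected$x, expected$y))
})

test_that("disjoint components of one class give separate contours", {
  m <- matrix(0L, 30, 30)
  m[5:10, 5:10] <- 6L
  m[20:26, 18:25] <- 6L
  cts <- extract_contours(labeled_slice(m, 1, 0))
  expect_length(cts, 2)
  expect_true(all(vapply(cts, function(ct) ct$tissue_class, integer(1)) == 6L))
  expect_identical(sort(vapply(cts, function(ct) ct$component_id,
                               integer(1))), c(1L, 2L))
})

test_that("components below the size floor are dropped", {
  m <- matrix(0L, 20, 20)
  m[5:10, 5:10] <- 6L   # 36 px, kept
  m[15:16, 15:16] <- 6L # 4 px, below 16 px floor
  cts <- extract_contours(labeled_slice(m, 1, 0), min_pixels = 16)
  expect_length(cts, 1)
})

test_that("traced pixels equal the component's exposed boundary pixels", {
  # oracle: on solid convex-ish components, the Moore-traced set is exactly
  # the pixels with a 4-neighbor outside the mask
  set.seed(9)
  for (rep in 1:3) {
    m <- matrix(0L, 60, 60)
    cx <- sample(20:40, 1); cy <- sample(20:40, 1); r <- sample(8:14, 1)
    idx <- as.matrix(expand.grid(1:60, 1:60))
    m[idx[(idx[, 1] - cx)^2 + (idx[, 2] - cy)^2 <= r^2, ]] <- 9L
    cts <- extract_contours(labeled_slice(m, 1, 0))
    expect_length(cts, 1)
    traced <- unique(round(cts[[1]]$points))
    mask <- m == 9L
    pad <- matrix(FALSE, 62, 62); pad[2:61, 2:61] <- mask
    exposed <- mask
    for (i in 1:60) for (j in 1:60) {
      if (!mask[i, j]) { exposed[i, j] <- FALSE; next }
      nb <- pad[i:(i + 2), j:(j + 2)]
      exposed[i, j] <- !(nb[1, 2] && nb[3, 2] && nb[2, 1] && nb[2, 3])
    }
    epix <- which(exposed, arr.ind = TRUE)
    expect_setequal(paste(traced[, 1], traced[, 2]),
                    paste(epix[, 2] - 1, epix[, 1] - 1))
  }
})

test_that("all extracted contours are counterclockwise (positive area)", {
  gen <- generate_phantom_stack(one_patch_spec(n_slices = 4))
  cts <- extract_contours(gen$slices[[3]])
  expect_gt(length(cts), 0)
  for (ct in cts) expect_gt(polygon_area(ct$points), 0)
})

test_that("resampling a side-4 square to 8 points spaces them exactly 2 apart", {
  sq <- contour2d(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)), 1)
  r8 <- resample_contour(sq, 8)
  expect_equal(nrow(r8$points), 8)
  # spacing derived from perimeter 16 / 8 points = 2
  d <- sqrt(rowSums((r8$points - r8$points[c(2:8, 1), ])^2))
  expect_equal(d, rep(2, 8))
  # starts at the original start vertex
  expect_equal(r8$points[1, ], c(0, 0))
})

test_that("resampling an already-uniform contour is a fixed point", {
  ct <- circle_contour(n = 32)
  r <- resample_contour(ct, 32)
  expect_equal(r$points, ct$points, tolerance = 1e-10)
})

test_that("perimeter is invariant within 1% for dense resampling", {
  ct <- blob_contour(n = 256)
  p0 <- polygon_perimeter(ct$points)
  for (n in c(64, 128)) {
    expect_lt(abs(polygon_perimeter(resample_contour(ct, n)$points) - p0) / p0,
              0.01)
  }
  expect_error(resample_contour(ct, 2), "n")
})

test_that("contours serialize to JSON lines and back", {
  cts <- list(circle_contour(class = 6L), blob_contour(class = 3L))
  cts[[1]]$slice_index <- 4L
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_contours_jsonl(cts, path)
  back <- read_contours_jsonl(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$points, cts[[1]]$points)
  expect_identical(back[[1]]$tissue_class, 6L)
  expect_identical(back[[1]]$slice_index, 4L)
})

test_that("rasterization and point-in-polygon agree on a known shape", {
  ct <- circle_contour(r = 20, center = c(30, 30), n = 128)
  ras <- rasterize_contour(ct, pitch = 1)
  # disk area pi r^2 within a few percent at 1 um pitch
  expect_lt(abs(sum(ras$mask) - pi * 400) / (pi * 400), 0.05)
})
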