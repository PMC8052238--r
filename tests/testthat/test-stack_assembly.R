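test_that("self-registration returns the identity transform", {
  ps <- phantom_slice_points()
  tr <- register_slices_cpd(ps$points, ps$points)
  expect_lt(max(abs(tr$linear - diag(2))), 1e-6)
  expect_lt(max(abs(tr$translation)), 1e-3)
})

test_that("a known affine applied to slice contours is recovered exactly", {
  ps <- phantom_slice_points()
  known <- rot_scale_affine(10, 1.05, c(30, -20))
  moved <- apply_affine(known, ps$points)
  rec <- register_slices_cpd(moved, ps$points,
                             moving_labels = ps$labels,
                             fixed_labels = ps$labels)
  # recovered o known = identity: RMS on the points
  err <- apply_affine(rec, moved) - ps$points
  expect_lt(sqrt(mean(rowSums(err^2))), 1)
})

test_that("registration tolerates 5% outlier points", {
  ps <- phantom_slice_points()
  known <- rot_scale_affine(10, 1.05, c(30, -20))
  moved <- apply_affine(known, ps$points)
  set.seed(11)
  n_out <- round(0.05 * nrow(moved))
  junk <- cbind(runif(n_out, 0, 3600), runif(n_out, 0, 3600))
  rec <- register_slices_cpd(rbind(moved, junk), ps$points,
                             moving_labels = c(ps$labels,
                                               rep(1L, n_out)),
                             fixed_labels = ps$labels)
  err <- apply_affine(rec, moved) - ps$points
  expect_lt(sqrt(mean(rowSums(err^2))), 5)
})

test_that("degenerate point sets are a registration error", {
  line <- cbind(1:20, 2 * (1:20))
  good <- blob_contour()$points
  expect_error(register_slices_cpd(line, good), "degenerate")
  expect_error(register_slices_cpd(good, line), "degenerate")
})

test_that("matching is restricted to equal tissue classes", {
  a <- circle_contour(r = 100, center = c(500, 500), n = 32, class = 6L)
  b <- circle_contour(r = 105, center = c(500, 500), n = 32, class = 6L)
  m <- match_contours(list(a), list(b), match_config())
  expect_equal(nrow(m), 1)
  b8 <- b; b8$tissue_class <- 8L
  expect_equal(nrow(match_contours(list(a), list(b8), match_config())), 0)
})

test_that("the nearer of two candidates wins (greedy and optimal agree)", {
  prev <- list(circle_contour(r = 100, center = c(500, 500), class = 6L))
  nxt <- list(circle_contour(r = 100, center = c(540, 500), class = 6L),
              circle_contour(r = 100, center = c(590, 500), class = 6L))
  nxt[[2]]$component_id <- 2L
  # brute force over the two possible single-pair assignments: center
  # distances are 40 and 90, so the 40 um candidate must win
  for (method in c("greedy", "optimal")) {
    m <- match_contours(prev, nxt, match_config(), method = method)
    expect_equal(nrow(m), 1)
    expect_equal(m$next_, 1)
    expect_equal(m$center_distance, 40, tolerance = 1e-9)
  }
})

test_that("matching is a partial injection and respects thresholds", {
  set.seed(13)
  prev <- lapply(1:3, function(i) {
    circle_contour(r = 80, center = c(400 * i, 500), class = 6L)
  })
  nxt <- lapply(1:4, function(i) {
    ct <- circle_contour(r = 80, center = c(400 * i + runif(1, -30, 30),
                                            500 + runif(1, -30, 30)),
                         class = 6L)
    ct$component_id <- i
    ct
  })
  m <- match_contours(prev, nxt, match_config())
  expect_false(any(duplicated(m$prev)))
  expect_false(any(duplicated(m$next_)))
  expect_true(all(m$center_distance <= 500))
  expect_true(all(m$mean_point_distance <= 400))
  # a far-away contour never matches
  far <- list(circle_contour(r = 80, center = c(4000, 4000), class = 6L))
  expect_equal(nrow(match_contours(far, nxt, match_config())), 0)
})

test_that("point clouds lift contours to z = slice_index x slice_distance", {
  track <- structure(list(
    tissue_class = 6L,
    contours = lapply(3:7, function(k) {
      ct <- circle_contour(r = 90, center = c(500, 500), n = 24, class = 6L)
      ct$slice_index <- k
      ct
    }),
    slice_indices = 3:7,
    link_center_distance = numeric(4),
    link_mean_point_distance = numeric(4)
  ), class = "segment_track")
  clouds <- build_point_clouds(list(track), slice_distance = 100)
  expect_length(clouds, 1)
  expect_setequal(unique(clouds[[1]]$points[, 3]), c(300, 400, 500, 600, 700))
  expect_equal(nrow(clouds[[1]]$points), 5 * 24)
  # slice 0 lifts to z = 0
  track$contours[[1]]$slice_index <- 0L
  track$slice_indices[1] <- 0L
  expect_true(0 %in% build_point_clouds(list(track), 100)[[1]]$points[, 3])
})

test_that("tracks recovered from a phantom are class-pure and contiguous", {
  gen <- generate_phantom_stack(one_patch_spec(n_slices = 8))
  cbs <- lapply(gen$slices, function(sl) {
    wc <- wall_contours(sl)
    cts <- extract_contours(sl)
    # drop the background wall component (class 9 spanning the annulus)
    keep <- vapply(cts, function(ct) {
      !(ct$tissue_class == 9L &&
          polygon_area(ct$points) > 0.8 * polygon_area(wc$outer$points))
    }, logical(1))
    c(cts[keep], list(wc$inner, wc$outer))
  })
  asm <- build_tracks(cbs, match_config())
  for (tr in asm$tracks) {
    expect_length(unique(vapply(tr$contours, function(ct) ct$tissue_class,
                                integer(1))), 1)
    expect_true(all(diff(tr$slice_indices) == 1))
    # resampled to the first contour's point count
    counts <- vapply(tr$contours, function(ct) nrow(ct$points), integer(1))
    expect_true(all(counts == counts[1]))
  }
  # the class-6 patch spans slices 2..5: one track of length 4
  t6 <- asm$tracks[vapply(asm$tracks, function(t) t$tissue_class == 6L,
                          logical(1))]
  expect_length(t6, 1)
  expect_identical(t6[[1]]$slice_indices, 2:5)
})
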