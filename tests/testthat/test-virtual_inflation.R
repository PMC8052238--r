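test_that("points sampled on a circle fit exactly", {
  ct <- circle_contour(r = 100, center = c(0, 0), n = 32)
  fit <- fit_inner_circle(ct)
  expect_equal(fit$center, c(0, 0), tolerance = 1e-9)
  expect_equal(fit$radius, 100, tolerance = 1e-9)
  expect_lt(fit$residual, 1e-9)
})

test_that("an ellipse fits to a radius strictly between its semi-axes", {
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  ct <- contour2d(cbind(100 * cos(th), 50 * sin(th)), 10L)
  fit <- fit_inner_circle(ct)
  expect_gt(fit$radius, 50)
  expect_lt(fit$radius, 100)
  expect_gt(fit$residual, 0)
})

test_that("the circle fit is translation-equivariant", {
  ct <- blob_contour(r0 = 80, center = c(0, 0), n = 48)
  f0 <- fit_inner_circle(ct)
  ct2 <- ct; ct2$points <- sweep(ct$points, 2, -c(37.5, -12.25))
  f1 <- fit_inner_circle(ct2)
  expect_equal(f1$center, f0$center + c(37.5, -12.25), tolerance = 1e-8)
  expect_equal(f1$radius, f0$radius, tolerance = 1e-8)
})

test_that("collinear points are rejected", {
  pts <- cbind(1:10, 2 * (1:10))
  expect_error(fit_inner_circle(contour2d(pts, 10L)), "collinear|degenerate")
})

make_wall_slice <- function() {
  gen <- generate_phantom_stack(one_patch_spec(n_slices = 4))
  sl <- gen$slices[[2]]
  wc <- wall_contours(sl)
  list(slice = sl, inner = wc$inner, outer = wc$outer)
}

test_that("t = 0 leaves the raster untouched", {
  w <- make_wall_slice()
  out <- inflate_slice(w$slice, w$inner, w$outer, inflation_config(0))
  expect_identical(out$slice$labels, w$slice$labels)
  expect_true(all(out$displacement$dx == 0))
})

test_that("t = 1 projects the inner contour onto the fitted circle", {
  w <- make_wall_slice()
  warp <- inflation_warp(w$inner, w$outer, inflation_config(1))
  wp <- warp_points(warp, w$inner$points)
  rr <- sqrt((wp[, 1] - warp$fit$center[1])^2 +
               (wp[, 2] - warp$fit$center[2])^2)
  # on the circle within half a pixel (12 um pitch)
  expect_lt(max(abs(rr - warp$fit$radius)), 6)
  # circularity: relative radial spread under 1%
  expect_lt(sd(rr) / mean(rr), 0.01)
})

test_that("t = 0.4 interpolates radii as (1-t) r + t R along each ray", {
  w <- make_wall_slice()
  warp <- inflation_warp(w$inner, w$outer, inflation_config(0.4))
  pts <- w$inner$points[seq(1, nrow(w$inner$points), by = 7), ]
  r0 <- sqrt((pts[, 1] - warp$fit$center[1])^2 +
               (pts[, 2] - warp$fit$center[2])^2)
  wp <- warp_points(warp, pts)
  r1 <- sqrt((wp[, 1] - warp$fit$center[1])^2 +
               (wp[, 2] - warp$fit$center[2])^2)
  # oracle: direct evaluation of the interpolation formula along the ray
  expect_equal(r1, 0.6 * r0 + 0.4 * warp$fit$radius, tolerance = 1e-2)
})

test_that("radial misfit is non-increasing in t and the outer boundary is fixed", {
  w <- make_wall_slice()
  prev <- Inf
  for (t in c(0, 0.25, 0.5, 0.75, 1)) {
    warp <- inflation_warp(w$inner, w$outer, inflation_config(t))
    wp <- warp_points(warp, w$inner$points)
    mis <- mean(abs(sqrt((wp[, 1] - warp$fit$center[1])^2 +
                           (wp[, 2] - warp$fit$center[2])^2) -
                      warp$fit$radius))
    expect_lte(mis, prev + 1e-9)
    prev <- mis
    # outer-contour displacement vanishes (up to angular binning)
    wo <- warp_points(warp, w$outer$points)
    expect_lt(max(abs(wo - w$outer$points)), 1)
  }
})

test_that("warping transports labels without inventing classes", {
  w <- make_wall_slice()
  out <- inflate_slice(w$slice, w$inner, w$outer, inflation_config(0.4))
  expect_true(all(unique(as.vector(out$slice$labels)) %in%
                    unique(as.vector(w$slice$labels))))
  expect_identical(dim(out$slice$labels), dim(w$slice$labels))
})

test_that("contours that cross each other are a geometry error", {
  inner <- circle_contour(r = 120, center = c(200, 200), n = 32, class = 10L)
  outer <- circle_contour(r = 100, center = c(260, 200), n = 32, class = 11L)
  expect_error(inflation_warp(inner, outer), "geometry error")
})
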