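test_that("a patch-free phantom fills the whole wall with intact tissue", {
  spec <- phantom_spec(n_slices = 3, patches = list(), seed = 1)
  gen <- generate_phantom_stack(spec)
  for (sl in gen$slices) {
    wall <- sl$labels[sl$labels %in% 1:9]
    expect_true(all(wall == 9L))
    expect_true(all(unique(as.vector(sl$labels)) %in% c(0L, 9L, 10L)))
  }
})

test_that("patches appear on exactly their slice span", {
  spec <- one_patch_spec(n_slices = 8) # class 6 on slices 2..5
  gen <- generate_phantom_stack(spec)
  present <- vapply(gen$slices, function(sl) any(sl$labels == 6L),
                    logical(1))
  expect_identical(which(present) - 1L, 2:5)
})

test_that("generation is bit-identical under a fixed seed", {
  spec <- one_patch_spec(jitter = TRUE, seed = 7)
  g1 <- generate_phantom_stack(spec)
  g2 <- generate_phantom_stack(spec)
  for (k in seq_along(g1$slices)) {
    expect_identical(g1$slices[[k]]$labels, g2$slices[[k]]$labels)
  }
  expect_identical(g1$truth$jitter, g2$truth$jitter)
  # a different seed changes the jittered rasters
  g3 <- generate_phantom_stack(one_patch_spec(jitter = TRUE, seed = 8))
  expect_false(identical(g1$slices[[3]]$labels, g3$slices[[3]]$labels))
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(n_slices = 5), "patches") # default span 4..13
  expect_error(phantom_spec(patches = list(list(class = 6L,
                                                theta = c(0, 1),
                                                radial = c(0.9, 0.1),
                                                slices = c(1L, 3L)))),
               "radial")
  expect_error(phantom_spec(image_size = 60), "image_size")
})

test_that("analytic wall volume matches the cylinder-shell closed form", {
  # a = 1 mm, b = 1.5 mm, h = 2 mm: V = pi (b^2 - a^2) h
  spec <- phantom_spec(n_slices = 21, image_size = 340, pixel_pitch = 12,
                       lumen_radius = 1000, eccentricity = 0,
                       wall_thickness = 500, patches = list(), seed = 1)
  gen <- generate_phantom_stack(spec)
  expect_equal(gen$truth$wall_volume, pi * (1.5^2 - 1^2) * 2 * 1e9,
               tolerance = 1e-6)
  expect_equal(gen$truth$z_range, c(0, 2000))
})

test_that("per-patch analytic areas integrate to the patch slab volume", {
  spec <- one_patch_spec(n_slices = 8)
  gen <- generate_phantom_stack(spec)
  p <- gen$truth$patches[[1]]
  expect_identical(p$slice_span, c(2L, 5L))
  expect_equal(p$n_slices, 4L)
  # pixel-counted areas agree with the quadrature areas within 3%
  for (k in (p$slice_span[1]:p$slice_span[2]) + 1L) {
    pix <- sum(gen$slices[[k]]$labels == p$class) *
      gen$slices[[k]]$pixel_pitch^2
    expect_lt(abs(pix - p$area_per_slice[k]) / p$area_per_slice[k], 0.03)
  }
})

test_that("jitter stays within its declared bounds", {
  spec <- one_patch_spec(jitter = TRUE, seed = 9)
  gen <- generate_phantom_stack(spec)
  for (k in seq_along(gen$truth$jitter)) {
    J <- gen$truth$jitter[[k]]
    ang <- atan2(J$linear[2, 1], J$linear[1, 1]) * 180 / pi
    expect_lte(abs(ang), 5 + 1e-9)
    if (k == 1) expect_equal(J$linear, diag(2))
  }
})
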