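test_that("the midpoint of a circle is its center", {
  ct <- circle_contour(r = 50, center = c(200, 300), n = 64)
  mid <- contour_midpoint(ct, pitch = 1)
  expect_lt(max(abs(mid - c(200, 300))), 1)
})

test_that("the midpoint of an elongated rectangle is its center", {
  ct <- contour2d(rbind(c(0, 0), c(40, 0), c(40, 10), c(0, 10)), 1)
  mid <- contour_midpoint(ct, pitch = 1)
  # the maximal-clearance medial point, within one pixel of (20, 5)
  expect_lt(abs(mid[1] - 20), 1 + 1e-9)
  expect_lt(abs(mid[2] - 5), 1 + 1e-9)
})

test_that("the midpoint of an L-shaped contour lies inside it", {
  ct <- contour2d(rbind(c(0, 0), c(30, 0), c(30, 10), c(10, 10),
                        c(10, 30), c(0, 30)), 1)
  mid <- contour_midpoint(ct, pitch = 1)
  expect_true(points_in_polygon(mid[1], mid[2], ct$points))
})

test_that("degenerate masks raise a midpoint error", {
  thin <- contour2d(rbind(c(0, 0), c(10, 0), c(10, 0.01), c(0, 0.01)), 1)
  expect_error(contour_midpoint(thin, pitch = 1), "midpoint error")
})

make_circle_track <- function(radius = 300, slices = 2:6, n = 48) {
  structure(list(
    tissue_class = 6L,
    contours = lapply(slices, function(k) {
      ct <- circle_contour(r = radius, center = c(500, 500), n = n,
                           class = 6L)
      ct$slice_index <- k
      ct
    }),
    slice_indices = slices,
    link_center_distance = numeric(length(slices) - 1),
    link_mean_point_distance = numeric(length(slices) - 1)
  ), class = "segment_track")
}

test_that("caps follow the parabolic profile with a fixed midpoint", {
  track <- make_circle_track(radius = 300)
  cloud <- build_point_clouds(list(track), 100)[[1]]
  capped <- add_caps(cloud, track, slice_distance = 100)
  info <- attr(capped, "cap_info")
  expect_length(info, 2)
  for (side in info) {
    # scale factors strictly decreasing toward the apex
    expect_true(all(diff(side$scales) < 0))
    expect_true(all(side$scales > 0))
    # ring-count rule and apex height
    expect_equal(side$rings, max(2, ceiling(side$height / 100)))
    # the paraboloid of revolution: s_j = sqrt(1 - j/(k+1))
    k <- side$rings
    expect_equal(side$scales, sqrt(1 - seq_len(k) / (k + 1)),
                 tolerance = 1e-12)
    # midpoint of a circle is its center
    expect_lt(max(abs(side$midpoint - c(500, 500))), 7)
  }
  # ring j of a circle of radius R has radius R * s_j (check first ring)
  z0 <- min(cloud$points[, 3])
  h <- info[[1]]$height; k <- info[[1]]$rings
  ring1 <- capped$points[abs(capped$points[, 3] - (z0 - h / (k + 1))) < 1e-9, ]
  r1 <- sqrt((ring1[, 1] - info[[1]]$midpoint[1])^2 +
               (ring1[, 2] - info[[1]]$midpoint[2])^2)
  expect_equal(mean(r1), 300 * sqrt(1 - 1 / (k + 1)), tolerance = 7)
  # cap z-extent is bounded by mean radius + one slice distance
  expect_lte(max(abs(range(capped$points[, 3]) - range(cloud$points[, 3]))),
             info[[1]]$height + 100)
  # apex sits exactly at the midpoint
  apex <- capped$points[which.min(capped$points[, 3]), ]
  expect_equal(unname(apex[1:2]), unname(info[[1]]$midpoint))
})

test_that("a sphere cloud shrink-wraps to the analytic volume within 5%", {
  set.seed(5)
  n <- 2000
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2)) * 500
  cloud <- structure(list(points = sweep(v, 2, -1000), tissue_class = 9L,
                          track_id = 1L), class = "point_cloud3")
  mesh <- fit_mesh(cloud)
  expect_lt(abs(mesh$volume - 4 / 3 * pi * 500^3) / (4 / 3 * pi * 500^3),
            0.05)
  chk <- mesh_check(mesh)
  expect_true(chk$closed && chk$oriented && chk$no_duplicate_faces &&
                chk$positive_volume)
})

test_that("fitted tube meshes stay close to their capped clouds", {
  track <- make_circle_track(radius = 400, slices = 0:5)
  cloud <- build_point_clouds(list(track), 100)[[1]]
  capped <- add_caps(cloud, track, 100)
  mesh <- fit_mesh(capped)
  expect_true(mesh_check(mesh)$ok)
  expect_lt(mesh_cloud_distance(mesh, capped), 2 * 100)
})

test_that("mesh volume is exact on a hand-built cube", {
  cube <- unit_cube_mesh()
  expect_equal(cube$volume, 1)
  expect_true(mesh_check(cube)$ok)
})

test_that("mesh_check flags holes and duplicate faces", {
  cube <- unit_cube_mesh()
  holed <- cube; holed$faces <- holed$faces[-1, ]
  expect_false(mesh_check(holed)$closed)
  dup <- cube; dup$faces <- rbind(dup$faces, dup$faces[1, ])
  expect_false(mesh_check(dup)$no_duplicate_faces)
})

test_that("disjoint meshes pass through cleanup unchanged", {
  ico <- icosphere(2)
  a <- surface_mesh(ico$vertices * 100, ico$faces, 6L)
  b <- surface_mesh(sweep(ico$vertices * 100, 2, c(-400, 0, 0)), ico$faces,
                    8L)
  out <- clean_and_filter(list(a, b), mesh_config(min_volume = 0))
  expect_length(out, 2)
  expect_identical(out[[1]]$vertices, a$vertices)
  expect_identical(out[[2]]$vertices, b$vertices)
})

test_that("overlapping spheres are separated with volume preserved", {
  ico <- icosphere(3)
  a <- surface_mesh(ico$vertices, ico$faces, 9L)
  b <- surface_mesh(sweep(ico$vertices, 2, c(-0.5, 0, 0)), ico$faces, 6L)
  va <- a$volume
  out <- clean_and_filter(list(a, b), mesh_config(min_volume = 0,
                                                  grid_n = 96))
  expect_length(out, 2)
  # zero residual intersection (within 1e-6 of the smaller volume)
  vols <- vapply(out, function(m) m$volume, numeric(1))
  expect_lt(mesh_intersection_volume(out[[1]], out[[2]], 96),
            1e-6 * min(vols))
  # union volume preserved within 1%: sum of outputs vs mesh of the union
  # (lens volume of two equal spheres: pi (4R + d)(2R - d)^2 / 12)
  lens <- pi * (4 * 1 + 0.5) * (2 * 1 - 0.5)^2 / 12
  expect_lt(abs(sum(vols) - (2 * va - lens)) / (2 * va - lens), 0.01)
  for (m in out) expect_true(mesh_check(m)$ok)
})

test_that("structures below the volume floor are removed and logged", {
  ico <- icosphere(2)
  big <- surface_mesh(ico$vertices * 800, ico$faces, 9L)   # ~2.1 mm^3
  small <- surface_mesh(sweep(ico$vertices * 480, 2, c(3000, 0, 0)),
                        ico$faces, 6L)                      # ~0.45 mm^3
  withr::local_options(histowall3d.log_level = "info")
  expect_message(
    out <- clean_and_filter(list(big, small), mesh_config(min_volume = 1e9)),
    "neglecting structure smaller than"
  )
  expect_length(out, 1)
  expect_identical(out[[1]]$tissue_class, 9L)
})

test_that("meshes serialize to ASCII PLY and STL", {
  cube <- unit_cube_mesh()
  ply <- withr::local_tempfile(fileext = ".ply")
  stl <- withr::local_tempfile(fileext = ".stl")
  write_ply(cube, ply)
  write_stl(cube, stl)
  expect_match(readLines(ply, n = 1), "^ply$")
  expect_equal(sum(grepl("^element", readLines(ply))), 2)
  expect_match(readLines(stl, n = 1), "^solid")
  expect_equal(sum(grepl("facet normal", readLines(stl))), 12)
})
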