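# Shared fixtures, built in code at test time.

# quiet logging during tests unless a test asserts on messages
options(histowall3d.log_level = "warning")

# closed contour sampled on a circle
circle_contour <- function(r = 100, center = c(0, 0), n = 64, class = 9L) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour2d(cbind(center[1] + r * cos(th), center[2] + r * sin(th)), class)
}

# irregular star-shaped blob (breaks rotational symmetry)
blob_contour <- function(r0 = 500, center = c(1000, 900), n = 64,
                         class = 9L) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- r0 + 0.16 * r0 * cos(2 * th) + 0.1 * r0 * sin(3 * th) +
    0.06 * r0 * cos(5 * th)
  contour2d(cbind(center[1] + r * cos(th), center[2] + r * sin(th)), class)
}

rot_scale_affine <- function(deg, s = 1, shift = c(0, 0)) {
  phi <- deg * pi / 180
  affine2d(s * matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2),
           shift)
}

# small phantom with one persisting patch, shared across tests
one_patch_spec <- function(n_slices = 8L, jitter = FALSE, seed = 4L) {
  s0 <- min(2L, n_slices - 2L)
  s1 <- min(5L, n_slices - 1L)
  phantom_spec(
    n_slices = n_slices, image_size = 290, pixel_pitch = 12,
    eccentricity = 0.12,
    patches = list(list(class = 6L, theta = c(0.2, 1.2),
                        radial = c(0.15, 0.85), slices = c(s0, s1))),
    jitter = jitter, seed = seed
  )
}

# contour points + labels of one phantom slice (for registration tests)
phantom_slice_points <- function(seed = 3L, slice = 8L) {
  gen <- generate_phantom_stack(phantom_spec(seed = seed))
  sl <- gen$slices[[slice]]
  cts <- c(extract_contours(sl), unname(wall_contours(sl)))
  pts <- do.call(rbind, lapply(cts, function(ct) ct$points))
  labs <- unlist(lapply(cts, function(ct) rep(ct$tissue_class,
                                              nrow(ct$points))))
  keep <- seq(1, nrow(pts), by = 4)
  list(points = pts[keep, ], labels = labs[keep])
}

# unit cube as a closed, outward-oriented triangle mesh (volume exactly 1)
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5),  # x = 0
    c(2, 8, 4), c(2, 6, 8),  # x = 1
    c(1, 5, 6), c(1, 6, 2),  # y = 0
    c(3, 4, 8), c(3, 8, 7),  # y = 1
    c(1, 2, 4), c(1, 4, 3),  # z = 0
    c(5, 7, 8), c(5, 8, 6)   # z = 1
  )
  # normalize orientation: flip faces whose normal points into the cube
  ctr <- c(0.5, 0.5, 0.5)
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c_ <- v[f[i, 3], ]
    n <- c((b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
           (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
           (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1])
    if (sum(n * ((a + b + c_) / 3 - ctr)) < 0) f[i, ] <- f[i, c(1, 3, 2)]
  }
  surface_mesh(v, f, 9L)
}
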