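# Virtual inflation: postmortem specimens deflate, so the segmented lumen is
# collapsed/elliptical. Each slice is warped so the inner (lumen) contour
# moves toward its least-squares circle at a fixed interpolation weight
# t = 4/10; the warp decays linearly to zero at the outer wall contour, and
# labels are transported by the inverse warp (pull-back, nearest neighbor).

#' Inflation configuration
#'
#' @param t interpolation weight in `[0, 1]` between the observed inner
#'   contour (0) and its fitted circle (1). Default 0.4, the empirically
#'   suitable interpolation step.
#' @return object of class `inflation_config`.
#' @export
inflation_config <- function(t = 0.4) {
  check_that(is_number(t) && t >= 0 && t <= 1, "t", "must lie in [0, 1]")
  structure(list(t = t), class = "inflation_config")
}

#' Least-squares circle fit to a closed contour
#'
#' Algebraic (Kasa) fit: minimizes the linearized residual
#' `x^2 + y^2 - 2ax - 2by - c` over center `(a, b)` and `c = R^2 - a^2 -
#' b^2`. The reported residual is the root-mean-square radial misfit.
#'
#' @param inner_contour a [contour2d()] (>= 8 points, positive area).
#' @return object of class `circle_fit`: `center` (um), `radius` (um),
#'   `residual` (um RMS).
#' @export
fit_inner_circle <- function(inner_contour) {
  pts <- if (inherits(inner_contour, "contour2d")) inner_contour$points
         else as.matrix(inner_contour)
  check_that(nrow(pts) >= 8, "inner_contour", "needs at least 8 points")
  check_that(abs(polygon_area(pts)) > 0, "inner_contour",
             "is degenerate (zero area)")
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) {
    stop("circle fit failed: points are collinear or degenerate",
         call. = FALSE)
  })
  center <- sol[1:2]
  r2 <- sol[3] + sum(center^2)
  check_that(r2 > 0, "inner_contour", "circle fit produced radius <= 0")
  radius <- sqrt(r2)
  rr <- sqrt((x - center[1])^2 + (y - center[2])^2)
  structure(list(
    center = unname(center),
    radius = radius,
    residual = sqrt(mean((rr - radius)^2))
  ), class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("Circle fit: center (%.2f, %.2f) um, radius %.2f um, RMS %.3g um\n",
              x$center[1], x$center[2], x$radius, x$residual))
  invisible(x)
}

# internal: radial distance from `center` to a polygon along `angles`,
# nearest crossing. Returns list(r = radii, n_cross = crossings per angle).
.ray_radii <- function(poly, center, angles) {
  p1 <- sweep(poly, 2, center)
  p2 <- p1[c(2:nrow(p1), 1), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]
  ey <- p2[, 2] - p1[, 2]
  nr <- length(angles)
  r <- rep(NA_real_, nr)
  ncross <- integer(nr)
  for (k in seq_len(nr)) {
    ux <- cos(angles[k]); uy <- sin(angles[k])
    # solve p1 + t e = s u ; cross-product elimination
    den <- ex * uy - ey * ux
    ok <- abs(den) > 1e-12
    tt <- (p1[, 2] * ux - p1[, 1] * uy) / den
    ss <- (p1[, 1] * ey - p1[, 2] * ex) / (-den)
    hit <- ok & tt >= 0 & tt < 1 & ss > 0
    ncross[k] <- sum(hit)
    if (ncross[k] > 0) r[k] <- min(ss[hit])
  }
  list(r = r, n_cross = ncross)
}

#' Build the virtual-inflation warp for one slice
#'
#' Fits a circle to the inner contour and precomputes the per-angle inner
#' and outer wall radii about the fit center. The forward warp moves an
#' inner-contour point `p` to `(1 - t) p + t q`, where `q` is `p`'s radial
#' projection onto the fitted circle; inside the wall the displacement
#' decays linearly to zero at the outer contour (normalized radial
#' coordinate `s`: displacement `(1 - s)` times the inner-contour
#' displacement at the same angle); the lumen interior is rescaled
#' proportionally. Rays with multiple inner-contour crossings use the
#' nearest crossing (a warning reports the count of affected angular bins).
#'
#' @param inner_contour,outer_contour closed [contour2d()] wall contours;
#'   the inner contour must lie strictly inside the outer.
#' @param config an [inflation_config()].
#' @param nbins angular resolution of the radius tables (default 720).
#' @return object of class `inflation_warp` with the fit, the angular
#'   tables and the weight `t`.
#' @export
inflation_warp <- function(inner_contour, outer_contour,
                           config = inflation_config(), nbins = 720L) {
  inside <- points_in_polygon(inner_contour$points[, 1],
                              inner_contour$points[, 2],
                              outer_contour$points)
  if (!all(inside)) {
    stop("geometry error: inner contour is not strictly inside the outer contour",
         call. = FALSE)
  }
  fit <- fit_inner_circle(inner_contour)
  angles <- -pi + (seq_len(nbins) - 0.5) * 2 * pi / nbins
  rin <- .ray_radii(inner_contour$points, fit$center, angles)
  rout <- .ray_radii(outer_contour$points, fit$center, angles)
  multi <- sum(rin$n_cross > 1)
  if (multi > 0) {
    hw_log(sprintf(
      "non-star-shaped lumen: %d of %d angular bins have multiple inner crossings (using nearest)",
      multi, nbins), "warning")
  }
  if (anyNA(rin$r) || anyNA(rout$r)) {
    stop("geometry error: fit center lies outside a wall contour",
         call. = FALSE)
  }
  if (any(rout$r <= rin$r)) {
    stop("geometry error: inner and outer contours cross along some ray",
         call. = FALSE)
  }
  t <- config$t
  # inner-contour radial displacement per angle; clamp so the warped inner
  # radius stays strictly inside the outer contour
  delta <- t * (fit$radius - rin$r)
  lim <- 0.95 * (rout$r - rin$r)
  n_clamp <- sum(delta > lim)
  if (n_clamp > 0) {
    hw_log(sprintf(
      "inflation clamped in %d angular bins (fitted circle near/beyond outer wall)",
      n_clamp), "warning")
    delta <- pmin(delta, lim)
  }
  structure(list(
    fit = fit, t = t, angles = angles, nbins = nbins,
    r_in = rin$r, r_out = rout$r, delta = delta
  ), class = "inflation_warp")
}

# internal: angular bin index for query angles
.angle_bin <- function(warp, theta) {
  k <- round((theta + pi) * warp$nbins / (2 * pi) + 0.5)
  ((as.integer(k) - 1L) %% warp$nbins) + 1L
}

#' Apply the forward inflation warp to points
#'
#' @param warp an [inflation_warp()].
#' @param pts n x 2 matrix of (x, y) in um.
#' @return warped n x 2 matrix.
#' @export
warp_points <- function(warp, pts) {
  pts <- as.matrix(pts)
  dx <- pts[, 1] - warp$fit$center[1]
  dy <- pts[, 2] - warp$fit$center[2]
  r <- sqrt(dx^2 + dy^2)
  k <- .angle_bin(warp, atan2(dy, dx))
  rin <- warp$r_in[k]; rout <- warp$r_out[k]; d <- warp$delta[k]
  rho <- ifelse(r <= rin,
                r * (rin + d) / pmax(rin, .Machine$double.eps),
                ifelse(r <= rout,
                       r + d * (rout - r) / (rout - rin),
                       r))
  scale <- ifelse(r > 0, rho / r, 1)
  cbind(warp$fit$center[1] + dx * scale, warp$fit$center[2] + dy * scale)
}

# internal: inverse of the per-ray radial map (for label pull-back)
.inverse_radius <- function(warp, r, k) {
  rin <- warp$r_in[k]; rout <- warp$r_out[k]; d <- warp$delta[k]
  ri <- rin + d
  ifelse(r <= ri,
         r * rin / pmax(ri, .Machine$double.eps),
         ifelse(r <= rout,
                rout - (rout - r) * (rout - rin) / pmax(rout - ri,
                                                        .Machine$double.eps),
                r))
}

#' Virtually inflate a labeled slice
#'
#' Warps the slice so its inner (lumen) contour moves toward the fitted
#' circle at weight `t`; `t = 0` returns the input unchanged. Labels are
#' transported by the inverse warp with nearest-neighbor lookup (pull-back,
#' no holes); the displacement field returned is the forward displacement
#' at every input pixel.
#'
#' @param slice a [labeled_slice()].
#' @param inner_contour,outer_contour wall [contour2d()]s (see
#'   [wall_contours()]).
#' @param config an [inflation_config()].
#' @return list with `slice` (warped [labeled_slice()]) and `displacement`
#'   (list of matrices `dx`, `dy`, um, forward displacement per input pixel).
#' @export
inflate_slice <- function(slice, inner_contour, outer_contour,
                          config = inflation_config()) {
  nr <- nrow(slice$labels); nc <- ncol(slice$labels)
  pitch <- slice$pixel_pitch
  if (config$t == 0) {
    zero <- matrix(0, nr, nc)
    return(list(slice = slice, displacement = list(dx = zero, dy = zero)))
  }
  warp <- inflation_warp(inner_contour, outer_contour, config)
  xs <- (seq_len(nc) - 1) * pitch
  ys <- (seq_len(nr) - 1) * pitch
  px <- matrix(xs, nr, nc, byrow = TRUE)
  py <- matrix(ys, nr, nc)
  dx0 <- px - warp$fit$center[1]
  dy0 <- py - warp$fit$center[2]
  r <- sqrt(dx0^2 + dy0^2)
  k <- .angle_bin(warp, atan2(dy0, dx0))
  # pull-back: source radius for each output pixel
  rsrc <- .inverse_radius(warp, r, k)
  scale <- ifelse(r > 0, rsrc / r, 1)
  sx <- warp$fit$center[1] + dx0 * scale
  sy <- warp$fit$center[2] + dy0 * scale
  si <- pmin(nr, pmax(1L, as.integer(round(sy / pitch) + 1L)))
  sj <- pmin(nc, pmax(1L, as.integer(round(sx / pitch) + 1L)))
  labels2 <- matrix(slice$labels[cbind(as.vector(si), as.vector(sj))], nr, nc)
  out <- slice
  out$labels <- labels2
  # forward displacement field at input pixels
  fwd <- warp_points(warp, cbind(as.vector(px), as.vector(py)))
  list(
    slice = out,
    displacement = list(
      dx = matrix(fwd[, 1] - as.vector(px), nr, nc),
      dy = matrix(fwd[, 2] - as.vector(py), nr, nc)
    ),
    warp = warp
  )
}

#' Extract the inner and outer wall contours of a slice
#'
#' The inner wall contour is the outer boundary of the lumen region (label
#' 10); the outer wall contour is the outer boundary of the union of lumen
#' and all tissue labels. The largest connected component is used for each.
#'
#' @param slice a [labeled_slice()].
#' @return list with `inner` and `outer` [contour2d()]s (classes 10/11).
#' @export
wall_contours <- function(slice) {
  pitch <- slice$pixel_pitch
  one_contour <- function(mask, cls) {
    comp <- cpp_label_components(mask)
    check_that(max(comp) > 0, "slice", "has no pixels for a wall contour")
    sizes <- tabulate(comp[comp > 0])
    big <- which.max(sizes)
    px <- trace_moore(comp == big)
    pts <- cbind((px[, 2] - 1) * pitch, (px[, 1] - 1) * pitch)
    if (polygon_area(pts) < 0) {
      pts <- pts[c(1, rev(seq_len(nrow(pts))[-1])), , drop = FALSE]
    }
    contour2d(pts, cls, slice$slice_index, 1L)
  }
  solid <- slice$labels >= 1L & slice$labels <= 10L
  list(
    inner = one_contour(slice$labels == 10L, 10L),
    outer = one_contour(solid, 11L)
  )
}

#' Write a displacement field as two plain-text TSV matrices
#'
#' @param displacement list with matrices `dx`, `dy` (um).
#' @param path_prefix output prefix; writes `<prefix>_dx.tsv` and
#'   `<prefix>_dy.tsv`.
#' @return the two paths, invisibly.
#' @export
write_displacement_field <- function(displacement, path_prefix) {
  p1 <- paste0(path_prefix, "_dx.tsv")
  p2 <- paste0(path_prefix, "_dy.tsv")
  write.table(displacement$dx, p1, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  write.table(displacement$dy, p2, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(c(p1, p2))
}
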