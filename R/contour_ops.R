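# Coordinate convention used throughout: pixel (row i, col j), 1-based, maps
# to x = (j-1)*pitch, y = (i-1)*pitch (um). Origin at the top-left pixel
# center, y increases downward (image convention). Orientation is normalized
# so the shoelace signed area in this frame is positive.

#' Construct a 2D contour
#'
#' A closed boundary polyline of one tissue component on one slice. The
#' closing edge (last point back to first) is implied, not stored.
#'
#' @param points n x 2 numeric matrix of (x, y) coordinates in um, n >= 3.
#' @param tissue_class tissue class id (1-9), or the markers 10
#'   (wall-inner) / 11 (wall-outer).
#' @param slice_index slice the contour belongs to.
#' @param component_id connected-component id within (slice, class).
#' @return object of class `contour2d`.
#' @export
contour2d <- function(points, tissue_class, slice_index = 0L,
                      component_id = 1L) {
  points <- as.matrix(points)
  check_that(is.numeric(points) && ncol(points) == 2 && nrow(points) >= 3,
             "points", "must be a numeric n x 2 matrix with n >= 3")
  structure(list(
    points = unname(points),
    tissue_class = as.integer(tissue_class),
    slice_index = as.integer(slice_index),
    component_id = as.integer(component_id)
  ), class = "contour2d")
}

#' @export
print.contour2d <- function(x, ...) {
  cat(sprintf(
    "Contour (class %d, slice %d, component %d): %d points, area %.4g um^2\n",
    x$tissue_class, x$slice_index, x$component_id, nrow(x$points),
    polygon_area(x$points)))
  invisible(x)
}

#' Shoelace signed area of a closed polygon
#' @param points n x 2 matrix, closure implied.
#' @return signed area (positive in this package's normalized orientation).
#' @export
polygon_area <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Perimeter of a closed polygon
#' @param points n x 2 matrix, closure implied.
#' @return total polyline length including the closing edge.
#' @export
polygon_perimeter <- function(points) {
  d <- points - points[c(2:nrow(points), 1), ]
  sum(sqrt(rowSums(d^2)))
}

#' Arithmetic-mean center of a contour
#'
#' The center used for across-slice contour matching: the mean of the
#' (resampled) contour points.
#' @param contour a `contour2d` (or bare point matrix).
#' @return length-2 numeric (x, y) in um.
#' @export
contour_center <- function(contour) {
  pts <- if (inherits(contour, "contour2d")) contour$points else contour
  colMeans(pts)
}

#' Even-odd test for points inside a closed polygon
#' @param px,py query coordinates (vectors).
#' @param poly n x 2 polygon matrix, closure implied.
#' @return logical vector.
#' @export
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    crosses <- (y[e] <= py & py < yn[e]) | (yn[e] <= py & py < y[e])
    if (!any(crosses)) next
    xi <- x[e] + (py[crosses] - y[e]) * (xn[e] - x[e]) / (yn[e] - y[e])
    flip <- xi > px[crosses]
    inside[crosses][flip] <- !inside[crosses][flip]
  }
  inside
}

# internal: clockwise Moore neighborhood offsets (row, col), starting north
.moore_offs <- rbind(
  c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
  c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L)
)

# internal: Moore-neighbor boundary tracing with Jacob's stopping criterion.
# mask: logical matrix holding one 8-connected component. Returns k x 2
# matrix of boundary pixel (row, col) indices in traversal order.
trace_moore <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc &&
    mask[p[1], p[2]]
  # start: first foreground pixel scanning rows top-to-bottom, left-to-right
  hit <- which(t(mask))[1]
  s <- c((hit - 1L) %/% nc + 1L, (hit - 1L) %% nc + 1L)
  b0 <- s + c(0L, -1L) # background pixel examined just before the start
  cur <- s; back <- b0
  pts <- matrix(0L, nrow = 4L * sum(mask) + 8L, ncol = 2)
  pts[1, ] <- s
  np <- 1L
  repeat {
    d <- back - cur
    k0 <- which(.moore_offs[, 1] == d[1] & .moore_offs[, 2] == d[2])
    moved <- FALSE
    for (step in 1:8) {
      k <- ((k0 - 1L + step) %% 8L) + 1L
      cand <- cur + .moore_offs[k, ]
      if (at(cand)) {
        prevk <- ((k - 2L) %% 8L) + 1L
        back <- cur + .moore_offs[prevk, ]
        cur <- cand
        moved <- TRUE
        break
      }
    }
    if (!moved) break # isolated pixel
    # Jacob: stop when the start pixel is re-entered from the start direction
    if (cur[1] == s[1] && cur[2] == s[2] &&
        back[1] == b0[1] && back[2] == b0[2]) break
    np <- np + 1L
    if (np > nrow(pts)) break # safety guard, cannot trigger on valid masks
    pts[np, ] <- cur
  }
  pts[seq_len(np), , drop = FALSE]
}

#' Extract closed per-class boundary contours from a labeled slice
#'
#' For each tissue class present, the class's binary mask is split into
#' 8-connected components and the outer boundary of each component is traced
#' with the Moore-neighbor algorithm using Jacob's stopping criterion.
#' Components smaller than `min_pixels` are dropped and logged, as are
#' degenerate (zero-area) traces. Holes inside a component are ignored
#' (only the outer boundary is traced) and logged.
#'
#' @param slice a [labeled_slice()].
#' @param classes label values to process (default: tissue classes 1-9).
#' @param min_pixels component size floor in pixels (default 16;
#'   sub-resolution specks are segmentation noise).
#' @return list of [contour2d()] (possibly empty). Points are pixel centers
#'   in um, orientation normalized to positive signed area.
#' @export
extract_contours <- function(slice, classes = 1:9, min_pixels = 16L) {
  out <- list()
  pitch <- slice$pixel_pitch
  present <- intersect(classes, unique(as.vector(slice$labels)))
  for (cl in present) {
    mask <- slice$labels == cl
    comp <- cpp_label_components(mask)
    ncomp <- max(comp)
    kept <- 0L
    for (ci in seq_len(ncomp)) {
      cmask <- comp == ci
      sz <- sum(cmask)
      if (sz < min_pixels) {
        hw_log(sprintf(
          "slice %d class %d: dropping component of %d px (< %d px floor)",
          slice$slice_index, cl, sz, min_pixels), "debug")
        next
      }
      px <- trace_moore(cmask)
      if (nrow(px) < 3) next
      pts <- cbind((px[, 2] - 1) * pitch, (px[, 1] - 1) * pitch)
      a <- polygon_area(pts)
      if (a == 0) {
        hw_log(sprintf(
          "slice %d class %d: dropping degenerate (zero-area) component",
          slice$slice_index, cl), "debug")
        next
      }
      if (a < 0) pts <- pts[c(1, rev(seq_len(nrow(pts))[-1])), , drop = FALSE]
      kept <- kept + 1L
      out[[length(out) + 1L]] <- contour2d(pts, cl, slice$slice_index, kept)
      # interior background enclosed by the component (holes) is ignored at
      # contour level: only the outer boundary is traced; log when present
      bg <- cpp_label_components(!cmask)
      border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
      holes <- setdiff(unique(as.vector(bg)), c(0L, border_ids))
      if (length(holes) > 0) {
        hw_log(sprintf(
          "slice %d class %d component %d: ignoring %d interior hole(s)",
          slice$slice_index, cl, kept, length(holes)), "debug")
      }
    }
  }
  out
}

#' Resample a closed contour to n points by arc length
#'
#' Places `n` points uniformly spaced by arc length along the closed
#' polyline, starting at the original start vertex; orientation is
#' preserved and the perimeter is invariant up to polyline discretization.
#'
#' @param contour a [contour2d()].
#' @param n number of output points (>= 3).
#' @return a resampled [contour2d()].
#' @export
resample_contour <- function(contour, n) {
  check_that(is_number(n) && n >= 3 && n == round(n),
             "n", "must be an integer >= 3")
  pts <- contour$points
  m <- nrow(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] -
                         closed[-(m + 1), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  per <- cum[m + 1]
  check_that(per > 0, "contour", "has zero perimeter")
  targets <- (seq_len(n) - 1) * per / n
  # locate each target on the cumulative-length axis
  idx <- findInterval(targets, cum, rightmost.closed = TRUE)
  idx[idx > m] <- m
  frac <- (targets - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  new_pts <- closed[idx, , drop = FALSE] +
    (closed[idx + 1, , drop = FALSE] - closed[idx, , drop = FALSE]) * frac
  out <- contour
  out$points <- new_pts
  out
}

#' Serialize contours to a JSON-lines file
#'
#' One JSON object per line: `slice_index`, `tissue_class`, `component_id`,
#' and the point array in um.
#'
#' @param contours list of [contour2d()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contours_jsonl <- function(contours, path) {
  lines <- vapply(contours, function(ct) {
    jsonlite::toJSON(list(
      slice_index = ct$slice_index,
      tissue_class = ct$tissue_class,
      component_id = ct$component_id,
      points = unname(ct$points)
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read contours from a JSON-lines file
#' @param path file written by [write_contours_jsonl()].
#' @return list of [contour2d()].
#' @export
read_contours_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    contour2d(obj$points, obj$tissue_class, obj$slice_index, obj$component_id)
  })
}

#' Rasterize a closed contour to a binary mask
#'
#' Even-odd scanline fill over a pixel grid aligned with the package's
#' pixel-center convention.
#'
#' @param contour a [contour2d()] (points in um).
#' @param pitch um per pixel of the output mask.
#' @param margin extra pixels of background padding around the bounding box.
#' @return list with `mask` (logical matrix), `origin` (um coordinates of
#'   pixel (1,1) center, length-2 `c(x, y)`), `pitch`.
#' @export
rasterize_contour <- function(contour, pitch, margin = 2L) {
  pts <- contour$points
  x0 <- min(pts[, 1]) - margin * pitch
  y0 <- min(pts[, 2]) - margin * pitch
  nc <- ceiling((max(pts[, 1]) - x0) / pitch) + margin + 1L
  nr <- ceiling((max(pts[, 2]) - y0) / pitch) + margin + 1L
  xs <- x0 + (seq_len(nc) - 1) * pitch
  ys <- y0 + (seq_len(nr) - 1) * pitch
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    mask[i, ] <- points_in_polygon(xs, rep(ys[i], nc), pts)
  }
  list(mask = mask, origin = c(x0, y0), pitch = pitch)
}
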