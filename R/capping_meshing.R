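# Closing point clouds with parabolic caps, shrink-wrap surface fitting and
# voxel-field boolean cleanup. Meshes must be closed, manifold and free of
# duplicate faces to be usable by structural solvers; sub-resolution
# structures (< 1 mm^3 by default) are neglected.

#' Meshing configuration
#'
#' @param min_volume um^3; meshes smaller than this are removed by
#'   [clean_and_filter()]. Default 1e9 um^3 = 1 mm^3.
#' @param fit_iterations shrink-wrap iteration cap (default 80).
#' @param pull_fraction fraction of the vertex-to-nearest-point step taken
#'   per iteration (default 0.5).
#' @param laplacian_lambda uniform Laplacian regularization weight per
#'   iteration (default 0.25).
#' @param taubin_iterations smoothing passes applied after fitting
#'   (default 10; Taubin lambda 0.5 / mu -0.53, low-shrink).
#' @param icosphere_subdiv subdivision level of the start mesh (default 3:
#'   642 vertices).
#' @param grid_n voxel-grid resolution along the longest axis for boolean
#'   operations and volume audits (default 96).
#' @return object of class `mesh_config`.
#' @export
mesh_config <- function(min_volume = 1e9, fit_iterations = 80L,
                        pull_fraction = 0.5, laplacian_lambda = 0.25,
                        taubin_iterations = 10L, icosphere_subdiv = 3L,
                        grid_n = 96L) {
  check_that(is_number(min_volume) && min_volume >= 0,
             "min_volume", "must be >= 0 (um^3)")
  structure(list(
    min_volume = min_volume,
    fit_iterations = as.integer(fit_iterations),
    pull_fraction = pull_fraction,
    laplacian_lambda = laplacian_lambda,
    taubin_iterations = as.integer(taubin_iterations),
    icosphere_subdiv = as.integer(icosphere_subdiv),
    grid_n = as.integer(grid_n)
  ), class = "mesh_config")
}

#' Construct a surface mesh
#'
#' @param vertices n x 3 numeric matrix (um).
#' @param faces m x 3 integer matrix of 1-based vertex indices, outward
#'   oriented.
#' @param tissue_class tissue class id, or NA for wall meshes.
#' @param role `"tissue"`, `"wall-inner"` or `"wall-outer"`.
#' @return object of class `surface_mesh` with a `volume` field (um^3).
#' @export
surface_mesh <- function(vertices, faces, tissue_class = NA_integer_,
                         role = "tissue") {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  check_that(ncol(vertices) == 3, "vertices", "must be n x 3")
  check_that(min(faces) >= 1 && max(faces) <= nrow(vertices),
             "faces", "index out of range")
  m <- structure(list(
    vertices = unname(vertices),
    faces = unname(faces),
    tissue_class = as.integer(tissue_class),
    role = role
  ), class = "surface_mesh")
  m$volume <- mesh_volume(m)
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf(
    "Surface mesh (%s%s): %d vertices, %d faces, volume %.4g um^3\n",
    x$role,
    if (!is.na(x$tissue_class)) sprintf(", class %d", x$tissue_class) else "",
    nrow(x$vertices), nrow(x$faces), x$volume))
  invisible(x)
}

#' Signed enclosed volume of a triangle mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for a
#' closed, outward-oriented surface.
#'
#' @param mesh a [surface_mesh()] (or list with `vertices`, `faces`).
#' @return volume in um^3 (signed).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Structural checks for a surface mesh
#'
#' A simulation-ready surface must be closed (every edge shared by exactly
#' two faces), manifold, consistently oriented (each shared edge traversed
#' once in each direction), free of duplicate faces, and enclose positive
#' volume.
#'
#' @param mesh a [surface_mesh()].
#' @return list of logicals `closed`, `oriented`, `no_duplicate_faces`,
#'   `positive_volume`, and `ok` (all of the above).
#' @export
mesh_check <- function(mesh) {
  f <- mesh$faces
  nv <- as.double(nrow(mesh$vertices) + 1)
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]) # directed half-edges
  ekey <- pmin(he[, 1], he[, 2]) * nv + pmax(he[, 1], he[, 2])
  cnt <- tabulate(match(ekey, unique(ekey)))
  closed <- all(cnt == 2)
  dkey <- he[, 1] * nv + he[, 2]
  oriented <- closed && !anyDuplicated(dkey)
  a <- pmin(f[, 1], f[, 2], f[, 3])
  c_ <- pmax(f[, 1], f[, 2], f[, 3])
  b <- f[, 1] + f[, 2] + f[, 3] - a - c_
  nodup <- if (nv^3 < 2^53) {
    !anyDuplicated((a * nv + b) * nv + c_)
  } else {
    !anyDuplicated(paste(a, b, c_))
  }
  vol <- mesh_volume(mesh)
  out <- list(closed = closed, oriented = oriented,
              no_duplicate_faces = nodup, positive_volume = vol > 0)
  out$ok <- closed && oriented && nodup && vol > 0
  out
}

#' Midpoint of a closed contour via morphological thinning
#'
#' The contour is rasterized to a binary mask, the mask is thinned to its
#' skeleton (Zhang-Suen), and the skeleton pixel with the largest distance
#' to the nearest contour point is returned (ties resolved toward the tie
#' set's centroid). The result is guaranteed strictly inside the contour
#' and is the anchor that the parabolic caps keep fixed.
#'
#' @param contour a [contour2d()].
#' @param pitch raster pitch in um; default scales the longest bounding-box
#'   side to ~128 px.
#' @return length-2 numeric (x, y) in um.
#' @export
contour_midpoint <- function(contour, pitch = NULL) {
  pts <- contour$points
  if (is.null(pitch)) {
    ext <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
    pitch <- ext / 128
  }
  ras <- rasterize_contour(contour, pitch)
  # thickness check: some pixel must have mask neighbors both vertically
  # and horizontally (a 1-pixel-wide line has no such pixel)
  m <- ras$mask
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  vert <- pad[1:nr, 2:(nc + 1)] | pad[3:(nr + 2), 2:(nc + 1)]
  horz <- pad[2:(nr + 1), 1:nc] | pad[2:(nr + 1), 3:(nc + 2)]
  if (sum(m) < 4 || !any(m & vert & horz)) {
    stop("midpoint error: contour mask is thinner than 2 pixels everywhere",
         call. = FALSE)
  }
  skel <- thin_mask(ras$mask)
  cand <- which(skel, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    stop("midpoint error: thinning produced an empty skeleton", call. = FALSE)
  }
  cx <- ras$origin[1] + (cand[, 2] - 1) * ras$pitch
  cy <- ras$origin[2] + (cand[, 1] - 1) * ras$pitch
  dmin <- FNN::get.knnx(pts, cbind(cx, cy), k = 1)$nn.dist[, 1]
  if (max(dmin) < ras$pitch) {
    stop("midpoint error: contour mask is thinner than 2 pixels everywhere",
         call. = FALSE)
  }
  top <- dmin >= max(dmin) - 0.5 * ras$pitch
  txc <- mean(cx[top]); tyc <- mean(cy[top])
  pick <- which(top)[which.min((cx[top] - txc)^2 + (cy[top] - tyc)^2)]
  mid <- c(cx[pick], cy[pick])
  if (!points_in_polygon(mid[1], mid[2], pts)) {
    # fall back to the deepest strictly-interior skeleton pixel
    inside <- points_in_polygon(cx, cy, pts)
    if (!any(inside)) {
      stop("midpoint error: no interior skeleton pixel found", call. = FALSE)
    }
    pick <- which(inside)[which.max(dmin[inside])]
    mid <- c(cx[pick], cy[pick])
  }
  mid
}

#' Zhang-Suen morphological thinning
#'
#' Iteratively peels boundary pixels while preserving connectivity,
#' yielding a 1-pixel-wide skeleton (centerline) of the mask.
#'
#' @param mask logical matrix.
#' @return logical matrix of skeleton pixels.
#' @export
thin_mask <- function(mask) {
  m <- mask
  shift <- function(a, dr, dc) {
    nr <- nrow(a); nc <- ncol(a)
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- a[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbors in circular order P2..P9 = N, NE, E, SE, S, SW, W, NW
      p2 <- shift(m, 1, 0);  p3 <- shift(m, 1, -1)
      p4 <- shift(m, 0, -1); p5 <- shift(m, -1, -1)
      p6 <- shift(m, -1, 0); p7 <- shift(m, -1, 1)
      p8 <- shift(m, 0, 1);  p9 <- shift(m, 1, 1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a01 <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
        (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (phase == 1) {
        cond <- m & bsum >= 2 & bsum <= 6 & a01 == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & bsum >= 2 & bsum <= 6 & a01 == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Close a segment point cloud with parabolic caps
#'
#' Serial sectioning truncates tissue segments abruptly, which is
#' unrealistic and creates sharp edges that corrupt simulations. A dome is
#' therefore added beyond the first and last contour: ring `j` of `k` is
#' the end contour scaled about its (fixed) midpoint by
#' `s_j = sqrt(1 - j / (k + 1))` at height offset `j / (k + 1) * h`, a
#' paraboloid of revolution for circular contours. The apex height `h`
#' equals the mean end-contour radius and `k = max(2, ceiling(h /
#' slice_distance))`, keeping ring spacing comparable to slice spacing.
#'
#' @param cloud a `point_cloud3` from [build_point_clouds()].
#' @param track the matching `segment_track` (supplies the end contours).
#' @param slice_distance um between slices.
#' @return the cloud with cap rings and the two apex points appended; the
#'   attribute `cap_info` records midpoints, heights and ring counts.
#' @export
add_caps <- function(cloud, track, slice_distance = 100) {
  ends <- list(
    list(ct = track$contours[[1]], dir = -1),
    list(ct = track$contours[[length(track$contours)]], dir = +1)
  )
  extra <- list()
  info <- list()
  for (e in ends) {
    ct <- e$ct
    zend <- ct$slice_index * slice_distance
    mid <- contour_midpoint(ct)
    h <- mean(sqrt((ct$points[, 1] - mid[1])^2 +
                     (ct$points[, 2] - mid[2])^2))
    k <- max(2L, as.integer(ceiling(h / slice_distance)))
    s <- sqrt(1 - seq_len(k) / (k + 1))
    for (j in seq_len(k)) {
      ring <- cbind(
        mid[1] + s[j] * (ct$points[, 1] - mid[1]),
        mid[2] + s[j] * (ct$points[, 2] - mid[2]),
        zend + e$dir * (j / (k + 1)) * h
      )
      extra[[length(extra) + 1L]] <- ring
    }
    extra[[length(extra) + 1L]] <- matrix(c(mid, zend + e$dir * h), 1, 3)
    info[[length(info) + 1L]] <- list(midpoint = mid, height = h, rings = k,
                                      scales = s, direction = e$dir)
  }
  out <- cloud
  out$points <- rbind(cloud$points, do.call(rbind, extra))
  attr(out, "cap_info") <- info
  out
}

#' Subdivided icosahedron on the unit sphere
#'
#' @param subdiv subdivision level (0 = icosahedron, each level quadruples
#'   the face count).
#' @return list with `vertices` (n x 3 on the unit sphere) and `faces`.
#' @export
icosphere <- function(subdiv = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (lev in seq_len(subdiv)) {
    cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- lapply(seq_len(nv), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- cache[[key]]
      if (!is.null(id)) return(id)
      p <- (vlist[[a]] + vlist[[b]]) / 2
      p <- p / sqrt(sum(p^2))
      vlist[[length(vlist) + 1L]] <<- p
      id <- length(vlist)
      cache[[key]] <- id
      id
    }
    nf <- nrow(f)
    newf <- matrix(0L, 4 * nf, 3)
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c_, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  list(vertices = v, faces = f)
}

# internal: vertex adjacency (sparse row-normalized) for smoothing
.mesh_adjacency <- function(faces, nv) {
  e <- rbind(faces[, 1:2], faces[, 2:3], faces[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1,
                            dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(x = 1 / deg) %*% A
}

# internal: one uniform-Laplacian step v <- v + w (Av - v)
.laplace_step <- function(V, W, w) {
  V + w * (as.matrix(W %*% V) - V)
}

#' Fit a watertight surface mesh to a capped point cloud
#'
#' Shrink-wraps a subdivided icosphere (centered at the cloud centroid,
#' scaled to the bounding sphere) onto the cloud: iterations alternate a
#' pull of every vertex toward its nearest cloud point and a uniform
#' Laplacian regularization, stopping at the iteration cap or when the mean
#' vertex displacement drops below 0.1 um. Low-shrink Taubin smoothing
#' (lambda 0.5, mu -0.53) replaces manual mesh smoothing. The spherical
#' start topology guarantees a closed manifold; the result is verified and
#' an error with diagnostics is raised if the checks fail.
#'
#' @param cloud a `point_cloud3` (>= 2 z-planes after capping, >= 50
#'   points).
#' @param config a [mesh_config()].
#' @return a [surface_mesh()] carrying the cloud's tissue class.
#' @export
fit_mesh <- function(cloud, config = mesh_config()) {
  pts <- cloud$points
  check_that(nrow(pts) >= 50, "cloud", "needs >= 50 points")
  check_that(length(unique(pts[, 3])) >= 2, "cloud",
             "needs >= 2 z-planes (cap it first)")
  ico <- icosphere(config$icosphere_subdiv)
  ctr <- colMeans(pts)
  rad <- 1.1 * sqrt(max(rowSums(sweep(pts, 2, ctr)^2)))
  V <- sweep(ico$vertices * rad, 2, -ctr)
  W <- .mesh_adjacency(ico$faces, nrow(V))
  beta <- config$pull_fraction
  lam <- config$laplacian_lambda
  for (it in seq_len(config$fit_iterations)) {
    nn <- FNN::get.knnx(pts, V, k = 1)$nn.index[, 1]
    Vp <- V + beta * (pts[nn, , drop = FALSE] - V)
    Vp <- .laplace_step(Vp, W, lam)
    step <- mean(sqrt(rowSums((Vp - V)^2)))
    V <- Vp
    if (step < 0.1) break
  }
  # final anchoring pass without regularization, then Taubin smoothing
  nn <- FNN::get.knnx(pts, V, k = 1)$nn.index[, 1]
  V <- V + beta * (pts[nn, , drop = FALSE] - V)
  for (it in seq_len(config$taubin_iterations)) {
    V <- .laplace_step(V, W, 0.5)
    V <- .laplace_step(V, W, -0.53)
  }
  mesh <- surface_mesh(V, ico$faces, cloud$tissue_class)
  chk <- mesh_check(mesh)
  if (!chk$ok) {
    stop(sprintf(
      "meshing error: closed=%s oriented=%s no_duplicates=%s positive_volume=%s",
      chk$closed, chk$oriented, chk$no_duplicate_faces, chk$positive_volume),
      call. = FALSE)
  }
  mesh
}

# internal: build a padded voxel grid over meshes; tiny irrational offset
# avoids rays hitting mesh edges exactly
.mesh_grid <- function(meshes, n, zlim = NULL) {
  vs <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  lo <- apply(vs, 2, min); hi <- apply(vs, 2, max)
  if (!is.null(zlim)) {
    lo[3] <- max(lo[3], zlim[1]); hi[3] <- min(hi[3], zlim[2])
  }
  h <- max(hi - lo) / n
  pad <- 2.5 * h
  lo <- lo - pad; hi <- hi + pad
  off <- h * 1e-4 * (sqrt(5) - 2)
  list(
    xs = seq(lo[1], hi[1], by = h) + off,
    ys = seq(lo[2], hi[2], by = h) + off * 0.7,
    zs = seq(lo[3], hi[3], by = h) + off * 1.3,
    h = h
  )
}

# internal: z-signed-distance field of a mesh on a grid
.mesh_field <- function(mesh, grid) {
  f <- cpp_mesh_zfield(mesh$vertices, mesh$faces, grid$xs, grid$ys, grid$zs)
  odd <- attr(f, "odd_columns")
  if (!is.null(odd) && odd > 0) {
    hw_log(sprintf("voxelization: %d ambiguous grid columns treated as outside",
                   odd), "debug")
  }
  f
}

# internal: extract the zero level of a field as a surface mesh
.field_mesh <- function(field, grid, tissue_class = NA_integer_,
                        role = "tissue") {
  res <- cpp_marching_tets(field, c(length(grid$xs), length(grid$ys),
                                    length(grid$zs)),
                           grid$xs, grid$ys, grid$zs, 0)
  if (nrow(res$faces) == 0) return(NULL)
  surface_mesh(res$vertices, res$faces, tissue_class, role)
}

#' Intersection volume of two meshes (voxel audit)
#'
#' @param m1,m2 [surface_mesh()] objects.
#' @param n grid resolution along the longest axis.
#' @return overlap volume in um^3 (0 when the bounding boxes are disjoint).
#' @export
mesh_intersection_volume <- function(m1, m2, n = 96L) {
  b1 <- apply(m1$vertices, 2, range); b2 <- apply(m2$vertices, 2, range)
  if (any(b1[2, ] < b2[1, ]) || any(b2[2, ] < b1[1, ])) return(0)
  grid <- .mesh_grid(list(m1, m2), n)
  f <- pmax(.mesh_field(m1, grid), .mesh_field(m2, grid))
  mm <- .field_mesh(f, grid)
  if (is.null(mm)) 0 else max(0, mesh_volume(mm))
}

#' Resolve mesh overlaps and drop sub-resolution structures
#'
#' Meshes are processed in descending volume order (large structural wall
#' meshes must not be eroded by small inclusions). Overlapping meshes are
#' re-extracted from voxel signed-distance fields with later meshes
#' subtracted by the union of already-accepted ones (boolean difference),
#' creating distinct interfaces; disjoint meshes pass through unchanged.
#' Finally, meshes with volume below `config$min_volume` are removed and
#' logged.
#'
#' @param meshes list of watertight [surface_mesh()] objects.
#' @param config a [mesh_config()].
#' @return list of watertight, pairwise non-overlapping meshes.
#' @export
clean_and_filter <- function(meshes, config = mesh_config()) {
  if (length(meshes) == 0) return(meshes)
  for (m in meshes) {
    chk <- mesh_check(m)
    check_that(chk$ok, "meshes", "must all be watertight before cleanup")
  }
  vols <- vapply(meshes, function(m) m$volume, numeric(1))
  ord <- order(vols, decreasing = TRUE)
  # bbox overlap screen
  bbs <- lapply(meshes, function(m) apply(m$vertices, 2, range))
  n <- length(meshes)
  overlaps <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      if (all(bbs[[i]][1, ] <= bbs[[j]][2, ]) &&
          all(bbs[[j]][1, ] <= bbs[[i]][2, ])) {
        overlaps[i, j] <- overlaps[j, i] <- TRUE
      }
    }
  }
  involved <- which(apply(overlaps, 1, any))
  out <- meshes
  if (length(involved) >= 2) {
    grid <- .mesh_grid(meshes[involved], config$grid_n)
    fields <- list()
    for (i in involved) fields[[as.character(i)]] <- .mesh_field(out[[i]], grid)
    cellv <- grid$h^3
    acc <- NULL # union field of accepted overlap-involved meshes
    for (i in ord[ord %in% involved]) {
      fi <- fields[[as.character(i)]]
      inter_cells <- if (is.null(acc)) 0 else sum(pmax(fi, acc) < 0)
      if (!is.null(acc) && inter_cells * cellv >
            1e-9 * max(cellv, out[[i]]$volume)) {
        fi_new <- pmax(fi, -acc)
        mm <- .field_mesh(fi_new, grid, out[[i]]$tissue_class, out[[i]]$role)
        if (is.null(mm)) {
          stop(sprintf(
            "boolean failure: mesh %d (class %s) vanished when subtracting accepted meshes",
            i, out[[i]]$tissue_class), call. = FALSE)
        }
        hw_log(sprintf(
          "boolean subtraction applied to mesh %d (class %s), %.3g -> %.3g um^3",
          i, out[[i]]$tissue_class, out[[i]]$volume, mm$volume), "info")
        out[[i]] <- mm
        fields[[as.character(i)]] <- fi_new
      } else if (!is.null(acc) || any(overlaps[i, ])) {
        # re-extract from its own field so interfaces share the same
        # discretization as later subtractions
        mm <- .field_mesh(fi, grid, out[[i]]$tissue_class, out[[i]]$role)
        if (!is.null(mm)) out[[i]] <- mm
      }
      acc <- if (is.null(acc)) fi else pmin(acc, fi)
    }
  }
  keep <- logical(length(out))
  for (i in seq_along(out)) {
    chk <- mesh_check(out[[i]])
    if (!chk$ok) {
      stop(sprintf("boolean failure: mesh %d not watertight after cleanup", i),
           call. = FALSE)
    }
    if (out[[i]]$volume < config$min_volume) {
      hw_log(sprintf(
        "neglecting structure smaller than %.3g mm^3: mesh %d (class %s, %.3g mm^3)",
        config$min_volume / 1e9, i, out[[i]]$tissue_class,
        out[[i]]$volume / 1e9), "info")
    } else {
      keep[i] <- TRUE
    }
  }
  out[keep]
}

#' Mean distance from cloud points to a mesh (vertex proxy)
#'
#' @param mesh a [surface_mesh()].
#' @param cloud a `point_cloud3`.
#' @return mean nearest-vertex distance in um.
#' @export
mesh_cloud_distance <- function(mesh, cloud) {
  mean(FNN::get.knnx(mesh$vertices, cloud$points, k = 1)$nn.dist[, 1])
}

#' Write a mesh as ASCII PLY
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  write.table(format(mesh$vertices, trim = TRUE, digits = 9), con,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(cbind(3L, mesh$faces - 1L), con, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a mesh as ASCII STL
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @param name solid name in the file.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, name = "histowall3d") {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(
      sprintf("  facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
      "    outer loop",
      sprintf("      vertex %g %g %g", a[i, 1], a[i, 2], a[i, 3]),
      sprintf("      vertex %g %g %g", b[i, 1], b[i, 2], b[i, 3]),
      sprintf("      vertex %g %g %g", c_[i, 1], c_[i, 2], c_[i, 3]),
      "    endloop", "  endfacet"
    ), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
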