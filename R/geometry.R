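# Planar/raster geometry primitives.
#
# Conventions (shared by every module):
#   * 0-based pixel coordinates; x grows rightward (matrix columns), y grows
#     downward (matrix rows); a pixel's location is its centre.
#   * A binary raster is a height x width matrix; any value > 0 is foreground.
#   * Angles are reported in degrees.

#' Construct a planar point
#'
#' @param x,y Finite continuous pixel coordinates.
#' @return Named numeric vector `c(x = , y = )`.
#' @export
planar_point <- function(x, y) {
  if (!is.finite(x) || !is.finite(y)) {
    abort_fourcv("invalid_point", "planar point coordinates must be finite")
  }
  c(x = as.numeric(x), y = as.numeric(y))
}

#' Construct an oriented line
#'
#' A line is stored as an anchor point plus a unit direction vector.
#'
#' @param anchor Planar point on the line.
#' @param direction Numeric length-2 vector; normalised internally.
#' @return Object of class `oriented_line` with fields `anchor`, `direction`.
#' @export
oriented_line <- function(anchor, direction) {
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || n < 1e-12) {
    abort_fourcv("invalid_line", "line direction must be a nonzero vector")
  }
  structure(
    list(anchor = planar_point(anchor[[1]], anchor[[2]]),
         direction = c(dx = direction[[1]] / n, dy = direction[[2]] / n)),
    class = "oriented_line"
  )
}

#' @export
print.oriented_line <- function(x, ...) {
  cat(sprintf("<oriented_line> anchor (%.2f, %.2f), direction (%.4f, %.4f)\n",
              x$anchor[1], x$anchor[2], x$direction[1], x$direction[2]))
  invisible(x)
}

#' Construct a contour polyline
#'
#' @param x,y Vertex coordinate vectors (0-based pixel coordinates).
#' @param closed Logical; closed polylines need at least 3 vertices.
#' @return Object of class `contour_polyline` with fields `x`, `y`, `closed`.
#' @export
contour_polyline <- function(x, y, closed = TRUE) {
  stopifnot(length(x) == length(y))
  # drop repeated consecutive vertices (including a duplicated closing vertex)
  if (length(x) > 1) {
    keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
    x <- x[keep]; y <- y[keep]
    if (length(x) > 1 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
      x <- x[-length(x)]; y <- y[-length(y)]
    }
  }
  if (closed && length(x) < 3) {
    abort_fourcv("invalid_contour", "a closed contour needs at least 3 vertices")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), closed = closed),
            class = "contour_polyline")
}

# foreground pixel centres as an n x 2 matrix (columns x, y)
mask_coords <- function(raster) {
  idx <- which(raster > 0, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
}

#' Centroid of a binary region
#'
#' Arithmetic mean of the foreground pixel centres.
#'
#' @param raster Binary matrix (rows = y, columns = x).
#' @return Planar point.
#' @export
region_centroid <- function(raster) {
  xy <- mask_coords(raster)
  if (nrow(xy) == 0) abort_fourcv("empty_region", "region is empty")
  planar_point(mean(xy[, 1]), mean(xy[, 2]))
}

# 8-connected component labelling; returns integer matrix of labels (0 = bg)
label_components <- function(raster) {
  h <- nrow(raster); w <- ncol(raster)
  fg <- raster > 0
  n_fg <- sum(fg)
  lab <- matrix(0L, h, w)
  if (n_fg == 0) return(lab)
  id <- matrix(0L, h, w)
  id[fg] <- seq_len(n_fg)
  edges <- vector("list", 4)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (k in seq_along(shifts)) {
    dr <- shifts[[k]][1]; dc <- shifts[[k]][2]
    if (h <= dr || w <= abs(dc)) next
    r1 <- seq_len(h - dr)
    c1 <- if (dc >= 0) seq_len(w - dc) else seq.int(1L - dc, w)
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + dr, c1 + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edges[[k]] <- cbind(a[keep], b[keep])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    membership <- seq_len(n_fg)          # all pixels isolated
  } else {
    g <- igraph::make_empty_graph(n = n_fg, directed = FALSE)
    g <- igraph::add_edges(g, t(edges))
    membership <- igraph::components(g)$membership
  }
  lab[fg] <- as.integer(membership)
  lab
}

# keep only the largest 8-connected component of a binary raster
largest_component <- function(raster) {
  lab <- label_components(raster)
  if (max(lab) == 0L) abort_fourcv("empty_region", "region is empty")
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  out <- matrix(0L, nrow(raster), ncol(raster))
  out[lab == best] <- 1L
  out
}

#' Trace the outer contour of a binary region
#'
#' Marching-squares boundary (via [grDevices::contourLines] at level 0.5) of
#' the largest 8-connected component, with sub-pixel vertices.
#'
#' @param raster Binary matrix.
#' @return Closed `contour_polyline`.
#' @export
extract_outer_contour <- function(raster) {
  comp <- largest_component(raster)
  h <- nrow(comp); w <- ncol(comp)
  padded <- matrix(0, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- comp
  cl <- grDevices::contourLines(x = seq(-1, w), y = seq(-1, h),
                                z = t(padded), levels = 0.5)
  if (length(cl) == 0) abort_fourcv("empty_region", "no contour found")
  areas <- vapply(cl, function(p) abs(pracma::polyarea(p$x, p$y)), numeric(1))
  best <- cl[[which.max(areas)]]
  x <- best$x; y <- best$y
  if (x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  # one vertex-averaging pass: marching squares on binary data staircases,
  # inflating perimeter by several percent; averaging restores smooth
  # boundaries at well under half-pixel displacement
  if (length(x) >= 8) {
    xs <- (c(x[-1], x[1]) + 2 * x + c(x[length(x)], x[-length(x)])) / 4
    ys <- (c(y[-1], y[1]) + 2 * y + c(y[length(y)], y[-length(y)])) / 4
    x <- xs; y <- ys
  }
  contour_polyline(x, y, closed = TRUE)
}

#' Principal (orthogonal least-squares) axis of a binary region
#'
#' Line anchored at the region centroid along the leading eigenvector of the
#' pixel-coordinate covariance. Orthogonal rather than ordinary least squares
#' so near-vertical regions (a ventricular septum can be) stay well-posed.
#' The direction sign is canonical: dy > 0, or dx > 0 when dy = 0.
#'
#' @param raster Binary matrix with at least two distinct foreground pixels.
#' @return `oriented_line`.
#' @export
principal_axis_line <- function(raster) {
  xy <- mask_coords(raster)
  if (nrow(xy) < 2) {
    abort_fourcv("degenerate_fit", "principal axis needs at least 2 pixels")
  }
  ctr <- colMeans(xy)
  centred <- sweep(xy, 2, ctr)
  cv <- crossprod(centred) / nrow(xy)
  e <- eigen(cv, symmetric = TRUE)
  gap <- e$values[1] - e$values[2]
  if (gap <= 1e-6 * max(e$values[1], 1e-12)) {
    abort_fourcv("degenerate_fit", "region is isotropic; principal axis undefined")
  }
  d <- e$vectors[, 1]
  if (d[2] < 0 || (d[2] == 0 && d[1] < 0)) d <- -d
  oriented_line(planar_point(ctr[1], ctr[2]), d)
}

#' Centroid of the spine hollow via the convex-envelope construction
#'
#' Fills the convex hull of the thorax foreground, subtracts the thorax, and
#' returns the centroid of the largest connected residual component. This is
#' the spine-locating step: the spine sits in the posterior hollow of the
#' thoracic segmentation.
#'
#' @param thorax_raster Binary thorax mask (spine hollow *not* filled).
#' @param min_hollow_px Residual components smaller than this are treated as
#'   rasterisation slivers, not hollows (default 10 pixels).
#' @return Planar point (the spine centroid, point S).
#' @export
convex_hollow_centroid <- function(thorax_raster, min_hollow_px = 10) {
  xy <- mask_coords(thorax_raster)
  if (nrow(xy) == 0) abort_fourcv("empty_region", "thorax is empty")
  hull_idx <- grDevices::chull(xy[, 1], xy[, 2])
  hx <- xy[hull_idx, 1]; hy <- xy[hull_idx, 2]
  # candidate pixels: bounding box of the hull; membership by half-plane
  # tests (chull returns the vertices in clockwise order)
  x0 <- floor(min(hx)); x1 <- ceiling(max(hx))
  y0 <- floor(min(hy)); y1 <- ceiling(max(hy))
  gx <- rep(x0:x1, each = y1 - y0 + 1)
  gy <- rep(y0:y1, times = x1 - x0 + 1)
  inside <- rep(TRUE, length(gx))
  nv <- length(hx)
  orient <- sign(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy))
  for (k in seq_len(nv)) {
    k2 <- if (k == nv) 1L else k + 1L
    ex <- hx[k2] - hx[k]; ey <- hy[k2] - hy[k]
    cr <- (gx - hx[k]) * ey - (gy - hy[k]) * ex
    inside <- inside & (orient * cr <= 0)
    if (!any(inside)) break
  }
  hull_mask <- matrix(0L, nrow(thorax_raster), ncol(thorax_raster))
  hull_mask[cbind(gy[inside] + 1, gx[inside] + 1)] <- 1L
  residual <- hull_mask
  residual[thorax_raster > 0] <- 0L
  lab <- label_components(residual)
  if (max(lab) == 0L) abort_fourcv("no_hollow", "thorax has no hollow region")
  sizes <- tabulate(lab[lab > 0L])
  if (max(sizes) < min_hollow_px) {
    abort_fourcv("no_hollow", "thorax has no hollow region beyond rasterisation slivers")
  }
  best <- which.max(sizes)
  region_centroid(lab == best)
}

# signed foreground balance of the half-planes of a line through `anchor`
# at angle `phi_deg` from image-vertical; rel is centred pixel coords
.halfplane_diff <- function(rel, phi_deg) {
  phi <- phi_deg * pi / 180
  d <- c(sin(phi), cos(phi))
  s <- rel[, 1] * d[2] - rel[, 2] * d[1]
  sum(s > 0) - sum(s < 0)
}

#' Line through an anchor bisecting a region's area
#'
#' Finds the line through `anchor` whose two half-planes contain (as nearly as
#' possible) equal foreground area, counted at pixel centres. A 1-degree
#' coarse sweep over \[0, 180) is followed by sign-change bisection of the
#' signed balance. Ties in the coarse sweep break toward the smallest angle to
#' image-vertical.
#'
#' @param raster Binary matrix.
#' @param anchor Planar point the line must pass through.
#' @return `oriented_line` with attribute `balance` (|area difference| as a
#'   fraction of total area).
#' @export
area_bisecting_line <- function(raster, anchor) {
  xy <- mask_coords(raster)
  n <- nrow(xy)
  if (n == 0) abort_fourcv("empty_region", "region is empty")
  rel <- cbind(xy[, 1] - anchor[[1]], xy[, 2] - anchor[[2]])
  # coarse 1-degree sweep; on large rasters a regular pixel subsample is
  # enough to bracket the crossing, which the full-resolution bisection then
  # localises exactly
  stride <- max(1L, floor(n / 8000))
  rel_c <- rel[seq(1, n, by = stride), , drop = FALSE]
  n_c <- nrow(rel_c)
  phis <- 0:179
  rad <- phis * pi / 180
  s <- rel_c %*% rbind(cos(rad), -sin(rad))
  nneg <- colSums(s < 0)
  nzero <- colSums(s == 0)
  diffs <- n_c - nzero - 2 * nneg
  adiffs <- abs(diffs)
  best_a <- min(adiffs)
  cand <- phis[adiffs == best_a]
  vert_dist <- pmin(cand %% 180, 180 - cand %% 180)
  phi0 <- cand[which.min(vert_dist)]
  # refinement: full-resolution fine sweep of the 1.5-degree neighbourhood
  # at 0.05-degree resolution, with the same tie-break (smallest angle to
  # image-vertical) applied among the equally balanced candidates
  cand <- phi0 + seq(-1.5, 1.5, by = 0.05)
  fv <- vapply(cand, function(p) .halfplane_diff(rel, p), numeric(1))
  af <- abs(fv)
  sel <- which(af == min(af))
  vd <- pmin(cand[sel] %% 180, 180 - cand[sel] %% 180)
  pick <- sel[which.min(vd)]
  best_phi <- cand[pick]
  best_diff <- fv[pick]
  balance <- abs(best_diff) / n
  if (balance > 0.05) {
    abort_fourcv("bisect_failure",
                 sprintf("no line through the anchor balances the area (best imbalance %.1f%%)",
                         100 * balance))
  }
  phi <- best_phi * pi / 180
  out <- oriented_line(anchor, c(sin(phi), cos(phi)))
  attr(out, "balance") <- balance
  out
}

#' Intersections of an infinite line with a closed contour
#'
#' Crossing points of the line with every contour segment, deduplicated within
#' `dedup_px` and ordered by position along the line direction.
#'
#' @param line `oriented_line`.
#' @param contour Closed `contour_polyline`.
#' @param dedup_px Merge radius in pixels (default 0.5).
#' @return Matrix with columns x, y (possibly 0 rows).
#' @export
line_contour_intersections <- function(line, contour, dedup_px = 0.5) {
  if (!isTRUE(contour$closed)) {
    abort_fourcv("invalid_contour", "contour must be closed")
  }
  vx <- c(contour$x, contour$x[1])
  vy <- c(contour$y, contour$y[1])
  ax <- line$anchor[1]; ay <- line$anchor[2]
  dx <- line$direction[1]; dy <- line$direction[2]
  # signed perpendicular offset of each vertex from the line
  s <- (vx - ax) * dy - (vy - ay) * dx
  n <- length(vx) - 1
  s1 <- s[1:n]; s2 <- s[2:(n + 1)]
  hit <- (s1 <= 0 & s2 > 0) | (s1 >= 0 & s2 < 0) | (s1 == 0 & s2 == 0)
  pts <- NULL
  if (any(hit)) {
    i <- which(hit)
    denom <- s1[i] - s2[i]
    t <- ifelse(denom == 0, 0, s1[i] / denom)
    px <- vx[i] + t * (vx[i + 1] - vx[i])
    py <- vy[i] + t * (vy[i + 1] - vy[i])
    pts <- cbind(x = px, y = py)
  }
  if (is.null(pts) || nrow(pts) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  proj <- (pts[, 1] - ax) * dx + (pts[, 2] - ay) * dy
  ord <- order(proj)
  pts <- pts[ord, , drop = FALSE]
  proj <- proj[ord]
  # greedy merge of clusters closer than dedup_px along the line
  keep_x <- numeric(0); keep_y <- numeric(0); keep_t <- numeric(0)
  grp_x <- pts[1, 1]; grp_y <- pts[1, 2]; grp_t <- proj[1]; last_t <- proj[1]
  flush <- function() {
    keep_x <<- c(keep_x, mean(grp_x)); keep_y <<- c(keep_y, mean(grp_y))
    keep_t <<- c(keep_t, mean(grp_t))
  }
  if (nrow(pts) > 1) {
    for (k in 2:nrow(pts)) {
      if (proj[k] - last_t < dedup_px) {
        grp_x <- c(grp_x, pts[k, 1]); grp_y <- c(grp_y, pts[k, 2])
        grp_t <- c(grp_t, proj[k])
      } else {
        flush()
        grp_x <- pts[k, 1]; grp_y <- pts[k, 2]; grp_t <- proj[k]
      }
      last_t <- proj[k]
    }
  }
  flush()
  cbind(x = keep_x, y = keep_y)[order(keep_t), , drop = FALSE]
}

#' Intersection point of two lines
#'
#' @param l1,l2 `oriented_line`s with non-parallel directions.
#' @return Planar point.
#' @export
line_line_intersection <- function(l1, l2) {
  d1 <- l1$direction; d2 <- l2$direction
  cr <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(cr) <= 1e-9) abort_fourcv("parallel_lines", "lines are parallel")
  dp <- c(l2$anchor[1] - l1$anchor[1], l2$anchor[2] - l1$anchor[2])
  t <- (dp[1] * d2[2] - dp[2] * d2[1]) / cr
  planar_point(l1$anchor[1] + t * d1[1], l1$anchor[2] + t * d1[2])
}

#' Angle at a vertex between two points, in degrees
#'
#' `acos` of the normalised dot product of the arms vertex->p1 and
#' vertex->p2; range \[0, 180\].
#'
#' @param vertex,p1,p2 Planar points; p1 and p2 must differ from the vertex.
#' @return Angle in degrees.
#' @export
angle_at_vertex <- function(vertex, p1, p2) {
  a <- c(p1[[1]] - vertex[[1]], p1[[2]] - vertex[[2]])
  b <- c(p2[[1]] - vertex[[1]], p2[[2]] - vertex[[2]])
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) {
    abort_fourcv("degenerate_angle", "angle arm has zero length")
  }
  ct <- sum(a * b) / (na * nb)
  acos(max(-1, min(1, ct))) * 180 / pi
}
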