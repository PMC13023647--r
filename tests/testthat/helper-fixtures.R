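# Raster fixtures and independent oracles used across the suite.
# All fixtures are generated in code; pixel centres are at integer (x, y)
# with x along columns and y along rows, matching the package convention.

pixel_grid <- function(h, w) {
  list(X = matrix(rep(0:(w - 1), each = h), h, w),
       Y = matrix(rep(0:(h - 1), times = w), h, w))
}

disk_raster <- function(h, w, cx, cy, r) {
  g <- pixel_grid(h, w)
  ((g$X - cx)^2 + (g$Y - cy)^2 <= r^2) * 1L
}

ellipse_raster <- function(h, w, cx, cy, a, b, angle_deg = 0) {
  g <- pixel_grid(h, w)
  th <- angle_deg * pi / 180
  u <- (g$X - cx) * cos(th) + (g$Y - cy) * sin(th)
  v <- -(g$X - cx) * sin(th) + (g$Y - cy) * cos(th)
  ((u / a)^2 + (v / b)^2 <= 1) * 1L
}

# thin strip along direction angle_deg (from +x axis), centred at (cx, cy)
strip_raster <- function(h, w, cx, cy, half_len, angle_deg, half_width = 0.6) {
  g <- pixel_grid(h, w)
  th <- angle_deg * pi / 180
  u <- (g$X - cx) * cos(th) + (g$Y - cy) * sin(th)
  v <- -(g$X - cx) * sin(th) + (g$Y - cy) * cos(th)
  (abs(u) <= half_len & abs(v) <= half_width) * 1L
}

# angle of an oriented line from image-vertical, folded to [0, 180)
line_angle_from_vertical <- function(line) {
  phi <- atan2(line$direction[["dx"]], line$direction[["dy"]]) * 180 / pi
  phi %% 180
}

angle_dist_mod180 <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

# Independent area-bisection oracle: exhaustive sweep of the signed
# half-plane imbalance on a fine angular grid (brute-force sign counting,
# a different algorithm from the package's coarse-sweep-plus-bisection).
bisect_sweep_oracle <- function(raster, anchor, step = 0.05) {
  idx <- which(raster > 0, arr.ind = TRUE)
  relx <- idx[, 2] - 1 - anchor[[1]]
  rely <- idx[, 1] - 1 - anchor[[2]]
  phis <- seq(0, 180 - step, by = step)
  best_phi <- NA_real_; best_diff <- Inf; best_vert <- Inf
  chunk <- 400
  for (start in seq(1, length(phis), by = chunk)) {
    ph <- phis[start:min(start + chunk - 1, length(phis))]
    rad <- ph * pi / 180
    s <- cbind(relx, rely) %*% rbind(cos(rad), -sin(rad))
    diffs <- abs(colSums(s > 0) - colSums(s < 0))
    for (j in seq_along(ph)) {
      vert <- min(ph[j], 180 - ph[j])
      if (diffs[j] < best_diff ||
          (diffs[j] == best_diff && vert < best_vert)) {
        best_diff <- diffs[j]; best_phi <- ph[j]; best_vert <- vert
      }
    }
  }
  list(angle = best_phi, imbalance = best_diff)
}

# quick phantom accessor used by several files
quick_phantom <- function(...) generate_phantom(phantom_spec(...))
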