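test_that("region centroid equals the brute-force pixel mean", {
  m <- matrix(0, 40, 40); m[21, 11] <- 1         # pixel at x = 10, y = 20
  expect_equal(unname(region_centroid(m)), c(10, 20))

  m2 <- matrix(0, 4, 4); m2[1:2, 1:2] <- 1       # 2x2 block at rows/cols {0,1}
  expect_equal(unname(region_centroid(m2)), c(0.5, 0.5))

  d <- disk_raster(160, 160, 64, 80, 20)
  ctr <- region_centroid(d)
  expect_lt(sqrt((ctr[1] - 64)^2 + (ctr[2] - 80)^2), 0.1)
  # exact agreement with an explicit mean over rasterised pixels
  idx <- which(d > 0, arr.ind = TRUE)
  expect_identical(unname(ctr), c(mean(idx[, 2] - 1), mean(idx[, 1] - 1)))

  expect_error(region_centroid(matrix(0, 5, 5)), class = "fourcv_empty_region")
})

test_that("outer contour traces the largest component with correct geometry", {
  sq <- matrix(0, 20, 20); sq[6:15, 6:15] <- 1   # 10x10 filled square
  ct <- extract_outer_contour(sq)
  area <- abs(pracma::polyarea(ct$x, ct$y))
  expect_lt(abs(area - 100) / 100, 0.05)

  d <- disk_raster(100, 100, 50, 50, 30)
  ct <- extract_outer_contour(d)
  seg <- sqrt(diff(c(ct$x, ct$x[1]))^2 + diff(c(ct$y, ct$y[1]))^2)
  expect_lt(abs(sum(seg) - 2 * pi * 30) / (2 * pi * 30), 0.03)

  two <- matrix(0, 60, 60)
  two[10:34, 10:29] <- 1                          # 500 px component
  two[50:54, 50:53] <- 1                          # 20 px component
  ct <- extract_outer_contour(two)
  expect_true(all(ct$x < 40) && all(ct$y < 40))   # traced the large one only
})

test_that("principal axis follows elongated regions and rejects isotropy", {
  strip <- matrix(0, 100, 100); strip[51, 11:91] <- 1  # y = 50, x in [10, 90]
  l <- principal_axis_line(strip)
  expect_equal(unname(l$direction), c(1, 0))
  expect_equal(unname(l$anchor), c(50, 50))

  diag45 <- strip_raster(128, 128, 64, 64, 40, 45)
  l45 <- principal_axis_line(diag45)
  expect_lt(angle_dist_mod180(atan2(l45$direction[2], l45$direction[1]) * 180 / pi, 45), 0.5)

  sq <- matrix(0, 30, 30); sq[6:25, 6:25] <- 1
  expect_error(principal_axis_line(sq), class = "fourcv_degenerate_fit")
  expect_error(principal_axis_line(matrix(0, 5, 5)), class = "fourcv_degenerate_fit")
})

test_that("principal axis is equivariant under quarter-turn rotation", {
  base <- strip_raster(120, 120, 60, 60, 35, 30)
  l0 <- principal_axis_line(base)
  a0 <- atan2(l0$direction[2], l0$direction[1]) * 180 / pi
  rot <- t(base[nrow(base):1, ])                  # 90 degrees clockwise
  l1 <- principal_axis_line(rot)
  a1 <- atan2(l1$direction[2], l1$direction[1]) * 180 / pi
  expect_lt(angle_dist_mod180(a1, a0 + 90), 0.5)
})

test_that("convex-envelope hollow centroid recovers an interior hollow", {
  ell <- ellipse_raster(256, 256, 128, 128, 100, 80)
  hole <- disk_raster(256, 256, 128, 58, 10)      # near the top interior
  thorax <- ell * (1 - hole)
  s <- convex_hollow_centroid(thorax)
  expect_lt(sqrt((s[1] - 128)^2 + (s[2] - 58)^2), 1.5)

  expect_error(convex_hollow_centroid(ell), class = "fourcv_no_hollow")

  hole2 <- disk_raster(256, 256, 170, 150, 4)
  thorax2 <- ell * (1 - hole) * (1 - hole2)
  s2 <- convex_hollow_centroid(thorax2)           # largest hollow wins
  expect_lt(sqrt((s2[1] - 128)^2 + (s2[2] - 58)^2), 1.5)
})

test_that("area-bisecting line balances the halves and honours symmetry", {
  d <- disk_raster(200, 200, 100, 100, 60)
  l <- area_bisecting_line(d, planar_point(100, 100))
  expect_lte(attr(l, "balance"), 0.005)

  ell <- ellipse_raster(256, 256, 128, 128, 100, 80)
  anchor <- planar_point(128, 128 + 79)           # on the minor (vertical) axis
  l2 <- area_bisecting_line(ell, anchor)
  expect_lt(angle_dist_mod180(line_angle_from_vertical(l2), 0), 0.5)
  expect_lte(attr(l2, "balance"), 0.005)
})

test_that("area-bisecting line matches the exhaustive sweep oracle", {
  blob <- disk_raster(128, 128, 50, 60, 32) | disk_raster(128, 128, 85, 70, 20)
  anchor <- planar_point(52, 90)
  l <- area_bisecting_line(blob, anchor)
  oracle <- bisect_sweep_oracle(blob, anchor)
  expect_lt(angle_dist_mod180(line_angle_from_vertical(l), oracle$angle), 0.2)
})

test_that("line/contour intersections find chords, misses and tangents", {
  d <- disk_raster(100, 100, 50, 50, 30)
  ct <- extract_outer_contour(d)
  l <- oriented_line(planar_point(50, 50), c(1, 0))
  pts <- line_contour_intersections(l, ct)
  expect_equal(nrow(pts), 2)
  expect_lt(abs(sqrt(sum((pts[2, ] - pts[1, ])^2)) - 60), 1.5)

  miss <- oriented_line(planar_point(50, 95), c(1, 0))
  expect_equal(nrow(line_contour_intersections(miss, ct)), 0)

  diamond <- contour_polyline(c(0, 10, 0, -10), c(-10, 0, 10, 0))
  graze <- oriented_line(planar_point(0, -9.9), c(1, 0))
  expect_equal(nrow(line_contour_intersections(graze, diamond)), 1)
})

test_that("line/line intersection solves and flags parallels", {
  xaxis <- oriented_line(planar_point(0, 0), c(1, 0))
  yaxis <- oriented_line(planar_point(0, 0), c(0, 1))
  expect_equal(unname(line_line_intersection(xaxis, yaxis)), c(0, 0))

  l1 <- oriented_line(planar_point(0, 0), c(1, 1))       # y = x
  l2 <- oriented_line(planar_point(0, 2), c(1, -1))      # y = -x + 2
  expect_equal(unname(line_line_intersection(l1, l2)), c(1, 1))

  h1 <- oriented_line(planar_point(0, 0), c(1, 0))
  h2 <- oriented_line(planar_point(0, 5), c(1, 0))
  expect_error(line_line_intersection(h1, h2), class = "fourcv_parallel_lines")
})

test_that("vertex angles are correct, symmetric and mirror-invariant", {
  o <- planar_point(0, 0)
  expect_equal(angle_at_vertex(o, planar_point(0, 1), planar_point(1, 0)), 90)
  expect_equal(angle_at_vertex(o, planar_point(1, 0), planar_point(2, 0)), 0)
  expect_equal(angle_at_vertex(o, planar_point(1, 0), planar_point(1, 1)), 45)
  expect_error(angle_at_vertex(o, o, planar_point(1, 1)),
               class = "fourcv_degenerate_angle")

  set.seed(42)
  for (i in 1:20) {
    v <- planar_point(runif(1, -5, 5), runif(1, -5, 5))
    p1 <- planar_point(runif(1, -5, 5), runif(1, -5, 5))
    p2 <- planar_point(runif(1, -5, 5), runif(1, -5, 5))
    a12 <- angle_at_vertex(v, p1, p2)
    expect_equal(a12, angle_at_vertex(v, p2, p1))
    mir <- function(p) planar_point(-p[1], p[2])
    expect_equal(a12, angle_at_vertex(mir(v), mir(p1), mir(p2)), tolerance = 1e-10)
  }
})
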