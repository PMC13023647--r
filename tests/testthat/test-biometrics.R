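# A single default phantom is reused across the blocks below.
ph <- quick_phantom()
rec <- measure_biometrics(ph$mask_set)

test_that("CTAR is the heart/whole-thorax pixel ratio", {
  ms <- ph$mask_set
  empty_heart <- ms
  empty_heart$masks$heart <- matrix(0L, ms$height, ms$width)
  expect_identical(compute_ctar(empty_heart), 0)

  full_heart <- ms
  full_heart$masks$heart <- ms$masks$whole_thorax
  expect_identical(compute_ctar(full_heart), 1)

  # analytic fixture: disk heart r = 32 inside a 100 x 80 ellipse thorax
  disk_heart <- ms
  disk_heart$masks$whole_thorax <- ellipse_raster(256, 256, 128, 128, 100, 80)
  disk_heart$masks$heart <- disk_raster(256, 256, 120, 120, 32)
  expect_lt(abs(compute_ctar(disk_heart) - pi * 32^2 / (pi * 100 * 80)), 0.01)

  no_thorax <- ms
  no_thorax$masks$whole_thorax <- matrix(0L, ms$height, ms$width)
  expect_error(compute_ctar(no_thorax), class = "fourcv_empty_region")
})

test_that("landmarks recover the phantom frame, tilt and optional aorta", {
  lm <- rec$landmarks
  expect_lt(abs(lm$theta - 0), 0.5)
  expect_lt(sqrt(sum((lm$O_prime - ph$truth$O_true)^2)), 0.5)
  expect_lt(sqrt(sum((lm$S - ph$truth$S_true)^2)), 1.5)
  # R on the thoracic contour, farther from S than any other crossing
  expect_gt(sqrt(sum((lm$R - lm$S)^2)), sqrt(sum((lm$V - lm$S)^2)))

  rot <- quick_phantom(thorax_rotation = 20, source_id = "tilted")
  lm20 <- locate_landmarks(rot$mask_set)
  expect_lt(abs(lm20$theta - 20), 0.7)

  no_ao <- quick_phantom(aorta_side = "absent", source_id = "no_aorta")
  lm_no <- locate_landmarks(no_ao$mask_set)
  expect_null(lm_no$A)
  expect_false(is.null(lm_no$V))
  expect_identical(classify_laterality(lm_no), "indeterminate")
  expect_identical(measure_biometrics(no_ao$mask_set)$laterality, "indeterminate")
})

test_that("cardiac axis matches construction, parallel limit and mirror", {
  expect_lt(abs(rec$cardiac_axis - 45), 2)

  straight <- quick_phantom(heart_axis_angle = 0,
                            placement = list(mode = "pointp", gx = 0.12, gy = -0.45),
                            source_id = "straight")
  rec0 <- measure_biometrics(straight$mask_set)
  expect_lte(rec0$cardiac_axis, 2)

  mir <- measure_biometrics(mirror_mask_set(ph$mask_set))
  expect_lt(abs(mir$cardiac_axis - rec$cardiac_axis), 0.5)
})

test_that("apex side maps to presentation and flips under mirroring", {
  expect_identical(rec$apex_side, "left_of_RS")
  expect_identical(rec$inferred_presentation, "cephalic")

  mir <- measure_biometrics(mirror_mask_set(ph$mask_set))
  expect_identical(mir$apex_side, "right_of_RS")
  expect_identical(mir$inferred_presentation, "breech")

  # V exactly on line RS is indeterminate
  lm_on <- rec$landmarks
  lm_on$V <- planar_point(lm_on$S[1], lm_on$S[2] - 40)   # on the vertical RS line
  expect_error(classify_apex_presentation(lm_on),
               class = "fourcv_indeterminate_side")
})

test_that("laterality sign test and angle criterion agree on both sides", {
  lm <- rec$landmarks
  expect_identical(classify_laterality(lm), "solitus")
  expect_identical(laterality_angle_criterion(lm), "solitus")
  vsa <- angle_at_vertex(lm$S, lm$V, lm$A)
  rsv <- angle_at_vertex(lm$S, lm$R, lm$V)
  rsa <- angle_at_vertex(lm$S, lm$R, lm$A)
  expect_lt(vsa, rsv + rsa - 1)

  inv <- quick_phantom(aorta_side = "contralateral", source_id = "inv")
  lm_inv <- locate_landmarks(inv$mask_set)
  expect_identical(classify_laterality(lm_inv), "inversus")
  vsa <- angle_at_vertex(lm_inv$S, lm_inv$V, lm_inv$A)
  rsv <- angle_at_vertex(lm_inv$S, lm_inv$R, lm_inv$V)
  rsa <- angle_at_vertex(lm_inv$S, lm_inv$R, lm_inv$A)
  expect_lte(abs(vsa - (rsv + rsa)), 1)
})

test_that("point P transform is exact on a hand-built landmark fixture", {
  # upright frame centred at (100, 100); x' chord 160 px, y' chord 160 px,
  # so one unit is 20 px
  lmf <- list(
    S = planar_point(100, 180), R = planar_point(100, 20),
    O_prime = planar_point(100, 100), theta = 0,
    B1 = planar_point(20, 100), B2 = planar_point(180, 100),
    A1 = planar_point(100, 20), A2 = planar_point(100, 180),
    rs_line = oriented_line(planar_point(100, 180), c(0, -1)),
    septal_line = oriented_line(planar_point(100, 100), c(1, 0)),
    septum_centroid = planar_point(140, 100)
  )
  class(lmf) <- "anatomical_landmarks"
  base <- quick_phantom()$mask_set

  # heart disk r = 30: P = (70, 100), 1.5 units along x', 0 along y'
  ms <- base
  ms$masks$heart <- disk_raster(256, 256, 100, 100, 30)
  g <- compute_point_p(ms, lmf)
  expect_lt(abs(g[["gx"]] - 1.5), 0.05)
  expect_lt(abs(g[["gy"]] - 0), 0.05)

  # heart disk r = 40: P halfway from O' to the contour crossing -> gx = 2
  ms$masks$heart <- disk_raster(256, 256, 100, 100, 40)
  g2 <- compute_point_p(ms, lmf)
  expect_lt(abs(g2[["gx"]] - 2), 0.05)

  # gy sign: heart centred 20 px anterior (up) of O', septal line through it
  lmf2 <- lmf
  lmf2$septal_line <- oriented_line(planar_point(100, 80), c(1, 0))
  lmf2$septum_centroid <- planar_point(140, 80)
  ms$masks$heart <- disk_raster(256, 256, 100, 80, 30)
  g3 <- compute_point_p(ms, lmf2)
  expect_lt(abs(g3[["gy"]] - 1), 0.05)             # anterior is positive
})

test_that("point P measurement matches phantom truth and mirror-folds", {
  expect_lt(abs(rec$point_p[["gx"]] - ph$truth$point_p_true[["gx"]]), 0.1)
  expect_lt(abs(rec$point_p[["gy"]] - ph$truth$point_p_true[["gy"]]), 0.1)

  mir <- measure_biometrics(mirror_mask_set(ph$mask_set))
  expect_lt(abs(mir$point_p[["gx"]] - rec$point_p[["gx"]]), 0.1)
  expect_lt(abs(mir$point_p[["gy"]] - rec$point_p[["gy"]]), 0.1)
})

test_that("biometric records serialise to parseable JSON", {
  txt <- biometric_record_json(rec)
  parsed <- jsonlite::fromJSON(txt)
  expect_equal(parsed$ctar, rec$ctar)
  expect_equal(parsed$cardiac_axis_deg, rec$cardiac_axis)
  expect_equal(parsed$point_p$gx, unname(rec$point_p["gx"]))
  expect_identical(parsed$laterality, "solitus")
  expect_equal(parsed$landmarks$theta_deg, rec$landmarks$theta)
})
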