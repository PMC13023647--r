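mk_rec <- function(ctar = 0.27, axis = 41, gx = 0.5, gy = -0.2,
                   presentation = "cephalic", laterality = "solitus",
                   id = "rec") {
  structure(list(ctar = ctar, cardiac_axis = axis,
                 apex_side = if (presentation == "cephalic") "left_of_RS" else "right_of_RS",
                 inferred_presentation = presentation,
                 laterality = laterality,
                 point_p = c(gx = gx, gy = gy), source_id = id),
            class = "biometric_record")
}

test_that("parameter classification follows the guideline boundaries", {
  r <- classify_parameters(mk_rec())
  expect_false(any(unlist(r$flags)))
  expect_identical(r$overall, "negative")

  # CTAR < 35% is normal, so exactly 0.35 and above are abnormal
  expect_true(classify_parameters(mk_rec(ctar = 0.36))$flags$ctar_abnormal)
  expect_true(classify_parameters(mk_rec(ctar = 0.35))$flags$ctar_abnormal)
  expect_false(classify_parameters(mk_rec(ctar = 0.349))$flags$ctar_abnormal)

  expect_true(classify_parameters(mk_rec(axis = 66))$flags$axis_abnormal)
  expect_false(classify_parameters(mk_rec(axis = 65))$flags$axis_abnormal)
  expect_true(classify_parameters(mk_rec(axis = 24))$flags$axis_abnormal)

  expect_true(classify_parameters(mk_rec(gy = -1.4))$flags$pointp_abnormal)
  expect_true(classify_parameters(mk_rec(gx = 2.2))$flags$pointp_abnormal)
  expect_false(classify_parameters(mk_rec(gx = 2.0, gy = 1.0))$flags$pointp_abnormal)

  m <- classify_parameters(mk_rec(presentation = "breech"),
                           declared_presentation = "cephalic")
  expect_true(m$flags$orientation_mismatch)
  expect_identical(m$overall, "positive")

  lat <- classify_parameters(mk_rec(laterality = "inversus"))
  expect_true(lat$flags$laterality_abnormal)
  expect_identical(lat$overall, "positive")

  ind <- classify_parameters(mk_rec(laterality = "indeterminate"))
  expect_false(ind$flags$laterality_abnormal)
  expect_match(ind$notes, "indeterminate")
})

test_that("video aggregation averages, majorities and breaks ties abnormal", {
  two <- aggregate_video(list(mk_rec(ctar = 0.26), mk_rec(ctar = 0.28)))
  expect_equal(two$record$ctar, 0.27)
  expect_identical(two$result$level, "video")
  expect_identical(two$result$overall, "negative")

  one <- aggregate_video(list(mk_rec(ctar = 0.31, axis = 50)))
  expect_equal(one$record$ctar, 0.31)
  expect_equal(one$record$cardiac_axis, 50)

  tie <- aggregate_video(list(mk_rec(laterality = "solitus"),
                              mk_rec(laterality = "inversus")))
  expect_true(tie$result$flags$laterality_abnormal)
  expect_identical(tie$result$overall, "positive")

  expect_error(aggregate_video(list()), class = "fourcv_empty_aggregate")
})

test_that("patient screening applies the non-extractable rule", {
  pos <- screen_patient(NULL, extractable = FALSE)
  expect_identical(pos$overall, "positive")
  expect_true(pos$non_extractable)

  vid <- aggregate_video(list(mk_rec(), mk_rec()))
  neg <- screen_patient(vid$result, extractable = TRUE)
  expect_identical(neg$overall, "negative")
  expect_identical(neg$level, "patient")

  expect_error(screen_patient(NULL, extractable = TRUE),
               class = "fourcv_inconsistency")
})

test_that("the ordinal score counts included parameters monotonically", {
  res <- classify_parameters(mk_rec(ctar = 0.4, axis = 70))
  expect_identical(screening_score(res, c("ctar", "axis", "pointp")), 2L)
  expect_identical(screening_score(res, c("ctar", "axis")), 2L)
  expect_identical(screening_score(res, "pointp"), 0L)

  all_norm <- classify_parameters(mk_rec())
  expect_identical(screening_score(all_norm), 0L)

  ne <- screen_patient(NULL, extractable = FALSE)
  expect_identical(screening_score(ne, c("ctar", "axis", "pointp")), 3L)
  expect_identical(screening_score(ne, c("ctar", "axis")), 2L)

  # monotonicity: adding a parameter never decreases the score
  combos <- list("ctar", c("ctar", "axis"), c("ctar", "axis", "pointp"))
  for (r in list(res, all_norm, ne)) {
    sc <- vapply(combos, function(inc) as.numeric(screening_score(r, inc)), numeric(1))
    expect_true(all(diff(sc) >= 0))
  }
})

test_that("flipping any flag to abnormal never turns a call negative", {
  base <- classify_parameters(mk_rec())
  for (f in names(base$flags)) {
    r2 <- mk_rec()
    r2 <- switch(f,
      ctar_abnormal = mk_rec(ctar = 0.40),
      axis_abnormal = mk_rec(axis = 70),
      pointp_abnormal = mk_rec(gy = -1.5),
      orientation_mismatch = mk_rec(presentation = "breech"),
      laterality_abnormal = mk_rec(laterality = "inversus"))
    res <- classify_parameters(r2, declared_presentation = "cephalic")
    expect_identical(res$overall, "positive")
    pat <- screen_patient(new_video_result <- aggregate_video(list(r2),
                          declared_presentation = "cephalic")$result, TRUE)
    expect_identical(pat$overall, "positive")
  }
})

test_that("the CHD cohort worked example reproduces the printed sensitivities", {
  un <- chd_worked_example("unet3p")
  sf <- chd_worked_example("segformer")
  expect_identical(un$n_patients, 22L)
  expect_identical(un$n_positive, 17L)
  expect_equal(un$sensitivity, 17 / 22)
  expect_identical(sf$n_positive, 18L)
  expect_equal(sf$sensitivity, 18 / 22)
  expect_equal(round(un$sensitivity, 3), 0.773)
  expect_equal(round(sf$sensitivity, 3), 0.818)
})
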