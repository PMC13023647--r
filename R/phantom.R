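# Synthetic four-chamber-view phantoms with analytic ground truth.
#
# The phantom stands in for a segmentation front end: an elliptical whole
# thorax with a posterior spine hollow, an interior heart ellipse whose
# septal axis carries a septum strip from the crux toward the apex, and a
# small descending-aorta disk beside the spine. Everything is rasterised by
# a pixel-centre-inside-analytic-region test (no anti-aliasing), so areas
# are exact pixel counts and rasters are platform-stable.
#
# Heart placement is parametrised either by the target point-P location in
# thorax-relative units (the basal wall of the heart is anchored there) or
# by a heart-centre offset; ground truth is computed analytically from the
# same parameters.

#' Construct a phantom specification
#'
#' @param canvas Width/height in pixels (square canvases recommended),
#'   default `c(256, 256)`.
#' @param thorax_semi_axes `c(a_t, b_t)`: lateral and anteroposterior thorax
#'   semi-axes in pixels.
#' @param thorax_rotation Tilt of the thorax anteroposterior axis from
#'   image-vertical, degrees (positive toward +x).
#' @param ctar_target Cardiothoracic area ratio the rasterised heart is
#'   matched to (within 0.01).
#' @param heart_axis_angle Angle of the septal axis to the spine-bisecting
#'   line, degrees; this is the ground-truth cardiac axis.
#' @param heart_axis_ratio Heart semi-axis perpendicular to the septum
#'   divided by the semi-axis along it. Values slightly above 1 keep the
#'   basal wall (point P) near the thorax centroid at realistic CTAR.
#' @param placement Either `list(mode = "pointp", gx = , gy = )` anchoring
#'   the basal septal-line crossing of the heart at that point-P location, or
#'   `list(mode = "center", lat = , ap = )` giving the heart-centre offset
#'   from the thorax centre in lateral/anteroposterior pixels.
#' @param apex_direction `"left"` or `"right"`: side of the bisecting line
#'   the apex points to (left infers cephalic presentation).
#' @param spine_radius,spine_margin Spine-hollow disk radius and its gap to
#'   the posterior thorax boundary, pixels.
#' @param septum_halfwidth Septum strip half-width, pixels.
#' @param aorta_radius Descending-aorta disk radius, pixels (0 = absent).
#' @param aorta_side `"apex_side"` (situs solitus), `"contralateral"`
#'   (inversus) or `"absent"`.
#' @param declared_presentation Examiner-declared presentation carried in the
#'   manifest; `NULL` means "matches the ground truth".
#' @param pointp_divisions Chord divisions of the point-P frame (default 8).
#' @param abnormality Label of the abnormality preset that produced this
#'   spec (bookkeeping only).
#' @param source_id Identifier written into the mask set.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(canvas = c(256, 256),
                         thorax_semi_axes = c(95, 78),
                         thorax_rotation = 0,
                         ctar_target = 0.26,
                         heart_axis_angle = 45,
                         heart_axis_ratio = 1.15,
                         placement = list(mode = "pointp", gx = 0.4, gy = -0.45),
                         apex_direction = "left",
                         spine_radius = 10,
                         spine_margin = 3,
                         septum_halfwidth = 3,
                         aorta_radius = 7,
                         aorta_side = "apex_side",
                         declared_presentation = NULL,
                         pointp_divisions = 8,
                         abnormality = "none",
                         source_id = "phantom") {
  stopifnot(ctar_target > 0, ctar_target < 1,
            placement$mode %in% c("pointp", "center"))
  apex_direction <- match.arg(apex_direction, c("left", "right"))
  aorta_side <- match.arg(aorta_side, c("apex_side", "contralateral", "absent"))
  structure(
    list(canvas = canvas, thorax_semi_axes = thorax_semi_axes,
         thorax_rotation = thorax_rotation, ctar_target = ctar_target,
         heart_axis_angle = heart_axis_angle,
         heart_axis_ratio = heart_axis_ratio, placement = placement,
         apex_direction = apex_direction, spine_radius = spine_radius,
         spine_margin = spine_margin, septum_halfwidth = septum_halfwidth,
         aorta_radius = aorta_radius, aorta_side = aorta_side,
         declared_presentation = declared_presentation,
         pointp_divisions = pointp_divisions, abnormality = abnormality,
         source_id = source_id),
    class = "phantom_spec"
  )
}

#' Scale a phantom specification to a different canvas
#'
#' Multiplies the canvas and every pixel-valued length by `factor`;
#' dimensionless quantities (angles, CTAR, point-P units) are untouched.
#' Rendering the same spec at two scales should reproduce the same biometry.
#'
#' @param spec `phantom_spec`.
#' @param factor Scale factor (e.g. 2 for 256 -> 512).
#' @return Scaled `phantom_spec`.
#' @export
scale_phantom_spec <- function(spec, factor) {
  spec$canvas <- round(spec$canvas * factor)
  spec$thorax_semi_axes <- spec$thorax_semi_axes * factor
  spec$spine_radius <- spec$spine_radius * factor
  spec$spine_margin <- spec$spine_margin * factor
  spec$septum_halfwidth <- spec$septum_halfwidth * factor
  spec$aorta_radius <- spec$aorta_radius * factor
  if (spec$placement$mode == "center") {
    spec$placement$lat <- spec$placement$lat * factor
    spec$placement$ap <- spec$placement$ap * factor
  }
  spec
}

# unit frame of a phantom: u_ap anterior, v_apex toward the apex side,
# w along the septum toward the apex
phantom_frame <- function(spec) {
  th <- spec$thorax_rotation * pi / 180
  u_ap <- c(sin(th), -cos(th))
  v_left <- c(u_ap[2], -u_ap[1])
  v_apex <- if (spec$apex_direction == "left") v_left else -v_left
  ax <- spec$heart_axis_angle * pi / 180
  w <- cos(ax) * u_ap + sin(ax) * v_apex
  list(u_ap = u_ap, v_left = v_left, v_apex = v_apex, w = w)
}

#' Generate a phantom mask set and its ground truth
#'
#' Rasterises the five structure masks from the analytic geometry and
#' returns them with the analytically known biometry. The heart semi-axes
#' are matched to `ctar_target` by bisection against the rasterised
#' whole-thorax pixel count (rasterisation quantises areas), keeping the
#' basal anchor point fixed.
#'
#' @param spec `phantom_spec`.
#' @return List with `mask_set`, `truth` (class `phantom_truth`) and `spec`.
#' @export
generate_phantom <- function(spec) {
  wpx <- spec$canvas[1]; hpx <- spec$canvas[2]
  a_t <- spec$thorax_semi_axes[1]; b_t <- spec$thorax_semi_axes[2]
  fr <- phantom_frame(spec)
  t_c <- c((wpx - 1) / 2, (hpx - 1) / 2)

  X <- matrix(rep(0:(wpx - 1), each = hpx), hpx, wpx)
  Y <- matrix(rep(0:(hpx - 1), times = wpx), hpx, wpx)
  rx <- X - t_c[1]; ry <- Y - t_c[2]
  lat <- rx * fr$v_left[1] + ry * fr$v_left[2]
  ap <- rx * fr$u_ap[1] + ry * fr$u_ap[2]

  whole_thorax <- (lat / a_t)^2 + (ap / b_t)^2 <= 1

  s_off <- b_t - spec$spine_margin - spec$spine_radius
  s_c <- t_c - s_off * fr$u_ap
  spine <- (X - s_c[1])^2 + (Y - s_c[2])^2 <= spec$spine_radius^2
  thorax <- whole_thorax & !spine

  n_thorax <- sum(whole_thorax)
  area_target <- spec$ctar_target * n_thorax
  a_h0 <- sqrt(area_target / (pi * spec$heart_axis_ratio))

  d_x <- 2 * a_t / spec$pointp_divisions
  d_y <- 2 * b_t / spec$pointp_divisions
  anchor_rel <- NULL                     # basal anchor (frame coords lat/ap)
  if (spec$placement$mode == "pointp") {
    anchor_rel <- c(spec$placement$gx * d_x, spec$placement$gy * d_y)
  }
  w_lat <- sum(fr$w * fr$v_left); w_ap <- sum(fr$w * fr$u_ap)
  v_apex_lat <- sum(fr$v_apex * fr$v_left)   # +1 or -1

  heart_of <- function(s) {
    a_h <- s * a_h0; b_h <- spec$heart_axis_ratio * a_h
    if (spec$placement$mode == "pointp") {
      hc_lat <- anchor_rel[1] * v_apex_lat + a_h * w_lat
      hc_ap <- anchor_rel[2] + a_h * w_ap
    } else {
      hc_lat <- spec$placement$lat
      hc_ap <- spec$placement$ap
    }
    hw <- (lat - hc_lat) * w_lat + (ap - hc_ap) * w_ap
    hp <- -(lat - hc_lat) * w_ap + (ap - hc_ap) * w_lat
    list(mask = whole_thorax & ((hw / a_h)^2 + (hp / b_h)^2 <= 1),
         a_h = a_h, b_h = b_h, hc_lat = hc_lat, hc_ap = hc_ap,
         hw = hw, hp = hp)
  }

  lo <- 0.85; hi <- 1.15; s <- 1
  h <- heart_of(s)
  for (i in 1:12) {
    err <- sum(h$mask) / n_thorax - spec$ctar_target
    if (abs(err) <= 0.004) break
    if (err > 0) hi <- s else lo <- s
    s <- (lo + hi) / 2
    h <- heart_of(s)
  }

  # feasibility: the analytic heart ellipse must sit inside the thorax
  phi <- seq(0, 2 * pi, length.out = 145)[-145]
  bl <- h$hc_lat + h$a_h * cos(phi) * w_lat - h$b_h * sin(phi) * w_ap
  ba <- h$hc_ap + h$a_h * cos(phi) * w_ap + h$b_h * sin(phi) * w_lat
  if (any((bl / (a_t - 1))^2 + (ba / (b_t - 1))^2 > 1)) {
    abort_fourcv("infeasible_spec", "heart ellipse does not fit inside the thorax")
  }

  septum <- h$mask & h$hw >= 0.08 * h$a_h & h$hw <= 0.85 * h$a_h &
    abs(h$hp) <= spec$septum_halfwidth

  aorta <- matrix(FALSE, hpx, wpx)
  if (spec$aorta_side != "absent" && spec$aorta_radius > 0) {
    side_sign <- if (spec$aorta_side == "apex_side") 1 else -1
    ao_rel_lat <- side_sign * v_apex_lat *
      (spec$spine_radius + spec$aorta_radius + 4)
    ao_c <- s_c + ao_rel_lat * fr$v_left
    aorta <- (X - ao_c[1])^2 + (Y - ao_c[2])^2 <= spec$aorta_radius^2
    # disjointness from the heart: every aorta boundary point must lie
    # outside the (slightly inflated) heart ellipse
    da_lat <- (ao_c[1] - t_c[1]) * fr$v_left[1] + (ao_c[2] - t_c[2]) * fr$v_left[2]
    da_ap <- (ao_c[1] - t_c[1]) * fr$u_ap[1] + (ao_c[2] - t_c[2]) * fr$u_ap[2]
    psi <- seq(0, 2 * pi, length.out = 73)[-73]
    ab_lat <- da_lat + spec$aorta_radius * cos(psi)
    ab_ap <- da_ap + spec$aorta_radius * sin(psi)
    dw <- (ab_lat - h$hc_lat) * w_lat + (ab_ap - h$hc_ap) * w_ap
    dp <- -(ab_lat - h$hc_lat) * w_ap + (ab_ap - h$hc_ap) * w_lat
    if (any((dw / (1.03 * h$a_h))^2 + (dp / (1.03 * h$b_h))^2 <= 1)) {
      abort_fourcv("infeasible_spec", "descending aorta overlaps the heart")
    }
  }

  # analytic ground truth
  p_rel <- if (spec$placement$mode == "pointp") {
    c(lat = anchor_rel[1] * v_apex_lat, ap = anchor_rel[2])
  } else {
    c(lat = h$hc_lat - h$a_h * w_lat, ap = h$hc_ap - h$a_h * w_ap)
  }
  gx_true <- abs(p_rel[["lat"]]) / d_x
  gy_true <- p_rel[["ap"]] / d_y
  theta_true <- spec$thorax_rotation
  theta_true <- ((theta_true + 90) %% 180) - 90
  if (theta_true == -90) theta_true <- 90
  presentation_true <- if (spec$apex_direction == "left") "cephalic" else "breech"
  laterality_true <- switch(spec$aorta_side,
                            apex_side = "solitus",
                            contralateral = "inversus",
                            absent = "indeterminate")
  declared <- spec$declared_presentation %||% presentation_true

  truth <- structure(
    list(ctar_true = spec$ctar_target,
         axis_true = spec$heart_axis_angle,
         apex_side_true = if (spec$apex_direction == "left") "left_of_RS" else "right_of_RS",
         presentation_true = presentation_true,
         declared_presentation = declared,
         laterality_true = laterality_true,
         point_p_true = c(gx = unname(gx_true), gy = unname(gy_true)),
         theta_true = theta_true,
         S_true = c(x = s_c[1], y = s_c[2]),
         O_true = c(x = t_c[1], y = t_c[2]),
         abnormality = spec$abnormality),
    class = "phantom_truth"
  )
  truth$expected_flags <- truth_flags(truth)

  ms <- mask_set(
    list(heart = h$mask * 1L,
         ventricular_septum = septum * 1L,
         whole_thorax = whole_thorax * 1L,
         thorax = thorax * 1L,
         descending_aorta = aorta * 1L),
    source_id = spec$source_id,
    presentation = declared,
    extractable = TRUE
  )
  list(mask_set = ms, truth = truth, spec = spec)
}

#' Expected screening flags of a phantom from its ground truth
#'
#' @param truth `phantom_truth`.
#' @param ranges `normal_ranges`.
#' @return Named logical list matching `screening_result$flags`.
#' @export
truth_flags <- function(truth, ranges = normal_ranges()) {
  box <- ranges$pointp_box
  list(
    ctar_abnormal = truth$ctar_true >= ranges$ctar_max,
    axis_abnormal = abs(truth$axis_true - ranges$axis_center) > ranges$axis_halfwidth,
    pointp_abnormal = truth$point_p_true[["gx"]] < box[["gx_min"]] ||
      truth$point_p_true[["gx"]] > box[["gx_max"]] ||
      truth$point_p_true[["gy"]] < box[["gy_min"]] ||
      truth$point_p_true[["gy"]] > box[["gy_max"]],
    orientation_mismatch = truth$declared_presentation %in% c("cephalic", "breech") &&
      !identical(truth$presentation_true, truth$declared_presentation),
    laterality_abnormal = identical(truth$laterality_true, "inversus")
  )
}

# run code with a temporarily seeded, then restored, RNG state
with_rng_seed <- function(seed, fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fun()
}

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

# draw a randomized spec for one preset; assumes an active RNG stream
phantom_preset_spec <- function(preset, canvas = c(256, 256), source_id = "phantom") {
  a_t <- runif1(90, 98)
  b_t <- a_t * runif1(0.78, 0.84)
  base <- list(
    canvas = canvas,
    thorax_semi_axes = c(a_t, b_t),
    thorax_rotation = runif1(-25, 25),
    spine_radius = runif1(8, 12),
    aorta_radius = runif1(6, 8),
    source_id = source_id,
    abnormality = preset
  )
  extra <- switch(
    preset,
    none = list(
      ctar_target = runif1(0.21, 0.31),
      heart_axis_angle = runif1(35, 55),
      heart_axis_ratio = runif1(1.1, 1.3),
      placement = list(mode = "pointp", gx = runif1(0.1, 0.55),
                       gy = runif1(-0.65, -0.15))
    ),
    cardiomegaly = list(
      ctar_target = runif1(0.41, 0.47),
      heart_axis_angle = runif1(36, 46),
      heart_axis_ratio = runif1(1.25, 1.4),
      placement = list(mode = "center", lat = runif1(-4, 2), ap = runif1(0, 6))
    ),
    axis_deviation = {
      low <- stats::runif(1) < 0.5
      list(
        ctar_target = runif1(0.21, 0.27),
        heart_axis_angle = if (low) runif1(5, 15) else runif1(78, 87),
        heart_axis_ratio = runif1(1.1, 1.25),
        placement = list(mode = "pointp", gx = runif1(0.1, 0.35),
                         gy = runif1(-0.6, -0.2))
      )
    },
    dextrocardia = list(
      ctar_target = runif1(0.21, 0.29),
      heart_axis_angle = runif1(35, 55),
      heart_axis_ratio = runif1(1.1, 1.3),
      placement = list(mode = "pointp", gx = runif1(0.1, 0.5),
                       gy = runif1(-0.6, -0.2)),
      apex_direction = "right",
      declared_presentation = "cephalic"
    ),
    inversus = list(
      ctar_target = runif1(0.21, 0.29),
      heart_axis_angle = runif1(35, 55),
      heart_axis_ratio = runif1(1.1, 1.3),
      placement = list(mode = "pointp", gx = runif1(0.1, 0.5),
                       gy = runif1(-0.6, -0.2)),
      aorta_side = "contralateral"
    ),
    displaced_p = {
      # posteriorly displaced heart (e.g. mediastinal shift); a deep thorax
      # and a small heart keep it clear of the spine and aorta
      a_t2 <- runif1(94, 100)
      list(
        thorax_semi_axes = c(a_t2, a_t2 * runif1(0.82, 0.86)),
        ctar_target = runif1(0.18, 0.22),
        heart_axis_angle = runif1(34, 46),
        heart_axis_ratio = runif1(1.0, 1.15),
        placement = list(mode = "pointp", gx = runif1(0.15, 0.4),
                         gy = runif1(-2.1, -1.6))
      )
    },
    abort_fourcv("invalid_argument", paste0("unknown preset: ", preset))
  )
  do.call(phantom_spec, utils::modifyList(base, extra))
}

#' Sample a reproducible phantom cohort
#'
#' Normal phantoms draw CTAR, cardiac axis, tilt and point-P location inside
#' the guideline normal ranges with comfortable margins; abnormal phantoms
#' draw from the requested presets with parameters outside the ranges by at
#' least twice the measurement tolerances, so classification suites are
#' deterministic. The abnormal count is allocated deterministically
#' (`round(n * abnormal_fraction)`, split over presets by largest remainder).
#'
#' @param n Number of phantoms.
#' @param abnormal_fraction Fraction drawn from abnormality presets.
#' @param preset_mix Named weights over
#'   `c("cardiomegaly", "axis_deviation", "dextrocardia", "inversus",
#'   "displaced_p")`; default equal.
#' @param seed Integer seed; the same seed reproduces bit-identical rasters.
#' @param canvas Canvas size, default `c(256, 256)`.
#' @return List of phantoms, each as returned by [generate_phantom()].
#' @export
sample_cohort <- function(n, abnormal_fraction = 0, preset_mix = NULL,
                          seed = 1, canvas = c(256, 256)) {
  stopifnot(n >= 1, abnormal_fraction >= 0, abnormal_fraction <= 1)
  presets <- c("cardiomegaly", "axis_deviation", "dextrocardia",
               "inversus", "displaced_p")
  if (is.null(preset_mix)) {
    preset_mix <- stats::setNames(rep(1, length(presets)), presets)
  }
  preset_mix <- preset_mix[preset_mix > 0]
  n_ab <- round(n * abnormal_fraction)
  wts <- preset_mix / sum(preset_mix)
  counts <- floor(wts * n_ab)
  rem <- n_ab - sum(counts)
  if (rem > 0) {
    frac_order <- order(wts * n_ab - counts, decreasing = TRUE)
    counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1
  }
  labels <- c(rep("none", n - n_ab), rep(names(counts), counts))
  with_rng_seed(seed, function() {
    lapply(seq_len(n), function(i) {
      # a draw that lands geometrically infeasible is redrawn from the same
      # stream, so the cohort is still a deterministic function of the seed
      for (attempt in 1:20) {
        spec <- phantom_preset_spec(labels[i], canvas = canvas,
                                    source_id = sprintf("phantom_%03d", i))
        ph <- tryCatch(generate_phantom(spec),
                       fourcv_infeasible_spec = function(e) NULL)
        if (!is.null(ph)) return(ph)
      }
      abort_fourcv("infeasible_spec",
                   paste0("could not draw a feasible phantom for preset ", labels[i]))
    })
  })
}

# 4-neighbour logical dilation/erosion by shifting
shift_or <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-h, ]
  out[-h, ] <- out[-h, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -w]
  out[, -w] <- out[, -w] | m[, -1]
  out
}

#' Perturb a mask set to emulate segmentation imperfection
#'
#' Seeded random boundary displacement (pixels adjacent to the boundary flip
#' in or out with probability proportional to `boundary_jitter_px`, applied
#' in unit-jitter rounds) and uniform foreground dropout per structure. The
#' output remains strictly binary.
#'
#' @param ms `mask_set`.
#' @param boundary_jitter_px Jitter magnitude in pixels (>= 0).
#' @param dropout_fraction Probability of dropping each foreground pixel.
#' @param seed Integer seed.
#' @return Perturbed `mask_set`.
#' @export
perturb_masks <- function(ms, boundary_jitter_px = 0, dropout_fraction = 0,
                          seed = 1) {
  stopifnot(boundary_jitter_px >= 0, dropout_fraction >= 0, dropout_fraction < 1)
  if (boundary_jitter_px == 0 && dropout_fraction == 0) return(ms)
  masks <- with_rng_seed(seed, function() {
    lapply(ms$masks, function(m) {
      fg <- m > 0
      rounds <- ceiling(boundary_jitter_px)
      for (r in seq_len(rounds)) {
        p <- 0.5 * min(1, boundary_jitter_px - (r - 1))
        if (p <= 0) break
        grow_cand <- shift_or(fg) & !fg
        shrink_cand <- fg & !(!shift_or(!fg))   # fg pixels with a bg 4-neighbour
        add <- grow_cand & matrix(stats::runif(length(fg)) < p, nrow(fg), ncol(fg))
        drop <- shrink_cand & matrix(stats::runif(length(fg)) < p, nrow(fg), ncol(fg))
        fg <- (fg | add) & !drop
      }
      if (dropout_fraction > 0) {
        keep <- matrix(stats::runif(length(fg)) >= dropout_fraction,
                       nrow(fg), ncol(fg))
        fg <- fg & keep
      }
      fg * 1L
    })
  })
  mask_set(masks, source_id = ms$source_id, pixel_spacing = ms$pixel_spacing,
           presentation = ms$presentation, extractable = ms$extractable)
}

#' Rotate a mask set by multiples of 90 degrees
#'
#' Exact raster rotation (pixel centres map to pixel centres); useful for
#' invariance checks. CTAR, cardiac axis, laterality and |point P| are
#' rotation-invariant.
#'
#' @param ms `mask_set`.
#' @param k Number of clockwise quarter-turns (0-3).
#' @return Rotated `mask_set`.
#' @export
rotate_mask_set <- function(ms, k = 1) {
  k <- k %% 4
  rot1 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  masks <- ms$masks
  for (i in seq_len(k)) masks <- lapply(masks, rot1)
  mask_set(masks, source_id = ms$source_id, pixel_spacing = ms$pixel_spacing,
           presentation = ms$presentation, extractable = ms$extractable)
}

#' Mirror a mask set horizontally
#'
#' Flips the image left-right. Apex side and inferred presentation flip;
#' the declared presentation in the manifest is flipped accordingly so that
#' orientation consistency is preserved. CTAR, cardiac axis and point P
#' (folded gx, signed gy) are mirror-invariant.
#'
#' @param ms `mask_set`.
#' @return Mirrored `mask_set`.
#' @export
mirror_mask_set <- function(ms) {
  masks <- lapply(ms$masks, function(m) m[, ncol(m):1, drop = FALSE])
  pres <- switch(ms$presentation, cephalic = "breech", breech = "cephalic",
                 "unknown")
  mask_set(masks, source_id = ms$source_id, pixel_spacing = ms$pixel_spacing,
           presentation = pres, extractable = ms$extractable)
}
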