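# Screening biometry from a structure mask set.
#
# The measurement chain: spine centroid S from the convex-envelope hollow of
# the thorax mask; the thorax-bisecting line through S ("line RS"); the
# ventricular-septal principal axis; then the cardiothoracic area ratio
# (CTAR), the cardiac axis angle RIV, the apex-side / presentation call, the
# heart-vs-descending-aorta laterality, and the cardiac-position landmark
# point P in a thorax-centred, tilt-corrected, chord-normalised frame.

cross2 <- function(a, b) a[[1]] * b[[2]] - a[[2]] * b[[1]]

#' Cardiothoracic area ratio by pixel counting
#'
#' Foreground pixel count of the heart divided by that of the whole thorax.
#' No elliptical approximation is involved: the ratio comes straight from the
#' contour-based segmentation masks.
#'
#' @param ms `mask_set`.
#' @return Fraction in \[0, 1\].
#' @export
compute_ctar <- function(ms) {
  n_t <- sum(ms$masks$whole_thorax)
  if (n_t == 0) abort_fourcv("empty_region", "whole_thorax is empty")
  sum(ms$masks$heart) / n_t
}

#' Locate the anatomical landmarks of the four-chamber view
#'
#' Constructs, in order:
#' * `S` — spine centroid, from the convex-envelope hollow of the thorax mask;
#' * `rs_line` — the whole-thorax area-bisecting line through S, re-oriented
#'   to point from S toward R (posterior to anterior);
#' * `R` — the rs_line/thoracic-contour intersection farthest from S;
#' * `septal_line` — principal axis of the ventricular septum;
#' * `I` — rs_line x septal_line intersection (`NULL` when parallel);
#' * `V` — the septal-line/thoracic-contour intersection nearer the septum
#'   centroid (the apex-side crossing);
#' * `A` — the crossing of the ray S -> descending-aorta centroid with the
#'   thoracic contour beyond the aorta (`NULL` when the aorta mask is empty);
#' * `O_prime` — whole-thorax centroid; `theta` — signed tilt of rs_line from
#'   image-vertical, folded to (-90, 90\];
#' * `B1`,`B2` / `A1`,`A2` — thoracic-contour crossings of the x'/y' axes
#'   through `O_prime` (x' perpendicular, y' parallel to rs_line).
#'
#' @param ms `mask_set` that passes [validate_mask_set()].
#' @return Object of class `anatomical_landmarks`.
#' @export
locate_landmarks <- function(ms) {
  violations <- validate_mask_set(ms)
  if (length(violations) > 0) {
    abort_fourcv("validation", paste0("mask set invalid: ",
                                      paste(violations, collapse = "; ")))
  }
  S <- convex_hollow_centroid(ms$masks$thorax)
  rs <- area_bisecting_line(ms$masks$whole_thorax, S)
  contour <- extract_outer_contour(ms$masks$whole_thorax)
  hits <- line_contour_intersections(rs, contour)
  if (nrow(hits) == 0) abort_fourcv("geometry", "bisecting line misses the thoracic contour")
  d2 <- (hits[, 1] - S[1])^2 + (hits[, 2] - S[2])^2
  R <- planar_point(hits[which.max(d2), 1], hits[which.max(d2), 2])
  # canonical orientation: rs_line points S -> R (posterior -> anterior)
  u <- c(R[1] - S[1], R[2] - S[2])
  rs_line <- oriented_line(S, u)
  u <- rs_line$direction

  septal_line <- principal_axis_line(ms$masks$ventricular_septum)
  sep_c <- septal_line$anchor
  cr <- cross2(rs_line$direction, septal_line$direction)
  I <- if (abs(cr) > 1e-9) line_line_intersection(rs_line, septal_line) else NULL

  sep_hits <- line_contour_intersections(septal_line, contour)
  if (nrow(sep_hits) == 0) {
    abort_fourcv("geometry", "septal line misses the thoracic contour")
  }
  d2v <- (sep_hits[, 1] - sep_c[1])^2 + (sep_hits[, 2] - sep_c[2])^2
  V <- planar_point(sep_hits[which.min(d2v), 1], sep_hits[which.min(d2v), 2])

  A <- NULL
  if (sum(ms$masks$descending_aorta) > 0) {
    ao_c <- region_centroid(ms$masks$descending_aorta)
    dir_a <- c(ao_c[1] - S[1], ao_c[2] - S[2])
    if (sqrt(sum(dir_a^2)) > 1e-9) {
      ray <- oriented_line(S, dir_a)
      a_hits <- line_contour_intersections(ray, contour)
      if (nrow(a_hits) > 0) {
        t_hit <- (a_hits[, 1] - S[1]) * ray$direction[1] +
                 (a_hits[, 2] - S[2]) * ray$direction[2]
        t_ao <- sqrt(sum(dir_a^2))
        beyond <- which(t_hit > t_ao)
        if (length(beyond) > 0) {
          k <- beyond[which.max(t_hit[beyond])]
          A <- planar_point(a_hits[k, 1], a_hits[k, 2])
        }
      }
    }
  }

  O_prime <- region_centroid(ms$masks$whole_thorax)
  # signed tilt from image-vertical, positive toward +x, folded to (-90, 90]
  theta <- unname(atan2(u[1], -u[2]) * 180 / pi)
  if (theta > 90) theta <- theta - 180
  if (theta <= -90) theta <- theta + 180

  v_perp <- c(u[2], -u[1])                      # x' direction
  x_axis <- oriented_line(O_prime, v_perp)
  y_axis <- oriented_line(O_prime, u)
  b_hits <- line_contour_intersections(x_axis, contour)
  a_hits <- line_contour_intersections(y_axis, contour)
  if (nrow(b_hits) < 2 || nrow(a_hits) < 2) {
    abort_fourcv("geometry", "relative-coordinate axes do not span the thoracic contour")
  }
  B1 <- planar_point(b_hits[1, 1], b_hits[1, 2])
  B2 <- planar_point(b_hits[nrow(b_hits), 1], b_hits[nrow(b_hits), 2])
  A1 <- planar_point(a_hits[1, 1], a_hits[1, 2])
  A2 <- planar_point(a_hits[nrow(a_hits), 1], a_hits[nrow(a_hits), 2])

  structure(
    list(S = S, R = R, I = I, V = V, A = A,
         O_prime = O_prime, theta = theta,
         B1 = B1, B2 = B2, A1 = A1, A2 = A2,
         rs_line = rs_line, septal_line = septal_line,
         septum_centroid = sep_c, thorax_contour = contour),
    class = "anatomical_landmarks"
  )
}

#' @export
print.anatomical_landmarks <- function(x, ...) {
  fmt <- function(p) if (is.null(p)) "absent" else sprintf("(%.1f, %.1f)", p[1], p[2])
  cat("<anatomical_landmarks>\n")
  cat("  S", fmt(x$S), " R", fmt(x$R), " I", fmt(x$I), " V", fmt(x$V),
      " A", fmt(x$A), "\n")
  cat(sprintf("  O' %s  theta %.2f deg\n", fmt(x$O_prime), x$theta))
  invisible(x)
}

#' Cardiac axis: the angle RIV in degrees
#'
#' Angle at I between the rays I->R and I->V, measured identically whether
#' the apex points left or right. When the septal line is parallel to line RS
#' (I undefined) the axis is the angle between the two line directions, 0 in
#' the exactly parallel limit.
#'
#' @param landmarks `anatomical_landmarks`.
#' @return Degrees in \[0, 180\].
#' @export
compute_cardiac_axis <- function(landmarks) {
  if (is.null(landmarks$I)) {
    d1 <- landmarks$rs_line$direction; d2 <- landmarks$septal_line$direction
    a <- acos(max(-1, min(1, abs(sum(d1 * d2))))) * 180 / pi
    return(a)
  }
  angle_at_vertex(landmarks$I, landmarks$R, landmarks$V)
}

#' Classify apex side and infer fetal presentation
#'
#' The apex substitute V is tested against line RS: if V lies on the negative
#' side (cross product of S->R with S->V negative), the apex is in the left
#' thoracic cavity and the presentation is inferred cephalic; the positive
#' side maps to breech.
#'
#' @param landmarks `anatomical_landmarks`.
#' @param tol_px V closer than this to line RS (perpendicular distance) is an
#'   indeterminate-side error (default 0.5).
#' @return List with `apex_side` (`"left_of_RS"`/`"right_of_RS"`) and
#'   `inferred_presentation` (`"cephalic"`/`"breech"`).
#' @export
classify_apex_presentation <- function(landmarks, tol_px = 0.5) {
  u <- landmarks$rs_line$direction
  sv <- c(landmarks$V[1] - landmarks$S[1], landmarks$V[2] - landmarks$S[2])
  cr <- cross2(u, sv)                   # = perpendicular signed distance
  if (abs(cr) < tol_px) {
    abort_fourcv("indeterminate_side", "V lies on line RS; apex side indeterminate")
  }
  if (cr < 0) {
    list(apex_side = "left_of_RS", inferred_presentation = "cephalic")
  } else {
    list(apex_side = "right_of_RS", inferred_presentation = "breech")
  }
}

side_of_rs <- function(landmarks, p) {
  u <- landmarks$rs_line$direction
  cross2(u, c(p[1] - landmarks$S[1], p[2] - landmarks$S[2]))
}

#' Classify heart/descending-aorta laterality
#'
#' In normal anatomy the cardiac apex and the descending aorta lie in the
#' same thoracic cavity (situs solitus); opposite cavities (here "inversus")
#' suggest laterality defects such as a right aortic arch. The primary rule
#' is the side-of-line sign test: V and A on the same side of line RS is
#' solitus, opposite sides inversus. The angular identity (solitus when
#' angle VSA < angle RSV + angle RSA, inversus at equality within `eps_deg`)
#' is exposed via [laterality_angle_criterion()] and asserted equivalent on
#' non-degenerate geometry.
#'
#' @param landmarks `anatomical_landmarks`.
#' @param tol_px V or A closer than this to line RS gives "indeterminate".
#' @return `"solitus"`, `"inversus"` or `"indeterminate"`.
#' @export
classify_laterality <- function(landmarks, tol_px = 0.5) {
  if (is.null(landmarks$A)) return("indeterminate")
  sv <- side_of_rs(landmarks, landmarks$V)
  sa <- side_of_rs(landmarks, landmarks$A)
  if (abs(sv) < tol_px || abs(sa) < tol_px) return("indeterminate")
  if (sign(sv) == sign(sa)) "solitus" else "inversus"
}

#' Laterality by the angular identity
#'
#' Compares angle VSA with angle RSV + angle RSA at vertex S: strictly
#' smaller means V lies on the arc AR (solitus); equality within `eps_deg`
#' means the heart and aorta occupy opposite cavities (inversus).
#'
#' @param landmarks `anatomical_landmarks`.
#' @param eps_deg Equality tolerance in degrees (default 1).
#' @return `"solitus"`, `"inversus"` or `"indeterminate"`.
#' @export
laterality_angle_criterion <- function(landmarks, eps_deg = 1.0) {
  if (is.null(landmarks$A)) return("indeterminate")
  vsa <- angle_at_vertex(landmarks$S, landmarks$V, landmarks$A)
  rsv <- angle_at_vertex(landmarks$S, landmarks$R, landmarks$V)
  rsa <- angle_at_vertex(landmarks$S, landmarks$R, landmarks$A)
  if (abs(vsa - (rsv + rsa)) <= eps_deg) "inversus"
  else if (vsa < rsv + rsa) "solitus"
  else "indeterminate"
}

#' Cardiac position: point P in thorax-relative units
#'
#' P is the crossing of the septal line with the cardiac circumference on the
#' side opposite the ventricular septum (the basal, atrial-wall crossing —
#' the published approximation of the atrial septum / atrial wall junction).
#' It is then expressed in the relative frame: translated by -O', rotated by
#' -theta so y' runs along line RS, y' sign flipped (anterior positive), and
#' scaled by the unit lengths d_x = |B1B2|/divisions, d_y = |A1A2|/divisions.
#' g_x is folded to the apex side (absolute value); g_y keeps its sign.
#'
#' @param ms `mask_set` (for the heart contour).
#' @param landmarks `anatomical_landmarks`.
#' @param divisions Number of equal parts each reference chord is divided
#'   into (default 8, so a semi-chord spans 4 units).
#' @return Named numeric `c(gx = , gy = )`.
#' @export
compute_point_p <- function(ms, landmarks, divisions = 8) {
  if (sum(ms$masks$heart) == 0) abort_fourcv("empty_region", "heart mask is empty")
  heart_contour <- extract_outer_contour(ms$masks$heart)
  hits <- line_contour_intersections(landmarks$septal_line, heart_contour)
  if (nrow(hits) == 0) {
    abort_fourcv("no_intersection", "septal line misses the cardiac circumference")
  }
  sep_c <- landmarks$septum_centroid
  d2 <- (hits[, 1] - sep_c[1])^2 + (hits[, 2] - sep_c[2])^2
  P <- planar_point(hits[which.max(d2), 1], hits[which.max(d2), 2])

  dx_len <- sqrt(sum((landmarks$B1 - landmarks$B2)^2)) / divisions
  dy_len <- sqrt(sum((landmarks$A1 - landmarks$A2)^2)) / divisions
  if (dx_len < 1e-9 || dy_len < 1e-9) {
    abort_fourcv("degenerate_chord", "reference chord has zero length")
  }
  u <- landmarks$rs_line$direction              # posterior -> anterior
  v <- c(u[2], -u[1])                           # x' direction
  rel <- c(P[1] - landmarks$O_prime[1], P[2] - landmarks$O_prime[2])
  gx <- abs(sum(rel * v)) / dx_len              # folded to the apex side
  gy <- sum(rel * u) / dy_len                   # anterior positive
  out <- c(gx = gx, gy = gy)
  attr(out, "pixel") <- P
  out
}

#' Measure all biometric parameters of one image
#'
#' Runs the full landmark construction and returns a biometric record with
#' the CTAR, cardiac axis, apex side, inferred presentation, laterality and
#' point P. A missing descending aorta degrades laterality to
#' "indeterminate" instead of failing.
#'
#' @param ms `mask_set`.
#' @param divisions Point-P chord divisions, see [compute_point_p()].
#' @return Object of class `biometric_record`.
#' @export
measure_biometrics <- function(ms, divisions = 8) {
  lm <- locate_landmarks(ms)
  ap <- classify_apex_presentation(lm)
  rec <- list(
    ctar = compute_ctar(ms),
    cardiac_axis = compute_cardiac_axis(lm),
    apex_side = ap$apex_side,
    inferred_presentation = ap$inferred_presentation,
    laterality = classify_laterality(lm),
    point_p = compute_point_p(ms, lm, divisions = divisions),
    landmarks = lm,
    source_id = ms$source_id
  )
  structure(rec, class = "biometric_record")
}

#' @export
print.biometric_record <- function(x, ...) {
  cat(sprintf("<biometric_record> %s\n", x$source_id))
  cat(sprintf("  CTAR          %.1f%%\n", 100 * x$ctar))
  cat(sprintf("  cardiac axis  %.1f deg\n", x$cardiac_axis))
  cat(sprintf("  apex side     %s (%s)\n", x$apex_side, x$inferred_presentation))
  cat(sprintf("  laterality    %s\n", x$laterality))
  cat(sprintf("  point P       (%.2f, %.2f)\n", x$point_p["gx"], x$point_p["gy"]))
  invisible(x)
}

#' Serialize a biometric record to JSON
#'
#' @param record `biometric_record`.
#' @param path Output file; when `NULL` the JSON string is returned.
#' @export
biometric_record_json <- function(record, path = NULL) {
  lm <- record$landmarks
  pt <- function(p) if (is.null(p)) NULL else list(x = p[[1]], y = p[[2]])
  payload <- list(
    source_id = record$source_id,
    ctar = record$ctar,
    cardiac_axis_deg = record$cardiac_axis,
    apex_side = record$apex_side,
    inferred_presentation = record$inferred_presentation,
    laterality = record$laterality,
    point_p = list(gx = unname(record$point_p["gx"]),
                   gy = unname(record$point_p["gy"])),
    landmarks = if (is.null(lm)) NULL else list(
      S = pt(lm$S), R = pt(lm$R), I = pt(lm$I), V = pt(lm$V), A = pt(lm$A),
      O_prime = pt(lm$O_prime), theta_deg = lm$theta,
      B1 = pt(lm$B1), B2 = pt(lm$B2), A1 = pt(lm$A1), A2 = pt(lm$A2)
    )
  )
  if (is.null(path)) {
    jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null", digits = NA)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
    invisible(path)
  }
}
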