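#' End-diastolic linear (1D) measurements
#'
#' Caliper measurements from the parasternal long-axis view: septal wall
#' thickness (IVS), LV internal diameter (LVID) and posterior wall thickness
#' (PWT), all at end-diastole and in centimetres.
#'
#' @param ivs_cm Interventricular septal thickness (cm), `>= 0`.
#' @param lvid_cm LV internal diameter (cm), `> 0` for volume computation.
#' @param pwt_cm Posterior wall thickness (cm), `>= 0`.
#' @return An object of class `linear_measurements`.
#' @examples
#' linear_measurements(1.0, 4.5, 1.0)
#' @export
linear_measurements <- function(ivs_cm, lvid_cm, pwt_cm) {
  check_number(ivs_cm, "ivs_cm", min = 0)
  check_number(lvid_cm, "lvid_cm", min = 0, strict = TRUE)
  check_number(pwt_cm, "pwt_cm", min = 0)
  structure(
    list(ivs_cm = ivs_cm, lvid_cm = lvid_cm, pwt_cm = pwt_cm),
    class = "linear_measurements"
  )
}

#' Short-axis traced areas
#'
#' Planimetered epicardial (outer, A1) and endocardial (inner, A2) areas from
#' a single parasternal short-axis frame, in cm^2, together with the LV level
#' at which the trace was made. The default level is the chordae level.
#'
#' @param a1_cm2 Outer (epicardial) traced area (cm^2).
#' @param a2_cm2 Inner (endocardial) traced area (cm^2). Must not exceed
#'   `a1_cm2`.
#' @param level Trace level, one of `"chordae"` (default), `"mitral"`,
#'   `"mid_papillary"`. Recorded as metadata; no level-specific correction is
#'   applied.
#' @return An object of class `sax_trace`.
#' @examples
#' sax_trace(a1_cm2 = 16 * pi, a2_cm2 = 9 * pi)
#' @export
sax_trace <- function(a1_cm2, a2_cm2, level = c("chordae", "mitral", "mid_papillary")) {
  level <- match.arg(level)
  check_number(a1_cm2, "a1_cm2", min = 0)
  check_number(a2_cm2, "a2_cm2", min = 0)
  if (a1_cm2 < a2_cm2) {
    abort_domain(sprintf(
      "epicardial area smaller than endocardial: a1_cm2 (%g) < a2_cm2 (%g)",
      a1_cm2, a2_cm2
    ))
  }
  structure(
    list(a1_cm2 = a1_cm2, a2_cm2 = a2_cm2, level = level),
    class = "sax_trace"
  )
}

#' Planar endocardial (or epicardial) contour in one apical view
#'
#' An ordered, non-self-intersecting open polyline of border vertices running
#' from one mitral-annulus endpoint to the other, plus the annulus endpoints
#' and the apex point. Coordinates are in cm in the image plane.
#'
#' @param points Two-column numeric matrix (x_cm, y_cm) of at least 3 border
#'   vertices, ordered along the border.
#' @param base_left,base_right Mitral-annulus endpoints, numeric length-2.
#'   Default to the first and last vertex of `points`.
#' @param apex Apex point, numeric length-2. Defaults to the vertex farthest
#'   from the mitral-annulus midpoint.
#' @return An object of class `planar_contour`.
#' @examples
#' pts <- cbind(c(-2, -2, 2, 2), c(0, 8, 8, 0))
#' planar_contour(pts, apex = c(0, 8))
#' @export
planar_contour <- function(points, base_left = NULL, base_right = NULL,
                           apex = NULL) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L || nrow(points) < 3L ||
      anyNA(points)) {
    abort_validation("`points` must be a numeric matrix with 2 columns and >= 3 complete rows")
  }
  colnames(points) <- c("x_cm", "y_cm")
  if (is.null(base_left)) base_left <- points[1L, ]
  if (is.null(base_right)) base_right <- points[nrow(points), ]
  base_left <- as.numeric(base_left)
  base_right <- as.numeric(base_right)
  mid <- (base_left + base_right) / 2
  if (is.null(apex)) {
    d2 <- (points[, 1] - mid[1])^2 + (points[, 2] - mid[2])^2
    apex <- points[which.max(d2), ]
  }
  apex <- as.numeric(apex)
  if (.point_on_segment(apex, base_left, base_right)) {
    abort_geometry("apex lies on the mitral-annulus base segment")
  }
  if (.polyline_self_intersects(points)) {
    abort_geometry("contour is self-intersecting")
  }
  structure(
    list(points = points, base_left = base_left, base_right = base_right,
         apex = apex),
    class = "planar_contour"
  )
}

.point_on_segment <- function(p, a, b, tol = 1e-9) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < tol^2) return(sum((p - a)^2) < tol^2)
  cross <- ab[1] * (p[2] - a[2]) - ab[2] * (p[1] - a[1])
  if (abs(cross) / sqrt(len2) > tol) return(FALSE)
  u <- sum((p - a) * ab) / len2
  u >= -tol && u <= 1 + tol
}

# Vectorised proper-intersection test over all non-adjacent segment pairs of
# the open polyline. O(n^2) in memory but n is a few hundred at most.
.polyline_self_intersects <- function(points) {
  n <- nrow(points) - 1L
  if (n < 3L) return(FALSE)
  p1x <- points[1:n, 1]; p1y <- points[1:n, 2]
  p2x <- points[2:(n + 1L), 1]; p2y <- points[2:(n + 1L), 2]
  cross_sign <- function(ax, ay, bx, by, cx, cy) {
    # sign of (b-a) x (c-a), outer over segment starts c
    sign((bx - ax) * (outer(rep(1, length(ax)), cy) - ay) -
         (by - ay) * (outer(rep(1, length(ax)), cx) - ax))
  }
  d1 <- cross_sign(p1x, p1y, p2x, p2y, p1x, p1y)
  d2 <- cross_sign(p1x, p1y, p2x, p2y, p2x, p2y)
  d3 <- t(cross_sign(p1x, p1y, p2x, p2y, p1x, p1y))
  d4 <- t(cross_sign(p1x, p1y, p2x, p2y, p2x, p2y))
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  idx <- abs(outer(seq_len(n), seq_len(n), "-")) > 1L
  any(proper & idx)
}

#' Ordered disc stack from biplane delineation
#'
#' Carrier of the modified-Simpson decomposition: `n` equal-height elliptical
#' discs ordered base-to-apex, with semi-axis `a_i` measured in the apical
#' four-chamber view and `b_i` in the two-chamber view. Disc height is the
#' effective long-axis length (maximum of the two views) divided by `n`.
#'
#' @param semi_axes Two-column numeric matrix (a_cm from 4CH, b_cm from 2CH),
#'   one row per disc, ordered base to apex; all entries `>= 0`.
#' @param length_4ch_cm,length_2ch_cm Long-axis lengths (cm) in the two
#'   apical views, `> 0`.
#' @return An object of class `disc_stack` with derived fields `n_discs` and
#'   `disc_height_cm`.
#' @examples
#' disc_stack(cbind(rep(2, 30), rep(2, 30)), 8, 8)
#' @export
disc_stack <- function(semi_axes, length_4ch_cm, length_2ch_cm) {
  semi_axes <- as.matrix(semi_axes)
  if (!is.numeric(semi_axes) || ncol(semi_axes) != 2L || nrow(semi_axes) < 1L ||
      anyNA(semi_axes)) {
    abort_validation("`semi_axes` must be a numeric matrix with 2 columns and >= 1 row")
  }
  if (any(semi_axes < 0)) abort_domain("all disc semi-axes must be >= 0")
  check_number(length_4ch_cm, "length_4ch_cm", min = 0, strict = TRUE)
  check_number(length_2ch_cm, "length_2ch_cm", min = 0, strict = TRUE)
  colnames(semi_axes) <- c("a_cm", "b_cm")
  n <- nrow(semi_axes)
  structure(
    list(
      n_discs = n,
      semi_axes = semi_axes,
      length_4ch_cm = length_4ch_cm,
      length_2ch_cm = length_2ch_cm,
      disc_height_cm = max(length_4ch_cm, length_2ch_cm) / n
    ),
    class = "disc_stack"
  )
}

#' Subject covariates
#'
#' @param id Subject identifier (string).
#' @param age_years Age in years. Values below 18 are accepted with a warning
#'   (adult reference strata).
#' @param sex `"M"` or `"F"`.
#' @param bsa_m2 Body surface area (m^2), `> 0`.
#' @return An object of class `subject`.
#' @export
subject <- function(id, age_years, sex = c("M", "F"), bsa_m2) {
  sex <- match.arg(sex)
  check_number(age_years, "age_years", min = 0)
  check_number(bsa_m2, "bsa_m2", min = 0, strict = TRUE)
  if (age_years < 18) {
    warning("age_years < 18: hypertrophy cutoffs are adult reference values",
            call. = FALSE)
  }
  structure(
    list(id = as.character(id), age_years = age_years, sex = sex,
         bsa_m2 = bsa_m2),
    class = "subject"
  )
}

.method_ids <- c("NOVEL", "BP", "TE", "AL", "DEV", "TEICHHOLZ_EDV",
                 "BIPLANE_EDV")

#' Result of one quantification method
#'
#' @param method One of `"NOVEL"`, `"BP"`, `"TE"`, `"AL"`, `"DEV"`,
#'   `"TEICHHOLZ_EDV"`, `"BIPLANE_EDV"`.
#' @param lvm_g LV mass (g) or `NA` for volume-only methods.
#' @param edv_ml End-diastolic volume (ml) or `NA`.
#' @param subject Optional [subject()]; when supplied, `indexed_g_per_m2 =
#'   lvm_g / bsa_m2` is attached.
#' @param details Optional named list of method internals (e.g. `t_cm`,
#'   `edv_epi_ml`) kept for auditing.
#' @return An object of class `method_result`.
#' @export
method_result <- function(method, lvm_g = NA_real_, edv_ml = NA_real_,
                          subject = NULL, details = list()) {
  if (!method %in% .method_ids) {
    abort_config(sprintf("unknown method id '%s'", method))
  }
  if (!is.na(lvm_g)) check_number(lvm_g, "lvm_g", min = 0)
  if (!is.na(edv_ml)) check_number(edv_ml, "edv_ml", min = 0)
  indexed <- if (!is.null(subject) && !is.na(lvm_g)) {
    lvm_g / subject$bsa_m2
  } else {
    NA_real_
  }
  structure(
    list(method = method, lvm_g = lvm_g, edv_ml = edv_ml,
         indexed_g_per_m2 = indexed,
         subject_id = if (is.null(subject)) NA_character_ else subject$id,
         details = details),
    class = "method_result"
  )
}

#' @export
print.method_result <- function(x, ...) {
  cat(sprintf("<method_result> %s\n", x$method))
  if (!is.na(x$lvm_g)) cat(sprintf("  LVM: %.1f g\n", x$lvm_g))
  if (!is.na(x$edv_ml)) cat(sprintf("  EDV: %.1f ml\n", x$edv_ml))
  if (!is.na(x$indexed_g_per_m2)) {
    cat(sprintf("  LVM index: %.1f g/m2\n", x$indexed_g_per_m2))
  }
  invisible(x)
}

#' @export
print.disc_stack <- function(x, ...) {
  cat(sprintf(
    "<disc_stack> %d discs, height %.3f cm, lengths 4CH %.2f / 2CH %.2f cm\n",
    x$n_discs, x$disc_height_cm, x$length_4ch_cm, x$length_2ch_cm
  ))
  invisible(x)
}
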