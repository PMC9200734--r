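#' Parameterised left-ventricle phantom
#'
#' An analytic LV geometry with closed-form cavity and myocardial volumes,
#' used to validate the quantification methods. Three shape families are
#' available:
#' \describe{
#'   \item{`hemi_ellipsoid`}{cavity is a half ellipsoid with long semi-axis
#'     `endo_long_cm` (base to apex) and short semi-axes `endo_b_cm` (4CH
#'     direction) and `endo_c_cm` (2CH direction); the epicardial surface is
#'     the half ellipsoid with every semi-axis enlarged by `wall_cm`.}
#'   \item{`cylinder_flat_cap`}{cavity is an elliptical cylinder of length
#'     `endo_long_cm`; the epicardium adds `wall_cm` radially and a flat
#'     apical cap of thickness `wall_cm`.}
#'   \item{`septal_bulge`}{a circular `cylinder_flat_cap` (requires
#'     `endo_b_cm == endo_c_cm`) with a smooth cosine-tapered epicardial
#'     thickening on the septal (4CH) side: extra thickness
#'     `bulge_extra_cm * cos^2(pi*theta/(2*alpha)) * cos^2(pi*(z-z0)/(2*w))`
#'     over half-angle `alpha = bulge_angle_rad` and longitudinal half-extent
#'     `w = bulge_extent_cm`, centred at the short-axis plane. This is the
#'     focal-asymmetry scenario in which single-chord wall measurements
#'     fail.}
#' }
#'
#' @param shape One of `"hemi_ellipsoid"`, `"cylinder_flat_cap"`,
#'   `"septal_bulge"`.
#' @param endo_long_cm Apex-to-base cavity length (cm).
#' @param endo_b_cm,endo_c_cm Cavity short semi-axes (cm) in the 4CH and 2CH
#'   directions.
#' @param wall_cm Uniform wall thickness (cm).
#' @param bulge_extra_cm Peak extra wall thickness of the septal bulge (cm).
#' @param bulge_angle_rad Angular half-extent of the bulge (rad).
#' @param bulge_extent_cm Longitudinal half-extent of the bulge (cm).
#' @param sax_level_fraction Position of the short-axis plane as a fraction
#'   of the cavity length from the base; the default 0.4 stands in for the
#'   chordae level (between the mitral and mid-papillary levels).
#' @return An object of class `phantom_spec`.
#' @examples
#' phantom_spec() # the default hemi-ellipsoid: L = 8, b = c = 2.5, t = 1
#' @export
phantom_spec <- function(shape = c("hemi_ellipsoid", "cylinder_flat_cap",
                                   "septal_bulge"),
                         endo_long_cm = 8, endo_b_cm = 2.5, endo_c_cm = 2.5,
                         wall_cm = 1,
                         bulge_extra_cm = 0.8, bulge_angle_rad = pi / 3,
                         bulge_extent_cm = 2,
                         sax_level_fraction = 0.4) {
  shape <- match.arg(shape)
  check_number(endo_long_cm, "endo_long_cm", min = 0, strict = TRUE)
  check_number(endo_b_cm, "endo_b_cm", min = 0, strict = TRUE)
  check_number(endo_c_cm, "endo_c_cm", min = 0, strict = TRUE)
  check_number(wall_cm, "wall_cm", min = 0)
  check_number(sax_level_fraction, "sax_level_fraction", min = 0, strict = TRUE)
  if (sax_level_fraction >= 1) {
    abort_domain("sax_level_fraction must be in (0, 1)")
  }
  if (shape == "septal_bulge") {
    if (endo_b_cm != endo_c_cm) {
      abort_config("septal_bulge requires a circular cavity (endo_b_cm == endo_c_cm)")
    }
    check_number(bulge_extra_cm, "bulge_extra_cm", min = 0)
    check_number(bulge_angle_rad, "bulge_angle_rad", min = 0, strict = TRUE)
    if (bulge_angle_rad > pi) abort_domain("bulge_angle_rad must be <= pi")
    check_number(bulge_extent_cm, "bulge_extent_cm", min = 0, strict = TRUE)
    z0 <- sax_level_fraction * endo_long_cm
    if (z0 - bulge_extent_cm < 0 || z0 + bulge_extent_cm > endo_long_cm) {
      abort_geometry("septal bulge extends beyond the cavity length")
    }
  }
  structure(
    list(shape = shape, endo_long_cm = endo_long_cm, endo_b_cm = endo_b_cm,
         endo_c_cm = endo_c_cm, wall_cm = wall_cm,
         bulge_extra_cm = bulge_extra_cm, bulge_angle_rad = bulge_angle_rad,
         bulge_extent_cm = bulge_extent_cm,
         sax_level_fraction = sax_level_fraction),
    class = "phantom_spec"
  )
}

#' Measurement-noise model
#'
#' Zero-mean Gaussian noise applied by [perturb()]. Distinct measurements
#' (each caliper reading, each traced area, each apical view) receive
#' independent draws; within one traced apical view a single common relative
#' factor scales all chord widths, since tracing error is strongly
#' correlated along one border. This is a stand-in for sonographer error,
#' not an estimate of it.
#'
#' @param linear_sd_cm Additive SD for the 1D measurements; a scalar or a
#'   length-3 vector ordered (IVS, LVID, PWT).
#' @param area_rel_sd Relative SD applied independently to each traced
#'   short-axis area.
#' @param contour_rel_sd Relative SD of the per-view chord-width factor.
#' @param seed Optional RNG seed; when set, [perturb()] is reproducible and
#'   leaves the global RNG state untouched.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(linear_sd_cm = 0, area_rel_sd = 0,
                        contour_rel_sd = 0, seed = NULL) {
  if (!is.numeric(linear_sd_cm) || !length(linear_sd_cm) %in% c(1L, 3L) ||
      anyNA(linear_sd_cm) || any(linear_sd_cm < 0)) {
    abort_config("linear_sd_cm must be a non-negative scalar or length-3 vector")
  }
  check_number(area_rel_sd, "area_rel_sd", min = 0)
  check_number(contour_rel_sd, "contour_rel_sd", min = 0)
  structure(
    list(linear_sd_cm = linear_sd_cm, area_rel_sd = area_rel_sd,
         contour_rel_sd = contour_rel_sd, seed = seed),
    class = "noise_model"
  )
}

# Longitudinal bulge taper at height z (1 at the bulge centre, 0 outside).
.bulge_f <- function(p, z) {
  z0 <- p$sax_level_fraction * p$endo_long_cm
  w <- p$bulge_extent_cm
  ifelse(abs(z - z0) < w, cos(pi * (z - z0) / (2 * w))^2, 0)
}

#' Closed-form cavity volume and myocardial mass of a phantom
#'
#' @param p A [phantom_spec()].
#' @param density_g_per_ml Myocardial density, default 1.05 g/ml.
#' @return A list with `edv_ml` (endocardial cavity volume) and
#'   `myocardial_mass_g`.
#' @examples
#' analytic_truth(phantom_spec()) # EDV 104.72 ml, mass 132.50 g
#' @export
analytic_truth <- function(p, density_g_per_ml = 1.05) {
  stopifnot(inherits(p, "phantom_spec"))
  L <- p$endo_long_cm; b <- p$endo_b_cm; cc <- p$endo_c_cm; t <- p$wall_cm
  if (p$shape == "hemi_ellipsoid") {
    edv <- (2 / 3) * pi * b * cc * L
    myo <- (2 / 3) * pi * ((b + t) * (cc + t) * (L + t) - b * cc * L)
  } else {
    edv <- pi * b * cc * L
    myo <- pi * ((b + t) * (cc + t) - b * cc) * L + pi * (b + t) * (cc + t) * t
    if (p$shape == "septal_bulge") {
      # outward thickening Delta(z, theta): extra volume
      # = int int [R*Delta + Delta^2/2] dtheta dz with R = r + t constant;
      # int cos^2 over its window = (half-extent), int cos^4 = 3/4 half-extent
      E <- p$bulge_extra_cm; al <- p$bulge_angle_rad; w <- p$bulge_extent_cm
      myo <- myo + (b + t) * E * al * w + (E^2 / 2) * (3 * al / 4) * (3 * w / 4)
    }
  }
  list(edv_ml = edv, myocardial_mass_g = density_g_per_ml * myo)
}

# Endo/epi half-width profiles along z in one direction (semi-axis bb).
.radius_profile <- function(shape, bb, L, z) {
  if (shape == "hemi_ellipsoid") {
    bb * sqrt(pmax(0, 1 - (z / L)^2))
  } else {
    rep(bb, length(z))
  }
}

#' Render exact measurements from a phantom
#'
#' Produces every input the quantification methods consume, noiselessly and
#' consistently with the geometry: short-axis areas are the true
#' cross-sections at the short-axis plane, apical contours are the true
#' meridional sections of the cavity, LVID is the endocardial diameter at
#' the plane (4CH direction), and IVS/PWT are the true in-plane wall
#' thicknesses on the septal and posterior side (the septal bulge, when
#' intersected, adds to IVS only).
#'
#' @param p A [phantom_spec()].
#' @param n_discs Disc count for the rendered stack (default 30).
#' @param contour_points Vertices per contour side (default 120).
#' @return A list of class `phantom_measurements` with elements `linear`,
#'   `sax`, `contour_4ch`, `contour_2ch`, `disc_stack`, `long_axis`.
#' @export
render_measurements <- function(p, n_discs = 30L, contour_points = 120L) {
  stopifnot(inherits(p, "phantom_spec"))
  L <- p$endo_long_cm; b <- p$endo_b_cm; cc <- p$endo_c_cm; t <- p$wall_cm
  z0 <- p$sax_level_fraction * L
  if (z0 <= 0 || z0 >= L) abort_geometry("short-axis plane lies outside the cavity")

  rb0 <- .radius_profile(p$shape, b, L, z0)
  rc0 <- .radius_profile(p$shape, cc, L, z0)
  if (p$shape == "hemi_ellipsoid") {
    Rb0 <- (b + t) * sqrt(1 - (z0 / (L + t))^2)
    Rc0 <- (cc + t) * sqrt(1 - (z0 / (L + t))^2)
  } else {
    Rb0 <- b + t
    Rc0 <- cc + t
  }

  ivs <- Rb0 - rb0
  pwt <- Rb0 - rb0
  a1 <- pi * Rb0 * Rc0
  a2 <- pi * rb0 * rc0
  if (p$shape == "septal_bulge") {
    E <- p$bulge_extra_cm; al <- p$bulge_angle_rad
    f0 <- .bulge_f(p, z0)
    ivs <- ivs + E * f0
    a1 <- a1 + f0 * (b + t) * E * al + f0^2 * (E^2 / 2) * (3 * al / 4)
  }

  zi <- (seq_len(n_discs) - 0.5) * L / n_discs
  stack <- disc_stack(
    cbind(.radius_profile(p$shape, b, L, zi), .radius_profile(p$shape, cc, L, zi)),
    length_4ch_cm = L, length_2ch_cm = L
  )

  list_out <- list(
    linear = linear_measurements(ivs, 2 * rb0, pwt),
    sax = sax_trace(a1_cm2 = a1, a2_cm2 = a2, level = "chordae"),
    contour_4ch = .phantom_contour(p, b, contour_points),
    contour_2ch = .phantom_contour(p, cc, contour_points),
    disc_stack = stack,
    long_axis = long_axis_split(a_cm = L - z0, d_cm = z0)
  )
  class(list_out) <- "phantom_measurements"
  list_out
}

# Endocardial meridional contour of the cavity in one view.
.phantom_contour <- function(p, bb, n_side) {
  L <- p$endo_long_cm
  if (p$shape == "hemi_ellipsoid") {
    u <- seq(0, pi / 2, length.out = n_side + 1L)
    left <- cbind(-bb * cos(u), L * sin(u))
    right <- cbind(bb * cos(rev(u[-length(u)])), L * sin(rev(u[-length(u)])))
    pts <- rbind(left, right)
  } else {
    pts <- rbind(c(-bb, 0), c(-bb, L), c(bb, L), c(bb, 0))
  }
  planar_contour(pts, base_left = c(-bb, 0), base_right = c(bb, 0),
                 apex = c(0, L))
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.rnorm_valid <- function(mean, sd, lower, max_tries = 100L) {
  if (sd == 0) return(mean)
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lower) return(x)
  }
  abort_domain("could not draw a valid noisy measurement in 100 tries")
}

# Rescale a contour's chord widths (perpendicular distance from the long
# axis) by a common factor.
.scale_contour_width <- function(contour, f) {
  mid <- (contour$base_left + contour$base_right) / 2
  axis <- contour$apex - mid
  len <- sqrt(sum(axis^2))
  u <- axis / len
  v <- c(-u[2], u[1])
  remap <- function(pts) {
    rel_x <- pts[, 1] - mid[1]
    rel_y <- pts[, 2] - mid[2]
    s <- rel_x * u[1] + rel_y * u[2]
    w <- (rel_x * v[1] + rel_y * v[2]) * f
    cbind(mid[1] + s * u[1] + w * v[1], mid[2] + s * u[2] + w * v[2])
  }
  pts <- remap(contour$points)
  ends <- remap(rbind(contour$base_left, contour$base_right))
  planar_contour(pts, base_left = ends[1, ], base_right = ends[2, ],
                 apex = contour$apex)
}

#' Apply measurement noise to rendered measurements
#'
#' Reproducible given `nm$seed`; the identity when all SDs are zero. Draws
#' are redrawn (up to 100 times) when they would violate a type invariant
#' (negative length, `A1 < A2`), so every perturbed record is valid.
#'
#' @param m A `phantom_measurements` list from [render_measurements()].
#' @param nm A [noise_model()].
#' @return A perturbed `phantom_measurements` list of the same structure.
#' @export
perturb <- function(m, nm) {
  stopifnot(inherits(m, "phantom_measurements"), inherits(nm, "noise_model"))
  .with_seed(nm$seed, {
    out <- m
    sds <- rep(nm$linear_sd_cm, length.out = 3L)
    out$linear <- linear_measurements(
      .rnorm_valid(m$linear$ivs_cm, sds[1], 0),
      .rnorm_valid(m$linear$lvid_cm, sds[2], 1e-6),
      .rnorm_valid(m$linear$pwt_cm, sds[3], 0)
    )
    if (nm$area_rel_sd > 0) {
      for (i in seq_len(100L)) {
        a1 <- m$sax$a1_cm2 * (1 + stats::rnorm(1, 0, nm$area_rel_sd))
        a2 <- m$sax$a2_cm2 * (1 + stats::rnorm(1, 0, nm$area_rel_sd))
        if (a1 >= a2 && a2 >= 0) break
        if (i == 100L) abort_domain("could not draw valid noisy areas in 100 tries")
      }
      out$sax <- sax_trace(a1, a2, level = m$sax$level)
    }
    if (nm$contour_rel_sd > 0) {
      f4 <- .rnorm_valid(1, nm$contour_rel_sd, 1e-3)
      f2 <- .rnorm_valid(1, nm$contour_rel_sd, 1e-3)
      out$contour_4ch <- .scale_contour_width(m$contour_4ch, f4)
      out$contour_2ch <- .scale_contour_width(m$contour_2ch, f2)
      out$disc_stack <- disc_stack(
        cbind(m$disc_stack$semi_axes[, 1] * f4,
              m$disc_stack$semi_axes[, 2] * f2),
        m$disc_stack$length_4ch_cm, m$disc_stack$length_2ch_cm
      )
    }
    out
  })
}

#' Simulate a cohort of phantom subjects
#'
#' Renders and perturbs every phantom once per session and returns a tidy
#' table with all method inputs plus the analytic truth columns. The disc
#' stack is stored as a compact JSON column (`stack_json`); decode with
#' [disc_stack_from_json()]. Deterministic (byte-identical CSV) for a fixed
#' `nm$seed`.
#'
#' @param specs A [phantom_spec()] or list of them.
#' @param nm A [noise_model()].
#' @param sessions Number of repeated sessions per subject (default 1).
#' @param n_discs Disc count for rendered stacks.
#' @return A `data.frame`, one row per subject x session.
#' @export
simulate_cohort <- function(specs, nm = noise_model(), sessions = 1L,
                            n_discs = 30L) {
  if (inherits(specs, "phantom_spec")) specs <- list(specs)
  if (length(specs) < 1L) abort_config("need at least one phantom_spec")
  stopifnot(all(vapply(specs, inherits, logical(1), "phantom_spec")))
  nm_inner <- nm
  nm_inner$seed <- NULL
  .with_seed(nm$seed, {
    rows <- list()
    for (i in seq_along(specs)) {
      p <- specs[[i]]
      truth <- analytic_truth(p)
      base <- render_measurements(p, n_discs = n_discs)
      for (s in seq_len(sessions)) {
        m <- perturb(base, nm_inner)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("P%03d", i),
          session = s,
          shape = p$shape,
          ivs_cm = m$linear$ivs_cm,
          lvid_cm = m$linear$lvid_cm,
          pwt_cm = m$linear$pwt_cm,
          a1_cm2 = m$sax$a1_cm2,
          a2_cm2 = m$sax$a2_cm2,
          sax_level = m$sax$level,
          a_cm = m$long_axis$a_cm,
          d_cm = m$long_axis$d_cm,
          n_discs = m$disc_stack$n_discs,
          stack_json = disc_stack_to_json(m$disc_stack),
          truth_edv_ml = truth$edv_ml,
          truth_lvm_g = truth$myocardial_mass_g,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}
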