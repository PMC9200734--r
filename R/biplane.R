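#' Slice two apical contours into a biplane disc stack
#'
#' Builds the modified-Simpson disc stack from endocardial (or epicardial)
#' contours delineated in the apical four- and two-chamber views. In each
#' view the long axis runs from the mitral-annulus midpoint to the apex; the
#' stack spans the effective length (maximum of the two view lengths) in `n`
#' equal-height discs, and semi-axis `i` is half the contour chord width at
#' the disc mid-level, measured perpendicular to that view's long axis. Each
#' view is sampled at the same fractional levels of its own length.
#'
#' @param c4,c2 [planar_contour()] objects from the four- and two-chamber
#'   views.
#' @param n Number of discs (default 30; some guideline software uses 20).
#' @return A [disc_stack()].
#' @examples
#' pts <- cbind(c(-2, -2, 2, 2), c(0, 8, 8, 0))
#' rect <- planar_contour(pts, apex = c(0, 8))
#' contours_to_discstack(rect, rect, n = 30)
#' @export
contours_to_discstack <- function(c4, c2, n = 30L) {
  stopifnot(inherits(c4, "planar_contour"), inherits(c2, "planar_contour"))
  n <- as.integer(n)
  if (n < 1L) abort_domain("disc count n must be >= 1")
  g4 <- .contour_axis_frame(c4)
  g2 <- .contour_axis_frame(c2)
  frac <- (seq_len(n) - 0.5) / n
  a_cm <- .chord_semi_axes(g4, frac)
  b_cm <- .chord_semi_axes(g2, frac)
  disc_stack(cbind(a_cm, b_cm), length_4ch_cm = g4$length,
             length_2ch_cm = g2$length)
}

# Rotate contour points into (s, w): s along the long axis from the
# mitral-annulus midpoint towards the apex, w perpendicular.
.contour_axis_frame <- function(contour) {
  mid <- (contour$base_left + contour$base_right) / 2
  axis <- contour$apex - mid
  len <- sqrt(sum(axis^2))
  if (len < 1e-9) {
    abort_geometry("degenerate geometry: apex coincides with the mitral-annulus midpoint")
  }
  u <- axis / len
  v <- c(-u[2], u[1])
  rel_x <- contour$points[, 1] - mid[1]
  rel_y <- contour$points[, 2] - mid[2]
  list(s = rel_x * u[1] + rel_y * u[2],
       w = rel_x * v[1] + rel_y * v[2],
       length = len)
}

# Half chord width of the (closed) contour polygon at each fractional level
# of the view's own long-axis length.
.chord_semi_axes <- function(frame, frac) {
  s <- c(frame$s, frame$s[1L]) # close the polygon through the base
  w <- c(frame$w, frame$w[1L])
  ns <- length(s) - 1L
  vapply(frac * frame$length, function(si) {
    ws <- numeric(0)
    for (k in seq_len(ns)) {
      s1 <- s[k]; s2 <- s[k + 1L]
      if (s1 == si && s2 == si) {
        ws <- c(ws, w[k], w[k + 1L])
      } else if ((s1 - si) * (s2 - si) <= 0 && s1 != s2) {
        u <- (si - s1) / (s2 - s1)
        ws <- c(ws, w[k] + u * (w[k + 1L] - w[k]))
      }
    }
    if (length(ws) < 2L) return(0)
    (max(ws) - min(ws)) / 2
  }, numeric(1))
}

#' Biplane (modified Simpson) end-diastolic volume
#'
#' Sum of elliptical disc sub-volumes,
#' \deqn{EDV = \sum_i \pi a_i b_i h,}
#' with `h` the common disc height.
#'
#' @param d A [disc_stack()].
#' @return Volume in ml.
#' @examples
#' biplane_edv(disc_stack(cbind(rep(2, 30), rep(2, 30)), 8, 8)) # pi*4*8
#' @export
biplane_edv <- function(d) {
  stopifnot(inherits(d, "disc_stack"))
  sum(pi * d$semi_axes[, 1] * d$semi_axes[, 2] * d$disc_height_cm)
}

#' Biplane LV mass from endocardial and epicardial disc stacks
#'
#' The conventional fully delineated biplane mass: myocardial shell volume as
#' the difference of the epicardial and endocardial biplane volumes, times
#' myocardial density.
#'
#' @param endo,epi [disc_stack()] objects with matching disc counts.
#' @param density_g_per_ml Myocardial density, default 1.05 g/ml.
#' @return LV mass in g.
#' @export
bp_lvm <- function(endo, epi, density_g_per_ml = 1.05) {
  stopifnot(inherits(endo, "disc_stack"), inherits(epi, "disc_stack"))
  if (endo$n_discs != epi$n_discs) {
    abort_geometry("endocardial and epicardial stacks must have matching n_discs")
  }
  v_endo <- biplane_edv(endo)
  v_epi <- biplane_edv(epi)
  if (v_epi < v_endo) {
    abort_geometry(sprintf(
      "epicardial volume (%.2f ml) smaller than endocardial volume (%.2f ml)",
      v_epi, v_endo
    ))
  }
  density_g_per_ml * (v_epi - v_endo)
}
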