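#' Long-axis split at the short-axis plane
#'
#' The LV long axis partitioned by the short-axis imaging plane: `a_cm` from
#' the apex to the plane, `d_cm` from the plane to the mitral plane. Used by
#' the area-length and truncated-ellipsoid methods.
#'
#' @param a_cm Apex-to-short-axis-plane length (cm), `> 0`.
#' @param d_cm Short-axis-plane-to-mitral-plane length (cm), `>= 0`.
#' @return An object of class `long_axis_split`.
#' @export
long_axis_split <- function(a_cm, d_cm) {
  check_number(a_cm, "a_cm", min = 0, strict = TRUE)
  check_number(d_cm, "d_cm", min = 0)
  structure(list(a_cm = a_cm, d_cm = d_cm), class = "long_axis_split")
}

#' Mean wall thickness from short-axis areas
#'
#' Difference of the equivalent-circle radii of the epicardial and
#' endocardial traces:
#' \deqn{t = \sqrt{A_1/\pi} - \sqrt{A_2/\pi}}
#' Because the whole circumference contributes to each area, this estimate
#' averages local tracing errors, unlike single-chord caliper readings.
#'
#' @param s A [sax_trace()] object.
#' @return Mean wall thickness in cm (`>= 0`).
#' @examples
#' mean_wall_thickness(sax_trace(16 * pi, 9 * pi)) # 1
#' @export
mean_wall_thickness <- function(s) {
  stopifnot(inherits(s, "sax_trace"))
  sqrt(s$a1_cm2 / pi) - sqrt(s$a2_cm2 / pi)
}

#' Minor semi-axis from the endocardial short-axis area
#'
#' Equivalent-circle radius of the endocardial trace, \eqn{b = \sqrt{A_2/\pi}}.
#'
#' @param s A [sax_trace()] object.
#' @return Semi-axis in cm.
#' @export
minor_semi_axis <- function(s) {
  stopifnot(inherits(s, "sax_trace"))
  sqrt(s$a2_cm2 / pi)
}

#' Area-length left-ventricular mass
#'
#' \deqn{LVM = 1.05 \cdot \tfrac{5}{6} \cdot [A_1 (a + d + t) - A_2 (a + d)]}
#' with \eqn{t} the mean wall thickness from the same short-axis trace.
#'
#' @param s A [sax_trace()] object.
#' @param L A [long_axis_split()] object.
#' @return LV mass in g.
#' @examples
#' area_length_lvm(sax_trace(9 * pi, 4 * pi), long_axis_split(4, 4)) # 134.7 g
#' @export
area_length_lvm <- function(s, L) {
  stopifnot(inherits(s, "sax_trace"), inherits(L, "long_axis_split"))
  t_cm <- mean_wall_thickness(s)
  1.05 * (5 / 6) * (s$a1_cm2 * (L$a_cm + L$d_cm + t_cm) -
                      s$a2_cm2 * (L$a_cm + L$d_cm))
}

#' Truncated-ellipsoid left-ventricular mass
#'
#' Difference of two truncated prolate ellipsoids of revolution (epicardial
#' minus endocardial):
#' \deqn{LVM = 1.05\pi \left\{ (b+t)^2 \left[\tfrac{2}{3}(a+t) + d -
#'   \tfrac{d^3}{3(a+t)^2}\right] - b^2 \left[\tfrac{2}{3}a + d -
#'   \tfrac{d^3}{3a^2}\right] \right\}}
#' where \eqn{b} and \eqn{t} come from the short-axis trace. A truncation
#' below the equator (`d > a`) is geometrically unusual and accepted with a
#' warning.
#'
#' @inheritParams area_length_lvm
#' @return LV mass in g.
#' @examples
#' truncated_ellipsoid_lvm(sax_trace(9 * pi, 4 * pi), long_axis_split(4, 4))
#' @export
truncated_ellipsoid_lvm <- function(s, L) {
  stopifnot(inherits(s, "sax_trace"), inherits(L, "long_axis_split"))
  if (L$a_cm <= 0) abort_domain("a_cm must be > 0 for the truncated ellipsoid")
  if (L$d_cm > L$a_cm) {
    warning("d_cm > a_cm: short-axis plane truncates below the equator",
            call. = FALSE)
  }
  b <- minor_semi_axis(s)
  t_cm <- mean_wall_thickness(s)
  a <- L$a_cm
  d <- L$d_cm
  seg <- function(semi, long) semi^2 * (2 / 3 * long + d - d^3 / (3 * long^2))
  1.05 * pi * (seg(b + t_cm, a + t_cm) - seg(b, a))
}
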