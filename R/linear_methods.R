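#' Teichholz end-diastolic volume
#'
#' One-dimensional LV volume from the internal diameter alone:
#' \deqn{EDV = \frac{7.0}{2.4 + LVID} \cdot LVID^3}
#' with LVID in cm and EDV in ml. Strictly increasing in LVID.
#'
#' @param m A [linear_measurements()] object (only `lvid_cm` is used).
#' @return End-diastolic volume in ml.
#' @examples
#' teichholz_edv(linear_measurements(1.0, 4.5, 1.0)) # 92.45 ml
#' @export
teichholz_edv <- function(m) {
  stopifnot(inherits(m, "linear_measurements"))
  if (m$lvid_cm <= 0) abort_domain("lvid_cm must be > 0 for the Teichholz volume")
  7.0 / (2.4 + m$lvid_cm) * m$lvid_cm^3
}

#' Devereux cube-formula left-ventricular mass
#'
#' The guideline-standard linear-measurement mass estimate:
#' \deqn{LVM = 0.8 \cdot 1.04 \cdot [(IVS + LVID + PWT)^3 - LVID^3] + 0.6\,g}
#' All inputs in cm, result in g. Because wall thickness enters through a
#' cube, small caliper errors are strongly amplified: with LVID 4.5 cm,
#' reading both walls as 1.1 cm instead of 1.0 cm inflates the mass by 14%.
#'
#' @param m A [linear_measurements()] object.
#' @return LV mass in g (`>= 0.6`).
#' @examples
#' devereux_lvm(linear_measurements(1.0, 4.5, 1.0)) # 153.3 g
#' @export
devereux_lvm <- function(m) {
  stopifnot(inherits(m, "linear_measurements"))
  if (m$lvid_cm <= 0) abort_domain("lvid_cm must be > 0 for the cube formula")
  s <- m$ivs_cm + m$lvid_cm + m$pwt_cm
  0.8 * 1.04 * (s^3 - m$lvid_cm^3) + 0.6
}
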