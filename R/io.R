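#' Validate a raw measurement record
#'
#' Takes a parsed record (a plain list, typically from
#' [read_measurement_record()]) and either returns a typed
#' `measurement_record` or a structured table of violations. Units are
#' normalised to cm / cm^2 on the way in: a record may declare
#' `units = list(length = "mm", area = "mm2")` and is converted on read.
#'
#' A record holds any subset of the components `linear` (ivs, lvid, pwt),
#' `sax` (a1, a2, level), `long_axis` (a, d), `disc_stack` (a, b,
#' length_4ch, length_2ch) and `subject` (age_years, sex, bsa_m2), plus an
#' `id`. Each quantification method states which components it requires.
#'
#' @param record A named list as described above.
#' @return On success, a list of class `measurement_record` with typed
#'   components; on failure, a list with `valid = FALSE` and a `violations`
#'   data frame (`field`, `message`).
#' @export
validate_record <- function(record) {
  if (!is.list(record)) abort_validation("record must be a list")
  violations <- list()
  note <- function(field, message) {
    violations[[length(violations) + 1L]] <<- data.frame(
      field = field, message = message, stringsAsFactors = FALSE
    )
  }
  units <- record$units
  len_div <- switch(if (is.null(units$length)) "cm" else units$length,
                    cm = 1, mm = 10,
                    { note("units.length", "must be 'cm' or 'mm'"); 1 })
  area_div <- switch(if (is.null(units$area)) "cm2" else units$area,
                     cm2 = 1, mm2 = 100,
                     { note("units.area", "must be 'cm2' or 'mm2'"); 1 })
  grab <- function(component, field) {
    x <- record[[component]][[field]]
    if (is.null(x)) NA_real_ else as.numeric(x)
  }
  typed <- list(id = if (is.null(record$id)) NA_character_ else as.character(record$id))

  wrap <- function(field, expr) {
    tryCatch(expr, error = function(e) {
      note(field, conditionMessage(e))
      NULL
    })
  }
  if (!is.null(record$linear)) {
    typed$linear <- wrap("linear", linear_measurements(
      grab("linear", "ivs") / len_div,
      grab("linear", "lvid") / len_div,
      grab("linear", "pwt") / len_div
    ))
  }
  if (!is.null(record$sax)) {
    lev <- record$sax$level
    typed$sax <- wrap("sax", sax_trace(
      grab("sax", "a1") / area_div,
      grab("sax", "a2") / area_div,
      level = if (is.null(lev)) "chordae" else lev
    ))
  }
  if (!is.null(record$long_axis)) {
    typed$long_axis <- wrap("long_axis", long_axis_split(
      grab("long_axis", "a") / len_div,
      grab("long_axis", "d") / len_div
    ))
  }
  if (!is.null(record$disc_stack)) {
    typed$disc_stack <- wrap("disc_stack", {
      a <- as.numeric(record$disc_stack$a) / len_div
      b <- as.numeric(record$disc_stack$b) / len_div
      if (length(a) != length(b)) {
        abort_validation("disc_stack: a and b must have the same length")
      }
      disc_stack(cbind(a, b),
                 as.numeric(record$disc_stack$length_4ch) / len_div,
                 as.numeric(record$disc_stack$length_2ch) / len_div)
    })
  }
  if (!is.null(record$subject)) {
    typed$subject <- wrap("subject", subject(
      id = typed$id,
      age_years = grab("subject", "age_years"),
      sex = record$subject$sex,
      bsa_m2 = grab("subject", "bsa_m2")
    ))
  }
  if (length(violations) > 0L) {
    return(list(valid = FALSE, violations = do.call(rbind, violations)))
  }
  structure(typed, class = "measurement_record")
}

#' Read a measurement record from JSON
#'
#' @param path Path to a JSON record file (see [validate_record()] for the
#'   schema; `inst/extdata/example_record.json` ships a full example).
#' @return A typed `measurement_record`.
#' @export
read_measurement_record <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  typed <- validate_record(raw)
  if (!inherits(typed, "measurement_record")) {
    abort_validation(
      paste0("invalid measurement record: ",
             paste(typed$violations$field, typed$violations$message,
                   sep = ": ", collapse = "; ")),
      violations = typed$violations
    )
  }
  typed
}

# Canonical raw form (fixed key order, cm units) so that
# write -> read -> write is byte-identical.
.record_to_raw <- function(rec) {
  out <- list(id = rec$id, units = list(length = "cm", area = "cm2"))
  if (!is.null(rec$linear)) {
    out$linear <- list(ivs = rec$linear$ivs_cm, lvid = rec$linear$lvid_cm,
                       pwt = rec$linear$pwt_cm)
  }
  if (!is.null(rec$sax)) {
    out$sax <- list(a1 = rec$sax$a1_cm2, a2 = rec$sax$a2_cm2,
                    level = rec$sax$level)
  }
  if (!is.null(rec$long_axis)) {
    out$long_axis <- list(a = rec$long_axis$a_cm, d = rec$long_axis$d_cm)
  }
  if (!is.null(rec$disc_stack)) {
    out$disc_stack <- list(
      a = rec$disc_stack$semi_axes[, 1],
      b = rec$disc_stack$semi_axes[, 2],
      length_4ch = rec$disc_stack$length_4ch_cm,
      length_2ch = rec$disc_stack$length_2ch_cm
    )
  }
  if (!is.null(rec$subject)) {
    out$subject <- list(age_years = rec$subject$age_years,
                        sex = rec$subject$sex, bsa_m2 = rec$subject$bsa_m2)
  }
  out
}

#' Write a measurement record to JSON
#'
#' Writes the canonical (cm-unit, fixed key order) form, so a write-read-
#' write round trip is byte-identical.
#'
#' @param rec A typed `measurement_record` from [validate_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurement_record <- function(rec, path) {
  stopifnot(inherits(rec, "measurement_record"))
  jsonlite::write_json(.record_to_raw(rec), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Serialise / deserialise a disc stack as compact JSON
#'
#' Used to embed stacks in cohort CSV tables.
#'
#' @param d A [disc_stack()].
#' @return `disc_stack_to_json()`: a single JSON string;
#'   `disc_stack_from_json()`: a [disc_stack()].
#' @export
disc_stack_to_json <- function(d) {
  stopifnot(inherits(d, "disc_stack"))
  as.character(jsonlite::toJSON(
    list(a = d$semi_axes[, 1], b = d$semi_axes[, 2],
         length_4ch = d$length_4ch_cm, length_2ch = d$length_2ch_cm),
    auto_unbox = TRUE, digits = NA
  ))
}

#' @rdname disc_stack_to_json
#' @param json A JSON string produced by `disc_stack_to_json()`.
#' @export
disc_stack_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  disc_stack(cbind(x$a, x$b), x$length_4ch, x$length_2ch)
}

#' Read a planar contour from CSV
#'
#' The CSV has columns `role`, `x_cm`, `y_cm`; border vertices carry role
#' `"point"` (in order along the border) and the landmark rows carry roles
#' `"base_left"`, `"base_right"`, `"apex"`.
#'
#' @param path CSV path.
#' @return A [planar_contour()].
#' @export
read_contour_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("role", "x_cm", "y_cm")
  if (!all(need %in% names(df))) {
    abort_validation("contour CSV must have columns role, x_cm, y_cm")
  }
  pick <- function(role) {
    r <- df[df$role == role, c("x_cm", "y_cm")]
    if (nrow(r) == 0L) NULL else as.numeric(r[1L, ])
  }
  pts <- as.matrix(df[df$role == "point", c("x_cm", "y_cm")])
  planar_contour(pts, base_left = pick("base_left"),
                 base_right = pick("base_right"), apex = pick("apex"))
}

#' Write a planar contour to CSV
#'
#' @param contour A [planar_contour()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  stopifnot(inherits(contour, "planar_contour"))
  df <- rbind(
    data.frame(role = "base_left", x_cm = contour$base_left[1],
               y_cm = contour$base_left[2]),
    data.frame(role = "base_right", x_cm = contour$base_right[1],
               y_cm = contour$base_right[2]),
    data.frame(role = "apex", x_cm = contour$apex[1], y_cm = contour$apex[2]),
    data.frame(role = "point", x_cm = contour$points[, 1],
               y_cm = contour$points[, 2])
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
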