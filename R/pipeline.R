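.method_aliases <- c(
  novel = "NOVEL", bp = "BP", te = "TE", al = "AL", dev = "DEV",
  teichholz = "TEICHHOLZ_EDV", biplane_edv = "BIPLANE_EDV"
)

.normalize_method <- function(method) {
  m <- tolower(method)
  if (m %in% names(.method_aliases)) return(unname(.method_aliases[m]))
  if (toupper(method) %in% .method_ids) return(toupper(method))
  abort_config(sprintf(
    "unknown method '%s' (use one of %s)", method,
    paste(names(.method_aliases), collapse = ", ")
  ))
}

.require_component <- function(rec, component, method) {
  if (is.null(rec[[component]])) {
    abort_validation(sprintf(
      "method %s requires record component '%s', which is missing", method,
      component
    ))
  }
  rec[[component]]
}

#' Run one quantification method on a measurement record
#'
#' Dispatches to the requested method, checking that the record carries the
#' components the method needs and naming the missing component otherwise.
#'
#' @param record A typed `measurement_record` (from
#'   [read_measurement_record()] / [validate_record()]) or a path to a JSON
#'   record file.
#' @param method Method name: `"novel"`, `"bp"`, `"te"`, `"al"`, `"dev"`,
#'   `"teichholz"` or `"biplane_edv"` (case-insensitive; canonical ids
#'   accepted).
#' @param config A [novel_config()]; used by the disc-expansion method and
#'   for the myocardial density of the biplane mass.
#' @param epi_record Optional second record (or path) carrying the
#'   epicardial `disc_stack` for method `"bp"`.
#' @return A [method_result()].
#' @examples
#' f <- system.file("extdata", "example_record.json", package = "echolvm")
#' run_quantify(f, "dev")
#' @export
run_quantify <- function(record, method, config = novel_config(),
                         epi_record = NULL) {
  if (is.character(record)) record <- read_measurement_record(record)
  stopifnot(inherits(record, "measurement_record"))
  method <- .normalize_method(method)
  subj <- record$subject
  switch(method,
    DEV = {
      m <- .require_component(record, "linear", method)
      method_result("DEV", lvm_g = devereux_lvm(m), subject = subj)
    },
    TEICHHOLZ_EDV = {
      m <- .require_component(record, "linear", method)
      method_result("TEICHHOLZ_EDV", edv_ml = teichholz_edv(m), subject = subj)
    },
    AL = {
      s <- .require_component(record, "sax", method)
      L <- .require_component(record, "long_axis", method)
      method_result("AL", lvm_g = area_length_lvm(s, L), subject = subj)
    },
    TE = {
      s <- .require_component(record, "sax", method)
      L <- .require_component(record, "long_axis", method)
      method_result("TE", lvm_g = truncated_ellipsoid_lvm(s, L), subject = subj)
    },
    BIPLANE_EDV = {
      d <- .require_component(record, "disc_stack", method)
      method_result("BIPLANE_EDV", edv_ml = biplane_edv(d), subject = subj)
    },
    NOVEL = {
      d <- .require_component(record, "disc_stack", method)
      s <- .require_component(record, "sax", method)
      novel_lvm(d, s, cfg = config, subj = subj)
    },
    BP = {
      d <- .require_component(record, "disc_stack", method)
      if (is.character(epi_record)) epi_record <- read_measurement_record(epi_record)
      if (is.null(epi_record) || is.null(epi_record$disc_stack)) {
        abort_validation("method BP requires an epi_record with a 'disc_stack' component")
      }
      method_result(
        "BP",
        lvm_g = bp_lvm(d, epi_record$disc_stack,
                       density_g_per_ml = config$density_g_per_ml),
        subject = subj
      )
    }
  )
}

.pipeline_methods <- c("novel", "dev", "teichholz", "al", "te", "biplane_edv")

.row_result <- function(row, method, config) {
  method_id <- .normalize_method(method)
  stack <- function() disc_stack_from_json(row$stack_json)
  lin <- function() linear_measurements(row$ivs_cm, row$lvid_cm, row$pwt_cm)
  sax <- function() sax_trace(row$a1_cm2, row$a2_cm2, level = row$sax_level)
  lax <- function() long_axis_split(row$a_cm, row$d_cm)
  switch(method_id,
    NOVEL = novel_lvm(stack(), sax(), cfg = config),
    DEV = method_result("DEV", lvm_g = devereux_lvm(lin())),
    TEICHHOLZ_EDV = method_result("TEICHHOLZ_EDV", edv_ml = teichholz_edv(lin())),
    AL = method_result("AL", lvm_g = area_length_lvm(sax(), lax())),
    TE = method_result("TE", lvm_g = truncated_ellipsoid_lvm(sax(), lax())),
    BIPLANE_EDV = method_result("BIPLANE_EDV", edv_ml = biplane_edv(stack())),
    abort_config(sprintf("method '%s' is not available on cohort tables", method))
  )
}

#' Run methods and agreement statistics over a cohort table
#'
#' Applies each requested method to every row of a cohort table (as produced
#' by [simulate_cohort()], or user data in the same layout), joins the
#' analytic truth columns when present, and computes pairwise agreement
#' statistics of each mass method against the truth. Malformed rows are
#' skipped with a logged count. The fully delineated biplane mass (`bp`)
#' needs an epicardial stack and is not available on cohort tables.
#'
#' @param cohort A data frame or path to a cohort CSV.
#' @param methods Character vector from `novel`, `dev`, `teichholz`, `al`,
#'   `te`, `biplane_edv`.
#' @param stats Agreement statistics to compute against `truth_lvm_g`, any
#'   of `"ba"`, `"cv"`, `"icc"`.
#' @param config A [novel_config()].
#' @return A list of class `pipeline_report` with `results` (long data
#'   frame: one row per cohort row per method) and `agreement` (one row per
#'   mass method, when truth columns and >= 2 rows are available).
#' @export
run_pipeline <- function(cohort, methods = c("novel", "dev"),
                         stats = c("ba", "cv", "icc"),
                         config = novel_config()) {
  if (is.character(cohort)) {
    cohort <- utils::read.csv(cohort, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    abort_validation("cohort is empty")
  }
  stats <- match.arg(stats, c("ba", "cv", "icc"), several.ok = TRUE)
  methods <- vapply(methods, function(m) {
    if (!tolower(m) %in% .pipeline_methods) {
      abort_config(sprintf("method '%s' is not available on cohort tables", m))
    }
    tolower(m)
  }, character(1))

  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    for (m in methods) {
      res <- tryCatch(.row_result(row, m, config), error = function(e) e)
      if (inherits(res, "error")) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = if ("subject_id" %in% names(row)) row$subject_id else NA,
        session = if ("session" %in% names(row)) row$session else NA,
        shape = if ("shape" %in% names(row)) row$shape else NA,
        method = res$method,
        lvm_g = res$lvm_g,
        edv_ml = res$edv_ml,
        truth_lvm_g = if ("truth_lvm_g" %in% names(row)) row$truth_lvm_g else NA,
        truth_edv_ml = if ("truth_edv_ml" %in% names(row)) row$truth_edv_ml else NA,
        stringsAsFactors = FALSE
      )
    }
  }
  if (skipped > 0L) {
    message(sprintf("run_pipeline: skipped %d malformed row-method evaluations",
                    skipped))
  }
  if (length(rows) == 0L) abort_validation("no method results could be computed")
  results <- do.call(rbind, rows)

  agreement <- NULL
  mass_rows <- results[!is.na(results$lvm_g) & !is.na(results$truth_lvm_g), ]
  if (nrow(mass_rows) >= 2L) {
    agr <- lapply(split(mass_rows, mass_rows$method), function(g) {
      if (nrow(g) < 2L) return(NULL)
      p <- paired_series(g$truth_lvm_g, g$lvm_g, "truth", g$method[1])
      out <- data.frame(method = g$method[1], n = nrow(g),
                        stringsAsFactors = FALSE)
      if ("ba" %in% stats) {
        ba <- bland_altman(p)
        out$bias <- ba$bias
        out$loa_low <- ba$loa_low
        out$loa_high <- ba$loa_high
      }
      if ("cv" %in% stats) out$cv_percent <- cv_percent(p)$cv_percent
      if ("icc" %in% stats && nrow(g) >= 3L) out$icc <- icc(p)$value
      out
    })
    agr <- agr[!vapply(agr, is.null, logical(1))]
    if (length(agr) > 0L) {
      cols <- unique(unlist(lapply(agr, names)))
      agreement <- do.call(rbind, lapply(agr, function(d) {
        d[setdiff(cols, names(d))] <- NA
        d[cols]
      }))
      rownames(agreement) <- NULL
    }
  }
  structure(list(results = results, agreement = agreement),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d method results\n", nrow(x$results)))
  if (!is.null(x$agreement)) {
    cat("agreement vs analytic truth:\n")
    print(x$agreement, digits = 4)
  }
  invisible(x)
}
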