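# Classed conditions so callers (and the CLI) can distinguish bad input
# values (domain), malformed records (validation), impossible geometry, and
# misconfiguration. All inherit from "echolvm_error".

abort_echolvm <- function(message, class, ...) {
  stop(structure(
    class = c(class, "echolvm_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

abort_domain <- function(message, ...) {
  abort_echolvm(message, "echolvm_domain_error", ...)
}

abort_validation <- function(message, violations = NULL) {
  abort_echolvm(message, "echolvm_validation_error", violations = violations)
}

abort_geometry <- function(message, ...) {
  abort_echolvm(message, "echolvm_geometry_error", ...)
}

abort_config <- function(message, ...) {
  abort_echolvm(message, "echolvm_config_error", ...)
}

check_number <- function(x, name, min = NULL, strict = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_domain(sprintf("`%s` must be a single non-missing number", name))
  }
  if (finite && !is.finite(x)) {
    abort_domain(sprintf("`%s` must be finite", name))
  }
  if (!is.null(min)) {
    ok <- if (strict) x > min else x >= min
    if (!ok) {
      abort_domain(sprintf(
        "`%s` must be %s %g (got %g)", name, if (strict) ">" else ">=", min, x
      ))
    }
  }
  invisible(x)
}
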