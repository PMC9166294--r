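# Structured condition classes used across the package.  Every error raised by
# pathflow carries the class "pathflow_error" plus a subclass naming the
# failure mode, so callers (and the command-line wrapper) can map failures to
# exit codes without parsing messages.

pf_error <- function(subclass, message, ..., call. = FALSE) {
  stop(errorCondition(
    message,
    ...,
    class = c(paste0("pathflow_", subclass), "pathflow_error")
  ))
}

#' Map a pathflow condition to a command-line exit code
#'
#' Exit-code contract: 0 success, 2 configuration error, 3 input error,
#' 4 numerical error.
#'
#' @param cond A condition object.
#' @return Integer exit code.
#' @keywords internal
pf_exit_code <- function(cond) {
  cls <- class(cond)
  if (any(c("pathflow_config_error", "pathflow_usage_error",
            "pathflow_spec_error") %in% cls)) return(2L)
  if (any(c("pathflow_format_error", "pathflow_input_error",
            "pathflow_topology_mismatch_error", "pathflow_empty_input_error",
            "pathflow_resolution_error", "pathflow_lookup_error",
            "pathflow_integrity_error", "pathflow_ambiguity_error") %in% cls))
    return(3L)
  if (any(c("pathflow_numerical_error", "pathflow_connectivity_error",
            "pathflow_geometry_error", "pathflow_range_error",
            "pathflow_degenerate_input_error") %in% cls)) return(4L)
  1L
}

# Parse a length given either as a bare number (interpreted as Angstrom) or a
# string with an "nm"/"A"/"Angstrom" suffix; returns Angstrom.  The package
# works internally in Angstrom throughout.
parse_length <- function(x, what = "length") {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1L)
    pf_error("config_error", sprintf("cannot parse %s: %s", what,
                                     deparse(substitute(x))))
  s <- trimws(x)
  m <- regmatches(s, regexec("^([-0-9.eE+]+)\\s*([A-Za-zÅÅ]*)$", s))[[1]]
  if (length(m) == 0L || is.na(suppressWarnings(as.numeric(m[2]))))
    pf_error("config_error", sprintf("cannot parse %s value '%s'", what, x))
  val <- as.numeric(m[2])
  unit <- tolower(m[3])
  if (unit %in% c("", "a", "å", "angstrom", "ang", "Å")) {
    val
  } else if (unit == "nm") {
    # shift the decimal point textually so "0.45 nm" parses to the same
    # double as the literal 4.5 (bit-identical unit handling)
    num <- m[2]
    if (grepl("^[0-9]*\\.?[0-9]+$", num)) {
      if (!grepl(".", num, fixed = TRUE)) num <- paste0(num, ".")
      dot <- regexpr(".", num, fixed = TRUE)
      digits <- paste0(sub(".", "", num, fixed = TRUE), "0")
      as.numeric(paste0(substr(digits, 1, dot), ".",
                        substr(digits, dot + 1, nchar(digits))))
    } else {
      val * 10
    }
  } else {
    pf_error("config_error",
             sprintf("unknown length unit '%s' in %s '%s'", m[3], what, x))
  }
}
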