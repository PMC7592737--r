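# Classed conditions so callers (and the command-line wrapper) can tell
# configuration mistakes apart from data problems.
abort_config <- function(msg) rlang::abort(msg, class = "betledger_config_error")
abort_domain <- function(msg) rlang::abort(msg, class = "betledger_domain_error")
abort_schema <- function(msg) rlang::abort(msg, class = "betledger_schema_error")
abort_integrity <- function(msg) rlang::abort(msg, class = "betledger_integrity_error")
abort_ordering <- function(msg) rlang::abort(msg, class = "betledger_ordering_error")

`%||%` <- function(x, y) if (is.null(x)) y else x

# UTC calendar date of a POSIXct instant; all "day" logic in the package
# uses UTC midnights (block timestamps are UTC).
utc_date <- function(time) as.Date(time, tz = "UTC")

as_utc_time <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC", origin = "1970-01-01")
}

format_utc <- function(time) format(time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_config(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  invisible(x)
}

# Derive a valid 32-bit seed from a base seed and stream indices.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) s <- (s * 48271 + as.double(i)) %% 2147483647
  as.integer(s)
}
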