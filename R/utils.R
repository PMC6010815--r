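#' Round half away from zero
#'
#' Reported RI values are conventionally rounded half-up (0.125 -> 0.13,
#' -0.125 -> -0.13), unlike [base::round()] which rounds half to even.
#' Used only when rendering reports; all internal arithmetic keeps full
#' precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.125, 2)  # 0.13
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Internal: stop with a consistent error class so callers can test on it.
ib_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "isobarrier_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Internal: coerce to Date, erroring informatively on failure.
ib_as_date <- function(x, what = "date") {
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(out)) {
    ib_stop(sprintf("could not parse %s as ISO-8601 date: %s",
                    what, paste(utils::head(x, 3), collapse = ", ")),
            "isobarrier_invalid_input")
  }
  out
}
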