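#' @keywords internal
"_PACKAGE"

# Timestamps are ISO-8601 at minute resolution in files; in memory they are
# POSIXct (UTC). All interval arithmetic is done in hours as doubles.

.TS_FORMATS <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M",
                 "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")

#' Parse ISO-8601 timestamps
#'
#' Accepts `YYYY-mm-ddTHH:MM[:SS]` (or a space separator) and bare dates;
#' returns POSIXct in UTC. Unparseable non-missing strings become `NA` and
#' are reported by the caller's validation.
#'
#' @param x character vector.
#' @return POSIXct vector (UTC).
#' @keywords internal
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  todo <- !is.na(x) & nzchar(x)
  for (fmt in .TS_FORMATS) {
    if (!any(todo)) break
    p <- as.POSIXct(x[todo], format = fmt, tz = "UTC")
    ok <- !is.na(p)
    idx <- which(todo)[ok]
    out[idx] <- p[ok]
    todo[idx] <- FALSE
  }
  out
}

#' Format timestamps for file output (minute resolution)
#' @keywords internal
format_timestamp <- function(x) {
  ifelse(is.na(x), "", format(x, "%Y-%m-%dT%H:%M", tz = "UTC"))
}

#' Hours elapsed between two timestamps
#' @keywords internal
hours_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "hours"))
}

#' Round half away from zero
#'
#' Report-style rounding (5 always rounds up in magnitude), as opposed to
#' IEEE banker's rounding used by [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)    # 1
#' round_half_up(2.5)    # 3 (base::round gives 2)
#' round_half_up(0.4965, 3)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
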