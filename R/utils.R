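# internal assertion/coercion helpers

np_stop <- function(...) abort(paste0(...), class = "nektonpulse_error")

np_assert <- function(cond, ...) {
  if (!isTRUE(cond)) np_stop(...)
  invisible(TRUE)
}

# parse character timestamps as UTC, pass POSIXct through untouched
as_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC")
  np_assert(!anyNA(out), "could not parse timestamps: ", paste(head(x[is.na(out)]), collapse = ", "))
  out
}

time_zone <- function(t) {
  tz <- attr(t, "tzone")
  if (is.null(tz) || !nzchar(tz[1])) "UTC" else tz[1]
}

# calendar day in the series' own time zone
calendar_day <- function(t) as.Date(t, tz = time_zone(t))

# standard error of the mean; NA for a single value
se_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  np_assert(length(missing) == 0,
            what, " is missing column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}
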