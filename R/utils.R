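# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_conedea <- function(fmt, ..., class = "conedea_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# "YYYY-MM" -> Date of first day
month_start <- function(month) {
  d <- as.Date(paste0(month, "-01"))
  if (anyNA(d)) stop_conedea("malformed month string (expected YYYY-MM): %s",
                             paste(month[is.na(d)], collapse = ", "))
  d
}

month_seq <- function(start_month, n_months) {
  format(seq(month_start(start_month), by = "month", length.out = n_months),
         "%Y-%m")
}

days_in_month <- function(month) {
  s <- month_start(month)
  as.integer(seq(s, by = "month", length.out = 2)[2] - s)
}

# ISO-8601 timestamps at minute precision, always UTC.
format_ts <- function(x) format(x, "%Y-%m-%dT%H:%M", tz = "UTC")

parse_ts <- function(x, what = "timestamp") {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop_conedea("malformed %s at row(s) %s (expected YYYY-MM-DDTHH:MM): %s",
                 what, paste(utils::head(bad, 5), collapse = ", "),
                 x[bad[1]])
  }
  out
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_conedea("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

# Moore-Penrose pseudoinverse via SVD (used for degenerate Gram systems).
pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
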