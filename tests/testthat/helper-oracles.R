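# Shared fixtures and independent oracles for the test suite.

# small synthetic fleet used across modules (fast to simulate)
tiny_fleet <- function(n_devices = 3, n_months = 3, seed = 11,
                       multipliers = NULL) {
  if (is.null(multipliers)) {
    multipliers <- stats::setNames(rep(1, n_devices),
                                   LETTERS[seq_len(n_devices)])
  }
  simulate_fleet(fleet_config(
    n_devices = n_devices, n_months = n_months, seed = seed,
    exams_per_day = 10, efficiency_multipliers = multipliers
  ))
}

# hand-built event table: one device-month with explicit timestamps
ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M", tz = "UTC")

events_row <- function(device = "A", booked, started, finished, report,
                       revenue = 100) {
  data.frame(device_id = device, booked_at = ts(booked), started_at = ts(started),
             finished_at = ts(finished), report_at = ts(report),
             revenue = revenue, stringsAsFactors = FALSE)
}

cost_row <- function(device = "A", month = "2022-01", operating_cost = 1000,
                     depreciation = 200, energized_minutes = 1800) {
  data.frame(device_id = device, month = month, operating_cost = operating_cost,
             depreciation = depreciation, energized_minutes = energized_minutes,
             stringsAsFactors = FALSE)
}

# Brute-force CCR oracle for m + s <= 3: exhaustive grid over the single
# free multiplier direction on the side with two indicators; the other
# side's optimum is closed-form given the direction.
brute_ccr <- function(X, Y, j0, npts = 4001) {
  m <- nrow(X); s <- nrow(Y)
  stopifnot(m + s <= 3)
  best <- 0
  if (m == 1) {
    w <- 1 / X[1, j0]
    wx <- w * X[1, ]
    if (s == 1) {
      mu <- min(wx / Y[1, ])
      return(mu * Y[1, j0])
    }
    for (a in seq(0, 1, length.out = npts)) {
      md <- c(a, 1 - a)
      den <- as.numeric(md %*% Y)
      if (all(den <= 0)) next
      beta <- min(wx[den > 0] / den[den > 0])
      if (any(den <= 0) && any(den > 1e-12)) next
      best <- max(best, beta * sum(md * Y[, j0]))
    }
  } else {
    # m == 2, s == 1
    for (a in seq(0, 1, length.out = npts)) {
      wd <- c(a, 1 - a)
      sc <- sum(wd * X[, j0])
      if (sc <= 0) next
      w <- wd / sc
      wx <- as.numeric(w %*% X)
      mu <- min(wx / Y[1, ])
      best <- max(best, mu * Y[1, j0])
    }
  }
  best
}

# Closed-form cone-constrained score: the consistent ratio-matrix cone pins
# each multiplier vector to the ray of its generator, so the score is the
# weighted output/input ratio normalized by the frontier maximum.
cone_closed_form <- function(X, Y, j0, w_in, w_out) {
  ratio <- as.numeric(w_out %*% Y) / as.numeric(w_in %*% X)
  ratio[j0] / max(ratio)
}

rand_instance <- function(n, m, s) {
  list(X = matrix(runif(m * n, 1, 10), m, n),
       Y = matrix(runif(s * n, 1, 10), s, n))
}
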