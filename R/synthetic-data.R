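#' Configure a synthetic MRI fleet
#'
#' Builds the configuration object consumed by [simulate_fleet()]. The
#' defaults describe a four-scanner MRI service observed for 24 months, with
#' one scanner (the first) planted as systematically more efficient: a higher
#' sweep speed translates into more examinations per day, shorter scan
#' durations and shorter patient waits, while tariffs and the cost base are
#' left untouched.
#'
#' The `efficiency_multipliers` vector (one entry per device, names become
#' device ids) scales examinations/day up and scan duration plus both waiting
#' times down. At most one device may carry a multiplier above 1 (the
#' "high-efficiency" device).
#'
#' @param n_devices number of scanners in the fleet.
#' @param n_months number of calendar months simulated.
#' @param start_month first month, as `"YYYY-MM"`.
#' @param exams_per_day mean examinations per device per day (a busy service
#'   always performs at least one exam a day).
#' @param exam_duration_min,exam_duration_sd mean and sd of the scan duration
#'   in minutes (truncated below at 5 minutes).
#' @param prep_min fixed preparation time between exams, minutes.
#' @param appointment_lead_mean_min,appointment_lead_shape mean (minutes) and
#'   gamma shape of the appointment-to-scan waiting time.
#' @param report_delay_mean_min,report_delay_shape mean (minutes) and gamma
#'   shape of the scan-to-report delay.
#' @param tariff revenue per examination (currency units).
#' @param operating_cost_base,operating_cost_sdlog monthly operating-cost base
#'   and the sdlog of its lognormal month-to-month noise.
#' @param depreciation monthly straight-line depreciation charge.
#' @param energized_min_per_day minutes per day the scanner is energized.
#' @param efficiency_multipliers named positive vector, one per device;
#'   values > 1 mark the single high-efficiency device.
#' @param seed integer seed; all randomness in [simulate_fleet()] flows from
#'   this single seed.
#' @return an object of class `fleet_config`.
#' @seealso [simulate_fleet()]
#' @examples
#' cfg <- fleet_config(n_devices = 2, n_months = 3, seed = 1,
#'                     efficiency_multipliers = c(A = 1.3, B = 1))
#' fleet <- simulate_fleet(cfg)
#' head(fleet$events)
#' @export
fleet_config <- function(n_devices = 4,
                         n_months = 24,
                         start_month = "2021-01",
                         exams_per_day = 25,
                         exam_duration_min = 28,
                         exam_duration_sd = 6,
                         prep_min = 2,
                         appointment_lead_mean_min = 1440,
                         appointment_lead_shape = 2,
                         report_delay_mean_min = 720,
                         report_delay_shape = 2,
                         tariff = 600,
                         operating_cost_base = 150000,
                         operating_cost_sdlog = 0.08,
                         depreciation = 120000,
                         energized_min_per_day = 960,
                         efficiency_multipliers = NULL,
                         seed = 42) {
  if (is.null(efficiency_multipliers)) {
    efficiency_multipliers <- stats::setNames(
      c(1.3, rep(1, max(0L, n_devices - 1L))),
      LETTERS[seq_len(n_devices)]
    )[seq_len(n_devices)]
  }
  cfg <- list(
    n_devices = as.integer(n_devices), n_months = as.integer(n_months),
    start_month = start_month,
    exams_per_day = exams_per_day,
    exam_duration_min = exam_duration_min, exam_duration_sd = exam_duration_sd,
    prep_min = prep_min,
    appointment_lead_mean_min = appointment_lead_mean_min,
    appointment_lead_shape = appointment_lead_shape,
    report_delay_mean_min = report_delay_mean_min,
    report_delay_shape = report_delay_shape,
    tariff = tariff,
    operating_cost_base = operating_cost_base,
    operating_cost_sdlog = operating_cost_sdlog,
    depreciation = depreciation,
    energized_min_per_day = energized_min_per_day,
    efficiency_multipliers = efficiency_multipliers,
    seed = as.integer(seed)
  )
  validate_fleet_config(cfg)
  class(cfg) <- "fleet_config"
  cfg
}

validate_fleet_config <- function(cfg) {
  if (cfg$n_devices < 1L) stop_conedea("n_devices must be >= 1")
  if (cfg$n_months < 1L) stop_conedea("n_months must be >= 1 (zero months would yield no data)")
  if (cfg$exams_per_day < 1) stop_conedea("exams_per_day must be >= 1 (zero exams/day is a configuration error)")
  pos <- c("exam_duration_min", "exam_duration_sd", "appointment_lead_mean_min",
           "appointment_lead_shape", "report_delay_mean_min", "report_delay_shape",
           "tariff", "operating_cost_base", "energized_min_per_day")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] <= 0) stop_conedea("%s must be > 0", p)
  }
  if (cfg$prep_min < 0) stop_conedea("prep_min must be >= 0")
  if (cfg$depreciation < 0) stop_conedea("depreciation must be >= 0")
  m <- cfg$efficiency_multipliers
  if (length(m) != cfg$n_devices) {
    stop_conedea("efficiency_multipliers must have one entry per device (%d != %d)",
                 length(m), cfg$n_devices)
  }
  if (any(m <= 0)) stop_conedea("efficiency multipliers must be > 0")
  if (sum(m > 1) > 1) {
    stop_conedea("at most one device may be flagged high-efficiency (multiplier > 1); found %d",
                 sum(m > 1))
  }
  if (is.null(names(m)) || anyDuplicated(names(m))) {
    stop_conedea("efficiency_multipliers must carry unique device names")
  }
  month_start(cfg$start_month)
  invisible(cfg)
}

#' Simulate examination event logs and cost records for an MRI fleet
#'
#' Generates a seeded synthetic dataset: one examination event log (booking,
#' scan start/end, report-ready timestamps and per-exam revenue) and one
#' device-month cost table (operating cost, depreciation, energized minutes).
#' The output is a pure function of the configuration, including its seed.
#'
#' Daily exam counts are `1 + Poisson(mean - 1)` (at least one exam per open
#' day), scan durations are truncated normal, appointment leads and report
#' delays are gamma, and the monthly operating cost is the configured base
#' scaled by lognormal noise. Exams on one device never overlap: scans are
#' scheduled sequentially from 08:00 with the configured preparation gap.
#'
#' @param config a [fleet_config()] object.
#' @return a list with elements `events` (data.frame: `device_id`,
#'   `booked_at`, `started_at`, `finished_at`, `report_at` as POSIXct UTC,
#'   `revenue`) and `costs` (data.frame: `device_id`, `month`,
#'   `operating_cost`, `depreciation`, `energized_minutes`), plus the
#'   generating `config`.
#' @examples
#' fleet <- simulate_fleet(fleet_config(n_devices = 2, n_months = 2, seed = 7,
#'                                      efficiency_multipliers = c(A = 1, B = 1)))
#' nrow(fleet$costs)  # one row per device-month
#' @export
simulate_fleet <- function(config) {
  if (!inherits(config, "fleet_config")) {
    stop_conedea("config must be created by fleet_config()")
  }
  validate_fleet_config(config)
  set.seed(config$seed)

  months <- month_seq(config$start_month, config$n_months)
  devices <- names(config$efficiency_multipliers)
  ev <- vector("list", length(devices) * length(months))
  co <- vector("list", length(devices) * length(months))
  k <- 0L

  for (d in seq_along(devices)) {
    mult <- config$efficiency_multipliers[[d]]
    lam <- config$exams_per_day * mult
    dur_mean <- config$exam_duration_min / mult
    dur_sd <- config$exam_duration_sd / mult
    lead_mean <- config$appointment_lead_mean_min / mult
    delay_mean <- config$report_delay_mean_min / mult

    for (m in seq_along(months)) {
      ndays <- days_in_month(months[m])
      day0 <- month_start(months[m])
      n_day <- 1L + stats::rpois(ndays, max(lam - 1, 0))
      n_tot <- sum(n_day)

      dur <- pmax(stats::rnorm(n_tot, dur_mean, dur_sd), 5)
      lead <- stats::rgamma(n_tot, shape = config$appointment_lead_shape,
                            scale = lead_mean / config$appointment_lead_shape)
      delay <- stats::rgamma(n_tot, shape = config$report_delay_shape,
                             scale = delay_mean / config$report_delay_shape)

      day_idx <- rep(seq_len(ndays), n_day)
      # sequential schedule from 08:00, prep gap between consecutive exams
      start_min <- numeric(n_tot)
      i <- 1L
      for (day in seq_len(ndays)) {
        nd <- n_day[day]
        if (nd == 0L) next
        idx <- i:(i + nd - 1L)
        starts <- 8 * 60 + cumsum(c(0, dur[idx[-nd]] + config$prep_min))
        start_min[idx] <- (day - 1) * 1440 + starts
        i <- i + nd
      }

      started <- as.POSIXct(day0, tz = "UTC") + round(start_min) * 60
      finished <- started + round(pmax(dur, 1)) * 60
      booked <- started - round(lead) * 60
      report <- finished + round(delay) * 60

      k <- k + 1L
      ev[[k]] <- data.frame(
        device_id = devices[d],
        booked_at = booked, started_at = started,
        finished_at = finished, report_at = report,
        revenue = rep(config$tariff, n_tot),
        stringsAsFactors = FALSE
      )
      busy <- sum(as.numeric(finished - started, units = "mins"))
      energized <- max(ndays * config$energized_min_per_day, busy * 1.05)
      co[[k]] <- data.frame(
        device_id = devices[d], month = months[m],
        operating_cost = config$operating_cost_base *
          stats::rlnorm(1, 0, config$operating_cost_sdlog),
        depreciation = config$depreciation,
        energized_minutes = energized,
        stringsAsFactors = FALSE
      )
    }
  }

  events <- do.call(rbind, ev[seq_len(k)])
  events <- events[order(events$device_id, events$started_at), , drop = FALSE]
  rownames(events) <- NULL
  costs <- do.call(rbind, co[seq_len(k)])
  rownames(costs) <- NULL
  list(events = events, costs = costs, config = config)
}

#' @export
print.fleet_config <- function(x, ...) {
  cat("Synthetic MRI fleet configuration\n")
  cat(sprintf("  %d device(s) x %d month(s) from %s, seed %d\n",
              x$n_devices, x$n_months, x$start_month, x$seed))
  cat(sprintf("  exams/day %.1f, scan %.0f'+/-%.0f', tariff %.0f\n",
              x$exams_per_day, x$exam_duration_min, x$exam_duration_sd,
              x$tariff))
  hi <- names(x$efficiency_multipliers)[x$efficiency_multipliers > 1]
  if (length(hi)) {
    cat(sprintf("  high-efficiency device: %s (x%.2f)\n", hi,
                x$efficiency_multipliers[[hi]]))
  }
  invisible(x)
}
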