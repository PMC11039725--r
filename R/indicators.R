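#' Eight-indicator device-month panel
#'
#' Aggregates an examination event log and a device-month cost table into the
#' operational indicator panel used for efficiency scoring. Per device-month
#' (a decision-making unit) the panel holds four input indicators
#' (X1 utilization rate, X2 average daily working hours, X3 operating cost,
#' X4 average cost per inspection) and four output indicators (X5 inspection
#' revenue, X6 mean appointment wait, X7 cost-benefit ratio, X8 mean report
#' wait):
#'
#' * `X1 = (tau + prep) * n / energized_minutes`, with `tau` the mean scan
#'   duration in minutes and `prep` the fixed preparation time (2 minutes by
#'   default), a dimensionless load ratio;
#' * `X2` = total scan hours / calendar days in the month (hours/day);
#' * `X3` = monthly operating cost;
#' * `X4` = (operating cost + depreciation) / number of exams;
#' * `X5` = total revenue; `X6` = mean booking-to-scan wait (minutes);
#' * `X7` = X5 / X3; `X8` = mean scan-end-to-report wait (minutes).
#'
#' Device-months with zero exams are dropped with a warning (efficiency
#' scoring requires strictly positive inputs).
#'
#' @param events examination events, as produced by [simulate_fleet()] or
#'   [read_events()].
#' @param costs device-month cost table.
#' @param prep_min preparation minutes added to the mean scan duration in X1.
#' @return a data.frame with columns `device_id`, `month`, `X1`..`X8`,
#'   `n_exams`, one row per device-month.
#' @examples
#' fleet <- simulate_fleet(fleet_config(n_devices = 2, n_months = 2, seed = 1,
#'                                      efficiency_multipliers = c(A = 1, B = 1)))
#' panel <- monthly_panel(fleet$events, fleet$costs)
#' panel[, c("device_id", "month", "X1", "X5", "X7")]
#' @export
monthly_panel <- function(events, costs, prep_min = 2) {
  assert_columns(events, c("device_id", "booked_at", "started_at",
                           "finished_at", "report_at", "revenue"), "events")
  assert_columns(costs, c("device_id", "month", "operating_cost",
                          "depreciation", "energized_minutes"), "costs")
  ev_month <- format(events$started_at, "%Y-%m", tz = "UTC")
  ev_key <- paste(events$device_id, ev_month)
  cost_key <- paste(costs$device_id, costs$month)

  orphan <- setdiff(unique(ev_key), cost_key)
  if (length(orphan)) {
    stop_conedea("no cost row for device-month(s): %s",
                 paste(orphan, collapse = ", "))
  }

  rows <- vector("list", nrow(costs))
  dropped <- character()
  for (i in seq_len(nrow(costs))) {
    sel <- ev_key == cost_key[i]
    if (!any(sel)) {
      dropped <- c(dropped, cost_key[i])
      next
    }
    rows[[i]] <- device_month_indicators(
      events[sel, , drop = FALSE], costs[i, , drop = FALSE], prep_min
    )
  }
  if (length(dropped)) {
    warning(sprintf("dropping %d device-month(s) with zero exams: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop_conedea("no device-month has any exams")
  out <- out[order(out$device_id, out$month), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# one device-month; `ev` already filtered, `cost` a single row
device_month_indicators <- function(ev, cost, prep_min) {
  n <- nrow(ev)
  if (cost$energized_minutes <= 0) {
    stop_conedea("energized_minutes must be > 0 for %s %s",
                 cost$device_id, cost$month)
  }
  if (cost$operating_cost <= 0) {
    stop_conedea("operating_cost must be > 0 for %s %s (cost-benefit ratio undefined)",
                 cost$device_id, cost$month)
  }
  dur_min <- as.numeric(ev$finished_at - ev$started_at, units = "mins")
  tau <- mean(dur_min)
  x5 <- sum(ev$revenue)
  x3 <- cost$operating_cost
  data.frame(
    device_id = cost$device_id, month = cost$month,
    X1 = (tau + prep_min) * n / cost$energized_minutes,
    X2 = sum(dur_min) / 60 / days_in_month(cost$month),
    X3 = x3,
    X4 = (cost$operating_cost + cost$depreciation) / n,
    X5 = x5,
    X6 = sum(as.numeric(ev$started_at - ev$booked_at, units = "mins")) / n,
    X7 = x5 / x3,
    X8 = sum(as.numeric(ev$report_at - ev$finished_at, units = "mins")) / n,
    n_exams = n,
    stringsAsFactors = FALSE
  )
}

#' Input indicators for one device-month
#'
#' Convenience accessor returning the four input indicators (X1 utilization
#' rate, X2 average daily working hours, X3 operating cost, X4 average cost
#' per inspection) for a single device-month. Errors if the device-month has
#' no exams or no matching cost row.
#'
#' @inheritParams monthly_panel
#' @param device,month the device id and `"YYYY-MM"` month to evaluate.
#' @return named numeric vector `c(X1, X2, X3, X4)`.
#' @export
input_indicators <- function(events, costs, device, month, prep_min = 2) {
  r <- single_cell(events, costs, device, month, prep_min)
  unlist(r[c("X1", "X2", "X3", "X4")])
}

#' Output indicators for one device-month
#'
#' Counterpart of [input_indicators()]: X5 inspection revenue, X6 mean
#' appointment wait (minutes), X7 cost-benefit ratio, X8 mean report wait
#' (minutes).
#'
#' @inheritParams input_indicators
#' @return named numeric vector `c(X5, X6, X7, X8)`.
#' @export
output_indicators <- function(events, costs, device, month, prep_min = 2) {
  r <- single_cell(events, costs, device, month, prep_min)
  unlist(r[c("X5", "X6", "X7", "X8")])
}

single_cell <- function(events, costs, device, month, prep_min) {
  ci <- which(costs$device_id == device & costs$month == month)
  if (!length(ci)) stop_conedea("no cost row for device-month: %s %s", device, month)
  sel <- events$device_id == device &
    format(events$started_at, "%Y-%m", tz = "UTC") == month
  if (!any(sel)) stop_conedea("no exams for device-month: %s %s", device, month)
  device_month_indicators(events[sel, , drop = FALSE],
                          costs[ci[1], , drop = FALSE], prep_min)
}

#' Pearson correlation screen of the indicator panel
#'
#' Pairwise Pearson correlations (with two-sided p-values) between the
#' indicator columns, used descriptively to check that the indicators carry
#' moderately correlated, complementary information. Constant columns are
#' flagged and their pairs reported as `NA`.
#'
#' @param panel a panel from [monthly_panel()].
#' @param columns which columns to correlate (default X1..X8).
#' @return an object of class `indicator_correlations`: list with symmetric
#'   matrices `r` and `p` (unit/zero diagonal), sample size `n` and any
#'   `constant` columns.
#' @export
indicator_correlations <- function(panel, columns = paste0("X", 1:8)) {
  assert_columns(panel, columns, "panel")
  if (nrow(panel) < 3) stop_conedea("correlation screen needs >= 3 rows")
  Z <- as.matrix(panel[, columns, drop = FALSE])
  const <- columns[apply(Z, 2, function(v) diff(range(v)) == 0)]
  if (length(const)) {
    warning(sprintf("constant column(s) %s: correlations undefined",
                    paste(const, collapse = ", ")))
  }
  k <- length(columns)
  r <- diag(1, k); p <- matrix(0, k, k)
  dimnames(r) <- dimnames(p) <- list(columns, columns)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (columns[i] %in% const || columns[j] %in% const) {
        r[i, j] <- r[j, i] <- NA_real_
        p[i, j] <- p[j, i] <- NA_real_
      } else {
        ct <- stats::cor.test(Z[, i], Z[, j], method = "pearson")
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
  }
  structure(list(r = r, p = p, n = nrow(Z), constant = const),
            class = "indicator_correlations")
}

#' @export
print.indicator_correlations <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlation screen (n = %d device-months)\n", x$n))
  print(round(x$r, digits))
  if (length(x$constant)) {
    cat("constant columns:", paste(x$constant, collapse = ", "), "\n")
  }
  invisible(x)
}
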