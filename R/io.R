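# CSV/JSON schemas and the end-to-end pipeline orchestrator.
# All files are UTF-8, comma-separated with a mandatory header row;
# timestamps are ISO-8601 at minute precision (UTC); months are YYYY-MM.

EVENT_COLS <- c("device_id", "booked_at", "started_at", "finished_at",
                "report_at", "revenue")
COST_COLS <- c("device_id", "month", "operating_cost", "depreciation",
               "energized_minutes")

#' Read and write examination event logs
#'
#' Events CSV schema: `device_id, booked_at, started_at, finished_at,
#' report_at, revenue` with ISO-8601 minute-precision timestamps. Reading
#' validates the chronology (`booked <= started < finished <= report`) and
#' nonnegative revenue, reporting offending row numbers.
#'
#' @param path file path.
#' @return `read_events()`: the validated events data.frame (POSIXct
#'   timestamps, UTC).
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, EVENT_COLS, sprintf("events file '%s'", path))
  for (col in c("booked_at", "started_at", "finished_at", "report_at")) {
    df[[col]] <- parse_ts(df[[col]], sprintf("%s in '%s'", col, basename(path)))
  }
  bad <- which(!(df$booked_at <= df$started_at &
                   df$started_at < df$finished_at &
                   df$finished_at <= df$report_at))
  if (length(bad)) {
    stop_conedea("event chronology violated at row(s) %s of '%s'",
                 paste(utils::head(bad, 5), collapse = ", "), basename(path))
  }
  if (any(df$revenue < 0)) stop_conedea("negative revenue in '%s'", basename(path))
  df
}

#' @rdname read_events
#' @param events events data.frame (as from [simulate_fleet()]).
#' @export
write_events <- function(events, path) {
  assert_columns(events, EVENT_COLS, "events")
  out <- events
  for (col in c("booked_at", "started_at", "finished_at", "report_at")) {
    out[[col]] <- format_ts(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write device-month cost tables
#'
#' Costs CSV schema: `device_id, month, operating_cost, depreciation,
#' energized_minutes` with months as `YYYY-MM`.
#'
#' @param path file path.
#' @return `read_costs()`: the validated costs data.frame.
#' @export
read_costs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, COST_COLS, sprintf("costs file '%s'", path))
  month_start(df$month)
  if (any(df$operating_cost <= 0)) stop_conedea("operating_cost must be > 0 in '%s'", basename(path))
  if (any(df$depreciation < 0)) stop_conedea("depreciation must be >= 0 in '%s'", basename(path))
  if (any(df$energized_minutes <= 0)) stop_conedea("energized_minutes must be > 0 in '%s'", basename(path))
  df
}

#' @rdname read_costs
#' @param costs costs data.frame.
#' @export
write_costs <- function(costs, path) {
  assert_columns(costs, COST_COLS, "costs")
  utils::write.csv(costs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write indicator panels
#'
#' Panel CSV schema: `device_id, month, X1..X8, n_exams`. Units: X1 and X7
#' dimensionless, X2 hours/day, X3 and X5 currency, X4 currency/exam, X6 and
#' X8 minutes.
#'
#' @param path file path.
#' @return `read_panel()`: the panel data.frame.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("device_id", "month", paste0("X", 1:8), "n_exams"),
                 sprintf("panel file '%s'", path))
  df
}

#' @rdname read_panel
#' @param panel panel data.frame from [monthly_panel()].
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write pairwise-comparison matrices
#'
#' Judgement matrices are square CSVs whose header row carries the indicator
#' labels. Reading validates positivity, the 1-9 scale, unit diagonal and
#' reciprocity (`A_ij * A_ji = 1` within a relative tolerance of 1e-2, which
#' accepts printed matrices with rounded reciprocal entries).
#'
#' @param path file path.
#' @param reciprocal_tol reciprocity tolerance.
#' @return `read_judgement_matrix()`: a validated labelled square matrix.
#' @export
read_judgement_matrix <- function(path, reciprocal_tol = 1e-2) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M)) stop_conedea("non-numeric entries in judgement matrix '%s'", basename(path))
  validate_judgement_matrix(M, labels = colnames(df),
                            reciprocal_tol = reciprocal_tol)
}

#' @rdname read_judgement_matrix
#' @param M labelled square matrix.
#' @export
write_judgement_matrix <- function(M, path) {
  utils::write.csv(as.data.frame(M), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write efficiency scores
#'
#' Scores CSV schema: `device_id, month, score_ccr[, score_cone],
#' solver_status`; the cone column is present only for cone-constrained
#' fits.
#'
#' @param fit a [dea()] fit.
#' @param path file path.
#' @export
write_scores <- function(fit, path) {
  stopifnot(inherits(fit, "dea"))
  s <- fit$scores
  out <- data.frame(device_id = s$device_id, month = s$month,
                    score_ccr = s$ccr, stringsAsFactors = FALSE)
  if (fit$cone) out$score_cone <- s$cone
  out$solver_status <- s$status
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

weights_to_list <- function(w) {
  lapply(c(input = "input", output = "output"), function(g) {
    comp <- w[[g]]
    list(group = g,
         labels = names(comp$game$weights),
         ahp = unname(coef(comp$ahp)),
         critic = unname(coef(comp$critic)),
         game = unname(comp$game$weights),
         lambda = comp$game$lambda,
         CR = comp$ahp$CR)
  })
}

#' Default pipeline configuration
#'
#' The run configuration consumed by [run_pipeline()]: a plain named list
#' that can also be loaded from YAML or JSON via [read_run_config()]. Any
#' subset of fields may be overridden; the remainder keep these defaults.
#'
#' @param seed master seed for the run (drives the synthetic fleet).
#' @return named list with elements `seed`, `simulate`, `fleet`
#'   (overrides for [fleet_config()]), `events_path`/`costs_path` (used when
#'   `simulate` is `FALSE`), `input_matrix_path`/`output_matrix_path`
#'   (`NULL` = bundled matrices), `directions`, `dea` (`mode`, `cone`) and
#'   `forecast` (`enabled`, `L`, `hidden`, `epochs`, `lr`, `train_fraction`,
#'   `attention`, `seed`).
#' @export
default_run_config <- function(seed = 42) {
  list(
    seed = seed,
    simulate = TRUE,
    fleet = list(),
    events_path = NULL, costs_path = NULL,
    input_matrix_path = NULL, output_matrix_path = NULL,
    directions = as.list(default_directions()),
    dea = list(mode = "pooled", cone = TRUE),
    forecast = list(enabled = TRUE, L = 6, hidden = 32, epochs = 200,
                    lr = 0.01, train_fraction = 0.8, attention = "dot",
                    seed = 7)
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Fields present in the file override the [default_run_config()] defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return merged configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_conedea("config file not found: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop_conedea("config must be .yaml/.yml or .json: %s", path)
  }
  utils::modifyList(default_run_config(), cfg)
}

#' Run the full evaluation pipeline
#'
#' Executes the end-to-end flow: (optionally) simulate the synthetic fleet,
#' compute the indicator panel and correlation screen, derive combined
#' AHP/CRITIC/game weights, score device-months with the cone-constrained
#' DEA model, forecast each device's efficiency series, and write all
#' artifacts plus a manifest (package version, seed, config hash, per-file
#' MD5 checksums) to `out_dir`. A rerun with identical inputs and seed
#' reproduces identical checksums.
#'
#' @param config configuration list from [default_run_config()] or
#'   [read_run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) a list with the in-memory results (`panel`,
#'   `weights`, `dea`, `forecasts`), the artifact `files` and the
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("conedea-run-"),
                         quiet = FALSE) {
  config <- utils::modifyList(default_run_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  files <- character()
  add_file <- function(p) files <<- c(files, p)

  # stage: data
  if (isTRUE(config$simulate)) {
    fc <- do.call(fleet_config, utils::modifyList(list(seed = config$seed),
                                                  config$fleet))
    fleet <- simulate_fleet(fc)
    events <- fleet$events; costs <- fleet$costs
    say("simulate: %d events, %d cost rows", nrow(events), nrow(costs))
  } else {
    if (is.null(config$events_path) || is.null(config$costs_path)) {
      stop_conedea("stage data: simulate = FALSE requires events_path and costs_path")
    }
    events <- read_events(config$events_path)
    costs <- read_costs(config$costs_path)
    say("load: %d events, %d cost rows", nrow(events), nrow(costs))
  }
  add_file(write_events(events, file.path(out_dir, "events.csv")))
  add_file(write_costs(costs, file.path(out_dir, "costs.csv")))

  # stage: indicators
  panel <- monthly_panel(events, costs)
  add_file(write_panel(panel, file.path(out_dir, "panel.csv")))
  corr <- indicator_correlations(panel)
  utils::write.csv(round(corr$r, 6), file.path(out_dir, "correlations.csv"))
  add_file(file.path(out_dir, "correlations.csv"))
  say("indicators: %d device-months", nrow(panel))

  # stage: weighting
  imat <- if (is.null(config$input_matrix_path)) default_judgement_matrix("input") else
    read_judgement_matrix(config$input_matrix_path)
  omat <- if (is.null(config$output_matrix_path)) default_judgement_matrix("output") else
    read_judgement_matrix(config$output_matrix_path)
  dirs <- unlist(config$directions)[paste0("X", 1:8)]
  w <- combined_weights(panel, imat, omat, directions = dirs)
  jsonlite::write_json(weights_to_list(w),
                       file.path(out_dir, "weights.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  add_file(file.path(out_dir, "weights.json"))
  say("weights: input CR %.4f, output CR %.4f",
      w$input$ahp$CR, w$output$ahp$CR)

  # stage: DEA
  use_cone <- isTRUE(config$dea$cone)
  fit <- dea(panel, weights = if (use_cone) w, cone = use_cone,
             mode = config$dea$mode %||% "pooled")
  add_file(write_scores(fit, file.path(out_dir, "scores.csv")))
  say("dea: mean %s score %.4f",
      if (use_cone) "cone" else "ccr",
      mean(fit$scores[[if (use_cone) "cone" else "ccr"]]))

  # stage: forecasting
  forecasts <- list()
  if (isTRUE(config$forecast$enabled)) {
    fcfg <- config$forecast
    sm <- score_matrix(fit)
    for (dev in rownames(sm)) {
      series <- sm[dev, ]
      if (length(series) <= fcfg$L + 1) {
        warning(sprintf("device %s: series too short to forecast (%d <= L + 1)",
                        dev, length(series)))
        next
      }
      forecasts[[dev]] <- forecast_efficiency(
        series, L = fcfg$L, hidden = fcfg$hidden, epochs = fcfg$epochs,
        lr = fcfg$lr, train_fraction = fcfg$train_fraction,
        attention = fcfg$attention, seed = fcfg$seed
      )
    }
    if (length(forecasts)) {
      fc_json <- lapply(forecasts, function(f) {
        list(metrics = f$metrics[c("MSE", "RMSE", "MAE", "MAPE", "R2", "n")],
             predictions = unname(f$predictions),
             actuals = unname(f$actuals),
             attention = f$attention)
      })
      jsonlite::write_json(fc_json, file.path(out_dir, "forecast.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      add_file(file.path(out_dir, "forecast.json"))
      lc <- as.data.frame(lapply(forecasts, function(f) f$loss_curve))
      utils::write.csv(lc, file.path(out_dir, "loss_curve.csv"),
                       row.names = FALSE)
      add_file(file.path(out_dir, "loss_curve.csv"))
      say("forecast: %d device series", length(forecasts))
    }
  }

  manifest <- list(
    package = "conedea",
    version = as.character(utils::packageVersion("conedea")),
    seed = config$seed,
    config_hash = hash_object(config),
    files = file_checksums(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(panel = panel, weights = w, dea = fit,
                 forecasts = forecasts, files = files,
                 manifest = manifest, out_dir = out_dir))
}

hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

file_checksums <- function(files) {
  as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
}
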