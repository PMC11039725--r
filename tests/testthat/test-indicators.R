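test_that("input indicators follow their defining arithmetic", {
  # 60 exams of exactly 28 minutes; energized 1800 -> X1 = (28+2)*60/1800 = 1
  ev <- do.call(rbind, lapply(1:60, function(i) {
    start <- sprintf("2022-01-%02d", (i - 1) %% 28 + 1)
    events_row(booked = paste0(start, "T07:00"),
               started = paste0(start, "T09:00"),
               finished = paste0(start, "T09:28"),
               report = paste0(start, "T10:00"))
  }))
  ev$started_at <- ev$started_at + rep(0:2, 20) * 3600  # avoid exact ties
  ev$finished_at <- ev$started_at + 28 * 60
  ev$report_at <- ev$finished_at + 1800
  co <- cost_row(month = "2022-01", operating_cost = 100000,
                 depreciation = 20000, energized_minutes = 1800)
  x <- input_indicators(ev, co, "A", "2022-01")
  expect_equal(unname(x["X1"]), 1.0, tolerance = 1e-12)
  expect_equal(unname(x["X3"]), 100000)
  # X4 = (C_t + P)/n = 120000/60
  expect_equal(unname(x["X4"]), 2000)
  # X2: 60 exams x 28 min = 28 h over 31 days
  expect_equal(unname(x["X2"]), 28 / 31, tolerance = 1e-12)
})

test_that("a single half-hour exam contributes 0.5 working hours on its day", {
  ev <- events_row(booked = "2022-01-05T08:00", started = "2022-01-05T09:00",
                   finished = "2022-01-05T09:30", report = "2022-01-05T10:15")
  co <- cost_row()
  x <- input_indicators(ev, co, "A", "2022-01")
  expect_equal(unname(x["X2"]) * 31, 0.5, tolerance = 1e-12)
})

test_that("output indicators follow their defining arithmetic", {
  ev <- events_row(booked = "2022-01-05T08:00", started = "2022-01-05T09:00",
                   finished = "2022-01-05T10:00", report = "2022-01-05T10:45",
                   revenue = 2000)
  co <- cost_row(operating_cost = 1000)
  y <- output_indicators(ev, co, "A", "2022-01")
  expect_equal(unname(y["X6"]), 60)   # booked 08:00, started 09:00
  expect_equal(unname(y["X8"]), 45)   # finished 10:00, report 10:45
  expect_equal(unname(y["X5"]), 2000)
  expect_equal(unname(y["X7"]), 2.0)  # R_t / C_t
})

test_that("panel invariants: X7 * X3 = X5, order invariance, monotonicity", {
  fl <- tiny_fleet(seed = 21)
  panel <- monthly_panel(fl$events, fl$costs)
  expect_equal(panel$X7 * panel$X3, panel$X5, tolerance = 1e-9)
  expect_true(all(panel$X1 > 0 & panel$X3 > 0 & panel$X4 > 0 & panel$X5 > 0))
  expect_true(all(panel$X2 >= 0 & panel$X6 >= 0 & panel$X8 >= 0))

  shuffled <- fl$events[sample(nrow(fl$events)), ]
  expect_equal(monthly_panel(shuffled, fl$costs), panel)

  extra <- events_row(device = fl$events$device_id[1],
                      booked = "2021-01-02T07:00", started = "2021-01-02T23:00",
                      finished = "2021-01-02T23:30", report = "2021-01-03T08:00",
                      revenue = 500)
  panel2 <- monthly_panel(rbind(fl$events, extra), fl$costs)
  r1 <- panel[panel$device_id == extra$device_id & panel$month == "2021-01", ]
  r2 <- panel2[panel2$device_id == extra$device_id & panel2$month == "2021-01", ]
  expect_identical(r2$n_exams, r1$n_exams + 1L)
  expect_equal(r2$X5, r1$X5 + 500)
})

test_that("missing cost rows and degenerate costs raise keyed errors", {
  fl <- tiny_fleet(seed = 3)
  expect_error(monthly_panel(fl$events, fl$costs[-1, ]), "no cost row")
  bad <- fl$costs
  bad$energized_minutes[1] <- 0
  expect_error(monthly_panel(fl$events, bad), "energized_minutes")
  bad2 <- fl$costs
  bad2$operating_cost[1] <- 0
  expect_error(monthly_panel(fl$events, bad2), "operating_cost")
})

test_that("device-months with zero exams are dropped with a warning", {
  fl <- tiny_fleet(n_devices = 1, n_months = 1, seed = 8)
  extra_cost <- cost_row(device = "A", month = "2021-02")
  expect_warning(p <- monthly_panel(fl$events, rbind(fl$costs, extra_cost)),
                 "zero exams")
  expect_identical(nrow(p), 1L)
})

test_that("correlation screen is symmetric with unit diagonal", {
  panel <- data.frame(device_id = "A", month = sprintf("2022-%02d", 1:6),
                      X1 = c(1, 2, 3, 5, 4, 6), X2 = c(2, 4, 7, 9, 8, 13),
                      X3 = c(5, 3, 1, 2, 4, 6), X4 = c(1, 1, 2, 3, 5, 8),
                      X5 = c(9, 7, 5, 3, 2, 1), X6 = c(2, 2, 3, 1, 5, 4),
                      X7 = c(1, 3, 2, 5, 4, 7), X8 = c(6, 5, 4, 4, 3, 1))
  cr <- indicator_correlations(panel)
  expect_equal(cr$r, t(cr$r))
  expect_equal(unname(diag(cr$r)), rep(1, 8))
  expect_true(all(abs(cr$r) <= 1 + 1e-12))
  # negated column correlates at exactly -1
  panel$X2 <- -panel$X1
  cr2 <- indicator_correlations(panel)
  expect_equal(unname(cr2$r["X1", "X2"]), -1)
})

test_that("a hand-checked Pearson pair reproduces its closed-form value", {
  panel <- data.frame(device_id = "A", month = c("2022-01", "2022-02", "2022-03"),
                      X1 = c(1, 2, 3), X2 = c(2, 4, 7))
  cr <- indicator_correlations(panel, columns = c("X1", "X2"))
  # r = S_xy / sqrt(S_xx S_yy) = 5 / sqrt(2 * 38/3)
  expect_equal(unname(cr$r["X1", "X2"]), 5 / sqrt(2 * 38 / 3), tolerance = 1e-9)
})

test_that("constant columns are flagged and their pairs undefined", {
  panel <- data.frame(device_id = "A", month = c("2022-01", "2022-02", "2022-03"),
                      X1 = c(1, 2, 3), X2 = c(5, 5, 5))
  expect_warning(cr <- indicator_correlations(panel, columns = c("X1", "X2")),
                 "constant")
  expect_true(is.na(cr$r["X1", "X2"]))
  expect_identical(cr$constant, "X2")
})
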