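panel_from_matrices <- function(X, Y) {
  n <- ncol(X)
  p <- data.frame(device_id = LETTERS[seq_len(n)],
                  month = rep("2022-01", n))
  for (i in seq_len(nrow(X))) p[[paste0("X", i)]] <- X[i, ]
  for (r in seq_len(nrow(Y))) p[[paste0("X", 4 + r)]] <- Y[r, ]
  p
}

# instance straight from matrices (no undesirable transformation)
raw_instance <- function(X, Y) {
  p <- panel_from_matrices(X, Y)
  dea_instance(p, inputs = paste0("X", seq_len(nrow(X))),
               outputs = paste0("X", 4 + seq_len(nrow(Y))),
               undesirable = character())
}

test_that("undesirable outputs are reversed by the translation rule", {
  p <- data.frame(device_id = c("A", "B", "C"), month = "2022-01",
                  X1 = c(1, 2, 3), X5 = c(5, 6, 7), X6 = c(10, 20, 30))
  inst <- dea_instance(p, inputs = "X1", outputs = c("X5", "X6"),
                       undesirable = "X6")
  # range 20, eps = 0.2, transformed = 30.2 - v
  expect_equal(unname(inst$Y["X6", ]), c(20.2, 10.2, 0.2))
  expect_true(all(inst$Y > 0))
  expect_identical(order(inst$Y["X6", ]), rev(order(p$X6)))
  # no undesirable set: verbatim columns
  inst2 <- dea_instance(p, inputs = "X1", outputs = c("X5", "X6"),
                        undesirable = character())
  expect_equal(unname(inst2$Y["X6", ]), p$X6)
})

test_that("nonpositive inputs are rejected by DMU and indicator", {
  p <- data.frame(device_id = c("A", "B"), month = "2022-01",
                  X1 = c(1, 0), X5 = c(1, 1))
  expect_error(dea_instance(p, inputs = "X1", outputs = "X5",
                            undesirable = character()),
               "X1.*B:2022-01")
})

test_that("CCR scores match closed forms on degenerate instances", {
  one <- raw_instance(matrix(2), matrix(3))
  expect_equal(ccr_efficiency(one, 1)$score, 1, tolerance = 1e-9)

  # single input / single output: theta_j = (y/x)_j / max(y/x)
  inst <- raw_instance(matrix(c(2, 4), 1), matrix(c(1, 4), 1))
  expect_equal(ccr_efficiency(inst, 1)$score, 0.5, tolerance = 1e-7)
  expect_equal(ccr_efficiency(inst, 2)$score, 1.0, tolerance = 1e-7)

  set.seed(31)
  x <- runif(5, 1, 9); y <- runif(5, 1, 9)
  inst2 <- raw_instance(matrix(x, 1), matrix(y, 1))
  ratio <- (y / x) / max(y / x)
  for (j in 1:5) {
    expect_equal(ccr_efficiency(inst2, j)$score, ratio[j], tolerance = 1e-7)
  }
})

test_that("LP scores match the brute-force multiplier-grid oracle", {
  set.seed(7)
  shapes <- list(c(2, 1), c(1, 2), c(1, 1))
  for (rep in 1:6) {
    sh <- shapes[[(rep - 1) %% 3 + 1]]
    n <- sample(2:4, 1)
    inst <- rand_instance(n, sh[1], sh[2])
    ri <- raw_instance(inst$X, inst$Y)
    for (j in seq_len(n)) {
      lp <- ccr_efficiency(ri, j)$score
      bf <- brute_ccr(inst$X, inst$Y, j)
      expect_equal(lp, bf, tolerance = 1e-2)
      expect_lte(lp, 1 + 1e-7)
      expect_gt(lp, 0)
    }
  }
})

test_that("optimal multipliers satisfy the LP constraints", {
  set.seed(19)
  inst <- rand_instance(5, 2, 1)
  ri <- raw_instance(inst$X, inst$Y)
  sol <- ccr_efficiency(ri, 3)
  expect_equal(sum(sol$w * inst$X[, 3]), 1, tolerance = 1e-7)
  slack <- as.numeric(sol$w %*% inst$X) - as.numeric(sol$mu %*% inst$Y)
  expect_true(all(slack >= -1e-7))
  expect_equal(sol$score, sum(sol$mu * inst$Y[, 3]), tolerance = 1e-9)
})

test_that("cone construction satisfies the eigen-identity B w* = 0", {
  u <- build_cone(rep(0.25, 4))
  expect_equal(u$B, matrix(1, 4, 4) - 4 * diag(4))
  expect_equal(as.numeric(u$B %*% u$generator), rep(0, 4), tolerance = 1e-12)

  b <- build_cone(c(2 / 3, 1 / 3))
  expect_equal(b$B, rbind(c(-1, 2), c(0.5, -1)), tolerance = 1e-12)

  set.seed(2)
  for (k in 1:5) {
    w <- runif(sample(2:6, 1), 0.1, 3)
    cn <- build_cone(w)
    expect_equal(as.numeric(cn$B %*% w), rep(0, length(w)), tolerance = 1e-12)
  }
  expect_error(build_cone(c(1, 0)), "positive")
})

test_that("cone scores equal the weighted-ratio closed form and never exceed CCR", {
  set.seed(23)
  for (rep in 1:3) {
    inst <- rand_instance(6, 2, 2)
    ri <- raw_instance(inst$X, inst$Y)
    w_in <- runif(2, 0.2, 1); w_in <- w_in / sum(w_in)
    w_out <- runif(2, 0.2, 1); w_out <- w_out / sum(w_out)
    ic <- build_cone(w_in); oc <- build_cone(w_out)
    for (j in 1:6) {
      ccr <- ccr_efficiency(ri, j)$score
      cone <- ccr_efficiency(ri, j, input_cone = ic, output_cone = oc)$score
      expect_lte(cone, ccr + 1e-7)
      expect_lte(ccr, 1 + 1e-7)
      expect_gt(cone, 0)
      expect_equal(cone, cone_closed_form(inst$X, inst$Y, j, w_in, w_out),
                   tolerance = 1e-5)
    }
  }
})

test_that("an input cone demotes a DMU that is efficient only off the preferred ray", {
  # A is CCR-efficient only by loading weight on input 2; the cone built
  # from (0.8, 0.2) pins the weights near input 1, where A is expensive.
  X <- rbind(c(10, 1), c(1, 10)); Y <- matrix(c(1, 1), 1)
  ri <- raw_instance(X, Y)
  expect_equal(ccr_efficiency(ri, 1)$score, 1, tolerance = 1e-7)
  ic <- build_cone(c(0.8, 0.2))
  cone <- ccr_efficiency(ri, 1, input_cone = ic)$score
  expect_lt(cone, 1 - 1e-4)
  expect_equal(cone, cone_closed_form(X, Y, 1, c(0.8, 0.2), 1), tolerance = 1e-6)
})

test_that("with m = s = 1 the cones are vacuous and scores equal CCR", {
  inst <- raw_instance(matrix(c(2, 3, 5), 1), matrix(c(1, 2, 6), 1))
  ic <- build_cone(1); oc <- build_cone(1)
  for (j in 1:3) {
    expect_equal(ccr_efficiency(inst, j, ic, oc)$score,
                 ccr_efficiency(inst, j)$score, tolerance = 1e-9)
  }
})

test_that("dea() fit: frontier properties and units invariance", {
  fl <- tiny_fleet(n_devices = 3, n_months = 4, seed = 17)
  panel <- monthly_panel(fl$events, fl$costs)
  w <- combined_weights(panel)
  fit <- dea(panel, weights = w)

  expect_true(all(fit$scores$cone <= fit$scores$ccr + 1e-7))
  expect_true(all(fit$scores$ccr <= 1 + 1e-7))
  expect_true(all(fit$scores$cone > 0))
  expect_gte(sum(fit$scores$ccr >= 1 - 1e-7), 1)  # at least one efficient DMU

  # rescaling an input column across all DMUs leaves CCR scores unchanged
  panel2 <- panel
  panel2$X3 <- panel2$X3 / 1000
  fit2 <- dea(panel2, weights = w)
  expect_equal(fit2$scores$ccr, fit$scores$ccr, tolerance = 1e-6)
})

test_that("a single device's best month is efficient on the pooled frontier", {
  fl <- tiny_fleet(n_devices = 1, n_months = 5, seed = 27)
  panel <- monthly_panel(fl$events, fl$costs)
  fit <- dea(panel)
  expect_equal(max(fit$scores$ccr), 1, tolerance = 1e-7)
})

test_that("per-month frontiers score singleton months 1 by convention", {
  fl <- tiny_fleet(n_devices = 2, n_months = 2, seed = 29)
  panel <- monthly_panel(fl$events, fl$costs)
  fit <- dea(panel, mode = "per_month")
  expect_identical(nrow(fit$scores), nrow(panel))
  expect_true(all(fit$scores$ccr <= 1 + 1e-7))

  expect_warning(
    expect_warning(fit1 <- dea(panel[panel$device_id == "A", ],
                               mode = "per_month"),
                   "convention"),
    "convention")
  expect_true(all(fit1$scores$ccr == 1))
  expect_true(all(fit1$scores$status == "singleton"))
})

test_that("the planted high-efficiency device ranks first end to end", {
  fl <- tiny_fleet(n_devices = 3, n_months = 6, seed = 33,
                   multipliers = c(A = 1.3, B = 1, C = 1))
  panel <- monthly_panel(fl$events, fl$costs)
  w <- combined_weights(panel)
  fit <- dea(panel, weights = w)
  means <- tapply(fit$scores$cone, fit$scores$device_id, mean)
  expect_identical(names(which.max(means)), "A")
})

test_that("score matrix and efficiency series expose the device-month grid", {
  fl <- tiny_fleet(n_devices = 2, n_months = 3, seed = 37)
  panel <- monthly_panel(fl$events, fl$costs)
  fit <- dea(panel)
  m <- score_matrix(fit, "ccr")
  expect_identical(dim(m), c(2L, 3L))
  s <- efficiency_series(fit, "A", "ccr")
  expect_identical(names(s), sort(unique(panel$month)))
  expect_equal(unname(s), unname(m["A", ]))
  expect_error(score_matrix(fit, "cone"), "no cone")
})
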