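table1_input <- function() default_judgement_matrix("input")
table1_output <- function() default_judgement_matrix("output")

test_that("AHP geometric-mean weights match closed-form cases", {
  w2 <- ahp(matrix(c(1, 3, 1 / 3, 1), 2, 2, byrow = TRUE))
  expect_equal(unname(w2$weights), c(0.75, 0.25), tolerance = 1e-12)
  expect_identical(w2$CR, 0)

  n <- 5
  u <- ahp(matrix(1, n, n))
  expect_equal(unname(u$weights), rep(1 / n, n), tolerance = 1e-12)
  expect_equal(u$CR, 0, tolerance = 1e-12)
})

test_that("AHP recovers the generating weights of consistent matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(3:6, 1)
    w <- runif(n, 0.5, 2); w <- w / sum(w)
    M <- outer(w, w, "/")
    # scale into the 1-9 band if needed
    if (max(M) > 9) {
      w <- w^(log(9) / log(max(M) / min(M) + 1e-12) * 2)
      w <- w / sum(w); M <- outer(w, w, "/")
    }
    skip_if(max(M) > 9)
    fit <- ahp(M)
    expect_equal(unname(fit$weights), w, tolerance = 1e-10)
    expect_equal(fit$CR, 0, tolerance = 1e-9)
    expect_equal(fit$lambda_max, n, tolerance = 1e-9)
  }
})

test_that("the bundled expert matrices yield the documented weights and CRs", {
  fin <- ahp(table1_input())
  expect_equal(unname(fin$weights), c(0.3547, 0.1220, 0.3250, 0.1984),
               tolerance = 2e-4)
  expect_lt(abs(fin$CR - 0.0287), 1e-3)
  expect_true(fin$acceptable)

  fout <- ahp(table1_output())
  expect_lt(abs(fout$CR - 0.0129), 1e-3)
  expect_true(fout$acceptable)

  # eigenvector mode agrees closely for near-consistent matrices
  fe <- ahp(table1_input(), method = "eigen")
  expect_equal(unname(fe$weights), unname(fin$weights), tolerance = 5e-3)
  expect_gte(fe$lambda_max, 4)
})

test_that("judgement matrix validation rejects malformed input", {
  expect_error(ahp(matrix(c(1, 3, 0.2, 1), 2, 2, byrow = TRUE)), "reciprocity")
  expect_error(ahp(matrix(c(1, -2, -0.5, 1), 2, 2, byrow = TRUE)), "positive")
  expect_error(ahp(matrix(c(1, 12, 1 / 12, 1), 2, 2, byrow = TRUE)), "1/9")
  expect_error(ahp(matrix(1, 2, 3)), "square")
})

test_that("min-max standardization orients benefit and cost columns", {
  expect_equal(unname(minmax_standardize(cbind(1:3), "benefit")[, 1]),
               c(0, 0.5, 1))
  expect_equal(unname(minmax_standardize(cbind(1:3), "cost")[, 1]),
               c(1, 0.5, 0))
  expect_error(minmax_standardize(cbind(a = c(2, 2, 2)), "benefit"),
               "constant")
})

test_that("CRITIC weights equalize symmetric independent columns and reject duplicates", {
  Z <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))  # r = 0, equal sd/entropy
  cw <- critic(Z)
  expect_equal(unname(coef(cw)), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(cw$weight), 1, tolerance = 1e-12)

  Zdup <- cbind(a = c(0, 0.5, 1), b = c(0, 0.5, 1))  # |r| = 1 everywhere
  expect_error(critic(Zdup), "information volume")
})

test_that("CRITIC is invariant to column permutation and raw-column scaling", {
  set.seed(4)
  raw <- matrix(runif(40, 1, 5), 10, 4,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  Z <- minmax_standardize(raw)
  w <- coef(critic(Z))

  perm <- c(3, 1, 4, 2)
  wp <- coef(critic(Z[, perm]))
  expect_equal(unname(wp), unname(w[perm]), tolerance = 1e-12)

  raw2 <- raw
  raw2[, 2] <- raw2[, 2] * 1000  # min-max removes scale
  w2 <- coef(critic(minmax_standardize(raw2)))
  expect_equal(unname(w2), unname(w), tolerance = 1e-12)
})

test_that("game combination solves the documented two-vector cases", {
  same <- game_weights(c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(unname(same$weights), c(0.3, 0.7))
  expect_equal(same$lambda, c(0.5, 0.5))

  g <- game_weights(c(0.6, 0.4), c(0.2, 0.8))
  # independent Cramer's-rule oracle on the 2x2 Gram system
  W1 <- c(0.6, 0.4); W2 <- c(0.2, 0.8)
  G <- rbind(c(sum(W1 * W1), sum(W1 * W2)), c(sum(W2 * W1), sum(W2 * W2)))
  rhs <- c(sum(W1 * W1), sum(W2 * W2))
  det <- G[1, 1] * G[2, 2] - G[1, 2] * G[2, 1]
  lam <- c(rhs[1] * G[2, 2] - G[1, 2] * rhs[2],
           G[1, 1] * rhs[2] - rhs[1] * G[2, 1]) / det
  lam <- lam / sum(lam)
  expect_equal(g$lambda, lam, tolerance = 1e-6)
  expect_equal(g$lambda, c(0.3036, 0.6964), tolerance = 1e-4)
  expect_equal(unname(g$weights), c(0.3214, 0.6786), tolerance = 1e-4)
})

test_that("combined weights are convex combinations when both lambda >= 0", {
  set.seed(6)
  for (k in 1:10) {
    W1 <- runif(4); W1 <- W1 / sum(W1)
    W2 <- runif(4); W2 <- W2 / sum(W2)
    g <- game_weights(W1, W2)
    expect_equal(sum(g$weights), 1, tolerance = 1e-9)
    if (all(g$lambda >= 0)) {
      expect_true(all(g$weights >= pmin(W1, W2) - 1e-9))
      expect_true(all(g$weights <= pmax(W1, W2) + 1e-9))
    }
  }
})

test_that("the solved lambda is each method's best response (grid oracle)", {
  # Nash-equilibrium property of the Gram system: with the other
  # coefficient held at its solved value, a dense grid over lambda_k finds
  # no better value for ||lambda_1 W1 + lambda_2 W2 - W_k||.
  set.seed(12)
  lam_grid <- seq(-1, 2, by = 5e-4)
  for (k in 1:5) {
    W1 <- runif(4); W1 <- W1 / sum(W1)
    W2 <- runif(4); W2 <- W2 / sum(W2)
    g <- game_weights(W1, W2)
    l <- g$lambda_raw
    dev1 <- vapply(lam_grid, function(a)
      sum((a * W1 + l[2] * W2 - W1)^2), numeric(1))
    dev2 <- vapply(lam_grid, function(a)
      sum((l[1] * W1 + a * W2 - W2)^2), numeric(1))
    expect_lt(abs(lam_grid[which.min(dev1)] - l[1]), 1e-3)
    expect_lt(abs(lam_grid[which.min(dev2)] - l[2]), 1e-3)
  }
})

test_that("combined_weights runs both groups and normalizes each to one", {
  fl <- tiny_fleet(n_devices = 3, n_months = 4, seed = 14)
  panel <- monthly_panel(fl$events, fl$costs)
  w <- combined_weights(panel)
  expect_equal(sum(w$weights$input), 1, tolerance = 1e-9)
  expect_equal(sum(w$weights$output), 1, tolerance = 1e-9)
  expect_true(all(unlist(w$weights) > 0))
  expect_named(w$weights$input, paste0("X", 1:4))
  expect_named(w$weights$output, paste0("X", 5:8))
})
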