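#' Sliding windows over an efficiency series
#'
#' Turns a monthly efficiency series into `(window, next-month)` training
#' pairs with a chronological train/test split. Min-max normalization is
#' fitted on the training segment only (the months any training window or
#' target can see) and applied to the whole series, so no test information
#' leaks into preprocessing.
#'
#' @param series numeric vector of monthly scores (chronological order).
#' @param L window length (months of history per prediction).
#' @param train_fraction fraction of the `(window, target)` pairs assigned
#'   to training, chronologically first.
#' @return an object of class `windowed_series`: list with matrix `x`
#'   (normalized windows, one row per pair), vector `y` (normalized
#'   targets), `train_idx`, `test_idx`, normalization parameters `norm`,
#'   `L`, and the raw `series`.
#' @examples
#' w <- make_windows(seq(0.3, 0.9, length.out = 12), L = 3)
#' dim(w$x)  # 9 windows of length 3
#' @export
make_windows <- function(series, L, train_fraction = 0.8) {
  series <- as.numeric(series)
  if (L < 2) stop_conedea("window length L must be >= 2")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_conedea("train_fraction must lie in (0, 1)")
  }
  T_ <- length(series)
  if (T_ <= L + 1) {
    stop_conedea("series length (%d) must exceed L + 1 (= %d)", T_, L + 1)
  }
  if (anyNA(series)) stop_conedea("series contains NA; fill gaps first (see fill_gaps)")
  n_pairs <- T_ - L
  train_n <- max(1L, min(n_pairs - 1L, floor(train_fraction * n_pairs)))

  seen <- series[seq_len(train_n + L)]
  mn <- min(seen); rng <- diff(range(seen))
  if (rng == 0) rng <- 1
  z <- (series - mn) / rng

  x <- t(vapply(seq_len(n_pairs), function(k) z[k:(k + L - 1)], numeric(L)))
  y <- z[(L + 1):T_]
  structure(list(x = x, y = y,
                 train_idx = seq_len(train_n),
                 test_idx = if (train_n < n_pairs) (train_n + 1L):n_pairs else integer(),
                 norm = list(min = mn, range = rng),
                 L = L, series = series),
            class = "windowed_series")
}

#' Linear interpolation of missing scores
#'
#' Fills internal `NA` gaps in an efficiency series by linear interpolation
#' (leading/trailing gaps take the nearest observed value).
#'
#' @param series numeric vector possibly containing `NA`.
#' @return the filled series.
#' @export
fill_gaps <- function(series) {
  if (!anyNA(series)) return(series)
  if (all(is.na(series))) stop_conedea("series is entirely NA")
  idx <- seq_along(series)
  stats::approx(idx[!is.na(series)], series[!is.na(series)], xout = idx,
                rule = 2)$y
}

# --- network internals -------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

.abilstm_init <- function(h, attention) {
  r <- 1 / sqrt(h)
  u <- function(...) {
    d <- c(...)
    array(stats::runif(prod(d), -r, r), dim = d)
  }
  p <- list(
    f_Wx = as.numeric(u(4 * h)), f_Uh = u(h, 4 * h), f_b = rep(0, 4 * h),
    b_Wx = as.numeric(u(4 * h)), b_Uh = u(h, 4 * h), b_b = rep(0, 4 * h),
    out_W = as.numeric(u(2 * h)), out_b = 0
  )
  # forget-gate bias starts open so early gradients propagate through time
  p$f_b[h + seq_len(h)] <- 1
  p$b_b[h + seq_len(h)] <- 1
  if (attention == "additive") {
    p$att_Wa <- u(2 * h, h); p$att_Ua <- u(2 * h, h)
    p$att_ba <- rep(0, h); p$att_va <- as.numeric(u(h))
  }
  p
}

.run_lstm <- function(X, Wx, Uh, b, order, h) {
  N <- nrow(X); L <- ncol(X)
  H <- vector("list", L); cache <- vector("list", L)
  Hprev <- matrix(0, N, h); Cprev <- matrix(0, N, h)
  bmat <- matrix(b, N, 4 * h, byrow = TRUE)
  ih <- seq_len(h)
  for (t in order) {
    Z <- outer(X[, t], Wx) + Hprev %*% Uh + bmat
    i <- sigmoid(Z[, ih, drop = FALSE])
    f <- sigmoid(Z[, h + ih, drop = FALSE])
    g <- tanh(Z[, 2 * h + ih, drop = FALSE])
    o <- sigmoid(Z[, 3 * h + ih, drop = FALSE])
    C <- f * Cprev + i * g
    tC <- tanh(C)
    Hc <- o * tC
    cache[[t]] <- list(x = X[, t], Hprev = Hprev, Cprev = Cprev,
                       i = i, f = f, g = g, o = o, tC = tC)
    H[[t]] <- Hc
    Hprev <- Hc; Cprev <- C
  }
  list(H = H, cache = cache)
}

.abilstm_forward <- function(p, X, attention, h) {
  N <- nrow(X); L <- ncol(X); d2 <- 2 * h
  fwd <- .run_lstm(X, p$f_Wx, p$f_Uh, p$f_b, seq_len(L), h)
  bwd <- .run_lstm(X, p$b_Wx, p$b_Uh, p$b_b, rev(seq_len(L)), h)
  Henc <- lapply(seq_len(L), function(t) cbind(fwd$H[[t]], bwd$H[[t]]))
  q <- Henc[[L]]

  alpha <- NULL; cvec <- NULL; A <- NULL
  if (attention == "none") {
    Hp <- q
  } else {
    E <- matrix(0, N, L)
    if (attention == "dot") {
      for (t in seq_len(L)) E[, t] <- rowSums(q * Henc[[t]]) / sqrt(d2)
    } else {
      A <- vector("list", L)
      qa <- q %*% p$att_Wa
      bmat <- matrix(p$att_ba, N, h, byrow = TRUE)
      for (t in seq_len(L)) {
        A[[t]] <- tanh(qa + Henc[[t]] %*% p$att_Ua + bmat)
        E[, t] <- A[[t]] %*% p$att_va
      }
    }
    E <- E - apply(E, 1, max)
    alpha <- exp(E) / rowSums(exp(E))
    cvec <- matrix(0, N, d2)
    for (t in seq_len(L)) cvec <- cvec + alpha[, t] * Henc[[t]]
    Hp <- cvec + q
  }
  yhat <- as.numeric(Hp %*% p$out_W + p$out_b)
  list(yhat = yhat, fwd = fwd, bwd = bwd, Henc = Henc, q = q,
       alpha = alpha, cvec = cvec, A = A, Hp = Hp, X = X)
}

.lstm_backward <- function(X, Uh, cache, dHext, order, h) {
  N <- nrow(X)
  dWx <- numeric(4 * h); dUh <- matrix(0, h, 4 * h); db <- numeric(4 * h)
  dHnext <- matrix(0, N, h); dCnext <- matrix(0, N, h)
  for (t in rev(order)) {
    cc <- cache[[t]]
    dH <- dHext[[t]] + dHnext
    do_ <- dH * cc$tC
    dC <- dCnext + dH * cc$o * (1 - cc$tC^2)
    di <- dC * cc$g
    df <- dC * cc$Cprev
    dg <- dC * cc$i
    dCnext <- dC * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + as.numeric(crossprod(dZ, cc$x))
    dUh <- dUh + crossprod(cc$Hprev, dZ)
    db <- db + colSums(dZ)
    dHnext <- dZ %*% t(Uh)
  }
  list(Wx = dWx, Uh = dUh, b = db)
}

# loss + exact gradients for one full batch
.abilstm_grads <- function(p, X, y, attention, h) {
  fw <- .abilstm_forward(p, X, attention, h)
  N <- nrow(X); L <- ncol(X); d2 <- 2 * h
  res <- fw$yhat - y
  loss <- mean(res^2)
  dy <- 2 * res / N

  g <- list(out_W = as.numeric(crossprod(fw$Hp, dy)), out_b = sum(dy))
  dHp <- outer(dy, p$out_W)

  dHenc <- lapply(seq_len(L), function(t) matrix(0, N, d2))
  if (attention == "none") {
    dHenc[[L]] <- dHp
  } else {
    dc <- dHp; dq <- dHp
    dalpha <- matrix(0, N, L)
    for (t in seq_len(L)) {
      dalpha[, t] <- rowSums(dc * fw$Henc[[t]])
      dHenc[[t]] <- dHenc[[t]] + fw$alpha[, t] * dc
    }
    S <- rowSums(fw$alpha * dalpha)
    dE <- fw$alpha * (dalpha - S)
    if (attention == "dot") {
      for (t in seq_len(L)) {
        dq <- dq + dE[, t] * fw$Henc[[t]] / sqrt(d2)
        dHenc[[t]] <- dHenc[[t]] + dE[, t] * fw$q / sqrt(d2)
      }
    } else {
      g$att_Wa <- matrix(0, d2, h); g$att_Ua <- matrix(0, d2, h)
      g$att_ba <- numeric(h); g$att_va <- numeric(h)
      for (t in seq_len(L)) {
        At <- fw$A[[t]]
        dA <- outer(dE[, t], p$att_va) * (1 - At^2)
        g$att_va <- g$att_va + as.numeric(crossprod(At, dE[, t]))
        g$att_Wa <- g$att_Wa + crossprod(fw$q, dA)
        g$att_Ua <- g$att_Ua + crossprod(fw$Henc[[t]], dA)
        g$att_ba <- g$att_ba + colSums(dA)
        dq <- dq + dA %*% t(p$att_Wa)
        dHenc[[t]] <- dHenc[[t]] + dA %*% t(p$att_Ua)
      }
    }
    dHenc[[L]] <- dHenc[[L]] + dq
  }

  ih <- seq_len(h)
  dHf <- lapply(dHenc, function(m) m[, ih, drop = FALSE])
  dHb <- lapply(dHenc, function(m) m[, h + ih, drop = FALSE])
  gf <- .lstm_backward(X, p$f_Uh, fw$fwd$cache, dHf, seq_len(ncol(X)), h)
  gb <- .lstm_backward(X, p$b_Uh, fw$bwd$cache, dHb, rev(seq_len(ncol(X))), h)
  g$f_Wx <- gf$Wx; g$f_Uh <- gf$Uh; g$f_b <- gf$b
  g$b_Wx <- gb$Wx; g$b_Uh <- gb$Uh; g$b_b <- gb$b
  list(loss = loss, grads = g, yhat = fw$yhat)
}

.abilstm_loss <- function(p, X, y, attention, h) {
  mean((.abilstm_forward(p, X, attention, h)$yhat - y)^2)
}

#' Fit the attention Bi-LSTM efficiency forecaster
#'
#' One-step-ahead forecaster for monthly efficiency series. A bidirectional
#' LSTM encodes each window of `L` past scores into per-step states
#' `H_t = [H_t^f, H_t^b]` (forward and backward hidden states
#' concatenated); an attention layer computes softmax weights
#' `alpha_i = softmax(score(s, H_i))` against the query `s` (the encoder
#' state at the last window position), forms the context
#' `c = sum_i alpha_i H_i`, and the attention-enhanced state `H' = c + s`
#' feeds a linear head. Training minimizes mean squared error with Adam for
#' a fixed number of epochs on the chronologically first
#' `train_fraction` of windows; the network and its exact gradients are
#' implemented in base R and verified against finite differences in the
#' test suite.
#'
#' The default attention score is scaled dot product; `"additive"`
#' (Bahdanau-style) and `"none"` (plain Bi-LSTM, `H' = s`) are available.
#' All randomness (parameter initialization) flows from `seed`, so a fixed
#' seed reproduces the fit exactly.
#'
#' @param series numeric monthly efficiency series (values typically in
#'   (0, 1\]); internal `NA`s are filled by linear interpolation.
#' @param L window length, months (default 6).
#' @param hidden LSTM width per direction (default 32).
#' @param epochs training epochs (default 200).
#' @param lr Adam learning rate.
#' @param train_fraction chronological train share of the windows.
#' @param attention `"dot"`, `"additive"` or `"none"`.
#' @param seed integer seed for parameter initialization.
#' @return an object of class `abilstm_forecast`: list with `params`,
#'   `loss_curve` (training MSE per epoch, normalized scale), `windows`,
#'   `predictions` (held-out, original scale), `actuals`, `metrics` (from
#'   [forecast_metrics()] when a test set exists), `attention` (per-window
#'   weight matrix, rows summing to 1), `fitted_all`, and the call
#'   configuration. Methods: `print`, `summary`, `predict`, `fitted`,
#'   `residuals`, `plot`.
#' @examples
#' s <- 0.5 + 0.3 * sin(2 * pi * (1:30) / 12)
#' fit <- forecast_efficiency(s, L = 4, hidden = 8, epochs = 50, seed = 1)
#' fit$metrics$RMSE
#' @export
forecast_efficiency <- function(series, L = 6, hidden = 32, epochs = 200,
                                lr = 0.01, train_fraction = 0.8,
                                attention = c("dot", "additive", "none"),
                                seed = 7) {
  attention <- match.arg(attention)
  if (epochs < 1) stop_conedea("epochs must be >= 1")
  series <- fill_gaps(as.numeric(series))
  w <- make_windows(series, L, train_fraction)
  h <- as.integer(hidden)

  set.seed(seed)
  p <- .abilstm_init(h, attention)
  Xtr <- w$x[w$train_idx, , drop = FALSE]
  ytr <- w$y[w$train_idx]

  mstate <- lapply(p, function(a) a * 0)
  vstate <- lapply(p, function(a) a * 0)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  loss_curve <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    gr <- .abilstm_grads(p, Xtr, ytr, attention, h)
    if (!is.finite(gr$loss)) {
      stop_conedea("training diverged at epoch %d (loss not finite); lower the learning rate (lr = %g)",
                   ep, lr)
    }
    loss_curve[ep] <- gr$loss
    for (nm in names(gr$grads)) {
      gnm <- gr$grads[[nm]]
      mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gnm
      vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gnm^2
      mhat <- mstate[[nm]] / (1 - b1^ep)
      vhat <- vstate[[nm]] / (1 - b2^ep)
      p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
    }
  }

  fw <- .abilstm_forward(p, w$x, attention, h)
  denorm <- function(z) z * w$norm$range + w$norm$min
  fitted_all <- denorm(fw$yhat)
  actual_all <- denorm(w$y)

  test_pred <- fitted_all[w$test_idx]
  test_act <- actual_all[w$test_idx]
  metrics <- if (length(w$test_idx) >= 2 && diff(range(test_act)) > 0) {
    forecast_metrics(test_act, test_pred)
  }

  structure(list(params = p, loss_curve = loss_curve, windows = w,
                 predictions = test_pred, actuals = test_act,
                 metrics = metrics, attention = fw$alpha,
                 fitted_all = fitted_all,
                 config = list(L = L, hidden = h, epochs = epochs, lr = lr,
                               train_fraction = train_fraction,
                               attention = attention, seed = seed)),
            class = "abilstm_forecast")
}

#' Forecast evaluation metrics
#'
#' Standard point-forecast quality metrics: mean squared error, its root,
#' mean absolute error, mean absolute percentage error
#' `(1/n) sum |M_i - P_i| / M_i` (points with `M_i = 0` are excluded with a
#' warning), and the coefficient of determination
#' `R2 = 1 - sum (M - P)^2 / sum (M - mean(M))^2`. Per-point relative
#' errors `(P - M)/M` are returned as a diagnostic.
#'
#' @param actual,predicted numeric vectors of equal length (>= 2).
#' @return list with `MSE`, `RMSE`, `MAE`, `MAPE`, `R2`, `relative_error`,
#'   `n`.
#' @examples
#' forecast_metrics(c(1, 2), c(1.1, 1.8))$MAPE  # 0.10
#' @export
forecast_metrics <- function(actual, predicted) {
  M <- as.numeric(actual); P <- as.numeric(predicted)
  if (length(M) != length(P)) stop_conedea("actual and predicted lengths differ")
  if (length(M) < 2) stop_conedea("need at least two points")
  if (diff(range(M)) == 0) stop_conedea("actuals are all equal: R2 undefined")
  err <- M - P
  mse <- mean(err^2)
  nz <- M != 0
  if (!all(nz)) warning(sprintf("%d point(s) with actual = 0 excluded from MAPE", sum(!nz)))
  list(MSE = mse,
       RMSE = sqrt(mse),
       MAE = mean(abs(err)),
       MAPE = mean(abs(err[nz]) / M[nz]),
       R2 = 1 - sum(err^2) / sum((M - mean(M))^2),
       relative_error = (P - M) / ifelse(nz, M, NA_real_),
       n = length(M))
}

#' @export
print.abilstm_forecast <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Attention Bi-LSTM forecaster (%s attention, L = %d, hidden = %d)\n",
              cfg$attention, cfg$L, cfg$hidden))
  cat(sprintf("trained %d epochs, final training MSE %.5f (normalized scale)\n",
              cfg$epochs, x$loss_curve[length(x$loss_curve)]))
  if (!is.null(x$metrics)) {
    cat(sprintf("held-out: n = %d, RMSE %.4f, MAPE %.2f%%, R2 %.4f\n",
                x$metrics$n, x$metrics$RMSE, 100 * x$metrics$MAPE,
                x$metrics$R2))
  }
  invisible(x)
}

#' @export
summary.abilstm_forecast <- function(object, ...) {
  print(object)
  if (!is.null(object$attention)) {
    cat("mean attention weight per window position:\n")
    print(round(colMeans(object$attention), 4))
  }
  invisible(object)
}

#' @export
predict.abilstm_forecast <- function(object, newdata = NULL, ...) {
  series <- if (is.null(newdata)) object$windows$series else
    fill_gaps(as.numeric(newdata))
  L <- object$config$L
  if (length(series) < L + 1) {
    stop_conedea("newdata must contain at least L + 1 = %d points", L + 1)
  }
  nm <- object$windows$norm
  z <- (series - nm$min) / nm$range
  n_pairs <- length(series) - L
  X <- t(vapply(seq_len(n_pairs), function(k) z[k:(k + L - 1)], numeric(L)))
  fw <- .abilstm_forward(object$params, X, object$config$attention,
                         object$config$hidden)
  stats::setNames(fw$yhat * nm$range + nm$min,
                  (L + 1):length(series))
}

#' @export
fitted.abilstm_forecast <- function(object, ...) {
  stats::setNames(object$fitted_all,
                  (object$config$L + 1):length(object$windows$series))
}

#' @export
residuals.abilstm_forecast <- function(object, ...) {
  L <- object$config$L
  act <- object$windows$series[(L + 1):length(object$windows$series)]
  stats::setNames(act - object$fitted_all, (L + 1):length(object$windows$series))
}

#' @export
plot.abilstm_forecast <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$loss_curve, type = "l", xlab = "epoch",
                 ylab = "training MSE", main = "loss curve", ...)
  s <- x$windows$series
  L <- x$config$L
  graphics::plot(seq_along(s), s, type = "l", xlab = "month",
                 ylab = "efficiency score", main = "fit")
  idx <- (L + 1):length(s)
  graphics::lines(idx, x$fitted_all, col = 2, lty = 2)
  test_months <- idx[x$windows$test_idx]
  graphics::points(test_months, x$predictions, col = 4, pch = 19)
  graphics::legend("bottomleft", c("actual", "fitted", "held-out prediction"),
                   col = c(1, 2, 4), lty = c(1, 2, NA), pch = c(NA, NA, 19),
                   bty = "n", cex = 0.8)
  invisible(x)
}
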