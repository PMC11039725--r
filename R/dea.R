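#' Assemble a DEA instance from an indicator panel
#'
#' Selects the input and output columns of the device-month panel into the
#' positive input matrix `X` (m x n) and output matrix `Y` (s x n) expected
#' by the efficiency models, with one column per decision-making unit
#' (device-month). Undesirable outputs (waiting times: smaller is better)
#' are direction-reversed by the linear translation
#' `v' = (max(v) + eps) - v` with `eps` equal to 1% of the column range, so
#' the transformed column is strictly positive and anti-monotone in the
#' original.
#'
#' @param panel a panel from [monthly_panel()].
#' @param inputs,outputs panel columns used as DEA inputs/outputs.
#' @param undesirable subset of `outputs` to direction-reverse (default the
#'   two waiting times).
#' @return an object of class `dea_instance`: list with matrices `X`, `Y`,
#'   `labels` (`device:month`), `device_id`, `month` and the transformation
#'   metadata in `undesirable`.
#' @export
dea_instance <- function(panel,
                         inputs = paste0("X", 1:4),
                         outputs = paste0("X", 5:8),
                         undesirable = c("X6", "X8")) {
  assert_columns(panel, c("device_id", "month", inputs, outputs), "panel")
  if (!nrow(panel)) stop_conedea("panel is empty")
  if (length(intersect(inputs, outputs))) {
    stop_conedea("inputs and outputs must be disjoint")
  }
  undesirable <- intersect(undesirable, outputs)
  labels <- paste(panel$device_id, panel$month, sep = ":")

  X <- t(as.matrix(panel[, inputs, drop = FALSE]))
  Y <- t(as.matrix(panel[, outputs, drop = FALSE]))
  dimnames(X) <- list(inputs, labels)
  dimnames(Y) <- list(outputs, labels)

  meta <- list()
  for (u in undesirable) {
    v <- Y[u, ]
    eps <- 0.01 * diff(range(v))
    if (eps == 0) eps <- max(0.01 * abs(v[1]), 1e-6)
    Y[u, ] <- (max(v) + eps) - v
    meta[[u]] <- list(max = max(v), eps = eps)
  }

  bad <- which(X <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_conedea("nonpositive input %s for DMU %s: DEA requires x_ij > 0",
                 rownames(X)[bad[1, 1]], labels[bad[1, 2]])
  }
  if (any(colSums(Y) <= 0)) {
    stop_conedea("DMU %s has no positive output", labels[which(colSums(Y) <= 0)[1]])
  }
  structure(list(X = X, Y = Y, labels = labels,
                 device_id = panel$device_id, month = panel$month,
                 inputs = inputs, outputs = outputs, undesirable = meta),
            class = "dea_instance")
}

#' Build a multiplier cone from a generator weight vector
#'
#' Constructs the assurance-region constraint for the DEA multipliers of one
#' side (inputs or outputs). From a strictly positive generator `w*` the
#' consistent ratio matrix `W[i,j] = w*_i / w*_j` is formed; its principal
#' eigenvalue equals the order `k`, so the constraint matrix is
#' `B = W - k I`, and the admissible cone is `{B w >= 0, w >= 0}`. By
#' construction `B w* = 0`, so the generator itself is always admissible.
#'
#' For a consistent ratio matrix this cone is exactly the ray spanned by
#' `w*`: the constraint pins the multiplier direction to the combined
#' weights, which is what gives the cone-constrained model its
#' discriminating power.
#'
#' @param w_star strictly positive numeric vector (combined weights).
#' @return an object of class `dea_cone`: list with `B`, `generator`,
#'   `order`.
#' @examples
#' build_cone(c(2/3, 1/3))$B
#' @export
build_cone <- function(w_star) {
  w_star <- as.numeric(w_star)
  if (any(w_star <= 0)) stop_conedea("cone generator weights must be strictly positive")
  k <- length(w_star)
  W <- outer(w_star, w_star, "/")
  B <- W - k * diag(k)
  structure(list(B = B, generator = w_star, order = k), class = "dea_cone")
}

# --- multiplier-form LP ------------------------------------------------------

# Solves: max mu' y0  s.t.  w' x_j - mu' y_j >= 0 (all j), w' x0 = 1,
#         B w >= 0, C mu >= 0, w, mu >= 0.
# Variables stacked as (w, mu). Returns list(score, w, mu, status).
solve_multiplier_lp <- function(X, Y, j0, B = NULL, C = NULL) {
  m <- nrow(X); s <- nrow(Y); n <- ncol(X)
  a <- c(rep(0, m), Y[, j0])
  A1 <- cbind(-t(X), t(Y))            # <= 0 : mu'y_j - w'x_j <= 0
  b1 <- rep(0, n)
  if (!is.null(B) && m > 1) {
    A1 <- rbind(A1, cbind(-B, matrix(0, nrow(B), s)))
    b1 <- c(b1, rep(0, nrow(B)))
  }
  if (!is.null(C) && s > 1) {
    A1 <- rbind(A1, cbind(matrix(0, nrow(C), m), -C))
    b1 <- c(b1, rep(0, nrow(C)))
  }
  A3 <- matrix(c(X[, j0], rep(0, s)), 1)

  sol <- try_simplex(a, A1, b1, A3, eps = 1e-10)
  if (is.null(sol)) sol <- try_simplex(a, A1, b1, A3, eps = 1e-9)
  if (is.null(sol)) {
    stop_conedea(paste0(
      "LP for DMU %d reported infeasible/unbounded; this cannot occur for a ",
      "valid instance (X > 0). Dump: m=%d s=%d n=%d"), j0, m, s, n)
  }
  w <- unname(sol$soln[seq_len(m)])
  mu <- unname(sol$soln[m + seq_len(s)])
  score <- unname(sol$value)
  # clip only within numerical slack of the boundary
  if (score > 1 && score < 1 + 1e-7) score <- 1
  if (score < 0 && score > -1e-7) score <- 0
  list(score = score, w = w, mu = mu, status = "optimal")
}

try_simplex <- function(a, A1, b1, A3, eps) {
  sol <- tryCatch(
    boot::simplex(a = a, A1 = A1, b1 = b1, A3 = A3, b3 = 1,
                  maxi = TRUE, eps = eps, n.iter = 200 + 20 * length(a)),
    error = function(e) NULL
  )
  if (is.null(sol) || sol$solved != 1) return(NULL)
  sol
}

#' CCR efficiency of one decision-making unit
#'
#' Solves the input-oriented multiplier-form CCR linear program under
#' constant returns to scale for DMU `j0`: maximize `mu' y_j0` subject to
#' `w' x_j >= mu' y_j` for every DMU, `w' x_j0 = 1` (Charnes-Cooper
#' normalization) and nonnegative multipliers. Optionally restricted to
#' multiplier cones from [build_cone()].
#'
#' @param instance a [dea_instance()].
#' @param j0 index (or label) of the evaluated DMU.
#' @param input_cone,output_cone optional `dea_cone` objects restricting the
#'   input/output multipliers.
#' @return list with `score` (in (0, 1\]), multipliers `w`, `mu` and solver
#'   `status`.
#' @export
ccr_efficiency <- function(instance, j0, input_cone = NULL, output_cone = NULL) {
  stopifnot(inherits(instance, "dea_instance"))
  if (is.character(j0)) j0 <- match(j0, instance$labels)
  if (is.na(j0) || j0 < 1 || j0 > ncol(instance$X)) {
    stop_conedea("j0 does not identify a DMU")
  }
  if (!is.null(input_cone)) {
    stopifnot(inherits(input_cone, "dea_cone"))
    if (input_cone$order != nrow(instance$X)) {
      stop_conedea("input cone order %d does not match m = %d",
                   input_cone$order, nrow(instance$X))
    }
  }
  if (!is.null(output_cone)) {
    stopifnot(inherits(output_cone, "dea_cone"))
    if (output_cone$order != nrow(instance$Y)) {
      stop_conedea("output cone order %d does not match s = %d",
                   output_cone$order, nrow(instance$Y))
    }
  }
  solve_multiplier_lp(instance$X, instance$Y, j0,
                      B = if (!is.null(input_cone)) input_cone$B,
                      C = if (!is.null(output_cone)) output_cone$B)
}

#' Cone-constrained DEA efficiency scores for a device-month panel
#'
#' The main fitting function: scores every device-month of the panel with
#' the multiplier-form CCR model under constant returns to scale and, when
#' combination weights are supplied, with the cone-constrained variant whose
#' admissible multipliers are confined to the cones generated by the
#' combined input/output weights. Waiting-time outputs are
#' direction-reversed via [dea_instance()] before scoring.
#'
#' In `"pooled"` mode one frontier spans all device-months; in
#' `"per_month"` mode each calendar month is scored against its own
#' cross-sectional frontier (months with fewer than two DMUs score 1 by
#' convention and are flagged).
#'
#' @param panel a device-month panel from [monthly_panel()].
#' @param weights a [combined_weights()] object, or a list with numeric
#'   elements `input` and `output`; `NULL` fits the unconstrained CCR model
#'   only.
#' @param cone logical: add the cone constraints (requires `weights`).
#' @param mode `"pooled"` (default) or `"per_month"` frontier.
#' @param inputs,outputs,undesirable passed to [dea_instance()].
#' @return an object of class `dea`: list with `scores` (data.frame
#'   `device_id`, `month`, `ccr`, `cone`, `status`), `multipliers`,
#'   `instance`, `weights`, `mode`. Methods: `print`, `summary`, `coef`
#'   (multipliers), `fitted` (scores), `plot` (score trajectories),
#'   [score_matrix()], [efficiency_series()].
#' @examples
#' fleet <- simulate_fleet(fleet_config(n_devices = 3, n_months = 4, seed = 1,
#'   efficiency_multipliers = c(A = 1.3, B = 1, C = 1)))
#' panel <- monthly_panel(fleet$events, fleet$costs)
#' fit <- dea(panel)  # unconstrained CCR
#' summary(fit)
#' @export
dea <- function(panel, weights = NULL, cone = !is.null(weights),
                mode = c("pooled", "per_month"),
                inputs = paste0("X", 1:4), outputs = paste0("X", 5:8),
                undesirable = c("X6", "X8")) {
  mode <- match.arg(mode)
  if (cone && is.null(weights)) {
    stop_conedea("cone = TRUE requires combination weights")
  }
  instance <- dea_instance(panel, inputs, outputs, undesirable)

  icone <- ocone <- NULL
  if (cone) {
    wl <- if (inherits(weights, "combination_weights")) weights$weights else weights
    if (!is.list(wl) || is.null(wl$input) || is.null(wl$output)) {
      stop_conedea("weights must provide $input and $output vectors")
    }
    if (length(wl$input) != length(inputs) || length(wl$output) != length(outputs)) {
      stop_conedea("weight vector lengths must match the input/output sets")
    }
    icone <- build_cone(wl$input)
    ocone <- build_cone(wl$output)
  }

  n <- ncol(instance$X)
  ccr <- conescore <- rep(NA_real_, n)
  status <- rep("optimal", n)
  mult <- vector("list", n)

  groups <- if (mode == "pooled") list(seq_len(n)) else
    split(seq_len(n), instance$month)

  for (idx in groups) {
    if (mode == "per_month" && length(idx) < 2) {
      warning(sprintf("month %s has < 2 DMUs: score 1 by convention",
                      instance$month[idx[1]]))
      ccr[idx] <- 1
      if (cone) conescore[idx] <- 1
      status[idx] <- "singleton"
      next
    }
    Xg <- instance$X[, idx, drop = FALSE]
    Yg <- instance$Y[, idx, drop = FALSE]
    for (k in seq_along(idx)) {
      base <- solve_multiplier_lp(Xg, Yg, k)
      ccr[idx[k]] <- base$score
      if (cone) {
        cc <- solve_multiplier_lp(Xg, Yg, k, B = icone$B, C = ocone$B)
        conescore[idx[k]] <- min(cc$score, ccr[idx[k]])
        mult[[idx[k]]] <- list(w = cc$w, mu = cc$mu)
      } else {
        mult[[idx[k]]] <- list(w = base$w, mu = base$mu)
      }
    }
  }

  scores <- data.frame(device_id = instance$device_id,
                       month = instance$month,
                       ccr = ccr, stringsAsFactors = FALSE)
  if (cone) scores$cone <- conescore
  scores$status <- status
  names(mult) <- instance$labels

  structure(list(scores = scores, multipliers = mult, instance = instance,
                 weights = if (cone) list(input = icone$generator,
                                          output = ocone$generator),
                 cone = cone, mode = mode),
            class = "dea")
}

#' Device-by-month matrix of efficiency scores
#'
#' @param fit a [dea()] fit.
#' @param type `"cone"` (if fitted) or `"ccr"`.
#' @return numeric matrix, devices in rows, months in columns.
#' @export
score_matrix <- function(fit, type = if (fit$cone) "cone" else "ccr") {
  stopifnot(inherits(fit, "dea"))
  type <- match.arg(type, c("cone", "ccr"))
  if (type == "cone" && !fit$cone) stop_conedea("fit has no cone scores")
  s <- fit$scores
  devices <- sort(unique(s$device_id))
  months <- sort(unique(s$month))
  out <- matrix(NA_real_, length(devices), length(months),
                dimnames = list(devices, months))
  out[cbind(match(s$device_id, devices), match(s$month, months))] <- s[[type]]
  out
}

#' Monthly efficiency series of one device
#'
#' Extracts the chronologically ordered efficiency scores of a device, the
#' input to [forecast_efficiency()].
#'
#' @inheritParams score_matrix
#' @param device device id.
#' @return named numeric vector ordered by month.
#' @export
efficiency_series <- function(fit, device,
                              type = if (fit$cone) "cone" else "ccr") {
  m <- score_matrix(fit, type)
  if (!device %in% rownames(m)) stop_conedea("unknown device '%s'", device)
  m[device, ]
}

#' @export
print.dea <- function(x, digits = 4, ...) {
  cat(sprintf("%s DEA fit (%s frontier): %d DMUs, %d input(s), %d output(s)\n",
              if (x$cone) "Cone-constrained" else "CCR", x$mode,
              ncol(x$instance$X), nrow(x$instance$X), nrow(x$instance$Y)))
  cat(sprintf("mean CCR score %.4f; %d CCR-efficient DMU(s)\n",
              mean(x$scores$ccr), sum(x$scores$ccr >= 1 - 1e-7)))
  if (x$cone) cat(sprintf("mean cone score %.4f\n", mean(x$scores$cone)))
  invisible(x)
}

#' @export
summary.dea <- function(object, ...) {
  s <- object$scores
  type <- if (object$cone) "cone" else "ccr"
  by_dev <- aggregate(s[[type]], list(device_id = s$device_id),
                      function(v) c(mean = mean(v), min = min(v), max = max(v)))
  tab <- data.frame(device_id = by_dev$device_id,
                    mean = by_dev$x[, "mean"],
                    min = by_dev$x[, "min"],
                    max = by_dev$x[, "max"])
  tab <- tab[order(-tab$mean), ]
  rownames(tab) <- NULL
  structure(list(by_device = tab, type = type, mode = object$mode,
                 n_efficient = sum(s$ccr >= 1 - 1e-7), n = nrow(s)),
            class = "summary.dea")
}

#' @export
print.summary.dea <- function(x, digits = 4, ...) {
  cat(sprintf("Efficiency by device (%s scores, %s frontier):\n",
              x$type, x$mode))
  print(round_df(x$by_device, digits))
  cat(sprintf("%d of %d DMUs CCR-efficient\n", x$n_efficient, x$n))
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  df
}

#' @export
fitted.dea <- function(object, type = if (object$cone) "cone" else "ccr", ...) {
  stats::setNames(object$scores[[type]], object$instance$labels)
}

#' @export
coef.dea <- function(object, ...) {
  t(vapply(object$multipliers, function(m) c(m$w, m$mu),
           numeric(nrow(object$instance$X) + nrow(object$instance$Y))))
}

#' @export
plot.dea <- function(x, type = if (x$cone) "cone" else "ccr",
                     col = NULL, ...) {
  m <- score_matrix(x, type)
  col <- col %||% seq_len(nrow(m))
  graphics::matplot(t(m), type = "b", pch = 19, lty = 1, col = col,
                    xaxt = "n", xlab = "month",
                    ylab = sprintf("%s efficiency score", type),
                    ylim = c(0, 1.02), ...)
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::legend("bottomleft", legend = rownames(m), col = col, pch = 19,
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
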