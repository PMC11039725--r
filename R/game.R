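#' Game-theoretic combination of weight vectors
#'
#' Fuses two (or more) weight vectors for the same indicators into a single
#' combined vector by minimizing the total Euclidean deviation of the linear
#' combination from each component vector. The first-order condition is the
#' Gram linear system `G lambda = diag(G)` with `G[k,l] = W_k . W_l`; the
#' solved coefficients are normalized to sum 1 and the combination
#' renormalized to a weight vector. The equilibrium balances a subjective
#' (expert) and an objective (data-driven) weighting so neither dominates.
#'
#' A singular Gram system (parallel vectors) falls back to the
#' Moore-Penrose pseudo-solution; identical vectors short-circuit to equal
#' coefficients.
#'
#' @param ... two or more numeric weight vectors of equal length (or a
#'   single list of them). Typically `L = 2`: AHP and improved-CRITIC
#'   weights.
#' @return an object of class `game_weights`: list with `weights` (combined,
#'   sums to 1), `lambda` (normalized combination coefficients),
#'   `lambda_raw` (the Gram-system solution) and `components`.
#' @examples
#' game_weights(c(0.6, 0.4), c(0.2, 0.8))
#' @export
game_weights <- function(...) {
  W <- list(...)
  if (length(W) == 1L && is.list(W[[1]])) W <- W[[1]]
  L <- length(W)
  if (L < 2) stop_conedea("game combination needs at least two weight vectors")
  n <- length(W[[1]])
  if (!all(vapply(W, length, 1L) == n)) {
    stop_conedea("all weight vectors must have the same length")
  }
  W <- lapply(W, as.numeric)
  M <- do.call(rbind, W)                       # L x n
  G <- M %*% t(M)                              # Gram matrix
  rhs <- diag(G)

  if (all(vapply(W[-1], function(w) isTRUE(all.equal(w, W[[1]])), TRUE))) {
    lambda_raw <- rep(1, L)
  } else {
    lambda_raw <- tryCatch(
      as.numeric(solve(G, rhs)),
      error = function(e) as.numeric(pinv(G) %*% rhs)
    )
    if (rcond(G) < 1e-12) lambda_raw <- as.numeric(pinv(G) %*% rhs)
  }

  lambda <- lambda_raw / sum(lambda_raw)
  w <- as.numeric(t(M) %*% lambda)
  w <- w / sum(w)
  names(w) <- names(W[[1]])
  structure(list(weights = w, lambda = lambda, lambda_raw = lambda_raw,
                 components = W),
            class = "game_weights")
}

#' @export
print.game_weights <- function(x, digits = 4, ...) {
  cat(sprintf("Game-combination weights (L = %d, lambda = %s)\n",
              length(x$components),
              paste(round(x$lambda, digits), collapse = ", ")))
  print(round(x$weights, digits))
  invisible(x)
}

#' @export
coef.game_weights <- function(object, ...) object$weights

#' Combined subjective/objective indicator weights for a panel
#'
#' Runs the full weighting stage on an indicator panel: AHP weights from the
#' two pairwise-comparison matrices (input indicators X1-X4, output
#' indicators X5-X8), improved-CRITIC weights from the min-max standardized
#' panel (computed within each group), and their game-theoretic combination
#' per group.
#'
#' The default direction map treats X3, X4 (costs) and X6, X8 (waits) as
#' cost-type and X1, X2, X5, X7 as benefit-type for the standardization step.
#'
#' @param panel a device-month panel from [monthly_panel()].
#' @param input_matrix,output_matrix 4x4 judgement matrices (see
#'   [read_judgement_matrix()]); defaults to the matrices bundled with the
#'   package.
#' @param directions named character vector mapping X1..X8 to
#'   `"benefit"`/`"cost"`.
#' @param ahp_method passed to [ahp()].
#' @return an object of class `combination_weights`: per group (`input`,
#'   `output`) the `ahp` fit, `critic` breakdown and `game` combination,
#'   plus the flat combined vectors in `$weights`.
#' @export
combined_weights <- function(panel,
                             input_matrix = default_judgement_matrix("input"),
                             output_matrix = default_judgement_matrix("output"),
                             directions = default_directions(),
                             ahp_method = "geometric") {
  groups <- list(input = paste0("X", 1:4), output = paste0("X", 5:8))
  assert_columns(panel, unlist(groups), "panel")
  out <- list()
  for (g in names(groups)) {
    cols <- groups[[g]]
    J <- if (g == "input") input_matrix else output_matrix
    J <- validate_judgement_matrix(J, labels = cols)
    a <- ahp(J, method = ahp_method)
    Z <- minmax_standardize(panel[, cols], directions[cols])
    cr <- critic(Z)
    gm <- game_weights(unname(coef(a)), unname(coef(cr)))
    names(gm$weights) <- cols
    out[[g]] <- list(ahp = a, critic = cr, game = gm)
  }
  structure(list(input = out$input, output = out$output,
                 directions = directions,
                 weights = list(input = out$input$game$weights,
                                output = out$output$game$weights)),
            class = "combination_weights")
}

#' Default benefit/cost direction map for the eight indicators
#' @return named character vector over X1..X8.
#' @export
default_directions <- function() {
  c(X1 = "benefit", X2 = "benefit", X3 = "cost", X4 = "cost",
    X5 = "benefit", X6 = "cost", X7 = "benefit", X8 = "cost")
}

#' Bundled pairwise-comparison matrices
#'
#' The 4x4 expert judgement matrices shipped with the package (input
#' indicators X1-X4 and output indicators X5-X8), used as defaults by
#' [combined_weights()] and [run_pipeline()].
#'
#' @param group `"input"` or `"output"`.
#' @return a validated judgement matrix.
#' @export
default_judgement_matrix <- function(group = c("input", "output")) {
  group <- match.arg(group)
  path <- system.file("extdata",
                      sprintf("ahp_%s_judgement.csv", group),
                      package = "conedea", mustWork = TRUE)
  read_judgement_matrix(path)
}

#' @export
print.combination_weights <- function(x, digits = 4, ...) {
  for (g in c("input", "output")) {
    cat(sprintf("%s indicators (AHP CR = %.4f, lambda = %s):\n", g,
                x[[g]]$ahp$CR,
                paste(round(x[[g]]$game$lambda, 3), collapse = "/")))
    m <- rbind(ahp = coef(x[[g]]$ahp),
               critic = coef(x[[g]]$critic),
               combined = x[[g]]$game$weights)
    colnames(m) <- names(x$weights[[g]])
    print(round(m, digits))
  }
  invisible(x)
}

#' @export
coef.combination_weights <- function(object, ...) {
  c(object$weights$input, object$weights$output)
}
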