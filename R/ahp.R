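#' Analytic hierarchy process weights and consistency test
#'
#' Derives priority weights from a positive reciprocal pairwise-comparison
#' matrix on the 1-9 scale and runs Saaty's consistency test. The default
#' estimator is the row geometric mean: `V_i = (prod_j A_ij)^(1/n)`,
#' `w_i = V_i / sum(V)`, with the principal eigenvalue estimated as
#' `lambda_max = sum_i (A w)_i / (n w_i)`. The principal-eigenvector method
#' is available via `method = "eigen"`.
#'
#' The consistency index is `CI = (lambda_max - n)/(n - 1)` and the
#' consistency ratio `CR = CI / RI(n)` with Saaty's random index; `CR < 0.10`
#' is conventionally acceptable. For `n <= 2` a reciprocal matrix is always
#' consistent and CR is defined as 0.
#'
#' @param M square numeric matrix of pairwise comparison ratios; printed
#'   matrices with rounded reciprocals are accepted (reciprocity is checked
#'   at relative tolerance `reciprocal_tol`).
#' @param labels optional indicator names (defaults to the matrix dimnames).
#' @param method weight estimator: `"geometric"` (row geometric means) or
#'   `"eigen"` (principal eigenvector).
#' @param reciprocal_tol relative tolerance for `A_ij * A_ji == 1`.
#' @return an object of class `ahp`: list with `weights` (named, summing to
#'   1), `lambda_max`, `CI`, `RI`, `CR`, `acceptable`, `n`, `method` and the
#'   validated `matrix`.
#' @examples
#' M <- matrix(c(1, 3, 1/3, 1), 2, 2, byrow = TRUE)
#' ahp(M, labels = c("cost", "revenue"))$weights
#' @export
ahp <- function(M, labels = NULL, method = c("geometric", "eigen"),
                reciprocal_tol = 1e-2) {
  method <- match.arg(method)
  M <- validate_judgement_matrix(M, labels, reciprocal_tol)
  n <- nrow(M)
  labels <- rownames(M)

  if (method == "geometric") {
    V <- apply(M, 1, function(r) exp(mean(log(r))))
    w <- V / sum(V)
    lambda_max <- sum((M %*% w) / (n * w))
  } else {
    e <- eigen(M)
    k <- which.max(Re(e$values))
    v <- Re(e$vectors[, k])
    v <- v * sign(sum(v))
    w <- v / sum(v)
    lambda_max <- Re(e$values[k])
  }
  names(w) <- labels

  if (n <= 2) {
    CI <- 0; RI <- NA_real_; CR <- 0
    note <- "reciprocal matrices of order <= 2 are always consistent"
  } else {
    CI <- (lambda_max - n) / (n - 1)
    RI <- saaty_ri(n)
    CR <- CI / RI
    note <- NULL
  }
  structure(list(weights = w, lambda_max = lambda_max, CI = CI, RI = RI,
                 CR = CR, acceptable = CR < 0.10, n = n, method = method,
                 matrix = M, note = note),
            class = "ahp")
}

# Saaty's random index
saaty_ri <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49, 1.51, 1.54,
          1.56, 1.57, 1.59)
  if (n > length(ri)) stop_conedea("no random-index value tabulated for n = %d", n)
  ri[n]
}

validate_judgement_matrix <- function(M, labels = NULL, reciprocal_tol = 1e-2) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop_conedea("judgement matrix must be square")
  if (!is.numeric(M) || anyNA(M)) stop_conedea("judgement matrix must be numeric without NA")
  if (any(M <= 0)) stop_conedea("judgement matrix entries must be positive")
  if (any(M < 1 / 9 - 1e-9 | M > 9 + 1e-9)) {
    stop_conedea("judgement matrix entries must lie in [1/9, 9]")
  }
  if (any(abs(diag(M) - 1) > 1e-9)) stop_conedea("judgement matrix diagonal must be 1")
  rec <- abs(M * t(M) - 1)
  if (any(rec > reciprocal_tol * (1 + 1e-9))) {
    bad <- which(rec == max(rec), arr.ind = TRUE)[1, ]
    stop_conedea("reciprocity violated beyond tolerance %.3g at (%d,%d): %g vs %g",
                 reciprocal_tol, bad[1], bad[2], M[bad[1], bad[2]], M[bad[2], bad[1]])
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(M)) stop_conedea("labels length must match matrix order")
    dimnames(M) <- list(labels, labels)
  } else if (is.null(rownames(M))) {
    lab <- paste0("C", seq_len(nrow(M)))
    dimnames(M) <- list(lab, lab)
  }
  M
}

#' @export
print.ahp <- function(x, digits = 4, ...) {
  cat(sprintf("AHP weights (%s method, n = %d)\n", x$method, x$n))
  print(round(x$weights, digits))
  cat(sprintf("lambda_max = %.4f, CI = %.4f, CR = %.4f (%s)\n",
              x$lambda_max, x$CI, x$CR,
              if (x$acceptable) "acceptable, CR < 0.10" else "NOT acceptable"))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' @export
coef.ahp <- function(object, ...) object$weights
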