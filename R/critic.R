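#' Min-max (deviation) standardization with indicator directions
#'
#' Rescales each column to \[0, 1\] by the deviation method: benefit columns
#' as `(x - min)/(max - min)`, cost columns (smaller is better) as
#' `(max - x)/(max - min)`. Constant columns are rejected by name, since the
#' range is zero and the standardized value undefined.
#'
#' @param x numeric matrix or data.frame of indicator columns.
#' @param direction character vector, one of `"benefit"`/`"cost"` per column
#'   (recycled if length 1).
#' @return numeric matrix of the same shape with values in \[0, 1\].
#' @examples
#' minmax_standardize(cbind(a = 1:3, b = 1:3), c("benefit", "cost"))
#' @export
minmax_standardize <- function(x, direction = "benefit") {
  Z <- as.matrix(x)
  if (!is.numeric(Z)) stop_conedea("x must be numeric")
  k <- ncol(Z)
  if (length(direction) == 1L) direction <- rep(direction, k)
  if (length(direction) != k) stop_conedea("direction must have one entry per column")
  if (!all(direction %in% c("benefit", "cost"))) {
    stop_conedea("direction entries must be 'benefit' or 'cost'")
  }
  nm <- colnames(Z) %||% paste0("V", seq_len(k))
  for (j in seq_len(k)) {
    rng <- range(Z[, j])
    if (diff(rng) == 0) {
      stop_conedea("column '%s' is constant: min-max standardization undefined", nm[j])
    }
    Z[, j] <- if (direction[j] == "benefit") {
      (Z[, j] - rng[1]) / diff(rng)
    } else {
      (rng[2] - Z[, j]) / diff(rng)
    }
  }
  Z
}

#' Improved CRITIC objective weights
#'
#' Objective indicator weighting from a standardized decision matrix,
#' combining three per-column signals: the entropy-method value `sigma_j`
#' (Shannon entropy of the column treated as a probability mass, scaled to
#' \[0, 1\]), the dispersion `h_j` (sample standard deviation), and the
#' conflict `sum_i(1 - |r_ij|)` over absolute Pearson correlations with the
#' other columns. The information volume is
#' `(sigma_j + h_j) * conflict_j`, and weights are the volumes normalized to
#' sum 1. Using `|r|` (rather than signed `r`) treats positively and
#' negatively correlated indicator pairs as equally redundant.
#'
#' @param Z standardized decision matrix from [minmax_standardize()]
#'   (columns in \[0, 1\], at least two columns).
#' @param eps shift applied before the entropy probability normalization to
#'   avoid `log(0)`.
#' @return an object of class `critic_weights`: data.frame with one row per
#'   indicator and columns `entropy`, `dispersion`, `conflict`, `volume`,
#'   `weight`.
#' @examples
#' Z <- minmax_standardize(cbind(a = c(1, 4, 2, 5), b = c(3, 1, 4, 2)))
#' critic(Z)
#' @export
critic <- function(Z, eps = 1e-12) {
  Z <- as.matrix(Z)
  if (ncol(Z) < 2) stop_conedea("CRITIC needs at least two indicator columns")
  if (nrow(Z) < 3) stop_conedea("CRITIC needs at least three observations")
  n <- nrow(Z)
  entropy <- apply(Z, 2, function(z) {
    p <- (z + eps) / sum(z + eps)
    -sum(p * log(p)) / log(n)
  })
  dispersion <- apply(Z, 2, stats::sd)
  r <- suppressWarnings(stats::cor(Z))
  if (anyNA(r)) stop_conedea("correlation undefined (constant column after standardization?)")
  conflict <- colSums(1 - abs(r))
  out <- critic_combine(entropy, dispersion, conflict)
  rownames(out) <- colnames(Z) %||% paste0("V", seq_len(ncol(Z)))
  structure(out, class = c("critic_weights", "data.frame"))
}

#' Combine CRITIC components into information volumes and weights
#'
#' The recomposition step of [critic()], exposed so that externally supplied
#' component rows (entropy value, dispersion, conflict) can be turned into
#' information volumes `(entropy + dispersion) * conflict` and normalized
#' weights. When `groups` is given, weights are normalized within each group
#' (e.g. input-side and output-side indicators separately).
#'
#' @param entropy,dispersion,conflict numeric vectors of equal length.
#' @param groups optional grouping vector for group-wise weight
#'   normalization.
#' @return data.frame with columns `entropy`, `dispersion`, `conflict`,
#'   `volume`, `weight`.
#' @export
critic_combine <- function(entropy, dispersion, conflict, groups = NULL) {
  k <- length(entropy)
  stopifnot(length(dispersion) == k, length(conflict) == k)
  volume <- (entropy + dispersion) * conflict
  if (sum(volume) <= .Machine$double.eps * k) {
    stop_conedea("degenerate CRITIC weights: total information volume is zero (all columns mutually |r| = 1?)")
  }
  if (is.null(groups)) groups <- rep(1L, k)
  weight <- numeric(k)
  for (g in unique(groups)) {
    sel <- groups == g
    tot <- sum(volume[sel])
    if (tot <= 0) stop_conedea("zero information volume in group %s", g)
    weight[sel] <- volume[sel] / tot
  }
  data.frame(entropy = entropy, dispersion = dispersion,
             conflict = conflict, volume = volume, weight = weight)
}

#' @export
print.critic_weights <- function(x, digits = 4, ...) {
  cat("Improved CRITIC weights\n")
  print(round(as.data.frame(x), digits))
  invisible(x)
}

#' @export
coef.critic_weights <- function(object, ...) {
  stats::setNames(object$weight, rownames(object))
}
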