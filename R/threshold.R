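#' Extract the pairwise connectivity value from a visitation map
#'
#' Masks a visitation map with a target ROI and returns the maximum
#' visitation count inside it — the single connection-probability estimate
#' for the seed-target pair (on the scale 0 to the number of streamlines
#' launched).
#'
#' @param map A [visitation_map] (or a numeric array of counts).
#' @param target_mask Logical array of the same dimension, or a matrix of
#'   voxel coordinates (one row per voxel), or for a `visitation_map` an
#'   ROI id/name present in its field labels.
#' @return A single count.
#' @export
extract_pair_value <- function(map, target_mask) {
  counts <- if (inherits(map, "visitation_map")) map$counts else map
  if (inherits(map, "visitation_map") && length(target_mask) == 1L &&
      !is.logical(target_mask)) {
    target_mask <- roi_mask(map, target_mask)
  }
  if (is.matrix(target_mask) && !is.logical(target_mask)) {
    idx <- target_mask
    if (ncol(idx) != length(dim(counts)))
      stop("voxel coordinate matrix must have one column per dimension")
    vals <- counts[idx]
  } else {
    if (!identical(dim(target_mask), dim(counts)))
      stop("mask dimensions do not match the map")
    vals <- counts[target_mask]
  }
  if (length(vals) == 0L) stop("target mask is empty")
  max(vals)
}

#' Combine the two directional estimates of a pair
#'
#' Tracking seeded in A gives one estimate of the A-B connection and
#' tracking seeded in B another; they are combined into a single symmetric
#' estimate. The default combination is the arithmetic mean; `"max"` is
#' available as an alternative.
#'
#' @param v_ab,v_ba Nonnegative counts (vectors are combined elementwise),
#'   or for the matrix method a square count matrix of ordered pairs.
#' @param method `"mean"` (default) or `"max"`.
#' @return Combined value(s); for a matrix input, a symmetric matrix.
#' @export
combine_bidirectional <- function(v_ab, v_ba = NULL, method = c("mean", "max")) {
  method <- match.arg(method)
  if (is.matrix(v_ab) && is.null(v_ba)) {
    m <- v_ab
    if (nrow(m) != ncol(m)) stop("pair matrix must be square")
    out <- if (method == "mean") (m + t(m)) / 2 else pmax(m, t(m))
    diag(out) <- 0
    return(out)
  }
  if (any(v_ab < 0) || any(v_ba < 0)) stop("counts must be nonnegative")
  if (method == "mean") (v_ab + v_ba) / 2 else pmax(v_ab, v_ba)
}

#' Poisson-tail individual threshold
#'
#' Fits a Poisson rate to a subject's combined connectivity values by the
#' method of moments — the mean of all off-diagonal values, zeros included
#' — and returns the smallest count whose upper-tail probability under that
#' Poisson falls below `alpha`. Values at or above the threshold are
#' considered significant connections for this subject.
#'
#' With all-zero input the fitted rate is 0 and the threshold is 1 (any
#' positive count would be significant). `alpha >= 1` disables the
#' threshold (`k_star = 0`).
#'
#' @param values Numeric vector or square matrix of combined values; for a
#'   matrix, the diagonal is dropped before fitting.
#' @param alpha Upper-tail significance level in `(0, 1]`; default 0.05.
#' @param n_streamlines Optional normalizing constant (streamlines per
#'   seed); when given, the threshold is also reported as a percentage of
#'   it.
#' @return Object of class `poisson_threshold`: list with `lambda_hat`,
#'   `k_star`, `alpha`, `percent_equiv`, `n_values`.
#' @examples
#' poisson_threshold(rpois(100, 3))
#' @export
poisson_threshold <- function(values, alpha = 0.05, n_streamlines = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")
  if (is.matrix(values)) {
    if (nrow(values) != ncol(values)) stop("value matrix must be square")
    values <- values[row(values) != col(values)]
  }
  if (length(values) == 0L) stop("no values to fit")
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and nonnegative")
  lambda_hat <- mean(values)
  k_star <- poisson_tail_cutoff(lambda_hat, alpha)
  structure(list(
    lambda_hat = lambda_hat,
    k_star = k_star,
    alpha = alpha,
    percent_equiv = if (is.null(n_streamlines)) NA_real_
                    else 100 * k_star / n_streamlines,
    n_values = length(values)
  ), class = "poisson_threshold")
}

# smallest k >= 0 with P(X >= k | Poisson(lambda)) < alpha; alpha >= 1 is
# treated as "no threshold" (k = 0, everything passes)
poisson_tail_cutoff <- function(lambda, alpha) {
  if (alpha >= 1) return(0L)
  if (lambda == 0) return(1L)
  # P(X >= k) = 1 - ppois(k - 1, lambda); start near the quantile and walk
  k <- stats::qpois(1 - alpha, lambda)
  while (k > 0 && stats::ppois(k - 1, lambda, lower.tail = FALSE) < alpha)
    k <- k - 1
  while (stats::ppois(k - 1, lambda, lower.tail = FALSE) >= alpha)
    k <- k + 1
  as.integer(k)
}

#' @export
print.poisson_threshold <- function(x, ...) {
  cat(sprintf(
    "Poisson threshold: lambda_hat = %.4g over %d values; k* = %d at alpha = %g\n",
    x$lambda_hat, x$n_values, x$k_star, x$alpha))
  if (!is.na(x$percent_equiv))
    cat(sprintf("  (%.3g%% of streamlines per seed)\n", x$percent_equiv))
  invisible(x)
}

#' Binarize a subject's combined matrix at the individual threshold
#'
#' @param combined Symmetric matrix of combined pairwise values.
#' @param k_star Threshold count, or a [poisson_threshold] object; entries
#'   `>= k_star` become 1.
#' @return Binary symmetric integer matrix with zero diagonal.
#' @export
apply_individual_threshold <- function(combined, k_star) {
  if (inherits(k_star, "poisson_threshold")) k_star <- k_star$k_star
  if (!isTRUE(all.equal(combined, t(combined), check.attributes = FALSE)))
    stop("combined matrix must be symmetric")
  out <- (combined >= k_star) * 1L
  diag(out) <- 0L
  storage.mode(out) <- "integer"
  out
}

#' Threshold one subject's pair matrix end to end
#'
#' Convenience wrapper: combines the two directional estimates, fits the
#' Poisson individual threshold, and binarizes.
#'
#' @param pair_matrix Square count matrix of ordered pairs (seed row,
#'   target column).
#' @param alpha Significance level for [poisson_threshold()].
#' @param combine Combination rule passed to [combine_bidirectional()].
#' @param n_streamlines Normalizing constant for the percent-equivalent
#'   report (defaults to the matrix's `n_streamlines` attribute, if any).
#' @return List with `binary` (thresholded matrix), `combined`, and
#'   `threshold` (the [poisson_threshold] fit).
#' @export
threshold_subject <- function(pair_matrix, alpha = 0.05,
                              combine = c("mean", "max"),
                              n_streamlines = NULL) {
  combine <- match.arg(combine)
  if (is.null(n_streamlines))
    n_streamlines <- attr(pair_matrix, "n_streamlines")
  combined <- combine_bidirectional(pair_matrix, method = combine)
  fit <- poisson_threshold(combined, alpha = alpha,
                           n_streamlines = n_streamlines)
  list(binary = apply_individual_threshold(combined, fit),
       combined = combined,
       threshold = fit)
}
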