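#' Design of a simulated tractography cohort
#'
#' Describes the matrix-level generative model used to emulate a cohort of
#' subjects: a fixed set of true anatomical connections that produce high
#' streamline counts, against a background of spurious low counts. For a
#' true edge (unless dropped out in a subject), each direction draws
#' `Binomial(n_streamlines, signal_rate)` counts; all other ordered pairs
#' draw `Poisson(noise_lambda)`. Dropout models a true pathway being missed
#' in an individual subject (both directions revert to noise).
#'
#' @param n_rois Number of regions.
#' @param true_edges Two-column matrix or data frame of ROI indices or
#'   names: the planted connections (unordered pairs).
#' @param n_subjects Cohort size; default 24.
#' @param signal_rate Expected fraction of streamlines reaching the target
#'   for a true connection; default 0.05 (i.e. 1000 of 20,000), at the
#'   upper end of typical individual thresholds.
#' @param noise_lambda Poisson mean of background counts; default 3.
#' @param subject_dropout Probability that a given subject misses a given
#'   true edge; default 0.
#' @param n_streamlines Streamlines per seed; default 20000.
#' @param roi_names Optional ROI names; default `ROI01`, `ROI02`, ...
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_rois, true_edges, n_subjects = 24,
                          signal_rate = 0.05, noise_lambda = 3,
                          subject_dropout = 0, n_streamlines = 20000,
                          roi_names = NULL) {
  if (n_rois < 2) stop("need at least two ROIs")
  if (!(signal_rate > 0 && signal_rate <= 1))
    stop("signal_rate must be in (0, 1]")
  if (noise_lambda < 0) stop("noise_lambda must be nonnegative")
  if (subject_dropout < 0 || subject_dropout >= 1)
    stop("subject_dropout must be in [0, 1)")
  if (is.null(roi_names))
    roi_names <- sprintf("ROI%02d", seq_len(n_rois))
  if (length(roi_names) != n_rois) stop("roi_names length mismatch")
  true_edges <- as.matrix(true_edges)
  if (length(true_edges) == 0L) {
    true_edges <- matrix(integer(0), 0, 2)
  } else {
    if (ncol(true_edges) != 2) stop("true_edges must have two columns")
    if (is.character(true_edges))
      true_edges <- matrix(match(true_edges, roi_names), ncol = 2)
    if (anyNA(true_edges) || any(true_edges < 1) || any(true_edges > n_rois))
      stop("true_edges refer to unknown ROIs")
    if (any(true_edges[, 1] == true_edges[, 2]))
      stop("true_edges must not contain self-pairs")
    true_edges <- t(apply(true_edges, 1, sort))
    true_edges <- unique(true_edges)
  }
  structure(list(n_rois = n_rois, n_subjects = n_subjects,
                 true_edges = true_edges, signal_rate = signal_rate,
                 noise_lambda = noise_lambda,
                 subject_dropout = subject_dropout,
                 n_streamlines = n_streamlines, roi_names = roi_names),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "cohort_design: %d ROIs, %d subjects, %d true edges\n",
    x$n_rois, x$n_subjects, nrow(x$true_edges)))
  cat(sprintf(
    "  signal ~ Binomial(%d, %g), noise ~ Poisson(%g), dropout %g\n",
    x$n_streamlines, x$signal_rate, x$noise_lambda, x$subject_dropout))
  invisible(x)
}

#' Simulate a cohort of subject pair matrices
#'
#' Draws one ordered-pair count matrix per subject under a
#' [cohort_design()]: both directions of every pair are generated
#' independently, so downstream bidirectional combination is exercised.
#' Counts are capped at `n_streamlines`.
#'
#' @param design A [cohort_design()].
#' @param rng_seed Integer seed; identical seeds give identical cohorts.
#' @return List of `n_subjects` integer matrices (class `subject_matrix`
#'   attributes: `n_streamlines`), with ROI dimnames and zero diagonal.
#' @export
simulate_cohort <- function(design, rng_seed = 1) {
  stopifnot(inherits(design, "cohort_design"))
  old <- local_seed(rng_seed)
  on.exit(restore_seed(old))
  r <- design$n_rois
  off <- row(matrix(0, r, r)) != col(matrix(0, r, r))
  lapply(seq_len(design$n_subjects), function(s) {
    m <- matrix(0L, r, r, dimnames = list(design$roi_names, design$roi_names))
    m[off] <- stats::rpois(sum(off), design$noise_lambda)
    if (nrow(design$true_edges)) {
      kept <- stats::runif(nrow(design$true_edges)) >= design$subject_dropout
      for (e in which(kept)) {
        i <- design$true_edges[e, 1]; j <- design$true_edges[e, 2]
        m[i, j] <- stats::rbinom(1, design$n_streamlines, design$signal_rate)
        m[j, i] <- stats::rbinom(1, design$n_streamlines, design$signal_rate)
      }
    }
    m[m > design$n_streamlines] <- design$n_streamlines
    diag(m) <- 0L
    storage.mode(m) <- "integer"
    attr(m, "n_streamlines") <- design$n_streamlines
    m
  })
}

#' Planted-partition benchmark graph
#'
#' Random binary graph with known module structure: within-module edges
#' are Bernoulli(`p_in`), between-module edges Bernoulli(`p_out`). Used to
#' benchmark module-detection recovery.
#'
#' @param module_sizes Integer vector of module sizes.
#' @param p_in,p_out Within/between edge probabilities; requires
#'   `0 <= p_out < p_in <= 1`.
#' @param rng_seed Integer seed.
#' @return List with `graph` (a [tract_graph()]) and `membership` (the
#'   planted assignment).
#' @export
planted_partition_graph <- function(module_sizes, p_in, p_out, rng_seed = 1) {
  if (!(p_in > p_out))
    stop("p_in must exceed p_out (degenerate benchmark otherwise)")
  if (p_out < 0 || p_in > 1) stop("edge probabilities must lie in [0, 1]")
  old <- local_seed(rng_seed)
  on.exit(restore_seed(old))
  n <- sum(module_sizes)
  memb <- rep(seq_along(module_sizes), module_sizes)
  a <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (memb[i] == memb[j]) p_in else p_out
      if (stats::runif(1) < p) {
        a[i, j] <- 1L
        a[j, i] <- 1L
      }
    }
  }
  list(graph = tract_graph(a), membership = memb)
}
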