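#' Group-consensus connectome
#'
#' Aggregates per-subject binary connection matrices into a group
#' percentage matrix — for each pair, the percentage of subjects in whom
#' the connection survived the individual threshold — and a binary group
#' adjacency retaining pairs present in at least `participant_threshold`
#' percent of subjects (so with 24 subjects, 12/24 passes at 50 and 18/24
#' at 75).
#'
#' @param subject_binaries List of symmetric 0/1 matrices, all with the
#'   same ROI names in the same order (dimnames are checked when present).
#' @param participant_threshold Consensus threshold in percent;
#'   conventionally 50 (relaxed) or 75 (stringent).
#' @return Object of class `group_connectome`: list with `percent` (R x R
#'   symmetric matrix of percentages), `graph` (a [tract_graph()]),
#'   `participant_threshold`, `n_subjects`, `roi_names`.
#' @export
group_consensus <- function(subject_binaries, participant_threshold = 50) {
  if (!is.list(subject_binaries) || length(subject_binaries) == 0L)
    stop("need at least one subject matrix")
  if (!is.numeric(participant_threshold) || participant_threshold < 0 ||
      participant_threshold > 100)
    stop("participant_threshold must be a percentage in [0, 100]")
  ref <- subject_binaries[[1L]]
  roi_names <- rownames(ref)
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(nrow(ref)))
  for (s in subject_binaries) {
    if (!identical(dim(s), dim(ref)))
      stop("subject matrices differ in dimension")
    if (!is.null(rownames(s)) && !identical(rownames(s), roi_names))
      stop("subject matrices have mismatched ROI orderings")
  }
  n <- length(subject_binaries)
  counts <- Reduce(`+`, lapply(subject_binaries, function(s) (s != 0) * 1L))
  percent <- 100 * counts / n
  diag(percent) <- 0
  dimnames(percent) <- list(roi_names, roi_names)
  adj <- (percent >= participant_threshold) * 1L
  diag(adj) <- 0L
  structure(list(percent = percent,
                 graph = tract_graph(adj, roi_names),
                 participant_threshold = participant_threshold,
                 n_subjects = n,
                 roi_names = roi_names),
            class = "group_connectome")
}

#' @export
print.group_connectome <- function(x, ...) {
  m <- sum(x$graph$adjacency) / 2
  cat(sprintf(
    "group_connectome: %d ROIs, %d subjects; %d edges at >= %g%% of participants\n",
    length(x$roi_names), x$n_subjects, m, x$participant_threshold))
  invisible(x)
}

#' @export
summary.group_connectome <- function(object, ...) {
  print(object)
  pct <- object$percent[upper.tri(object$percent)]
  cat("pairwise consensus percentages:\n")
  print(summary(pct))
  invisible(object)
}

#' @export
plot.group_connectome <- function(x, ...) {
  n <- length(x$roi_names)
  graphics::image(seq_len(n), seq_len(n), t(x$percent[n:1, ]),
                  zlim = c(0, 100), col = grey.colors(25, 1, 0),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::box()
  invisible(x)
}

#' Round consensus percentages for table output
#'
#' Group percentages are multiples of `100 / n_subjects`; printed tables
#' carry one decimal. This helper applies that rounding.
#'
#' @param x A `group_connectome` or numeric matrix/vector of percentages.
#' @return Same shape as the input, rounded to one decimal.
#' @export
percent_table <- function(x) {
  if (inherits(x, "group_connectome")) x <- x$percent
  round(x, 1)
}
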