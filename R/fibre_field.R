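#' Synthetic fibre-orientation field
#'
#' A voxel grid in which each voxel carries zero or more fibre-orientation
#' distributions — an axially symmetric (Watson-style) distribution with a
#' unit mean axis and a concentration parameter `kappa` — plus integer ROI
#' labels. Voxels on a bundle path get the bundle's local tangent as mean
#' axis; all other voxels are isotropic (`kappa = 0`, every direction
#' equally likely). `kappa = Inf` is the zero-dispersion limit (the axis is
#' followed exactly). Where bundles cross, the shared voxel carries one
#' orientation entry per bundle.
#'
#' @param dims Integer triple: grid size in voxels.
#' @param bundles List of bundles; each a list with `path` (matrix of voxel
#'   coordinates, one row per voxel, tracing the bundle) and optional
#'   `kappa` (concentration, default `Inf`).
#' @param rois Named list of ROI voxel sets, each a matrix of voxel
#'   coordinates (one row per voxel). Every ROI must label at least one
#'   voxel inside the grid.
#' @param voxel_size Edge length of a voxel in mm (scalar or length-3).
#' @param default_kappa Concentration given to bundle voxels whose bundle
#'   does not set its own.
#' @return Object of class `fibre_field`.
#' @examples
#' f <- fibre_field(
#'   dims = c(10, 3, 3),
#'   bundles = list(list(path = cbind(1:10, 2, 2))),
#'   rois = list(A = cbind(1, 2, 2), B = cbind(10, 2, 2))
#' )
#' @export
fibre_field <- function(dims, bundles = list(), rois = list(),
                        voxel_size = 1, default_kappa = Inf) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be three positive integers")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  nvox <- prod(dims)
  orientations <- vector("list", nvox)

  check_coords <- function(xyz, what) {
    xyz <- as.matrix(xyz)
    if (ncol(xyz) != 3L) stop(what, " coordinates must have three columns")
    if (any(xyz < 1L) || any(xyz[, 1] > dims[1]) || any(xyz[, 2] > dims[2]) ||
        any(xyz[, 3] > dims[3]))
      stop(what, " leaves the grid")
    storage.mode(xyz) <- "integer"
    xyz
  }
  lin <- function(xyz) {
    (xyz[, 3] - 1L) * dims[1] * dims[2] + (xyz[, 2] - 1L) * dims[1] + xyz[, 1]
  }

  for (b in bundles) {
    path <- check_coords(b$path, "bundle path")
    kappa <- if (is.null(b$kappa)) default_kappa else b$kappa
    if (is.na(kappa) || kappa < 0) stop("bundle kappa must be >= 0")
    if (nrow(path) < 2L) stop("a bundle path needs at least two voxels")
    centres <- sweep(path - 0.5, 2, voxel_size, `*`)
    for (i in seq_len(nrow(path))) {
      lo <- max(1L, i - 1L); hi <- min(nrow(path), i + 1L)
      tangent <- centres[hi, ] - centres[lo, ]
      nt <- sqrt(sum(tangent^2))
      if (nt == 0) stop("bundle path has a zero-length segment")
      v <- lin(path[i, , drop = FALSE])
      orientations[[v]] <- c(orientations[[v]],
                             list(list(mu = tangent / nt, kappa = kappa)))
    }
  }

  roi_labels <- array(0L, dims)
  roi_names <- names(rois)
  if (length(rois) && (is.null(roi_names) || any(roi_names == "")))
    stop("rois must be a named list")
  for (r in seq_along(rois)) {
    xyz <- check_coords(rois[[r]], paste0("ROI ", roi_names[r]))
    if (nrow(xyz) == 0L) stop("ROI ", roi_names[r], " labels no voxel")
    roi_labels[xyz] <- r
  }
  structure(list(dims = dims, voxel_size = voxel_size,
                 orientations = orientations, roi_labels = roi_labels,
                 roi_names = roi_names %||% character(0)),
            class = "fibre_field")
}

#' @export
print.fibre_field <- function(x, ...) {
  nb <- sum(!vapply(x$orientations, is.null, TRUE))
  cat(sprintf(
    "fibre_field: %s voxels (%g x %g x %g mm), %d bundle voxels, %d ROIs (%s)\n",
    paste(x$dims, collapse = "x"), x$voxel_size[1], x$voxel_size[2],
    x$voxel_size[3], nb, length(x$roi_names),
    paste(x$roi_names, collapse = ", ")))
  invisible(x)
}

#' Straight voxel path between two voxels
#'
#' Convenience builder for bundle paths: linear interpolation between two
#' voxel coordinates, rounded to the voxel grid.
#'
#' @param from,to Voxel coordinate triples.
#' @return Matrix of voxel coordinates, one row per step.
#' @export
straight_path <- function(from, to) {
  n <- max(abs(to - from)) + 1L
  t(vapply(seq_len(n), function(i) {
    round(from + (to - from) * (i - 1) / max(1L, n - 1L))
  }, numeric(3)))
}

# count of orientation entries per voxel, as an array (used in tests)
orientation_count <- function(field, voxel) {
  v <- (voxel[3] - 1L) * field$dims[1] * field$dims[2] +
    (voxel[2] - 1L) * field$dims[1] + voxel[1]
  length(field$orientations[[v]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
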