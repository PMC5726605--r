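#' Streamline propagation policy
#'
#' Tracking parameters for Monte Carlo streamline propagation. Defaults
#' follow the acquisition-scale protocol (20,000 streamlines per seed
#' voxel, 0.5 mm steps, stop at 180 degrees of within-voxel curvature or a
#' 500 mm path limit); simulations at desk scale reduce
#' `n_streamlines_per_voxel`.
#'
#' `polarity` controls how the sign ambiguity of fibre axes is resolved:
#' `"axial"` (default) treats orientations as axes and aligns each sampled
#' direction with the previous step (the first step takes a random sign);
#' `"polar"` follows the stored mean direction as an oriented vector,
#' which is useful for deterministic synthetic flow fields.
#'
#' @param n_streamlines_per_voxel Streamlines launched from every seed
#'   voxel.
#' @param step_mm Step length in mm.
#' @param curvature_stop_deg Stop when the turning accumulated while inside
#'   one voxel exceeds this angle (degrees, in `(0, 180]`).
#' @param max_path_mm Stop when the path length exceeds this limit (mm).
#' @param rng_seed Integer seed.
#' @param polarity `"axial"` or `"polar"`.
#' @return Object of class `streamline_policy`.
#' @export
streamline_policy <- function(n_streamlines_per_voxel = 20000,
                              step_mm = 0.5, curvature_stop_deg = 180,
                              max_path_mm = 500, rng_seed = 1,
                              polarity = c("axial", "polar")) {
  polarity <- match.arg(polarity)
  vals <- c(n_streamlines_per_voxel, step_mm, curvature_stop_deg, max_path_mm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("policy values must be positive and finite")
  if (curvature_stop_deg > 180)
    stop("curvature_stop_deg must lie in (0, 180]")
  structure(list(n_streamlines_per_voxel = as.integer(n_streamlines_per_voxel),
                 step_mm = step_mm, curvature_stop_deg = curvature_stop_deg,
                 max_path_mm = max_path_mm, rng_seed = as.integer(rng_seed),
                 polarity = polarity),
            class = "streamline_policy")
}

#' Propagate Monte Carlo streamlines from a seed ROI
#'
#' Launches `n_streamlines_per_voxel` streamlines from the centre of every
#' voxel of the seed ROI. Each streamline repeatedly samples a direction
#' from the local orientation distribution (in voxels with several
#' orientation entries, the entry whose axis is closest to the incoming
#' direction is used; isotropic voxels sample uniformly on the sphere),
#' resolves the axial sign against the previous step, and advances
#' `step_mm`. It terminates when it leaves the grid, its path exceeds
#' `max_path_mm`, or the turning accumulated within the current voxel
#' exceeds `curvature_stop_deg`.
#'
#' @param field A [fibre_field()].
#' @param seed_roi ROI name or index present in the field.
#' @param policy A [streamline_policy()].
#' @return Object of class `visitation_map`: per-voxel counts of distinct
#'   visiting streamlines, the number launched, termination causes, and
#'   per-ROI arrival counts (streamlines that visited at least one voxel
#'   of each ROI).
#' @export
propagate_streamlines <- function(field, seed_roi, policy = streamline_policy()) {
  stopifnot(inherits(field, "fibre_field"), inherits(policy, "streamline_policy"))
  if (is.character(seed_roi)) {
    seed_id <- match(seed_roi, field$roi_names)
    if (is.na(seed_id)) stop("seed ROI '", seed_roi, "' not present in field")
  } else seed_id <- as.integer(seed_roi)
  seed_vox <- which(field$roi_labels == seed_id)
  if (length(seed_vox) == 0L) stop("seed ROI is empty")

  dims <- field$dims
  vs <- field$voxel_size
  nvox <- prod(dims)
  counts <- integer(nvox)
  n_rois <- length(field$roi_names)
  arrivals <- integer(max(n_rois, 1L))
  terminations <- c(exit_grid = 0L, max_path = 0L, curvature = 0L)
  labels <- as.integer(field$roi_labels)
  max_steps <- ceiling(policy$max_path_mm / policy$step_mm)

  old <- local_seed(policy$rng_seed)
  on.exit(restore_seed(old))

  seed_xyz <- arrayInd(seed_vox, dims)
  for (sv in seq_along(seed_vox)) {
    start <- (seed_xyz[sv, ] - 0.5) * vs
    for (k in seq_len(policy$n_streamlines_per_voxel)) {
      res <- trace_streamline(start, dims, vs, field$orientations, labels,
                              policy, max_steps, n_rois)
      counts[res$visited] <- counts[res$visited] + 1L
      if (n_rois) arrivals <- arrivals + res$roi_hit
      terminations[res$cause] <- terminations[res$cause] + 1L
    }
  }
  structure(list(counts = array(counts, dims), dims = dims,
                 voxel_size = vs, seed_roi = seed_id,
                 roi_names = field$roi_names,
                 roi_labels = field$roi_labels,
                 n_launched = length(seed_vox) * policy$n_streamlines_per_voxel,
                 n_per_voxel = policy$n_streamlines_per_voxel,
                 terminations = terminations,
                 roi_arrivals = if (n_rois)
                   stats::setNames(arrivals, field$roi_names) else integer(0)),
            class = "visitation_map")
}

# one streamline; returns visited voxel ids, ROI hits, termination cause
trace_streamline <- function(start, dims, vs, orientations, labels,
                             policy, max_steps, n_rois) {
  visited <- logical(length(labels))
  roi_hit <- if (n_rois) logical(n_rois) else logical(0)
  pos <- start
  dir_prev <- NULL
  cur_voxel <- -1L
  turn_in_voxel <- 0
  cause <- "max_path"
  for (step in seq_len(max_steps)) {
    iv <- floor(pos / vs) + 1
    if (any(iv < 1) || any(iv > dims)) { cause <- "exit_grid"; break }
    v <- (iv[3] - 1) * dims[1] * dims[2] + (iv[2] - 1) * dims[1] + iv[1]
    if (v != cur_voxel) {
      cur_voxel <- v
      turn_in_voxel <- 0
      if (!visited[v]) {
        visited[v] <- TRUE
        lb <- labels[v]
        if (lb > 0L) roi_hit[lb] <- TRUE
      }
    }
    d <- sample_step_direction(orientations[[v]], dir_prev, policy$polarity)
    if (!is.null(dir_prev)) {
      turn <- acos(min(1, max(-1, sum(d * dir_prev)))) * 180 / pi
      turn_in_voxel <- turn_in_voxel + turn
      if (turn_in_voxel > policy$curvature_stop_deg) {
        cause <- "curvature"
        break
      }
    }
    pos <- pos + d * policy$step_mm
    dir_prev <- d
  }
  list(visited = which(visited), roi_hit = roi_hit, cause = cause)
}

sample_step_direction <- function(entries, dir_prev, polarity) {
  if (is.null(entries)) {
    d <- random_unit_vector()
  } else {
    if (length(entries) > 1L && !is.null(dir_prev)) {
      dots <- vapply(entries, function(e) abs(sum(e$mu * dir_prev)), 0)
      e <- entries[[which.max(dots)]]
    } else if (length(entries) > 1L) {
      e <- entries[[sample.int(length(entries), 1L)]]
    } else e <- entries[[1L]]
    d <- sample_watson(e$mu, e$kappa)
  }
  if (polarity == "axial") {
    if (is.null(dir_prev)) {
      if (stats::runif(1) < 0.5) d <- -d
    } else if (sum(d * dir_prev) < 0) d <- -d
  }
  d
}

# draw from an axially symmetric Watson-style distribution around axis mu;
# kappa = 0 is uniform on the sphere, kappa = Inf returns mu exactly
sample_watson <- function(mu, kappa) {
  if (is.infinite(kappa)) return(mu)
  if (kappa == 0) return(random_unit_vector())
  # rejection sampling of u = cos(theta) with density prop. to exp(kappa u^2)
  repeat {
    u <- stats::runif(1, -1, 1)
    if (stats::runif(1) < exp(kappa * (u * u - 1))) break
  }
  phi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(1 - u * u)
  # orthonormal basis around mu
  ref <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  u * mu + s * (cos(phi) * e1 + sin(phi) * e2)
}

random_unit_vector <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  s <- sqrt(1 - z * z)
  c(s * cos(phi), s * sin(phi), z)
}

#' @export
print.visitation_map <- function(x, ...) {
  cat(sprintf(
    "visitation_map: seed ROI %s, %d streamlines launched, %d voxels visited\n",
    if (length(x$roi_names)) x$roi_names[x$seed_roi] else x$seed_roi,
    x$n_launched, sum(x$counts > 0)))
  cat("terminations: ",
      paste(names(x$terminations), x$terminations, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# logical mask of an ROI stored with a map or field
roi_mask <- function(x, roi) {
  id <- if (is.character(roi)) match(roi, x$roi_names) else as.integer(roi)
  if (is.na(id)) stop("unknown ROI: ", roi)
  x$roi_labels == id
}

#' Fraction of launched streamlines that reached an ROI
#'
#' @param map A [visitation_map].
#' @param roi ROI name or index.
#' @return Fraction in `[0, 1]`.
#' @export
arrival_fraction <- function(map, roi) {
  stopifnot(inherits(map, "visitation_map"))
  id <- if (is.character(roi)) match(roi, map$roi_names) else as.integer(roi)
  if (is.na(id)) stop("unknown ROI: ", roi)
  map$roi_arrivals[id] / map$n_launched
}

#' Build a subject pair matrix from a fibre field
#'
#' Runs [propagate_streamlines()] once per ROI and fills the ordered-pair
#' matrix with [extract_pair_value()] — the maximum visitation count within
#' each target ROI. The matrix's `n_streamlines` attribute is set to the
#' per-voxel launch count, the scale of the extracted maxima.
#'
#' @inheritParams propagate_streamlines
#' @return Integer matrix of ordered pairs with ROI dimnames.
#' @export
subject_matrix_from_field <- function(field, policy = streamline_policy()) {
  stopifnot(inherits(field, "fibre_field"))
  r <- length(field$roi_names)
  if (r < 2) stop("field needs at least two ROIs")
  m <- matrix(0L, r, r, dimnames = list(field$roi_names, field$roi_names))
  for (s in seq_len(r)) {
    pol <- policy
    pol$rng_seed <- policy$rng_seed + s - 1L
    map <- propagate_streamlines(field, s, pol)
    for (t in seq_len(r)) {
      if (t == s) next
      m[s, t] <- extract_pair_value(map, roi_mask(map, t))
    }
  }
  attr(m, "n_streamlines") <- policy$n_streamlines_per_voxel
  m
}
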