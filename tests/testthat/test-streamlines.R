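# small fields reused across tests
straight_field <- function(nx = 20, kappa = Inf) {
  fibre_field(
    dims = c(nx, 1, 1),
    bundles = list(list(path = cbind(seq_len(nx), 1, 1), kappa = kappa)),
    rois = list(A = cbind(1:5, 1, 1), B = cbind(nx, 1, 1))
  )
}

test_that("fibre fields validate bundles and ROIs and mark orientations", {
  f <- straight_field()
  # every bundle voxel's mean axis is tangent to the (straight) path
  for (x in c(1, 7, 19)) {
    v <- tractnet:::orientation_count(f, c(x, 1, 1))
    expect_identical(v, 1L)
  }
  e <- f$orientations[[3]][[1]]
  expect_equal(e$mu, c(1, 0, 0))
  # zero bundles: everything isotropic
  f0 <- fibre_field(c(4, 4, 4), rois = list(A = cbind(1, 1, 1)))
  expect_true(all(vapply(f0$orientations, is.null, TRUE)))
  # two crossing bundles share a voxel with two orientation entries
  fx <- fibre_field(
    dims = c(5, 5, 1),
    bundles = list(list(path = cbind(1:5, 3, 1)),
                   list(path = cbind(3, 1:5, 1))),
    rois = list(A = cbind(1, 3, 1), B = cbind(5, 3, 1))
  )
  expect_identical(tractnet:::orientation_count(fx, c(3, 3, 1)), 2L)
  expect_identical(tractnet:::orientation_count(fx, c(2, 3, 1)), 1L)
  # errors
  expect_error(fibre_field(c(5, 1, 1),
                           bundles = list(list(path = cbind(1:9, 1, 1)))),
               "leaves the grid")
  expect_error(fibre_field(c(5, 1, 1), rois = list(A = cbind(9, 1, 1))),
               "leaves the grid")
})

test_that("zero-dispersion straight bundles deliver every streamline to the target", {
  f <- straight_field()
  pol <- streamline_policy(n_streamlines_per_voxel = 100, rng_seed = 1,
                           polarity = "polar")
  map <- propagate_streamlines(f, "A", pol)
  expect_equal(unname(arrival_fraction(map, "B")), 1.0)
  # all 500 streamlines traverse the far ROI voxel: extracted value 500
  expect_equal(extract_pair_value(map, tractnet:::roi_mask(map, "B")), 500)
  # conservation: every launched streamline terminates exactly once
  expect_equal(sum(map$terminations), map$n_launched)
  # visitation at a seed voxel is at least what was launched from it
  expect_gte(map$counts[1, 1, 1], pol$n_streamlines_per_voxel)
})

test_that("axial tracking with a random first sign sends about half each way", {
  f <- straight_field()
  pol <- streamline_policy(n_streamlines_per_voxel = 200, rng_seed = 8,
                           polarity = "axial")
  map <- propagate_streamlines(f, "A", pol)
  fr <- unname(arrival_fraction(map, "B"))
  expect_gt(fr, 0.35)
  expect_lt(fr, 0.65)
})

test_that("an orientation reversal under a 90-degree curvature stop blocks all arrivals", {
  # +x flow on the first half, -x flow on the second: following the field
  # would require a 180-degree turn inside the interface voxel
  f <- fibre_field(
    dims = c(20, 1, 1),
    bundles = list(list(path = cbind(1:10, 1, 1)),
                   list(path = cbind(20:11, 1, 1))),
    rois = list(A = cbind(1:5, 1, 1), B = cbind(20, 1, 1))
  )
  pol <- streamline_policy(n_streamlines_per_voxel = 50,
                           curvature_stop_deg = 90, rng_seed = 2,
                           polarity = "polar")
  map <- propagate_streamlines(f, "A", pol)
  expect_equal(unname(arrival_fraction(map, "B")), 0)
  expect_gt(map$terminations[["curvature"]], 0)
  # the same field is transparent to axial tracking, which ignores axis sign
  pol_ax <- streamline_policy(n_streamlines_per_voxel = 50,
                              curvature_stop_deg = 90, rng_seed = 2,
                              polarity = "axial")
  map_ax <- propagate_streamlines(f, "A", pol_ax)
  expect_gt(unname(arrival_fraction(map_ax, "B")), 0)
})

test_that("isotropic visitation decays with distance from the seed", {
  f <- fibre_field(c(9, 9, 9), rois = list(S = cbind(5, 5, 5)))
  centre <- c(5, 5, 5)
  grid <- as.matrix(expand.grid(1:9, 1:9, 1:9))
  dist <- sqrt(rowSums(sweep(grid, 2, centre)^2))
  bins <- pmin(floor(dist), 4)
  mean_by_bin <- matrix(0, 10, 5)
  for (s in 1:10) {
    pol <- streamline_policy(n_streamlines_per_voxel = 150,
                             max_path_mm = 12, rng_seed = 100 + s)
    map <- propagate_streamlines(f, "S", pol)
    mean_by_bin[s, ] <- tapply(as.vector(map$counts), bins, mean)
  }
  avg <- colMeans(mean_by_bin)
  expect_true(all(diff(avg) <= 0))
})

test_that("identical seeds give bit-identical maps and policies validate", {
  f <- straight_field(10, kappa = 30)
  pol <- streamline_policy(n_streamlines_per_voxel = 40, rng_seed = 5)
  m1 <- propagate_streamlines(f, "A", pol)
  m2 <- propagate_streamlines(f, "A", pol)
  expect_identical(m1$counts, m2$counts)
  m3 <- propagate_streamlines(f, "A",
                              streamline_policy(n_streamlines_per_voxel = 40,
                                                rng_seed = 6))
  expect_false(identical(m1$counts, m3$counts))
  expect_error(streamline_policy(step_mm = 0), "positive")
  expect_error(streamline_policy(max_path_mm = Inf), "finite")
  expect_error(streamline_policy(curvature_stop_deg = 200), "180")
  expect_error(propagate_streamlines(f, "C"), "not present")
  f2 <- fibre_field(c(4, 1, 1), rois = list(A = cbind(1, 1, 1)))
  f2$roi_labels[1, 1, 1] <- 0L   # emptied ROI
  expect_error(propagate_streamlines(f2, "A"), "empty")
})

test_that("a subject pair matrix built from a field shows the bundle and little else", {
  f <- fibre_field(
    dims = c(12, 3, 1),
    bundles = list(list(path = cbind(1:12, 2, 1), kappa = Inf)),
    rois = list(A = cbind(1, 2, 1), B = cbind(12, 2, 1),
                C = cbind(6, 1, 1))   # off-bundle region
  )
  pol <- streamline_policy(n_streamlines_per_voxel = 60, rng_seed = 3,
                           polarity = "polar")
  m <- subject_matrix_from_field(f, pol)
  expect_equal(m["A", "B"], 60)
  expect_equal(m["B", "A"], 0)   # polar mode follows +mu, away from A
  expect_identical(attr(m, "n_streamlines"), 60L)
  expect_true(all(diag(m) == 0))
})
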