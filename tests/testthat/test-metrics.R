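test_that("voxelization reproduces analytic volumes and translates rigidly", {
  cube <- box_mesh(c(0, 0, 0), c(2, 2, 2))
  v <- voxelize(cube, spacing = 0.5)
  expect_equal(sum(v$occ) * 0.5^3, 8, tolerance = 0.02)
  shifted <- transform_mesh(cube, t = c(7.3, -2.1, 4.4))
  v2 <- voxelize(shifted, spacing = 0.5)
  expect_identical(sum(v2$occ), sum(v$occ))
  expect_equal(v2$origin - v$origin, c(7.3, -2.1, 4.4), tolerance = 1e-9)
})

test_that("non-watertight meshes are refused with the offending edges named", {
  cube <- box_mesh()
  cube$faces <- cube$faces[-1, ]
  expect_error(voxelize(cube), "open")
})

test_that("DICE has its closed-form fixed points", {
  a <- box_mesh(c(0, 0, 0), c(4, 4, 4))
  b <- box_mesh(c(2, 0, 0), c(6, 4, 4))   # half-overlapping equal boxes
  c2 <- box_mesh(c(10, 0, 0), c(14, 4, 4)) # disjoint
  expect_equal(voxel_dice(a, a, 0.5), 1)
  expect_equal(voxel_dice(a, b, 0.5), 0.5, tolerance = 0.02)
  expect_equal(voxel_dice(a, c2, 0.5), 0)
  # empty-vs-empty convention
  expect_warning(d <- dice(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))),
                 "empty")
  expect_equal(d, 1)
  # disjoint occupancies on a shared grid
  lo <- pmin(apply(a$vertices, 2, min), apply(c2$vertices, 2, min))
  hi <- pmax(apply(a$vertices, 2, max), apply(c2$vertices, 2, max))
  va <- voxelize(a, 0.5, rbind(lo, hi)); vc <- voxelize(c2, 0.5, rbind(lo, hi))
  expect_equal(sum(va$occ & vc$occ), 0)
})

test_that("DICE grows monotonically with overlap in nested box families", {
  a <- box_mesh(c(0, 0, 0), c(4, 4, 4))
  d <- vapply(c(3, 2, 1, 0), function(s)
    voxel_dice(a, box_mesh(c(s, 0, 0), c(s + 4, 4, 4)), 0.5), numeric(1))
  expect_true(all(diff(d) > 0))
  expect_equal(d[4], 1)
})

test_that("surface metrics are exact on identical meshes and parallel planes", {
  m <- fx_phantom()
  expect_equal(nsd(m, m, tau = 1, n = 2000), 1)
  expect_equal(hd95(m, m, n = 2000), 0)
  expect_equal(masd(m, m, n = 2000), 0)
  plane <- function(z) labeled_mesh(
    rbind(c(0, 0, z), c(10, 0, z), c(10, 10, z), c(0, 10, z)),
    rbind(c(1, 2, 3), c(1, 3, 4)), validate = FALSE)
  expect_equal(masd(plane(0), plane(3), n = 4000), 3, tolerance = 1e-9)
  expect_equal(hd95(plane(0), plane(3), n = 4000), 3, tolerance = 1e-9)
  expect_equal(nsd(plane(0), plane(2), tau = 1, n = 2000), 0)
})

test_that("surface metrics match exhaustive oracles on small point sets", {
  set.seed(5)
  A <- matrix(stats::rnorm(90, sd = 5), ncol = 3)
  B <- matrix(stats::rnorm(90, sd = 5), ncol = 3)
  D <- sqrt(spinefit:::dist2_matrix_cpp(A, B))
  dab <- apply(D, 1, min); dba <- apply(D, 2, min)
  mesh_of <- function(P) labeled_mesh(P, matrix(c(1L, 2L, 3L), 1),
                                      validate = FALSE)
  d <- spinefit:::surface_distances_points(A, B)
  expect_equal(d$ab, dab, tolerance = 1e-12)
  expect_equal(d$ba, dba, tolerance = 1e-12)
  expect_equal(max(stats::quantile(dab, 0.95, names = FALSE),
                   stats::quantile(dba, 0.95, names = FALSE)),
               hd95(A, B))
  expect_equal((mean(dab) + mean(dba)) / 2, masd(A, B))
  tau <- stats::median(c(dab, dba))
  expect_equal((sum(dab <= tau) + sum(dba <= tau)) / 60, nsd(A, B, tau = tau))
})

test_that("concentric spheres match closed-form surface distances", {
  s1 <- sphere_mesh(10, n_theta = 48, n_phi = 24)
  s2 <- sphere_mesh(12, n_theta = 48, n_phi = 24)
  expect_equal(masd(s1, s2, n = 8000), 2, tolerance = 0.05)
  expect_equal(hd95(s1, s2, n = 8000), 2, tolerance = 0.1)
  expect_equal(nsd(s1, s2, tau = 1, n = 4000), 0, tolerance = 0.01)
  expect_equal(nsd(s1, s2, tau = 3, n = 4000), 1, tolerance = 0.01)
})

test_that("surface metrics are symmetric and converge with sample count", {
  a <- fx_phantom()
  b <- generate_vertebra(phantom_params(body_a = 20, body_height = 32))
  expect_equal(masd(a, b, n = 4000), masd(b, a, n = 4000), tolerance = 0.05)
  expect_equal(nsd(a, b, n = 4000), nsd(b, a, n = 4000), tolerance = 0.02)
  m1 <- masd(a, b, n = 5000); m2 <- masd(a, b, n = 10000)
  expect_lt(abs(m1 - m2) / m2, 0.01)
})

test_that("pose errors agree with the quaternion-angle formula", {
  mod <- fx_model()
  k <- length(mod$eigenvalues)
  z <- pose_shape_params(coeffs = rep(0, k))
  expect_equal(unlist(pose_error(z, z)), c(rotation_deg = 0,
                                           translation_mm = 0,
                                           coeff_rmse = 0))
  ten <- pose_shape_params(rotation = c(0, 0, 10 * pi / 180),
                           coeffs = rep(0, k))
  expect_equal(pose_error(ten, z)$rotation_deg, 10, tolerance = 1e-9)
  quat_angle <- function(R) {
    qw <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
    2 * acos(min(1, qw)) * 180 / pi
  }
  set.seed(9)
  for (i in 1:5) {
    a <- pose_shape_params(rotation = stats::rnorm(3, sd = 0.5),
                           translation = stats::rnorm(3), coeffs = rep(0, k))
    b <- pose_shape_params(rotation = stats::rnorm(3, sd = 0.5),
                           translation = stats::rnorm(3), coeffs = rep(0, k))
    Rrel <- crossprod(axis_angle_to_matrix(a$rotation),
                      axis_angle_to_matrix(b$rotation))
    expect_equal(pose_error(a, b)$rotation_deg, quat_angle(Rrel),
                 tolerance = 1e-9)
  }
})

test_that("the combined metric report carries all fields", {
  a <- fx_phantom()
  rep1 <- metric_report(a, a, spacing = 1, n = 2000)
  expect_equal(rep1$dice, 1, tolerance = 1e-6)
  expect_equal(rep1$nsd, 1)
  expect_equal(rep1$masd, 0)
  expect_true(is.na(rep1$rotation_deg))
})
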