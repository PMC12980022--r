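test_that("zero-parameter propagation reproduces the template annotation", {
  mod <- fx_model()
  for (side in c("left", "right")) {
    tpl <- mod$path_annotations[[side]]
    pl <- propagate_path(mod, zero_params(mod), side = side)
    expect_equal(pl$entry,
                 spinefit:::eval_barycentric(mod$template, tpl$entry_face,
                                             tpl$entry_bary),
                 tolerance = 1e-12)
    expect_equal(pl$diameter, 5)
  }
})

test_that("path propagation commutes exactly with rigid motion", {
  mod <- fx_model()
  k <- length(mod$eigenvalues)
  base <- pose_shape_params(coeffs = rep(0.7, k))
  pl0 <- propagate_path(mod, base, side = "left")
  tg <- c(4, -6, 2)
  plt <- propagate_path(mod, pose_shape_params(translation = tg,
                                               coeffs = base$coeffs),
                        side = "left")
  expect_equal(plt$entry, pl0$entry + tg, tolerance = 1e-13)
  expect_equal(plt$exit, pl0$exit + tg, tolerance = 1e-13)
  Rg <- random_rotation(5)
  plr <- propagate_path(mod,
                        pose_shape_params(rotation = matrix_to_axis_angle(Rg),
                                          coeffs = base$coeffs),
                        side = "left")
  expect_equal(plr$entry, as.numeric(Rg %*% pl0$entry), tolerance = 1e-12)
  expect_equal(plr$exit, as.numeric(Rg %*% pl0$exit), tolerance = 1e-12)
})

test_that("breach verdicts follow the minimum wall distance rule on tubes", {
  tube <- tube_phantom(radius = 4, n_theta = 256)
  wall_r <- 4 * cos(pi / 256)
  centred <- breach_check(path_plan(c(0, 0, -8), c(0, 0, 8), side = "left"), tube)
  expect_equal(centred$min_wall_distance_mm, wall_r, tolerance = 0.01)
  expect_false(centred$breach)
  off2 <- breach_check(path_plan(c(2, 0, -8), c(2, 0, 8), side = "left"), tube)
  expect_equal(off2$min_wall_distance_mm, wall_r - 2, tolerance = 0.01)
  expect_true(off2$breach)
  # verdict flips exactly at the 2.5 mm threshold (strict-below rule)
  d_at <- centred$min_wall_distance_mm - 2.5
  at <- breach_check(path_plan(c(d_at, 0, -8), c(d_at, 0, 8), side = "left"),
                     tube)
  expect_false(at$breach)
  just_in <- breach_check(path_plan(c(d_at + 0.08, 0, -8), c(d_at + 0.08, 0, 8),
                                    side = "left"), tube)
  expect_true(just_in$breach)
})

test_that("wall distances agree with a brute-force dense sampling oracle", {
  tube <- tube_phantom(radius = 4, n_theta = 64)
  wall_faces <- which(apply(matrix(tube$region_labels[tube$faces] == "pedicle_left",
                                   ncol = 3), 1, all))
  dense <- sample_surface(tube, 200000L, seed = 99, faces = wall_faces)
  set.seed(7)
  for (i in 1:4) {
    off <- stats::runif(2, -2, 2)
    a <- c(off[1], off[2], -8); b <- c(off[1], off[2], 8)
    oracle <- min(spinefit:::point_segment_distance(dense, a, b))
    got <- breach_check(path_plan(a, b, side = "left"), tube,
                        seed = i)$min_wall_distance_mm
    expect_lt(abs(got - oracle), 0.05)
  }
})

crossprod3_test <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  v / sqrt(sum(v^2))
}

test_that("breach verdicts are monotone in the phantom pedicle radius", {
  prev <- Inf
  for (r in c(6, 5, 4, 3)) {
    m <- generate_vertebra(phantom_params(pedicle_radius = r))
    ax <- m$pedicle_axes$left
    # fixed 1.5 mm lateral offset from the axis
    d <- ax$p1 - ax$p0; d <- d / sqrt(sum(d^2))
    perp <- crossprod3_test(d, c(0, 0, 1))
    a <- ax$p0 + 1.5 * perp; b <- ax$p1 + 1.5 * perp
    pl <- breach_check(path_plan(a, b, side = "left"), m)
    expect_lte(pl$min_wall_distance_mm, prev + 1e-9)
    prev <- pl$min_wall_distance_mm
  }
  # the narrowest tube must breach at that offset, the widest must not
  expect_true(prev < 2.5)
})

test_that("the triangulation baseline recovers noise-free paths exactly", {
  m <- fx_phantom()
  cams <- biplanar_cameras(colMeans(m$vertices))
  ax <- m$pedicle_axes$left
  uv_of <- function(p) lapply(cams, function(cm)
    as.numeric(project_points(cm, rbind(p))$uv))
  pl <- geoplan_triangulate(uv_of(ax$p0), uv_of(ax$p1), cams, side = "left")
  expect_lt(sqrt(sum((pl$entry - ax$p0)^2)), 1e-6)
  expect_lt(sqrt(sum((pl$exit - ax$p1)^2)), 1e-6)
  expect_equal(pl$diameter, 5)
  # a missing endpoint in one view fails that pedicle only
  bad <- uv_of(ax$p0); bad[[2]] <- NA
  expect_error(geoplan_triangulate(bad, uv_of(ax$p1), cams, side = "left"),
               class = "spinefit_planning_failure")
})

test_that("noisy baseline endpoint errors match a Monte-Carlo triangulation oracle", {
  m <- fx_phantom()
  cams <- biplanar_cameras(colMeans(m$vertices))
  ax <- m$pedicle_axes$left
  uv0 <- lapply(cams, function(cm)
    as.numeric(project_points(cm, rbind(ax$p0))$uv))
  set.seed(11)
  errs <- replicate(200, {
    uvn <- lapply(uv0, function(u) u + stats::rnorm(2, 0, 2))
    sqrt(sum((triangulate(uvn[[1]], uvn[[2]], cams[[1]], cams[[2]])$point -
                ax$p0)^2))
  })
  # analytic scale: 2 px noise at depth z maps to ~2 z/f mm per view
  z <- project_points(cams[[1]], rbind(ax$p0))$depth[1]
  scale_mm <- 2 * z / cams[[1]]$K[1, 1]
  expect_gt(mean(errs), 0.3 * scale_mm)
  expect_lt(mean(errs), 3 * scale_mm)
})

test_that("bipedicular success logic matches the truth table", {
  ok <- path_plan(c(0, 0, 0), c(0, 0, 10), min_wall_distance_mm = 4,
                  breach = FALSE)
  br <- path_plan(c(0, 0, 0), c(0, 0, 10), min_wall_distance_mm = 1,
                  breach = TRUE)
  fail <- simpleError("planning failure")
  expect_true(plan_success(ok, ok))
  expect_false(plan_success(ok, br))
  expect_false(plan_success(br, ok))
  expect_false(plan_success(br, br))
  expect_false(plan_success(ok, fail))
  expect_false(plan_success(fail, fail))
})

test_that("path plans serialize to the documented JSON schema", {
  pl <- path_plan(c(1, 2, 3), c(4, 5, 6), side = "right",
                  min_wall_distance_mm = 3.2, breach = FALSE)
  path <- tempfile(fileext = ".json")
  write_plan(pl, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_named(back, c("side", "entry_mm", "exit_mm", "diameter_mm",
                       "min_wall_distance_mm", "breach"))
  expect_equal(back$entry_mm, c(1, 2, 3))
  expect_false(back$breach)
})
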