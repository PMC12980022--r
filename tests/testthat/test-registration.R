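test_that("noise-free triangulation recovers 3D points exactly", {
  cams <- fx_cams()
  p <- c(4.2, -7.1, 9.3)
  ua <- project_points(cams$ap, rbind(p))$uv[1, ]
  ub <- project_points(cams$lat, rbind(p))$uv[1, ]
  tr <- triangulate(ua, ub, cams$ap, cams$lat)
  expect_lt(sqrt(sum((tr$point - p)^2)), 1e-6)
  expect_lt(tr$residual, 1e-9)
  expect_equal(tr$angle_deg, 90, tolerance = 0.05)
})

test_that("near-parallel rays raise a degenerate-geometry error naming the angle", {
  cam <- fx_cams()$ap
  expect_error(triangulate(c(40, 40), c(41, 40), cam, cam),
               "deg", class = "spinefit_degenerate_geometry")
})

test_that("symmetric pixel perturbations move the midpoint within the depth-scaled bound", {
  cams <- fx_cams()
  p <- c(0, 0, 0)
  ua <- project_points(cams$ap, rbind(p))$uv[1, ]
  ub <- project_points(cams$lat, rbind(p))$uv[1, ]
  z <- project_points(cams$ap, rbind(p))$depth[1]
  f <- cams$ap$K[1, 1]
  for (d in list(c(1, 0), c(0, 1), c(-1, -1))) {
    tr <- triangulate(ua + d, ub - d, cams$ap, cams$lat)
    bound <- 2 * sqrt(2) * z / f  # 1 px in each view, orthogonal geometry
    expect_lt(sqrt(sum((tr$point - p)^2)), bound)
  }
})

test_that("pose initialization from exact detections recovers the pose", {
  mod <- fx_model()
  Rg <- random_rotation(51); tg <- c(8, -5, 12)
  params <- pose_shape_params(rotation = matrix_to_axis_angle(Rg),
                              translation = tg,
                              coeffs = rep(0, length(mod$eigenvalues)))
  mesh <- predict(mod, params)
  cams <- biplanar_cameras(colMeans(mesh$vertices))
  dets <- lapply(cams, function(cm) simulate_detections(mesh, cm))
  init <- initialize_pose(dets, cams, mod)
  expect_false(init$report$fallback)
  expect_equal(init$report$n_common, 10)
  pe <- pose_error(init$params, params)
  expect_lt(pe$rotation_deg, 1e-4)
  expect_lt(pe$translation_mm, 1e-4)
  expect_equal(init$params$scale, 1, tolerance = 1e-6)
})

test_that("the three-landmark rule gates the backup fallback exactly", {
  mod <- fx_model()
  mesh <- predict(mod, zero_params(mod))
  cams <- biplanar_cameras(colMeans(mesh$vertices))
  dets <- lapply(cams, function(cm) simulate_detections(mesh, cm))
  # exactly 3 in common: keep 3 anatomical landmarks in view 1
  d1 <- dets[[1]]
  keep <- c("body_left", "body_superior", "process_spinous_tip")
  d1$present[d1$landmark_name %in% LANDMARK_NAMES &
             !(d1$landmark_name %in% keep)] <- FALSE
  init3 <- initialize_pose(list(d1, dets[[2]]), cams, mod)
  expect_false(init3$report$fallback)
  expect_setequal(init3$report$landmarks, keep)
  # oracle: closed-form similarity fit on the 3 triangulated points
  tri <- t(sapply(keep, function(nm) {
    a <- d1[d1$landmark_name == nm, ]; b <- dets[[2]][dets[[2]]$landmark_name == nm, ]
    triangulate(c(a$u_px, a$v_px), c(b$u_px, b$v_px), cams[[1]], cams[[2]])$point
  }))
  tp <- mod$template$vertices[mod$template$landmark_indices[keep], ]
  fit <- spinefit:::similarity_fit(tp, tri)
  expect_equal(init3$params$translation, fit$t, tolerance = 1e-9)
  expect_equal(axis_angle_to_matrix(init3$params$rotation), fit$R,
               tolerance = 1e-9)
  # below 3: all anatomical landmarks dropped in one view -> fallback
  d1$present[d1$landmark_name %in% LANDMARK_NAMES] <- FALSE
  initf <- initialize_pose(list(d1, dets[[2]]), cams, mod)
  expect_true(initf$report$fallback)
  # and with the backups also gone, initialization fails
  d1$present <- FALSE
  expect_error(initialize_pose(list(d1, dets[[2]]), cams, mod),
               class = "spinefit_init_failure")
})

test_that("initialization is equivariant under a rigid world transform", {
  mod <- fx_model()
  mesh <- predict(mod, zero_params(mod))
  cams <- biplanar_cameras(colMeans(mesh$vertices))
  dets <- lapply(cams, function(cm) simulate_detections(mesh, cm))
  init0 <- initialize_pose(dets, cams, mod)
  Rg <- random_rotation(77); tg <- c(-15, 9, 4)
  mesh2 <- transform_mesh(mesh, Rg, tg)
  cams2 <- lapply(cams, function(cm)
    camera(cm$K, cm$R %*% t(Rg), as.numeric(cm$t - cm$R %*% t(Rg) %*% tg),
           cm$height, cm$width))
  dets2 <- lapply(cams2, function(cm) simulate_detections(mesh2, cm))
  init1 <- initialize_pose(dets2, cams2, mod)
  R0 <- axis_angle_to_matrix(init0$params$rotation)
  R1 <- axis_angle_to_matrix(init1$params$rotation)
  expect_lt(rotation_angle_deg(R1, Rg %*% R0), 1e-6)
  expect_equal(init1$params$translation,
               as.numeric(Rg %*% init0$params$translation + tg),
               tolerance = 1e-6)
})

test_that("a warning is issued for weakly separated views", {
  mod <- fx_model()
  mesh <- predict(mod, zero_params(mod))
  tgt <- colMeans(mesh$vertices)
  c1 <- look_at_camera(tgt, c(0, 1, 0), 500, 500, 96, 96)
  c2 <- look_at_camera(tgt, c(sin(0.1), cos(0.1), 0), 500, 500, 96, 96)
  dets <- lapply(list(c1, c2), function(cm) simulate_detections(mesh, cm))
  expect_warning(initialize_pose(dets, list(c1, c2), mod), "weak")
})

test_that("the optimizer stays at an exact optimum and returns best-seen parameters", {
  mod <- fx_model()
  cfg <- fx_render()
  cams <- fx_cams()
  truth <- pose_shape_params(rotation = c(0.02, -0.03, 0.05),
                             translation = c(2, -1, 3),
                             coeffs = rep(0.3, length(mod$eigenvalues)))
  targets <- lapply(render_instance(mod, truth, cams, cfg), function(v) v$image)
  fit <- reconstruct(mod, targets, cams, truth,
                     config = optimization_config(stage_iters = c(10, 10)),
                     render_config = cfg)
  expect_lte(fit$final_loss, fit$initial_loss)
  expect_lt(max(abs(coef(fit) - c(truth$rotation, truth$translation,
                                  truth$coeffs))), 1e-3)
  expect_true(all(is.finite(fit$loss_trace)))
})

test_that("a zero-gradient metric leaves the parameters untouched", {
  mod <- fx_model()
  cfg <- fx_render()
  cams <- fx_cams()
  const_metric <- similarity_metric(
    "const", function(r, t) 0.5,
    function(r, t) lapply(r, function(v) {
      m <- spinefit:::as_image(v); m[] <- 0; m
    }))
  init <- pose_shape_params(rotation = c(0.1, 0, 0), translation = c(5, 0, 0),
                            coeffs = rep(0, length(mod$eigenvalues)))
  targets <- lapply(render_instance(mod, init, cams, cfg), function(v) v$image)
  fit <- reconstruct(mod, targets, cams, init, metric = const_metric,
                     config = optimization_config(stage_iters = c(5, 0)),
                     render_config = cfg)
  expect_identical(unname(coef(fit)),
                   c(init$rotation, init$translation, init$coeffs))
  expect_true(fit$non_improved)
})

test_that("best-seen loss is monotone in the iteration budget", {
  mod <- fx_model()
  cfg <- fx_render()
  cams <- fx_cams()
  k <- length(mod$eigenvalues)
  set.seed(61)
  truth <- pose_shape_params(coeffs = pmin(2, pmax(-2, stats::rnorm(k))))
  targets <- make_target_views(predict(mod, truth), cams, seed = 61)
  init <- pose_shape_params(rotation = c(0.05, 0.05, 0),
                            translation = c(3, -3, 2), coeffs = rep(0, k))
  fits <- lapply(c(5, 25), function(n)
    reconstruct(mod, targets, cams, init,
                config = optimization_config(stage_iters = c(n, n)),
                render_config = cfg))
  expect_lte(fits[[2]]$final_loss, fits[[1]]$final_loss + 1e-12)
})

test_that("fit accessors expose coefficients, mesh, residuals and summary", {
  mod <- fx_model()
  cfg <- fx_render()
  cams <- fx_cams()
  init <- zero_params(mod)
  targets <- make_target_views(predict(mod, init), cams, seed = 3)
  fit <- reconstruct(mod, targets, cams, init,
                     config = optimization_config(stage_iters = c(3, 3)),
                     render_config = cfg)
  expect_length(coef(fit), 6 + length(mod$eigenvalues))
  expect_s3_class(fitted(fit), "labeled_mesh")
  res <- residuals(fit)
  expect_length(res, 2)
  expect_identical(dim(res[[1]]), dim(targets[[1]]))
  s <- summary(fit)
  expect_s3_class(s, "summary.vertebra_fit")
  expect_output(print(s), "Vertebra reconstruction")
  expect_output(print(fit), "vertebra_fit")
})
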