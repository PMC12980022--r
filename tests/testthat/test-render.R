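test_that("a single splat is a unimodal blob at the rounded projection", {
  cam <- fx_cams()$ap
  p <- camera_center(cam) + 400 * camera_axis(cam) +
    cam$R[1, ] * 7.3 + cam$R[2, ] * (-4.1)
  pr <- project_points(cam, rbind(p))
  rv <- splat_render(pr$uv, pr$depth, cam, splat_config(sigma_mm = 2))
  am <- which(rv$image == max(rv$image), arr.ind = TRUE)[1, ]
  expect_equal(unname(am["col"]) - 1, unname(round(pr$uv[1, 1])))
  expect_equal(unname(am["row"]) - 1, unname(round(pr$uv[1, 2])))
  expect_true(all(rv$image >= 0 & rv$image <= 1))
})

test_that("coincident splats renormalize to the single-splat image", {
  cam <- fx_cams()$ap
  p <- camera_center(cam) + 420 * camera_axis(cam)
  pr1 <- project_points(cam, rbind(p))
  pr2 <- project_points(cam, rbind(p, p))
  r1 <- splat_render(pr1$uv, pr1$depth, cam, splat_config(sigma_mm = 2))
  r2 <- splat_render(pr2$uv, pr2$depth, cam, splat_config(sigma_mm = 2))
  expect_equal(r2$image, r1$image, tolerance = 1e-12)
  expect_equal(max(r2$raw), 2 * max(r1$raw), tolerance = 1e-12)
})

test_that("rendering an empty view warns and returns a zero image", {
  cam <- fx_cams()$ap
  behind <- camera_center(cam) - 50 * camera_axis(cam)
  pr <- project_points(cam, rbind(behind))
  expect_warning(rv <- splat_render(pr$uv, pr$depth, cam,
                                    splat_config(sigma_mm = 2)),
                 "no visible points")
  expect_true(all(rv$image == 0))
})

test_that("rendering is gauge invariant under joint rigid motion of scene and cameras", {
  mod <- fx_model()
  cfg <- fx_render()
  params <- pose_shape_params(coeffs = rep(0, length(mod$eigenvalues)))
  cams <- fx_cams()
  v0 <- render_instance(mod, params, cams, cfg)
  Rg <- random_rotation(9); tg <- c(12, -7, 5)
  # move the instance by (Rg, tg) and the cameras along with it
  params2 <- pose_shape_params(rotation = matrix_to_axis_angle(Rg),
                               translation = tg,
                               coeffs = params$coeffs)
  cams2 <- lapply(cams, function(cm)
    camera(cm$K, cm$R %*% t(Rg),
           as.numeric(cm$t - cm$R %*% t(Rg) %*% tg),
           cm$height, cm$width, cm$pixel_spacing_mm))
  v1 <- render_instance(mod, params2, cams2, cfg)
  for (i in seq_along(v0))
    expect_lt(max(abs(v0[[i]]$image - v1[[i]]$image)), 1e-6)
})

test_that("camera-parallel translation shifts the image by the predicted pixel offset", {
  mod <- fx_model()
  cfg <- fx_render()
  cam <- fx_cams()$ap
  params <- zero_params(mod)
  # shift along the camera x axis by an exact multiple of mm-per-pixel at
  # the object depth so the image translates by whole pixels
  z <- mean(project_points(cam, instance_points(mod, params))$depth)
  px <- 4L
  dx_mm <- px * z / cam$K[1, 1]
  params2 <- pose_shape_params(translation = as.numeric(cam$R[1, ] * dx_mm),
                               coeffs = params$coeffs)
  i0 <- render_instance(mod, params, list(cam), cfg)[[1]]$image
  i1 <- render_instance(mod, params2, list(cam), cfg)[[1]]$image
  # the correlation-maximizing integer shift must equal the prediction
  w <- ncol(i0)
  score <- vapply(-6:6, function(s) {
    if (s >= 0) sum(i1[, (s + 1):w] * i0[, 1:(w - s)])
    else sum(i1[, 1:(w + s)] * i0[, (1 - s):w])
  }, numeric(1))
  expect_identical((-6:6)[which.max(score)], px)
  # and the shifted images agree closely (residual is perspective-only)
  err <- i1[, (px + 1):w] - i0[, 1:(w - px)]
  expect_lt(max(abs(err)), 0.05)
})

test_that("shape coefficients change the image and carry loss gradient", {
  mod <- fx_model()
  cfg <- fx_render()
  cams <- fx_cams()
  k <- length(mod$eigenvalues)
  p0 <- zero_params(mod)
  p1 <- pose_shape_params(coeffs = c(3, rep(0, k - 1)))
  v0 <- render_instance(mod, p0, cams, cfg)
  v1 <- render_instance(mod, p1, cams, cfg)
  expect_gt(max(abs(v0[[1]]$image - v1[[1]]$image)), 0.01)
  targets <- lapply(v1, function(v) v$image)
  rg <- render_gradient(mod, p0, targets, cams, cfg)
  expect_gt(abs(rg$grad["c1"]), 0)
})

test_that("anisotropic splats follow the projected covariance", {
  cam <- fx_cams()$ap
  p <- camera_center(cam) + 450 * camera_axis(cam)
  pr <- project_points(cam, rbind(p))
  cfg <- splat_config(sigma_mm = 4, anisotropic = TRUE, normal_ratio = 0.3)
  # surface normal along the camera x axis: sigma shrinks along image u
  n_cam <- rbind(c(1, 0, 0))
  rv <- splat_render(pr$uv, pr$depth, cam, cfg, normals_cam = n_cam)
  img <- rv$raw
  tot <- sum(img)
  us <- col(img) - 1; vs <- row(img) - 1
  mu_u <- sum(us * img) / tot; mu_v <- sum(vs * img) / tot
  var_u <- sum((us - mu_u)^2 * img) / tot
  var_v <- sum((vs - mu_v)^2 * img) / tot
  f <- cam$K[1, 1]; z <- unname(pr$depth[1])
  # the measured axis ratio must match the J Sigma J^T prediction within
  # 5%; the absolute width is slightly shrunk by the kernel truncation
  expect_lt(abs(sqrt(var_u / var_v) - 0.3) / 0.3, 0.05)
  expect_lt(abs(sqrt(var_v) - 4 * f / z) / (4 * f / z), 0.1)
})

test_that("rendering is deterministic for fixed inputs", {
  mod <- fx_model()
  cfg <- fx_render()
  p <- pose_shape_params(rotation = c(0.05, -0.02, 0.1),
                         translation = c(3, 1, -2),
                         coeffs = rep(0.5, length(mod$eigenvalues)))
  a <- render_instance(mod, p, fx_cams(), cfg)
  b <- render_instance(mod, p, fx_cams(), cfg)
  expect_identical(a[[1]]$image, b[[1]]$image)
  expect_identical(a[[2]]$image, b[[2]]$image)
})
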