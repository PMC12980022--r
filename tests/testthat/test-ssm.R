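test_that("identical shapes give a zero-variance model equal to the shape", {
  set.seed(1)
  s <- as.numeric(t(matrix(stats::rnorm(30), ncol = 3)))
  mod <- build_ssm(lapply(1:5, function(i) s), k = 3)
  expect_equal(mod$mean_shape, s)
  expect_true(all(mod$eigenvalues < 1e-20))
})

test_that("a planted two-mode population is recovered exactly", {
  set.seed(2)
  n <- 3 * 40
  mu <- stats::rnorm(n)
  q <- qr.Q(qr(matrix(stats::rnorm(n * 2), ncol = 2)))
  shapes <- lapply(1:30, function(i)
    mu + q %*% stats::rnorm(2, sd = c(4, 2)))
  mod <- suppressWarnings(build_ssm(shapes, k = 2))
  # principal angles between recovered and planted subspaces
  sv <- svd(crossprod(mod$basis, q))$d
  angles <- acos(pmin(1, sv))
  expect_lt(max(angles), 1e-6)
  expect_lt(max(abs(crossprod(mod$basis) - diag(2))), 1e-8)
})

test_that("reconstruction error of training shapes equals the SVD truncation error", {
  set.seed(3)
  n <- 3 * 50
  S <- matrix(stats::rnorm(40 * n), nrow = 40)
  k <- 15
  mod <- build_ssm(S, k = k)
  Xc <- sweep(S, 2, colMeans(S))
  proj <- Xc %*% mod$basis %*% t(mod$basis)
  err_model <- sum((Xc - proj)^2)
  sv <- svd(Xc, nu = 0, nv = 0)$d
  err_svd <- sum(sv[-(1:k)]^2)
  expect_equal(err_model, err_svd, tolerance = 1e-9)
})

test_that("requesting more modes than available reduces k with a warning", {
  set.seed(4)
  S <- matrix(stats::rnorm(5 * 30), nrow = 5)
  expect_warning(mod <- build_ssm(S, k = 10), "reducing k")
  expect_lte(length(mod$eigenvalues), 4)
})

test_that("instantiation follows the linear shape-pose model exactly", {
  mod <- fx_model()
  k <- length(mod$eigenvalues)
  inst0 <- predict(mod, zero_params(mod))
  expect_identical(as.numeric(t(inst0$vertices)), as.numeric(mod$mean_shape))
  # pure translation
  instt <- predict(mod, pose_shape_params(translation = c(10, 0, 0),
                                          coeffs = rep(0, k)))
  expect_equal(instt$vertices, sweep(inst0$vertices, 2, -c(10, 0, 0)),
               tolerance = 1e-12)
  # one standard deviation of mode 1 against direct matrix arithmetic
  inst1 <- predict(mod, pose_shape_params(coeffs = c(1, rep(0, k - 1))))
  direct <- mod$mean_shape + sqrt(mod$eigenvalues[1]) * mod$basis[, 1]
  expect_equal(as.numeric(t(inst1$vertices)), direct, tolerance = 1e-12)
  # labels, faces, landmarks are carried over from the template
  expect_identical(inst1$faces, mod$template$faces)
  expect_identical(inst1$landmark_indices, mod$template$landmark_indices)
})

test_that("coefficients outside the admissible band are rejected", {
  expect_error(pose_shape_params(coeffs = c(0, 3.2)), "bound")
  expect_silent(pose_shape_params(coeffs = c(3, -3)))
})

test_that("variance fractions behave on closed-form spectra", {
  expect_equal(variance_explained(eigenvalues = c(4, 1)), c(0.8, 0.2))
  expect_equal(variance_explained(eigenvalues = c(7, 0, 0)), c(1, 0, 0))
  expect_equal(variance_explained(eigenvalues = c(0, 0)), c(0, 0))
  ve <- variance_explained(fx_model())
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(sum(ve), 1 + 1e-12)
})

test_that("simulated shapes respect the coefficient bound and the seed", {
  mod <- fx_model()
  draws <- simulate(mod, nsim = 5, seed = 9, sd = 2)
  expect_length(draws, 5)
  for (d in draws) expect_lte(max(abs(d$coeffs)), 3)
  draws2 <- simulate(mod, nsim = 5, seed = 9, sd = 2)
  expect_identical(draws[[3]]$coeffs, draws2[[3]]$coeffs)
})

test_that("refinement is a fixed point on model-generated populations", {
  big <- fx_model()
  draws <- simulate(big, nsim = 10, seed = 13)
  shapes <- lapply(draws, function(d) predict(big, d)$vertices)
  mod <- build_ssm(shapes, k = 6, template = big$template)
  meshes <- lapply(shapes, function(v) {
    m <- big$template; m$vertices <- v; m
  })
  r0 <- refine_ssm(mod, meshes, rounds = 0)
  expect_identical(r0$mean_shape, mod$mean_shape)
  r1 <- refine_ssm(mod, meshes, rounds = 1)
  expect_lt(max(abs(r1$mean_shape - mod$mean_shape)), 1e-6)
  ang <- acos(pmin(1, svd(crossprod(r1$basis, mod$basis))$d))
  expect_lt(max(ang), 1e-6)
})

test_that("refinement repairs a planted correspondence shuffle", {
  mod <- fx_model()
  draws <- simulate(mod, nsim = 8, seed = 17)
  meshes <- lapply(draws, function(d) predict(mod, d))
  # plant a vertex shuffle within one region of half the meshes
  idx <- which(meshes[[1]]$region_labels == "process")[1:60]
  set.seed(21)
  perm <- sample(idx)
  broken_shapes <- lapply(seq_along(meshes), function(i) {
    v <- meshes[[i]]$vertices
    if (i %% 2 == 0) v[idx, ] <- v[perm, ]
    v
  })
  broken <- suppressWarnings(build_ssm(broken_shapes, k = 6,
                                       template = mod$template))
  fit_res <- function(model) mean(vapply(meshes, function(m)
    spinefit:::fit_model_to_mesh(model, m, gn_steps = 3)$residual, numeric(1)))
  res0 <- fit_res(broken)
  refined <- suppressWarnings(refine_ssm(broken, meshes, rounds = 3,
                                         gn_steps = 3))
  expect_lt(fit_res(refined), res0)
  expect_true(all(is.finite(attr(refined, "residual_trace"))))
})

test_that("annotation propagation applies the inclusive DICE threshold", {
  mod <- fx_model()
  draw <- simulate(mod, nsim = 1, seed = 31)[[1]]
  raw <- predict(mod, draw)
  f <- spinefit:::fit_model_to_mesh(mod, raw)
  inst <- predict(mod, f$params)
  acc <- propagate_annotation(inst, raw, mod, spacing = 1)
  expect_true(acc$accepted)
  expect_gt(acc$dice, 0.95)
  expect_setequal(names(acc$landmark_indices), LANDMARK_NAMES)
  expect_named(acc$path_points, c("left", "right"))
  # a wildly different shape is rejected, carrying the score
  far <- raw
  far$vertices <- 0.3 * sweep(raw$vertices, 2, -c(60, 0, 0))
  rej <- propagate_annotation(inst, far, mod, spacing = 1)
  expect_false(rej$accepted)
  expect_lt(rej$dice, 0.85)
  # the threshold is inclusive: a fit exactly at min_dice is accepted
  at <- propagate_annotation(inst, raw, mod, min_dice = acc$dice, spacing = 1)
  expect_true(at$accepted)
})

test_that("a shape model round-trips through its archive", {
  mod <- fx_model()
  path <- tempfile(fileext = ".ssm.json")
  write_ssm(mod, path)
  back <- read_ssm(path)
  expect_equal(back$mean_shape, mod$mean_shape, tolerance = 1e-12)
  expect_equal(back$basis, mod$basis, tolerance = 1e-12)
  expect_equal(back$eigenvalues, mod$eigenvalues, tolerance = 1e-12)
  draw <- simulate(mod, nsim = 1, seed = 2)[[1]]
  expect_equal(predict(back, draw)$vertices, predict(mod, draw)$vertices,
               tolerance = 1e-12)
  bad <- path
  writeLines(gsub(spinefit:::SSM_FORMAT_VERSION, "other-2",
                  readLines(path, warn = FALSE)), bad)
  expect_error(read_ssm(bad), "version")
})
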