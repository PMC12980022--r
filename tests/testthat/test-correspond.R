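test_that("ICP on an identical target is the identity with zero residual", {
  set.seed(1)
  X <- matrix(stats::rnorm(90, sd = 10), ncol = 3)
  r <- icp_correspond(X, X)
  expect_identical(as.integer(r$correspondence$mapping), seq_len(nrow(X)))
  expect_lt(r$correspondence$mean_residual, 1e-12)
  expect_error(icp_correspond(X[0, ], X), "non-empty")
})

test_that("ICP recovers a pure translation", {
  set.seed(2)
  X <- matrix(stats::rnorm(120, sd = 10), ncol = 3)
  Y <- sweep(X, 2, -c(5, 0, 0)) # X + (5,0,0)
  r <- icp_correspond(X, Y)
  expect_lt(max(abs(r$t - c(5, 0, 0))), 1e-6)
  expect_lt(r$correspondence$mean_residual, 1e-6)
})

test_that("ICP mapping equals exhaustive nearest neighbours at the returned pose", {
  set.seed(3)
  X <- matrix(stats::rnorm(300, sd = 10), ncol = 3)
  Rz <- axis_angle_to_matrix(c(0, 0, 10 * pi / 180))
  Y <- X %*% t(Rz) + matrix(stats::rnorm(300, sd = 0.1), ncol = 3)
  r <- icp_correspond(X, Y)
  moved <- sweep(X %*% t(r$R), 2, -r$t)
  D <- spinefit:::dist2_matrix_cpp(moved, Y)
  oracle <- apply(D, 1, which.min) # which.min keeps the lowest index on ties
  expect_identical(as.integer(r$correspondence$mapping), as.integer(oracle))
  expect_true(all(diff(r$residual_trace) <= 1e-12))
})

test_that("CPD leaves an identical target essentially undeformed", {
  set.seed(4)
  X <- matrix(stats::rnorm(150, sd = 5), ncol = 3)
  r <- cpd_nonrigid(X, X, max_iter = 20)
  diag_len <- sqrt(sum((apply(X, 2, max) - apply(X, 2, min))^2))
  expect_lt(max(sqrt(rowSums((r$points - X)^2))), 1e-3 * diag_len)
})

test_that("CPD tracks a smooth bulge to sub-millimetre surface distance", {
  m <- fx_phantom()
  set.seed(5)
  idx <- sample(nrow(m$vertices), 400)
  X <- m$vertices[sort(idx), ]
  # smooth radial bulge of one region
  ctr <- c(0, -14, 0)
  d2 <- rowSums(sweep(X, 2, ctr)^2)
  w <- exp(-d2 / (2 * 8^2))
  Y <- X + 2.5 * w * sweep(X, 2, ctr) / pmax(sqrt(d2), 1e-9)
  r <- cpd_nonrigid(X, Y, max_iter = 80)
  nn <- spinefit:::nn_bruteforce_cpp(r$points, Y)
  expect_lt(mean(nn$dist), 0.5)
  expect_true(all(diff(r$objective_trace) <= 1e-8))
})

test_that("a single CPD EM step reproduces hand-computed responsibilities", {
  Y <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))   # template
  X <- rbind(c(0.1, 0, 0), c(0.9, 0.1, 0), c(0, 1.1, 0))
  r <- cpd_nonrigid(Y, X, beta = 2, lambda = 3, max_iter = 1)
  # oracle E-step in the same normalized frame
  M <- 3; N <- 3; D <- 3
  ym <- colMeans(Y); xm <- colMeans(X)
  s <- sqrt((sum(sweep(Y, 2, ym)^2) + sum(sweep(X, 2, xm)^2)) / (M + N))
  Yn <- sweep(Y, 2, ym) / s; Xn <- sweep(X, 2, xm) / s
  D2 <- as.matrix(stats::dist(rbind(Yn, Xn)))[1:3, 4:6]^2
  sigma2 <- sum(D2) / (D * M * N)
  K <- exp(-D2 / (2 * sigma2))
  P <- sweep(K, 2, colSums(K), "/")
  expect_equal(unname(r$responsibilities), unname(P), tolerance = 1e-12)
})

test_that("CPD validates inputs", {
  X <- matrix(stats::rnorm(30), ncol = 3)
  expect_error(cpd_nonrigid(X, X, beta = 0), "beta")
  expect_error(cpd_nonrigid(X[0, ], X), "non-empty")
})

test_that("correspond_population returns template-cardinality resamplings", {
  tpl <- fx_phantom()
  set.seed(6)
  sub <- function(m, n, seed) {
    set.seed(seed)
    m$vertices[sort(sample(nrow(m$vertices), n)), ]
  }
  X <- sub(tpl, 350, 7)
  targets <- lapply(1:2, function(i) {
    v <- sub(generate_vertebra(phantom_params(body_a = 18 + i)), 380, 8 + i)
    labeled_mesh(v, matrix(c(1L, 2L, 3L), 1), validate = FALSE)
  })
  tpl_small <- labeled_mesh(X, matrix(c(1L, 2L, 3L), 1), validate = FALSE)
  out <- correspond_population(tpl_small, targets, max_iter = 30)
  expect_length(out, 2)
  for (o in out) expect_identical(dim(o), dim(X))
})
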