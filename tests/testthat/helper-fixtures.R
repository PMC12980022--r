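# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fx_phantom <- function() fx("phantom", function() generate_vertebra())

fx_population <- function() fx("population", function()
  sample_population(12, seed = 3))

fx_model <- function() fx("model", function()
  build_ssm_population(fx_population(), k = 6))

fx_cams <- function() fx("cams", function() biplanar_cameras(c(0, 2, 0)))

fx_render <- function() fx("render", function()
  resolve_render_config(splat_config(n_points = 400), fx_model()))

# axis-aligned box mesh (12 triangles, outward-oriented)
box_mesh <- function(lo = c(0, 0, 0), hi = c(1, 1, 1)) {
  corners <- as.matrix(expand.grid(x = c(lo[1], hi[1]),
                                   y = c(lo[2], hi[2]),
                                   z = c(lo[3], hi[3])))
  # faces as quads on each side, split into triangles, wound outward
  quads <- rbind(
    c(1, 3, 4, 2),  # z = lo (viewed from below)
    c(5, 6, 8, 7),  # z = hi
    c(1, 2, 6, 5),  # y = lo
    c(3, 7, 8, 4),  # y = hi
    c(1, 5, 7, 3),  # x = lo
    c(2, 4, 8, 6))  # x = hi
  F <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  m <- labeled_mesh(corners, F, validate = FALSE)
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  validate_mesh(m)
  m
}

# UV sphere mesh
sphere_mesh <- function(r = 10, center = c(0, 0, 0), n_theta = 24L,
                        n_phi = 12L) {
  V <- rbind(center + c(0, 0, -r), center + c(0, 0, r))
  rings <- list()
  for (i in seq_len(n_phi - 1)) {
    phi <- -pi / 2 + pi * i / n_phi
    th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
    ring <- cbind(center[1] + r * cos(phi) * cos(th),
                  center[2] + r * cos(phi) * sin(th),
                  center[3] + r * sin(phi))
    rings[[i]] <- nrow(V) + seq_len(n_theta)
    V <- rbind(V, ring)
  }
  F <- NULL
  n <- n_theta
  jn <- c(2:n, 1)
  F <- rbind(F, cbind(1L, rings[[1]][jn], rings[[1]]))
  for (i in seq_len(n_phi - 2)) {
    a <- rings[[i]]; b <- rings[[i + 1]]
    F <- rbind(F, cbind(a, a[jn], b[jn]), cbind(a, b[jn], b))
  }
  top <- rings[[n_phi - 1]]
  F <- rbind(F, cbind(2L, top, top[jn]))
  m <- labeled_mesh(V, F, validate = FALSE)
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# labeled tube phantom for breach tests: lateral wall labeled as a pedicle
tube_phantom <- function(radius = 4, length = 20, n_theta = 128L,
                         side = "left") {
  tube <- spinefit:::closed_cylinder(c(0, 0, -length / 2),
                                     c(0, 0, length / 2),
                                     radius, radius,
                                     n_theta = n_theta, n_len = 6L)
  lab <- rep(paste0("pedicle_", side), nrow(tube$V))
  lab[1:2] <- "body"
  labeled_mesh(tube$V, tube$F, region_labels = lab)
}

random_rotation <- function(seed) {
  set.seed(seed)
  v <- stats::rnorm(3)
  axis_angle_to_matrix(v / sqrt(sum(v^2)) * stats::runif(1, 0, pi / 2))
}

expect_equal_mm <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}

# central finite differences of the rendered multi-view loss
fd_gradient <- function(mod, params, targets, cams, cfg, h = 1e-3) {
  k <- length(params$coeffs)
  th0 <- c(params$rotation, params$translation, params$coeffs)
  vapply(seq_along(th0), function(i) {
    ev <- function(s) {
      th <- th0; th[i] <- th[i] + s * h
      p <- pose_shape_params(th[1:3], th[4:6],
                             if (k > 0) th[6 + seq_len(k)] else numeric(0),
                             scale = params$scale)
      render_loss(mod, p, targets, cams, cfg)
    }
    (ev(1) - ev(-1)) / (2 * h)
  }, numeric(1))
}
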