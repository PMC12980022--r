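# Differentiable Gaussian-splat rendering. Model vertices are projected
# through a pinhole camera and accumulated additively as 2D Gaussian blobs
# (X-ray-like integration, not alpha compositing); the image-plane width of
# an isotropic world-space Gaussian scales with perspective as
# sigma_px = sigma_world * f / z. The kernel is truncated at `cutoff` sigma
# with a C1 roll-off so the image is a smooth function of the parameters.

#' Splat rendering configuration
#'
#' @param sigma_mm world-space Gaussian sigma (mm); `NULL` means "mean
#'   nearest-neighbour spacing of the rendered point set", resolved when a
#'   model is first rendered.
#' @param intensity per-splat amplitude before normalization.
#' @param cutoff kernel truncation radius in sigma units; the kernel and
#'   its first derivative vanish continuously at the cutoff.
#' @param anisotropic render normal-aligned elliptical splats (forward
#'   only; the analytic gradient path supports the isotropic renderer).
#' @param normal_ratio for anisotropic splats, the sigma along the surface
#'   normal as a fraction of `sigma_mm`.
#' @param n_points render at most this many vertices (evenly-spaced
#'   deterministic subsample); `NULL` renders all.
#' @return an object of class `splat_config`.
#' @export
splat_config <- function(sigma_mm = NULL, intensity = 1, cutoff = 4,
                         anisotropic = FALSE, normal_ratio = 0.3,
                         n_points = NULL) {
  stopifnot(is.null(sigma_mm) || sigma_mm > 0, cutoff > 0)
  structure(list(sigma_mm = sigma_mm, intensity = intensity, cutoff = cutoff,
                 anisotropic = anisotropic, normal_ratio = normal_ratio,
                 n_points = n_points),
            class = "splat_config")
}

# evenly spaced deterministic subsample of vertex indices
render_indices <- function(n_vertices, config) {
  if (is.null(config$n_points) || config$n_points >= n_vertices)
    return(seq_len(n_vertices))
  unique(round(seq(1, n_vertices, length.out = config$n_points)))
}

resolve_sigma <- function(config, points3d) {
  if (!is.null(config$sigma_mm)) return(config$sigma_mm)
  mean_vertex_spacing(points3d)
}

#' Render projected points as Gaussian splats
#'
#' @param points2d n x 2 matrix of pixel positions (u, v), 0-based; rows
#'   with `NA` (behind-camera) are skipped.
#' @param depths camera-frame depths (mm) matching `points2d`.
#' @param cam a [camera].
#' @param config a [splat_config] with `sigma_mm` resolved.
#' @param normals_cam optional n x 3 camera-frame unit normals (anisotropic
#'   mode only).
#' @return object of class `rendered_view`: `image` (max-normalized to
#'   [0,1]), `raw` (unnormalized accumulation), `camera`.
#' @export
splat_render <- function(points2d, depths, cam, config, normals_cam = NULL) {
  keep <- is.finite(points2d[, 1]) & is.finite(points2d[, 2]) & depths > 1e-6
  if (!any(keep)) {
    warning("no visible points; returning zero image")
    img <- matrix(0, cam$height, cam$width)
    return(structure(list(image = img, raw = img, camera = cam),
                     class = "rendered_view"))
  }
  if (is.null(config$sigma_mm)) stop("sigma_mm unresolved; use render_instance or set it")
  uv <- points2d[keep, , drop = FALSE]
  z <- depths[keep]
  f <- cam$K[1, 1]
  if (isTRUE(config$anisotropic)) {
    raw <- splat_render_aniso(uv, z, cam, config,
                              if (is.null(normals_cam)) NULL else normals_cam[keep, , drop = FALSE])
  } else {
    sig <- config$sigma_mm * f / z
    raw <- splat_forward_cpp(uv[, 1], uv[, 2], sig,
                             rep(config$intensity, nrow(uv)),
                             cam$height, cam$width, config$cutoff)
  }
  mx <- max(raw)
  img <- if (mx > 0) raw / mx else raw
  structure(list(image = img, raw = raw, camera = cam),
            class = "rendered_view")
}

# Elliptical splats: 2D covariance J Sigma J^T with J the projection
# Jacobian at the point and Sigma the normal-aligned world covariance
# sigma^2 * (ratio^2 n n^T + (I - n n^T)). Plain-R forward pass.
splat_render_aniso <- function(uv, z, cam, config, normals_cam) {
  H <- cam$height; W <- cam$width
  K <- cam$K
  img <- matrix(0, H, W)
  s2 <- config$sigma_mm^2
  sc <- config$cutoff^2 / 2
  esc <- exp(-sc)
  for (i in seq_len(nrow(uv))) {
    u <- uv[i, 1]; v <- uv[i, 2]; zi <- z[i]
    # camera-frame point consistent with (u, v, z)
    Xc <- c((u - K[1, 3]) / K[1, 1] * zi, (v - K[2, 3]) / K[2, 2] * zi, zi)
    J <- rbind(c(K[1, 1], K[1, 2], K[1, 3] - u) / zi,
               c(0, K[2, 2], K[2, 3] - v) / zi)
    Sg <- if (is.null(normals_cam)) s2 * diag(3) else {
      n <- normals_cam[i, ]
      s2 * (config$normal_ratio^2 * tcrossprod(n) + diag(3) - tcrossprod(n))
    }
    C2 <- J %*% Sg %*% t(J)
    Cinv <- solve(C2)
    # footprint from the largest eigenvalue
    rad <- config$cutoff * sqrt(max(eigen(C2, symmetric = TRUE, only.values = TRUE)$values))
    c0 <- max(0L, ceiling(u - rad)); c1 <- min(W - 1L, floor(u + rad))
    r0 <- max(0L, ceiling(v - rad)); r1 <- min(H - 1L, floor(v + rad))
    if (c0 > c1 || r0 > r1) next
    cs <- c0:c1; rs <- r0:r1
    du <- outer(rep(1, length(rs)), cs - u)
    dv <- outer(rs - v, rep(1, length(cs)))
    s <- 0.5 * (Cinv[1, 1] * du^2 + 2 * Cinv[1, 2] * du * dv + Cinv[2, 2] * dv^2)
    g <- ifelse(s < sc, exp(-s) - esc + esc * (s - sc), 0)
    img[rs + 1, cs + 1] <- img[rs + 1, cs + 1] + config$intensity * g
  }
  img
}

# model-frame shape for given standardized coefficients (N x 3, mm)
shape_points <- function(model, coeffs, indices = NULL) {
  k <- length(model$eigenvalues)
  stopifnot(length(coeffs) == k)
  c_raw <- coeffs * sqrt(model$eigenvalues)
  x <- model$mean_shape
  if (k > 0 && any(c_raw != 0)) x <- x + as.numeric(model$basis %*% c_raw)
  P <- matrix(x, ncol = 3, byrow = TRUE)
  if (!is.null(indices)) P <- P[indices, , drop = FALSE]
  P
}

# world-frame instance points for pose+shape parameters
instance_points <- function(model, params, indices = NULL) {
  P <- shape_points(model, params$coeffs, indices)
  R <- axis_angle_to_matrix(params$rotation)
  sweep((params$scale * P) %*% t(R), 2, -params$translation)
}

#' Render a shape-model instance into one or more views
#'
#' Instantiates the model at the given pose/shape parameters, projects the
#' vertices through each camera and splats them. The whole map from the
#' 21 parameters (axis-angle rotation, translation, standardized shape
#' coefficients) to the images is differentiable; see [render_gradient].
#'
#' @param model a `vertebra_ssm`.
#' @param params a [pose_shape_params].
#' @param cameras list of [camera] objects.
#' @param config a [splat_config].
#' @return list of `rendered_view`, one per camera.
#' @export
render_instance <- function(model, params, cameras, config = splat_config()) {
  idx <- render_indices(nrow(model$template$vertices), config)
  pts <- instance_points(model, params, idx)
  if (is.null(config$sigma_mm)) config$sigma_mm <- resolve_sigma(config, pts)
  lapply(cameras, function(cam) {
    pr <- project_points(cam, pts)
    normals_cam <- NULL
    if (isTRUE(config$anisotropic)) {
      vn <- vertex_normals(model$template)[idx, , drop = FALSE]
      R <- axis_angle_to_matrix(params$rotation)
      normals_cam <- (vn %*% t(R)) %*% t(cam$R)
    }
    splat_render(pr$uv, pr$depth, cam, config, normals_cam)
  })
}

# area-weighted per-vertex normals of a mesh
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh) * face_areas(mesh)
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (j in 1:3) {
    idx <- mesh$faces[, j]
    for (d in 1:3) vn[, d] <- vn[, d] + tabulate_weighted(idx, fn[, d], nrow(vn))
  }
  vn / pmax(sqrt(rowSums(vn^2)), 1e-300)
}

tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  acc <- tapply(w, idx, sum)
  out[as.integer(names(acc))] <- acc
  out
}
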