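#' Pinhole camera
#'
#' A calibrated pinhole geometry `P = K [R | t]`: world points (mm) map to
#' camera coordinates `Xc = R x + t`, then to pixels by `u = (K Xc)_1 /
#' (K Xc)_3`, `v = (K Xc)_2 / (K Xc)_3`. Pixel coordinates are 0-based with
#' `u` along image columns and `v` along rows.
#'
#' @param K 3 x 3 upper-triangular intrinsics with positive diagonal (px).
#' @param R 3 x 3 rotation (world to camera), orthonormal within 1e-9.
#' @param t length-3 translation (mm).
#' @param height,width image raster size (px).
#' @param pixel_spacing_mm detector pixel pitch metadata (mm/px).
#' @return an object of class `camera`.
#' @export
camera <- function(K, R, t, height, width, pixel_spacing_mm = NA_real_) {
  K <- as.matrix(K); R <- as.matrix(R)
  if (any(abs(K[lower.tri(K)]) > 1e-12) || any(diag(K)[1:2] <= 0) || K[3, 3] != 1)
    stop("K must be upper-triangular with positive focal lengths and K[3,3] = 1")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("R must be a rotation matrix (orthonormal, det +1) within 1e-9")
  structure(list(K = K, R = R, t = as.numeric(t),
                 height = as.integer(height), width = as.integer(width),
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "camera")
}

#' @export
print.camera <- function(x, ...) {
  cat(sprintf("camera: %dx%d px, f = (%.1f, %.1f) px\n",
              x$width, x$height, x$K[1, 1], x$K[2, 2]))
  invisible(x)
}

#' 3 x 4 projection matrix of a camera
#' @param cam a [camera].
#' @return the matrix `K [R | t]`.
#' @export
projection_matrix <- function(cam) cam$K %*% cbind(cam$R, cam$t)

#' Project 3D points through a pinhole camera
#'
#' @param cam a [camera].
#' @param points3d n x 3 matrix of world points (mm).
#' @param eps depth below which a point is flagged behind the camera.
#' @return list with `uv` (n x 2, px), `depth` (camera-frame z, mm) and
#'   logical `behind` (depth <= eps; their `uv` is `NA`).
#' @export
project_points <- function(cam, points3d, eps = 1e-6) {
  points3d <- rbind2mat(points3d)
  stopifnot(all(is.finite(points3d)))
  Xc <- points3d %*% t(cam$R)
  Xc <- sweep(Xc, 2, -cam$t)
  p <- Xc %*% t(cam$K)
  z <- p[, 3]
  behind <- z <= eps
  uv <- cbind(p[, 1] / z, p[, 2] / z)
  uv[behind, ] <- NA_real_
  list(uv = uv, depth = z, behind = behind)
}

rbind2mat <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

#' Optical axis of a camera in world coordinates
#' @param cam a [camera].
#' @return unit 3-vector (viewing direction).
#' @export
camera_axis <- function(cam) as.numeric(cam$R[3, ])

#' Camera centre in world coordinates
#' @param cam a [camera].
#' @return 3-vector (mm).
#' @export
camera_center <- function(cam) as.numeric(-crossprod(cam$R, cam$t))

#' Angular separation between two cameras
#' @param cam_a,cam_b [camera] objects.
#' @return angle between optical axes, degrees.
#' @export
view_separation_deg <- function(cam_a, cam_b) {
  ct <- sum(camera_axis(cam_a) * camera_axis(cam_b))
  acos(min(1, max(-1, ct))) * 180 / pi
}

# Camera looking at `target` from direction `dir` (unit, world), at
# distance d, with world `up` resolved into the image -v direction.
look_at_camera <- function(target, dir, dist, f, height, width,
                           up = c(0, 0, 1)) {
  dir <- dir / sqrt(sum(dir^2))
  center <- target - dist * dir
  zc <- dir
  # y_cam points down in the image: -up, made orthogonal to the axis
  yc <- -up + sum(up * zc) * zc
  ny <- sqrt(sum(yc^2))
  if (ny < 1e-8) { # viewing along up: fall back to another reference
    yc <- -c(0, 1, 0) + sum(c(0, 1, 0) * zc) * zc
    ny <- sqrt(sum(yc^2))
  }
  yc <- yc / ny
  xc <- crossprod3(yc, zc) # right-handed: x = y cross z
  R <- rbind(xc, yc, zc)
  rownames(R) <- NULL
  # re-orthonormalize defensively
  s <- svd(R); R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  t <- -R %*% center
  K <- matrix(c(f, 0, 0, 0, f, 0, (width - 1) / 2, (height - 1) / 2, 1), 3, 3)
  camera(K, R, as.numeric(t), height, width, pixel_spacing_mm = dist / f)
}

#' Standard AP/LAT biplanar camera pair
#'
#' Two pinhole views of a target point: anteroposterior (viewing along +y)
#' and lateral (viewing along +x), approximately orthogonal, with the
#' superior axis (+z) up in both images.
#'
#' @param target world point the cameras look at (mm).
#' @param dist source-to-target distance (mm).
#' @param f focal length (px).
#' @param height,width raster size (px).
#' @return list of two [camera] objects named `ap` and `lat`.
#' @export
biplanar_cameras <- function(target = c(0, 0, 0), dist = 500, f = 500,
                             height = 96L, width = 96L) {
  list(ap = look_at_camera(target, c(0, 1, 0), dist, f, height, width),
       lat = look_at_camera(target, c(1, 0, 0), dist, f, height, width))
}

#' Random-view camera pair sampler
#'
#' Cameras on a sphere about the target: uniform azimuth, elevation limited
#' to +/-`max_elev_deg`, resampled until the pairwise angular separation is
#' at least `min_sep_deg`.
#'
#' @param target world point (mm); `dist`, `f`, `height`, `width` as in
#'   [biplanar_cameras].
#' @param min_sep_deg minimum pairwise separation (deg).
#' @param max_elev_deg elevation limit (deg).
#' @param seed integer seed.
#' @inheritParams biplanar_cameras
#' @return list of two [camera] objects.
#' @export
random_view_cameras <- function(target = c(0, 0, 0), dist = 500, f = 500,
                                height = 96L, width = 96L,
                                min_sep_deg = 15, max_elev_deg = 45,
                                seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  draw_dir <- function() {
    az <- stats::runif(1, 0, 2 * pi)
    el <- stats::runif(1, -max_elev_deg, max_elev_deg) * pi / 180
    c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  }
  repeat {
    d1 <- draw_dir(); d2 <- draw_dir()
    ang <- acos(min(1, max(-1, sum(d1 * d2)))) * 180 / pi
    if (ang >= min_sep_deg) break
  }
  list(a = look_at_camera(target, d1, dist, f, height, width),
       b = look_at_camera(target, d2, dist, f, height, width))
}

#' Read / write cameras as JSON
#'
#' The JSON schema stores `K`, `R`, `t`, `height`, `width` and
#' `pixel_spacing_mm` per camera; the projection matrix is always derived,
#' never stored.
#' @param cams named list of [camera] objects.
#' @param path file path.
#' @return `read_cameras` returns a named list of [camera] objects.
#' @export
write_cameras <- function(cams, path) {
  enc <- lapply(cams, function(cm) list(
    K = cm$K, R = cm$R, t = cm$t,
    height = cm$height, width = cm$width,
    pixel_spacing_mm = cm$pixel_spacing_mm))
  jsonlite::write_json(enc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_cameras
#' @export
read_cameras <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat3 <- function(x) {
    if (is.matrix(x)) unname(x) else matrix(unlist(x), 3, 3, byrow = TRUE)
  }
  lapply(raw, function(cm) camera(
    K = as_mat3(cm$K), R = as_mat3(cm$R),
    t = unlist(cm$t), height = cm$height, width = cm$width,
    pixel_spacing_mm = cm$pixel_spacing_mm))
}
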