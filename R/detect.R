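# Simulated 2D landmark detections and target radiographs. These stand in
# for a trained landmark detector and for externally acquired images: true
# 3D landmarks are projected, perturbed with pixel noise and random
# dropout, and five silhouette-derived backup landmarks are always
# emitted. Target views are rendered with a deliberately wider splat
# kernel than the registration renderer plus speckle and read noise, so
# that self-registration is never trivially exact (inverse-crime
# mitigation).

#' Simulate landmark detections in one view
#'
#' Projects the mesh's ten anatomical landmarks through the camera, adds
#' isotropic Gaussian pixel noise and drops each landmark independently
#' with probability `dropout_prob` (confidence is one minus the dropout
#' draw). Landmarks behind the camera or outside the raster are marked
#' absent. Five backup landmarks are derived from the projected
#' silhouette's bounding box: its centre (`centroid`) and the midpoints of
#' its top, bottom, left and right edges (`superior`, `inferior`, `left`,
#' `right`, in image-frame terms).
#'
#' @param mesh a [labeled_mesh] with landmarks.
#' @param cam a [camera].
#' @param pixel_noise_sd isotropic detection noise (px).
#' @param dropout_prob per-landmark dropout probability.
#' @param seed integer seed.
#' @param view_id identifier recorded in the output.
#' @return data frame with columns `view_id`, `landmark_name`, `u_px`,
#'   `v_px`, `confidence`, `present` (anatomical landmarks first, then the
#'   5 backups).
#' @export
simulate_detections <- function(mesh, cam, pixel_noise_sd = 0,
                                dropout_prob = 0, seed = 1L,
                                view_id = "view") {
  stopifnot(pixel_noise_sd >= 0, dropout_prob >= 0, dropout_prob <= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lm_pts <- mesh$vertices[mesh$landmark_indices, , drop = FALSE]
  pr <- project_points(cam, lm_pts)
  q <- stats::runif(length(LANDMARK_NAMES))
  noise <- matrix(stats::rnorm(2 * length(LANDMARK_NAMES), 0, pixel_noise_sd),
                  ncol = 2)
  uv <- pr$uv + noise
  inside <- !pr$behind &
    uv[, 1] >= 0 & uv[, 1] <= cam$width - 1 &
    uv[, 2] >= 0 & uv[, 2] <= cam$height - 1
  present <- inside & (q >= dropout_prob)
  ana <- data.frame(
    view_id = view_id,
    landmark_name = names(mesh$landmark_indices),
    u_px = ifelse(present, uv[, 1], NA_real_),
    v_px = ifelse(present, uv[, 2], NA_real_),
    confidence = 1 - q,
    present = present,
    stringsAsFactors = FALSE)

  # backup landmarks from the full-mesh silhouette bounding box
  prv <- project_points(cam, mesh$vertices)
  vis <- !prv$behind
  bk <- if (any(vis)) {
    u <- prv$uv[vis, 1]; v <- prv$uv[vis, 2]
    u0 <- min(u); u1 <- max(u); v0 <- min(v); v1 <- max(v)
    cu <- (u0 + u1) / 2; cv <- (v0 + v1) / 2
    pos <- rbind(centroid = c(cu, cv),
                 superior = c(cu, v0), inferior = c(cu, v1),
                 left = c(u0, cv), right = c(u1, cv))
    data.frame(view_id = view_id, landmark_name = rownames(pos),
               u_px = pos[, 1], v_px = pos[, 2],
               confidence = 1, present = TRUE, stringsAsFactors = FALSE)
  } else {
    data.frame(view_id = view_id, landmark_name = BACKUP_NAMES,
               u_px = NA_real_, v_px = NA_real_,
               confidence = 0, present = FALSE, stringsAsFactors = FALSE)
  }
  out <- rbind(ana, bk)
  rownames(out) <- NULL
  out
}

#' Render target views of a ground-truth mesh
#'
#' Renders the mesh vertices through each camera with a splat kernel
#' `sigma_scale` times wider than the mesh's mean vertex spacing (the
#' registration default), then applies multiplicative log-normal speckle
#' and additive Gaussian read noise and clips to [0, 1]. The widened
#' kernel plus noise prevents the registration from committing an inverse
#' crime against its own renderer.
#'
#' @param mesh a [labeled_mesh] (the ground truth).
#' @param cameras list of [camera] objects.
#' @param sigma_scale kernel width multiplier relative to the mesh's mean
#'   vertex spacing.
#' @param speckle_sd log-normal speckle sigma (0 disables).
#' @param read_noise_sd additive Gaussian noise sd (0 disables).
#' @param seed integer seed.
#' @param config optional [splat_config] overriding the kernel entirely.
#' @return list of image matrices in [0, 1], one per camera.
#' @export
make_target_views <- function(mesh, cameras, sigma_scale = 1.5,
                              speckle_sd = 0.05, read_noise_sd = 0.01,
                              seed = 1L, config = NULL) {
  stopifnot(length(cameras) >= 1)
  if (is.null(config)) {
    spacing <- mean_vertex_spacing(mesh$vertices)
    config <- splat_config(sigma_mm = sigma_scale * spacing)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lapply(cameras, function(cam) {
    pr <- project_points(cam, mesh$vertices)
    img <- splat_render(pr$uv, pr$depth, cam, config)$image
    if (speckle_sd > 0)
      img <- img * exp(matrix(stats::rnorm(length(img), 0, speckle_sd),
                              nrow(img)))
    if (read_noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, read_noise_sd),
                          nrow(img))
    pmin(pmax(img, 0), 1)
  })
}

#' Read / write detections as CSV
#'
#' Columns: `view_id`, `landmark_name`, `u_px`, `v_px`, `confidence`,
#' `present`.
#' @param detections a detection data frame or a list of them (rows are
#'   concatenated).
#' @param path file path.
#' @return `read_detections` returns a list of data frames split by
#'   `view_id`, in order of first appearance.
#' @export
write_detections <- function(detections, path) {
  if (is.data.frame(detections)) detections <- list(detections)
  df <- do.call(rbind, detections)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$present <- as.logical(df$present)
  ids <- unique(df$view_id)
  lapply(stats::setNames(ids, ids), function(v) df[df$view_id == v, , drop = FALSE])
}
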