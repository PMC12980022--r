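# Multi-view initialization and gradient-based 2D/3D registration. Pose is
# initialized by triangulating landmarks detected in both views (at least
# three in common; silhouette-derived backup landmarks below that) and
# fitting a least-squares similarity transform from the template landmarks
# to the triangulated points; shape and pose are then refined by staged
# momentum gradient descent on a multi-view image similarity loss.

#' Triangulate a 3D point from two views
#'
#' Back-projects the two detections into rays and returns the midpoint of
#' the shortest segment between them; the residual is that segment's
#' length, a direct diagnostic of detection consistency.
#'
#' @param det_a,det_b length-2 pixel positions (u, v) in each view.
#' @param cam_a,cam_b the corresponding [camera] objects.
#' @param min_angle_deg rays closer to parallel than this raise a
#'   degenerate-geometry error naming the angle.
#' @return list with `point` (3-vector, mm), `residual` (mm) and
#'   `angle_deg` (ray separation).
#' @export
triangulate <- function(det_a, det_b, cam_a, cam_b, min_angle_deg = 1) {
  ra <- backproject_ray(cam_a, det_a)
  rb <- backproject_ray(cam_b, det_b)
  ct <- abs(sum(ra$d * rb$d))
  ang <- acos(min(1, max(-1, ct))) * 180 / pi
  if (ang < min_angle_deg) {
    stop(errorCondition(
      sprintf("degenerate triangulation geometry: rays separated by %.4f deg (< %.4f)",
              ang, min_angle_deg),
      class = c("spinefit_degenerate_geometry", "error")))
  }
  # closest points on the two lines o + s d
  w0 <- ra$o - rb$o
  a <- 1; b <- sum(ra$d * rb$d); c <- 1
  d0 <- sum(ra$d * w0); e0 <- sum(rb$d * w0)
  den <- a * c - b * b
  sA <- (b * e0 - c * d0) / den
  sB <- (a * e0 - b * d0) / den
  pa <- ra$o + sA * ra$d
  pb <- rb$o + sB * rb$d
  list(point = (pa + pb) / 2, residual = sqrt(sum((pa - pb)^2)),
       angle_deg = ang)
}

backproject_ray <- function(cam, uv) {
  o <- camera_center(cam)
  d <- as.numeric(crossprod(cam$R, solve(cam$K, c(uv[1], uv[2], 1))))
  list(o = o, d = d / sqrt(sum(d^2)))
}

# least-squares similarity transform (Umeyama): s * A %*% R + t ~ B
# (row-vector convention; the column-form rotation is t(R))
similarity_fit <- function(A, B, estimate_scale = TRUE) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  R <- kabsch_rotation(Ac, Bc)
  s <- if (estimate_scale) sum((Ac %*% R) * Bc) / sum(Ac^2) else 1
  t <- cb - s * as.numeric(ca %*% R)
  resid <- sqrt(mean(rowSums((s * A %*% R + rep(t, each = nrow(A)) - B)^2)))
  list(R_row = R, R = t(R), s = s, t = t, residual = resid)
}

# 3D reference points paired with the image-derived backup landmarks:
# bounding-box face centres and centre, which the silhouette bounding box
# approximates under the anteroposterior/lateral prior (image left/right
# are image-frame; the pairing assumes roughly AP geometry for the first
# view, which is the regime the backup fallback is meant for).
template_backup_points <- function(model) {
  V <- model$template$vertices
  lo <- apply(V, 2, min); hi <- apply(V, 2, max)
  ct <- (lo + hi) / 2
  rbind(centroid = ct,
        superior = c(ct[1], ct[2], hi[3]),
        inferior = c(ct[1], ct[2], lo[3]),
        left     = c(lo[1], ct[2], ct[3]),
        right    = c(hi[1], ct[2], ct[3]))
}

#' Initialize pose from multi-view landmark detections
#'
#' Finds the anatomical landmarks present in both views; with at least
#' three in common they are triangulated and a least-squares similarity
#' transform from the template landmark positions is solved. With fewer
#' than three, the five backup landmarks (silhouette centroid, superior,
#' inferior, left, right) are used instead and the fallback is flagged.
#' Below three usable correspondences the case fails initialization.
#' The estimated isotropic scale compensates patient size and is frozen
#' during subsequent gradient optimization. A warning is issued when the
#' views are separated by less than 15 degrees (weak geometry).
#'
#' @param detections list of detection data frames (one per view, see
#'   [simulate_detections]).
#' @param cameras list of [camera] objects matching `detections`.
#' @param model a `vertebra_ssm`.
#' @param min_common the common-landmark rule threshold (3).
#' @param estimate_scale solve for isotropic scale (default) or fix at 1.
#' @return list with `params` (a [pose_shape_params], coefficients zero)
#'   and `report` (landmarks used, counts, fallback flag, view separation,
#'   fit residual).
#' @export
initialize_pose <- function(detections, cameras, model, min_common = 3L,
                            estimate_scale = TRUE) {
  stopifnot(length(detections) >= 2, length(detections) == length(cameras))
  da <- detections[[1]]; db <- detections[[2]]
  sep <- view_separation_deg(cameras[[1]], cameras[[2]])
  if (sep < 15)
    warning(sprintf("views separated by only %.1f deg; geometry is weak", sep))

  present <- function(d, nms) {
    d <- d[d$present & d$landmark_name %in% nms, , drop = FALSE]
    out <- lapply(seq_len(nrow(d)), function(i) c(d$u_px[i], d$v_px[i]))
    stats::setNames(out, d$landmark_name)
  }
  pa <- present(da, LANDMARK_NAMES); pb <- present(db, LANDMARK_NAMES)
  common <- intersect(names(pa), names(pb))
  fallback <- FALSE
  if (length(common) >= min_common) {
    used <- common
    tmpl_pts <- model$template$vertices[model$template$landmark_indices[used], , drop = FALSE]
  } else {
    fallback <- TRUE
    ba <- present(da, BACKUP_NAMES); bb <- present(db, BACKUP_NAMES)
    used <- intersect(names(ba), names(bb))
    if (length(used) < min_common) {
      stop(errorCondition(
        sprintf("initialization failure: %d anatomical and %d backup landmarks in common (need %d)",
                length(common), length(used), min_common),
        class = c("spinefit_init_failure", "error")))
    }
    pa <- ba; pb <- bb
    tmpl_pts <- template_backup_points(model)[used, , drop = FALSE]
  }
  tri <- t(vapply(used, function(nm)
    triangulate(pa[[nm]], pb[[nm]], cameras[[1]], cameras[[2]])$point,
    numeric(3)))
  fit <- similarity_fit(tmpl_pts, tri, estimate_scale = estimate_scale)
  params <- pose_shape_params(
    rotation = matrix_to_axis_angle(fit$R),
    translation = fit$t,
    coeffs = rep(0, length(model$eigenvalues)),
    scale = fit$s)
  list(params = params,
       report = list(n_common = length(used), landmarks = used,
                     fallback = fallback, separation_deg = sep,
                     scale = fit$s, fit_residual_mm = fit$residual))
}

#' Optimizer configuration
#'
#' Staged momentum gradient descent: stage 1 refines pose only, stage 2
#' pose and shape jointly. Step sizes are per parameter block (axis-angle
#' radians, mm, standardized coefficients).
#'
#' @param stage_iters iterations per stage.
#' @param lr_rot,lr_t,lr_c step sizes for rotation, translation, shape.
#' @param momentum momentum coefficient.
#' @param tol stop a stage when the loss changes less than this over
#'   `tol_window` iterations.
#' @param tol_window window (iterations) for the convergence test.
#' @param coeff_bound coefficient clamp (standard deviations).
#' @param optimize_sigma jointly self-calibrate the splat kernel width
#'   (log scale) as a nuisance parameter; robustifies against the unknown
#'   blur of the target images.
#' @param lr_sigma step size for the log kernel width.
#' @param seed recorded for provenance; the optimizer itself is
#'   deterministic.
#' @return object of class `optimization_config`.
#' @export
optimization_config <- function(stage_iters = c(150L, 250L),
                                lr_rot = 0.01, lr_t = 0.5, lr_c = 0.05,
                                momentum = 0.9, tol = 1e-6,
                                tol_window = 20L, coeff_bound = 3,
                                optimize_sigma = TRUE, lr_sigma = 0.02,
                                seed = 1L) {
  stopifnot(all(stage_iters >= 0), tol > 0)
  structure(list(stage_iters = as.integer(stage_iters), lr_rot = lr_rot,
                 lr_t = lr_t, lr_c = lr_c, momentum = momentum, tol = tol,
                 tol_window = as.integer(tol_window),
                 coeff_bound = coeff_bound,
                 optimize_sigma = isTRUE(optimize_sigma),
                 lr_sigma = lr_sigma, seed = as.integer(seed)),
            class = "optimization_config")
}

#' Reconstruct a vertebra from multi-view images
#'
#' The package's central fit: starting from an initialization (typically
#' [initialize_pose]), minimizes a multi-view image similarity loss over
#' the 21 pose/shape parameters by staged momentum gradient descent with
#' analytic gradients through the splat renderer. Shape coefficients are
#' clamped to the admissible band; the best-seen parameters (not the last
#' iterate) are returned.
#'
#' @param model a `vertebra_ssm`.
#' @param targets list of target images (matrices matching the camera
#'   rasters).
#' @param cameras list of [camera] objects.
#' @param init a [pose_shape_params] or the list returned by
#'   [initialize_pose].
#' @param metric a [similarity_metric] with a gradient (default NCC).
#' @param config an [optimization_config].
#' @param render_config a [splat_config] for the registration renderer.
#' @return an object of class `vertebra_fit` with methods `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `plot`.
#' @export
reconstruct <- function(model, targets, cameras, init,
                        metric = ncc_metric(),
                        config = optimization_config(),
                        render_config = splat_config()) {
  report <- NULL
  if (!inherits(init, "pose_shape_params")) {
    report <- init$report
    init <- init$params
  }
  render_config <- resolve_render_config(render_config, model)
  k <- length(model$eigenvalues)
  stopifnot(length(init$coeffs) == k)

  theta <- c(init$rotation, init$translation, init$coeffs)
  lr <- c(rep(config$lr_rot, 3), rep(config$lr_t, 3), rep(config$lr_c, k))
  make_params <- function(th) pose_shape_params(
    rotation = th[1:3], translation = th[4:6],
    coeffs = if (k > 0) th[6 + seq_len(k)] else numeric(0),
    scale = init$scale, coeff_bound = config$coeff_bound)

  log_sigma <- log(render_config$sigma_mm)
  cfg_at <- function(ls) { rc <- render_config; rc$sigma_mm <- exp(ls); rc }

  g0 <- render_gradient(model, make_params(theta), targets, cameras,
                        cfg_at(log_sigma), metric)
  if (!is.finite(g0$loss)) {
    bad <- which(!vapply(g0$rendered, function(v) all(is.finite(v$raw)), logical(1)))
    stop("non-finite loss at initialization (view ",
         paste(bad, collapse = ", "), ")")
  }
  loss_trace <- g0$loss
  best <- list(theta = theta, loss = g0$loss, log_sigma = log_sigma)

  stages <- list(pose = 1:6, pose_shape = seq_len(6 + k))
  beta1 <- config$momentum; beta2 <- 0.999; eps <- 1e-8
  for (stage in seq_along(config$stage_iters)) {
    free <- if (stage == 1) stages$pose else stages$pose_shape
    m1 <- numeric(length(theta)); m2 <- numeric(length(theta))
    ms1 <- 0; ms2 <- 0
    stage_losses <- numeric(0)
    for (it in seq_len(config$stage_iters[stage])) {
      rg <- render_gradient(model, make_params(theta), targets, cameras,
                            cfg_at(log_sigma), metric)
      if (any(!is.finite(rg$grad))) {
        bad <- names(rg$grad)[!is.finite(rg$grad)]
        stop("non-finite gradient component: ", paste(bad, collapse = ", "))
      }
      loss_trace <- c(loss_trace, rg$loss)
      stage_losses <- c(stage_losses, rg$loss)
      if (rg$loss < best$loss)
        best <- list(theta = theta, loss = rg$loss, log_sigma = log_sigma)
      # Adam-style adaptive momentum step, per-block step sizes
      g <- rg$grad
      m1 <- beta1 * m1 + (1 - beta1) * g
      m2 <- beta2 * m2 + (1 - beta2) * g^2
      mh <- m1 / (1 - beta1^it); vh <- m2 / (1 - beta2^it)
      upd <- numeric(length(theta))
      upd[free] <- lr[free] * mh[free] / (sqrt(vh[free]) + eps)
      theta <- theta - upd
      if (config$optimize_sigma) {
        gs <- rg$grad_log_sigma
        ms1 <- beta1 * ms1 + (1 - beta1) * gs
        ms2 <- beta2 * ms2 + (1 - beta2) * gs^2
        log_sigma <- log_sigma - config$lr_sigma *
          (ms1 / (1 - beta1^it)) / (sqrt(ms2 / (1 - beta2^it)) + eps)
      }
      if (k > 0) {
        ci <- 6 + seq_len(k)
        theta[ci] <- pmin(config$coeff_bound, pmax(-config$coeff_bound, theta[ci]))
      }
      w <- config$tol_window
      if (length(stage_losses) > w) {
        recent <- stage_losses[(length(stage_losses) - w):length(stage_losses)]
        if (max(recent) - min(recent) < config$tol) break
      }
    }
    # evaluate the stage's final iterate too
    fl <- render_loss(model, make_params(theta), targets, cameras,
                      cfg_at(log_sigma), metric)
    loss_trace <- c(loss_trace, fl)
    if (fl < best$loss)
      best <- list(theta = theta, loss = fl, log_sigma = log_sigma)
  }

  render_config$sigma_mm <- exp(best$log_sigma)
  params <- make_params(best$theta)
  structure(list(
    params = params,
    init_params = init,
    init_report = report,
    loss_trace = loss_trace,
    initial_loss = loss_trace[1],
    final_loss = best$loss,
    non_improved = best$loss >= loss_trace[1] - 1e-15,
    model = model,
    cameras = cameras,
    targets = targets,
    metric = metric$name,
    config = config,
    render_config = render_config,
    fitted_mesh = predict(model, params)
  ), class = "vertebra_fit")
}

#' @export
print.vertebra_fit <- function(x, ...) {
  cat(sprintf("vertebra_fit: %s loss %.5f -> %.5f over %d evaluations%s\n",
              x$metric, x$initial_loss, x$final_loss,
              length(x$loss_trace),
              if (x$non_improved) " [non-improved]" else ""))
  if (!is.null(x$init_report))
    cat(sprintf("  init: %d landmarks%s, views %.1f deg apart\n",
                x$init_report$n_common,
                if (x$init_report$fallback) " (backup fallback)" else "",
                x$init_report$separation_deg))
  invisible(x)
}

#' @export
coef.vertebra_fit <- function(object, ...) {
  p <- object$params
  stats::setNames(c(p$rotation, p$translation, p$coeffs),
                  c(paste0("rot", 1:3), paste0("t", 1:3),
                    if (length(p$coeffs)) paste0("c", seq_along(p$coeffs))))
}

#' @export
fitted.vertebra_fit <- function(object, ...) object$fitted_mesh

#' Per-view image residuals of a fit
#'
#' Differences between the max-normalized rendered views at the fitted
#' parameters and the (max-normalized) targets.
#' @param object a `vertebra_fit`.
#' @param ... unused.
#' @return list of residual matrices, one per view.
#' @export
residuals.vertebra_fit <- function(object, ...) {
  views <- render_instance(object$model, object$params, object$cameras,
                           object$render_config)
  Map(function(v, tg) {
    tg <- as_image(tg)
    mx <- max(tg)
    v$image - if (mx > 0) tg / mx else tg
  }, views, object$targets)
}

#' @export
summary.vertebra_fit <- function(object, ...) {
  r <- residuals(object)
  structure(list(
    metric = object$metric,
    initial_loss = object$initial_loss,
    final_loss = object$final_loss,
    non_improved = object$non_improved,
    n_eval = length(object$loss_trace),
    init_report = object$init_report,
    coef = coef(object),
    residual_rms = vapply(r, function(m) sqrt(mean(m^2)), numeric(1))
  ), class = "summary.vertebra_fit")
}

#' @export
print.summary.vertebra_fit <- function(x, ...) {
  cat(sprintf("Vertebra reconstruction (%s metric)\n", x$metric))
  cat(sprintf("  loss: %.5f -> %.5f (%d evaluations)%s\n", x$initial_loss,
              x$final_loss, x$n_eval,
              if (x$non_improved) " [non-improved]" else ""))
  if (!is.null(x$init_report))
    cat(sprintf("  init: %d landmarks%s, separation %.1f deg, fit residual %.2f mm\n",
                x$init_report$n_common,
                if (x$init_report$fallback) " (backup fallback)" else "",
                x$init_report$separation_deg, x$init_report$fit_residual_mm))
  cat(sprintf("  per-view residual RMS: %s\n",
              paste(sprintf("%.4f", x$residual_rms), collapse = ", ")))
  cat("  coefficients:\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' @export
plot.vertebra_fit <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace) - 1, x$loss_trace, type = "l",
                 xlab = "evaluation", ylab = paste(x$metric, "loss"),
                 main = "Reconstruction loss trajectory", ...)
  graphics::abline(h = x$final_loss, lty = 2, col = "grey50")
  invisible(x)
}
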