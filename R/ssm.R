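# Statistical shape model: mean + PCA basis over corresponded vertices,
# instantiated as x_i = R (s * (mean_i + W_i (c * sqrt(lambda)))) + t.
# Coefficients are stored in standardized units (multiples of the mode
# standard deviation) and bounded, which gives the optimizer uniform
# scaling across modes.

#' Pose and shape parameters
#'
#' The 21 optimized degrees of freedom: a rotation (axis-angle 3-vector),
#' a translation (mm) and `k` standardized shape coefficients. An optional
#' isotropic scale, estimated at initialization and frozen during gradient
#' optimization, compensates patient size (the shape model removes scale
#' during Procrustes alignment).
#'
#' @param rotation length-3 axis-angle vector (radians).
#' @param translation length-3 vector (mm).
#' @param coeffs standardized shape coefficients (units of sqrt
#'   eigenvalue); each must lie within `coeff_bound`.
#' @param scale frozen isotropic scale (unitless).
#' @param coeff_bound admissible coefficient magnitude (standard
#'   deviations).
#' @return an object of class `pose_shape_params`.
#' @export
pose_shape_params <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                              coeffs = numeric(0), scale = 1,
                              coeff_bound = 3) {
  rotation <- as.numeric(rotation); translation <- as.numeric(translation)
  coeffs <- as.numeric(coeffs)
  stopifnot(length(rotation) == 3, length(translation) == 3,
            all(is.finite(rotation)), all(is.finite(translation)),
            all(is.finite(coeffs)), is.finite(scale), scale > 0)
  if (length(coeffs) && max(abs(coeffs)) > coeff_bound + 1e-12)
    stop("shape coefficients exceed the +/-", coeff_bound, " SD bound")
  structure(list(rotation = rotation, translation = translation,
                 coeffs = coeffs, scale = scale, coeff_bound = coeff_bound),
            class = "pose_shape_params")
}

#' @export
print.pose_shape_params <- function(x, ...) {
  cat(sprintf("pose_shape_params: |rot| = %.3f rad, t = (%.2f, %.2f, %.2f) mm, %d coeffs, scale %.3f\n",
              sqrt(sum(x$rotation^2)), x$translation[1], x$translation[2],
              x$translation[3], length(x$coeffs), x$scale))
  invisible(x)
}

#' Generalized Procrustes Analysis
#'
#' Similarity-aligns a population of corresponded point sets to an evolving
#' consensus: each set is centred, scaled to unit centroid size and
#' rotated (Kabsch) onto the mean, iterating until the consensus moves
#' less than `tol`. Global translation, rotation and scale differences are
#' removed; what remains is shape.
#'
#' @param point_sets list of n x 3 matrices with equal n (pre-resampled).
#' @param tol convergence tolerance on the Frobenius change of the mean.
#' @param max_iter iteration cap; non-convergence warns and returns the
#'   last iterate.
#' @return list with `aligned` (point sets, centroid 0, unit size),
#'   `transforms` (per set: `centroid`, `size`, `R` such that the aligned
#'   set is `((X - centroid) / size) R`), `mean` (consensus), `mean_size`
#'   (average centroid size, mm, for restoring metric units),
#'   `iterations`, `converged`.
#' @export
generalized_procrustes <- function(point_sets, tol = 1e-10, max_iter = 200L) {
  if (length(point_sets) < 2) stop("need at least 2 point sets")
  ns <- vapply(point_sets, nrow, integer(1))
  if (length(unique(ns)) != 1) stop("point sets must have equal cardinality")
  if (any(!vapply(point_sets, function(x) all(is.finite(x)), logical(1))))
    stop("point sets contain non-finite values")
  centroids <- lapply(point_sets, colMeans)
  centred <- Map(function(X, c0) sweep(X, 2, c0), point_sets, centroids)
  sizes <- vapply(centred, function(X) sqrt(sum(X^2)), numeric(1))
  if (any(sizes == 0)) stop("degenerate point set (zero centroid size)")
  aligned <- Map(function(X, s) X / s, centred, sizes)
  Rs <- rep(list(diag(3)), length(aligned))
  consensus <- aligned[[1]]
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_along(aligned)) {
      R <- kabsch_rotation(aligned[[i]], consensus)
      aligned[[i]] <- aligned[[i]] %*% R
      Rs[[i]] <- Rs[[i]] %*% R
    }
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - consensus)^2))
    consensus <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("generalized_procrustes did not converge in ", max_iter, " iterations")
  list(aligned = aligned,
       transforms = Map(function(c0, s, R) list(centroid = c0, size = s, R = R),
                        centroids, sizes, Rs),
       mean = consensus, mean_size = mean(sizes),
       iterations = it, converged = converged)
}

# rotation (no reflection) minimizing ||X R - Y||_F
kabsch_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

#' Build a statistical shape model by PCA
#'
#' @param shapes corresponded, aligned shapes: a list of n x 3 matrices or
#'   of 3n vectors (x1, y1, z1, x2, ...), or a matrix with one shape per
#'   row. Units are whatever the caller aligned in (mm for
#'   [build_ssm_population]).
#' @param k number of retained modes (default 15); reduced with a warning
#'   if it exceeds the available rank.
#' @param template a [labeled_mesh] supplying the canonical connectivity,
#'   labels and landmarks; its vertices are replaced by the mean shape.
#' @param path_annotations optional list of two [path_template] entries
#'   (left/right).
#' @return an object of class `vertebra_ssm` with fields `template`,
#'   `mean_shape` (3n), `basis` (3n x k, orthonormal columns),
#'   `eigenvalues` (mm^2, nonincreasing), `full_eigenvalues`,
#'   `path_annotations`.
#' @export
build_ssm <- function(shapes, k = 15L, template = NULL,
                      path_annotations = NULL) {
  S <- shapes_to_matrix(shapes)
  n <- nrow(S)
  if (n < 2) stop("need at least 2 shapes")
  mu <- colMeans(S)
  Xc <- sweep(S, 2, mu)
  sv <- svd(Xc, nu = 0)
  lambda_full <- sv$d^2 / (n - 1)
  rank_avail <- min(n - 1L, ncol(S))
  if (k > rank_avail) {
    warning("requested ", k, " modes but only ", rank_avail,
            " are available; reducing k")
    k <- rank_avail
  }
  basis <- sv$v[, seq_len(k), drop = FALSE]
  model <- structure(list(
    template = template,
    mean_shape = mu,
    basis = basis,
    eigenvalues = lambda_full[seq_len(k)],
    full_eigenvalues = lambda_full,
    n_training = n,
    path_annotations = path_annotations
  ), class = "vertebra_ssm")
  if (!is.null(template)) {
    model$template$vertices <- matrix(mu, ncol = 3, byrow = TRUE)
  }
  model
}

shapes_to_matrix <- function(shapes) {
  if (is.matrix(shapes)) return(shapes)
  rows <- lapply(shapes, function(s) {
    if (is.matrix(s)) as.numeric(t(s)) else as.numeric(s)
  })
  do.call(rbind, rows)
}

#' Build an SSM from a corresponded mesh population
#'
#' Convenience wrapper: GPA-align the vertex sets (removing translation,
#' rotation and scale), restore metric units at the population mean
#' centroid size, run PCA, and carry over connectivity, labels, landmarks
#' and template path annotations (derived from the template pedicle axes
#' when present).
#'
#' @param meshes list of [labeled_mesh] sharing connectivity.
#' @param k retained modes.
#' @return a `vertebra_ssm`.
#' @export
build_ssm_population <- function(meshes, k = 15L) {
  sets <- lapply(meshes, `[[`, "vertices")
  g <- generalized_procrustes(sets)
  shapes <- lapply(g$aligned, function(X) X * g$mean_size)
  template <- meshes[[1]]
  model <- build_ssm(shapes, k = k, template = template)
  # ground-truth axes of the first mesh, mapped into model frame, give the
  # template-side path annotation anchors
  if (!is.null(template$pedicle_axes)) {
    tr <- g$transforms[[1]]
    map_pt <- function(p) as.numeric(((p - tr$centroid) / tr$size) %*% tr$R) * g$mean_size
    axes <- lapply(template$pedicle_axes, function(ax)
      list(p0 = map_pt(ax$p0), p1 = map_pt(ax$p1)))
    model$template$pedicle_axes <- axes
    model$path_annotations <- annotate_template_paths(model$template, axes)
  }
  model
}

#' Fractions of variance per mode
#'
#' @param model a `vertebra_ssm` (used for its stored full eigenvalue
#'   spectrum) or `NULL`.
#' @param eigenvalues full eigenvalue list; defaults to the model's.
#' @return numeric vector of per-mode variance fractions (nonincreasing,
#'   summing to at most 1; all zero when the spectrum is all zero).
#' @export
variance_explained <- function(model = NULL, eigenvalues = model$full_eigenvalues) {
  stopifnot(all(eigenvalues >= -1e-12))
  tot <- sum(eigenvalues)
  if (tot <= 0) return(rep(0, length(eigenvalues)))
  eigenvalues / tot
}

#' Instantiate a shape-model instance as a mesh
#'
#' Evaluates `x_i = R (s (mean_i + W_i (c * sqrt(lambda)))) + t` and wraps
#' the result in the template connectivity with labels and landmarks
#' copied over.
#'
#' @param object a `vertebra_ssm`.
#' @param params a [pose_shape_params]; zero parameters reproduce the mean
#'   shape exactly.
#' @param ... unused.
#' @return a [labeled_mesh].
#' @export
predict.vertebra_ssm <- function(object, params = NULL, ...) {
  if (is.null(params)) params <- zero_params(object)
  stopifnot(length(params$coeffs) == length(object$eigenvalues))
  V <- instance_points(object, params)
  out <- object$template
  out$vertices <- V
  if (!is.null(object$template$pedicle_axes)) {
    R <- axis_angle_to_matrix(params$rotation)
    out$pedicle_axes <- lapply(object$template$pedicle_axes, function(ax)
      list(p0 = as.numeric(params$scale * (R %*% ax$p0) + params$translation),
           p1 = as.numeric(params$scale * (R %*% ax$p1) + params$translation)))
  }
  out
}

#' @rdname predict.vertebra_ssm
#' @export
instantiate <- function(object, params = NULL, ...) {
  predict(object, params, ...)
}

#' Zero (mean-shape) parameters for a model
#' @param model a `vertebra_ssm`.
#' @return a [pose_shape_params] with identity pose and zero coefficients.
#' @export
zero_params <- function(model) {
  pose_shape_params(coeffs = rep(0, length(model$eigenvalues)))
}

#' Draw random plausible shapes from the model
#'
#' Standardized coefficients are sampled from a standard normal truncated
#' to the coefficient bound; pose stays at identity.
#'
#' @param object a `vertebra_ssm`.
#' @param nsim number of draws.
#' @param seed integer seed.
#' @param sd coefficient scale (1 = population variability).
#' @param bound truncation bound in standard deviations.
#' @param ... unused.
#' @return list of [pose_shape_params].
#' @export
simulate.vertebra_ssm <- function(object, nsim = 1, seed = 1L, sd = 1,
                                  bound = 3, ...) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  k <- length(object$eigenvalues)
  lapply(seq_len(nsim), function(i) {
    cc <- stats::rnorm(k, 0, sd)
    cc <- pmin(bound, pmax(-bound, cc))
    pose_shape_params(coeffs = cc, coeff_bound = bound)
  })
}

#' @export
print.vertebra_ssm <- function(x, ...) {
  n <- length(x$mean_shape) / 3
  cat(sprintf("vertebra_ssm: %d vertices, %d modes (from %d training shapes)\n",
              n, length(x$eigenvalues), x$n_training))
  ve <- variance_explained(x)
  cat(sprintf("  variance in retained modes: %.1f%%\n",
              100 * sum(ve[seq_along(x$eigenvalues)])))
  if (!is.null(x$path_annotations)) cat("  template path annotations: left/right\n")
  invisible(x)
}

#' @export
summary.vertebra_ssm <- function(object, ...) {
  ve <- variance_explained(object)
  tab <- data.frame(mode = seq_along(object$eigenvalues),
                    eigenvalue_mm2 = object$eigenvalues,
                    var_fraction = ve[seq_along(object$eigenvalues)],
                    cumulative = cumsum(ve)[seq_along(object$eigenvalues)])
  structure(list(modes = tab, n_vertices = length(object$mean_shape) / 3,
                 n_training = object$n_training),
            class = "summary.vertebra_ssm")
}

#' @export
print.summary.vertebra_ssm <- function(x, ...) {
  cat(sprintf("Statistical shape model: %d vertices, %d training shapes\n",
              x$n_vertices, x$n_training))
  print(x$modes, row.names = FALSE, digits = 4)
  invisible(x)
}
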