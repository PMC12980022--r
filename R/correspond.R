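# Correspondence machinery for model building on meshes of arbitrary
# topology: rigid ICP for initial correspondences, non-rigid coherent
# point drift (Gaussian mixture with motion-coherence regularization) for
# deformable alignment, and the alternating fit/re-correspond/PCA
# refinement loop.

#' Iterative closest point correspondence
#'
#' Alternates nearest-neighbour matching (ties broken by lowest target
#' index) with a rigid Kabsch fit until the mean residual stops
#' improving. The mean residual is nonincreasing across iterations.
#'
#' @param template n x 3 moving point set.
#' @param target m x 3 fixed point set.
#' @param max_iter iteration cap.
#' @param tol stop when the mean residual improves by less than this (mm).
#' @return list with `correspondence` (fields `source_size`,
#'   `target_size`, `mapping` — per-template index into the target —,
#'   `mean_residual` in mm), `R` (column-form rotation), `t`
#'   (translation), `aligned` (transformed template), `residual_trace`.
#' @export
icp_correspond <- function(template, target, max_iter = 50L, tol = 1e-9) {
  template <- rbind2mat(template); target <- rbind2mat(target)
  if (nrow(template) == 0 || nrow(target) == 0)
    stop("icp_correspond requires non-empty point sets")
  X <- template
  R_tot <- diag(3); t_tot <- c(0, 0, 0)
  trace <- numeric(0)
  prev <- Inf
  mapping <- NULL
  for (it in seq_len(max_iter)) {
    nn <- nn_bruteforce_cpp(X, target)
    mapping <- nn$idx
    res <- mean(nn$dist)
    trace <- c(trace, res)
    if (prev - res < tol) break
    prev <- res
    Yp <- target[mapping, , drop = FALSE]
    cx <- colMeans(X); cy <- colMeans(Yp)
    R <- kabsch_rotation(sweep(X, 2, cx), sweep(Yp, 2, cy))
    tt <- cy - as.numeric(cx %*% R)
    X <- sweep(X %*% R, 2, -tt)
    R_tot <- R_tot %*% R
    t_tot <- as.numeric(t_tot %*% R) + tt
  }
  nn <- nn_bruteforce_cpp(X, target)
  list(correspondence = list(source_size = nrow(template),
                             target_size = nrow(target),
                             mapping = nn$idx,
                             mean_residual = mean(nn$dist)),
       R = t(R_tot), t = t_tot, aligned = X, residual_trace = trace)
}

#' Non-rigid coherent point drift
#'
#' Standard non-rigid CPD: the template points are Gaussian mixture
#' centres drifting toward the target under a motion-coherence prior
#' (Gaussian kernel of width `beta`, weight `lambda`). Point sets are
#' internally centred and jointly scaled; `beta` is expressed in those
#' normalized units. The regularized negative log-likelihood is
#' nonincreasing across EM steps.
#'
#' @param template n x 3 moving point set (mixture centres).
#' @param target m x 3 fixed point set (data).
#' @param beta kernel width (normalized units).
#' @param lambda motion-coherence regularization weight.
#' @param max_iter EM iteration cap.
#' @param tol stop when sigma^2 changes by less than `tol` relatively.
#' @param w uniform-outlier weight in [0, 1).
#' @return list with `points` (deformed template, original units/frame of
#'   the target), `objective_trace` (regularized NLL), `sigma2_trace`,
#'   `iterations`.
#' @export
cpd_nonrigid <- function(template, target, beta = 2, lambda = 3,
                         max_iter = 60L, tol = 1e-8, w = 0) {
  template <- rbind2mat(template); target <- rbind2mat(target)
  if (nrow(template) == 0 || nrow(target) == 0)
    stop("cpd_nonrigid requires non-empty point sets")
  stopifnot(beta > 0, lambda > 0, w >= 0, w < 1)
  M <- nrow(template); N <- nrow(target); D <- 3
  ym <- colMeans(template); xm <- colMeans(target)
  Yc <- sweep(template, 2, ym); Xc <- sweep(target, 2, xm)
  s <- sqrt((sum(Yc^2) + sum(Xc^2)) / (M + N))
  Y <- Yc / s; X <- Xc / s

  G <- exp(-dist2_matrix_cpp(Y, Y) / (2 * beta^2))
  W <- matrix(0, M, D)
  Tm <- Y
  sigma2 <- sum(dist2_matrix_cpp(X, Y)) / (D * M * N)
  obj_trace <- numeric(0); s2_trace <- numeric(0)

  for (it in seq_len(max_iter)) {
    D2 <- dist2_matrix_cpp(Tm, X)            # M x N
    Kmat <- exp(-D2 / (2 * sigma2))
    denom <- colSums(Kmat)
    cconst <- if (w > 0) (w / (1 - w)) * (2 * pi * sigma2)^(D / 2) * M / N else 0
    denom <- denom + cconst
    denom[denom < 1e-300] <- 1e-300
    # regularized negative log-likelihood at the current state
    nll <- -sum(log(denom / M / (2 * pi * sigma2)^(D / 2))) +
      lambda / 2 * sum(W * (G %*% W))
    if (!is.finite(nll))
      stop("cpd_nonrigid: non-finite objective at iteration ", it,
           " (sigma2 = ", signif(sigma2, 4), ")")
    obj_trace <- c(obj_trace, nll)
    s2_trace <- c(s2_trace, sigma2)

    P <- sweep(Kmat, 2, denom, "/")          # responsibilities
    P1 <- rowSums(P); Pt1 <- colSums(P); Np <- sum(P1)
    A <- G * P1 + diag(lambda * sigma2, M)   # (d(P1) G + lambda sigma2 I)
    B <- P %*% X - P1 * Y
    W <- solve(A, B)
    Tm <- Y + G %*% W
    xPx <- sum(Pt1 * rowSums(X^2))
    trPT <- sum((P %*% X) * Tm)
    tTT <- sum(P1 * rowSums(Tm^2))
    sigma2_new <- (xPx - 2 * trPT + tTT) / (Np * D)
    sigma2_new <- max(sigma2_new, 1e-12)
    if (abs(sigma2_new - sigma2) < tol * sigma2) { sigma2 <- sigma2_new; break }
    sigma2 <- sigma2_new
  }
  list(points = sweep(Tm * s, 2, -xm), objective_trace = obj_trace,
       sigma2_trace = s2_trace, iterations = length(s2_trace), W = W,
       responsibilities = P)
}

#' Correspond a population of meshes to a template
#'
#' For each target mesh: rigidly align the template vertex set by ICP,
#' deform it onto the target with non-rigid CPD, and take the deformed
#' template points as the corresponded resampling of the target at the
#' template's cardinality. All outputs share the template's vertex count
#' and order, ready for [generalized_procrustes] and [build_ssm].
#'
#' @param template a [labeled_mesh] (canonical topology).
#' @param meshes list of [labeled_mesh] targets.
#' @param beta,lambda CPD hyperparameters (see [cpd_nonrigid]).
#' @param max_iter CPD iteration cap.
#' @return list of n x 3 corresponded point sets.
#' @export
correspond_population <- function(template, meshes, beta = 2, lambda = 3,
                                  max_iter = 60L) {
  lapply(meshes, function(m) {
    icp <- icp_correspond(template$vertices, m$vertices)
    cpd <- cpd_nonrigid(icp$aligned, m$vertices, beta = beta,
                        lambda = lambda, max_iter = max_iter)
    cpd$points
  })
}

# Fit pose (+ optional scale) and shape coefficients of a model to a raw
# mesh by point-to-surface least squares: ICP alignment of the mean shape
# for the pose seed, Gauss-Newton steps on closest-surface-point
# residuals (point-to-triangle, tolerant of tangential parametrization
# slide), then the same number of point-to-point polishing steps against
# nearest target vertices, which pin down the parametrization once the
# surfaces coincide (so model-generated meshes are refitted exactly).
fit_model_to_mesh <- function(model, mesh, gn_steps = 5L,
                              estimate_scale = TRUE, damping = 1e-8) {
  k <- length(model$eigenvalues)
  mean_pts <- shape_points(model, rep(0, k))
  icp <- icp_correspond(mean_pts, mesh$vertices)
  v <- matrix_to_axis_angle(icp$R)
  tt <- icp$t
  cc <- rep(0, k)
  sc <- 1
  if (estimate_scale) {
    # closed-form scale given the ICP pose (centroid-size ratio)
    sc <- sqrt(sum(scale(mesh$vertices, scale = FALSE)^2) /
                 sum(scale(mean_pts, scale = FALSE)^2))
  }
  sqrtl <- sqrt(model$eigenvalues)
  for (step in seq_len(2L * gn_steps)) {
    point_to_point <- step > gn_steps
    R <- axis_angle_to_matrix(v)
    P <- shape_points(model, cc)
    Y <- sc * P
    Xw <- sweep(Y %*% t(R), 2, -tt)
    Q <- if (point_to_point) {
      mesh$vertices[nn_bruteforce_cpp(Xw, mesh$vertices)$idx, , drop = FALSE]
    } else {
      point_mesh_closest_cpp(Xw, mesh$vertices, mesh$faces - 1L)$closest
    }
    r <- as.numeric(t(Xw - Q))                      # 3n residual vector
    n <- nrow(Xw)
    A <- rotation_jacobian(v)
    J <- matrix(0, 3 * n, 6 + k)
    for (a in 1:3) {
      J[, a] <- as.numeric(t(Y %*% t(A[[a]])))      # dX/dv_a
      J[, 3 + a] <- rep(diag(3)[, a], n)            # dX/dt_a
    }
    if (k > 0) {
      RW <- model$basis                              # 3n x k, model frame
      # rotate each vertex block: dX/dc_j = s sqrt(l_j) R W_ij
      for (j in seq_len(k)) {
        Wj <- matrix(RW[, j], ncol = 3, byrow = TRUE)
        J[, 6 + j] <- sc * sqrtl[j] * as.numeric(t(Wj %*% t(R)))
      }
    }
    H <- crossprod(J)
    # Levenberg-Marquardt damping: strong in the surface stage, where
    # tangential slide makes directions nearly unobservable, negligible in
    # the well-posed point-to-point stage
    mu <- if (point_to_point) damping else 1e-3
    H <- H + diag(mu * mean(diag(H)) + damping, 6 + k)
    delta <- solve(H, crossprod(J, -r))
    v <- v + delta[1:3]; tt <- tt + delta[4:6]
    if (k > 0) cc <- pmin(3, pmax(-3, cc + delta[6 + seq_len(k)]))
  }
  R <- axis_angle_to_matrix(v)
  Xw <- sweep((sc * shape_points(model, cc)) %*% t(R), 2, -tt)
  cp <- point_mesh_closest_cpp(Xw, mesh$vertices, mesh$faces - 1L)
  nn <- nn_bruteforce_cpp(Xw, mesh$vertices)
  list(params = pose_shape_params(rotation = v, translation = tt,
                                  coeffs = cc, scale = sc),
       residual = mean(cp$dist), instance = Xw, mapping = nn$idx,
       closest = cp$closest)
}

#' Refine a shape model by alternating correspondence and PCA
#'
#' Each round: (1) fit the current model to every raw mesh (pose + shape,
#' point-to-surface Gauss-Newton), (2) re-establish ICP correspondences
#' from the fitted instance to the raw mesh and pull the matched surface
#' points back into the model frame, (3) rebuild the PCA. The population
#' mean fitting residual is tracked and must not increase (tolerance
#' 1e-6 mm); if it does, refinement stops and the best round is returned.
#'
#' @param model a `vertebra_ssm`.
#' @param meshes list of raw [labeled_mesh] targets.
#' @param rounds number of refinement rounds; 0 returns the model
#'   unchanged.
#' @param gn_steps Gauss-Newton steps per per-mesh fit.
#' @return the refined `vertebra_ssm` with attribute `residual_trace`.
#' @export
refine_ssm <- function(model, meshes, rounds = 3L, gn_steps = 5L) {
  if (rounds == 0) return(model)
  k <- length(model$eigenvalues)
  best <- model
  best_res <- Inf
  trace <- numeric(0)
  for (r in seq_len(rounds)) {
    # scale stays fixed during refinement: within-population size
    # variation belongs to the shape space, and a free scale would make
    # model-generated populations drift instead of being a fixed point
    fits <- lapply(meshes, function(m)
      fit_model_to_mesh(model, m, gn_steps, estimate_scale = FALSE))
    res <- mean(vapply(fits, `[[`, numeric(1), "residual"))
    trace <- c(trace, res)
    if (res > best_res + 1e-6) {
      warning("refinement residual increased at round ", r,
              "; returning best model")
      break
    }
    if (res < best_res) { best_res <- res; best <- model }
    shapes <- lapply(seq_along(meshes), function(i) {
      f <- fits[[i]]
      y <- f$closest   # nearest raw-surface point per template vertex
      Rm <- axis_angle_to_matrix(f$params$rotation)
      sweep(y, 2, f$params$translation) %*% Rm / f$params$scale
    })
    model <- build_ssm(shapes, k = k, template = model$template,
                       path_annotations = model$path_annotations)
  }
  # final fit quality of the last rebuilt model
  fits <- lapply(meshes, function(m)
    fit_model_to_mesh(model, m, gn_steps, estimate_scale = FALSE))
  res <- mean(vapply(fits, `[[`, numeric(1), "residual"))
  trace <- c(trace, res)
  if (res <= best_res + 1e-6) best <- model
  attr(best, "residual_trace") <- trace
  best
}

#' Propagate template annotations onto a raw mesh
#'
#' Computes the volumetric DICE between a fitted model instance and the
#' raw mesh; if the fit reaches `min_dice` (inclusive), landmarks and
#' template path endpoints are transferred by correspondence (nearest raw
#' vertex for landmarks, barycentric evaluation for path endpoints);
#' otherwise the mesh is rejected, carrying the score. The default
#' threshold 0.85 mirrors the supervision filter used when curating
#' training annotations.
#'
#' @param fitted a fitted instance [labeled_mesh] (e.g.
#'   `fitted(reconstruct(...))` or `fit_model_to_mesh()$instance` wrapped
#'   in the template connectivity), or a `vertebra_fit`.
#' @param mesh the raw [labeled_mesh].
#' @param model the `vertebra_ssm` providing template path annotations.
#' @param min_dice acceptance threshold (inclusive).
#' @param spacing voxel spacing for the DICE computation (mm).
#' @return list with `accepted`, `dice`, and when accepted
#'   `landmark_indices` (on the raw mesh) and `path_points` (left/right
#'   entry/exit, mm).
#' @export
propagate_annotation <- function(fitted, mesh, model = NULL,
                                 min_dice = 0.85, spacing = 1) {
  if (inherits(fitted, "vertebra_fit")) {
    model <- fitted$model
    fitted <- fitted$fitted_mesh
  }
  d <- voxel_dice(fitted, mesh, spacing = spacing)
  if (d < min_dice) return(list(accepted = FALSE, dice = d))
  lm_pos <- fitted$vertices[fitted$landmark_indices, , drop = FALSE]
  nn <- nn_bruteforce_cpp(lm_pos, mesh$vertices)
  lm_idx <- stats::setNames(nn$idx, names(fitted$landmark_indices))
  path_points <- NULL
  if (!is.null(model) && !is.null(model$path_annotations)) {
    path_points <- lapply(model$path_annotations, function(tpl)
      list(entry = eval_barycentric(fitted, tpl$entry_face, tpl$entry_bary),
           exit = eval_barycentric(fitted, tpl$exit_face, tpl$exit_bary)))
  }
  list(accepted = TRUE, dice = d, landmark_indices = lm_idx,
       path_points = path_points)
}
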