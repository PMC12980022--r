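# Transpedicular trajectory planning. Entry and exit points are annotated
# once on the model template as barycentric anchors on template faces
# (sub-facet precision, exactly equivariant under pose), propagated to any
# reconstruction by evaluating the anchors on the instantiated mesh, and
# screened against the cortical pedicle wall with a minimum-distance rule.

#' Barycentric path anchor template
#'
#' @param side `"left"` or `"right"`.
#' @param entry_face,exit_face template face indices carrying the anchors.
#' @param entry_bary,exit_bary barycentric weights (length 3, nonnegative,
#'   summing to 1).
#' @return an object of class `path_template`.
#' @export
path_template <- function(side, entry_face, entry_bary, exit_face, exit_bary) {
  check_bary <- function(b) {
    stopifnot(length(b) == 3, all(b >= -1e-12), abs(sum(b) - 1) < 1e-9)
    pmax(b, 0) / sum(pmax(b, 0))
  }
  structure(list(side = match.arg(side, c("left", "right")),
                 entry_face = as.integer(entry_face),
                 entry_bary = check_bary(entry_bary),
                 exit_face = as.integer(exit_face),
                 exit_bary = check_bary(exit_bary)),
            class = "path_template")
}

eval_barycentric <- function(mesh, face, bary) {
  f <- mesh$faces[face, ]
  as.numeric(bary[1] * mesh$vertices[f[1], ] +
             bary[2] * mesh$vertices[f[2], ] +
             bary[3] * mesh$vertices[f[3], ])
}

# all intersections of the line p0 + t*(p1-p0) with mesh faces
# (Moller-Trumbore, vectorized); returns data frame (t, face, bary)
ray_mesh_intersections <- function(mesh, p0, dir) {
  V <- mesh$vertices; F <- mesh$faces
  v0 <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - v0
  e2 <- V[F[, 3], , drop = FALSE] - v0
  h <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
             dir[3] * e2[, 1] - dir[1] * e2[, 3],
             dir[1] * e2[, 2] - dir[2] * e2[, 1])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  s <- sweep(-v0, 2, -p0)       # p0 - v0
  u <- rowSums(s * h) / a
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  v <- (q[, 1] * dir[1] + q[, 2] * dir[2] + q[, 3] * dir[3]) / a
  t <- rowSums(e2 * q) / a
  hit <- ok & u >= -1e-10 & v >= -1e-10 & (u + v) <= 1 + 1e-10
  data.frame(t = t[hit], face = which(hit),
             u = u[hit], v = v[hit])
}

#' Annotate transpedicular path templates on a template mesh
#'
#' Anchors the entry point at the posterior pedicle-axis endpoint and the
#' exit point where the extended axis pierces the anterior surface, both
#' as barycentric coordinates on template faces.
#' @param template a [labeled_mesh] with pedicle axes.
#' @param axes optional axes list overriding `template$pedicle_axes`.
#' @return list with elements `left` and `right`, each a [path_template].
#' @export
annotate_template_paths <- function(template, axes = template$pedicle_axes) {
  stopifnot(!is.null(axes))
  lapply(stats::setNames(names(axes), names(axes)), function(side) {
    ax <- axes[[side]]
    d <- ax$p1 - ax$p0
    hits <- ray_mesh_intersections(template, ax$p0, d)
    if (nrow(hits) == 0) stop("pedicle axis does not intersect the template")
    ent <- hits[which.min(hits$t), ]
    ext <- hits[which.max(hits$t), ]
    path_template(side,
                  entry_face = ent$face,
                  entry_bary = c(1 - ent$u - ent$v, ent$u, ent$v),
                  exit_face = ext$face,
                  exit_bary = c(1 - ext$u - ext$v, ext$u, ext$v))
  })
}

#' Transpedicular path plan
#'
#' @param entry,exit 3D points (mm), distinct.
#' @param diameter cylinder diameter (mm), default 5.
#' @param side `"left"`, `"right"` or `NA`.
#' @param min_wall_distance_mm,breach filled by [breach_check].
#' @return an object of class `path_plan`.
#' @export
path_plan <- function(entry, exit, diameter = 5, side = NA_character_,
                      min_wall_distance_mm = NA_real_, breach = NA) {
  entry <- as.numeric(entry); exit <- as.numeric(exit)
  stopifnot(length(entry) == 3, length(exit) == 3, diameter > 0)
  if (sqrt(sum((entry - exit)^2)) < 1e-12) stop("entry and exit coincide")
  structure(list(entry = entry, exit = exit, diameter = diameter,
                 side = side, min_wall_distance_mm = min_wall_distance_mm,
                 breach = breach),
            class = "path_plan")
}

#' @export
print.path_plan <- function(x, ...) {
  cat(sprintf("path_plan (%s): %.1f mm cylinder, length %.1f mm",
              x$side, x$diameter, sqrt(sum((x$exit - x$entry)^2))))
  if (!is.na(x$breach))
    cat(sprintf(", wall distance %.2f mm [%s]", x$min_wall_distance_mm,
                if (x$breach) "BREACH" else "ok"))
  cat("\n")
  invisible(x)
}

#' Propagate a template path through a fitted model
#'
#' Evaluates the barycentric anchors on the instantiated mesh; no
#' per-case optimization. Propagation commutes exactly with rigid motion
#' of the instance.
#' @param model a `vertebra_ssm`.
#' @param params a [pose_shape_params].
#' @param template a [path_template] (defaults to the model's annotation
#'   for `side`).
#' @param side used when `template` is `NULL`.
#' @return a [path_plan] without breach verdict.
#' @export
propagate_path <- function(model, params, template = NULL, side = "left") {
  if (is.null(template)) {
    stopifnot(!is.null(model$path_annotations))
    template <- model$path_annotations[[side]]
  }
  inst <- predict(model, params)
  path_plan(entry = eval_barycentric(inst, template$entry_face, template$entry_bary),
            exit = eval_barycentric(inst, template$exit_face, template$exit_bary),
            side = template$side)
}

point_segment_distance <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  w <- sweep(pts, 2, a)
  t <- pmin(1, pmax(0, as.numeric(w %*% ab) / len2))
  proj <- outer(t, ab)
  sqrt(rowSums((w - proj)^2))
}

#' Check a path plan for cortical breach
#'
#' Samples the labeled pedicle wall densely (area-weighted, at least
#' `samples_per_mm2` per mm^2) and measures the exact point-to-segment
#' distance to the path axis. A trajectory breaches when the minimum wall
#' distance falls below `threshold` (2.5 mm, which for a 5 mm-diameter
#' cylinder detects cylinder-wall contact exactly).
#'
#' @param plan a [path_plan] with a `side`.
#' @param mesh a [labeled_mesh] with pedicle region labels.
#' @param threshold breach threshold (mm).
#' @param samples_per_mm2 wall sampling density.
#' @param seed integer seed for the surface sampling.
#' @return the plan with `min_wall_distance_mm` and `breach` filled in.
#' @export
breach_check <- function(plan, mesh, threshold = 2.5, samples_per_mm2 = 10,
                         seed = 1L) {
  if (is.null(mesh$region_labels))
    stop("mesh has no region labels; cannot locate pedicle walls")
  lab <- paste0("pedicle_", plan$side)
  vlab <- mesh$region_labels
  fidx <- which(vlab[mesh$faces[, 1]] == lab &
                vlab[mesh$faces[, 2]] == lab &
                vlab[mesh$faces[, 3]] == lab)
  if (length(fidx) == 0)
    stop("mesh has no '", lab, "' wall faces")
  area <- sum(face_areas(mesh)[fidx])
  nsamp <- max(1000L, ceiling(area * samples_per_mm2))
  pts <- sample_surface(mesh, nsamp, seed = seed, faces = fidx)
  d <- point_segment_distance(pts, plan$entry, plan$exit)
  plan$min_wall_distance_mm <- min(d)
  plan$breach <- plan$min_wall_distance_mm < threshold
  plan
}

#' Triangulation-based 2D path planning baseline
#'
#' The geometric-planning baseline: entry and exit are annotated (or
#' detected) independently in each 2D view and triangulated to 3D; a
#' 5 mm-diameter cylinder is constructed. A missing endpoint in any view
#' is a planning failure for that pedicle.
#'
#' @param entry_uv,exit_uv lists of length-2 pixel positions per view
#'   (`NULL`/`NA` marks a missing detection).
#' @param cameras list of two [camera] objects.
#' @param diameter cylinder diameter (mm).
#' @param side recorded on the plan.
#' @return a [path_plan] (without breach verdict).
#' @export
geoplan_triangulate <- function(entry_uv, exit_uv, cameras, diameter = 5,
                                side = NA_character_) {
  ok <- function(p) !is.null(p) && length(p) == 2 && all(is.finite(p))
  if (length(entry_uv) < length(cameras) || length(exit_uv) < length(cameras) ||
      !all(vapply(entry_uv, ok, logical(1))) ||
      !all(vapply(exit_uv, ok, logical(1)))) {
    stop(errorCondition(
      paste0("planning failure (", side, "): path endpoint missing in a view"),
      class = c("spinefit_planning_failure", "error")))
  }
  ent <- triangulate(entry_uv[[1]], entry_uv[[2]], cameras[[1]], cameras[[2]])
  ext <- triangulate(exit_uv[[1]], exit_uv[[2]], cameras[[1]], cameras[[2]])
  path_plan(ent$point, ext$point, diameter = diameter, side = side)
}

#' Bipedicular planning success
#'
#' A case counts as a success iff both pedicles yield a plan without
#' breach. Planning failures (missing endpoints, degenerate geometry)
#' count as failures.
#' @param left,right [path_plan] objects with verdicts, or anything else
#'   (e.g. a captured error condition) to denote a per-pedicle failure.
#' @return logical.
#' @export
plan_success <- function(left, right) {
  ok <- function(p) inherits(p, "path_plan") && !is.na(p$breach) && !p$breach
  ok(left) && ok(right)
}
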