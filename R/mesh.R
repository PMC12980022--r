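#' @useDynLib spinefit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Canonical anatomical landmark names
#'
#' The ten landmarks carried by every labeled vertebra mesh: five on the
#' vertebral body (anterior, left, right, superior, inferior), the two
#' posterior pedicle entry points, and the tips of the spinous and the two
#' transverse processes.
#' @export
LANDMARK_NAMES <- c(
  "body_anterior", "body_left", "body_right",
  "body_superior", "body_inferior",
  "pedicle_left_entry", "pedicle_right_entry",
  "process_spinous_tip",
  "process_transverse_left_tip", "process_transverse_right_tip"
)

#' Backup landmark names
#'
#' Image-derived fallback landmarks (silhouette centroid plus the
#' superior/inferior/left/right extremes) used to initialize pose when
#' fewer than three anatomical landmarks are shared between views.
#' @export
BACKUP_NAMES <- c("centroid", "superior", "inferior", "left", "right")

REGION_LEVELS <- c("body", "pedicle_left", "pedicle_right", "process")

#' Labeled triangle mesh
#'
#' The package's mesh container: vertices in mm, 1-based triangular faces,
#' a per-vertex anatomical region label, named landmark vertex indices and
#' (optionally) ground-truth pedicle axis segments.
#'
#' @param vertices numeric n x 3 matrix of vertex positions (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices, wound
#'   counter-clockwise seen from outside (outward normals).
#' @param region_labels character vector of length n with values from
#'   `body`, `pedicle_left`, `pedicle_right`, `process`, or `NULL`.
#' @param landmark_indices named integer vector mapping the 10 canonical
#'   landmark names to vertex indices, or `NULL`.
#' @param pedicle_axes optional list with elements `left` and `right`, each
#'   a list of two 3-vectors `p0`, `p1` (mm) giving the tube centerline.
#' @param validate check invariants (watertightness, index ranges,
#'   degenerate faces). Disable only for meshes known valid.
#' @return an object of class `labeled_mesh`.
#' @export
labeled_mesh <- function(vertices, faces, region_labels = NULL,
                         landmark_indices = NULL, pedicle_axes = NULL,
                         validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  m <- structure(list(
    vertices = vertices, faces = faces,
    region_labels = region_labels,
    landmark_indices = landmark_indices,
    pedicle_axes = pedicle_axes
  ), class = "labeled_mesh")
  if (validate) validate_mesh(m)
  m
}

#' Validate a labeled mesh
#'
#' Checks the container invariants: finite vertices, in-range face and
#' landmark indices, positive face areas, exactly 10 canonical landmark
#' names when present, and watertightness (every edge shared by exactly
#' two faces).
#' @param mesh a [labeled_mesh].
#' @return the mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (!all(is.finite(v))) stop("mesh vertices contain non-finite values")
  if (min(f) < 1L || max(f) > nrow(v)) stop("face indices out of range")
  a <- face_areas(mesh)
  if (any(a <= 0)) stop("mesh has ", sum(a <= 0), " degenerate (zero-area) faces")
  if (!is.null(mesh$region_labels)) {
    if (length(mesh$region_labels) != nrow(v))
      stop("region_labels length must equal vertex count")
    bad <- setdiff(unique(mesh$region_labels), REGION_LEVELS)
    if (length(bad)) stop("unknown region labels: ", paste(bad, collapse = ", "))
  }
  if (!is.null(mesh$landmark_indices)) {
    li <- mesh$landmark_indices
    if (!setequal(names(li), LANDMARK_NAMES) || length(li) != 10L)
      stop("landmark_indices must carry exactly the 10 canonical names")
    if (min(li) < 1L || max(li) > nrow(v)) stop("landmark indices out of range")
  }
  if (!is_watertight(mesh)) {
    op <- open_edges(mesh)
    stop("mesh is not watertight: ", nrow(op), " edges not shared by exactly 2 faces")
  }
  invisible(mesh)
}

edge_table <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' @rdname validate_mesh
#' @export
is_watertight <- function(mesh) {
  e <- edge_table(mesh)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

open_edges <- function(mesh) {
  e <- edge_table(mesh)
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  bad <- names(tab)[tab != 2L]
  e[match(bad, key), , drop = FALSE]
}

#' Per-face areas and outward normals
#' @param mesh a [labeled_mesh].
#' @return `face_areas`: numeric vector (mm^2); `face_normals`: m x 3 matrix
#'   of unit outward normals.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  cr / pmax(sqrt(rowSums(cr^2)), 1e-300)
}

#' Signed enclosed volume (divergence theorem)
#'
#' Positive for outward-oriented closed meshes; used to verify and fix
#' face winding after construction.
#' @param mesh a [labeled_mesh].
#' @return signed volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p0 <- v[f[, 1], , drop = FALSE]
  p1 <- v[f[, 2], , drop = FALSE]
  p2 <- v[f[, 3], , drop = FALSE]
  sum(p0[, 1] * (p1[, 2] * p2[, 3] - p1[, 3] * p2[, 2]) +
      p0[, 2] * (p1[, 3] * p2[, 1] - p1[, 1] * p2[, 3]) +
      p0[, 3] * (p1[, 1] * p2[, 2] - p1[, 2] * p2[, 1])) / 6
}

#' Area-weighted uniform surface sampling
#'
#' @param mesh a [labeled_mesh].
#' @param n number of samples.
#' @param seed integer seed (sampling is always seeded).
#' @param faces optional subset of face indices to sample from.
#' @return n x 3 matrix of surface points (mm).
#' @export
sample_surface <- function(mesh, n = 10000L, seed = 1L, faces = NULL) {
  if (is.null(faces)) faces <- seq_len(nrow(mesh$faces))
  a <- face_areas(mesh)[faces]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fi <- faces[sample.int(length(faces), n, replace = TRUE, prob = a)]
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  w0 <- 1 - r1; w1 <- r1 * (1 - r2); w2 <- r1 * r2
  v <- mesh$vertices; f <- mesh$faces
  w0 * v[f[fi, 1], , drop = FALSE] +
    w1 * v[f[fi, 2], , drop = FALSE] +
    w2 * v[f[fi, 3], , drop = FALSE]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Apply a similarity transform to a mesh
#'
#' Vertices (and pedicle axes, if present) map as `x -> s * R x + t`.
#' @param mesh a [labeled_mesh].
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation (mm).
#' @param s isotropic scale.
#' @return transformed [labeled_mesh] (labels/landmarks preserved).
#' @export
transform_mesh <- function(mesh, R = diag(3), t = c(0, 0, 0), s = 1) {
  out <- mesh
  out$vertices <- sweep(s * (mesh$vertices %*% t(R)), 2, -t)
  if (!is.null(mesh$pedicle_axes)) {
    out$pedicle_axes <- lapply(mesh$pedicle_axes, function(ax)
      list(p0 = as.numeric(s * (R %*% ax$p0) + t),
           p1 = as.numeric(s * (R %*% ax$p1) + t)))
  }
  out
}

bbox_diagonal <- function(pts) {
  sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
}

mean_vertex_spacing <- function(pts) {
  D <- dist2_matrix_cpp(pts, pts)
  diag(D) <- Inf
  mean(sqrt(apply(D, 1, min)))
}

#' @export
print.labeled_mesh <- function(x, ...) {
  cat("labeled_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  if (!is.null(x$region_labels)) {
    tb <- table(x$region_labels)
    cat("  regions:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  if (!is.null(x$landmark_indices)) cat("  landmarks:", length(x$landmark_indices), "\n")
  if (!is.null(x$pedicle_axes)) cat("  pedicle axes: present\n")
  invisible(x)
}
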