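# Axis-angle <-> rotation-matrix machinery. Rotations are optimized as
# axis-angle 3-vectors v with R = exp([v]x); the exponential map and its
# Jacobian have removable singularities at theta = 0 handled by series
# expansion.

skew <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Axis-angle to rotation matrix (exponential map)
#' @param v length-3 axis-angle vector (radians times unit axis).
#' @return 3 x 3 rotation matrix.
#' @export
axis_angle_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  K <- skew(v)
  if (th < 1e-8) {
    # second-order series keeps the map and Jacobian smooth through 0
    return(diag(3) + K + 0.5 * K %*% K)
  }
  diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * K %*% K
}

#' Rotation matrix to axis-angle (logarithm map)
#' @param R 3 x 3 rotation matrix.
#' @return length-3 axis-angle vector with angle in [0, pi].
#' @export
matrix_to_axis_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-8) {
    w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
    return(w)
  }
  if (th > pi - 1e-6) {
    # near pi: extract axis from R + I
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs from off-diagonals
    i <- which.max(ax)
    ax <- B[, i] / ax[i]
    ax <- ax / sqrt(sum(ax^2))
    return(th * ax)
  }
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  th * w
}

# dR/dv_i for the exponential map (Gallego & Yezzi closed form); returns a
# list of three 3x3 matrices.
rotation_jacobian <- function(v) {
  th2 <- sum(v^2)
  R <- axis_angle_to_matrix(v)
  if (th2 < 1e-12) {
    return(lapply(1:3, function(i) skew(diag(3)[, i])))
  }
  ImR <- diag(3) - R
  lapply(1:3, function(i) {
    e <- diag(3)[, i]
    (v[i] * skew(v) + skew(crossprod3(v, ImR %*% e))) %*% R / th2
  })
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Geodesic angle between two rotations
#' @param Ra,Rb 3 x 3 rotation matrices.
#' @return angle in degrees.
#' @export
rotation_angle_deg <- function(Ra, Rb) {
  ct <- (sum(diag(crossprod(Ra, Rb))) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}
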