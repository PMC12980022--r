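# Parametric vertebra phantoms. The geometry is schematic, not anatomical:
# the point is a watertight labeled mesh with analytically known landmarks
# and pedicle axes, so every downstream stage (model building, rendering,
# registration, planning, metrics) can be exercised and checked exactly.
#
# Frame convention: +z superior, +y posterior, +x left (all mm).

#' Phantom vertebra parameters
#'
#' @param body_a,body_b elliptic vertebral-body radii along x and y (mm).
#' @param body_height body height along z (mm).
#' @param pedicle_radius pedicle tube radius (mm); must exceed 2.5 mm so a
#'   centred 5 mm-diameter trajectory cannot breach by construction.
#' @param pedicle_length pedicle tube length (mm).
#' @param pedicle_inclination_deg inward inclination of the pedicle axes
#'   toward the midline; length 1 (symmetric) or 2 (left, right).
#' @param process_spinous_length,process_transverse_length capsule process
#'   lengths (mm).
#' @param scale global isotropic scale (unitless).
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(body_a = 18, body_b = 14, body_height = 30,
                           pedicle_radius = 6, pedicle_length = 14,
                           pedicle_inclination_deg = 15,
                           process_spinous_length = 26,
                           process_transverse_length = 14,
                           scale = 1) {
  if (length(pedicle_inclination_deg) == 1)
    pedicle_inclination_deg <- rep(pedicle_inclination_deg, 2)
  p <- structure(list(
    body_a = body_a, body_b = body_b, body_height = body_height,
    pedicle_radius = pedicle_radius, pedicle_length = pedicle_length,
    pedicle_inclination_deg = pedicle_inclination_deg,
    process_spinous_length = process_spinous_length,
    process_transverse_length = process_transverse_length,
    scale = scale), class = "phantom_params")
  check_phantom_params(p)
  p
}

check_phantom_params <- function(p) {
  lens <- c(p$body_a, p$body_b, p$body_height, p$pedicle_radius,
            p$pedicle_length, p$process_spinous_length,
            p$process_transverse_length, p$scale)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("phantom parameters must be positive and finite")
  # the 16-gon tube wall lies at radius * cos(pi/16); the centred 5 mm
  # path must clear the 2.5 mm breach rule against that polyhedral wall
  if (p$pedicle_radius * cos(pi / 16) <= 2.5)
    stop("pedicle_radius must exceed ", round(2.5 / cos(pi / 16), 3),
         " mm (centred 5 mm path must be breach-free by construction)")
  if (any(abs(p$pedicle_inclination_deg) >= 40))
    stop("pedicle inclination must stay below 40 degrees")
  # derived layout must keep the pedicle tip on its own side of the midline
  x_e <- 0.55 * p$body_a
  for (s in 1:2) {
    a <- p$pedicle_inclination_deg[s] * pi / 180
    tip_x <- x_e - p$pedicle_length * sin(a)
    if (tip_x <= p$pedicle_radius * 0.2)
      stop("pedicle axis crosses the midline: shorten pedicle_length or inclination")
  }
  if (0.55 * p$body_a + p$pedicle_radius >= p$body_a + p$body_b)
    stop("pedicles too wide for the vertebral body")
  invisible(p)
}

# --- primitive builders (closed, outward-oriented) -------------------------

orthonormal_frame <- function(u, e1_hint = NULL) {
  u <- u / sqrt(sum(u^2))
  if (is.null(e1_hint)) e1_hint <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- e1_hint - sum(e1_hint * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- crossprod3(u, e1)
  list(u = u, e1 = e1, e2 = e2)
}

strip_faces <- function(ring_ids_a, ring_ids_b) {
  n <- length(ring_ids_a)
  j <- seq_len(n); jn <- c(seq_len(n)[-1], 1L)
  rbind(cbind(ring_ids_a[j], ring_ids_a[jn], ring_ids_b[jn]),
        cbind(ring_ids_a[j], ring_ids_b[jn], ring_ids_b[j]))
}

fan_faces <- function(apex_id, ring_ids, apex_at_start) {
  n <- length(ring_ids)
  j <- seq_len(n); jn <- c(seq_len(n)[-1], 1L)
  if (apex_at_start) cbind(apex_id, ring_ids[jn], ring_ids[j])
  else cbind(apex_id, ring_ids[j], ring_ids[jn])
}

orient_outward <- function(V, F) {
  vol <- signed_volume(list(vertices = V, faces = F))
  if (vol < 0) F <- F[, c(1, 3, 2)]
  F
}

# Elliptic cylinder from p0 to p1, radii (ra, rb) along (e1, e2); flat caps
# with centre vertices. Vertex 1 = cap centre at p0, vertex 2 = cap centre
# at p1, then rings bottom-to-top with theta = 2*pi*(j-1)/n_theta.
closed_cylinder <- function(p0, p1, ra, rb, n_theta = 32L, n_len = 8L,
                            e1_hint = NULL) {
  L <- sqrt(sum((p1 - p0)^2))
  fr <- orthonormal_frame(p1 - p0, e1_hint)
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  ring <- function(center, sa, sb)
    t(vapply(th, function(a) center + sa * cos(a) * fr$e1 + sb * sin(a) * fr$e2,
             numeric(3)))
  V <- rbind(p0, p1)
  ring_ids <- list()
  for (i in 0:n_len) {
    c_i <- p0 + (i / n_len) * (p1 - p0)
    V <- rbind(V, ring(c_i, ra, rb))
    ring_ids[[i + 1]] <- 2L + i * n_theta + seq_len(n_theta)
  }
  F <- fan_faces(1L, ring_ids[[1]], apex_at_start = TRUE)
  for (i in seq_len(n_len))
    F <- rbind(F, strip_faces(ring_ids[[i]], ring_ids[[i + 1]]))
  F <- rbind(F, fan_faces(2L, ring_ids[[n_len + 1]], apex_at_start = FALSE))
  F <- orient_outward(V, F)
  list(V = V, F = F, cap0 = 1L, cap1 = 2L, frame = fr, n_theta = n_theta)
}

# Capsule (cylinder with hemispherical ends) from p0 to p1, radius r.
# Vertex 1 = apex beyond p0, vertex 2 = apex beyond p1.
capsule <- function(p0, p1, r, n_theta = 16L, n_len = 4L, n_cap = 4L) {
  fr <- orthonormal_frame(p1 - p0)
  u <- fr$u
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  ring <- function(center, rad)
    t(vapply(th, function(a) center + rad * (cos(a) * fr$e1 + sin(a) * fr$e2),
             numeric(3)))
  V <- rbind(p0 - r * u, p1 + r * u)
  ring_ids <- list(); k <- 0L
  add_ring <- function(center, rad) {
    V <<- rbind(V, ring(center, rad))
    k <<- k + 1L
    ring_ids[[k]] <<- 2L + (k - 1L) * n_theta + seq_len(n_theta)
  }
  for (j in rev(seq_len(n_cap - 1))) { # bottom cap, apex upward to equator
    phi <- (pi / 2) * j / n_cap
    add_ring(p0 - r * sin(phi) * u, r * cos(phi))
  }
  for (i in 0:n_len) add_ring(p0 + (i / n_len) * (p1 - p0), r)
  for (j in seq_len(n_cap - 1)) {
    phi <- (pi / 2) * j / n_cap
    add_ring(p1 + r * sin(phi) * u, r * cos(phi))
  }
  F <- fan_faces(1L, ring_ids[[1]], apex_at_start = TRUE)
  for (i in seq_len(k - 1))
    F <- rbind(F, strip_faces(ring_ids[[i]], ring_ids[[i + 1]]))
  F <- rbind(F, fan_faces(2L, ring_ids[[k]], apex_at_start = FALSE))
  F <- orient_outward(V, F)
  list(V = V, F = F, apex0 = 1L, apex1 = 2L)
}

# --- phantom assembly ------------------------------------------------------

#' Generate a labeled vertebra phantom
#'
#' Builds a watertight mesh as a union of closed primitives: an elliptic
#' cylinder for the vertebral body, two tube pedicles whose centerlines are
#' the ground-truth transpedicular axes, and capsules for the spinous and
#' transverse processes. Vertices carry region labels (the pedicle label
#' covers only the lateral tube wall, the cortical surface the breach rule
#' measures against), the 10 canonical landmarks sit on exact mesh
#' vertices, and the mesh connectivity is independent of the parameters so
#' phantom populations are corresponded by construction.
#'
#' @param params a [phantom_params].
#' @param seed accepted for interface symmetry; the mesh is a deterministic
#'   function of `params` only.
#' @return a [labeled_mesh] with landmarks and pedicle axes.
#' @export
generate_vertebra <- function(params = phantom_params(), seed = 1L) {
  p <- params
  check_phantom_params(p)
  sc <- p$scale
  x_e <- 0.55 * p$body_a
  y_e <- p$body_b + 6
  comps <- list(); labels <- character(0)
  Vall <- NULL; Fall <- NULL
  add_comp <- function(V, F, label_per_vertex) {
    off <- if (is.null(Vall)) 0L else nrow(Vall)
    Vall <<- rbind(Vall, V)
    Fall <<- rbind(Fall, F + off)
    labels <<- c(labels, label_per_vertex)
    off
  }

  # vertebral body
  body <- closed_cylinder(c(0, 0, -p$body_height / 2), c(0, 0, p$body_height / 2),
                          p$body_a, p$body_b, n_theta = 32L, n_len = 8L,
                          e1_hint = c(1, 0, 0))
  off_body <- add_comp(body$V, body$F, rep("body", nrow(body$V)))

  # pedicles: tubes from posterior entry toward the body, inclined inward
  axes <- list()
  ped_offsets <- integer(2)
  for (s in 1:2) {
    sgn <- if (s == 1) 1 else -1      # s = 1: left (+x)
    a <- p$pedicle_inclination_deg[s] * pi / 180
    d <- c(-sgn * sin(a), -cos(a), 0)
    p0 <- c(sgn * x_e, y_e, 0)
    p1 <- p0 + p$pedicle_length * d
    tube <- closed_cylinder(p0, p1, p$pedicle_radius, p$pedicle_radius,
                            n_theta = 16L, n_len = 6L)
    lab <- rep(if (s == 1) "pedicle_left" else "pedicle_right", nrow(tube$V))
    lab[c(tube$cap0, tube$cap1)] <- "body"  # caps are junctions, not cortical wall
    ped_offsets[s] <- add_comp(tube$V, tube$F, lab)
    axes[[if (s == 1) "left" else "right"]] <- list(p0 = p0, p1 = p1)
  }

  # spinous process (posterior midline, anchored into the body; slim
  # enough that the pedicle axes keep > 2.5 mm clearance from it)
  sp0 <- c(0, p$body_b - 1.5, 0)
  sp1 <- sp0 + c(0, p$process_spinous_length, 0)
  spin <- capsule(sp0, sp1, 3.5, n_theta = 16L, n_len = 4L, n_cap = 4L)
  off_spin <- add_comp(spin$V, spin$F, rep("process", nrow(spin$V)))

  # transverse processes (lateral, anchored into the posterior body wall,
  # clear of the pedicle tubes)
  tr_off <- integer(2)
  for (s in 1:2) {
    sgn <- if (s == 1) 1 else -1
    t0 <- c(sgn * (p$body_a - 2), 6, 0)
    t1 <- t0 + c(sgn * p$process_transverse_length, 0, 0)
    tr <- capsule(t0, t1, 3, n_theta = 16L, n_len = 4L, n_cap = 4L)
    tr_off[s] <- add_comp(tr$V, tr$F, rep("process", nrow(tr$V)))
  }

  Vall <- Vall * sc
  axes <- lapply(axes, function(ax) list(p0 = ax$p0 * sc, p1 = ax$p1 * sc))

  # landmarks on exact vertices; body ring layout: theta = 0 at +x,
  # pi/2 at +y (posterior); n_theta = 32, mid ring (z = 0) is ring index 4
  nb <- 32L
  mid_ring_start <- off_body + 2L + 4L * nb
  lm <- c(
    body_anterior = mid_ring_start + 1L + 3L * nb / 4L, # theta = 3pi/2 -> -y
    body_left     = mid_ring_start + 1L,                # theta = 0 -> +x
    body_right    = mid_ring_start + 1L + nb / 2L,      # theta = pi -> -x
    body_superior = off_body + 2L,                      # top cap centre
    body_inferior = off_body + 1L,                      # bottom cap centre
    pedicle_left_entry  = ped_offsets[1] + 1L,          # posterior cap centre
    pedicle_right_entry = ped_offsets[2] + 1L,
    process_spinous_tip = off_spin + 2L,                # apex beyond sp1
    process_transverse_left_tip  = tr_off[1] + 2L,
    process_transverse_right_tip = tr_off[2] + 2L
  )
  storage.mode(lm) <- "integer"

  labeled_mesh(Vall, Fall, region_labels = labels,
               landmark_indices = lm, pedicle_axes = axes)
}

#' Sample a phantom population
#'
#' Draws phantom parameters around the defaults — log-normal multiplicative
#' variation for lengths/radii/scale, additive normal variation (degrees)
#' for the pedicle inclinations — and generates one phantom per draw. All
#' phantoms share mesh connectivity, so the population is corresponded
#' vertex-by-vertex by construction.
#'
#' @param n population size (>= 1).
#' @param variation named list of variation magnitudes: relative log-normal
#'   sigma for `body_a`, `body_b`, `body_height`, `pedicle_radius`,
#'   `pedicle_length`, `process_spinous_length`,
#'   `process_transverse_length`, `scale`; absolute normal sd (deg) for
#'   `pedicle_inclination_deg`. Missing entries default to
#'   `default_variation()`; pass an empty list for no variation.
#' @param seed integer seed; populations are reproducible.
#' @param base baseline [phantom_params].
#' @return list of [labeled_mesh] phantoms, with the drawn
#'   `phantom_params` attached as attribute `params`.
#' @export
sample_population <- function(n, variation = default_variation(), seed = 1L,
                              base = phantom_params()) {
  stopifnot(n >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  vr <- variation
  draw <- function() {
    ln <- function(x, key) {
      s <- vr[[key]]
      if (is.null(s) || s == 0) x else x * exp(stats::rnorm(1, 0, s))
    }
    incl <- base$pedicle_inclination_deg
    s_incl <- vr[["pedicle_inclination_deg"]]
    if (!is.null(s_incl) && s_incl > 0) incl <- incl + stats::rnorm(2, 0, s_incl)
    phantom_params(
      body_a = ln(base$body_a, "body_a"),
      body_b = ln(base$body_b, "body_b"),
      body_height = ln(base$body_height, "body_height"),
      pedicle_radius = ln(base$pedicle_radius, "pedicle_radius"),
      pedicle_length = ln(base$pedicle_length, "pedicle_length"),
      pedicle_inclination_deg = incl,
      process_spinous_length = ln(base$process_spinous_length, "process_spinous_length"),
      process_transverse_length = ln(base$process_transverse_length, "process_transverse_length"),
      scale = ln(base$scale, "scale"))
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    prm <- draw()
    m <- generate_vertebra(prm)
    attr(m, "params") <- prm
    out[[i]] <- m
  }
  out
}

#' Default population variation
#'
#' Relative (log-normal sigma) and angular (sd, degrees) variation
#' magnitudes chosen to emulate moderate inter-subject vertebral
#' variability at phantom scale.
#' @return named list, see [sample_population].
#' @export
default_variation <- function() {
  list(body_a = 0.06, body_b = 0.06, body_height = 0.07,
       pedicle_radius = 0.06, pedicle_length = 0.08,
       pedicle_inclination_deg = 2,
       process_spinous_length = 0.08, process_transverse_length = 0.08,
       scale = 0.05)
}
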