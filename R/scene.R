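#' Neurosphere geometry
#'
#' @param center Sphere center `c(x, y)` in micrometres.
#' @param radius Sphere radius in micrometres (> 0).  All ring radii in the
#'   Sholl profile and all exclusion distances are measured from the rim.
#' @return A `sphere_geometry` list.
#' @export
sphere_geometry <- function(center, radius) {
  stopifnot(length(center) == 2L, is.numeric(center))
  stopifnot_scalar_pos(radius, "radius")
  structure(list(center = as.numeric(center), radius = radius),
            class = "sphere_geometry")
}

#' Parameters of a synthetic stripe-assay scene
#'
#' The generative model for a neurosphere on a striped substratum: neurites
#' leave the rim at uniform angles and grow as persistent random walks; a
#' proposed step whose endpoint lands on a cue lane is accepted with
#' probability `exp(-avoidance_beta)`, otherwise the heading is redrawn.
#' `avoidance_beta = 0` is indifference, large values give near-complete
#' cue avoidance.
#'
#' @param sphere_radius Sphere radius, micrometres.  Spheres in the assays
#'   this emulates range roughly 100-500 um in radius.
#' @param n_neurites Number of neurites to grow (>= 0).
#' @param step_length Random-walk step, micrometres.
#' @param turn_sd Per-step heading change SD, radians.
#' @param avoidance_beta Cue avoidance strength (>= 0).
#' @param max_length Maximum neurite path length, micrometres.
#' @param seed Integer RNG seed; the simulation is a pure function of the
#'   parameter object including this seed.
#' @return A `scene_params` list.
#' @export
scene_params <- function(sphere_radius = 150, n_neurites = 200,
                         step_length = 5, turn_sd = 0.35,
                         avoidance_beta = 0, max_length = 400, seed = 1) {
  stopifnot_scalar_pos(sphere_radius, "sphere_radius")
  stopifnot_scalar_pos(step_length, "step_length")
  stopifnot_scalar_pos(max_length, "max_length")
  stopifnot(n_neurites >= 0, turn_sd >= 0, avoidance_beta >= 0)
  structure(list(sphere_radius = sphere_radius,
                 n_neurites = as.integer(n_neurites),
                 step_length = step_length, turn_sd = turn_sd,
                 avoidance_beta = avoidance_beta, max_length = max_length,
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' Simulate neurite traces on a striped substratum
#'
#' Each trace starts on the sphere rim at a uniform angle with an outward
#' radial heading and advances in fixed-length steps with Gaussian heading
#' noise.  Steps that *enter* a cue lane (endpoint on cue, current
#' position not) are accepted with probability `exp(-beta)`; on rejection
#' the heading is redrawn (up to `max_retries` times, after which the step
#' is taken parallel to the stripes, in the parallel direction closest to
#' the current heading, sliding along the lane boundary).  Movement within
#' a lane is free, so a growth cone that finds itself on cue can leave but
#' is reluctant to return.  One acceptance uniform is drawn per proposal
#' whether or not it enters a cue lane, so at `beta = 0` the trace set is
#' identical for any stripe map under the same seed.
#'
#' @param scene A [scene_params()] object (the sphere is centred on the
#'   canvas implied by `center`).
#' @param stripes A [generate_stripe_pattern()] object.
#' @param center Sphere center in micrometres; defaults to the canvas
#'   center of `stripes`.
#' @param max_retries Heading redraws before stepping parallel.
#' @return A `neurite_traces` data.frame with columns `trace_id`,
#'   `vertex_index`, `x_um`, `y_um`; attribute `sphere` carries the
#'   [sphere_geometry()].
#' @export
simulate_neurite_traces <- function(scene, stripes, center = NULL,
                                    max_retries = 10L) {
  stopifnot(inherits(scene, "scene_params"),
            inherits(stripes, "stripe_pattern"))
  if (is.null(center)) {
    center <- c(nrow(stripes$label), ncol(stripes$label)) * stripes$scale / 2
  }
  sphere <- sphere_geometry(center, scene$sphere_radius)
  n <- scene$n_neurites
  n_steps <- max(1L, ceiling(scene$max_length / scene$step_length))
  accept_p <- exp(-scene$avoidance_beta)
  par_ang <- atan2(stripes$orientation[2], stripes$orientation[1])

  if (n == 0L) {
    out <- data.frame(trace_id = integer(), vertex_index = integer(),
                      x_um = numeric(), y_um = numeric())
    class(out) <- c("neurite_traces", "data.frame")
    attr(out, "sphere") <- sphere
    return(out)
  }

  xs <- matrix(NA_real_, n, n_steps + 1L)
  ys <- matrix(NA_real_, n, n_steps + 1L)

  with_seed(scene$seed, {
    ang0 <- runif(n, 0, 2 * pi)
    px <- center[1] + scene$sphere_radius * cos(ang0)
    py <- center[2] + scene$sphere_radius * sin(ang0)
    heading <- ang0
    xs[, 1L] <- px; ys[, 1L] <- py
    L <- scene$step_length

    for (s in seq_len(n_steps)) {
      on_cue_now <- stripe_is_cue(stripes, px, py)
      prop <- heading + rnorm(n, 0, scene$turn_sd)
      ex <- px + L * cos(prop); ey <- py + L * sin(prop)
      u <- runif(n)
      enters <- stripe_is_cue(stripes, ex, ey) & !on_cue_now
      accept <- !enters | (u < accept_p)
      tries <- 0L
      while (any(!accept) && tries < max_retries) {
        idx <- which(!accept)
        prop[idx] <- heading[idx] + rnorm(length(idx), 0, scene$turn_sd)
        ex[idx] <- px[idx] + L * cos(prop[idx])
        ey[idx] <- py[idx] + L * sin(prop[idx])
        u2 <- runif(length(idx))
        accept[idx] <- !(stripe_is_cue(stripes, ex[idx], ey[idx]) &
                           !on_cue_now[idx]) | (u2 < accept_p)
        tries <- tries + 1L
      }
      if (any(!accept)) {
        # step parallel to the stripes, in the parallel direction closest
        # to the current heading
        idx <- which(!accept)
        sgn <- ifelse(cos(heading[idx] - par_ang) >= 0, 1, -1)
        prop[idx] <- par_ang + (1 - sgn) * pi / 2
        ex[idx] <- px[idx] + L * cos(prop[idx])
        ey[idx] <- py[idx] + L * sin(prop[idx])
      }
      heading <- prop
      px <- ex; py <- ey
      xs[, s + 1L] <- px; ys[, s + 1L] <- py
    }
  })

  out <- data.frame(
    trace_id = rep(seq_len(n), each = n_steps + 1L),
    vertex_index = rep(seq_len(n_steps + 1L), times = n),
    x_um = as.vector(t(xs)),
    y_um = as.vector(t(ys))
  )
  class(out) <- c("neurite_traces", "data.frame")
  attr(out, "sphere") <- sphere
  out
}

#' Split a traces table into per-trace coordinate matrices
#' @param traces A `neurite_traces` data.frame.
#' @return Named list of two-column matrices `(x_um, y_um)`.
#' @export
split_traces <- function(traces) {
  lapply(split(traces[, c("x_um", "y_um")], traces$trace_id), as.matrix)
}
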