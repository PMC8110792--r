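#' Quadrant-binned modified Sholl profile
#'
#' Counts neurite crossings of concentric rings placed every
#' `ring_spacing` micrometres beyond the sphere rim (ring k has radius
#' `sphere$radius + k * ring_spacing`), binned into parallel vs
#' perpendicular quadrants relative to the stripe orientation.  A crossing
#' is a sign change of (distance-from-center minus ring radius) along
#' consecutive polyline vertices; a vertex lying exactly on a ring is
#' treated as inside, so it belongs to the outward-going crossing, and
#' tangencies count zero.  Each crossing is assigned to the quadrant of
#' the exact segment-circle intersection point.
#'
#' @param traces A `neurite_traces` data.frame.
#' @param sphere A [sphere_geometry()]; defaults to the one attached to
#'   `traces`.
#' @param ring_spacing Ring spacing from the rim, micrometres.
#' @param stripe_orientation Orientation vector along the lanes.
#' @param max_ring_um Optional outermost ring distance from the rim;
#'   defaults to the furthest vertex.
#' @return A `sholl_profile` data.frame with columns `ring_um` (distance
#'   from the rim), `crossings_parallel`, `crossings_perpendicular`, and
#'   `crossings_total`; attribute `n_inside` counts traces that never left
#'   the sphere.
#' @export
sholl_quadrant_profile <- function(traces, sphere = NULL, ring_spacing = 10,
                                   stripe_orientation = c(0, 1),
                                   max_ring_um = NULL) {
  sphere <- sphere %||% attr(traces, "sphere")
  stopifnot(inherits(sphere, "sphere_geometry"))
  stopifnot_scalar_pos(ring_spacing, "ring_spacing")
  qfun <- assign_quadrants(sphere, stripe_orientation)
  cx <- sphere$center[1]; cy <- sphere$center[2]

  tr_list <- split_traces(traces)
  if (length(tr_list)) {
    dmax <- max(vapply(tr_list, function(m) {
      max(sqrt((m[, 1] - cx)^2 + (m[, 2] - cy)^2))
    }, numeric(1)))
  } else {
    dmax <- sphere$radius
  }
  outer_um <- max_ring_um %||% (dmax - sphere$radius)
  K <- max(0L, floor(outer_um / ring_spacing))
  ring_um <- seq_len(K) * ring_spacing
  radii <- sphere$radius + ring_um
  cpar <- cper <- integer(K)
  n_inside <- 0L

  for (m in tr_list) {
    d <- sqrt((m[, 1] - cx)^2 + (m[, 2] - cy)^2)
    if (all(d <= sphere$radius)) n_inside <- n_inside + 1L
    if (K == 0L || nrow(m) < 2L) next
    # inside[i, k]: vertex i at or inside ring k (on-ring maps to inside)
    inside <- outer(d, radii, `<=`)
    cross <- inside[-nrow(inside), , drop = FALSE] !=
      inside[-1L, , drop = FALSE]
    hits <- which(cross, arr.ind = TRUE)
    if (nrow(hits) == 0L) next
    i <- hits[, 1L]; k <- hits[, 2L]
    p1x <- m[i, 1]; p1y <- m[i, 2]
    dx <- m[i + 1L, 1] - p1x; dy <- m[i + 1L, 2] - p1y
    fx <- p1x - cx; fy <- p1y - cy
    a <- dx^2 + dy^2
    b <- 2 * (fx * dx + fy * dy)
    cc <- fx^2 + fy^2 - radii[k]^2
    disc <- pmax(b^2 - 4 * a * cc, 0)
    sq <- sqrt(disc)
    t1 <- (-b - sq) / (2 * a)
    t2 <- (-b + sq) / (2 * a)
    # With a sign change there is exactly one root in (0, 1); pick it.
    tt <- ifelse(t1 > 0 & t1 <= 1, t1, t2)
    tt <- pmin(pmax(tt, 0), 1)
    q <- qfun(p1x + tt * dx, p1y + tt * dy)
    for (j in seq_along(k)) {
      if (q[j] == "parallel") cpar[k[j]] <- cpar[k[j]] + 1L
      else cper[k[j]] <- cper[k[j]] + 1L
    }
  }

  out <- data.frame(ring_um = ring_um,
                    crossings_parallel = cpar,
                    crossings_perpendicular = cper,
                    crossings_total = cpar + cper)
  class(out) <- c("sholl_profile", "data.frame")
  attr(out, "n_inside") <- n_inside
  attr(out, "ring_spacing") <- ring_spacing
  out
}
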