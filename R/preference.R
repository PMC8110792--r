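#' Normalized substratum-preference score
#'
#' Compares neurite coverage density on cue lanes vs laminin-only lanes
#' within the analysis region: pixels at least `exclusion_radius`
#' micrometres beyond the sphere rim, optionally intersected with the
#' parallel quadrants.  Each substratum's neurite area is divided by the
#' available area of that substratum inside the region (density
#' correction, so unequal lane availability does not bias the score), and
#' the preference is the cue density over the laminin density: 1 means no
#' preference, values below 1 mean cue avoidance.
#'
#' @param neurite_mask Logical mask from [segment_neurites()] (same grid
#'   as the pattern).
#' @param stripes A [generate_stripe_pattern()] object.
#' @param sphere A [sphere_geometry()].
#' @param exclusion_radius Micrometres beyond the rim excluded from
#'   analysis.
#' @param restrict_to_parallel_quadrants Restrict the region to the
#'   parallel quadrants (default `TRUE`).
#' @return A `preference_result` list: `area_on_cue`, `area_on_LN`
#'   (square micrometres), `density_cue`, `density_LN`,
#'   `normalized_preference`, `valid` (FALSE when the laminin density is
#'   zero or a substratum has no available area in the region).
#' @export
substratum_preference <- function(neurite_mask, stripes, sphere,
                                  exclusion_radius = 100,
                                  restrict_to_parallel_quadrants = TRUE) {
  stopifnot(inherits(stripes, "stripe_pattern"),
            inherits(sphere, "sphere_geometry"))
  if (!all(dim(neurite_mask) == dim(stripes$label))) {
    stop("mask and stripe pattern must share the same pixel grid",
         call. = FALSE)
  }
  sc <- stripes$scale
  nx <- nrow(neurite_mask); ny <- ncol(neurite_mask)
  xs <- pixel_centers(nx, sc); ys <- pixel_centers(ny, sc)
  dx2 <- (xs - sphere$center[1])^2
  dy2 <- (ys - sphere$center[2])^2
  dist <- sqrt(outer(dx2, dy2, `+`))
  region <- dist >= sphere$radius + exclusion_radius
  if (restrict_to_parallel_quadrants) {
    qfun <- assign_quadrants(sphere, stripes$orientation)
    xg <- matrix(xs, nx, ny)
    yg <- matrix(ys, nx, ny, byrow = TRUE)
    region <- region & (qfun(xg, yg) == "parallel")
  }
  cue_avail <- region & stripes$label
  ln_avail <- region & !stripes$label
  a_cue <- sum(neurite_mask & cue_avail)
  a_ln <- sum(neurite_mask & ln_avail)
  n_cue <- sum(cue_avail); n_ln <- sum(ln_avail)
  d_cue <- if (n_cue > 0) a_cue / n_cue else NA_real_
  d_ln <- if (n_ln > 0) a_ln / n_ln else NA_real_
  valid <- is.finite(d_cue) && is.finite(d_ln) && d_ln > 0
  structure(
    list(area_on_cue = a_cue * sc^2, area_on_LN = a_ln * sc^2,
         available_cue = n_cue * sc^2, available_LN = n_ln * sc^2,
         density_cue = d_cue, density_LN = d_ln,
         normalized_preference = if (valid) d_cue / d_ln else NA_real_,
         valid = valid),
    class = "preference_result"
  )
}

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf(
    "<preference_result> cue %.1f um2 / LN %.1f um2, normalized preference %s\n",
    x$area_on_cue, x$area_on_LN,
    if (x$valid) sprintf("%.3f", x$normalized_preference) else "undefined"))
  invisible(x)
}
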