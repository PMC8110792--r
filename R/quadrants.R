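#' Quadrant labelling relative to the stripe orientation
#'
#' Partitions the plane around the sphere center into four 90-degree
#' sectors bounded by the +/-45-degree diagonals relative to the stripe
#' orientation.  The two sectors bisected by the stripe direction are
#' "parallel", the other two "perpendicular".  Sector boundaries are
#' half-open with the counter-clockwise edge included, so a point at
#' exactly +45 degrees from the stripe direction is perpendicular, and
#' rotating the orientation by 90 degrees swaps every label.
#'
#' @param sphere A [sphere_geometry()].
#' @param stripe_orientation Orientation vector along the lanes (nonzero).
#' @return A vectorized function `f(x, y)` returning `"parallel"` or
#'   `"perpendicular"` for points in micrometres.
#' @export
assign_quadrants <- function(sphere, stripe_orientation) {
  stopifnot(inherits(sphere, "sphere_geometry"))
  v <- as.numeric(stripe_orientation)
  if (length(v) != 2L || !all(is.finite(v)) || sum(v^2) == 0) {
    stop("`stripe_orientation` must be a nonzero length-2 vector",
         call. = FALSE)
  }
  cx <- sphere$center[1]; cy <- sphere$center[2]
  vang <- atan2(v[2], v[1])
  function(x, y) {
    deg <- ((atan2(y - cy, x - cx) - vang) * 180 / pi) %% 360
    par <- (deg < 45) | (deg >= 315) | (deg >= 135 & deg < 225)
    ifelse(par, "parallel", "perpendicular")
  }
}
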