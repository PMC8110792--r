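#' Acceptor-photobleaching FRET efficiency
#'
#' Donor-dequenching estimator: after background subtraction over the
#' bleach ROI, `E = 1 - donor_pre_mean / donor_post_mean`.  The acceptor
#' bleach completeness `1 - acceptor_post / acceptor_pre` is reported and
#' the result is marked invalid (not an error) when it falls below
#' `min_bleach_fraction` or the post-bleach donor mean is nonpositive.
#' Raw pre/post means are always emitted so alternative efficiency
#' definitions can be recomputed.
#'
#' @param pair A `fret_pair` (see [simulate_fret_pair()]) or a list with
#'   congruent `donor_pre`, `donor_post`, `acceptor_pre`,
#'   `acceptor_post` matrices, a logical `bleach_roi`, and `scale`.
#' @param min_bleach_fraction Minimum acceptor bleach completeness for a
#'   valid efficiency.
#' @param background_mode `"annulus"` (median of a 2-um ring around the
#'   ROI) or `"global_percentile"` (5th percentile of the field).
#' @return An `efficiency_result`: list with `efficiency`,
#'   `donor_pre_mean`, `donor_post_mean` (background-subtracted),
#'   `acceptor_bleach_fraction`, `valid`.
#' @export
fret_efficiency <- function(pair, min_bleach_fraction = 0.7,
                            background_mode = c("annulus",
                                                "global_percentile")) {
  background_mode <- match.arg(background_mode)
  imgs <- pair[c("donor_pre", "donor_post", "acceptor_pre", "acceptor_post")]
  if (any(vapply(imgs, is.null, logical(1)))) {
    stop("pair must carry donor/acceptor pre/post images", call. = FALSE)
  }
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims != dims[, 1])) stop("images must be congruent", call. = FALSE)
  roi <- pair$bleach_roi
  if (is.null(roi) || !any(roi)) stop("bleach ROI is empty", call. = FALSE)
  if (!all(dim(roi) == dims[, 1])) {
    stop("bleach ROI must match the image grid", call. = FALSE)
  }
  scale <- pair$scale %||% 1

  bgsub_mean <- function(img) {
    m <- measure_roi_intensity(img, roi, scale = scale,
                               background_mode = background_mode)
    m$raw_mean - m$background
  }
  dpre <- bgsub_mean(pair$donor_pre)
  dpost <- bgsub_mean(pair$donor_post)
  apre <- bgsub_mean(pair$acceptor_pre)
  apost <- bgsub_mean(pair$acceptor_post)

  bleach <- if (apre > 0) 1 - apost / apre else NA_real_
  bleach <- min(max(bleach, 0), 1)
  valid <- is.finite(bleach) && bleach >= min_bleach_fraction && dpost > 0
  eff <- if (dpost > 0) 1 - dpre / dpost else NA_real_
  structure(
    list(efficiency = eff, donor_pre_mean = dpre, donor_post_mean = dpost,
         acceptor_bleach_fraction = bleach, valid = valid),
    class = "efficiency_result"
  )
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("<efficiency_result> E = %.4f (bleach %.2f, %s)\n",
              x$efficiency, x$acceptor_bleach_fraction,
              if (x$valid) "valid" else "invalid"))
  invisible(x)
}

#' G-LISA fold activity relative to a control condition
#'
#' Each absorbance reading is first divided by its sample's protein
#' concentration (loading correction), then by the mean protein-corrected
#' absorbance of the control condition, so the control mean fold is
#' exactly 1.  The score is invariant to global absorbance units.
#'
#' @param plate Data frame with columns `sample_id`, `condition`,
#'   `absorbance` (AU, >= 0), `protein_conc` (mg/mL, > 0).
#' @param control_condition The condition to normalize against.
#' @return The plate with `corrected` and `fold_activity` columns.
#' @export
glisa_fold_activity <- function(plate, control_condition) {
  need <- c("sample_id", "condition", "absorbance", "protein_conc")
  stopifnot(all(need %in% names(plate)))
  if (any(plate$absorbance < 0)) stop("absorbance must be >= 0", call. = FALSE)
  if (any(plate$protein_conc <= 0)) {
    stop("protein_conc must be > 0", call. = FALSE)
  }
  ctrl <- plate$condition == control_condition
  if (!any(ctrl)) stop("control condition not present", call. = FALSE)
  plate$corrected <- plate$absorbance / plate$protein_conc
  plate$fold_activity <- plate$corrected / mean(plate$corrected[ctrl])
  plate
}
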