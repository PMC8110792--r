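#' Mean ROI fluorescence with background subtraction
#'
#' Measures the mean immunolabel intensity within a growth-cone ROI mask,
#' subtracting a background estimate: the median of a 2-micrometre
#' dilation ring around the ROI (`"annulus"`) or the 5th percentile of
#' the whole field (`"global_percentile"`).  The background-subtracted
#' mean is floored at zero with a flag.
#'
#' @param label_image Numeric matrix of the immunolabel channel.
#' @param roi_mask Logical mask on the same grid (nonempty).
#' @param scale Micrometres per pixel; defaults to the mask's `scale`
#'   attribute.
#' @param background_mode `"annulus"` or `"global_percentile"`.
#' @param annulus_um Dilation ring width, micrometres.
#' @return An `intensity_measurement`: list with `mean_intensity`
#'   (background-subtracted), `raw_mean`, `background`, `mask_area`
#'   (square micrometres), `floored` flag.
#' @export
measure_roi_intensity <- function(label_image, roi_mask, scale = NULL,
                                  background_mode = c("annulus",
                                                      "global_percentile"),
                                  annulus_um = 2) {
  background_mode <- match.arg(background_mode)
  scale <- scale %||% attr(roi_mask, "scale") %||% 1
  if (!all(dim(label_image) == dim(roi_mask))) {
    stop("label image and ROI mask must share the same grid", call. = FALSE)
  }
  if (!any(roi_mask)) stop("ROI mask is empty", call. = FALSE)
  raw <- mean(label_image[roi_mask])
  bg <- if (background_mode == "annulus") {
    ring <- (EBImage::dilate(roi_mask, disc_brush(annulus_um, scale)) > 0) &
      !roi_mask
    if (!any(ring)) 0 else median(label_image[ring])
  } else {
    as.numeric(quantile(label_image, 0.05))
  }
  val <- raw - bg
  floored <- val < 0
  structure(
    list(mean_intensity = max(val, 0), raw_mean = raw, background = bg,
         mask_area = mask_area_um2(roi_mask, scale), floored = floored,
         background_mode = background_mode),
    class = "intensity_measurement"
  )
}

#' Normalize grouped measurements to a control group mean
#'
#' Divides every value by the mean of the control group, so the control
#' group mean of the normalized values is exactly 1.  Idempotent on
#' already-normalized data and order-preserving.
#'
#' @param measurements Data frame with columns `value` and `condition`.
#' @param control_label The condition acting as control.
#' @return The input data frame with a `normalized_value` column.
#' @export
normalize_to_control <- function(measurements, control_label) {
  stopifnot(all(c("value", "condition") %in% names(measurements)))
  ctrl <- measurements$value[measurements$condition == control_label]
  if (!length(ctrl)) stop("control group is empty", call. = FALSE)
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0) {
    stop("control group mean must be positive", call. = FALSE)
  }
  measurements$normalized_value <- measurements$value / m
  measurements
}
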