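#' Threshold the F-actin channel into a neurite mask
#'
#' Thresholds a single-channel image (Otsu or a fixed value) and removes
#' connected components smaller than `min_object_area`.  A zero-variance
#' image yields an empty mask with a warning rather than an error.
#'
#' @param factin_image Numeric matrix (see package geometry conventions).
#' @param scale Micrometres per pixel.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_value Threshold used when `threshold_method = "fixed"`.
#' @param min_object_area Minimum connected-component area, square
#'   micrometres.
#' @return Logical mask with attributes `scale` and `threshold`.
#' @export
segment_neurites <- function(factin_image, scale = 1,
                             threshold_method = c("otsu", "fixed"),
                             fixed_value = NULL, min_object_area = 5) {
  threshold_method <- match.arg(threshold_method)
  stopifnot_scalar_pos(scale, "scale")
  img <- factin_image
  empty <- function() {
    m <- matrix(FALSE, nrow(img), ncol(img))
    attr(m, "scale") <- scale; attr(m, "threshold") <- NA_real_
    m
  }
  if (stats::var(as.vector(img)) == 0) {
    warning("image has zero variance; returning an empty mask")
    return(empty())
  }
  thr <- if (threshold_method == "otsu") {
    rng <- range(img)
    scaled <- (img - rng[1]) / diff(rng)
    EBImage::otsu(scaled) * diff(rng) + rng[1]
  } else {
    if (is.null(fixed_value)) stop("`fixed_value` required", call. = FALSE)
    fixed_value
  }
  mask <- img > thr
  mask <- drop_small_components(mask, min_px = min_object_area / scale^2)
  attr(mask, "scale") <- scale
  attr(mask, "threshold") <- thr
  mask
}

# 8-connected component labels via EBImage's 4-connected bwlabel on a
# 1-px dilation, restricted back to the mask (thin diagonal structures
# must not fragment).
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::dilate(mask, matrix(1, 3, 3)) > 0)
  lab[!mask] <- 0L
  lab
}

drop_small_components <- function(mask, min_px) {
  if (!any(mask)) return(mask)
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Growth-cone ROI mask from the F-actin channel
#'
#' Thresholds a single growth-cone field, keeps the largest connected
#' component as the growth-cone ROI, and fills holes.
#'
#' @inheritParams segment_neurites
#' @param min_object_area Components below this area (square micrometres)
#'   are ignored when picking the largest.
#' @return Logical mask with attributes `scale` and `threshold`; empty
#'   (with a warning) for a zero-variance image.
#' @export
make_factin_mask <- function(factin_image, scale = 1,
                             threshold_method = c("otsu", "fixed"),
                             fixed_value = NULL, min_object_area = 2) {
  threshold_method <- match.arg(threshold_method)
  mask <- segment_neurites(factin_image, scale = scale,
                           threshold_method = threshold_method,
                           fixed_value = fixed_value,
                           min_object_area = min_object_area)
  if (!any(mask)) return(mask)
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  out <- EBImage::fillHull(lab == big) > 0
  attr(out, "scale") <- attr(mask, "scale")
  attr(out, "threshold") <- attr(mask, "threshold")
  out
}
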