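#' Rasterize polyline traces onto a pixel grid
#'
#' Marks every pixel visited by the traces at a fixed 1-pixel linewidth
#' (optionally dilated).  Segment interiors are sampled densely enough
#' that no pixel on the path is skipped.
#'
#' @param traces A `neurite_traces` data.frame (`trace_id`, `x_um`, `y_um`).
#' @param dim Canvas size in pixels, `c(nx, ny)`.
#' @param scale Micrometres per pixel.
#' @param linewidth_px Line width in pixels (odd; 1 = single pixel).
#' @return Logical matrix mask; attribute `n_clipped` counts sample points
#'   that fell outside the canvas.
#' @export
rasterize_traces <- function(traces, dim, scale, linewidth_px = 1L) {
  nx <- as.integer(dim[1]); ny <- as.integer(dim[2])
  mask <- matrix(FALSE, nx, ny)
  if (nrow(traces) == 0L) {
    attr(mask, "n_clipped") <- 0L
    return(mask)
  }
  same <- c(diff(traces$trace_id) == 0L)
  x1 <- traces$x_um[-nrow(traces)][same]; y1 <- traces$y_um[-nrow(traces)][same]
  x2 <- traces$x_um[-1L][same];           y2 <- traces$y_um[-1L][same]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  ns <- pmax(2L, ceiling(len / (0.4 * scale)) + 1L)
  seg <- rep.int(seq_along(ns), ns)
  tt <- (sequence(ns) - 1) / (rep.int(ns, ns) - 1)
  sx <- x1[seg] + tt * (x2 - x1)[seg]
  sy <- y1[seg] + tt * (y2 - y1)[seg]
  ix <- floor(sx / scale) + 1
  iy <- floor(sy / scale) + 1
  inb <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  mask[cbind(ix[inb], iy[inb])] <- TRUE
  if (linewidth_px > 1L) {
    mask <- EBImage::dilate(mask, EBImage::makeBrush(
      as.integer(linewidth_px) %/% 2L * 2L + 1L, "disc")) > 0
  }
  attr(mask, "n_clipped") <- sum(!inb)
  mask
}

#' Render a synthetic two-channel stripe-assay scene
#'
#' Rasterizes the traces at fixed linewidth into an F-actin channel,
#' applies a Gaussian blur of width `psf_sigma`, and adds a constant
#' background plus Gaussian noise.  The stripe channel encodes the cue
#' lanes as a clean 0/1 map.  Ground truth (traces, pattern, sphere) is
#' retained alongside the images.
#'
#' @param traces A `neurite_traces` data.frame.
#' @param stripes A [generate_stripe_pattern()] object (sets the canvas).
#' @param sphere A [sphere_geometry()]; defaults to the one attached to
#'   `traces`.
#' @param psf_sigma Gaussian blur sigma, micrometres (0 = no blur).
#' @param background Constant background intensity.
#' @param noise_sd Gaussian noise SD (intensity units).
#' @param seed RNG seed for the noise.
#' @return A `scene_render` list with `factin`, `stripe` (numeric
#'   matrices), `traces`, `stripes`, `sphere`, `scale`, `n_clipped`.
#'   A warning is raised when trace points fall outside the canvas.
#' @export
render_scene <- function(traces, stripes, sphere = NULL, psf_sigma = 1,
                         background = 0, noise_sd = 0, seed = 1) {
  stopifnot(inherits(stripes, "stripe_pattern"))
  sphere <- sphere %||% attr(traces, "sphere")
  dim <- c(nrow(stripes$label), ncol(stripes$label))
  raster <- rasterize_traces(traces, dim, stripes$scale)
  if (attr(raster, "n_clipped") > 0L) {
    warning(sprintf("%d trace sample points outside the canvas were clipped",
                    attr(raster, "n_clipped")))
  }
  img <- raster * 1.0
  if (psf_sigma > 0) {
    img <- as_num_matrix(EBImage::gblur(img, sigma = psf_sigma / stripes$scale))
  }
  img <- img + background
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(rnorm(length(img), 0, noise_sd),
                                        nrow(img), ncol(img)))
  }
  structure(
    list(factin = img, stripe = stripes$label * 1.0, traces = traces,
         stripes = stripes, sphere = sphere, scale = stripes$scale,
         raster = raster, n_clipped = attr(raster, "n_clipped")),
    class = "scene_render"
  )
}
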