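#' Parameters of a synthetic growth-cone image
#'
#' Generative model for the two morphologies a collapse assay
#' distinguishes.  A *spread* growth cone is a filled lamellipodial veil
#' (disc sector facing the growth direction) with filopodia radiating
#' from its rim (count Poisson, lengths Gamma); a *collapsed* growth cone
#' has no veil, only a short distal shaft tip bearing at most two short
#' filopodia.  In both states an axon shaft runs from the image border to
#' the growth cone, matching the convention that border-touching skeleton
#' branches are shaft, not filopodia.
#'
#' @param state `"spread"` or `"collapsed"` (the ground-truth label).
#' @param veil_radius Veil radius for the spread state, micrometres.
#' @param filopodia_count_mean Expected filopodium count (spread state).
#' @param filopodia_length_shape,filopodia_length_scale Gamma parameters
#'   of spread-state filopodium lengths, micrometres (defaults give a
#'   15 um mean).
#' @param noise_sd Gaussian image noise SD (intensity units; structures
#'   render at unit intensity).
#' @param scale Micrometres per pixel.
#' @param image_size Canvas size in pixels (square).
#' @param seed Integer RNG seed.
#' @return A `growth_cone_params` list.
#' @export
growth_cone_params <- function(state = c("spread", "collapsed"),
                               veil_radius = 6, filopodia_count_mean = 8,
                               filopodia_length_shape = 4,
                               filopodia_length_scale = 3.75,
                               noise_sd = 0.03, scale = 0.25,
                               image_size = 256, seed = 1) {
  state <- match.arg(state)
  stopifnot_scalar_pos(veil_radius, "veil_radius")
  stopifnot_scalar_pos(scale, "scale")
  stopifnot(noise_sd >= 0, filopodia_count_mean >= 0)
  structure(list(state = state, veil_radius = veil_radius,
                 filopodia_count_mean = filopodia_count_mean,
                 filopodia_length_shape = filopodia_length_shape,
                 filopodia_length_scale = filopodia_length_scale,
                 noise_sd = noise_sd, scale = scale,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "growth_cone_params")
}

#' Simulate a growth-cone image with ground-truth morphology
#'
#' @param params A [growth_cone_params()] object.
#' @param psf_sigma_px Gaussian blur applied after rasterization, pixels.
#' @return A `growth_cone_image`: list with `image` (numeric matrix),
#'   `scale`, `state` (ground-truth label), and `params`.  The image is a
#'   pure function of `params` including its seed.
#' @export
simulate_growth_cone <- function(params, psf_sigma_px = 0.8) {
  stopifnot(inherits(params, "growth_cone_params"))
  n <- params$image_size
  sc <- params$scale
  half <- n * sc / 2
  center <- c(half, half)

  with_seed(params$seed, {
    shaft_ang <- runif(1, 0, 2 * pi)
    u <- c(cos(shaft_ang), sin(shaft_ang))
    # shaft from the border to the growth cone, along -u from center
    t_exit <- border_exit_t(center, -u, n * sc)
    shaft_from <- center - u * t_exit

    shaft_df <- data.frame(trace_id = 1L, vertex_index = 1:2,
                           x_um = c(shaft_from[1], center[1]),
                           y_um = c(shaft_from[2], center[2]))
    # the axon shaft is a few pixels wide, unlike the 1-px filopodia
    shaft_raster <- rasterize_traces(shaft_df, c(n, n), sc,
                                     linewidth_px = 3L)
    segs <- list()
    veil <- matrix(FALSE, n, n)

    if (params$state == "spread") {
      half_ang <- 110 * pi / 180
      veil <- sector_mask(n, sc, center, params$veil_radius, shaft_ang,
                          half_ang)
      k <- rpois(1, params$filopodia_count_mean)
      if (k > 0) {
        angs <- shaft_ang + runif(k, -half_ang, half_ang)
        lens <- rgamma(k, shape = params$filopodia_length_shape,
                       scale = params$filopodia_length_scale)
        for (i in seq_len(k)) {
          d <- c(cos(angs[i]), sin(angs[i]))
          # root the filopodium slightly inside the veil so the raster
          # stays connected even without optical blur
          base <- center + (params$veil_radius - 0.5) * d
          segs <- c(segs, list(rbind(base, base + (lens[i] + 0.5) * d)))
        }
      }
    } else {
      k <- sample(0:2, 1)
      if (k > 0) {
        offs <- sample(c(-60, -25, 25, 60), k) * pi / 180
        lens <- pmin(rgamma(k, shape = 3, scale = 1.3), 8)
        for (i in seq_len(k)) {
          d <- c(cos(shaft_ang + offs[i]), sin(shaft_ang + offs[i]))
          segs <- c(segs, list(rbind(center, center + lens[i] * d)))
        }
      }
    }

    raster <- if (length(segs)) {
      tr <- do.call(rbind, lapply(seq_along(segs), function(i) {
        data.frame(trace_id = i, vertex_index = 1:2,
                   x_um = segs[[i]][, 1], y_um = segs[[i]][, 2])
      }))
      rasterize_traces(tr, c(n, n), sc)
    } else {
      matrix(FALSE, n, n)
    }
    img <- (raster | shaft_raster | veil) * 1.0
    if (psf_sigma_px > 0) {
      img <- as_num_matrix(EBImage::gblur(img, sigma = psf_sigma_px))
    }
    if (params$noise_sd > 0) {
      img <- img + matrix(rnorm(n * n, 0, params$noise_sd), n, n)
    }
    img <- pmin(pmax(img, 0), 1)
  })

  structure(list(image = img, scale = sc, state = params$state,
                 params = params),
            class = "growth_cone_image")
}

# Distance along direction `d` from `p` to the square canvas border.
border_exit_t <- function(p, d, size) {
  ts <- c(if (d[1] > 0) (size - p[1]) / d[1] else if (d[1] < 0) -p[1] / d[1],
          if (d[2] > 0) (size - p[2]) / d[2] else if (d[2] < 0) -p[2] / d[2])
  ts <- ts[is.finite(ts) & ts > 0]
  if (!length(ts)) return(0)
  min(ts)
}

# Filled disc sector of radius r centred at `center`, opening towards
# `ang` with the given half-angle.
sector_mask <- function(n, scale, center, r, ang, half_ang) {
  xs <- pixel_centers(n, scale)
  dx <- matrix(xs - center[1], n, n)
  dy <- matrix(xs - center[2], n, n, byrow = TRUE)
  within_r <- dx^2 + dy^2 <= r^2
  dang <- atan2(dy, dx) - ang
  dang <- atan2(sin(dang), cos(dang))  # wrap to (-pi, pi]
  within_r & abs(dang) <= half_ang
}

#' Run the full collapse pipeline on one growth-cone image
#'
#' Convenience wrapper: F-actin mask, veil/filopodium extraction, and the
#' rule-based collapse call.
#'
#' @param gc A [simulate_growth_cone()] result, or a list with `image`
#'   and `scale`.
#' @param ... Passed to [classify_collapse()].
#' @return A `collapse_call`.
#' @export
score_growth_cone <- function(gc, ...) {
  mask <- make_factin_mask(gc$image, scale = gc$scale)
  seg <- extract_filopodia(mask)
  classify_collapse(seg, ...)
}
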