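#' Parameters of a synthetic acceptor-photobleaching FRET pair
#'
#' Donor-dequenching model: a biosensor-expressing growth cone (the
#' bleach ROI) emits donor counts `donor_base * (1 - E)` before bleaching
#' and `donor_base * (1 - E * (1 - bleach_fraction))` after, so with a
#' complete bleach the ideal donor-dequenching estimator
#' `E = 1 - pre / post` recovers the true efficiency exactly.  The
#' acceptor channel is reduced by `bleach_fraction` inside the ROI.
#' Photon (Poisson) noise is applied per pixel on top of a uniform
#' background.
#'
#' @param true_efficiency Ground-truth FRET efficiency in `[0, 1)`.
#' @param donor_base Unquenched donor photon counts per pixel.
#' @param acceptor_base Acceptor photon counts per pixel.
#' @param bleach_fraction Fraction of acceptor destroyed in the ROI
#'   (`(0, 1]`).
#' @param background Background counts per pixel outside (and under) the
#'   cell.
#' @param noise `"poisson"` or `"none"`.
#' @param image_size Canvas size in pixels (square).
#' @param scale Micrometres per pixel.
#' @param roi_radius_um Radius of the disc-shaped bleach ROI,
#'   micrometres.
#' @param seed Integer RNG seed.
#' @return A `fret_params` list.
#' @export
fret_params <- function(true_efficiency = 0.2, donor_base = 1e4,
                        acceptor_base = donor_base, bleach_fraction = 1,
                        background = 50, noise = c("poisson", "none"),
                        image_size = 64, scale = 0.25, roi_radius_um = 5,
                        seed = 1) {
  noise <- match.arg(noise)
  stopifnot(true_efficiency >= 0, true_efficiency < 1,
            bleach_fraction > 0, bleach_fraction <= 1,
            donor_base > 0, background >= 0)
  structure(list(true_efficiency = true_efficiency, donor_base = donor_base,
                 acceptor_base = acceptor_base,
                 bleach_fraction = bleach_fraction, background = background,
                 noise = noise, image_size = as.integer(image_size),
                 scale = scale, roi_radius_um = roi_radius_um,
                 seed = as.integer(seed)),
            class = "fret_params")
}

#' Simulate a CFP/YFP pre/post-bleach image set
#'
#' @param params A [fret_params()] object.
#' @return A `fret_pair`: list with `donor_pre`, `donor_post`,
#'   `acceptor_pre`, `acceptor_post` (numeric count matrices),
#'   `bleach_roi` (logical mask), `scale`, and `truth` (the parameters).
#' @export
simulate_fret_pair <- function(params) {
  stopifnot(inherits(params, "fret_params"))
  n <- params$image_size; sc <- params$scale
  c0 <- n * sc / 2
  xs <- pixel_centers(n, sc)
  d2 <- outer((xs - c0)^2, (xs - c0)^2, `+`)
  roi <- d2 <= params$roi_radius_um^2
  E <- params$true_efficiency; b <- params$bleach_fraction
  bg <- params$background

  mk <- function(inside_mean) {
    m <- matrix(bg, n, n)
    m[roi] <- bg + inside_mean
    m
  }
  dpre <- mk(params$donor_base * (1 - E))
  dpost <- mk(params$donor_base * (1 - E * (1 - b)))
  apre <- mk(params$acceptor_base)
  apost <- mk(params$acceptor_base * (1 - b))

  if (params$noise == "poisson") {
    with_seed(params$seed, {
      dpre <- matrix(rpois(n * n, dpre), n, n)
      dpost <- matrix(rpois(n * n, dpost), n, n)
      apre <- matrix(rpois(n * n, apre), n, n)
      apost <- matrix(rpois(n * n, apost), n, n)
    })
  }
  structure(list(donor_pre = dpre, donor_post = dpost,
                 acceptor_pre = apre, acceptor_post = apost,
                 bleach_roi = roi, scale = sc, truth = params),
            class = "fret_pair")
}
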