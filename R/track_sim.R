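#' Parameters of a synthetic time-lapse leading-edge track
#'
#' Models live outgrowth imaging: the leading edge advances at
#' `true_rate` with occasional discrete retraction events, and each
#' frame's position is read with Gaussian measurement noise.
#'
#' @param true_rate Ground-truth extension rate, micrometres per hour.
#' @param frame_interval Frame interval, minutes.
#' @param n_frames Number of frames (>= 2).
#' @param position_noise_sd Per-frame position measurement noise SD,
#'   micrometres.
#' @param retraction_prob Per-frame retraction probability in `[0, 1]`.
#' @param retraction_magnitude Retraction size, micrometres.
#' @param seed Integer RNG seed.
#' @return A `track_params` list.
#' @export
track_params <- function(true_rate = 12, frame_interval = 5, n_frames = 60,
                         position_noise_sd = 0.5, retraction_prob = 0,
                         retraction_magnitude = 8, seed = 1) {
  stopifnot_scalar_pos(frame_interval, "frame_interval")
  stopifnot(n_frames >= 2, retraction_prob >= 0, retraction_prob <= 1,
            position_noise_sd >= 0, retraction_magnitude >= 0)
  structure(list(true_rate = true_rate, frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 position_noise_sd = position_noise_sd,
                 retraction_prob = retraction_prob,
                 retraction_magnitude = retraction_magnitude,
                 seed = as.integer(seed)),
            class = "track_params")
}

#' Simulate a leading-edge position track
#'
#' The true position advances `true_rate * frame_interval / 60` per frame
#' minus `retraction_magnitude` on retraction frames; the observed
#' position adds independent Gaussian noise per frame.
#'
#' @param params A [track_params()] object.
#' @return A `timelapse_track` data.frame with columns `track_id`,
#'   `frame`, `t_min`, `x_um` (observed leading-edge position) and
#'   `y_um` (zero for this 1-D generator); attribute `truth` holds the
#'   noise-free positions and retraction flags.
#' @export
simulate_timelapse_track <- function(params) {
  stopifnot(inherits(params, "track_params"))
  n <- params$n_frames
  step <- params$true_rate * params$frame_interval / 60
  with_seed(params$seed, {
    retract <- c(FALSE, rbinom(n - 1L, 1L, params$retraction_prob) == 1L)
    incr <- c(0, rep(step, n - 1L)) -
      retract * params$retraction_magnitude
    true_pos <- cumsum(incr)
    obs <- true_pos + rnorm(n, 0, params$position_noise_sd)
  })
  out <- data.frame(track_id = 1L, frame = seq_len(n) - 1L,
                    t_min = (seq_len(n) - 1L) * params$frame_interval,
                    x_um = obs, y_um = 0)
  class(out) <- c("timelapse_track", "data.frame")
  attr(out, "truth") <- data.frame(true_x_um = true_pos, retracted = retract)
  out
}
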