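#' Path length of a neurite trace
#'
#' Sum of consecutive vertex distances (path length, not rim-to-tip
#' chord).
#'
#' @param trace Two-column matrix of `(x, y)` micrometre coordinates, or a
#'   data frame with `x_um`, `y_um` columns, for a single neurite.
#' @return Length in micrometres.
#' @export
measure_neurite_length <- function(trace) {
  m <- if (is.data.frame(trace)) {
    as.matrix(trace[, c("x_um", "y_um")])
  } else {
    as.matrix(trace)
  }
  if (nrow(m) < 2L) stop("a trace needs at least 2 vertices", call. = FALSE)
  d <- sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  if (any(d == 0)) stop("consecutive trace vertices must be distinct",
                        call. = FALSE)
  sum(d)
}

#' Lengths of every trace in a traces table
#' @param traces A `neurite_traces` data.frame.
#' @return Data frame with `trace_id` and `length_um`.
#' @export
measure_neurite_lengths <- function(traces) {
  tr <- split_traces(traces)
  data.frame(trace_id = names(tr),
             length_um = vapply(tr, measure_neurite_length, numeric(1)),
             row.names = NULL)
}

#' Per-sphere mean of the k longest neurites
#'
#' The standard fixed-culture outgrowth summary: for each neurosphere the
#' `k` longest neurite lengths are averaged.  Spheres with fewer than `k`
#' neurites contribute the mean of all their lengths and are flagged;
#' empty spheres are excluded with a warning.
#'
#' @param lengths Data frame with columns `sphere_id` and `length_um`, or
#'   a named list of numeric length vectors.
#' @param k Number of longest neurites to average.
#' @return Data frame with `sphere_id`, `n_neurites`, `mean_longest_k`,
#'   `truncated` (TRUE when fewer than `k` neurites were available).
#' @export
longest_k_summary <- function(lengths, k = 20) {
  if (is.data.frame(lengths)) {
    lst <- split(lengths$length_um, lengths$sphere_id)
  } else {
    lst <- lengths
  }
  n0 <- vapply(lst, length, integer(1))
  if (any(n0 == 0L)) {
    warning(sprintf("spheres with no neurites excluded: %s",
                    paste(names(lst)[n0 == 0L], collapse = ", ")))
    lst <- lst[n0 > 0L]
  }
  data.frame(
    sphere_id = names(lst),
    n_neurites = vapply(lst, length, integer(1)),
    mean_longest_k = vapply(lst, function(v) {
      mean(sort(v, decreasing = TRUE)[seq_len(min(k, length(v)))])
    }, numeric(1)),
    truncated = vapply(lst, function(v) length(v) < k, logical(1)),
    row.names = NULL
  )
}

#' Extension rate from a leading-edge track, with retraction capping
#'
#' Per-interval signed displacements are summed and converted to
#' micrometres per hour.  Retraction intervals larger than
#' `retraction_cap` are truncated at `-retraction_cap` (and counted), so
#' single very large retractions do not dominate the average.  For 2-D
#' tracks the displacement is the projection onto a local growth axis
#' estimated by principal components over a rolling 5-frame window; 1-D
#' tracks (constant `y_um`, or a `pos_um` column) bypass projection.
#' When `treatment_time` is given, separate pre- and post-treatment rates
#' and their ratio (`normalized_rate = post / pre`) are reported.
#'
#' @param track Data frame with `t_min` and either `pos_um`, or `x_um`
#'   (+ optional `y_um`).
#' @param retraction_cap Per-interval retraction cap, micrometres
#'   (`Inf` disables capping, making the rate exactly net displacement
#'   over elapsed time).
#' @param treatment_time Treatment time in minutes, or `NULL`.
#' @return A `rate_estimate`: list with `rate` (um/hr), `n_intervals`,
#'   `capped_intervals`, and (when `treatment_time` is set) `rate_pre`,
#'   `rate_post`, `normalized_rate`, plus `normalization_flag` when the
#'   pre-treatment window is too short.
#' @export
extension_rate <- function(track, retraction_cap = 30,
                           treatment_time = NULL) {
  stopifnot("t_min" %in% names(track))
  t <- track$t_min
  if (length(t) < 2L || any(diff(t) <= 0)) {
    stop("track needs >= 2 frames with strictly increasing time",
         call. = FALSE)
  }
  delta <- track_displacements(track)

  cap_sum <- function(d, tt) {
    capped <- d < -retraction_cap
    d[capped] <- -retraction_cap
    list(rate = 60 * sum(d) / (tt[length(tt)] - tt[1L]),
         capped = sum(capped))
  }
  all_r <- cap_sum(delta, t)
  out <- list(rate = all_r$rate, n_intervals = length(delta),
              capped_intervals = all_r$capped)

  if (!is.null(treatment_time)) {
    pre_i <- which(t[-1L] <= treatment_time)        # intervals ending <= t0
    post_i <- which(t[-length(t)] >= treatment_time) # intervals starting >= t0
    if (length(pre_i) < 1L || sum(t <= treatment_time) < 2L) {
      out$normalized_rate <- NA_real_
      out$normalization_flag <- "pre-treatment window shorter than 2 frames"
    } else {
      out$rate_pre <- 60 * sum(pmax(delta[pre_i], -retraction_cap)) /
        (t[max(pre_i) + 1L] - t[min(pre_i)])
      if (length(post_i) >= 1L) {
        out$rate_post <- 60 * sum(pmax(delta[post_i], -retraction_cap)) /
          (t[max(post_i) + 1L] - t[min(post_i)])
        out$normalized_rate <- out$rate_post / out$rate_pre
      } else {
        out$normalized_rate <- NA_real_
        out$normalization_flag <- "no post-treatment intervals"
      }
    }
  }
  structure(out, class = "rate_estimate")
}

# Signed per-interval displacement along the growth axis.
track_displacements <- function(track) {
  if ("pos_um" %in% names(track)) return(diff(track$pos_um))
  x <- track$x_um
  y <- if ("y_um" %in% names(track)) track$y_um else rep(0, length(x))
  if (all(y == y[1L])) return(diff(x))
  n <- length(x)
  delta <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    w <- max(1L, i - 2L):min(n, i + 2L)
    pts <- cbind(x[w], y[w])
    v <- prcomp(pts, center = TRUE)$rotation[, 1L]
    span <- pts[nrow(pts), ] - pts[1L, ]
    if (sum(span * v) < 0) v <- -v
    delta[i] <- sum((c(x[i + 1L], y[i + 1L]) - c(x[i], y[i])) * v)
  }
  delta
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %.2f um/hr over %d intervals (%d capped)\n",
              x$rate, x$n_intervals, x$capped_intervals))
  if (!is.null(x$normalized_rate) && is.finite(x$normalized_rate)) {
    cat(sprintf("  pre %.2f / post %.2f um/hr, normalized %.3f\n",
                x$rate_pre, x$rate_post, x$normalized_rate))
  }
  invisible(x)
}

#' Two-sided F test comparing group variances
#'
#' Ratio of sample variances (group A over group B) with
#' `(n_a - 1, n_b - 1)` degrees of freedom and a two-sided p-value from
#' the F distribution.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @return List with `F`, `df`, `p_value`, and the group variances.
#' @export
variance_comparison <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  va <- var(group_a); vb <- var(group_b)
  if (vb == 0) stop("zero variance in the denominator group", call. = FALSE)
  F <- va / vb
  df <- c(length(group_a) - 1L, length(group_b) - 1L)
  p <- 2 * min(pf(F, df[1], df[2]), pf(F, df[1], df[2], lower.tail = FALSE))
  list(F = F, df = df, p_value = min(p, 1),
       var_a = va, var_b = vb)
}
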