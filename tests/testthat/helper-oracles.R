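# Shared fixtures and independent oracles, built in code at test time.

# Brute-force Sholl oracle: for every segment and ring, enumerate the
# roots of |P1 + t*D - C|^2 = r^2 by the quadratic formula; a segment
# crosses the ring when an odd number of roots lies in (0, 1) (an even
# count is a tangency or a dip that returns, which sign-change counting
# also scores as zero).  The quadrant is read at the in-range root.
oracle_sholl <- function(traces, sphere, ring_spacing, orientation, K) {
  cx <- sphere$center[1]; cy <- sphere$center[2]
  vang <- atan2(orientation[2], orientation[1])
  radii <- sphere$radius + seq_len(K) * ring_spacing
  cpar <- cper <- integer(K)
  for (m in split(traces[, c("x_um", "y_um")], traces$trace_id)) {
    m <- as.matrix(m)
    for (i in seq_len(nrow(m) - 1L)) {
      p1 <- m[i, ]; p2 <- m[i + 1L, ]
      D <- p2 - p1; f <- p1 - c(cx, cy)
      a <- sum(D^2); b <- 2 * sum(f * D)
      for (k in seq_len(K)) {
        c0 <- sum(f^2) - radii[k]^2
        disc <- b^2 - 4 * a * c0
        if (disc <= 0) next
        rts <- c((-b - sqrt(disc)) / (2 * a), (-b + sqrt(disc)) / (2 * a))
        inr <- rts[rts > 0 & rts < 1]
        if (length(inr) %% 2 == 1L) {
          pt <- p1 + inr[1] * D
          deg <- ((atan2(pt[2] - cy, pt[1] - cx) - vang) * 180 / pi) %% 360
          par <- (deg < 45) | (deg >= 315) | (deg >= 135 & deg < 225)
          if (par) cpar[k] <- cpar[k] + 1L else cper[k] <- cper[k] + 1L
        }
      }
    }
  }
  list(par = cpar, per = cper)
}

# Random polyline set leaving a sphere rim, for oracle-equivalence checks.
random_trace_set <- function(seed, n_traces = 10, n_segments = 50,
                             step = 3, turn_sd = 0.4,
                             radius = NULL, center = c(0, 0)) {
  set.seed(seed)
  radius <- radius %||% runif(1, 80, 150)
  sp <- sphere_geometry(center, radius)
  dfs <- lapply(seq_len(n_traces), function(id) {
    ang <- runif(1, 0, 2 * pi); h <- ang
    pos <- matrix(NA_real_, n_segments + 1L, 2L)
    pos[1L, ] <- center + radius * c(cos(ang), sin(ang))
    for (s in seq_len(n_segments)) {
      h <- h + rnorm(1, 0, turn_sd)
      pos[s + 1L, ] <- pos[s, ] + step * c(cos(h), sin(h))
    }
    data.frame(trace_id = id, vertex_index = seq_len(n_segments + 1L),
               x_um = pos[, 1], y_um = pos[, 2])
  })
  traces <- do.call(rbind, dfs)
  class(traces) <- c("neurite_traces", "data.frame")
  attr(traces, "sphere") <- sp
  traces
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Disc mask on the package pixel grid.
disc_mask <- function(n, scale, center, radius) {
  xs <- (seq_len(n) - 0.5) * scale
  outer((xs - center[1])^2, (xs - center[2])^2, `+`) <= radius^2
}

# Hand-made segmentation object for rule-level collapse tests.
fake_seg <- function(veil_area, lengths) {
  structure(
    list(veil_mask = NULL, veil_area = veil_area,
         filopodia = data.frame(length_um = lengths,
                                base_x = rep(0, length(lengths)),
                                base_y = rep(0, length(lengths))),
         shaft_axis = c(1, 0), scale = 1),
    class = "growth_cone_segmentation"
  )
}
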