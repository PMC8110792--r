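# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  All generators route their randomness through this so
# that no call mutates global RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

# Image convention: numeric matrix `img[ix, iy]` where the pixel (ix, iy)
# covers [ (ix-1)*scale, ix*scale ) x [ (iy-1)*scale, iy*scale ) in
# micrometres; origin top-left, x rightward, y downward.
pixel_index <- function(u, scale, n) {
  i <- floor(u / scale) + 1L
  pmin(pmax(i, 1L), n)
}

pixel_centers <- function(n, scale) (seq_len(n) - 0.5) * scale

mask_area_um2 <- function(mask, scale) sum(mask) * scale^2

# Odd-sized disc brush with radius approximately `r_um`.
disc_brush <- function(r_um, scale) {
  r_px <- max(1L, round(r_um / scale))
  EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
}

as_num_matrix <- function(x) {
  x <- EBImage::imageData(x)
  storage.mode(x) <- "double"
  x
}
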