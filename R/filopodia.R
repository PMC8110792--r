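# 8-connected component labelling (EBImage::bwlabel is 4-connected, which
# fragments diagonal skeleton runs).  Intended for sparse skeleton masks.
label8 <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  todo <- which(mask)
  cur <- 0L
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  for (seed in todo) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    frontier <- seed
    lab[seed] <- cur
    while (length(frontier)) {
      ix <- (frontier - 1L) %% nx + 1L
      iy <- (frontier - 1L) %/% nx + 1L
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        jx <- ix + offs$dx[o]; jy <- iy + offs$dy[o]
        ok <- jx >= 1L & jx <= nx & jy >= 1L & jy <= ny
        if (!any(ok)) next
        cand <- (jy[ok] - 1L) * nx + jx[ok]
        cand <- cand[mask[cand] & lab[cand] == 0L]
        if (length(cand)) {
          lab[cand] <- cur
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Decompose a growth-cone mask into veil and filopodia
#'
#' The lamellipodial veil is the morphological opening of the mask by a
#' disc of radius `r_open` (removing thin protrusions); filopodia are the
#' skeleton branches of the residual (mask minus veil).  The residual is
#' skeletonized (Zhang-Suen thinning), split into branches at junction
#' pixels, and each qualifying branch is reported with its geodesic
#' skeleton length in micrometres.  Branches touching the image border are
#' treated as the axon shaft and never counted as filopodia; when the veil
#' is nonempty, a filopodium must additionally be rooted at the veil
#' boundary.
#'
#' @param mask Logical growth-cone mask (from [make_factin_mask()]).
#' @param scale Micrometres per pixel; defaults to the mask's `scale`
#'   attribute.
#' @param r_open Opening radius defining the veil, micrometres.
#' @param min_filopodium_um Branches shorter than this are ignored.
#' @return A `growth_cone_segmentation`: list with `veil_mask`,
#'   `veil_area` (square micrometres), `filopodia` (data.frame
#'   `length_um`, `base_x`, `base_y`), `shaft_axis` (unit vector), and
#'   `scale`.
#' @export
extract_filopodia <- function(mask, scale = NULL, r_open = 1.5,
                              min_filopodium_um = 1) {
  scale <- scale %||% attr(mask, "scale") %||% 1
  nx <- nrow(mask); ny <- ncol(mask)
  empty_seg <- function(veil, area) {
    structure(list(veil_mask = veil, veil_area = area,
                   filopodia = data.frame(length_um = numeric(),
                                          base_x = numeric(),
                                          base_y = numeric()),
                   shaft_axis = c(NA_real_, NA_real_), scale = scale),
              class = "growth_cone_segmentation")
  }
  if (!any(mask)) return(empty_seg(mask, 0))

  veil <- EBImage::opening(mask, disc_brush(r_open, scale)) > 0
  veil_area <- mask_area_um2(veil, scale)
  resid <- mask & !veil
  shaft_axis <- mask_principal_axis(mask)

  if (!any(resid)) {
    seg <- empty_seg(veil, veil_area)
    seg$shaft_axis <- shaft_axis
    return(seg)
  }

  sk <- skeleton_branches(resid, scale)
  lab <- sk$branches
  junctions <- sk$junctions
  nlab <- max(lab)
  veil_zone <- if (any(veil)) {
    EBImage::dilate(veil, disc_brush(3 * scale, scale)) > 0
  } else {
    NULL
  }
  margin <- 3L  # thinning can retract a blunt border end by a few px

  # The axon shaft enters the field through the image border: the branch
  # nearest the mask's border-contact pixels is shaft, not filopodium.
  shaft_label <- 0L
  bidx <- which(mask)
  bix <- (bidx - 1L) %% nx + 1L
  biy <- (bidx - 1L) %/% nx + 1L
  on_border <- bix == 1L | bix == nx | biy == 1L | biy == ny
  if (any(on_border) && nlab > 0L) {
    bx <- bix[on_border]; by <- biy[on_border]
    lidx <- which(lab > 0L)
    lx <- (lidx - 1L) %% nx + 1L
    ly <- (lidx - 1L) %/% nx + 1L
    d2 <- outer(lx, bx, `-`)^2 + outer(ly, by, `-`)^2
    shaft_label <- lab[lidx[which(d2 == min(d2), arr.ind = TRUE)[1L, 1L]]]
  }

  lens <- basex <- basey <- numeric(0)
  for (b in seq_len(nlab)) {
    if (b == shaft_label) next
    bm <- lab == b
    idx <- which(bm)
    ix <- (idx - 1L) %% nx + 1L
    iy <- (idx - 1L) %/% nx + 1L
    if (any(ix <= margin | ix > nx - margin |
              iy <= margin | iy > ny - margin)) next  # axon shaft
    if (!is.null(veil_zone) && !any(veil_zone[idx])) next  # not rooted
    len <- skeleton_length_um(bm, scale)
    if (len < min_filopodium_um) next
    # base: branch pixel nearest the veil (or nearest a junction)
    anchor <- if (!is.null(veil_zone)) veil else junctions
    if (any(anchor)) {
      aidx <- which(anchor)
      ax <- (aidx - 1L) %% nx + 1L
      ay <- (aidx - 1L) %/% nx + 1L
      d2 <- outer(ix, ax, function(a, b) (a - b)^2) +
        outer(iy, ay, function(a, b) (a - b)^2)
      w <- which(d2 == min(d2), arr.ind = TRUE)[1L, 1L]
    } else {
      w <- 1L
    }
    lens <- c(lens, len)
    basex <- c(basex, (ix[w] - 0.5) * scale)
    basey <- c(basey, (iy[w] - 0.5) * scale)
  }

  structure(
    list(veil_mask = veil, veil_area = veil_area,
         filopodia = data.frame(length_um = lens, base_x = basex,
                                base_y = basey),
         shaft_axis = shaft_axis, scale = scale),
    class = "growth_cone_segmentation"
  )
}

mask_principal_axis <- function(mask) {
  idx <- which(mask)
  if (length(idx) < 2L) return(c(NA_real_, NA_real_))
  nx <- nrow(mask)
  pts <- cbind((idx - 1L) %% nx + 1L, (idx - 1L) %/% nx + 1L)
  v <- prcomp(pts, center = TRUE)$rotation[, 1L]
  as.numeric(v / sqrt(sum(v^2)))
}

#' Rule-based growth cone collapse call
#'
#' A growth cone is scored collapsed when the lamellipodial veil is
#' disassembled (veil area at most `veil_min_area`) AND it carries at most
#' `filopodia_max_count` filopodia AND every filopodium is shorter than
#' `filopodia_max_length` micrometres.  All three sub-criteria are
#' reported so alternate rules can be recomputed without re-segmentation.
#'
#' @param seg A [extract_filopodia()] segmentation.
#' @param veil_min_area Veil area threshold, square micrometres.
#' @param filopodia_max_count Maximum filopodium count compatible with
#'   collapse.
#' @param filopodia_max_length Filopodia must be strictly shorter than
#'   this (micrometres) for a collapse call.
#' @return A `collapse_call`: list with `collapsed`, `veil_area`,
#'   `n_filopodia`, `max_filopodium_length`.
#' @export
classify_collapse <- function(seg, veil_min_area = 5,
                              filopodia_max_count = 2,
                              filopodia_max_length = 10) {
  stopifnot(inherits(seg, "growth_cone_segmentation"))
  n_filo <- nrow(seg$filopodia)
  max_len <- if (n_filo > 0) max(seg$filopodia$length_um) else 0
  collapsed <- (seg$veil_area <= veil_min_area) &&
    (n_filo <= filopodia_max_count) &&
    (max_len < filopodia_max_length)
  structure(
    list(collapsed = collapsed, veil_area = seg$veil_area,
         n_filopodia = n_filo, max_filopodium_length = max_len),
    class = "collapse_call"
  )
}

#' @export
print.collapse_call <- function(x, ...) {
  cat(sprintf(
    "<collapse_call> %s (veil %.1f um2, %d filopodia, max %.1f um)\n",
    if (x$collapsed) "collapsed" else "not collapsed",
    x$veil_area, x$n_filopodia, x$max_filopodium_length))
  invisible(x)
}

#' Per-condition collapse contingency table
#'
#' @param calls Data frame with columns `condition` and `collapsed`
#'   (logical).
#' @return A `collapse_table`: data.frame with per-condition counts
#'   (`n_collapsed`, `n_not_collapsed`, `n`, `percent_collapsed`) plus a
#'   `counts` attribute holding the 2 x K matrix (rows collapsed / not)
#'   ready for [fisher_exact_2x2()] or [chi_squared()].  Conditions with
#'   no calls are excluded with a warning.
#' @export
collapse_table <- function(calls) {
  stopifnot(all(c("condition", "collapsed") %in% names(calls)))
  if (nrow(calls) == 0L) stop("no collapse calls supplied", call. = FALSE)
  cond <- as.factor(calls$condition)
  empty <- levels(cond)[tabulate(cond, nbins = nlevels(cond)) == 0L]
  if (length(empty)) {
    warning(sprintf("conditions with no calls excluded: %s",
                    paste(empty, collapse = ", ")))
    cond <- droplevels(cond)
  }
  tab <- table(factor(calls$collapsed, levels = c(TRUE, FALSE)), cond)
  out <- data.frame(
    condition = colnames(tab),
    n_collapsed = as.integer(tab[1L, ]),
    n_not_collapsed = as.integer(tab[2L, ]),
    stringsAsFactors = FALSE
  )
  out$n <- out$n_collapsed + out$n_not_collapsed
  out$percent_collapsed <- 100 * out$n_collapsed / out$n
  class(out) <- c("collapse_table", "data.frame")
  counts <- unclass(tab)
  rownames(counts) <- c("collapsed", "not_collapsed")
  attr(out, "counts") <- counts
  out
}
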