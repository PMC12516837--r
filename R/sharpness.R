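#' Convert a tile to a luminance grid
#'
#' Grayscale tiles pass through unchanged; 3-channel tiles are combined with
#' the ITU-R BT.601 weights `0.299 R + 0.587 G + 0.114 B`, staying on the
#' 0--255 scale.
#'
#' @param tile numeric matrix or 3-channel array.
#' @return numeric matrix.
#' @export
to_luminance <- function(tile) {
  if (is.matrix(tile)) return(tile)
  if (is.array(tile) && length(dim(tile)) == 3L) {
    nch <- dim(tile)[3L]
    if (nch != 3L) stop("tile must have 1 or 3 channels, got ", nch)
    return(0.299 * tile[, , 1L] + 0.587 * tile[, , 2L] + 0.114 * tile[, , 3L])
  }
  stop("tile must be a numeric matrix (grayscale) or a 3-channel array")
}

#' Variance-of-Laplacian sharpness score
#'
#' The focus measure used for tile quality control and gating: the population
#' variance of the response of the 3x3 four-neighbour Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` applied to the tile's luminance with
#' reflect-101 borders.  Sharp, high-frequency texture gives large values;
#' blur collapses the score towards 0.
#'
#' @param tile numeric matrix or 3-channel array, at least 3x3.
#' @return non-negative scalar, in squared intensity units.
#' @examples
#' laplacian_variance(matrix(100, 16, 16))  # constant tile -> 0
#' @export
laplacian_variance <- function(tile) {
  lum <- to_luminance(tile)
  if (nrow(lum) < 3L || ncol(lum) < 3L)
    stop("tile must be at least 3x3, got ", nrow(lum), "x", ncol(lum))
  resp <- laplacian4_cpp(lum)
  mean(resp^2) - mean(resp)^2
}

#' Compute per-tile sharpness for a slide bag
#'
#' @param bag a `slide_bag`.
#' @return the bag with `$theta` set to the vector of per-tile LV values.
#' @export
bag_sharpness <- function(bag) {
  stopifnot(inherits(bag, "slide_bag"))
  bag$theta <- vapply(bag$tiles, laplacian_variance, numeric(1))
  bag
}

#' Quality-control filter on tile sharpness
#'
#' Discards tiles whose LV is strictly less than the threshold (the
#' conventional out-of-focus cut-off is 500 on 0--255-scale tiles at
#' diagnostic tile sizes; synthetic datasets recalibrate it).  A tile with LV
#' exactly equal to the threshold is retained.
#'
#' @param bag a `slide_bag`; per-tile `theta` is computed if absent.
#' @param lv_threshold LV cut-off (default 500).
#' @return list with `bag` (filtered, tile order preserved), `report` (a
#'   data.frame of `tile_id`, `theta`, `kept`) and `empty` (flag set when no
#'   tile survives; this is reported, not raised).
#' @export
qc_filter <- function(bag, lv_threshold = 500) {
  stopifnot(inherits(bag, "slide_bag"))
  if (is.null(bag$theta)) bag <- bag_sharpness(bag)
  keep <- bag$theta >= lv_threshold
  report <- data.frame(tile_id = bag$tile_ids, theta = bag$theta, kept = keep,
                       stringsAsFactors = FALSE)
  out <- bag
  out$tiles <- bag$tiles[keep]
  out$tile_ids <- bag$tile_ids[keep]
  out$base_sigma <- bag$base_sigma[keep]
  out$theta <- bag$theta[keep]
  list(bag = out, report = report, empty = !any(keep))
}

#' Slide-level blur summary: lower quartile of tile LV
#'
#' The 25th percentile (linear interpolation between order statistics) of a
#' slide's per-tile LV values; used to rank slides by overall blurriness in
#' real-world subset analyses.
#'
#' @param bag a `slide_bag` with `theta` computed, or a numeric vector of LV
#'   values.
#' @return scalar Q1 of LV.
#' @export
slide_blur_q1 <- function(bag) {
  theta <- if (inherits(bag, "slide_bag")) {
    if (is.null(bag$theta)) bag_sharpness(bag)$theta else bag$theta
  } else bag
  if (length(theta) == 0L) stop("no tiles: cannot summarise blur for an empty bag")
  unname(quantile(theta, 0.25, type = 7))
}
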