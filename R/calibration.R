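#' Calibrate the sigma-to-LV mapping
#'
#' For every sigma on the grid, every sampled tile is blurred at that sigma,
#' its LV is computed, and the per-sigma median is stored.  The resulting
#' table bridges simulated blur levels to the sharpness scores observed on
#' real tiles, and is the basis for deriving LV gating thresholds.
#'
#' @param tiles list of tile matrices (a representative sample; at least
#'   `min_tiles`).
#' @param sigma_grid ascending sigma grid (default `{0, 0.5, ..., 10}`).
#' @param n_sample number of tiles to sample from `tiles` (default: all).
#' @param seed seed for the tile subsample.
#' @param min_tiles minimum sample size guard (default 100).
#' @return object of class `lv_calibration`: data.frame `entries` with
#'   columns `sigma`, `median_lv`, plus `n_tiles_sampled` and `seed`.
#' @export
calibrate_sigma_to_lv <- function(tiles, sigma_grid = seq(0, 10, by = 0.5),
                                  n_sample = NULL, seed = 1L,
                                  min_tiles = 100L) {
  stopifnot(is.list(tiles), !is.unsorted(sigma_grid, strictly = TRUE))
  if (!is.null(n_sample) && n_sample < length(tiles))
    tiles <- with_seed(seed, sample(tiles, n_sample))
  if (length(tiles) < min_tiles)
    stop("need at least ", min_tiles, " tiles for calibration, got ",
         length(tiles))
  med <- vapply(sigma_grid, function(sg) {
    median(vapply(tiles, function(tl) laplacian_variance(apply_blur(tl, sg)),
                  numeric(1)))
  }, numeric(1))
  if (max(med) <= 0)
    stop("degenerate tile sample: all LV medians are 0 (constant tiles?)")
  structure(list(entries = data.frame(sigma = sigma_grid, median_lv = med),
                 n_tiles_sampled = length(tiles), seed = seed),
            class = "lv_calibration")
}

#' @export
print.lv_calibration <- function(x, ...) {
  cat(sprintf("sigma-to-LV calibration over %d tiles, %d sigma levels:\n",
              x$n_tiles_sampled, nrow(x$entries)))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Select best-expert sigma ranges from a cross-blur AUC matrix
#'
#' Given a sensitivity matrix (experts x validation sigma levels of AUCs),
#' picks per validation sigma the argmax-AUC expert, breaking ties towards
#' the expert trained at the lower sigma (the sharper specialist).
#' Non-contiguous winners are first smoothed by a majority vote over a
#' 3-cell window (the original winner is kept on a tie), then adjacent
#' sigmas with the same winner are merged into contiguous intervals covering
#' the calibrated sigma domain.
#'
#' @param auc_matrix numeric matrix, rows = experts (rownames = expert ids),
#'   columns = validation sigma grid (numeric colnames); no missing cells.
#' @param train_sigmas per-row training sigmas (default: the
#'   `train_sigmas` attribute of the matrix).
#' @param tol AUC slack within which experts count as tied to the column
#'   maximum (default 0.01, conservative against the sampling error of an
#'   AUC estimated on ~100 slides).
#' @param smooth logical; apply the 3-cell majority smoothing (default TRUE).
#' @return object of class `expert_range_map`: data.frame with columns
#'   `expert_id`, `sigma_lo`, `sigma_hi`, `lo_idx`, `hi_idx` (grid indices),
#'   with the sigma grid attached as attribute `sigma_grid`.
#' @export
select_expert_ranges <- function(auc_matrix,
                                 train_sigmas = attr(auc_matrix, "train_sigmas"),
                                 tol = 0.01, smooth = TRUE) {
  if (any(is.na(auc_matrix))) {
    bad <- which(is.na(auc_matrix), arr.ind = TRUE)[1L, ]
    stop("missing AUC cell for expert '", rownames(auc_matrix)[bad[1L]],
         "' at sigma ", colnames(auc_matrix)[bad[2L]])
  }
  stopifnot(!is.null(rownames(auc_matrix)), !is.null(colnames(auc_matrix)),
            length(train_sigmas) == nrow(auc_matrix))
  grid <- as.numeric(colnames(auc_matrix))
  ord <- order(train_sigmas)   # remaining ties: lower training sigma wins
  A <- auc_matrix[ord, , drop = FALSE]
  ts <- train_sigmas[ord]
  win <- vapply(seq_along(grid), function(j) {
    tied <- which(A[, j] >= max(A[, j]) - tol)
    tied[which.min(abs(ts[tied] - grid[j]))]
  }, integer(1))
  win <- ord[win]
  if (smooth && ncol(auc_matrix) >= 3L) {
    sm <- win
    for (i in 2:(length(win) - 1L)) {
      wnd <- win[(i - 1L):(i + 1L)]
      tb <- table(wnd)
      if (max(tb) >= 2L && !win[i] %in% as.integer(names(tb)[tb >= 2L]))
        sm[i] <- as.integer(names(tb)[which.max(tb)])
    }
    win <- sm
  }
  runs <- rle(win)
  hi_idx <- cumsum(runs$lengths)
  lo_idx <- hi_idx - runs$lengths + 1L
  out <- data.frame(expert_id = rownames(auc_matrix)[runs$values],
                    sigma_lo = grid[lo_idx], sigma_hi = grid[hi_idx],
                    lo_idx = lo_idx, hi_idx = hi_idx,
                    stringsAsFactors = FALSE)
  attr(out, "sigma_grid") <- grid
  class(out) <- c("expert_range_map", "data.frame")
  out
}

#' Derive LV gating thresholds from a calibration table and expert ranges
#'
#' For each boundary between consecutive expert ranges -- the lower range
#' ending at grid sigma `s`, the upper starting at its successor `s'` -- the
#' threshold is the average of the two calibrated medians,
#' \eqn{\tau = (\mathrm{median LV}(s) + \mathrm{median LV}(s')) / 2}.
#' Thresholds are emitted sharpest-first (strictly decreasing when the
#' calibration table is strictly decreasing).
#'
#' @param calib an `lv_calibration`.
#' @param ranges an `expert_range_map`.
#' @return object of class `gating_table`: list with `thresholds`
#'   (length m-1, decreasing) and `expert_ids` (length m, sharpest-first).
#' @export
derive_lv_thresholds <- function(calib, ranges) {
  stopifnot(inherits(calib, "lv_calibration"),
            inherits(ranges, "expert_range_map"))
  m <- nrow(ranges)
  lookup <- function(sg) {
    i <- match(TRUE, abs(calib$entries$sigma - sg) < 1e-9)
    if (is.na(i)) stop("range boundary sigma ", sg,
                       " is not on the calibration grid")
    calib$entries$median_lv[i]
  }
  thresholds <- if (m <= 1L) numeric(0) else
    vapply(seq_len(m - 1L), function(k) {
      (lookup(ranges$sigma_hi[k]) + lookup(ranges$sigma_lo[k + 1L])) / 2
    }, numeric(1))
  gating_table(thresholds, ranges$expert_id)
}

#' Construct a gating table
#'
#' @param thresholds LV thresholds, strictly decreasing, one fewer than
#'   experts.
#' @param expert_ids expert identifiers ordered sharpest-first.
#' @return object of class `gating_table`.
#' @export
gating_table <- function(thresholds, expert_ids) {
  m <- length(expert_ids)
  if (length(thresholds) != m - 1L)
    stop("need exactly m-1 thresholds for m experts: got ",
         length(thresholds), " thresholds for ", m, " experts")
  if (m > 1L && (any(diff(thresholds) >= 0) || any(thresholds <= 0)))
    stop("thresholds must be strictly decreasing and positive")
  structure(list(thresholds = thresholds, expert_ids = expert_ids),
            class = "gating_table")
}

#' @export
print.gating_table <- function(x, ...) {
  m <- length(x$expert_ids)
  cat("LV gating table (", m, " experts):\n", sep = "")
  if (m == 1L) {
    cat("  all tiles -> ", x$expert_ids, "\n", sep = "")
  } else {
    cat(sprintf("  LV > %.1f -> %s\n", x$thresholds[1], x$expert_ids[1]))
    if (m > 2L) for (k in 2:(m - 1L))
      cat(sprintf("  %.1f < LV <= %.1f -> %s\n", x$thresholds[k],
                  x$thresholds[k - 1L], x$expert_ids[k]))
    cat(sprintf("  LV <= %.1f -> %s\n", x$thresholds[m - 1L], x$expert_ids[m]))
  }
  invisible(x)
}
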