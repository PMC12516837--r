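test_that("sigma-to-LV calibration reproduces the identity at sigma 0 and is deterministic", {
  set.seed(17)
  cfg <- synthetic_config(n_patients = 2, tiles_per_slide = 1, tile_size = 48)
  tiles <- replicate(120, generate_tile(1, cfg), simplify = FALSE)
  grid <- c(0, 1, 3, 6)
  cal <- calibrate_sigma_to_lv(tiles, grid, seed = 3)
  expect_equal(cal$entries$median_lv[1],
               median(vapply(tiles, laplacian_variance, numeric(1))))
  expect_true(all(diff(cal$entries$median_lv) < 0))
  cal2 <- calibrate_sigma_to_lv(tiles, grid, seed = 3)
  expect_identical(cal, cal2)

  expect_error(calibrate_sigma_to_lv(tiles[1:10], grid), "at least")
  flat <- replicate(120, matrix(100, 32, 32), simplify = FALSE)
  expect_error(calibrate_sigma_to_lv(flat, grid), "degenerate")
})

test_that("expert range selection: argmax, tie-break, merging", {
  # toy 2-expert matrix over grid {0, 5}
  m <- matrix(c(0.9, 0.6, 0.7, 0.8), 2, 2, byrow = TRUE,
              dimnames = list(c("E0", "E1"), c("0", "5")))
  rg <- select_expert_ranges(m, train_sigmas = c(0, 5))
  expect_identical(rg$expert_id, c("E0", "E1"))
  expect_identical(rg$sigma_lo, c(0, 5))

  # one expert dominating everywhere -> single interval
  dom <- matrix(c(0.9, 0.9, 0.9, 0.5, 0.6, 0.7), 2, 3, byrow = TRUE,
                dimnames = list(c("A", "B"), c("0", "2", "4")))
  rd <- select_expert_ranges(dom, train_sigmas = c(0, 4))
  expect_identical(nrow(rd), 1L)
  expect_identical(rd$expert_id, "A")

  # AUC ties (within the estimation tolerance) go to the lower training sigma
  tie <- matrix(c(0.8, 0.8), 2, 1,
                dimnames = list(c("hi", "lo"), "3"))
  expect_identical(select_expert_ranges(tie, train_sigmas = c(5, 1))$expert_id,
                   "lo")
  near <- matrix(c(0.805, 0.80), 2, 1,
                 dimnames = list(c("hi", "lo"), "3"))
  expect_identical(select_expert_ranges(near, train_sigmas = c(5, 1))$expert_id,
                   "lo")

  # non-contiguous winner smoothed away by the 3-cell majority window
  noisy <- matrix(c(0.9, 0.9, 0.50, 0.9, 0.2, 0.2,
                    0.1, 0.1, 0.55, 0.1, 0.8, 0.8), 2, 6, byrow = TRUE,
                  dimnames = list(c("A", "B"), c("0", "1", "2", "3", "4", "5")))
  rn <- select_expert_ranges(noisy, train_sigmas = c(0, 4))
  expect_identical(rn$expert_id, c("A", "B"))

  miss <- matrix(c(0.9, NA), 1, 2, dimnames = list("A", c("0", "1")))
  expect_error(select_expert_ranges(miss, train_sigmas = 0), "missing AUC")
})

test_that("LV thresholds average consecutive calibrated medians", {
  calib <- structure(list(entries = data.frame(
    sigma = c(0, 1.5, 2, 4), median_lv = c(900, 400, 300, 50)),
    n_tiles_sampled = 100, seed = 1), class = "lv_calibration")
  ranges <- structure(data.frame(expert_id = c("sharp", "soft"),
                                 sigma_lo = c(0, 2), sigma_hi = c(1.5, 4),
                                 lo_idx = c(1L, 3L), hi_idx = c(2L, 4L)),
                      class = c("expert_range_map", "data.frame"))
  g <- derive_lv_thresholds(calib, ranges)
  expect_equal(g$thresholds, 350)   # (400 + 300) / 2
  expect_identical(g$expert_ids, c("sharp", "soft"))

  # single range -> empty threshold list
  one <- ranges[1, ]; class(one) <- class(ranges)
  expect_identical(derive_lv_thresholds(calib, one)$thresholds, numeric(0))

  # off-grid boundary is an error
  bad <- ranges; bad$sigma_hi[1] <- 1.7
  expect_error(derive_lv_thresholds(calib, bad), "not on the calibration grid")
})

test_that("thresholds from decreasing tables are strictly decreasing (property)", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    grid <- sort(runif(n, 0, 10))
    med <- sort(runif(n, 1, 2000), decreasing = TRUE)
    calib <- structure(list(entries = data.frame(sigma = grid, median_lv = med),
                            n_tiles_sampled = 100, seed = 1),
                       class = "lv_calibration")
    m <- sample(2:(n - 1), 1)
    cuts <- sort(sample(n - 1, m - 1))
    ranges <- structure(data.frame(
      expert_id = paste0("e", 1:m),
      sigma_lo = grid[c(1, cuts + 1)], sigma_hi = grid[c(cuts, n)],
      lo_idx = c(1L, cuts + 1L), hi_idx = c(cuts, n)),
      class = c("expert_range_map", "data.frame"))
    g <- derive_lv_thresholds(calib, ranges)
    expect_identical(length(g$thresholds), m - 1L)
    expect_true(all(diff(g$thresholds) < 0))
    # idempotence
    expect_identical(g, derive_lv_thresholds(calib, ranges))
  }
})

test_that("a five-group cross-blur outcome is recovered from a clear AUC matrix", {
  # Structure mirroring the canonical tile-classifier sweep: the baseline
  # wins below sigma 1.5, the 0.5-expert up to 2.5, then the 3.0-, 4.0- and
  # 5.0-experts take over, five contiguous groups in total.
  grid <- c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 7, 8, 9, 10)
  sigmas <- c(0, 0.5, 1, 2, 3, 4, 5, 6, 7, 8, 9)
  winner <- function(sg) {
    if (sg < 1.5) "expert_0"
    else if (sg < 2.5) "expert_0.5"
    else if (sg < 3.5) "expert_3"
    else if (sg < 5) "expert_4"
    else "expert_5"
  }
  A <- matrix(0.5, length(sigmas), length(grid),
              dimnames = list(paste0("expert_", sigmas), as.character(grid)))
  for (j in seq_along(grid)) {
    A[, j] <- pmax(0.5, 0.85 - 0.04 * abs(sigmas - grid[j]))
    A[winner(grid[j]), j] <- 0.92   # clear winner, margin above tolerance
  }
  rg <- select_expert_ranges(A, train_sigmas = sigmas)
  expect_identical(rg$expert_id,
                   c("expert_0", "expert_0.5", "expert_3", "expert_4",
                     "expert_5"))
  expect_identical(rg$sigma_lo, c(0, 1.5, 2.5, 3.5, 5))
  expect_identical(rg$sigma_hi, c(1, 2, 3, 4, 10))
})

test_that("tiles blurred inside an expert's sigma interval route back to it", {
  set.seed(77)
  cfg <- synthetic_config(n_patients = 2, tiles_per_slide = 1, tile_size = 64)
  tiles <- replicate(110, generate_tile(1, cfg), simplify = FALSE)
  grid <- c(0, 1, 2, 4, 6, 8)
  calib <- calibrate_sigma_to_lv(tiles, grid, seed = 7)
  ranges <- structure(data.frame(
    expert_id = c("sharp", "mid", "soft"),
    sigma_lo = c(0, 2, 6), sigma_hi = c(1, 4, 8),
    lo_idx = c(1L, 3L, 5L), hi_idx = c(2L, 4L, 6L)),
    class = c("expert_range_map", "data.frame"))
  gate <- derive_lv_thresholds(calib, ranges)
  hits <- 0L
  probes <- tiles[1:50]
  for (tl in probes) {
    theta <- laplacian_variance(apply_blur(tl, 3))   # midpoint of "mid"
    hits <- hits + (route_tiles(theta, gate)$expert_ids == "mid")
  }
  expect_gte(hits / length(probes), 0.9)
})
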