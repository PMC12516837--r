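#' Configuration for the synthetic tile cohort generator
#'
#' The generator emulates the statistical structure of a binary-labelled
#' cohort of slides whose class signal is carried partly by high-spatial-
#' frequency texture: each tile is a smooth random background plus a
#' Poisson-distributed number of small dark blobs (more blobs in class 1)
#' plus i.i.d. pixel noise.  Gaussian blur smears the blobs into the
#' background, so class separability degrades progressively with sigma --
#' the property the blur-robustness machinery is designed around.
#'
#' Intensity nuisance is split into a per-slide level offset
#' (`bg_level_sd_slide`, emulating staining variation between slides) and a
#' per-tile offset (`bg_level_sd_tile`), which keeps mean intensity a weak,
#' bounded class cue at slide level.
#'
#' @param n_patients number of patients (one slide each).
#' @param tiles_per_slide tiles per slide bag.
#' @param tile_size tile side in pixels (default 128; >= 32).
#' @param class_blob_density per-class Poisson mean blob count per tile,
#'   `c(class0, class1)` (default 40 and 120).
#' @param blob_radius_px range of blob radii in pixels, sampled uniformly
#'   per blob (default 2--4).
#' @param blob_contrast intensity depression of a blob, 0--255 scale
#'   (default 80).
#' @param density_jitter_sd SD of the per-slide log-normal blob-density
#'   multiplier (default 0.7), emulating biological heterogeneity between
#'   patients; this bounds achievable slide-level AUC away from 1.
#' @param radius_jitter_sd SD of the per-slide log-normal blob-radius
#'   multiplier (default 0.15): slides differ in characteristic object
#'   size, so no single-tile statistic reads the class size structure
#'   noiselessly.
#' @param mass_matched logical (default TRUE): scale class-0 blob radii by
#'   `sqrt(density_1 / density_0)` so both classes deposit the same expected
#'   blob mass per tile.  Mean intensity and global contrast then carry no
#'   class signal -- the classes differ in high-frequency structure (many
#'   small objects versus few large ones), which is exactly the information
#'   Gaussian blur destroys.
#' @param common_blob_count Poisson mean count of large, faint blobs shared
#'   by both classes (default 15): non-discriminative coarse structure that
#'   masks coarse-scale energy as a class cue in sharp tiles.
#' @param common_blob_radius radius range of the common blobs (default
#'   6--10 px).
#' @param common_blob_contrast intensity depression of the common blobs
#'   (default 40).
#' @param background_smoothness sigma (pixels) of the low-frequency random
#'   background field (default 16).
#' @param bg_level mean background intensity (default 200).
#' @param bg_level_sd_slide SD of the per-slide intensity offset (default 8).
#' @param bg_level_sd_tile SD of the per-tile intensity offset (default 6).
#' @param bg_texture_amp amplitude (SD) of the low-frequency background
#'   field (default 15).
#' @param pixel_noise_sd SD of i.i.d. pixel noise (default 5).
#' @param class_balance fraction of patients in class 1 (default 0.6).
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   cohort.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 100, tiles_per_slide = 50,
                             tile_size = 128,
                             class_blob_density = c(40, 120),
                             blob_radius_px = c(2, 4),
                             blob_contrast = 80,
                             density_jitter_sd = 0.7,
                             radius_jitter_sd = 0.15,
                             mass_matched = TRUE,
                             common_blob_count = 15,
                             common_blob_radius = c(6, 10),
                             common_blob_contrast = 40,
                             background_smoothness = 16,
                             bg_level = 200,
                             bg_level_sd_slide = 8,
                             bg_level_sd_tile = 6,
                             bg_texture_amp = 15,
                             pixel_noise_sd = 5,
                             class_balance = 0.6,
                             seed = 1L) {
  stopifnot(tile_size >= 32, tiles_per_slide >= 1,
            class_balance > 0, class_balance < 1,
            length(class_blob_density) == 2L, all(class_blob_density >= 0),
            length(blob_radius_px) == 2L, blob_radius_px[1] <= blob_radius_px[2],
            blob_contrast >= 0, density_jitter_sd >= 0,
            radius_jitter_sd >= 0,
            common_blob_count >= 0, common_blob_contrast >= 0,
            background_smoothness > 0,
            pixel_noise_sd >= 0, is.numeric(seed), length(seed) == 1L)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate one synthetic tile
#'
#' A `tile_size x tile_size` grayscale grid on the 0--255 scale: smooth
#' random background + a Poisson-distributed number of dark, soft-edged disc
#' blobs (count mean given by the class's blob density) + i.i.d. pixel
#' noise, clipped to `[0, 255]`.  Blob centres are uniform over the tile
#' interior with a two-blob-radius margin.  The planted blob count is
#' attached as attribute `n_blobs` so that tests can audit it.
#'
#' Draws from the current RNG stream unless `seed` is given.
#'
#' @param class_label 0 or 1.
#' @param params a `synthetic_config`.
#' @param level_offset additive intensity offset (slide/tile nuisance; the
#'   cohort generator supplies it).
#' @param blob_density optional override of the class's mean blob count
#'   (the cohort generator passes the slide's jittered density).
#' @param radius_scale multiplier on the class blob radii (the cohort
#'   generator passes the slide's jittered size factor).
#' @param seed optional integer seed for a self-contained draw.
#' @return numeric matrix with attributes `n_blobs` and `class_label`.
#' @export
generate_tile <- function(class_label, params = synthetic_config(),
                          level_offset = 0, blob_density = NULL,
                          radius_scale = 1, seed = NULL) {
  if (!is.numeric(class_label) || length(class_label) != 1L ||
      !class_label %in% c(0, 1))
    stop("class_label must be 0 or 1, got: ", format(class_label))
  stopifnot(inherits(params, "synthetic_config"))
  with_seed(seed, {
    ts <- params$tile_size
    # Low-frequency background field: white noise smoothed at
    # `background_smoothness`, synthesised on a coarse grid (factor f) and
    # bilinearly upsampled -- statistically a smooth stationary field with
    # the requested correlation length, at a fraction of the cost.
    f <- max(1L, floor(params$background_smoothness / 4))
    cs <- ceiling(ts / f) + 2L
    coarse <- sep_convolve_cpp(matrix(rnorm(cs * cs), cs, cs),
                               gaussian_kernel_1d(params$background_smoothness / f))
    field <- upsample_bilinear_cpp(coarse, f, ts, ts)
    fs <- sd(field)
    if (fs > 0) field <- field / fs * params$bg_texture_amp
    tile <- params$bg_level + level_offset + field

    paint_blobs <- function(tile, n, r_lo, r_hi, contrast) {
      if (n == 0 || contrast == 0) return(tile)
      radii <- runif(n, r_lo, r_hi)
      for (b in seq_len(n)) {
        r <- radii[b]
        m <- min(2 * r, (ts - 1) / 2)   # blobs near tile scale stay placeable
        cx <- runif(1, 1 + m, ts - m)
        cy <- runif(1, 1 + m, ts - m)
        # dark disc of radius r with a 1-pixel soft (anti-aliased) edge
        w <- ceiling(r + 1)
        ix <- max(1L, floor(cx - w)):min(ts, ceiling(cx + w))
        iy <- max(1L, floor(cy - w)):min(ts, ceiling(cy + w))
        d <- sqrt(outer((ix - cx)^2, (iy - cy)^2, "+"))
        tile[ix, iy] <- tile[ix, iy] - contrast * pmin(1, pmax(0, r + 0.5 - d))
      }
      tile
    }
    dens <- blob_density %||% params$class_blob_density[class_label + 1L]
    rscale <- if (params$mass_matched && class_label == 0)
      sqrt(params$class_blob_density[2] / params$class_blob_density[1]) else 1
    rscale <- rscale * radius_scale
    n_blobs <- rpois(1L, dens)
    tile <- paint_blobs(tile, n_blobs, rscale * params$blob_radius_px[1],
                        rscale * params$blob_radius_px[2],
                        params$blob_contrast)
    n_common <- rpois(1L, params$common_blob_count)
    tile <- paint_blobs(tile, n_common, params$common_blob_radius[1],
                        params$common_blob_radius[2],
                        params$common_blob_contrast)
    if (params$pixel_noise_sd > 0)
      tile <- tile + rnorm(ts * ts, sd = params$pixel_noise_sd)
    tile <- pmin(pmax(tile, 0), 255)
    attr(tile, "n_blobs") <- n_blobs
    attr(tile, "n_common") <- n_common
    attr(tile, "class_label") <- class_label
    tile
  })
}

#' Generate a labelled synthetic cohort
#'
#' Produces `n_patients` slide bags, each holding `tiles_per_slide` pristine
#' tiles (`base_sigma = 0`) of that patient's class.  Class counts follow
#' `class_balance` to within rounding.  One RNG stream is derived from the
#' config seed and sub-streamed per patient by index, so regenerating any
#' single patient is stable.
#'
#' @param config a `synthetic_config`.
#' @return object of class `slide_cohort`: list with `bags` (list of
#'   `slide_bag`), `labels` (0/1 integer vector) and `patient_ids`.
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients
  if (n < 2) stop("n_patients must be at least 2, got ", n)
  n1 <- round(config$class_balance * n)
  if (n1 < 1 || n1 > n - 1)
    stop("class_balance ", config$class_balance, " with n_patients ", n,
         " yields a single-class cohort")
  seeds <- sub_seeds(config$seed, n + 1L)
  labels <- with_seed(seeds[n + 1L],
                      sample(c(rep(1L, n1), rep(0L, n - n1))))
  patient_ids <- sprintf("P%04d", seq_len(n))
  bags <- lapply(seq_len(n), function(i) {
    with_seed(seeds[i], {
      slide_offset <- rnorm(1, 0, config$bg_level_sd_slide)
      slide_density <- config$class_blob_density[labels[i] + 1L] *
        exp(rnorm(1, 0, config$density_jitter_sd))
      slide_rscale <- exp(rnorm(1, 0, config$radius_jitter_sd))
      tiles <- lapply(seq_len(config$tiles_per_slide), function(t) {
        generate_tile(labels[i], config,
                      level_offset = slide_offset +
                        rnorm(1, 0, config$bg_level_sd_tile),
                      blob_density = slide_density,
                      radius_scale = slide_rscale)
      })
      new_slide_bag(slide_id = patient_ids[i], patient_id = patient_ids[i],
                    label = labels[i], tiles = tiles)
    })
  })
  structure(list(bags = bags, labels = labels, patient_ids = patient_ids,
                 config = config),
            class = "slide_cohort")
}

#' Construct a slide bag
#'
#' @param slide_id,patient_id identifiers.
#' @param label binary slide label.
#' @param tiles list of tile matrices.
#' @param base_sigma per-tile baseline blur sigma (default 0).
#' @param tile_ids per-tile identifiers (default `<slide_id>_T<k>`).
#' @return object of class `slide_bag`.
#' @export
new_slide_bag <- function(slide_id, patient_id = slide_id, label, tiles,
                          base_sigma = rep(0, length(tiles)),
                          tile_ids = sprintf("%s_T%03d", slide_id,
                                             seq_along(tiles))) {
  stopifnot(label %in% c(0, 1), length(base_sigma) == length(tiles),
            length(tile_ids) == length(tiles))
  structure(list(slide_id = slide_id, patient_id = patient_id,
                 label = as.integer(label), tiles = tiles,
                 tile_ids = tile_ids, base_sigma = base_sigma, theta = NULL),
            class = "slide_bag")
}

#' @export
print.slide_bag <- function(x, ...) {
  cat(sprintf("slide_bag %s: label %d, %d tiles%s\n", x$slide_id, x$label,
              length(x$tiles),
              if (is.null(x$theta)) "" else sprintf(", median LV %.1f",
                                                    median(x$theta))))
  invisible(x)
}

#' @export
print.slide_cohort <- function(x, ...) {
  cat(sprintf("slide_cohort: %d patients (%d class 1, %d class 0), %d tiles/slide, %dpx tiles\n",
              length(x$bags), sum(x$labels == 1L), sum(x$labels == 0L),
              length(x$bags[[1L]]$tiles), nrow(x$bags[[1L]]$tiles[[1L]])))
  invisible(x)
}

#' Stratified patient-level cross-validation splits
#'
#' Partitions patients into `k` folds at the patient level, stratified by
#' label: within each class, shuffled patients are dealt round-robin across
#' folds (the deal position carries over between classes to balance fold
#' sizes), so each fold's class proportion deviates from the global
#' proportion by less than one patient.
#'
#' @param patient_ids character vector of unique ids.
#' @param labels binary labels, same length.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of `k` elements, each `list(train = ids, validation = ids)`.
#' @export
make_cv_splits <- function(patient_ids, labels, k = 5, seed = 1L) {
  stopifnot(length(patient_ids) == length(labels), k >= 2,
            !anyDuplicated(patient_ids), all(labels %in% c(0, 1)))
  if (length(patient_ids) < k)
    stop("fewer patients (", length(patient_ids), ") than folds (", k, ")")
  for (cl in c(0, 1)) {
    if (sum(labels == cl) < 1)
      stop("class ", cl, " has no patients; both classes are required")
  }
  fold <- integer(length(patient_ids))
  with_seed(seed, {
    pos <- 0L
    for (cl in c(1, 0)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
      pos <- pos + length(idx)
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = patient_ids[fold != f], validation = patient_ids[fold == f])
  })
}
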