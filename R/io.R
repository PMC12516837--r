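#' Write a tile as a plain-text PGM image
#'
#' Tiles are stored as ASCII PGM (P2), a plain-text grayscale format that
#' any image tool reads; intensities are rounded to the 0--255 integer
#' scale on write (the in-memory pipeline stays in floating point).
#'
#' @param tile numeric matrix (or 3-channel array, converted to luminance).
#' @param path output file path.
#' @export
write_pgm <- function(tile, path) {
  lum <- to_luminance(tile)
  v <- round(pmin(pmax(lum, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(v), nrow(v)), "255"), con)
  # one image row per line, row-major as PGM expects
  writeLines(apply(v, 1, paste, collapse = " "), con)
}

#' Read a plain-text PGM image
#'
#' @param path file path of an ASCII (P2) PGM image.
#' @return numeric matrix on the 0--255 scale.
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  dims <- as.integer(toks[2:3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != prod(dims))
    stop("corrupt PGM ", path, ": expected ", prod(dims), " pixels, got ",
         length(vals))
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
}

#' Write a cohort to disk as tiles plus a manifest
#'
#' Tiles are written as ASCII PGM files under `dir/tiles/`, and a manifest
#' CSV with columns `slide_id`, `patient_id`, `label`, `tile_path`,
#' `base_sigma` is written to `dir/manifest.csv`.
#'
#' @param cohort a `slide_cohort`.
#' @param dir output directory (created if needed).
#' @return path of the manifest, invisibly.
#' @export
write_manifest <- function(cohort, dir) {
  tiledir <- file.path(dir, "tiles")
  dir.create(tiledir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (bag in cohort$bags) {
    for (k in seq_along(bag$tiles)) {
      rel <- file.path("tiles", paste0(bag$tile_ids[k], ".pgm"))
      write_pgm(bag$tiles[[k]], file.path(dir, rel))
      rows[[length(rows) + 1L]] <- data.frame(
        slide_id = bag$slide_id, patient_id = bag$patient_id,
        label = bag$label, tile_path = rel, base_sigma = bag$base_sigma[k],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from a manifest
#'
#' @param path manifest CSV with columns `slide_id`, `patient_id`, `label`,
#'   `tile_path`, `base_sigma`; tile paths are resolved relative to the
#'   manifest's directory.
#' @return a `slide_cohort`.
#' @export
read_manifest <- function(path) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("slide_id", "patient_id", "label", "tile_path", "base_sigma")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(man) == 0L) stop("no slides: manifest is empty")
  if (!all(man$label %in% c(0, 1))) {
    bad <- which(!man$label %in% c(0, 1))[1L]
    stop("non-binary label '", man$label[bad], "' at manifest row ", bad)
  }
  base <- dirname(path)
  full <- file.path(base, man$tile_path)
  missing <- !file.exists(full)
  if (any(missing))
    stop("missing tile file(s), first at manifest row ", which(missing)[1L],
         ": ", man$tile_path[which(missing)[1L]])
  bags <- lapply(split(seq_len(nrow(man)), man$slide_id), function(idx) {
    new_slide_bag(slide_id = man$slide_id[idx[1L]],
                  patient_id = man$patient_id[idx[1L]],
                  label = man$label[idx[1L]],
                  tiles = lapply(full[idx], read_pgm),
                  base_sigma = man$base_sigma[idx],
                  tile_ids = sub("\\.pgm$", "", basename(man$tile_path[idx])))
  })
  bags <- bags[order(names(bags))]
  structure(list(bags = unname(bags),
                 labels = unname(vapply(bags, `[[`, integer(1), "label")),
                 patient_ids = unname(vapply(bags, `[[`, character(1),
                                             "patient_id"))),
            class = "slide_cohort")
}

#' Serialise calibration and gating tables to JSON
#'
#' @param calib an `lv_calibration`.
#' @param gating a `gating_table`.
#' @param path output JSON path.
#' @param seed seed recorded for replay.
#' @export
write_gates_json <- function(calib, gating, path, seed = NULL) {
  jsonlite::write_json(list(
    sigma_grid = calib$entries$sigma,
    median_lv = calib$entries$median_lv,
    n_tiles_sampled = calib$n_tiles_sampled,
    thresholds = gating$thresholds,
    expert_ids = gating$expert_ids,
    seed = seed), path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read calibration and gating tables from JSON
#'
#' @param path JSON written by [write_gates_json()].
#' @return list with `calibration` (`lv_calibration`) and `gating`
#'   (`gating_table`).
#' @export
read_gates_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  calib <- structure(list(entries = data.frame(sigma = j$sigma_grid,
                                               median_lv = j$median_lv),
                          n_tiles_sampled = j$n_tiles_sampled,
                          seed = j$seed),
                     class = "lv_calibration")
  list(calibration = calib,
       gating = gating_table(as.numeric(j$thresholds), j$expert_ids))
}
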