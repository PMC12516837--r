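#' Fit a sharpness-gated mixture of experts
#'
#' The top-level model fit.  Given a labelled cohort of slide bags and a
#' train/validation split, it (1) trains one expert per entry of
#' `expert_sigmas`, each on training tiles blurred at that sigma (sigma 0 is
#' the sharp baseline); (2) calibrates the sigma-to-LV mapping on a sample
#' of training tiles; (3) sweeps every expert over validation sets uniformly
#' blurred along `sigma_grid` to obtain the cross-blur AUC sensitivity
#' matrix; (4) selects, per validation sigma, the best expert and merges the
#' winners into contiguous sigma ranges; and (5) converts the range
#' boundaries into LV gating thresholds by averaging consecutive calibrated
#' medians.  The returned object routes tiles at prediction time with the
#' deterministic LV gate.
#'
#' @param cohort a `slide_cohort` (or any list with `bags`, `labels`,
#'   `patient_ids`).
#' @param train_ids,validation_ids patient ids for the split.
#' @param expert_sigmas training blur levels; must include 0 (the
#'   baseline).  Default `{0, 0.5, 1, 2, 3, 4, 5, 6, 7, 8, 9}`.
#' @param kind `"tile"` (logistic tile classifier, 75th-percentile pooling)
#'   or `"attention"` (gated-attention bag head, weighted-average
#'   combination).
#' @param sigma_grid validation sweep grid (default the 15-level grid).
#' @param calib_n tiles sampled for LV calibration (default 500).
#' @param control training settings passed to the expert trainers.
#' @param seed integer seed governing expert initialisation, calibration
#'   sampling and any scenario draws.
#' @return object of class `moe` with components `experts`, `baseline`,
#'   `calibration`, `sensitivity`, `ranges`, `gating`, `kind`, `seed`.
#' @seealso [predict.moe()], [scenario_benchmark()]
#' @examples
#' \donttest{
#' cfg <- synthetic_config(n_patients = 20, tiles_per_slide = 8,
#'                         tile_size = 64, seed = 7)
#' co <- generate_cohort(cfg)
#' split <- make_cv_splits(co$patient_ids, co$labels, k = 5, seed = 7)[[1]]
#' fit <- moe_fit(co, split$train, split$validation,
#'                expert_sigmas = c(0, 3, 8), sigma_grid = c(0, 3, 8),
#'                calib_n = 100, seed = 7)
#' print(fit)
#' }
#' @export
moe_fit <- function(cohort, train_ids, validation_ids,
                    expert_sigmas = c(0, 0.5, 1, 2, 3, 4, 5, 6, 7, 8, 9),
                    kind = c("tile", "attention"),
                    sigma_grid = c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6,
                                   7, 8, 9, 10),
                    calib_n = 500, control = list(), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(0 %in% expert_sigmas, all(expert_sigmas >= 0 & expert_sigmas <= 10))
  expert_sigmas <- sort(unique(expert_sigmas))
  pick <- function(ids) {
    i <- match(ids, cohort$patient_ids)
    if (any(is.na(i))) stop("unknown patient ids: ",
                            paste(ids[is.na(i)], collapse = ", "))
    i
  }
  itr <- pick(train_ids); iva <- pick(validation_ids)
  train_bags <- cohort$bags[itr]; ytr <- cohort$labels[itr]
  val_bags <- cohort$bags[iva]; yva <- cohort$labels[iva]
  seeds <- sub_seeds(seed, length(expert_sigmas) + 1L)

  trainer <- if (kind == "tile") train_tile_expert else train_attention_expert
  experts <- lapply(seq_along(expert_sigmas), function(k)
    trainer(train_bags, ytr, sigma = expert_sigmas[k], config = control,
            seed = seeds[k],
            expert_id = sprintf("expert_%g", expert_sigmas[k])))

  all_tiles <- unlist(lapply(train_bags, `[[`, "tiles"), recursive = FALSE)
  calibration <- calibrate_sigma_to_lv(all_tiles, sigma_grid,
                                       n_sample = min(calib_n, length(all_tiles)),
                                       seed = seeds[length(seeds)],
                                       min_tiles = min(100L, length(all_tiles)))
  sensitivity <- blur_sensitivity_sweep(experts, val_bags, yva, sigma_grid)
  ranges <- select_expert_ranges(sensitivity)
  gating <- derive_lv_thresholds(calibration, ranges)
  structure(list(kind = kind, experts = experts,
                 baseline = experts[[which(expert_sigmas == 0)]],
                 expert_sigmas = expert_sigmas,
                 calibration = calibration, sensitivity = sensitivity,
                 ranges = ranges, gating = gating, sigma_grid = sigma_grid,
                 seed = seed, n_train = length(train_bags),
                 n_validation = length(val_bags), call = match.call()),
            class = "moe")
}

#' @export
print.moe <- function(x, ...) {
  cat(sprintf("Sharpness-gated mixture of experts (%s track)\n", x$kind))
  cat(sprintf("  %d experts at sigma {%s}; %d train / %d validation slides\n",
              length(x$experts), paste(x$expert_sigmas, collapse = ", "),
              x$n_train, x$n_validation))
  cat(sprintf("  %d gated blur groups:\n", nrow(x$ranges)))
  for (k in seq_len(nrow(x$ranges)))
    cat(sprintf("    sigma [%g, %g] -> %s\n", x$ranges$sigma_lo[k],
                x$ranges$sigma_hi[k], x$ranges$expert_id[k]))
  print(x$gating)
  invisible(x)
}

#' @export
summary.moe <- function(object, ...) {
  print(object)
  cat("\nCross-blur AUC sensitivity matrix (rows = experts):\n")
  print(round(unclass(object$sensitivity), 3))
  cat("\nSigma-to-LV calibration medians:\n")
  print(object$calibration$entries, row.names = FALSE)
  invisible(object)
}

#' Plot the cross-blur sensitivity curves of a fitted MoE
#'
#' One AUC-versus-sigma curve per expert, with the selected expert-range
#' boundaries marked.
#'
#' @param x a fitted `moe`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.moe <- function(x, ...) {
  S <- unclass(x$sensitivity)
  grid <- as.numeric(colnames(S))
  graphics::matplot(grid, t(S), type = "b", pch = 16, lty = 1,
                    xlab = "validation blur sigma (px)", ylab = "slide-level AUC",
                    main = "Expert sensitivity to blur", ...)
  if (nrow(x$ranges) > 1L)
    graphics::abline(v = (x$ranges$sigma_hi[-nrow(x$ranges)] +
                          x$ranges$sigma_lo[-1]) / 2, lty = 3)
  graphics::legend("bottomleft", legend = rownames(S), col = seq_len(nrow(S)),
                   lty = 1, pch = 16, cex = 0.8)
  invisible(x)
}

#' Predict slide-level probabilities with a fitted MoE
#'
#' Scores a set of slide bags with both the sharpness-gated MoE and the
#' baseline expert (the latter sees all tiles), optionally after applying a
#' mixed-blur scenario to the pristine bags.
#'
#' @param object a fitted `moe`.
#' @param bags list of `slide_bag`s (or a `slide_cohort`).
#' @param scenario optional scenario id (1--12) or `blur_scenario` applied
#'   to the bags before scoring.
#' @param seed seed for the scenario draw.
#' @param ... unused.
#' @return data.frame with columns `slide_id`, `p_moe`, `p_baseline`.
#' @export
predict.moe <- function(object, bags, scenario = NULL, seed = 1L, ...) {
  if (inherits(bags, "slide_cohort")) bags <- bags$bags
  if (!is.null(scenario) && is.numeric(scenario))
    scenario <- blur_scenario(scenario)
  score <- function() {
    out <- lapply(bags, function(bg) {
      if (!is.null(scenario)) bg <- assign_scenario_blur(bg, scenario)$bag
      bg <- bag_sharpness(bg)
      F <- do.call(rbind, lapply(bg$tiles, extract_features))
      if (object$kind == "tile") {
        pm <- run_moe_simple(bg, object$experts, object$gating, features = F)
        pb <- aggregate_75th(predict_expert_features(object$baseline, F))
      } else {
        pm <- run_moe_attention(bg, object$experts, object$gating, features = F)
        pb <- predict_bag_attention(object$baseline, F)
      }
      data.frame(slide_id = bg$slide_id, p_moe = pm$p_final, p_baseline = pb,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  if (is.null(scenario)) score() else with_seed(seed, score())
}
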