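#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' slide scores above a random negative one, with ties counting 1/2.
#'
#' @param labels binary slide labels (both classes must be present).
#' @param scores numeric scores, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires both classes; got ", n1, " positives and ", n0,
         " negatives")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# slide-level scores for a set of bags from precomputed per-tile features
slide_scores <- function(expert, X, bag_index) {
  if (inherits(expert, "tile_expert")) {
    p <- predict_expert_features(expert, X)
    as.numeric(tapply(p, bag_index, aggregate_75th))
  } else {
    vapply(sort(unique(bag_index)), function(b)
      predict_bag_attention(expert, X[bag_index == b, , drop = FALSE]),
      numeric(1))
  }
}

#' Cross-blur sensitivity sweep
#'
#' Evaluates every expert on validation bags uniformly blurred at each sigma
#' of the grid: per cell, all validation tiles are blurred at that sigma,
#' featurised once, scored by the expert, aggregated to slide level
#' (75th-percentile pooling for tile experts, attention pooling for bag
#' experts), and summarised as the AUC (mean over folds when several fold
#' sets are given).  The resulting matrix is the input to
#' [select_expert_ranges()].
#'
#' @param experts list of trained experts (all the same kind).
#' @param validation_bags list of pristine `slide_bag`s (used when `folds`
#'   is NULL).
#' @param labels slide labels for `validation_bags`.
#' @param sigma_grid validation sigma grid (default the 15-level grid
#'   `{0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6, 7, 8, 9, 10}`).
#' @param folds optional list of folds, each `list(bags =, labels =)`; cells
#'   are then fold-averaged AUCs.
#' @return object of class `sensitivity_matrix`: experts x sigma AUC matrix
#'   with attribute `train_sigmas`.
#' @export
blur_sensitivity_sweep <- function(experts, validation_bags = NULL,
                                   labels = NULL,
                                   sigma_grid = c(0, 0.5, 1, 1.5, 2, 2.5, 3,
                                                  3.5, 4, 5, 6, 7, 8, 9, 10),
                                   folds = NULL) {
  stopifnot(length(experts) >= 1L)
  if (is.null(folds)) folds <- list(list(bags = validation_bags, labels = labels))
  ids <- vapply(experts, function(e) e$spec$expert_id, character(1))
  out <- matrix(0, length(experts), length(sigma_grid),
                dimnames = list(ids, as.character(sigma_grid)))
  for (fd in folds) {
    for (j in seq_along(sigma_grid)) {
      ft <- bag_features(fd$bags, fd$labels, sigma_grid[j])
      for (k in seq_along(experts)) {
        sc <- slide_scores(experts[[k]], ft$X, ft$bag_index)
        out[k, j] <- out[k, j] + auc(fd$labels, sc) / length(folds)
      }
    }
  }
  attr(out, "train_sigmas") <- vapply(experts,
                                      function(e) e$spec$train_sigma,
                                      numeric(1))
  class(out) <- c("sensitivity_matrix", class(out))
  out
}

#' Benchmark MoE against the baseline over mixed-blur scenarios
#'
#' For each scenario, scenario blur is applied once to every validation bag
#' (a seeded draw shared between both systems), per-tile LV and features are
#' computed once, and the same blurred inputs are scored by (a) the baseline
#' expert on all tiles and (b) the sharpness-gated MoE.  Deltas therefore
#' isolate the modelling strategy.
#'
#' @param baseline the baseline expert (trained at sigma 0).
#' @param experts the MoE ensemble (same kind as `baseline`).
#' @param gating a `gating_table` for `experts`.
#' @param validation_bags list of pristine `slide_bag`s.
#' @param labels slide labels.
#' @param scenarios scenario ids, subset of 1--12 (default all).
#' @param seed integer seed; one sub-seed is drawn per scenario.
#' @return object of class `scenario_report`: data.frame with one row per
#'   scenario (`scenario`, `p_low`, `p_moderate`, `p_high`, `auc_baseline`,
#'   `auc_moe`, `delta`).
#' @export
scenario_benchmark <- function(baseline, experts, gating, validation_bags,
                               labels, scenarios = 1:12, seed = 1L) {
  if (!all(scenarios %in% 1:12))
    stop("scenario ids must lie in 1..12, got: ",
         paste(setdiff(scenarios, 1:12), collapse = ", "))
  attention <- inherits(baseline, "attention_expert")
  tab <- blur_scenarios()
  seeds <- sub_seeds(seed, 12L)
  rows <- lapply(scenarios, function(sid) {
    scen <- blur_scenario(sid)
    res <- with_seed(seeds[sid], {
      p_base <- numeric(length(validation_bags))
      p_moe <- numeric(length(validation_bags))
      for (b in seq_along(validation_bags)) {
        blurred <- assign_scenario_blur(validation_bags[[b]], scen)$bag
        blurred <- bag_sharpness(blurred)
        F <- do.call(rbind, lapply(blurred$tiles, extract_features))
        if (attention) {
          p_base[b] <- predict_bag_attention(baseline, F)
          p_moe[b] <- run_moe_attention(blurred, experts, gating,
                                        features = F)$p_final
        } else {
          p_base[b] <- aggregate_75th(predict_expert_features(baseline, F))
          p_moe[b] <- run_moe_simple(blurred, experts, gating,
                                     features = F)$p_final
        }
      }
      c(auc(labels, p_base), auc(labels, p_moe))
    })
    data.frame(scenario = as.integer(sid), p_low = tab$p_low[sid],
               p_moderate = tab$p_moderate[sid], p_high = tab$p_high[sid],
               auc_baseline = res[1], auc_moe = res[2],
               delta = res[2] - res[1])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("scenario_report", "data.frame")
  out
}

#' Select the blurriest slides by Q1-of-LV
#'
#' @param slide_ids slide identifiers.
#' @param q1_values per-slide lower-quartile LV summaries (see
#'   [slide_blur_q1()]).
#' @param n number of slides to select (smallest Q1 first; ties broken by
#'   slide id order).
#' @return character vector of `n` slide ids.
#' @export
blurriest_subset <- function(slide_ids, q1_values, n) {
  stopifnot(length(slide_ids) == length(q1_values))
  if (n <= 0) stop("n must be positive, got ", n)
  if (n > length(slide_ids))
    stop("n (", n, ") exceeds the number of slides (", length(slide_ids), ")")
  slide_ids[order(q1_values, slide_ids)][seq_len(n)]
}
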