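#' Route tiles to experts by sharpness
#'
#' Applies the deterministic gating rule: a tile with LV \eqn{\theta >
#' \tau_1} goes to expert 1; \eqn{\tau_{k+1} < \theta \le \tau_k} goes to
#' expert k+1; \eqn{\theta \le \tau_{m-1}} goes to expert m.  A tile sitting
#' exactly on a threshold is routed to the blurrier expert (the intervals
#' are half-open, closed above).
#'
#' @param thetas numeric vector of per-tile LV values.
#' @param gating a `gating_table`.
#' @return object of class `routing_result`: list with `assignments`
#'   (per-tile expert index), `expert_ids` (per-tile id), `counts` (tiles
#'   per expert, named, including zeros) and `n_tot`.
#' @export
route_tiles <- function(thetas, gating) {
  stopifnot(inherits(gating, "gating_table"), is.numeric(thetas))
  m <- length(gating$expert_ids)
  tau <- gating$thresholds
  idx <- if (m == 1L) rep(1L, length(thetas)) else
    vapply(thetas, function(th) 1L + sum(tau >= th), integer(1))
  counts <- setNames(tabulate(idx, nbins = m), gating$expert_ids)
  structure(list(assignments = idx, expert_ids = gating$expert_ids[idx],
                 counts = counts, n_tot = length(thetas)),
            class = "routing_result")
}

#' 75th-percentile tile-to-slide aggregation
#'
#' The slide-level probability is the 75th percentile (linear interpolation
#' between closest order statistics) of the pooled tile-level probabilities.
#'
#' @param tile_probs non-empty numeric vector of probabilities.
#' @return scalar probability.
#' @export
aggregate_75th <- function(tile_probs) {
  if (length(tile_probs) == 0L) stop("cannot aggregate an empty set of tile predictions")
  unname(quantile(tile_probs, 0.75, type = 7))
}

#' Tile-fraction expert weights
#'
#' Each expert's weight is the fraction of the slide's tiles it handled,
#' \eqn{w_{m_i} = n_{m_i} / n_{tot}}; experts with zero tiles get weight 0
#' and the weights sum to 1.
#'
#' @param routing a `routing_result` (or a named vector of per-expert tile
#'   counts).
#' @return named numeric vector of weights.
#' @export
moe_weights <- function(routing) {
  counts <- if (inherits(routing, "routing_result")) routing$counts else routing
  n_tot <- sum(counts)
  if (n_tot < 1) stop("no tiles routed: n_tot is 0")
  counts / n_tot
}

#' Weighted-average combination of expert slide probabilities
#'
#' The final slide probability is \eqn{\hat p_{MoE} = \sum_i w_{m_i}
#' \hat p_{m_i}} over the experts that received tiles; zero-weight experts
#' may omit their probability (pass `NA`).
#'
#' @param weights per-expert weights summing to 1.
#' @param per_expert_probs per-expert probabilities (NA allowed where the
#'   weight is 0).
#' @return scalar probability in `[min p, max p]` of the active experts.
#' @export
moe_combine <- function(weights, per_expert_probs) {
  if (length(weights) != length(per_expert_probs))
    stop("weights and per-expert probabilities differ in length: ",
         length(weights), " vs ", length(per_expert_probs))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  active <- weights > 0
  p <- per_expert_probs[active]
  if (any(is.na(p))) stop("missing probability for an expert with positive weight")
  if (any(p < 0 | p > 1)) stop("expert probabilities must lie in [0, 1]")
  sum(weights[active] * p)
}

#' MoE inference with tile-level experts and percentile pooling
#'
#' Each tile's LV routes it to one expert; that expert alone predicts the
#' tile; all tile probabilities are pooled and the slide probability is
#' their 75th percentile.
#'
#' @param bag a `slide_bag` (per-tile `theta` computed if absent).
#' @param experts list of `tile_expert`s ordered to match the gating table
#'   (sharpest-first).
#' @param gating a `gating_table` whose `expert_ids` name entries of
#'   `experts`.
#' @param features optional precomputed per-tile feature matrix (rows in
#'   tile order) to avoid re-extraction.
#' @return object of class `slide_prediction`.
#' @export
run_moe_simple <- function(bag, experts, gating, features = NULL) {
  stopifnot(inherits(bag, "slide_bag"))
  if (length(bag$tiles) == 0L) stop("empty bag: ", bag$slide_id)
  if (is.null(bag$theta)) bag <- bag_sharpness(bag)
  experts <- match_experts(experts, gating)
  routing <- route_tiles(bag$theta, gating)
  if (is.null(features))
    features <- do.call(rbind, lapply(bag$tiles, extract_features))
  probs <- numeric(routing$n_tot)
  p_expert <- setNames(rep(NA_real_, length(experts)), gating$expert_ids)
  for (k in seq_along(experts)) {
    sel <- routing$assignments == k
    if (!any(sel)) next
    probs[sel] <- predict_expert_features(experts[[k]],
                                          features[sel, , drop = FALSE])
    p_expert[k] <- aggregate_75th(probs[sel])
  }
  new_slide_prediction(bag$slide_id, mode = "simple",
                       p_final = aggregate_75th(probs),
                       routing = routing,
                       weights = moe_weights(routing),
                       p_expert = p_expert, tile_probs = probs)
}

#' MoE inference with attention-bag experts and weighted averaging
#'
#' Tiles are partitioned by the gate; every expert with at least one tile
#' produces a bag-level probability from its own tiles only; the final slide
#' probability is the tile-fraction weighted average of the active experts'
#' probabilities.  Zero-tile experts are skipped with weight 0.
#'
#' @inheritParams run_moe_simple
#' @param experts list of `attention_expert`s matching the gating table.
#' @return object of class `slide_prediction`.
#' @export
run_moe_attention <- function(bag, experts, gating, features = NULL) {
  stopifnot(inherits(bag, "slide_bag"))
  if (length(bag$tiles) == 0L) stop("empty bag: ", bag$slide_id)
  if (is.null(bag$theta)) bag <- bag_sharpness(bag)
  experts <- match_experts(experts, gating)
  routing <- route_tiles(bag$theta, gating)
  if (is.null(features))
    features <- do.call(rbind, lapply(bag$tiles, extract_features))
  p_expert <- setNames(rep(NA_real_, length(experts)), gating$expert_ids)
  for (k in seq_along(experts)) {
    sel <- routing$assignments == k
    if (!any(sel)) next
    p_expert[k] <- predict_bag_attention(experts[[k]],
                                         features[sel, , drop = FALSE])
  }
  w <- moe_weights(routing)
  new_slide_prediction(bag$slide_id, mode = "attention",
                       p_final = moe_combine(w, p_expert),
                       routing = routing, weights = w, p_expert = p_expert)
}

match_experts <- function(experts, gating) {
  ids <- vapply(experts, function(e) e$spec$expert_id, character(1))
  pos <- match(gating$expert_ids, ids)
  if (any(is.na(pos)))
    stop("gating table references unknown expert(s): ",
         paste(gating$expert_ids[is.na(pos)], collapse = ", "))
  experts[pos]
}

new_slide_prediction <- function(slide_id, mode, p_final, routing, weights,
                                 p_expert, tile_probs = NULL) {
  structure(list(slide_id = slide_id, mode = mode, p_final = p_final,
                 counts = routing$counts, n_tot = routing$n_tot,
                 weights = weights, p_expert = p_expert,
                 tile_probs = tile_probs),
            class = "slide_prediction")
}

#' @export
print.slide_prediction <- function(x, ...) {
  cat(sprintf("slide_prediction %s (%s): p = %.4f over %d tiles\n",
              x$slide_id, x$mode, x$p_final, x$n_tot))
  act <- x$counts > 0
  cat(paste(sprintf("  %s: n=%d w=%.3f p=%s", names(x$counts)[act],
                    x$counts[act], x$weights[act],
                    ifelse(is.na(x$p_expert[act]), "-",
                           sprintf("%.3f", x$p_expert[act]))),
            collapse = "\n"), "\n")
  invisible(x)
}
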