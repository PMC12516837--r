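test_that("routing follows the half-open LV intervals", {
  g <- gating_table(c(350, 120), c("e1", "e2", "e3"))
  r <- route_tiles(c(400, 200, 100), g)
  expect_identical(r$expert_ids, c("e1", "e2", "e3"))

  # boundary theta == tau_1 belongs to the blurrier expert
  expect_identical(route_tiles(350, g)$expert_ids, "e2")
  expect_identical(route_tiles(120, g)$expert_ids, "e3")
  expect_identical(route_tiles(350 + 1e-9, g)$expert_ids, "e1")

  single <- gating_table(numeric(0), "only")
  rs <- route_tiles(c(1, 5, 9), single)
  expect_identical(rs$expert_ids, rep("only", 3))
  expect_identical(unname(rs$counts), 3L)

  expect_error(gating_table(c(100), c("a", "b", "c")), "m-1 thresholds")
  expect_error(gating_table(c(100, 200), c("a", "b", "c")), "decreasing")
})

test_that("routing agrees with a brute-force interval scan", {
  set.seed(13)
  for (rep in 1:1000) {
    m <- sample(1:6, 1)
    tau <- if (m == 1) numeric(0) else sort(runif(m - 1, 0, 1000),
                                            decreasing = TRUE)
    g <- gating_table(tau, paste0("e", seq_len(m)))
    theta <- c(runif(5, 0, 1100), tau)   # include exact boundary hits
    r <- route_tiles(theta, g)
    expect_identical(r$assignments, route_naive(theta, tau))
    expect_identical(sum(r$counts), r$n_tot)
  }
})

test_that("75th-percentile aggregation interpolates linearly", {
  expect_equal(aggregate_75th(0.7), 0.7)
  expect_equal(aggregate_75th(c(0.1, 0.2, 0.3, 0.4)), 0.325)
  expect_equal(aggregate_75th(rep(0.42, 9)), 0.42)
  set.seed(2)
  for (rep in 1:20) {
    x <- runif(sample(1:30, 1))
    expect_equal(aggregate_75th(x), percentile_naive(x, 0.75))
  }
  expect_error(aggregate_75th(numeric(0)), "empty")
})

test_that("tile-fraction weights and the weighted-average combination", {
  w <- moe_weights(c(a = 60, b = 30, c = 10))
  expect_equal(unname(w), c(0.6, 0.3, 0.1))
  expect_lt(abs(sum(w) - 1), 1e-12)

  expect_equal(moe_combine(c(0.6, 0.3, 0.1), c(0.9, 0.5, 0.1)), 0.70)
  expect_equal(moe_combine(c(0.5, 0.5), c(0.2, 0.8)), 0.5)
  expect_equal(moe_combine(c(1, 0), c(0.37, NA)), 0.37)

  expect_equal(unname(moe_weights(c(1, 1, 1))), rep(1 / 3, 3))
  expect_equal(sum(moe_weights(c(1, 1, 1))), 1)

  expect_error(moe_weights(c(0, 0)), "n_tot")
  expect_error(moe_combine(c(0.6, 0.4), c(0.5, NA)), "missing probability")
  expect_error(moe_combine(c(0.5, 0.5), c(0.2, 1.4)), "\\[0, 1\\]")

  # bounding: weighted average lies within the active expert probabilities
  set.seed(4)
  for (rep in 1:50) {
    m <- sample(2:5, 1)
    cnt <- rpois(m, 5); cnt[1] <- cnt[1] + 1
    w <- moe_weights(setNames(cnt, paste0("e", 1:m)))
    p <- runif(m)
    p[w == 0] <- NA
    f <- moe_combine(w, p)
    expect_gte(f, min(p[w > 0])); expect_lte(f, max(p[w > 0]))
  }
})

make_fixture_experts <- function() {
  co <- tiny_cohort(n_patients = 8, tiles = 3, size = 64, seed = 9)
  e0 <- train_tile_expert(co$bags, co$labels, sigma = 0,
                          config = list(epochs = 30), seed = 1,
                          expert_id = "e_sharp")
  e1 <- train_tile_expert(co$bags, co$labels, sigma = 4,
                          config = list(epochs = 30), seed = 2,
                          expert_id = "e_blur")
  list(cohort = co, experts = list(e0, e1))
}

test_that("single-expert MoE degenerates to the plain baseline bit-exactly", {
  fx <- make_fixture_experts()
  bag <- bag_sharpness(fx$cohort$bags[[1]])
  gate1 <- gating_table(numeric(0), "e_sharp")

  pred <- run_moe_simple(bag, fx$experts[1], gate1)
  X <- do.call(rbind, lapply(bag$tiles, extract_features))
  direct <- aggregate_75th(sharpgate:::predict_expert_features(fx$experts[[1]], X))
  expect_identical(pred$p_final, direct)
  expect_identical(unname(pred$counts), length(bag$tiles))
  expect_identical(unname(pred$weights), 1)
})

test_that("MoE pooling and routing bookkeeping are conserved", {
  fx <- make_fixture_experts()
  gate <- gating_table(1000, c("e_sharp", "e_blur"))
  for (bag in fx$cohort$bags[1:4]) {
    bag <- bag_sharpness(bag)
    pred <- run_moe_simple(bag, fx$experts, gate)
    expect_identical(sum(pred$counts), pred$n_tot)
    expect_lt(abs(sum(pred$weights) - 1), 1e-12)
    expect_gte(pred$p_final, 0); expect_lte(pred$p_final, 1)
  }
})

test_that("heterogeneous pooled percentile matches the hand computation", {
  # two constant-output experts: routed probabilities pooled, then 75th pct
  fx <- make_fixture_experts()
  bag <- bag_sharpness(fx$cohort$bags[[2]])
  gate <- gating_table(median(bag$theta), c("e_sharp", "e_blur"))
  pred <- run_moe_simple(bag, fx$experts, gate)
  X <- do.call(rbind, lapply(bag$tiles, extract_features))
  r <- route_tiles(bag$theta, gate)
  probs <- numeric(length(bag$tiles))
  for (k in 1:2) {
    sel <- r$assignments == k
    if (any(sel))
      probs[sel] <- sharpgate:::predict_expert_features(fx$experts[[k]],
                                                        X[sel, , drop = FALSE])
  }
  expect_equal(pred$p_final, aggregate_75th(probs))
})
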