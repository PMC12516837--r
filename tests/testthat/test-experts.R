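test_that("feature extractor matches the pure-R reference and its contracts", {
  set.seed(41)
  cfg <- synthetic_config(n_patients = 2, tiles_per_slide = 1, tile_size = 48)
  for (rep in 1:4) {
    tl <- generate_tile(rep %% 2, cfg)
    expect_equal(extract_features(tl), extract_features_ref(tl),
                 tolerance = 1e-8)
  }

  # constant tile: all texture components zero, finite everywhere
  f0 <- extract_features(matrix(120, 48, 48))
  expect_true(all(is.finite(f0)))
  expect_equal(unname(f0[c("sd", "lv_s0", "lv_s1", "lv_s2", "lv_s4",
                           "grad_s1", "grad_s2", "blob_s1", "blob_s2",
                           "coarse_energy")]), rep(0, 10))

  # determinism and blur-sensitivity
  tl <- generate_tile(1, cfg, seed = 9)
  expect_identical(extract_features(tl), extract_features(tl))
  fb <- extract_features(apply_blur(tl, 4))
  fs <- extract_features(tl)
  expect_lt(fb["lv_s0"], fs["lv_s0"])
  expect_lt(fb["grad_s1"], fs["grad_s1"])
})

test_that("tile expert training is seeded, deterministic and learns sharp data", {
  co <- tiny_cohort(n_patients = 14, tiles = 6, size = 64, seed = 19)
  e1 <- train_tile_expert(co$bags, co$labels, sigma = 0,
                          config = list(epochs = 150), seed = 7)
  e2 <- train_tile_expert(co$bags, co$labels, sigma = 0,
                          config = list(epochs = 150), seed = 7)
  expect_identical(e1, e2)
  expect_false(identical(e1$w,
                         train_tile_expert(co$bags, co$labels, 0,
                                           config = list(epochs = 150),
                                           seed = 8)$w))

  # single-class data refused
  one <- which(co$labels == 1)
  expect_error(train_tile_expert(co$bags[one], co$labels[one], 0), "single class")

  # in-sample slide-level separation on sharp tiles should be strong
  sc <- vapply(co$bags, function(b)
    aggregate_75th(predict_tile(e1, b$tiles)), numeric(1))
  expect_gte(auc(co$labels, sc), 0.85)
})

test_that("raw logistic output honours the sigmoid contract; batch == per-tile", {
  co <- tiny_cohort(n_patients = 8, tiles = 3, size = 48, seed = 23)
  ex <- train_tile_expert(co$bags, co$labels, sigma = 0,
                          config = list(epochs = 40), seed = 1)
  # zero logit -> probability 1/2
  zero <- ex
  zero$w[] <- 0; zero$b <- 0
  expect_equal(predict_tile(zero, co$bags[[1]]$tiles[[1]], calibrated = FALSE),
               0.5)

  tiles <- co$bags[[2]]$tiles
  batch <- predict_tile(ex, tiles)
  each <- vapply(tiles, function(t) predict_tile(ex, t), numeric(1))
  expect_equal(batch, each)
  expect_true(all(batch >= 0 & batch <= 1))

  # monotone in a positively weighted feature, holding others fixed
  X <- extract_features(tiles[[1]])
  j <- which.max(ex$w)
  lo <- hi <- X
  hi[j] <- hi[j] + ex$s[j]
  expect_gt(sharpgate:::predict_expert_features(ex, hi, calibrated = FALSE),
            sharpgate:::predict_expert_features(ex, lo, calibrated = FALSE))

  expect_error(predict_tile(structure(list(), class = "attention_expert"),
                            tiles[[1]]), "tile_classifier")
})

test_that("expert trained at high blur beats the baseline on matching blur", {
  co <- tiny_cohort(n_patients = 24, tiles = 8, size = 64, seed = 29,
                    density_jitter_sd = 0.7)
  sp <- make_cv_splits(co$patient_ids, co$labels, k = 2, seed = 29)[[1]]
  itr <- match(sp$train, co$patient_ids)
  iva <- match(sp$validation, co$patient_ids)
  base <- train_tile_expert(co$bags[itr], co$labels[itr], 0, seed = 1)
  blur5 <- train_tile_expert(co$bags[itr], co$labels[itr], 5, seed = 1)
  ft <- sharpgate:::bag_features(co$bags[iva], co$labels[iva], sigma = 5)
  auc_of <- function(ex) {
    sc <- as.numeric(tapply(sharpgate:::predict_expert_features(ex, ft$X),
                            ft$bag_index, aggregate_75th))
    auc(co$labels[iva], sc)
  }
  expect_gt(auc_of(blur5), auc_of(base))
})

test_that("gated attention head: analytic gradients match numerical ones", {
  set.seed(51)
  d <- 5; h <- 3; n <- 7
  H <- matrix(rnorm(n * d), n, d)
  par <- list(V = matrix(rnorm(h * d, 0, 0.3), h, d),
              U = matrix(rnorm(h * d, 0, 0.3), h, d),
              wa = rnorm(h, 0, 0.3), wc = rnorm(d, 0, 0.3), bc = 0.1)
  y <- 1
  loss_fn <- function(p) {
    fw <- sharpgate:::attention_forward(p, H)
    -(y * log(fw$p) + (1 - y) * log(1 - fw$p))
  }
  fw <- sharpgate:::attention_forward(par, H)
  g <- sharpgate:::attention_backward(par, H, fw, fw$p - y)
  eps <- 1e-6
  for (nm in names(g)) {
    num <- par[[nm]]
    for (i in seq_along(num)) {
      up <- par; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- par; dn[[nm]][i] <- dn[[nm]][i] - eps
      num[i] <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
    }
    expect_equal(as.vector(g[[nm]]), as.vector(num), tolerance = 1e-5)
  }
})

test_that("attention pooling: softmax, symmetry, permutation and duplication", {
  co <- tiny_cohort(n_patients = 10, tiles = 5, size = 48, seed = 37)
  ex <- train_attention_expert(co$bags, co$labels, sigma = 0,
                               config = list(epochs = 60), seed = 3)
  F <- do.call(rbind, lapply(co$bags[[1]]$tiles, extract_features))

  a <- sharpgate:::attention_weights(ex, F)
  expect_lt(abs(sum(a) - 1), 1e-9)

  # identical tiles share the attention mass equally
  Fsame <- F[rep(1, 6), ]
  expect_equal(sharpgate:::attention_weights(ex, Fsame), rep(1 / 6, 6))

  p <- predict_bag_attention(ex, F)
  expect_lt(abs(p - predict_bag_attention(ex, F[sample(nrow(F)), ])), 1e-12)
  expect_lt(abs(predict_bag_attention(ex, F, calibrated = FALSE) -
                predict_bag_attention(ex, F[rep(seq_len(nrow(F)), 2), ],
                                      calibrated = FALSE)), 1e-9)

  # single-tile bag and error contracts
  expect_identical(predict_bag_attention(ex, F[1, , drop = FALSE]),
                   predict_bag_attention(ex, F[c(1, 1), ]))
  expect_error(predict_bag_attention(ex, F[0, , drop = FALSE]), "empty")
  expect_error(predict_bag_attention(structure(list(), class = "tile_expert"),
                                     F), "attention_bag")

  # training determinism
  ex2 <- train_attention_expert(co$bags, co$labels, sigma = 0,
                                config = list(epochs = 60), seed = 3)
  expect_identical(ex$par, ex2$par)
})

test_that("attention pooling degrades less than percentile pooling on heavy mixed blur", {
  co <- generate_cohort(synthetic_config(n_patients = 60, tiles_per_slide = 15,
                                         seed = 83))
  sp <- make_cv_splits(co$patient_ids, co$labels, k = 2, seed = 83)[[1]]
  itr <- match(sp$train, co$patient_ids)
  iva <- match(sp$validation, co$patient_ids)
  tile_base <- train_tile_expert(co$bags[itr], co$labels[itr], 0, seed = 83)
  attn_base <- train_attention_expert(co$bags[itr], co$labels[itr], 0,
                                      seed = 83)
  set.seed(83)
  scen <- blur_scenario(11)   # 10% low / 10% moderate / 80% high blur
  p_tile <- p_attn <- numeric(length(iva))
  for (b in seq_along(iva)) {
    bg <- assign_scenario_blur(co$bags[[iva[b]]], scen)$bag
    F <- do.call(rbind, lapply(bg$tiles, extract_features))
    p_tile[b] <- aggregate_75th(sharpgate:::predict_expert_features(tile_base, F))
    p_attn[b] <- predict_bag_attention(attn_base, F)
  }
  expect_gt(auc(co$labels[iva], p_attn), auc(co$labels[iva], p_tile))
})
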