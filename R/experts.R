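#' Handcrafted tile feature vector
#'
#' A fixed 12-dimensional, deterministic descriptor standing in for a deep
#' feature extractor.  Blur-sensitive components (LV at several smoothing
#' scales, gradient energy, fine blob counts) strictly decrease under added
#' blur on textured tiles, while mean intensity, coarse-scale energy and
#' histogram entropy survive blur -- so experts trained at different blur
#' levels can specialise.
#'
#' Components: intensity mean and SD; LV of the tile smoothed at sigma
#' `{0, 1, 2, 4}`; mean squared gradient magnitude at smoothing scales
#' `{1, 2}`; dark-blob counts (strict local minima deeper than
#' `blob_depths` below the median) at smoothing scales `{1, 2}`; SD of the
#' sigma-4-smoothed tile (coarse energy); entropy of the 32-bin intensity
#' histogram.  All
#' energy-like components (everything except the mean and the entropy) are
#' reported as `log1p` of the raw statistic.
#'
#' @param tile numeric matrix or 3-channel array.
#' @param blob_depths detection depths (intensity units) for the fine and
#'   mid-scale blob counters (defaults 45 and 25): a minimum must sit this
#'   far below the tile median to count, so fine-scale counts fade as blur
#'   erodes blob contrast.
#' @return named numeric vector of length 12.
#' @export
extract_features <- function(tile, blob_depths = c(45, 25)) {
  lum <- to_luminance(tile)
  f <- tile_features_cpp(lum, gaussian_kernel_1d(1), gaussian_kernel_1d(2),
                         gaussian_kernel_1d(4), blob_depths[1], blob_depths[2])
  # energy-like components live on a log scale: multiplicative blur-induced
  # collapse becomes an additive shift, keeping cross-blur behaviour smooth
  en <- c("sd", "lv_s0", "lv_s1", "lv_s2", "lv_s4", "grad_s1", "grad_s2",
          "blob_s1", "blob_s2", "coarse_energy")
  f[en] <- log1p(f[en])
  f
}

# Blur every tile of every bag at `sigma`, then extract features.
# Returns list(X = feature matrix, bag_index, labels per tile, theta per tile)
bag_features <- function(bags, labels, sigma = 0, with_theta = FALSE) {
  rows <- list(); bi <- integer(0); yl <- integer(0); th <- numeric(0)
  for (b in seq_along(bags)) {
    for (tl in bags[[b]]$tiles) {
      tb <- if (sigma > 0) apply_blur(tl, sigma) else tl
      rows[[length(rows) + 1L]] <- extract_features(tb)
      if (with_theta) th <- c(th, laplacian_variance(tb))
    }
    n <- length(bags[[b]]$tiles)
    bi <- c(bi, rep(b, n))
    yl <- c(yl, rep(labels[b], n))
  }
  list(X = do.call(rbind, rows), bag_index = bi, labels = yl,
       theta = if (with_theta) th else NULL)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Quantile (ECDF) calibration: map a score onto the fraction of the expert's
# own training scores lying below it, interpolating linearly between order
# statistics.  Puts every expert's output on a common [0, 1] scale, the way
# same-architecture deep experts share a confidence profile; essential when
# tile scores from different experts are pooled into one percentile.
# Scores outside the training range decay exponentially within the bottom /
# top half-rank, so extreme inputs saturate (like a softmax head) while
# their relative order is preserved.
ecdf_calibrate <- function(x, sorted_train) {
  n <- length(sorted_train)
  lo <- sorted_train[1L]; hi <- sorted_train[n]
  tail_scale <- max((hi - lo) / 4, 1e-8)
  i <- findInterval(x, sorted_train)
  p <- numeric(length(x))
  inside <- i >= 1L & i < n
  if (any(inside)) {
    a <- sorted_train[i[inside]]
    b <- sorted_train[i[inside] + 1L]
    gap <- b - a
    frac <- ifelse(gap > 0, (x[inside] - a) / gap, 0)
    p[inside] <- (i[inside] - 0.5 + frac) / n
  }
  below <- i < 1L
  if (any(below)) p[below] <- 0.5 / n * exp(-(lo - x[below]) / tail_scale)
  above <- i >= n
  if (any(above)) p[above] <- 1 - 0.5 / n * exp(-(x[above] - hi) / tail_scale)
  pmin(pmax(p, 0), 1)
}

# z-scores clamped: far-out-of-distribution inputs (e.g. sharp tiles scored
# by a heavy-blur expert) saturate instead of exploding.  Linear tile
# experts use +-10; the attention head uses +-3, emulating the bounded
# activation range of a neural feature extractor, which keeps mixed-quality
# bags within the head's calibrated logit range (the graceful degradation
# attention pooling is known for).
standardise <- function(X, mu, s, clamp = 10) {
  Z <- sweep(sweep(X, 2, mu), 2, s, "/")
  pmin(pmax(Z, -clamp), clamp)
}

#' Train a blur-specialised tile-level expert
#'
#' Every training tile is blurred at exactly `sigma`, features are
#' extracted, tiles inherit their slide's label, and a logistic-loss linear
#' classifier on standardised features is fitted by full-batch gradient
#' descent with a fixed epoch count, fixed learning rate and seeded
#' initialisation (determinism over schedule sophistication).
#'
#' @param train_bags list of `slide_bag`s.
#' @param labels binary slide labels, one per bag.
#' @param sigma training blur level in `[0, 10]` (0 = baseline expert).
#' @param config list of training settings: `epochs` (default 300) and
#'   `lr` (default 0.5).
#' @param seed integer seed for the parameter initialisation.
#' @param expert_id identifier (default `"expert_<sigma>"`).
#' @return object of class `tile_expert`.
#' @export
train_tile_expert <- function(train_bags, labels, sigma, config = list(),
                              seed = 1L, expert_id = NULL) {
  stopifnot(length(train_bags) == length(labels), sigma >= 0, sigma <= 10)
  if (length(unique(labels)) < 2L)
    stop("training data contains a single class; need both classes")
  epochs <- config$epochs %||% 300L
  lr <- config$lr %||% 0.5
  ft <- bag_features(train_bags, labels, sigma)
  X <- ft$X; y <- ft$labels
  mu <- colMeans(X)
  s <- apply(X, 2, sd); s[s == 0 | !is.finite(s)] <- 1
  Z <- standardise(X, mu, s)
  d <- ncol(Z); n <- nrow(Z)
  w <- with_seed(seed, rnorm(d, 0, 0.01)); b <- 0
  for (e in seq_len(epochs)) {
    p <- sigmoid(drop(Z %*% w) + b)
    g <- p - y
    w <- w - lr * drop(crossprod(Z, g)) / n
    b <- b - lr * mean(g)
  }
  logits <- drop(Z %*% w) + b
  p <- sigmoid(logits)
  loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  structure(list(
    spec = list(expert_id = expert_id %||% sprintf("expert_%g", sigma),
                train_sigma = sigma, kind = "tile_classifier",
                feature_dim = d, seed = seed),
    mu = mu, s = s, w = setNames(w, colnames(X)), b = b,
    train_logits = sort(logits),
    meta = list(epochs = epochs, lr = lr, final_loss = loss, n_tiles = n)),
    class = "tile_expert")
}

#' @export
print.tile_expert <- function(x, ...) {
  cat(sprintf("tile_expert '%s': train sigma %g, %d features, %d tiles, final loss %.4f\n",
              x$spec$expert_id, x$spec$train_sigma, x$spec$feature_dim,
              x$meta$n_tiles, x$meta$final_loss))
  invisible(x)
}

# class-1 score from a precomputed feature matrix; `calibrated` maps the
# logit through the expert's training-score ECDF (the scale shared across an
# ensemble), FALSE gives the raw logistic probability
predict_expert_features <- function(expert, X, calibrated = TRUE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1,
                                   dimnames = list(NULL, names(X)))
  logit <- drop(standardise(X, expert$mu, expert$s) %*% expert$w) + expert$b
  if (calibrated) ecdf_calibrate(logit, expert$train_logits)
  else sigmoid(logit)
}

#' Predict a tile's class-1 probability with a tile-level expert
#'
#' With `calibrated = TRUE` (the default, and what the MoE pooling uses)
#' the logistic score is mapped through the expert's training-score ECDF so
#' that every expert in an ensemble shares one output scale; with
#' `calibrated = FALSE` the raw logistic probability `sigmoid(w'x + b)` is
#' returned.
#'
#' @param expert a `tile_expert`.
#' @param tile a tile matrix/array, or a list of tiles.
#' @param calibrated logical, see above.
#' @return probability (or vector of probabilities) in `[0, 1]`.
#' @export
predict_tile <- function(expert, tile, calibrated = TRUE) {
  if (!inherits(expert, "tile_expert"))
    stop("predict_tile requires a tile_classifier expert, got ",
         class(expert)[1])
  tiles <- if (is.list(tile)) tile else list(tile)
  X <- do.call(rbind, lapply(tiles, extract_features))
  p <- predict_expert_features(expert, X, calibrated = calibrated)
  if (is.list(tile)) p else p[[1L]]
}

# --- gated-attention multiple-instance head ------------------------------

attention_forward <- function(par, H) {
  At <- tanh(H %*% t(par$V))            # n x h
  As <- sigmoid(H %*% t(par$U))         # n x h
  M <- At * As
  sc <- drop(M %*% par$wa)              # n
  sc <- sc - max(sc)
  a <- exp(sc) / sum(exp(sc))           # softmax attention over the bag
  z <- drop(crossprod(H, a))            # d
  logit <- sum(par$wc * z) + par$bc
  list(At = At, As = As, M = M, a = a, z = z, logit = logit,
       p = sigmoid(logit))
}

attention_backward <- function(par, H, fw, dlogit) {
  g <- list(wc = dlogit * fw$z, bc = dlogit,
            V = matrix(0, nrow(par$V), ncol(par$V)),
            U = matrix(0, nrow(par$U), ncol(par$U)),
            wa = numeric(length(par$wa)))
  dz <- dlogit * par$wc                                   # d
  da <- drop(H %*% dz)                                    # n
  ds <- fw$a * (da - sum(fw$a * da))                      # softmax backprop
  g$wa <- drop(crossprod(fw$M, ds))
  dM <- outer(ds, par$wa)                                 # n x h
  dAt <- dM * fw$As
  dAs <- dM * fw$At
  g$V <- crossprod(dAt * (1 - fw$At^2), H)                # h x d
  g$U <- crossprod(dAs * fw$As * (1 - fw$As), H)
  g
}

#' Train a blur-specialised gated-attention bag expert
#'
#' A simplified attention-based multiple-instance head with bag-level
#' supervision only: per-tile attention scores come from tanh and sigmoid
#' branches of hidden width `hidden`, are softmax-normalised over the bag,
#' the bag embedding is the attention-weighted feature sum, and a linear
#' classifier maps it to a slide probability.  Training tiles are blurred at
#' `sigma` before feature extraction; optimisation is full-batch gradient
#' descent on the cross-entropy with fixed epochs and seeded initialisation.
#'
#' @param train_bags list of `slide_bag`s (or list of per-bag feature
#'   matrices when `features = TRUE`).
#' @param labels binary slide labels.
#' @param sigma training blur level.
#' @param config list: `hidden` (default 8), `epochs` (default 400),
#'   `lr` (default 0.05).
#' @param seed integer seed.
#' @param expert_id identifier.
#' @param features logical; `train_bags` already holds feature matrices.
#' @return object of class `attention_expert`.
#' @export
train_attention_expert <- function(train_bags, labels, sigma, config = list(),
                                   seed = 1L, expert_id = NULL,
                                   features = FALSE) {
  stopifnot(length(train_bags) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("training data contains a single class; need both classes")
  hidden <- config$hidden %||% 8L
  epochs <- config$epochs %||% 400L
  lr <- config$lr %||% 0.05
  if (features) {
    Hs <- train_bags
  } else {
    Hs <- lapply(train_bags, function(b) {
      if (length(b$tiles) == 0L) stop("empty bag in training set: ", b$slide_id)
      do.call(rbind, lapply(b$tiles, function(tl)
        extract_features(if (sigma > 0) apply_blur(tl, sigma) else tl)))
    })
  }
  Xall <- do.call(rbind, Hs)
  mu <- colMeans(Xall)
  s <- apply(Xall, 2, sd); s[s == 0 | !is.finite(s)] <- 1
  Hs <- lapply(Hs, standardise, mu = mu, s = s, clamp = 3)
  d <- ncol(Xall)
  par <- with_seed(seed, list(
    V = matrix(rnorm(hidden * d, 0, 0.1), hidden, d),
    U = matrix(rnorm(hidden * d, 0, 0.1), hidden, d),
    wa = rnorm(hidden, 0, 0.1),
    wc = rnorm(d, 0, 0.1), bc = 0))
  nb <- length(Hs)
  for (e in seq_len(epochs)) {
    acc <- list(V = par$V * 0, U = par$U * 0, wa = par$wa * 0,
                wc = par$wc * 0, bc = 0)
    for (b in seq_len(nb)) {
      fw <- attention_forward(par, Hs[[b]])
      g <- attention_backward(par, Hs[[b]], fw, fw$p - labels[b])
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g[[nm]]
    }
    for (nm in names(acc)) par[[nm]] <- par[[nm]] - lr * acc[[nm]] / nb
  }
  loss <- 0
  train_logits <- numeric(nb)
  for (b in seq_len(nb)) {
    fw <- attention_forward(par, Hs[[b]])
    train_logits[b] <- fw$logit
    loss <- loss - (labels[b] * log(pmax(fw$p, 1e-12)) +
                    (1 - labels[b]) * log(pmax(1 - fw$p, 1e-12))) / nb
  }
  structure(list(
    spec = list(expert_id = expert_id %||% sprintf("attn_%g", sigma),
                train_sigma = sigma, kind = "attention_bag",
                feature_dim = d, hidden = hidden, seed = seed),
    mu = mu, s = s, par = par, train_logits = sort(train_logits),
    meta = list(epochs = epochs, lr = lr, final_loss = loss, n_bags = nb)),
    class = "attention_expert")
}

#' @export
print.attention_expert <- function(x, ...) {
  cat(sprintf("attention_expert '%s': train sigma %g, hidden %d, %d bags, final loss %.4f\n",
              x$spec$expert_id, x$spec$train_sigma, x$spec$hidden,
              x$meta$n_bags, x$meta$final_loss))
  invisible(x)
}

#' Slide-level probability from a gated-attention expert
#'
#' @param expert an `attention_expert`.
#' @param features per-tile feature matrix for the bag (rows = tiles), or a
#'   `slide_bag` whose tiles are featurised on the fly.
#' @param calibrated logical: map the bag logit through the expert's
#'   training-bag score ECDF (common ensemble scale, used by the MoE
#'   combination); `FALSE` gives the raw logistic probability.
#' @return probability in `[0, 1]`, invariant to tile order.
#' @export
predict_bag_attention <- function(expert, features, calibrated = TRUE) {
  if (!inherits(expert, "attention_expert"))
    stop("predict_bag_attention requires an attention_bag expert, got ",
         class(expert)[1])
  if (inherits(features, "slide_bag"))
    features <- do.call(rbind, lapply(features$tiles, extract_features))
  if (is.null(dim(features)) || nrow(features) == 0L)
    stop("empty feature bag: attention experts must not receive zero tiles")
  H <- standardise(features, expert$mu, expert$s, clamp = 3)
  fw <- attention_forward(expert$par, H)
  if (calibrated) ecdf_calibrate(fw$logit, expert$train_logits) else fw$p
}

# attention weights over a bag (diagnostics / tests)
attention_weights <- function(expert, features) {
  H <- standardise(features, expert$mu, expert$s, clamp = 3)
  attention_forward(expert$par, H)$a
}

`%||%` <- function(a, b) if (is.null(a)) b else a
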