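#' Build a 2-D Gaussian blur kernel
#'
#' The kernel weights follow \eqn{G(x, y) = \frac{1}{2\pi\sigma^2}
#' e^{-(x^2 + y^2) / 2\sigma^2}}, evaluated on the integer grid
#' \eqn{x, y \in [-r, r]} with truncation radius \eqn{r = \lceil 4\sigma
#' \rceil} (the truncated mass is below 1e-4).  With `normalise = TRUE`
#' (the default) the weights are rescaled to sum to exactly 1 so that
#' convolution preserves constant images; `normalise = FALSE` returns the raw
#' Gaussian density values.
#'
#' @param sigma non-negative standard deviation of the Gaussian, in pixels.
#'   `sigma = 0` yields the identity kernel (radius 0, single weight 1).
#' @param normalise logical; rescale weights to sum to 1.
#' @return An object of class `gaussian_kernel`: a list with elements
#'   `sigma`, `radius` and the `(2r+1) x (2r+1)` `weights` matrix.
#' @examples
#' k <- gaussian_kernel(1)
#' sum(k$weights)  # 1
#' @export
gaussian_kernel <- function(sigma, normalise = TRUE) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number, got: ",
         deparse(substitute(sigma)), " = ", format(sigma))
  if (sigma == 0) {
    w <- matrix(1, 1L, 1L)
    return(structure(list(sigma = 0, radius = 0L, weights = w),
                     class = "gaussian_kernel"))
  }
  r <- as.integer(ceiling(4 * sigma))
  x <- -r:r
  g1 <- exp(-x^2 / (2 * sigma^2))
  w <- outer(g1, g1) / (2 * pi * sigma^2)
  if (normalise) w <- w / sum(w)
  structure(list(sigma = sigma, radius = r, weights = w),
            class = "gaussian_kernel")
}

#' @export
print.gaussian_kernel <- function(x, ...) {
  cat(sprintf("Gaussian kernel: sigma = %g, radius = %d (%dx%d weights, sum %.6f)\n",
              x$sigma, x$radius, 2L * x$radius + 1L, 2L * x$radius + 1L,
              sum(x$weights)))
  invisible(x)
}

# normalised 1-D Gaussian kernel; the 2-D kernel is its outer product
gaussian_kernel_1d <- function(sigma) {
  r <- as.integer(ceiling(4 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Apply Gaussian blur to a tile
#'
#' Convolves the tile with a normalised Gaussian kernel, \eqn{I' = I * G},
#' using reflect-101 border handling (mirror about the edge pixel, which
#' avoids edge darkening).  The convolution is run separably in floating
#' point; the output has the same shape and stays on the input's intensity
#' scale.  Multi-channel tiles (`tile_size x tile_size x 3` arrays) are
#' blurred channel-wise.  `sigma = 0` returns the input unchanged.
#'
#' @param tile numeric matrix (grayscale) or 3-channel array, 0--255 scale.
#' @param sigma non-negative blur standard deviation in pixels.
#' @return blurred tile of the same shape (floating point; rounding back to
#'   8-bit happens only when tiles are written to disk).
#' @export
apply_blur <- function(tile, sigma) {
  if (is.null(tile) || length(tile) == 0L) stop("empty tile")
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number")
  if (sigma == 0) return(tile)
  k <- gaussian_kernel_1d(sigma)
  if (is.matrix(tile)) {
    out <- sep_convolve_cpp(tile, k)
    attributes(out) <- attributes(tile)
    return(out)
  }
  if (is.array(tile) && length(dim(tile)) == 3L) {
    out <- tile
    for (ch in seq_len(dim(tile)[3L])) out[, , ch] <- sep_convolve_cpp(tile[, , ch], k)
    return(out)
  }
  stop("'tile' must be a numeric matrix or a 3-channel array")
}

#' Mixed-blur scenario definitions
#'
#' Returns the table of 12 benchmark scenarios that assign varying
#' proportions of tiles within a slide to three empirically defined blur
#' groups: low (\eqn{\sigma \sim U(0, 1.5)}), moderate
#' (\eqn{\sigma \sim U(1.5, 5)}) and high (\eqn{\sigma \sim U(5, 10)}).
#' Scenario 1 is all-low, 2 all-moderate, 3 all-high; 4--12 mix the groups.
#'
#' @return data.frame with columns `scenario`, `p_low`, `p_moderate`,
#'   `p_high` (percentages summing to 100 per row).
#' @export
blur_scenarios <- function() {
  data.frame(
    scenario   = 1:12,
    p_low      = c(100, 0, 0, 50, 25, 25, 50, 0, 80, 10, 10, 80),
    p_moderate = c(0, 100, 0, 25, 50, 25, 50, 50, 10, 80, 10, 15),
    p_high     = c(0, 0, 100, 25, 25, 50, 0, 50, 10, 10, 80, 5)
  )
}

#' Construct a blur scenario
#'
#' @param scenario_id integer 1--12 selecting a row of [blur_scenarios()], or
#'   `NULL` when explicit percentages are given.
#' @param p_low,p_moderate,p_high percentages of tiles assigned to each blur
#'   group; must sum to 100.
#' @param group_ranges 3x2 matrix of sigma intervals for the low, moderate
#'   and high groups (defaults `[0,1.5]`, `(1.5,5]`, `[5,10]`).
#' @return object of class `blur_scenario`.
#' @export
blur_scenario <- function(scenario_id = NULL, p_low = NULL, p_moderate = NULL,
                          p_high = NULL,
                          group_ranges = rbind(low = c(0, 1.5),
                                               moderate = c(1.5, 5),
                                               high = c(5, 10))) {
  if (!is.null(scenario_id)) {
    tab <- blur_scenarios()
    if (!scenario_id %in% tab$scenario)
      stop("scenario id must be in 1..12, got ", scenario_id)
    row <- tab[tab$scenario == scenario_id, ]
    p_low <- row$p_low; p_moderate <- row$p_moderate; p_high <- row$p_high
  }
  p <- c(low = p_low, moderate = p_moderate, high = p_high)
  if (any(is.na(p)) || any(p < 0) || abs(sum(p) - 100) > 1e-9)
    stop("group percentages must be non-negative and sum to 100, got ",
         paste(p, collapse = "/"))
  stopifnot(nrow(group_ranges) == 3L, all(diff(as.vector(t(group_ranges))) >= 0))
  structure(list(scenario_id = scenario_id, p = p, group_ranges = group_ranges),
            class = "blur_scenario")
}

#' Apply a mixed-blur scenario to a slide bag
#'
#' Each tile is independently assigned to the low / moderate / high blur
#' group with the scenario's probabilities (or, with `exact = TRUE`, a
#' shuffled exact-proportion partition), a group blur \eqn{g_i \sim U(a, b)}
#' is drawn from the group's sigma range, and the pristine source tile is
#' blurred once at the final level \eqn{\hat g = g + g_i}, where \eqn{g} is
#' the tile's base sigma (0 for pristine synthetic tiles).
#'
#' Whether combining a base blur with an added one means adding sigmas or
#' convolving sequentially is ambiguous when `g > 0` (the two coincide for
#' pristine tiles): `combine = "additive"` applies one convolution at
#' `g + g_i` (the default and the recorded reading of the algorithm);
#' `combine = "quadrature"` uses the Gaussian composition
#' \eqn{\sigma_{eff} = \sqrt{g^2 + g_i^2}}, equivalent to blurring the
#' already-blurred tile again at `g_i`.
#'
#' Uses the current RNG stream; seed the caller for reproducibility.
#'
#' @param bag a `slide_bag`.
#' @param scenario a `blur_scenario` (or an integer scenario id).
#' @param exact logical; use an exact-proportion partition instead of
#'   independent multinomial draws.
#' @param combine `"additive"` or `"quadrature"`, see above.
#' @return list with elements `bag` (the blurred bag) and `records`, a
#'   data.frame (`tile_id`, `g`, `g_i`, `sigma_hat`, `group`) for audit;
#'   `sigma_hat` is the effective sigma actually applied.
#' @export
assign_scenario_blur <- function(bag, scenario, exact = FALSE,
                                 combine = c("additive", "quadrature")) {
  combine <- match.arg(combine)
  if (is.numeric(scenario)) scenario <- blur_scenario(scenario)
  stopifnot(inherits(scenario, "blur_scenario"), inherits(bag, "slide_bag"))
  n <- length(bag$tiles)
  groups <- c("low", "moderate", "high")
  if (exact) {
    counts <- floor(scenario$p / 100 * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      frac <- scenario$p / 100 * n - counts
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[add] <- counts[add] + 1L
    }
    gl <- sample(rep(groups, counts))
  } else {
    gl <- sample(groups, n, replace = TRUE, prob = scenario$p / 100)
  }
  rng <- scenario$group_ranges[gl, , drop = FALSE]
  g_i <- runif(n, rng[, 1L], rng[, 2L])
  g <- bag$base_sigma
  sigma_hat <- if (combine == "additive") g + g_i else sqrt(g^2 + g_i^2)
  out <- bag
  out$tiles <- lapply(seq_len(n), function(i) apply_blur(bag$tiles[[i]], sigma_hat[i]))
  out$base_sigma <- sigma_hat
  out$theta <- NULL
  list(bag = out,
       records = data.frame(tile_id = bag$tile_ids, g = g, g_i = g_i,
                            sigma_hat = sigma_hat, group = gl,
                            stringsAsFactors = FALSE))
}
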