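#' Synthetic environmental stacks with controlled collinearity
#'
#' Generates smooth, standardized environmental fields so the whole SDM
#' pipeline can be exercised against a known truth. Each layer is a mix of a
#' random linear lon/lat gradient and Gaussian-smoothed white noise, z-scored
#' to mean 0, sd 1. Collinearity between named layer pairs is induced by
#' mixing: the target layer is rebuilt as
#' `r * source + sqrt(1 - r^2) * residual`, where the residual is the target
#' field empirically orthogonalised against the source, so the realised
#' Pearson correlation equals the requested `r` up to floating point.
#'
#' @param spec A [grid_spec()].
#' @param n_layers Number of layers (named `env01`, `env02`, ...).
#' @param collinear_pairs A list of `list(source =, target =, r =)` entries
#'   (or a data frame with those columns) requesting a correlation of `r`
#'   between two generated layers. `|r| <= 1`; names must reference layers.
#' @param seed Integer seed; identical seeds give bit-identical stacks.
#' @param smooth_sigma Gaussian smoothing bandwidth in cells. Default 3.
#' @param gradient_weight Mixing weight of the lon/lat gradient relative to
#'   the smoothed-noise component, both standardized first. Default 0.5.
#' @return An [env_stack()] of standardized layers.
#' @examples
#' stack <- make_env_stack(grid_spec(20, 30), n_layers = 5, seed = 1)
#' sapply(stack$layers, sd)
#' @export
make_env_stack <- function(spec, n_layers, collinear_pairs = list(), seed,
                           smooth_sigma = 3, gradient_weight = 0.5) {
  stopifnot(inherits(spec, "grid_spec"), n_layers >= 1)
  pairs <- normalize_pairs(collinear_pairs)
  layer_names <- sprintf("env%02d", seq_len(n_layers))
  bad <- setdiff(c(pairs$source, pairs$target), layer_names)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "collinear pair references missing layer(s): ",
      paste(unique(bad), collapse = ", ")
    ))
  }
  if (any(abs(pairs$r) > 1)) rlang::abort("requested |r| must be <= 1")

  layers <- withr::with_seed(seed, {
    out <- lapply(layer_names, function(nm) {
      smooth_field(spec, smooth_sigma, gradient_weight)
    })
    names(out) <- layer_names
    out
  })
  for (k in seq_len(nrow(pairs))) {
    src <- layers[[pairs$source[k]]]
    tgt <- layers[[pairs$target[k]]]
    r <- pairs$r[k]
    resid <- standardize(tgt - mean(src * tgt) / mean(src * src) * src)
    layers[[pairs$target[k]]] <-
      standardize(r * src + sqrt(1 - r^2) * resid)
  }
  env_stack(layers, spec)
}

normalize_pairs <- function(collinear_pairs) {
  if (is.data.frame(collinear_pairs)) {
    stopifnot(all(c("source", "target", "r") %in% names(collinear_pairs)))
    return(tibble::as_tibble(collinear_pairs))
  }
  if (length(collinear_pairs) == 0) {
    return(tibble::tibble(source = character(), target = character(),
                          r = numeric()))
  }
  purrr::map_dfr(collinear_pairs, function(p) {
    p <- as.list(p)
    if (is.null(names(p)) || !all(c("source", "target", "r") %in% names(p))) {
      names(p) <- c("source", "target", "r")
    }
    tibble::tibble(source = as.character(p$source),
                   target = as.character(p$target), r = as.numeric(p$r))
  })
}

# empirical z-score; population of cells, sample sd
standardize <- function(m) {
  v <- as.vector(m)
  (m - mean(v)) / stats::sd(v)
}

# one standardized field: random-orientation linear gradient + smoothed noise
smooth_field <- function(spec, sigma, gradient_weight) {
  nr <- spec$n_rows
  nc <- spec$n_cols
  theta <- stats::runif(1, 0, 2 * pi)
  u <- if (nr > 1) seq(-1, 1, length.out = nr) else 0
  v <- if (nc > 1) seq(-1, 1, length.out = nc) else 0
  grad <- outer(u, rep(1, nc)) * sin(theta) + outer(rep(1, nr), v) * cos(theta)
  noise <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  g <- if (stats::sd(grad) > 0) standardize(grad) else grad
  z <- standardize(noise)
  standardize(gradient_weight * g + (1 - gradient_weight) * z)
}

# separable Gaussian blur with edge renormalisation (kernel mass rescaled
# where the window is truncated at the border)
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  smooth_1d <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1, i - half)
      hi <- min(n, i + half)
      w <- k[(lo - i + half + 1):(hi - i + half + 1)]
      out[i] <- sum(x[lo:hi] * w) / sum(w)
    }
    out
  }
  m <- apply(m, 2, smooth_1d)
  t(apply(m, 1, smooth_1d))
}

#' A known logistic niche over named layers
#'
#' The synthetic truth every downstream estimate is checked against: the
#' presence probability in a cell with predictor values \eqn{x} is
#' \deqn{p(x) = 1 / (1 + e^{-(\beta_0 + \sum_i \beta_i x_i)})}
#'
#' @param intercept Intercept \eqn{\beta_0} on the log-odds scale.
#' @param coefficients Named numeric vector of slopes; names must be layer
#'   names of the stack the truth is evaluated on.
#' @return An object of class `niche_truth`.
#' @export
niche_truth <- function(intercept, coefficients) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients), !is.null(names(coefficients)),
            all(names(coefficients) != ""))
  structure(list(intercept = intercept, coefficients = coefficients),
            class = "niche_truth")
}

#' Evaluate a niche truth on a stack
#'
#' @param stack An [env_stack()].
#' @param truth A [niche_truth()]; every coefficient name must be a layer.
#' @return Matrix of true presence probabilities in `[0, 1]` (`NA` where any
#'   referenced layer is missing).
#' @export
true_suitability <- function(stack, truth) {
  stopifnot(inherits(stack, "env_stack"), inherits(truth, "niche_truth"))
  missing_layers <- setdiff(names(truth$coefficients), names(stack$layers))
  if (length(missing_layers) > 0) {
    rlang::abort(paste0(
      "niche references missing layer(s): ",
      paste(missing_layers, collapse = ", ")
    ))
  }
  eta <- matrix(truth$intercept, stack$spec$n_rows, stack$spec$n_cols)
  for (nm in names(truth$coefficients)) {
    eta <- eta + truth$coefficients[[nm]] * stack$layers[[nm]]
  }
  stats::plogis(eta)
}

#' Sample presence records from a known niche
#'
#' Emulates opportunistic presence-only records: each cell flips a Bernoulli
#' coin with its true presence probability `p(x)`; if more than `n_target`
#' cells succeed a uniform subsample is kept, if fewer, the shortfall is
#' topped up by weighted sampling (without replacement, weights `p`) among
#' the remaining cells so exactly `n_target` distinct presence cells return.
#' Coordinates are cell centres.
#'
#' @param stack An [env_stack()].
#' @param truth A [niche_truth()].
#' @param n_target Number of presence records wanted; must not exceed the
#'   number of grid cells with `p > 0`.
#' @param seed Integer seed (deterministic draw).
#' @return A tibble of occurrences: `lon`, `lat`, `source` (`"synthetic"`).
#' @export
sample_occurrences <- function(stack, truth, n_target, seed) {
  stopifnot(n_target >= 1)
  p <- true_suitability(stack, truth)
  cc <- cell_centers(stack$spec)
  pv <- p[cbind(cc$row, cc$col)]
  eligible <- which(!is.na(pv) & pv > 0)
  if (length(eligible) == 0) {
    rlang::abort("sampling error: true presence probability is 0 everywhere")
  }
  if (n_target > length(eligible)) {
    rlang::abort(sprintf(
      "sampling error: n_target (%d) exceeds the %d cells with p > 0",
      n_target, length(eligible)
    ))
  }
  keep <- withr::with_seed(seed, {
    hits <- eligible[stats::runif(length(eligible)) < pv[eligible]]
    if (length(hits) > n_target) {
      sort(sample(hits, n_target))
    } else if (length(hits) < n_target) {
      rest <- setdiff(eligible, hits)
      top_up <- rest[sample.int(length(rest), n_target - length(hits),
                                prob = pv[rest])]
      sort(c(hits, top_up))
    } else {
      sort(hits)
    }
  })
  tibble::tibble(lon = cc$lon[keep], lat = cc$lat[keep], source = "synthetic")
}

#' Shift layers additively to mimic a future scenario
#'
#' Produces a "future" stack by adding a constant to each named layer —
#' the synthetic stand-in for warming/precipitation-change scenario layers.
#' Since synthetic layers are standardized, deltas are in sd units.
#'
#' @param stack An [env_stack()].
#' @param deltas Named numeric vector/list: layer name -> additive shift.
#'   Layers not named are returned unchanged.
#' @return An [env_stack()] on the same grid.
#' @export
make_future_stack <- function(stack, deltas) {
  stopifnot(inherits(stack, "env_stack"))
  deltas <- unlist(deltas)
  if (length(deltas) == 0) return(stack)
  bad <- setdiff(names(deltas), names(stack$layers))
  if (length(bad) > 0) {
    rlang::abort(paste0("delta references missing layer(s): ",
                        paste(bad, collapse = ", ")))
  }
  layers <- stack$layers
  for (nm in names(deltas)) layers[[nm]] <- layers[[nm]] + deltas[[nm]]
  env_stack(layers, stack$spec)
}
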