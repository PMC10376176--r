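#' Logistic regression fitted by IRLS
#'
#' The native GLM learner: binomial regression with a logit link fitted by
#' iteratively reweighted least squares. Step-halving guarantees the
#' deviance never increases between iterations. Predictors are centred and
#' scaled internally for numerical stability; coefficients are reported on
#' the original scale. Complete or quasi-complete separation (detected as
#' diverging standardized coefficients or a non-finite step) triggers a
#' refit with a tiny L2 ridge (`1e-6`) so the estimate stays bounded; the
#' fit is then flagged `separation = TRUE`.
#'
#' @param data Data frame with a binary `label` column and predictor
#'   columns, or a predictor matrix if `y` is given.
#' @param y Optional response vector when `data` is a bare matrix.
#' @param predictors Predictor column names; default every non-reserved
#'   column of `data`.
#' @param max_iter Maximum IRLS iterations. Default 100.
#' @param tol Convergence tolerance on the relative deviance change.
#'   Default 1e-8.
#' @return An object of class `sdm_glm`: coefficients, intercept,
#'   `converged`, `separation`, `deviance` (final), `deviance_trace`,
#'   `n_iter`.
#' @examples
#' d <- data.frame(x = rnorm(200))
#' d$label <- rbinom(200, 1, plogis(-1 + 2 * d$x))
#' fit <- fit_glm(d, predictors = "x")
#' coef(fit)
#' @export
fit_glm <- function(data, y = NULL, predictors = NULL, max_iter = 100,
                    tol = 1e-8) {
  if (is.null(y)) {
    stopifnot(is.data.frame(data), "label" %in% names(data))
    y <- data$label
    if (is.null(predictors)) {
      predictors <- setdiff(names(data),
                            c("label", "cell_id", "row", "col", "lon", "lat",
                              "source"))
    }
    x <- as.matrix(data[predictors])
  } else {
    x <- as.matrix(data)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    predictors <- colnames(x)
  }
  if (!all(y %in% c(0, 1))) rlang::abort("label must be 0/1")
  if (all(y == 0) || all(y == 1)) {
    rlang::abort("both classes must be present to fit")
  }
  if (!all(is.finite(x))) rlang::abort("predictors must be finite")

  centers <- colMeans(x)
  scales <- apply(x, 2, stats::sd)
  scales[scales == 0] <- 1
  xs <- sweep(sweep(x, 2, centers), 2, scales, "/")

  fit <- irls_logistic(xs, y, max_iter, tol, ridge = 0)
  if (!fit$ok || max(abs(fit$beta[-1])) > 15) {
    fit <- irls_logistic(xs, y, max_iter, tol, ridge = 1e-6)
    fit$separation <- TRUE
    rlang::warn("separation detected; ridge-stabilized (lambda = 1e-6) fit returned")
  }
  # back-transform to the original predictor scale
  slopes <- fit$beta[-1] / scales
  intercept <- fit$beta[1] - sum(fit$beta[-1] * centers / scales)
  structure(
    list(
      coefficients = stats::setNames(slopes, predictors),
      intercept = intercept,
      predictors = predictors,
      converged = fit$converged,
      separation = isTRUE(fit$separation),
      deviance = fit$deviance,
      deviance_trace = fit$trace,
      n_iter = fit$n_iter,
      n = length(y)
    ),
    class = "sdm_glm"
  )
}

# IRLS with step-halving on the (penalized) deviance; the intercept is
# never penalized.
irls_logistic <- function(x, y, max_iter, tol, ridge = 0) {
  X <- cbind(1, x)
  p <- ncol(X)
  beta <- numeric(p)
  pen <- function(b) ridge * sum(b[-1]^2)
  dev_of <- function(b) {
    eta <- drop(X %*% b)
    -2 * sum(y * stats::plogis(eta, log.p = TRUE) +
               (1 - y) * stats::plogis(-eta, log.p = TRUE))
  }
  obj <- dev_of(beta) + pen(beta)
  trace <- dev_of(beta)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X
    if (ridge > 0) {
      H <- H + diag(c(0, rep(ridge, p - 1)))
    }
    beta_new <- tryCatch(drop(solve(H, XtW %*% z)),
                         error = function(e) rep(NA_real_, p))
    if (anyNA(beta_new) || !all(is.finite(beta_new))) {
      return(list(beta = beta, deviance = dev_of(beta), trace = trace,
                  converged = FALSE, n_iter = iter, ok = FALSE))
    }
    # step-halving: never let the penalized deviance increase
    step <- 1
    obj_new <- dev_of(beta_new) + pen(beta_new)
    while (obj_new > obj + 1e-12 && step > 1e-8) {
      step <- step / 2
      beta_new <- beta + step * (beta_new - beta)
      obj_new <- dev_of(beta_new) + pen(beta_new)
    }
    beta <- beta_new
    trace <- c(trace, dev_of(beta))
    if (abs(obj - obj_new) / (abs(obj_new) + 0.1) < tol) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  list(beta = beta, deviance = dev_of(beta), trace = trace,
       converged = converged, n_iter = iter,
       ok = all(is.finite(beta)))
}

#' @export
coef.sdm_glm <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
predict.sdm_glm <- function(object, newdata, ...) {
  x <- as.matrix(tibble::as_tibble(newdata)[object$predictors])
  stats::plogis(object$intercept + drop(x %*% object$coefficients))
}

#' @export
print.sdm_glm <- function(x, ...) {
  cat(sprintf("<sdm_glm> %d predictor(s), deviance %.3f, %s%s\n",
              length(x$coefficients), x$deviance,
              if (x$converged) "converged" else "NOT converged",
              if (x$separation) " (ridge-stabilized: separation)" else ""))
  print(coef(x))
  invisible(x)
}

#' @rdname fit_glm
#' @param x,object An `sdm_glm` fit.
#' @param ... Unused.
#' @return `tidy()`: tibble of `term`, `estimate`. `glance()`: one-row
#'   tibble with `deviance`, `n_iter`, `converged`, `separation`, `nobs`.
#' @export
tidy.sdm_glm <- function(x, ...) {
  tibble::tibble(term = names(coef(x)), estimate = unname(coef(x)))
}

#' @rdname fit_glm
#' @export
glance.sdm_glm <- function(x, ...) {
  tibble::tibble(deviance = x$deviance, n_iter = x$n_iter,
                 converged = x$converged, separation = x$separation,
                 nobs = x$n)
}

#' Surface range envelope (BIOCLIM-style) learner
#'
#' The classic rectilinear climate envelope: per predictor, the interval
#' between the `quantile` and `1 - quantile` empirical quantiles of the
#' presence values. A cell is predicted suitable (1) only if it lies inside
#' every interval, otherwise 0 — so the "continuous" output is binary, and
#' the learner enters an ensemble through its binary score.
#'
#' @param presences Data frame or matrix of predictor values at presence
#'   sites (pseudo-absences are not used); >= 5 rows.
#' @param predictors Columns to use; default all columns.
#' @param quantile Tail fraction trimmed at each end, in `[0, 0.5)`.
#'   Default 0.025 (the central 95% envelope).
#' @return An object of class `sdm_sre` holding the per-predictor bounds.
#' @export
fit_sre <- function(presences, predictors = NULL, quantile = 0.025) {
  if (quantile < 0 || quantile >= 0.5) {
    rlang::abort("configuration error: quantile must be in [0, 0.5)")
  }
  d <- tibble::as_tibble(presences)
  if (is.null(predictors)) {
    predictors <- setdiff(names(d),
                          c("label", "cell_id", "row", "col", "lon", "lat",
                            "source"))
  }
  x <- as.matrix(d[predictors])
  if (nrow(x) < 5) rlang::abort("at least 5 presence rows required")
  bounds <- apply(x, 2, stats::quantile,
                  probs = c(quantile, 1 - quantile), names = FALSE)
  structure(
    list(
      lower = stats::setNames(bounds[1, ], predictors),
      upper = stats::setNames(bounds[2, ], predictors),
      predictors = predictors,
      quantile = quantile
    ),
    class = "sdm_sre"
  )
}

#' @export
predict.sdm_sre <- function(object, newdata, ...) {
  x <- as.matrix(tibble::as_tibble(newdata)[object$predictors])
  inside <- rep(TRUE, nrow(x))
  for (j in seq_along(object$predictors)) {
    inside <- inside & x[, j] >= object$lower[j] & x[, j] <= object$upper[j]
  }
  out <- as.numeric(inside)
  out[rowSums(is.na(x)) > 0] <- NA_real_
  out
}

#' @export
print.sdm_sre <- function(x, ...) {
  cat(sprintf("<sdm_sre> %.1f%% envelope over %d predictor(s)\n",
              100 * (1 - 2 * x$quantile), length(x$predictors)))
  invisible(x)
}

#' @rdname fit_sre
#' @param x An `sdm_sre` fit.
#' @param ... Unused.
#' @return `tidy()`: tibble of `term`, `lower`, `upper`.
#' @export
tidy.sdm_sre <- function(x, ...) {
  tibble::tibble(term = x$predictors, lower = unname(x$lower),
                 upper = unname(x$upper))
}
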