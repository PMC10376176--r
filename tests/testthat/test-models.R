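test_that("native logistic regression recovers generating coefficients", {
  set.seed(10)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 2 * x))
  fit <- fit_glm(cbind(x = x), y = y)
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_lt(abs(fit$intercept - (-1)), 0.2)
  expect_lt(abs(fit$coefficients[["x"]] - 2), 0.2)
  # positive class at larger x -> positive slope
  expect_gt(fit$coefficients[["x"]], 0)
  # fitted probabilities strictly inside (0, 1)
  p <- predict(fit, tibble::tibble(x = x))
  expect_true(all(p > 0 & p < 1))
})

test_that("IRLS agrees with the reference fitter and never increases deviance", {
  set.seed(11)
  n <- 400
  d <- tibble::tibble(a = rnorm(n), b = rnorm(n))
  d$label <- rbinom(n, 1, plogis(0.5 - 1.2 * d$a + 0.7 * d$b))
  fit <- fit_glm(d, predictors = c("a", "b"))
  ref <- glm(label ~ a + b, data = d, family = binomial())
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$deviance, deviance(ref), tolerance = 1e-8)
  # deviance trace is monotone non-increasing
  expect_true(all(diff(fit$deviance_trace) <= 1e-8))
  # broom-style accessors
  expect_identical(tidy(fit)$term, c("(Intercept)", "a", "b"))
  expect_identical(glance(fit)$nobs, 400L)
})

test_that("complete separation falls back to a bounded ridge fit", {
  d <- tibble::tibble(x = c(-(5:1), 1:5) / 2,
                      label = c(rep(0L, 5), rep(1L, 5)))
  expect_warning(fit <- fit_glm(d, predictors = "x"), "separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(coef(fit))))
  # still a perfect classifier on the training side
  p <- predict(fit, d)
  expect_true(all(p[d$label == 1] > 0.5) && all(p[d$label == 0] < 0.5))
})

test_that("surface range envelope implements per-variable quantile intervals", {
  # deterministic presences on [0, 1]: quantile 0.025 interval is exact
  pres <- tibble::tibble(u = (0:40) / 40, v = (0:40) / 40)
  sre <- fit_sre(pres, quantile = 0.025)
  expect_equal(unname(sre$lower), c(0.025, 0.025))
  expect_equal(unname(sre$upper), c(0.975, 0.975))

  # quantile 0: min/max hull, every training presence predicted suitable
  hull <- fit_sre(pres, quantile = 0)
  expect_true(all(predict(hull, pres) == 1))

  # conjunction: outside any single interval -> 0
  expect_identical(predict(sre, tibble::tibble(u = 0.5, v = 0.99)), 0)
  expect_identical(predict(sre, tibble::tibble(u = 0.5, v = 0.5)), 1)

  # monotone in quantile: tighter envelopes are nested
  set.seed(12)
  newdata <- tibble::tibble(u = runif(200, -0.2, 1.2),
                            v = runif(200, -0.2, 1.2))
  p_wide <- predict(fit_sre(pres, quantile = 0.01), newdata)
  p_narrow <- predict(fit_sre(pres, quantile = 0.1), newdata)
  expect_true(all(p_narrow <= p_wide))

  expect_error(fit_sre(pres, quantile = 0.5), "configuration")
  expect_error(fit_sre(pres[1:3, ]), "at least 5")
})

test_that("run_all fits every learner x repetition, deterministically, skipping failures", {
  setup <- tiny_setup(seed = 21)
  runs <- suppressWarnings(run_all(setup$table, setup$splits,
                                   default_learners(), setup$stack))
  expect_length(runs, 2 * 3)
  st <- scores_table(runs)
  expect_setequal(unique(st$learner), c("GLM", "SRE"))
  # grid predictions bounded, missing cells flagged as NA only
  for (r in runs) {
    v <- r$grid[!is.na(r$grid)]
    expect_true(all(v >= 0 & v <= 1))
  }
  # rerun is identical (grids included)
  runs2 <- suppressWarnings(run_all(setup$table, setup$splits,
                                    default_learners(), setup$stack))
  expect_identical(lapply(runs, `[[`, "grid"), lapply(runs2, `[[`, "grid"))

  # single learner, single split -> exactly one run
  one_split <- setup$splits[setup$splits$repetition == 1, ]
  one <- run_all(setup$table, one_split, get_learners("GLM"), setup$stack)
  expect_length(one, 1)

  # a failing learner is logged and skipped, not fatal
  register_learner(learner_spec("BROKEN", fit = function(data, predictors, ...)
    stop("boom")), overwrite = TRUE)
  runs3 <- suppressWarnings(suppressMessages(
    run_all(setup$table, one_split,
            get_learners(c("GLM", "BROKEN")), setup$stack)
  ))
  expect_length(runs3, 1)
  fails <- attr(runs3, "failures")
  expect_identical(fails$learner, "BROKEN")
  expect_match(fails$message, "boom")
  # all learners failing is fatal
  expect_error(
    suppressMessages(run_all(setup$table, one_split,
                             get_learners("BROKEN"), setup$stack)),
    "every learner run failed"
  )
})
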