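fake_run <- function(tss_val, auc_val, grid, learner = "GLM", rep_i = 1L) {
  structure(
    list(learner = learner, repetition = rep_i, fit = NULL,
         pred_test = NULL, test_labels = NULL, grid = grid,
         scores = tibble::tibble(auc = auc_val, tss = tss_val, kappa = NA_real_,
                                 cutoff = 0.5, sensitivity = NA_real_,
                                 specificity = NA_real_)),
    class = "model_run"
  )
}

test_that("gating applies strict inequalities on both scores", {
  g <- matrix(runif(9), 3, 3)
  runs <- structure(
    list(
      fake_run(0.7, 0.95, g),        # TSS exactly at gate -> excluded
      fake_run(0.9, 0.8, g),         # AUC exactly at gate -> excluded
      fake_run(0.71, 0.81, g),       # both above -> retained
      fake_run(0.9, 0.95, g)         # clear pass
    ),
    class = "model_runs",
    failures = tibble::tibble()
  )
  kept <- suppressMessages(gate_runs(runs))
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(r) r$scores$tss, numeric(1)),
               c(0.71, 0.9))
  # empty retention is reported, not fatal
  none <- suppressMessages(gate_runs(runs, tss_gate = 0.99))
  expect_length(none, 0)
  expect_error(combine(none, table = NULL), "no retained")
})

test_that("normalization is the stated affine with the constant-grid rule", {
  # grid already spanning [0, 1]: unchanged
  g <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  r <- normalize_predictions(fake_run(0.9, 0.9, g))
  expect_identical(r$grid, g)
  # [0.2, 0.6] -> affine onto [0, 1]
  g2 <- matrix(c(0.2, 0.3, 0.4, 0.6), 2, 2)
  r2 <- normalize_predictions(fake_run(0.9, 0.9, g2))
  expect_equal(r2$grid, (g2 - 0.2) / 0.4)
  # constant grid -> all 0.5 with a warning
  g3 <- matrix(0.4, 2, 2)
  expect_warning(r3 <- normalize_predictions(fake_run(0.9, 0.9, g3)),
                 "constant")
  expect_true(all(r3$grid == 0.5))
})

test_that("weights follow the scores and the ensemble is their convex combination", {
  g1 <- matrix(c(0, 0.5, 1, 0.25), 2, 2)
  g2 <- matrix(c(1, 0.5, 0, 0.75), 2, 2)
  # identical scores -> equal weights -> arithmetic mean
  ens <- combine(list(fake_run(0.8, 0.9, g1), fake_run(0.8, 0.9, g2)),
                 table = NULL)
  expect_equal(ens$weights$weight, c(0.5, 0.5))
  expect_equal(ens$grid, (g1 + g2) / 2)

  # mean-of-both scores 0.9 and 0.6 -> weights 0.6 / 0.4
  ens2 <- combine(list(fake_run(0.9, 0.9, g1), fake_run(0.6, 0.6, g2)),
                  table = NULL)
  expect_equal(ens2$weights$weight, c(0.6, 0.4))

  # single run: ensemble is that run's normalized grid
  ens1 <- combine(list(fake_run(0.9, 0.9, g2)), table = NULL)
  expect_equal(ens1$grid, g2)

  # cell-wise convexity and order invariance
  lo <- pmin(g1, g2)
  hi <- pmax(g1, g2)
  expect_true(all(ens2$grid >= lo - 1e-12 & ens2$grid <= hi + 1e-12))
  ens2_perm <- combine(list(fake_run(0.6, 0.6, g2), fake_run(0.9, 0.9, g1)),
                       table = NULL)
  expect_equal(ens2$grid, ens2_perm$grid)

  # negative TSS weighting: scores shifted so weights stay non-negative
  ens3 <- combine(list(fake_run(-0.2, 0.5, g1), fake_run(0.4, 0.7, g2)),
                  table = NULL, weight_mode = "tss")
  expect_true(all(ens3$weights$weight >= 0))
  expect_equal(sum(ens3$weights$weight), 1)
})

test_that("ensemble skill tracks the best member on synthetic data", {
  for (seed in 1:10) {
    setup <- tiny_setup(seed = 100 + seed)
    runs <- suppressWarnings(run_all(setup$table, setup$splits,
                                     default_learners(), setup$stack))
    retained <- suppressMessages(gate_runs(runs))
    if (length(retained) == 0) next
    ens <- combine(retained, setup$table)
    member_auc <- vapply(retained, function(r) r$scores$auc, numeric(1))
    expect_gte(ens$scores$auc, max(member_auc) - 0.05)
    # ensemble grid stays in [0, 1]
    v <- ens$grid[!is.na(ens$grid)]
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("projection re-applies member normalization and weights", {
  setup <- tiny_setup(seed = 77)
  runs <- suppressWarnings(run_all(setup$table, setup$splits,
                                   default_learners(), setup$stack))
  retained <- suppressMessages(gate_runs(runs, tss_gate = 0.3, auc_gate = 0.5))
  ens <- combine(retained, setup$table)
  # projecting onto the training stack reproduces the fitted ensemble grid
  reproj <- project_ensemble(ens, setup$stack,
                             predictors = names(setup$stack$layers))
  expect_equal(reproj, ens$grid, tolerance = 1e-12)
})
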