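test_that("confusion counts enumerate the four cases with inclusive ties", {
  preds <- c(0.9, 0.4, 0.8, 0.2)
  labels <- c(1, 1, 0, 0)
  cm <- confusion_at(preds, labels, 0.5)
  expect_identical(unclass(cm)[c("tp", "fn", "fp", "tn")],
                   list(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  # degenerate thresholds
  cm0 <- confusion_at(preds, labels, 0)
  expect_identical(c(cm0$fn, cm0$tn), c(0L, 0L))
  cm1 <- confusion_at(preds, labels, 0.91)
  expect_identical(c(cm1$tp, cm1$fp), c(0L, 0L))
  # a prediction equal to the threshold counts as predicted presence
  cm_tie <- confusion_at(c(0.4, 0.6), c(0, 1), 0.4)
  expect_identical(cm_tie$fp, 1L)
  expect_error(confusion_at(numeric(0), numeric(0), 0.5), "empty")
})

test_that("TSS and kappa match their closed forms", {
  cm <- structure(list(tp = 40L, fn = 10L, tn = 45L, fp = 5L),
                  class = "confusion")
  expect_equal(tss(cm), 0.8 + 0.9 - 1)
  expect_equal(cohen_kappa(cm), 0.7) # p_o = .85, p_e = .5
  perfect <- structure(list(tp = 5L, fn = 0L, tn = 5L, fp = 0L),
                       class = "confusion")
  expect_equal(tss(perfect), 1)
  expect_equal(cohen_kappa(perfect), 1)
  chance <- structure(list(tp = 25L, fn = 25L, tn = 25L, fp = 25L),
                      class = "confusion")
  expect_equal(tss(chance), 0)
  expect_equal(cohen_kappa(chance), 0)
  one_class <- structure(list(tp = 3L, fn = 1L, tn = 0L, fp = 0L),
                         class = "confusion")
  expect_error(tss(one_class), "class is absent")
})

test_that("kappa equals TSS at balanced prevalence", {
  set.seed(30)
  for (i in 1:20) {
    k <- sample(3:30, 1)
    tp <- sample(0:k, 1)
    tn <- sample(0:k, 1)
    cm <- structure(list(tp = tp, fn = k - tp, tn = tn, fp = k - tn),
                    class = "confusion")
    if (cm$tp + cm$fn > 0 && cm$tn + cm$fp > 0) {
      expect_equal(cohen_kappa(cm), tss(cm), tolerance = 1e-12)
    }
  }
})

test_that("rank AUC matches pairwise and trapezoidal oracles", {
  preds <- c(0.9, 0.7, 0.7, 0.2)
  labels <- c(1, 0, 1, 0)
  expect_equal(auc(preds, labels), (3 + 0.5) / 4)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # complement symmetry for tie-free scores
  set.seed(31)
  p <- runif(50)
  y <- rbinom(50, 1, 0.4)
  y[1:2] <- c(0, 1)
  expect_equal(auc(p, y) + auc(1 - p, y), 1)
  # oracle agreement on random score sets
  for (i in 1:25) {
    p <- round(runif(40), 2) # force ties
    y <- c(1, 0, rbinom(38, 1, 0.3))
    expect_equal(auc(p, y), oracle_auc_pairs(p, y), tolerance = 1e-12)
    expect_equal(auc(p, y), oracle_auc_trapezoid(p, y), tolerance = 1e-12)
  }
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")
  # third, library-independent cross-check
  set.seed(33)
  p <- round(runif(60), 2)
  y <- c(1, 0, rbinom(58, 1, 0.4))
  expect_equal(auc(p, y),
               as.numeric(pROC::auc(pROC::roc(
                 y, p, levels = c(0, 1), direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("best_cutoff maximises TSS over the midpoint sweep", {
  # separable: TSS 1 at any separating threshold
  sep <- best_cutoff(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$scores$tss, 1)
  expect_gt(sep$cutoff, 0.3)
  expect_lte(sep$cutoff, 0.8)

  # uninformative: every candidate gives 0; smallest threshold returned
  flat <- best_cutoff(rep(0.4, 8), c(1, 0, 1, 0, 1, 0, 1, 0))
  expect_equal(flat$scores$tss, 0)
  expect_identical(flat$cutoff, 0)

  # exhaustive oracle: no threshold anywhere beats the returned TSS
  set.seed(32)
  for (i in 1:10) {
    p <- round(runif(30), 2)
    y <- c(1, 0, rbinom(28, 1, 0.5))
    bc <- best_cutoff(p, y)
    dense <- seq(0, 1, by = 0.001)
    tss_dense <- vapply(dense, function(t) tss(confusion_at(p, y, t)),
                        numeric(1))
    expect_gte(bc$scores$tss + 1e-12, max(tss_dense))
    # invariant stored in the scores row
    expect_equal(bc$scores$tss,
                 bc$scores$sensitivity + bc$scores$specificity - 1)
  }
})
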