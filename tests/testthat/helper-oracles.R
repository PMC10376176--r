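# Independent oracles the implementations are checked against. These stay
# deliberately naive: brute-force pair counting, explicit ROC integration,
# explicit normal-equation least squares.

# AUC as the trapezoidal integral of the empirical ROC curve
oracle_auc_trapezoid <- function(predictions, labels) {
  thresholds <- c(Inf, sort(unique(predictions), decreasing = TRUE), -Inf)
  tpr <- fpr <- numeric(length(thresholds))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  for (i in seq_along(thresholds)) {
    pos <- predictions >= thresholds[i]
    tpr[i] <- sum(pos & labels == 1) / n_pos
    fpr[i] <- sum(pos & labels == 0) / n_neg
  }
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# AUC by brute force over all positive-negative pairs, ties = 1/2
oracle_auc_pairs <- function(predictions, labels) {
  pos <- predictions[labels == 1]
  neg <- predictions[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# metrics recomputed from scratch from a labelled vector pair
oracle_tss <- function(pred_class, labels) {
  sens <- sum(pred_class == 1 & labels == 1) / sum(labels == 1)
  spec <- sum(pred_class == 0 & labels == 0) / sum(labels == 0)
  sens + spec - 1
}

oracle_kappa <- function(pred_class, labels) {
  n <- length(labels)
  p_o <- mean(pred_class == labels)
  p_e <- (mean(pred_class == 1) * mean(labels == 1) +
            mean(pred_class == 0) * mean(labels == 0))
  if (p_e == 1) return(0)
  (p_o - p_e) / (1 - p_e)
}

# R^2 of column j on the others via explicit normal equations
oracle_vif <- function(m, j) {
  y <- m[, j]
  x <- cbind(1, m[, -j, drop = FALSE])
  beta <- solve(t(x) %*% x, t(x) %*% y)
  res <- y - x %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  1 / (1 - r2)
}

# a small synthetic analysis setup shared across tests
tiny_setup <- function(seed = 42, n_rows = 40, n_cols = 40, n_presence = 150,
                       n_absence = 600,
                       truth = niche_truth(-8, c(env01 = 7, env02 = -5))) {
  spec <- grid_spec(n_rows, n_cols, lon_min = 60, lat_min = 35)
  stack <- make_env_stack(spec, 4, seed = seed)
  occ <- sample_occurrences(stack, truth, n_presence, seed = seed + 1)
  thinned <- thin_to_grid(occ, spec)
  table <- sample_pseudo_absences(stack, thinned, n = n_absence,
                                  seed = seed + 2)
  splits <- split_train_test(table, n_repetitions = 3, seed = seed + 3)
  list(spec = spec, stack = stack, truth = truth, occ = thinned,
       table = table, splits = splits)
}
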