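#' Confusion counts at a threshold
#'
#' A prediction greater than or equal to the threshold counts as predicted
#' presence (ties at the cutoff are inclusive).
#'
#' @param predictions Numeric scores in `[0, 1]`.
#' @param labels Binary observed labels (0/1), same length.
#' @param threshold Decision threshold.
#' @return A `confusion` object: list with `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_at <- function(predictions, labels, threshold) {
  check_pred_labels(predictions, labels, require_both = FALSE)
  pred_pos <- predictions >= threshold
  structure(
    list(
      tp = sum(pred_pos & labels == 1),
      fn = sum(!pred_pos & labels == 1),
      tn = sum(!pred_pos & labels == 0),
      fp = sum(pred_pos & labels == 0)
    ),
    class = "confusion"
  )
}

check_pred_labels <- function(predictions, labels, require_both = TRUE) {
  if (length(predictions) == 0) rlang::abort("empty input")
  stopifnot(length(predictions) == length(labels))
  if (!all(labels %in% c(0, 1))) {
    rlang::abort("labels must be 0/1")
  }
  if (require_both && (all(labels == 1) || all(labels == 0))) {
    rlang::abort("undefined metric: both classes must be present")
  }
  invisible(TRUE)
}

sensitivity_of <- function(c) c$tp / (c$tp + c$fn)
specificity_of <- function(c) c$tn / (c$tn + c$fp)

#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1`; ranges over `[-1, 1]`, 0 at chance
#' level, and unlike kappa is insensitive to prevalence.
#'
#' @param c A `confusion` object from [confusion_at()].
#' @return TSS in `[-1, 1]`.
#' @export
tss <- function(c) {
  stopifnot(inherits(c, "confusion"))
  if (c$tp + c$fn == 0 || c$tn + c$fp == 0) {
    rlang::abort("undefined metric: a class is absent")
  }
  sensitivity_of(c) + specificity_of(c) - 1
}

#' Cohen's kappa
#'
#' Chance-corrected agreement
#' \deqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed agreement
#' \eqn{p_o = (tp+tn)/n} and expected agreement
#' \eqn{p_e = [(tp+fp)(tp+fn) + (fn+tn)(fp+tn)]/n^2}. Returns 0 when
#' \eqn{p_e = 1} (all mass in one cell of the marginals).
#'
#' @param c A `confusion` object from [confusion_at()].
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(c) {
  stopifnot(inherits(c, "confusion"))
  n <- c$tp + c$fn + c$tn + c$fp
  if (n == 0) rlang::abort("empty input")
  p_o <- (c$tp + c$tn) / n
  p_e <- ((c$tp + c$fp) * (c$tp + c$fn) + (c$fn + c$tn) * (c$fp + c$tn)) / n^2
  if (p_e == 1) return(0)
  (p_o - p_e) / (1 - p_e)
}

#' Rank-based AUC
#'
#' The probability that a randomly chosen presence receives a higher score
#' than a randomly chosen absence, with ties counted half — the
#' Mann–Whitney form of the area under the ROC curve, computed from ranks
#' rather than an explicit curve.
#'
#' @param predictions Numeric scores.
#' @param labels Binary labels (0/1); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(predictions, labels) {
  check_pred_labels(predictions, labels)
  r <- rank(predictions)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' TSS-maximising cutoff and full score set
#'
#' Sweeps candidate thresholds at the midpoints between consecutive distinct
#' prediction values (plus 0 and 1) and returns the threshold maximising
#' TSS, ties broken toward the smallest threshold, together with the full
#' scores at that cutoff. This is the binarisation rule used to split
#' continuous suitability into suitable/unsuitable.
#'
#' @param predictions Numeric scores in `[0, 1]`.
#' @param labels Binary labels (0/1); both classes required.
#' @return A list with `cutoff` and `scores`, a one-row tibble:
#'   `auc`, `tss`, `kappa`, `cutoff`, `sensitivity`, `specificity`.
#' @export
best_cutoff <- function(predictions, labels) {
  check_pred_labels(predictions, labels)
  s <- sort(unique(predictions))
  candidates <- unique(c(0, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, 1))
  tss_at <- vapply(candidates,
                   function(t) tss(confusion_at(predictions, labels, t)),
                   numeric(1))
  cutoff <- candidates[which.max(tss_at)] # which.max -> first (smallest) tie
  list(cutoff = cutoff,
       scores = evaluate_predictions(predictions, labels, cutoff))
}

#' Score predictions against labels
#'
#' Convenience wrapper: AUC plus threshold-dependent scores at a given
#' cutoff (default: the TSS-maximising one).
#'
#' @inheritParams best_cutoff
#' @param cutoff Threshold; `NULL` (default) picks the TSS-maximising one.
#' @return One-row tibble: `auc`, `tss`, `kappa`, `cutoff`, `sensitivity`,
#'   `specificity`.
#' @export
evaluate_predictions <- function(predictions, labels, cutoff = NULL) {
  if (is.null(cutoff)) return(best_cutoff(predictions, labels)$scores)
  cm <- confusion_at(predictions, labels, cutoff)
  tibble::tibble(
    auc = auc(predictions, labels),
    tss = tss(cm),
    kappa = cohen_kappa(cm),
    cutoff = cutoff,
    sensitivity = sensitivity_of(cm),
    specificity = specificity_of(cm)
  )
}
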