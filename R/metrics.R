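# Discrimination, precision-recall, operating-point and group-contrast
# metrics.

# Rank-based pairwise concordance with ties counted 1/2.
concordance_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- as.numeric(sum(labels == 1L))
  n0 <- as.numeric(sum(labels == 0L))
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Confusion counts at every threshold of a descending sweep.  A subject
# is predicted positive when score >= threshold; the +Inf row is the
# predict-nobody operating point.
threshold_sweep <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  keep <- c(diff(s) != 0, TRUE)  # last index of each tied block
  tp <- c(0L, cumsum(y == 1L)[keep])
  fp <- c(0L, cumsum(y == 0L)[keep])
  tibble::tibble(threshold = c(Inf, s[keep]),
                 tp = tp, fp = fp, fn = n1 - tp, tn = n0 - fp)
}

#' ROC curve and AUC
#'
#' The AUC is the probability that a random event outscores a random
#' non-event, with ties counted one half; the curve is a threshold sweep
#' where a subject is called positive when its score is at or above the
#' threshold.  The curve starts at (0, 0) and ends at (1, 1).
#'
#' @param scores Numeric risk scores (higher = riskier).
#' @param labels 0/1 outcome labels.
#' @return List with `auc` and `roc_points`
#'   (tibble `fpr`, `tpr`, `threshold`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- assert_binary_outcome(labels)
  assert_both_classes(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  sw <- threshold_sweep(scores, labels)
  pts <- tibble::tibble(fpr = sw$fp / (sw$fp + sw$tn),
                        tpr = sw$tp / (sw$tp + sw$fn),
                        threshold = sw$threshold)
  list(auc = concordance_auc(scores, labels), roc_points = pts)
}

#' Precision-recall metrics
#'
#' Average precision is the step-sum of precision over increments of
#' recall along the descending-score sweep; `best_f1` is the largest
#' harmonic mean of precision and recall over all thresholds.
#'
#' @inheritParams roc_auc
#' @return List with `average_precision`, `best_f1` and `pr_points`
#'   (tibble `recall`, `precision`, `threshold`).
#' @export
pr_metrics <- function(scores, labels) {
  labels <- assert_binary_outcome(labels)
  assert_both_classes(labels)
  sw <- threshold_sweep(scores, labels)
  sw <- sw[-1L, ]  # drop the predict-nobody point (recall 0, 0/0 precision)
  recall <- sw$tp / (sw$tp + sw$fn)
  precision <- sw$tp / (sw$tp + sw$fp)
  ap <- sum(diff(c(0, recall)) * precision)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(average_precision = ap,
       best_f1 = max(f1),
       pr_points = tibble::tibble(recall = recall, precision = precision,
                                  threshold = sw$threshold))
}

#' Operating point at a false-positive-rate budget
#'
#' Chooses the threshold that maximizes the true positive rate subject
#' to an achieved false positive rate at or below `target_fpr`, and
#' reports the confusion-matrix metrics there.  A target of 0 is always
#' feasible at threshold `+Inf`; when no subject is called positive the
#' precision is reported as 1 with `degenerate = TRUE`.
#'
#' @inheritParams roc_auc
#' @param target_fpr Maximum acceptable false positive rate in \[0, 1\].
#' @return List with `achieved_fpr`, `tpr`, `precision`, `threshold`,
#'   `degenerate`.
#' @export
operating_point <- function(scores, labels, target_fpr) {
  labels <- assert_binary_outcome(labels)
  assert_both_classes(labels)
  stopifnot(target_fpr >= 0, target_fpr <= 1)
  sw <- threshold_sweep(scores, labels)
  fpr <- sw$fp / (sw$fp + sw$tn)
  tpr <- sw$tp / (sw$tp + sw$fn)
  feasible <- which(fpr <= target_fpr)
  # among feasible thresholds: max TPR, then min FPR, then max threshold
  best <- feasible[order(-tpr[feasible], fpr[feasible],
                         -sw$threshold[feasible])][1L]
  n_pos_called <- sw$tp[best] + sw$fp[best]
  list(achieved_fpr = fpr[best],
       tpr = tpr[best],
       precision = if (n_pos_called == 0L) 1 else sw$tp[best] / n_pos_called,
       threshold = sw$threshold[best],
       degenerate = n_pos_called == 0L)
}

#' Compare risk-score distributions between outcome groups
#'
#' Tests whether the log-odds (risk scores) of subjects who went on to
#' be injured differ in distribution from those who did not.  The
#' default is a two-sided Mann-Whitney U test, which matches a
#' quartile-based presentation of the two score distributions; Welch's
#' t-test is available as an alternative.
#'
#' @param log_odds Numeric per-subject scores.
#' @param labels 0/1 group labels.
#' @param method `"wilcoxon"` (default) or `"welch"`.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
compare_logit_groups <- function(log_odds, labels,
                                 method = c("wilcoxon", "welch")) {
  method <- match.arg(method)
  labels <- assert_binary_outcome(labels)
  g1 <- log_odds[labels == 1L]
  g0 <- log_odds[labels == 0L]
  if (length(g1) < 2L || length(g0) < 2L) {
    stop("each group needs at least 2 members", call. = FALSE)
  }
  ht <- if (method == "wilcoxon") {
    stats::wilcox.test(g1, g0, alternative = "two.sided")
  } else {
    stats::t.test(g1, g0, alternative = "two.sided", var.equal = FALSE)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}

#' Full evaluation report for a score vector
#'
#' Bundles discrimination (ROC/AUC), precision-recall (AP, best F1),
#' requested operating points, and the outcome-group score contrast
#' into one report.
#'
#' @inheritParams roc_auc
#' @param target_fprs False-positive-rate budgets for operating points.
#' @param group_method Test passed to [compare_logit_groups()].
#' @return List of class `evaluation_report`.
#' @export
evaluation_report <- function(scores, labels, target_fprs = c(0.0667),
                              group_method = "wilcoxon") {
  roc <- roc_auc(scores, labels)
  pr <- pr_metrics(scores, labels)
  ops <- lapply(target_fprs, function(t) {
    op <- operating_point(scores, labels, t)
    tibble::tibble(target_fpr = t, achieved_fpr = op$achieved_fpr,
                   tpr = op$tpr, precision = op$precision,
                   threshold = op$threshold)
  })
  structure(
    list(auc = roc$auc, roc_points = roc$roc_points,
         average_precision = pr$average_precision,
         best_f1 = pr$best_f1, pr_points = pr$pr_points,
         operating_points = do.call(rbind, ops),
         group_test = compare_logit_groups(scores, labels,
                                           method = group_method)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> AUC ", sprintf("%.3f", x$auc),
      ", AP ", sprintf("%.3f", x$average_precision),
      ", best F1 ", sprintf("%.3f", x$best_f1),
      "; group test p = ", format(x$group_test$p_value, digits = 3),
      "\n", sep = "")
  invisible(x)
}
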