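# ROC / AUC statistics for image-level anomaly decisions.
#
# Anomalous is the positive class throughout. AUC variance, confidence
# intervals and paired curve comparisons use the DeLong placement-value
# machinery; the Youden index selects operating thresholds; the Mann-Whitney
# rank-sum test compares score distributions (exact by enumeration at small
# sample sizes, normal approximation with tie correction otherwise).

as_binary_labels <- function(labels) {
  if (is.character(labels)) {
    check_flag(all(labels %in% c("normal", "anomalous")),
               "labels must be 'normal'/'anomalous' or 0/1")
    return(as.integer(labels == "anomalous"))
  }
  check_flag(all(labels %in% c(0, 1)), "labels must be 'normal'/'anomalous' or 0/1")
  as.integer(labels)
}

#' Compute an ROC curve
#'
#' Thresholds sweep the unique score values (ties grouped), with the strict
#' `score > threshold` positive rule matching [classify()]. The curve starts
#' at (0, 0) (`threshold = Inf`) and ends at (1, 1) (`threshold = -Inf`).
#'
#' @param scores numeric scores (higher = more anomalous).
#' @param labels `"normal"`/`"anomalous"` strings or 0/1 with 1 = anomalous.
#' @return A `roc_curve`: data.frame with columns threshold, fpr, tpr.
#' @export
compute_roc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  check_flag(length(scores) == length(y), "scores and labels differ in length")
  check_flag(any(y == 1) && any(y == 0), "both classes must be present")
  np <- sum(y == 1); nn <- sum(y == 0)
  ths <- c(Inf, sort(unique(scores), decreasing = TRUE)[-1] , -Inf)
  # predicted positive: score > th. th = max(scores) gives (0,0) like Inf, so
  # the sweep uses Inf then each unique value except the largest, then -Inf.
  fpr <- vapply(ths, function(th) sum(scores > th & y == 0) / nn, numeric(1))
  tpr <- vapply(ths, function(th) sum(scores > th & y == 1) / np, numeric(1))
  structure(data.frame(threshold = ths, fpr = fpr, tpr = tpr),
            class = c("roc_curve", "data.frame"))
}

#' Area under the ROC curve
#'
#' Trapezoidal area of [compute_roc()]; identical to the Mann-Whitney
#' statistic `(wins + 0.5 * ties) / (n_pos * n_neg)`.
#'
#' @inheritParams compute_roc
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  rc <- compute_roc(scores, labels)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties count 1/2); and symmetrically for negatives.
delong_placements <- function(scores, y) {
  xs <- scores[y == 1]; ys <- scores[y == 0]
  v10 <- vapply(xs, function(x) (sum(x > ys) + 0.5 * sum(x == ys)) / length(ys), numeric(1))
  v01 <- vapply(ys, function(x) (sum(xs > x) + 0.5 * sum(xs == x)) / length(xs), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' AUC with DeLong variance, confidence interval and test against chance
#'
#' Nonparametric AUC variance from the placement-value components, a normal-
#' approximation confidence interval, and a two-sided z-test of the AUC
#' against the chance level 0.5.
#'
#' @inheritParams compute_roc
#' @param alpha confidence level is `1 - alpha`.
#' @return An `auc_result`: list with `auc`, `variance`, `ci95 = c(lo, hi)`
#'   (clipped to \[0, 1\]), and `p_vs_chance`.
#' @export
auc_with_ci <- function(scores, labels, alpha = 0.05) {
  y <- as_binary_labels(labels)
  check_flag(sum(y == 1) >= 2 && sum(y == 0) >= 2,
             "need at least 2 members per class for the DeLong variance")
  pl <- delong_placements(scores, y)
  v <- stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
  z <- stats::qnorm(1 - alpha / 2)
  ci <- clip(pl$auc + c(-1, 1) * z * sqrt(v), 0, 1)
  p <- if (v > 0) {
    2 * stats::pnorm(-abs((pl$auc - 0.5) / sqrt(v)))
  } else if (pl$auc == 0.5) 1 else 0
  structure(list(auc = pl$auc, variance = v, ci95 = ci, p_vs_chance = p),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), p vs chance %s\n",
              x$auc, x$ci95[1], x$ci95[2], format.pval(x$p_vs_chance, digits = 3)))
  invisible(x)
}

#' Paired DeLong comparison of two ROC curves
#'
#' Both score vectors must refer to the same samples (identical labels), the
#' paired design of comparing two models on one test set. Two-sided p-value
#' from the paired DeLong z-statistic using the covariance of placement
#' values.
#'
#' @param scores_a,scores_b score vectors of the two models.
#' @inheritParams compute_roc
#' @return List with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  check_flag(length(scores_a) == length(scores_b),
             "paired comparison needs score vectors of equal length")
  y <- as_binary_labels(labels)
  check_flag(length(scores_a) == length(y), "scores and labels differ in length")
  check_flag(sum(y == 1) >= 2 && sum(y == 0) >= 2,
             "need at least 2 members per class")
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  m <- length(pa$v10); n <- length(pa$v01)
  v <- (stats::var(pa$v10) + stats::var(pb$v10) - 2 * stats::cov(pa$v10, pb$v10)) / m +
       (stats::var(pa$v01) + stats::var(pb$v01) - 2 * stats::cov(pa$v01, pb$v01)) / n
  d <- pa$auc - pb$auc
  if (v <= .Machine$double.eps) {
    p <- if (abs(d) < 1e-12) 1 else 0
    z <- if (abs(d) < 1e-12) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p_value = p)
}

#' Youden-optimal operating point
#'
#' Maximizes `J = TPR - FPR` over the curve; ties are broken toward the
#' lower false-positive rate (higher specificity).
#'
#' @param roc a `roc_curve` from [compute_roc()].
#' @return List with `threshold` and `j`.
#' @export
youden_optimal <- function(roc) {
  j <- roc$tpr - roc$fpr
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(roc$fpr[best])][1]
  list(threshold = roc$threshold[best], j = j[best])
}

#' Confusion metrics at a threshold
#'
#' Counts follow the strict `score > threshold` positive rule; metrics are
#' the standard identities accuracy = (TP+TN)/N, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), precision = TP/(TP+FP), Youden index =
#' sensitivity + specificity - 1.
#'
#' @inheritParams compute_roc
#' @param threshold decision threshold.
#' @return A `confusion_report` list with counts and derived metrics.
#' @export
confusion_report <- function(scores, labels, threshold) {
  y <- as_binary_labels(labels)
  check_flag(any(y == 1) && any(y == 0), "both classes must be present")
  pred <- as.integer(scores > threshold)
  confusion_report_from_counts(tp = sum(pred == 1 & y == 1),
                               fp = sum(pred == 1 & y == 0),
                               tn = sum(pred == 0 & y == 0),
                               fn = sum(pred == 0 & y == 1))
}

#' Confusion metrics from raw counts
#'
#' Useful for reconstructing a published confusion matrix from reported
#' sensitivity/specificity and class sizes.
#'
#' @param tp,fp,tn,fn confusion-matrix counts.
#' @return A `confusion_report` list: counts plus accuracy, sensitivity,
#'   specificity, precision, youden_index.
#' @export
confusion_report_from_counts <- function(tp, fp, tn, fn) {
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = sens,
                 specificity = spec,
                 precision = tp / (tp + fp),
                 youden_index = sens + spec - 1),
            class = "confusion_report")
}

#' @export
print.confusion_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("accuracy %.3f  sensitivity %.3f  specificity %.3f  precision %.3f  Youden %.3f\n",
              round_half_up(x$accuracy), round_half_up(x$sensitivity),
              round_half_up(x$specificity), round_half_up(x$precision),
              round_half_up(x$youden_index)))
  invisible(x)
}

# Exact null distribution of the Mann-Whitney U statistic under random group
# assignment, handling ties through midranks. Works on doubled midranks
# (integers) with a subset-sum dynamic program over the smaller group, which
# is equivalent to full enumeration of all assignments.
exact_u_distribution <- function(ranks2, k) {
  total <- sum(ranks2)
  dp <- matrix(0, k + 1, total + 1)   # dp[j+1, s+1] = #subsets of size j, sum s
  dp[1, 1] <- 1
  for (r in ranks2) {
    # 0/1 knapsack update, subset size descending to avoid reusing r
    for (j in seq(k, 1)) {
      s_idx <- seq_len(total + 1 - r)
      dp[j + 1, s_idx + r] <- dp[j + 1, s_idx + r] + dp[j, s_idx]
    }
  }
  dp[k + 1, ]
}

#' Mann-Whitney rank-sum test for anomaly-score separation
#'
#' `U` counts positive-negative pairs won by the positive group (ties count
#' one half), computed from midranks. The two-sided p-value is exact - by a
#' dynamic program equivalent to enumerating all group assignments - when
#' `n_pos * n_neg <= 400`, otherwise a normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param pos_scores,neg_scores score vectors of the two groups.
#' @return A `rank_test_result`: list with `u`, `p_value`, `method`.
#' @export
rank_sum_test <- function(pos_scores, neg_scores) {
  check_flag(length(pos_scores) >= 1 && length(neg_scores) >= 1,
             "both groups must be non-empty")
  n1 <- length(pos_scores); n2 <- length(neg_scores)
  all_s <- c(pos_scores, neg_scores)
  rk <- rank(all_s)                       # midranks
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 * n2 <= 400) {
    ranks2 <- as.integer(round(2 * rk))
    small <- min(n1, n2)
    counts <- exact_u_distribution(ranks2, small)
    sums <- (seq_along(counts) - 1)       # doubled rank sums of the small group
    u_small <- sums / 2 - small * (small + 1) / 2
    u_stat <- if (small == n1) u else n1 * n2 - u
    tot <- sum(counts)
    p_le <- sum(counts[u_small <= u_stat + 1e-9]) / tot
    p_ge <- sum(counts[u_small >= u_stat - 1e-9]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(all_s)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_approx"
  }
  structure(list(u = u, p_value = p, method = method),
            class = "rank_test_result")
}

#' Long-format table of normalized scores with per-group summaries
#'
#' Export behind the grouped scatter plot of normalized anomaly scores:
#' one row per sample plus per-group mean and 95% confidence interval of
#' the mean (t-based; degenerate groups get zero-width intervals).
#'
#' @param scores_norm normalized scores in \[0, 1\].
#' @param labels group labels (any vector).
#' @return List with `points` (data.frame: group, normalized_score) and
#'   `summary` (data.frame: group, n, mean, ci_lo, ci_hi).
#' @export
scatter_export <- function(scores_norm, labels) {
  check_flag(length(scores_norm) == length(labels),
             "scores and labels differ in length")
  check_flag(all(scores_norm >= 0 & scores_norm <= 1),
             "scores must be normalized to [0, 1]")
  pts <- data.frame(group = as.character(labels), normalized_score = scores_norm,
                    stringsAsFactors = FALSE)
  sm <- do.call(rbind, lapply(split(pts$normalized_score, pts$group), function(v) {
    n <- length(v); m <- mean(v)
    half <- if (n > 1 && stats::sd(v) > 0) stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n) else 0
    data.frame(n = n, mean = m, ci_lo = m - half, ci_hi = m + half)
  }))
  sm <- cbind(group = rownames(sm), sm, stringsAsFactors = FALSE)
  rownames(sm) <- NULL
  list(points = pts, summary = sm)
}
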