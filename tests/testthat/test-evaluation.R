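test_that("ROC curves hit the canonical endpoints and tie behavior", {
  rc <- compute_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))   # passes through (0, 1)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
  # all-tied scores: the diagonal
  rcd <- compute_roc(rep(2, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(rcd$fpr, rcd$tpr)
  expect_equal(auc(rep(2, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_true(all(diff(rcd$fpr) >= 0) && all(diff(rcd$tpr) >= 0))
  expect_error(compute_roc(1:4, c(1, 1, 1, 1)), "both classes")
  # label strings work and anomalous is positive
  expect_equal(auc(c(1, 5), c("normal", "anomalous")), 1)
})

test_that("AUC equals exhaustive pair counting on random tied fixtures", {
  set.seed(42)
  for (rep in 1:20) {
    np <- sample(2:30, 1); nn <- sample(2:30, 1)
    scores <- c(sample(0:12, np, replace = TRUE), sample(0:12, nn, replace = TRUE))
    labels <- c(rep(1, np), rep(0, nn))
    expect_equal(auc(scores, labels), pair_count_auc(scores, labels),
                 info = sprintf("rep %d", rep))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(7)
  scores <- rnorm(40); labels <- rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)
  a0 <- auc(scores, labels)
  expect_equal(auc(exp(scores), labels), a0)
  expect_equal(auc(2 * scores + 7, labels), a0)
  expect_equal(auc(rank(scores), labels), a0)
})

test_that("DeLong AUC machinery: known values, variance oracle, CI consistency", {
  r <- auc_with_ci(c(1, 2, 10, 11), c(0, 0, 1, 1))
  expect_equal(r$auc, 1); expect_equal(r$variance, 0)

  r2 <- auc_with_ci(c(1, 2, 3, 4, 5, 6), c(0, 0, 1, 0, 1, 1))
  expect_equal(r2$auc, 8 / 9)    # (wins + 0.5 ties) / 9 by enumeration

  # variance vs a 10,000-rep bootstrap on a 20+20 sample
  set.seed(11)
  s <- c(rnorm(20, 1), rnorm(20)); y <- rep(c(1, 0), each = 20)
  res <- auc_with_ci(s, y)
  rank_auc <- function(s, y) {
    (sum(rank(s)[y == 1]) - sum(y == 1) * (sum(y == 1) + 1) / 2) /
      (sum(y == 1) * sum(y == 0))
  }
  boots <- replicate(10000, {
    i <- c(sample(which(y == 1), 20, TRUE), sample(which(y == 0), 20, TRUE))
    rank_auc(s[i], y[i])
  })
  expect_lt(abs(res$variance - var(boots)) / var(boots), 0.15)

  # p-vs-chance agrees with whether 0.5 falls outside the CI
  set.seed(13)
  for (rep in 1:10) {
    sh <- runif(1, 0, 1.2)
    sc <- c(rnorm(15, sh), rnorm(15)); yy <- rep(c(1, 0), each = 15)
    rr <- auc_with_ci(sc, yy)
    outside <- rr$ci95[1] > 0.5 || rr$ci95[2] < 0.5
    expect_equal(rr$p_vs_chance < 0.05, outside, info = sprintf("rep %d", rep))
  }
  expect_error(auc_with_ci(c(1, 2, 3), c(1, 0, 0)), "at least 2")
})

test_that("DeLong machinery agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  s <- c(rnorm(25, 0.8), rnorm(30)); y <- rep(c(1, 0), c(25, 30))
  mine <- auc_with_ci(s, y)
  ref <- suppressMessages(pROC::roc(y, s, direction = "<", quiet = TRUE))
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(ref, method = "delong")))
  expect_equal(mine$ci95[1], ci[1], tolerance = 1e-8)
  expect_equal(mine$ci95[2], ci[3], tolerance = 1e-8)

  s2 <- s + rnorm(55, 0, 0.6)
  cmp <- delong_compare(s, s2, y)
  ref2 <- suppressMessages(pROC::roc(y, s2, direction = "<", quiet = TRUE))
  pref <- pROC::roc.test(ref, ref2, method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, pref$p.value, tolerance = 1e-8)
})

test_that("paired curve comparison recognizes identity, monotone maps, and real gaps", {
  set.seed(19)
  s <- c(rnorm(20, 1), rnorm(20)); y <- rep(c(1, 0), each = 20)
  expect_equal(delong_compare(s, s, y)$p_value, 1)
  expect_equal(delong_compare(s, exp(s) + 3, y)$p_value, 1)

  # model A separates perfectly, model B is noise, 30+30
  set.seed(21)
  ya <- rep(c(1, 0), each = 30)
  sa <- c(rnorm(30, 10), rnorm(30))
  sb <- rnorm(60)
  cmp <- delong_compare(sa, sb, ya)
  expect_lt(cmp$p_value, 0.01)
  # label-preserving bootstrap of the AUC difference excludes zero
  rank_auc <- function(s, y) {
    (sum(rank(s)[y == 1]) - sum(y == 1) * (sum(y == 1) + 1) / 2) /
      (sum(y == 1) * sum(y == 0))
  }
  d <- replicate(5000, {
    i <- c(sample(1:30, 30, TRUE), sample(31:60, 30, TRUE))
    rank_auc(sa[i], ya[i]) - rank_auc(sb[i], ya[i])
  })
  expect_gt(quantile(d, 0.005), 0)
  expect_error(delong_compare(sa[1:10], sb, ya), "equal length")
})

test_that("the Youden-optimal threshold matches an exhaustive sweep", {
  rc <- compute_roc(c(1, 2, 10, 11), c(0, 0, 1, 1))
  expect_equal(youden_optimal(rc)$j, 1)

  diag_rc <- compute_roc(rep(1, 8), rep(c(0, 1), 4))
  yd <- youden_optimal(diag_rc)
  expect_equal(yd$j, 0)
  expect_equal(diag_rc$fpr[diag_rc$threshold == yd$threshold], 0)  # min-FPR tie-break

  sweep_oracle <- function(scores, labels) {
    cand <- c(Inf, sort(unique(scores)), -Inf)
    best <- -Inf; bt <- Inf
    for (th in cand) {
      tpr <- mean(scores[labels == 1] > th)
      fpr <- mean(scores[labels == 0] > th)
      if (tpr - fpr > best + 1e-12) { best <- tpr - fpr; bt <- th }
    }
    list(threshold = bt, j = best)
  }
  o <- sweep_oracle(c(1, 2, 3, 4, 5), c(0, 0, 1, 0, 1))
  y <- youden_optimal(compute_roc(c(1, 2, 3, 4, 5), c(0, 0, 1, 0, 1)))
  expect_equal(y$j, o$j)
  set.seed(23)
  for (rep in 1:10) {
    sc <- sample(0:8, 30, TRUE); lb <- rbinom(30, 1, 0.4); lb[1:2] <- c(0, 1)
    expect_equal(youden_optimal(compute_roc(sc, lb))$j,
                 sweep_oracle(sc, lb)$j, info = sprintf("rep %d", rep))
  }
})

test_that("confusion reports satisfy the metric identities", {
  cr <- confusion_report(c(1, 2, 3, 4), c(0, 0, 1, 1), threshold = 0)
  expect_equal(cr$sensitivity, 1); expect_equal(cr$specificity, 0)

  set.seed(29)
  sc <- runif(100); lb <- rep(c(1, 0), each = 50); th <- 0.5
  cr2 <- confusion_report(sc, lb, th)
  tp <- sum(sc > th & lb == 1); fp <- sum(sc > th & lb == 0)
  tn <- sum(sc <= th & lb == 0); fn <- sum(sc <= th & lb == 1)
  expect_equal(c(cr2$tp, cr2$fp, cr2$tn, cr2$fn), c(tp, fp, tn, fn))
  expect_equal(cr2$accuracy, (tp + tn) / 100)
  expect_equal(cr2$precision, tp / (tp + fp))
  expect_equal(cr2$youden_index, cr2$sensitivity + cr2$specificity - 1)
  # Youden from the optimal threshold equals sens + spec - 1 there
  y <- youden_optimal(compute_roc(sc, lb))
  cr3 <- confusion_report(sc, lb, y$threshold)
  expect_equal(y$j, cr3$sensitivity + cr3$specificity - 1)
})

test_that("rank-sum tests: exact small-sample p-values and tie-corrected approximation", {
  r <- rank_sum_test(c(3, 4), c(1, 2))
  expect_equal(r$u, 4)
  expect_equal(r$p_value, 2 / 6)
  expect_equal(r$method, "exact")

  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5, 5))$p_value, 1)

  # exact DP vs literal enumeration of group assignments, with ties
  scores <- c(1, 2, 2, 3, 4, 4)
  full_enum_p <- function(scores, n1) {
    rk <- rank(scores)
    u_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
    u_obs <- u_of(seq_len(n1))
    us <- apply(combn(length(scores), n1), 2, u_of)
    min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
  }
  expect_equal(rank_sum_test(scores[1:3], scores[4:6])$p_value,
               full_enum_p(scores, 3))
  set.seed(31)
  for (rep in 1:5) {
    sc <- sample(1:5, 9, TRUE)
    expect_equal(rank_sum_test(sc[1:4], sc[5:9])$p_value,
                 full_enum_p(sc, 4), info = sprintf("rep %d", rep))
  }

  # 30+30 normal approximation vs a large permutation oracle (moderate shift
  # so the p-value sits where the normal approximation is meaningful)
  set.seed(33)
  pos <- rnorm(30, 0.3); neg <- rnorm(30)
  rt <- rank_sum_test(pos, neg)
  expect_equal(rt$method, "normal_approx")
  rk <- rank(c(pos, neg))
  u_obs <- sum(rk[1:30]) - 30 * 31 / 2
  mu <- 900 / 2
  perm <- replicate(100000, {
    idx <- sample.int(60, 30)
    sum(rk[idx]) - 30 * 31 / 2
  })
  p_perm <- mean(abs(perm - mu) >= abs(u_obs - mu) - 1e-9)
  expect_lt(abs(rt$p_value - p_perm) / p_perm, 0.10)
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum agrees with the reference implementation where both are exact", {
  set.seed(37)
  pos <- runif(6); neg <- runif(7)   # continuous: no ties
  mine <- rank_sum_test(pos, neg)
  ref <- wilcox.test(pos, neg, exact = TRUE, correct = FALSE)
  expect_equal(mine$u, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)
})

test_that("scatter export summarizes per-group means with confidence intervals", {
  se <- scatter_export(c(0.2, 0.2, 0.8, 0.8), c("normal", "normal", "anomalous", "anomalous"))
  expect_equal(nrow(se$points), 4L)
  expect_equal(se$summary$ci_lo, se$summary$mean)   # zero-width for constants
  expect_equal(se$summary$ci_hi, se$summary$mean)

  set.seed(41)
  v <- runif(30); g <- rep(c("a", "b", "c"), 10)
  se2 <- scatter_export(v, g)
  expect_equal(se2$summary$mean[se2$summary$group == "a"],
               mean(v[g == "a"]))
  m <- mean(v[g == "b"]); s <- sd(v[g == "b"]) / sqrt(10)
  expect_equal(se2$summary$ci_hi[se2$summary$group == "b"],
               m + qt(0.975, 9) * s)

  single <- scatter_export(c(0.1, 0.4), c("x", "x"))
  expect_equal(nrow(single$summary), 1L)
  expect_error(scatter_export(c(0.5, 1.2), c("a", "b")), "normalized")
})
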