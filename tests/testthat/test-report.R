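test_that("confusion metrics match direct formula evaluation", {
  perfect <- confusion_metrics(c(0, 1, 1, 0), c(0, 1, 1, 0))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)
  # all-positive predictions on mixed labels: zero-denominator convention
  allpos <- confusion_metrics(c(0, 1, 0, 1), c(1, 1, 1, 1))
  expect_equal(allpos$mcc, 0)
  # tp 45, tn 40, fp 10, fn 5 against the closed formula
  y <- c(rep(1, 50), rep(0, 50))
  yhat <- c(rep(1, 45), rep(0, 5), rep(1, 10), rep(0, 40))
  m <- confusion_metrics(y, yhat)
  expect_equal(m$mcc, (45 * 40 - 10 * 5) /
                 sqrt((45 + 10) * (45 + 5) * (40 + 10) * (40 + 5)))
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
  expect_error(confusion_metrics(1, c(1, 0)), "length")
})

test_that("MCC is symmetric under a simultaneous label/prediction swap", {
  set.seed(4)
  y <- rbinom(60, 1, 0.4); yhat <- rbinom(60, 1, 0.5)
  expect_equal(confusion_metrics(y, yhat)$mcc,
               confusion_metrics(1 - y, 1 - yhat)$mcc)
})

test_that("AUC matches the O(n^2) pairwise oracle and its edge conventions", {
  set.seed(9)
  y <- rbinom(20, 1, 0.5); y[1:2] <- c(0, 1)
  s <- round(rnorm(20), 1)  # rounding forces ties
  pairwise_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(s, y)$auc, pairwise_auc(s, y))
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13), rep(0:1, each = 3))$auc, 1)
  expect_equal(roc_auc(rep(1, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(2)
  y <- rbinom(40, 1, 0.5); y[1:2] <- 0:1
  s <- rnorm(40)
  a0 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a0)
  expect_equal(roc_auc(3 * s - 10, y)$auc, a0)
})

test_that("time-in-range bands follow the printed boundary conventions", {
  r <- tir_report(rep(100, 50))
  expect_equal(r$pct_70_180, 100)
  expect_equal(r$pct_below_54 + r$pct_54_70 + r$pct_above_180, 0)
  expect_equal(r$cv_pct, 0)
  v <- c(40, 50, 60, 70, 100, 150, 180, 200, 250, 300)
  r2 <- tir_report(v)
  expect_equal(r2$pct_below_54, 20)       # 40, 50
  expect_equal(r2$pct_54_70, 20)          # 60, 70 (band closed both sides)
  expect_equal(r2$pct_70_180, 30)         # 100, 150, 180
  expect_equal(r2$pct_above_180, 30)      # 200, 250, 300
  expect_equal(r2$pct_above_250, 10)      # 300 only (250 not > 250)
  expect_error(tir_report(rep(NA_real_, 5)), "missing")
})

test_that("the five-band partition identity holds on random traces", {
  set.seed(77)
  for (i in 1:10) {
    v <- runif(200, 30, 350)
    r <- tir_report(v)
    expect_equal(r$pct_below_54 + r$pct_54_70 + r$pct_70_180 +
                   r$pct_180_250 + r$pct_above_250, 100, tolerance = 0.01)
  }
})

test_that("postprandial summaries find first peaks and flat-window identities", {
  rec <- toy_record()
  w <- segment_meal_windows(rec)[[1]]
  # triangular bump peaking at slot 21 -> time to peak 105 min
  w$post$values <- c(seq(100, 160, length.out = 21),
                     seq(157, 100, length.out = 27))
  r <- postprandial_report(rec, list(w))
  expect_equal(r$time_to_peak, 105)
  # constant window: zero excursion, min = max
  w2 <- segment_meal_windows(rec)[[1]]
  r2 <- postprandial_report(rec, list(w2))
  expect_equal(r2$excursion, 0)
  expect_equal(r2$min_bg, r2$max_bg)
  # two equal maxima: the earlier is taken
  w3 <- segment_meal_windows(rec)[[1]]
  w3$post$values <- rep(100, 48); w3$post$values[c(10, 30)] <- 170
  expect_equal(postprandial_report(rec, list(w3))$time_to_peak, 50)
})

test_that("exact Wilcoxon matches brute-force sign enumeration", {
  brute_p <- function(d) {
    d <- d[d != 0]; n <- length(d); r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- expand.grid(rep(list(0:1), n))
    ws <- as.matrix(signs) %*% r
    p_le <- mean(ws <= w_obs + 1e-9); p_ge <- mean(ws >= w_obs - 1e-9)
    min(1, 2 * min(p_le, p_ge))
  }
  set.seed(3)
  for (i in 1:5) {
    d <- round(rnorm(9), 1)
    res <- wilcoxon_paired(rep(0, 9), d)
    expect_equal(res$p, brute_p(d), tolerance = 1e-12)
  }
  # all positive differences, n = 10: two-sided p = 2/2^10
  res10 <- wilcoxon_paired(rep(0, 10), 1:10)
  expect_equal(res10$statistic, 55)
  expect_equal(res10$p, 2 / 1024)
})

test_that("Wilcoxon conventions: zeros excluded, identical pairs give p = 1", {
  expect_equal(wilcoxon_paired(1:6, 1:6)$p, 1)
  a <- c(1, 2, 3, 4, 5, 6); b <- c(1, 5, 1, 8, 2, 9)
  with_zero <- wilcoxon_paired(c(a, 7), c(b, 7))
  expect_equal(with_zero$n, sum(a != b))
  expect_equal(with_zero$p, wilcoxon_paired(a, b)$p)
})

test_that("exact and normal-approximation p agree at moderate n", {
  set.seed(21)
  before <- rnorm(20); after <- before + rnorm(20, 0.3)
  ex <- wilcoxon_paired(before, after, exact_max = 25)
  ap <- wilcoxon_paired(before, after, exact_max = 5)
  expect_equal(ex$method, "exact"); expect_equal(ap$method, "normal")
  expect_lt(abs(ex$p - ap$p), 0.01)
  # and both agree with the reference implementation (no ties, no zeros)
  ref <- stats::wilcox.test(after, before, paired = TRUE)$p.value
  expect_equal(ex$p, ref, tolerance = 1e-10)
})
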