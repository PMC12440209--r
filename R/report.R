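# Evaluation metrics: confusion-matrix statistics, ROC/AUC and Youden
# threshold, glycemic time-in-range reports, postprandial summaries, and the
# paired Wilcoxon signed-rank test.

#' Confusion-matrix classification metrics
#'
#' Accuracy, sensitivity, specificity and the Matthews correlation
#' coefficient. MCC uses the convention that a zero denominator yields 0.
#'
#' @param y binary labels (0/1).
#' @param yhat binary predictions (0/1).
#' @return named list with `tp, tn, fp, fn, accuracy, sensitivity,
#'   specificity` (percent) and `mcc`.
#' @export
confusion_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("confusion_metrics: length mismatch")
  if (length(y) == 0) stop("confusion_metrics: empty input")
  y <- as.integer(y); yhat <- as.integer(yhat)
  tp <- sum(y == 1 & yhat == 1); tn <- sum(y == 0 & yhat == 0)
  fp <- sum(y == 0 & yhat == 1); fn <- sum(y == 1 & yhat == 0)
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = 100 * (tp + tn) / length(y),
       sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
       mcc = mcc)
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) statistic, equivalent to the trapezoid over
#' all score thresholds with tied scores rank-averaged. The curve is returned
#' over the unique-score threshold grid.
#'
#' @param scores continuous scores (higher = more event-like).
#' @param y binary labels.
#' @return list with `auc` and `curve` (data.frame `threshold, sensitivity,
#'   specificity`).
#' @export
roc_auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc: both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- threshold_grid(scores)
  curve <- do.call(rbind, lapply(thr, function(t) {
    m <- confusion_metrics(y, as.integer(scores >= t))
    data.frame(threshold = t, sensitivity = m$sensitivity,
               specificity = m$specificity)
  }))
  list(auc = auc, curve = curve)
}

# candidate thresholds: midpoints of consecutive unique scores plus extremes
threshold_grid <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1) return(u)
  c(u[1] - 1e-9, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1e-9)
}

#' Youden-optimal decision threshold
#'
#' The threshold maximizing Youden's J = sensitivity + specificity - 1 over
#' the score grid; with perfectly separated classes this is the midpoint of
#' the separating gap. Ties take the smallest threshold.
#'
#' @inheritParams roc_auc
#' @export
youden_threshold <- function(scores, y) {
  y <- as.integer(y)
  thr <- threshold_grid(scores)
  j <- vapply(thr, function(t) {
    m <- confusion_metrics(y, as.integer(scores >= t))
    m$sensitivity / 100 + m$specificity / 100 - 1
  }, numeric(1))
  thr[which.max(j)]
}

# MCC-optimal threshold (used by subgroup classifiers)
mcc_threshold <- function(scores, y) {
  thr <- threshold_grid(scores)
  m <- vapply(thr, function(t)
    confusion_metrics(y, as.integer(scores >= t))$mcc, numeric(1))
  thr[which.max(m)]
}

#' Time-in-range glycemic report
#'
#' Band fractions over non-missing samples with the printed-boundary
#' convention: below 54 is `< 54`; 54-70 is `[54, 70]`; 70-180 is
#' `(70, 180]`; above 180 is `> 180`; above 250 is `> 250` (so the >180 band
#' contains the >250 band; the internal 180-250 band completes the
#' partition). Also reports mean, median, SD and CV (= 100*SD/mean) of
#' glucose.
#'
#' @param trace a [glucose_trace()] or numeric vector of mg/dL values.
#' @return named list (`pct_below_54`, `pct_54_70`, `pct_70_180`,
#'   `pct_above_180`, `pct_above_250`, `pct_180_250`, `mean_bg`, `median_bg`,
#'   `sd_bg`, `cv_pct`).
#' @export
tir_report <- function(trace) {
  v <- if (inherits(trace, "glucose_trace")) trace$values else as.numeric(trace)
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("tir_report: all samples missing")
  pct <- function(cond) 100 * mean(cond)
  list(pct_below_54 = pct(v < 54),
       pct_54_70 = pct(v >= 54 & v <= 70),
       pct_70_180 = pct(v > 70 & v <= 180),
       pct_above_180 = pct(v > 180),
       pct_above_250 = pct(v > 250),
       pct_180_250 = pct(v > 180 & v <= 250),
       mean_bg = mean(v), median_bg = median(v), sd_bg = sd(v),
       cv_pct = 100 * sd(v) / mean(v))
}

#' Postprandial glycemic report for one patient
#'
#' Per meal window: initial BG (at meal onset), min/max/mean/median over the
#' 4-h postprandial trace, BG excursion (mean postprandial BG minus initial
#' BG), and time to peak (minutes from onset to the first maximum). The
#' patient value of each metric is the median over meals; time-in-range
#' percentages are computed over all postprandial samples pooled.
#'
#' @param record a [patient_record()] (used for the trace values at meal
#'   onset).
#' @param windows meal windows from [segment_meal_windows()].
#' @return named list of patient-level postprandial metrics.
#' @export
postprandial_report <- function(record, windows) {
  if (length(windows) == 0) stop("postprandial_report: no windows")
  per_meal <- lapply(windows, function(w) {
    post <- w$post$values
    initial <- tail(w$pre$values, 1)
    peak_slot <- which.max(post)   # first occurrence on ties
    c(min_bg = min(post, na.rm = TRUE), max_bg = max(post, na.rm = TRUE),
      mean_bg = mean(post, na.rm = TRUE),
      median_bg = median(post, na.rm = TRUE), initial_bg = initial,
      excursion = mean(post, na.rm = TRUE) - initial,
      time_to_peak = peak_slot * w$post$step)
  })
  mm <- do.call(rbind, per_meal)
  pooled <- unlist(lapply(windows, function(w) w$post$values))
  out <- as.list(apply(mm, 2, median))
  c(out, tir_report(pooled)[c("pct_below_54", "pct_54_70", "pct_70_180",
                              "pct_above_180", "pct_above_250")])
}

# exact null distribution of the signed-rank statistic W+ for given ranks:
# dynamic programming over doubled ranks (integers even under tie-averaging)
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  p <- numeric(total + 1); p[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), p[seq_len(total + 1 - r)])
    p <- (p + shifted) / 2
  }
  p  # p[w+1] = P(2*W+ = w)
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test with zero-difference exclusion and tie-averaged ranks.
#' The null distribution is exact (enumerated by convolution over the
#' realized ranks) for n <= `exact_max` non-zero pairs, and a
#' normal approximation with tie correction and continuity correction above.
#' All differences zero returns p = 1 by convention.
#'
#' @param before,after paired numeric vectors.
#' @param exact_max largest n using the exact null.
#' @return list `statistic` (W+, sum of positive-difference ranks), `p`
#'   (two-sided), `n` (non-zero pairs), `method`.
#' @export
wilcoxon_paired <- function(before, after, exact_max = 25) {
  if (length(before) != length(after)) stop("wilcoxon_paired: length mismatch")
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p = 1, n = 0, method = "degenerate"))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * r))
    null <- signed_rank_null(ranks2)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(null[seq_len(w2 + 1)])
    p_ge <- sum(null[(w2 + 1):length(null)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, p = p, n = n, method = method)
}
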