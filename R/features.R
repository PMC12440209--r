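# 13 time-domain features per meal window and binary postprandial event
# labels (hypoglycemia / hyperglycemia).

# canonical feature column order used across the package
ppg_feature_names <- function() {
  c("cgm_at_meal", paste0("mean_cgm_h", 1:6), "lbgi_6h", "hbgi_6h",
    "excursion_60", "cho", "meal_hour", "mib")
}

# continuous features used for clustering (meal_hour excluded: Euclidean
# distance on a cyclic integer hour is ill-posed)
ppg_cluster_features <- function(include_hour = FALSE) {
  f <- ppg_feature_names()
  if (include_hour) f else setdiff(f, "meal_hour")
}

#' Low and high blood glucose indices
#'
#' Kovatchev risk indices over a preprandial trace: the symmetrising transform
#' \eqn{f(BG) = 1.509 (\ln(BG)^{1.084} - 5.381)} (BG in mg/dL) maps glucose to
#' a risk scale whose zero point is 112.5 mg/dL; LBGI is the mean of
#' \eqn{10 f^2} over samples with \eqn{f < 0}, HBGI over samples with
#' \eqn{f > 0} (non-contributing samples count as zero risk). Missing samples
#' are excluded from the means.
#'
#' @param pre a [glucose_trace()] (or bare numeric vector of mg/dL values).
#' @return named numeric vector `c(lbgi =, hbgi =)`, both non-negative.
#' @export
risk_indices <- function(pre) {
  bg <- if (inherits(pre, "glucose_trace")) pre$values else as.numeric(pre)
  bg <- bg[!is.na(bg)]
  if (length(bg) == 0) stop("risk_indices: all samples missing")
  if (any(bg <= 0)) stop("risk_indices: non-positive glucose")
  fbg <- 1.509 * (log(bg)^1.084 - 5.381)
  rl <- ifelse(fbg < 0, 10 * fbg^2, 0)
  rh <- ifelse(fbg > 0, 10 * fbg^2, 0)
  c(lbgi = mean(rl), hbgi = mean(rh))
}

#' Extract the 13-feature vector from a meal window
#'
#' Features: CGM at meal onset; mean CGM over each of the six preprandial
#' hours (most recent hour first); LBGI and HBGI over the 6-h preprandial
#' window; the 60-minute glucose excursion BG(m0) - BG(m0 - 60 min);
#' announced carbohydrates (g); meal hour (integer 0-23, local clock);
#' and the meal insulin bolus (U).
#'
#' @param window a `meal_window` from [segment_meal_windows()].
#' @return named numeric vector of length 13.
#' @export
extract_features <- function(window) {
  pre <- window$pre$values
  n <- length(pre)             # 72, ending at m0 inclusive
  step <- window$pre$step
  per_h <- as.integer(60 / step)
  cgm_at_meal <- pre[n]
  hourly <- vapply(1:6, function(h) {
    block <- pre[(n - h * per_h + 1):(n - (h - 1) * per_h)]
    mean(block, na.rm = TRUE)
  }, numeric(1))
  ri <- risk_indices(window$pre)
  bg60 <- pre[n - per_h]       # sample exactly 60 min before m0
  excursion <- cgm_at_meal - bg60
  hour <- as.integer(format(window$meal$time, "%H"))
  v <- c(cgm_at_meal, hourly, ri[["lbgi"]], ri[["hbgi"]], excursion,
         window$meal$cho_announced, hour, window$bolus_units)
  names(v) <- ppg_feature_names()
  v
}

# run-length check: any run of >= k consecutive TRUEs (NA breaks a run)
has_sustained_run <- function(flag, k = 3) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  any(r$values & r$lengths >= k)
}

#' Postprandial hypoglycemia label
#'
#' 1 iff glucose is at or below 70 mg/dL sustained for at least 15 minutes
#' (three consecutive 5-min samples) anywhere in the 4-hour postprandial
#' window.
#'
#' @param post postprandial [glucose_trace()] (48 samples).
#' @return integer 0/1.
#' @export
label_hypo <- function(post) {
  v <- if (inherits(post, "glucose_trace")) post$values else as.numeric(post)
  as.integer(has_sustained_run(v <= 70, 3))
}

#' Postprandial hyperglycemia label
#'
#' Two detection phases: glucose at or above 250 mg/dL during the first two
#' hours, or at or above 180 mg/dL during hours two to four, each sustained
#' for at least 15 minutes (three consecutive samples). The sample at exactly
#' 120 min opens the second phase.
#'
#' @param post postprandial [glucose_trace()] (48 samples).
#' @return integer 0/1.
#' @export
label_hyper <- function(post) {
  v <- if (inherits(post, "glucose_trace")) post$values else as.numeric(post)
  step <- if (inherits(post, "glucose_trace")) post$step else 5
  t_min <- seq_along(v) * step              # sample i sits at m0 + i*step
  phase1 <- v[t_min < 120]
  phase2 <- v[t_min >= 120]
  as.integer(has_sustained_run(phase1 >= 250, 3) ||
               has_sustained_run(phase2 >= 180, 3))
}

#' Build the meal-instance dataset from patient records
#'
#' Segments each record into meal windows, extracts the 13 features and both
#' event labels, and stacks everything into one data.frame (one row per valid
#' meal window).
#'
#' @param records list of [patient_record()].
#' @param ... passed to [segment_meal_windows()].
#' @return data.frame with `patient_id`, `meal_time`, the 13 feature columns,
#'   `label_hypo` and `label_hyper`. Label prevalences are attached as
#'   attribute `prevalence`.
#' @export
build_dataset <- function(records, ...) {
  rows <- list()
  for (r in records) {
    windows <- segment_meal_windows(r, ...)
    for (w in windows) {
      v <- extract_features(w)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = r$patient_id,
        meal_time = w$meal$time,
        as.list(v),
        label_hypo = label_hypo(w$post),
        label_hyper = label_hyper(w$post))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), meal_time = as.POSIXct(character()))
  rownames(out) <- NULL
  if (nrow(out))
    attr(out, "prevalence") <- c(hypo = mean(out$label_hypo),
                                 hyper = mean(out$label_hyper))
  out
}
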