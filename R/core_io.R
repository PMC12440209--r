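# Data model for patient logs: glucose traces on a uniform 5-min grid,
# meal/bolus events, therapy parameters, CSV readers/writers and meal-window
# segmentation.

#' Construct a gridded CGM trace
#'
#' A `glucose_trace` holds a continuous glucose monitoring series on a uniform
#' time grid (default 5-minute cadence). Missing samples are `NA`; values are
#' validated against the physical sensor range (20, 600) mg/dL and flagged
#' missing outside it.
#'
#' @param start_time POSIXct time of the first sample (stored timezone-naive,
#'   i.e. interpreted as local clock time).
#' @param values numeric vector of glucose readings in mg/dL (`NA` = missing).
#' @param step grid step in minutes.
#' @param validate flag out-of-range readings as missing (with a warning).
#' @return An object of class `glucose_trace`.
#' @export
glucose_trace <- function(start_time, values, step = 5, validate = TRUE) {
  stopifnot(step > 0, inherits(start_time, "POSIXct"))
  values <- as.numeric(values)
  if (validate) {
    bad <- !is.na(values) & (values <= 20 | values >= 600 | !is.finite(values))
    if (any(bad)) {
      warning(sprintf("%d glucose value(s) outside (20, 600) mg/dL marked missing",
                      sum(bad)))
      values[bad] <- NA_real_
    }
  }
  structure(list(start_time = start_time, step = step, values = values),
            class = "glucose_trace")
}

#' @export
print.glucose_trace <- function(x, ...) {
  cat(sprintf("<glucose_trace> %d samples @ %g min from %s (%.1f%% missing)\n",
              length(x$values), x$step, format(x$start_time),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
length.glucose_trace <- function(x) length(x$values)

trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$values) - 1) * trace$step * 60
}

trace_end <- function(trace) {
  trace$start_time + (length(trace$values) - 1) * trace$step * 60
}

# index of the grid slot at time t (1-based); NA when off-grid
trace_slot <- function(trace, t) {
  i <- as.numeric(difftime(t, trace$start_time, units = "mins")) / trace$step
  ifelse(i >= 0 & i <= length(trace$values) - 1 & abs(i - round(i)) < 1e-6,
         as.integer(round(i)) + 1L, NA_integer_)
}

#' Therapy parameters
#'
#' Carbohydrate-to-insulin ratio (CR, g/U), correction factor (CF, mg/dL per
#' U), CGM target used by the bolus calculator (150 mg/dL default) and
#' duration of insulin action (DIA, hours).
#'
#' @param cr carbohydrate ratio, grams per insulin unit.
#' @param cf correction factor, mg/dL per insulin unit.
#' @param cgm_target bolus-calculator glucose target, mg/dL.
#' @param dia duration of insulin action, hours.
#' @export
therapy_params <- function(cr, cf, cgm_target = 150, dia = 4) {
  stopifnot(cr > 0, cf > 0, cgm_target >= 80, cgm_target <= 200, dia > 0)
  structure(list(cr = cr, cf = cf, cgm_target = cgm_target, dia = dia),
            class = "therapy_params")
}

#' Assemble a patient record
#'
#' @param patient_id character id.
#' @param trace a [glucose_trace()].
#' @param meals data.frame with columns `time` (POSIXct), `cho_announced` (g)
#'   and optionally `cho_actual` (g; defaults to announced, used only by the
#'   simulator).
#' @param boluses data.frame with columns `time` (POSIXct), `units` (U).
#' @param therapy a [therapy_params()].
#' @export
patient_record <- function(patient_id, trace, meals, boluses, therapy) {
  stopifnot(inherits(trace, "glucose_trace"), inherits(therapy, "therapy_params"))
  if (is.null(meals$cho_actual)) meals$cho_actual <- meals$cho_announced
  stopifnot(all(meals$cho_announced >= 0), all(boluses$units >= 0))
  rng <- c(trace$start_time, trace_end(trace))
  for (tm in list(meals$time, boluses$time)) {
    if (length(tm) && (min(tm) < rng[1] || max(tm) > rng[2]))
      stop("meal/bolus timestamps fall outside the trace span")
  }
  meals <- meals[order(meals$time), , drop = FALSE]
  boluses <- boluses[order(boluses$time), , drop = FALSE]
  structure(list(patient_id = patient_id, trace = trace, meals = meals,
                 boluses = boluses, therapy = therapy),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s: %d CGM samples, %d meals, %d boluses\n",
              x$patient_id, length(x$trace$values), nrow(x$meals),
              nrow(x$boluses)))
  invisible(x)
}

#' Snap irregular CGM samples onto a uniform grid
#'
#' Each raw sample is assigned to its nearest grid slot (grid anchored at the
#' first timestamp rounded down to the step). When several samples land in one
#' slot the last wins (with a warning). Interior gaps of at most
#' `max_fill_min` minutes are filled by linear interpolation; longer gaps stay
#' missing. Idempotent on already-gridded input.
#'
#' @param times POSIXct vector, strictly increasing.
#' @param values numeric glucose values, mg/dL.
#' @param step grid step, minutes.
#' @param max_fill_min longest gap (minutes) bridged by linear interpolation.
#' @return A [glucose_trace()].
#' @export
align_to_grid <- function(times, values, step = 5, max_fill_min = 15) {
  stopifnot(length(times) == length(values), length(times) > 0)
  if (any(diff(as.numeric(times)) <= 0))
    stop("timestamps must be strictly increasing")
  origin <- as.POSIXct(floor(as.numeric(times[1]) / (step * 60)) * (step * 60),
                       origin = "1970-01-01", tz = attr(times, "tzone") %||% "UTC")
  slot <- as.integer(round(as.numeric(difftime(times, origin, units = "mins")) /
                             step)) + 1L
  n <- max(slot)
  out <- rep(NA_real_, n)
  if (anyDuplicated(slot))
    warning("duplicate samples in one grid slot; keeping the last")
  out[slot] <- values  # later assignments (last in time) win
  # linear fill across short interior gaps
  obs <- which(!is.na(out))
  if (length(obs) >= 2) {
    for (k in seq_len(length(obs) - 1)) {
      a <- obs[k]; b <- obs[k + 1]
      gap_min <- (b - a) * step
      if (b - a > 1 && gap_min <= max_fill_min) {
        idx <- (a + 1):(b - 1)
        out[idx] <- out[a] + (out[b] - out[a]) * (idx - a) / (b - a)
      }
    }
  }
  glucose_trace(origin, out, step = step)
}

#' Load patient records from long-format CSV
#'
#' Expects columns `patient_id, timestamp, cgm_mg_dl, cho_g, bolus_u` (empty
#' cells mean "no event"); ISO-8601 timestamps. A JSON sidecar named
#' `<file>.therapy.json` may map patient ids to therapy parameters; patients
#' without an entry get `default_therapy`.
#'
#' @param path a CSV file or a directory of CSV files.
#' @param default_therapy therapy used when no sidecar entry exists.
#' @return list of [patient_record()].
#' @export
load_patient_records <- function(path,
                                 default_therapy = therapy_params(10, 40)) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.csv$", full.names = TRUE) else path
  out <- list()
  for (f in files) {
    df <- read.csv(f, stringsAsFactors = FALSE)
    need <- c("patient_id", "timestamp", "cgm_mg_dl", "cho_g", "bolus_u")
    if (!all(need %in% names(df)))
      stop(sprintf("%s: missing required columns (%s)", f,
                   paste(setdiff(need, names(df)), collapse = ", ")))
    if (nrow(df) == 0) stop(sprintf("%s: empty file", f))
    ts <- as.POSIXct(strptime(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
    alt <- is.na(ts)
    ts[alt] <- as.POSIXct(strptime(df$timestamp[alt], "%Y-%m-%d %H:%M:%S",
                                   tz = "UTC"))
    if (anyNA(ts))
      stop(sprintf("%s: unparseable timestamp at row %d", f,
                   which(is.na(ts))[1]))
    sidecar <- paste0(sub("\\.csv$", "", f), ".therapy.json")
    tmap <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
    for (pid in unique(df$patient_id)) {
      d <- df[df$patient_id == pid, , drop = FALSE]
      t_p <- ts[df$patient_id == pid]
      cgm <- !is.na(d$cgm_mg_dl)
      if (!any(cgm)) stop(sprintf("%s: patient %s has no CGM data", f, pid))
      trace <- align_to_grid(t_p[cgm], d$cgm_mg_dl[cgm])
      meals <- data.frame(time = t_p[!is.na(d$cho_g)],
                          cho_announced = d$cho_g[!is.na(d$cho_g)])
      boluses <- data.frame(time = t_p[!is.na(d$bolus_u)],
                            units = d$bolus_u[!is.na(d$bolus_u)])
      th <- if (!is.null(tmap[[pid]]))
        do.call(therapy_params, tmap[[pid]]) else default_therapy
      out[[pid]] <- patient_record(pid, trace, meals, boluses, th)
    }
  }
  out
}

#' Write patient records to the long CSV dialect
#'
#' Inverse of [load_patient_records()]: one CSV per call (all records
#' appended) plus a therapy JSON sidecar.
#'
#' @param records list of [patient_record()].
#' @param file output CSV path.
#' @export
write_patient_records <- function(records, file) {
  rows <- lapply(records, function(r) {
    tt <- trace_times(r$trace)
    df <- data.frame(patient_id = r$patient_id,
                     timestamp = format(c(tt, r$meals$time, r$boluses$time),
                                        "%Y-%m-%dT%H:%M:%S"),
                     cgm_mg_dl = c(r$trace$values,
                                   rep(NA, nrow(r$meals) + nrow(r$boluses))),
                     cho_g = c(rep(NA, length(tt)), r$meals$cho_announced,
                               rep(NA, nrow(r$boluses))),
                     bolus_u = c(rep(NA, length(tt) + nrow(r$meals)),
                                 r$boluses$units))
    df[order(df$timestamp), ]
  })
  write.csv(do.call(rbind, rows), file, row.names = FALSE, na = "")
  tmap <- lapply(records, function(r) unclass(r$therapy))
  names(tmap) <- vapply(records, `[[`, "", "patient_id")
  jsonlite::write_json(tmap, paste0(sub("\\.csv$", "", file), ".therapy.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Segment a record into pre/post meal windows
#'
#' For each meal the preprandial trace is the 72 grid samples (6 h at 5-min
#' cadence) ending at meal onset inclusive, and the postprandial trace the 48
#' samples after onset (4-hour prediction horizon). Windows whose pre or post
#' coverage falls below `min_coverage` are dropped (reasons returned in the
#' `dropped` attribute). The meal bolus is the sum of boluses within
#' `bolus_assoc_min` minutes of meal onset.
#'
#' @param record a [patient_record()] on the 5-min grid.
#' @param min_coverage minimum non-missing fraction per window.
#' @param bolus_assoc_min half-width (minutes) of the bolus-meal association
#'   window.
#' @return list of `meal_window` objects (fields `meal`, `pre`, `post`,
#'   `bolus_units`), with dropped-window reasons as attribute `dropped`.
#' @export
segment_meal_windows <- function(record, min_coverage = 0.9,
                                 bolus_assoc_min = 15) {
  trace <- record$trace
  step <- trace$step
  n_pre <- as.integer(6 * 60 / step)   # 72 samples, ending at m0
  n_post <- as.integer(4 * 60 / step)  # 48 samples after m0
  out <- list(); dropped <- character()
  for (i in seq_len(nrow(record$meals))) {
    meal <- record$meals[i, , drop = FALSE]
    # snap meal onset to nearest grid slot
    off <- as.numeric(difftime(meal$time, trace$start_time, units = "mins"))
    m0 <- as.integer(round(off / step)) + 1L
    if (m0 - n_pre + 1 < 1 || m0 + n_post > length(trace$values)) {
      dropped <- c(dropped, sprintf("meal %s: window exceeds trace span",
                                    format(meal$time)))
      next
    }
    pre_v <- trace$values[(m0 - n_pre + 1):m0]
    post_v <- trace$values[(m0 + 1):(m0 + n_post)]
    if (mean(!is.na(pre_v)) < min_coverage) {
      dropped <- c(dropped, sprintf("meal %s: pre-window coverage < %g",
                                    format(meal$time), min_coverage))
      next
    }
    if (mean(!is.na(post_v)) < min_coverage) {
      dropped <- c(dropped, sprintf("meal %s: post-window coverage < %g",
                                    format(meal$time), min_coverage))
      next
    }
    near <- abs(as.numeric(difftime(record$boluses$time, meal$time,
                                    units = "mins"))) <= bolus_assoc_min
    pre <- glucose_trace(trace$start_time + (m0 - n_pre) * step * 60, pre_v,
                         step, validate = FALSE)
    post <- glucose_trace(trace$start_time + m0 * step * 60, post_v, step,
                          validate = FALSE)
    out[[length(out) + 1]] <- structure(
      list(meal = meal, pre = pre, post = post,
           bolus_units = sum(record$boluses$units[near])),
      class = "meal_window")
  }
  attr(out, "dropped") <- dropped
  out
}
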