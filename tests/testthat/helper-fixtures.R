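# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# constant-glucose trace helper
const_trace <- function(value, n = 48, start = as.POSIXct("2024-01-01 08:00:00",
                                                          tz = "UTC")) {
  glucose_trace(start, rep(value, n), validate = FALSE)
}

# a complete one-day record with one meal at 08:00 and a 6 U bolus
toy_record <- function(bg = 120, cho = 60, bolus = 6) {
  start <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  trace <- glucose_trace(start, rep(bg, 288))
  patient_record("p1", trace,
                 meals = data.frame(time = start + 8 * 3600,
                                    cho_announced = cho),
                 boluses = data.frame(time = start + 8 * 3600, units = bolus),
                 therapy = therapy_params(10, 40))
}

# small simulated cohort + instance table (shared across test files)
small_cohort <- function() memo("small_cohort", {
  generate_cohort(sim_scenario(n_patients = 6, n_days = 12, seed = 101))
})

small_instances <- function() memo("small_instances", {
  build_dataset(small_cohort())
})

# fast control for fitting in tests
fast_control <- function(som_epochs = 60, ...) {
  ppg_control(n_draws = 3, cv_folds = 3, som_epochs = som_epochs, ...)
}

# Planted-subgroup instance generator: three well-separated behavioural
# subgroups (disjoint CGM-history dimensions) whose event-label rules are
# subgroup-conditional — the sign of the label-generating shift flips
# between subgroups, so pooled models must learn an interaction that
# cluster-local models see as a clean main effect. Hypo labels live on
# (lbgi_6h, excursion_60), hyper labels on (hbgi_6h, mib).
planted_instances <- function(n_per = 40, sep = 4, seed = 1,
                              label_noise = 0, label_shift = 3) {
  set.seed(seed)
  base <- c(cgm_at_meal = 120, mean_cgm_h1 = 120, mean_cgm_h2 = 120,
            mean_cgm_h3 = 120, mean_cgm_h4 = 120, mean_cgm_h5 = 120,
            mean_cgm_h6 = 120, lbgi_6h = 3, hbgi_6h = 5, excursion_60 = 0,
            cho = 60, meal_hour = 12, mib = 6)
  sds <- c(15, 12, 12, 12, 12, 12, 12, 1, 2, 8, 10, 4, 1.5)
  # subgroup locations on CGM-history dims only (label dims untouched)
  sub_dirs <- list(c(mean_cgm_h1 = 1, mean_cgm_h2 = 1),
                   c(mean_cgm_h3 = 1, mean_cgm_h4 = 1),
                   c(mean_cgm_h5 = 1, cho = 1))
  # subgroup-conditional label shift signs
  hypo_sign <- c(1, -1, 1)
  hyper_sign <- c(-1, 1, 1)
  rows <- list()
  for (g in 1:3) for (y_hypo in 0:1) for (y_hyper in 0:1) {
    n <- n_per
    x <- matrix(rnorm(n * 13), n, 13)
    x <- sweep(x, 2, sds, "*")
    x <- sweep(x, 2, base, "+")
    colnames(x) <- names(base)
    off <- sub_dirs[[g]]
    for (nm in names(off))
      x[, nm] <- x[, nm] + sep * sds[match(nm, names(base))] * off[nm] * g
    sd_of <- function(nm) sds[match(nm, names(base))]
    if (y_hypo == 1) {
      x[, "lbgi_6h"] <- x[, "lbgi_6h"] + hypo_sign[g] * label_shift * sd_of("lbgi_6h")
      x[, "excursion_60"] <- x[, "excursion_60"] -
        hypo_sign[g] * label_shift * sd_of("excursion_60")
    }
    if (y_hyper == 1) {
      x[, "hbgi_6h"] <- x[, "hbgi_6h"] + hyper_sign[g] * label_shift * sd_of("hbgi_6h")
      x[, "mib"] <- x[, "mib"] - hyper_sign[g] * label_shift * sd_of("mib")
    }
    x[, "cgm_at_meal"] <- pmax(x[, "cgm_at_meal"], 40)
    df <- as.data.frame(x)
    df$patient_id <- sprintf("plant%d", g)
    df$meal_time <- as.POSIXct("2024-01-01", tz = "UTC") +
      (length(rows) * n_per + seq_len(n)) * 3600
    df$label_hypo <- y_hypo
    df$label_hyper <- y_hyper
    df$subgroup <- g
    rows[[length(rows) + 1]] <- df
  }
  out <- do.call(rbind, rows)
  if (label_noise > 0) {
    flip <- runif(nrow(out)) < label_noise
    out$label_hypo[flip] <- 1 - out$label_hypo[flip]
  }
  rownames(out) <- NULL
  out
}

# fitted system on the planted dataset, shared across test files
planted_fit <- function() memo("planted_fit", {
  inst <- planted_instances(n_per = 30, sep = 4, seed = 21)
  suppressWarnings(ppg_system(inst, seed = 13, control = fast_control()))
})

# repeated-split protocol on planted data with moderate class overlap
# (1.2 sd label shift) and subgroup-conditional label rules: the regime
# where subgroup-local models have a real edge over pooled baselines
planted_protocol <- function() memo("planted_protocol", {
  inst <- planted_instances(n_per = 50, sep = 4, seed = 21,
                            label_shift = 1.2)
  suppressWarnings(run_protocol(inst, n_iter = 3, seed = 17,
                                control = fast_control(som_epochs = 120)))
})
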