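# Dual prediction system: 12 subgroup random forests (6 per system),
# nearest-two-centroid routing, AND-gate fusion, baselines, and the repeated
# 90/10 split evaluation protocol.

#' Training control for the dual prediction system
#'
#' @param n_draws randomized-search draws per model.
#' @param cv_folds cross-validation folds for the search.
#' @param trees,depth,min_node integer ranges sampled by the search
#'   (`num.trees`, `max.depth`, `min.node.size` of the random forest).
#' @param k clusters per profiling subset.
#' @param som_epochs SOM epochs per profiling subset.
#' @param negatives how a subgroup model's opposite-label training instances
#'   are chosen: `"local"` (equally many nearest the subgroup centroid,
#'   class-balanced) or `"all"`.
#' @param include_hour include meal hour in the clustering vector.
#' @export
ppg_control <- function(n_draws = 25, cv_folds = 5, trees = c(100, 500),
                        depth = c(3, 12), min_node = c(1, 8), k = 3,
                        som_epochs = 500,
                        negatives = c("local", "all"),
                        include_hour = FALSE) {
  list(n_draws = n_draws, cv_folds = cv_folds, trees = trees, depth = depth,
       min_node = min_node, k = k, som_epochs = som_epochs,
       negatives = match.arg(negatives), include_hour = include_hour)
}

system_label <- function(system) if (system == "S1") "label_hypo" else "label_hyper"
cluster_col <- function(system) if (system == "S1") "cluster_s1" else "cluster_s2"

# map a store key to the 0-5 cluster-label feature id
key_to_cluster_id <- function(key) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  as.integer(parts[3]) + if (parts[2] == "nonevent") 3L else 0L
}

# model matrix for a system's classifiers: 13 features + that system's
# cluster-label feature
model_matrix <- function(instances, system, cluster_ids) {
  x <- as.matrix(instances[, ppg_feature_names(), drop = FALSE])
  cbind(x, cluster = as.numeric(cluster_ids))
}

# attach the store's training cluster assignments to an instance table
with_assignments <- function(instances, store) {
  m <- merge(instances, store$assignments, by = c("patient_id", "meal_time"),
             sort = FALSE)
  if (nrow(m) != nrow(instances))
    stop("instances do not match the store's training assignments")
  m[order(m$patient_id, m$meal_time), , drop = FALSE]
}

# randomized hyperparameter search with k-fold CV scored by MCC; returns the
# refitted best model, its out-of-fold scores, and the search record
rf_search <- function(x, y, control, seed, score_metric = "mcc") {
  set.seed(seed)
  grid <- data.frame(
    num.trees = sample(control$trees[1]:control$trees[2], control$n_draws,
                       replace = TRUE),
    max.depth = sample(control$depth[1]:control$depth[2], control$n_draws,
                       replace = TRUE),
    min.node.size = sample(control$min_node[1]:control$min_node[2],
                           control$n_draws, replace = TRUE))
  grid <- unique(grid)
  # stratified fold ids
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(control$cv_folds), length(idx)))
  }
  best <- list(score = -Inf)
  for (g in seq_len(nrow(grid))) {
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(control$cv_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) next
      fit <- ranger::ranger(
        x = x[tr, , drop = FALSE], y = factor(y[tr], levels = c(0, 1)),
        probability = TRUE, num.trees = grid$num.trees[g],
        max.depth = grid$max.depth[g], min.node.size = grid$min.node.size[g],
        seed = derive_seed(seed, "cv", g * 100 + f), num.threads = 1)
      oof[!tr] <- predict(fit, x[!tr, , drop = FALSE],
                          num.threads = 1)$predictions[, "1"]
    }
    ok <- !is.na(oof)
    thr <- if (score_metric == "mcc") mcc_threshold(oof[ok], y[ok])
           else youden_threshold(oof[ok], y[ok])
    score <- if (score_metric == "mcc")
      confusion_metrics(y[ok], as.integer(oof[ok] >= thr))$mcc
    else {
      m <- confusion_metrics(y[ok], as.integer(oof[ok] >= thr))
      m$sensitivity / 100 + m$specificity / 100 - 1
    }
    if (score > best$score)
      best <- list(score = score, params = grid[g, ], threshold = thr,
                   oof = oof)
  }
  final <- ranger::ranger(
    x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
    num.trees = best$params$num.trees, max.depth = best$params$max.depth,
    min.node.size = best$params$min.node.size,
    seed = derive_seed(seed, "final"), num.threads = 1)
  list(model = final, threshold = best$threshold, params = best$params,
       cv_score = best$score, oof = best$oof)
}

#' Train one subgroup classifier
#'
#' A binary event-vs-non-event random forest for one behavioural subgroup:
#' trained on all instances of the subgroup's cluster plus (by default)
#' equally many opposite-label instances nearest the subgroup centroid in
#' normalized feature space (class balancing). Hyperparameters come from a
#' randomized search with cross-validation scored by MCC; the decision
#' threshold maximizes MCC on the out-of-fold scores.
#'
#' @param instances training instances (with assignments merged from the
#'   store; see [build_profile_index()]).
#' @param key store key, e.g. `"S1.event.0"`.
#' @param store the [build_profile_index()] result fitted on these instances.
#' @param seed integer seed.
#' @param control a [ppg_control()].
#' @export
train_subgroup_model <- function(instances, key, store, seed,
                                 control = ppg_control()) {
  system <- strsplit(key, ".", fixed = TRUE)[[1]][1]
  lab <- system_label(system)
  ccol <- cluster_col(system)
  cid <- key_to_cluster_id(key)
  if (!ccol %in% names(instances))
    instances <- with_assignments(instances, store)
  members <- instances[instances[[ccol]] == cid, , drop = FALSE]
  if (nrow(members) < 10)
    stop(sprintf("train_subgroup_model: cluster %s has %d (< 10) instances",
                 key, nrow(members)))
  member_label <- members[[lab]][1]
  opp <- instances[instances[[lab]] != member_label, , drop = FALSE]
  if (control$negatives == "local" && nrow(opp) > nrow(members)) {
    oz <- apply_zstats(as.matrix(opp[, store$features, drop = FALSE]),
                       store$zstats)
    d <- sqrt(rowSums(sweep(oz, 2, store$centroids[key, ])^2))
    opp <- opp[order(d)[seq_len(nrow(members))], , drop = FALSE]
  }
  train <- rbind(members, opp)
  x <- model_matrix(train, system, train[[ccol]])
  y <- train[[lab]]
  fit <- rf_search(x, y, control, derive_seed(seed, key), "mcc")
  structure(list(key = key, system = system, model = fit$model,
                 threshold = fit$threshold, params = fit$params,
                 cv_mcc = fit$cv_score, n_train = nrow(train)),
            class = "ppg_subgroup_model")
}

#' Train one system (S1 or S2) of six subgroup classifiers
#'
#' @param instances training instances.
#' @param system `"S1"` (hypoglycemia) or `"S2"` (hyperglycemia).
#' @param store centroid store fitted on the same training split.
#' @param seed integer seed.
#' @param control a [ppg_control()].
#' @return object of class `ppg_trained_system` holding the six models keyed
#'   like the store.
#' @export
train_system <- function(instances, system, store, seed,
                         control = ppg_control()) {
  instances <- with_assignments(instances, store)
  keys <- store_keys(system)
  models <- lapply(keys, function(k)
    train_subgroup_model(instances, k, store, seed, control))
  names(models) <- keys
  structure(list(system = system, models = models, seed = seed,
                 control = control),
            class = "ppg_trained_system")
}


#' Predict one instance with centroid routing and AND-gate fusion
#'
#' The two centroids of the system nearest the instance select two subgroup
#' models; each votes through its own MCC-optimal threshold; the fused vote
#' is the logical AND of the two votes and the fused continuous score the
#' minimum of the two event probabilities (AND-consistent).
#'
#' @param sys a `ppg_trained_system`.
#' @param store the matching centroid store.
#' @param v named 13-feature vector (or 1-row data.frame).
#' @return list `selected` (2 keys), `probs`, `votes`, `vote` (0/1),
#'   `score`.
#' @export
predict_instance <- function(sys, store, v) {
  v <- unlist(v)[ppg_feature_names()]
  rk <- assign_clusters(store, v, sys$system)
  sel <- rk$key[1:2]
  cid <- key_to_cluster_id(rk$key[1])
  x <- matrix(c(as.numeric(v), cid), nrow = 1,
              dimnames = list(NULL, c(ppg_feature_names(), "cluster")))
  probs <- vapply(sel, function(k)
    predict(sys$models[[k]]$model, x, num.threads = 1)$predictions[, "1"],
    numeric(1))
  votes <- as.integer(probs >= vapply(sel, function(k)
    sys$models[[k]]$threshold, numeric(1)))
  list(selected = sel, probs = probs, votes = votes,
       vote = as.integer(all(votes == 1)), score = min(probs))
}

# vectorized routed prediction over an instance table: squared distances to
# the system's six centroids in one matrix product, then one batched forest
# predict per model
predict_system_table <- function(sys, store, instances) {
  n <- nrow(instances)
  keys <- store_keys(sys$system)
  xz <- apply_zstats(as.matrix(instances[, store$features, drop = FALSE]),
                    store$zstats)
  cent <- store$centroids[keys, , drop = FALSE]
  d2 <- matrix(rowSums(xz^2), n, 6) - 2 * xz %*% t(cent) +
    matrix(rowSums(cent^2), n, 6, byrow = TRUE)
  # top-2 with stable key-order tie break (max.col "first" on negated d2)
  i1 <- max.col(-d2, ties.method = "first")
  d2_masked <- d2
  d2_masked[cbind(seq_len(n), i1)] <- Inf
  i2 <- max.col(-d2_masked, ties.method = "first")
  inst_cl <- vapply(keys[i1], key_to_cluster_id, integer(1))
  x <- model_matrix(instances, sys$system, inst_cl)
  probs_all <- sapply(sys$models, function(m)
    predict(m$model, x, num.threads = 1)$predictions[, "1"])
  if (is.null(dim(probs_all)))
    probs_all <- matrix(probs_all, nrow = 1,
                        dimnames = list(NULL, names(sys$models)))
  thr <- vapply(sys$models, function(m) m$threshold, numeric(1))
  p1 <- probs_all[cbind(seq_len(n), i1)]
  p2 <- probs_all[cbind(seq_len(n), i2)]
  vote <- as.integer(p1 >= thr[i1] & p2 >= thr[i2])
  data.frame(vote = vote, score = pmin(p1, p2), key1 = keys[i1],
             key2 = keys[i2], stringsAsFactors = FALSE)
}

#' Fit the dual postprandial glycemic-event prediction system
#'
#' The package's central model fit: builds the 12-centroid glycemic profile
#' index on the training instances (SOM + k-means per event-label subset)
#' and trains the two systems of six subgroup random forests (S1:
#' hypoglycemia, S2: hyperglycemia). Prediction routes each instance to the
#' two nearest subgroup centroids per system and fuses the two model votes
#' with an AND gate.
#'
#' @param data meal-instance data.frame from [build_dataset()].
#' @param seed integer master seed (profiling and each model derive their own
#'   stream from it).
#' @param control a [ppg_control()].
#' @return object of class `ppg_system` with elements `store`, `systems`
#'   (list `S1`, `S2`), `control`, `seed`, `call`.
#' @seealso [predict.ppg_system()], [run_protocol()]
#' @export
ppg_system <- function(data, seed = 1, control = ppg_control()) {
  stopifnot(all(c(ppg_feature_names(), "label_hypo", "label_hyper")
                %in% names(data)))
  store <- build_profile_index(data, seed = derive_seed(seed, "profile"),
                               k = control$k,
                               include_hour = control$include_hour,
                               som_epochs = control$som_epochs)
  systems <- list(
    S1 = train_system(data, "S1", store, derive_seed(seed, "S1"), control),
    S2 = train_system(data, "S2", store, derive_seed(seed, "S2"), control))
  structure(list(store = store, systems = systems, control = control,
                 seed = seed, n = nrow(data), call = match.call()),
            class = "ppg_system")
}

#' @export
print.ppg_system <- function(x, ...) {
  cat("Dual postprandial glycemic-event prediction system\n")
  cat(sprintf("  fitted on %d meal instances (seed %d)\n", x$n, x$seed))
  cat(sprintf("  profile index: %d centroids (k = %d per subset)\n",
              nrow(x$store$centroids), x$store$k))
  for (s in c("S1", "S2"))
    cat(sprintf("  %s (%s): 6 subgroup RFs, median CV MCC %.2f\n", s,
                if (s == "S1") "hypoglycemia" else "hyperglycemia",
                median(vapply(x$systems[[s]]$models, `[[`, 0, "cv_mcc"))))
  invisible(x)
}

#' @export
summary.ppg_system <- function(object, ...) {
  rows <- do.call(rbind, lapply(c("S1", "S2"), function(s)
    do.call(rbind, lapply(object$systems[[s]]$models, function(m)
      data.frame(key = m$key, n_train = m$n_train,
                 num_trees = m$params$num.trees,
                 max_depth = m$params$max.depth,
                 min_node = m$params$min.node.size,
                 threshold = m$threshold, cv_mcc = m$cv_mcc)))))
  rownames(rows) <- NULL
  structure(list(models = rows, n = object$n, seed = object$seed),
            class = "summary.ppg_system")
}

#' @export
print.summary.ppg_system <- function(x, ...) {
  cat(sprintf("ppg_system fitted on %d instances (seed %d)\n\n", x$n, x$seed))
  print(x$models, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predict glycemic events for new meal instances
#'
#' @param object a fitted [ppg_system()].
#' @param newdata data.frame with the 13 feature columns.
#' @param target `"hypo"` (system S1), `"hyper"` (S2) or `"both"`.
#' @param type `"vote"` for fused binary votes, `"score"` for the fused
#'   continuous score (min of the two routed probabilities), `"full"` for
#'   votes, scores and routed keys.
#' @param ... unused.
#' @export
predict.ppg_system <- function(object, newdata,
                               target = c("both", "hypo", "hyper"),
                               type = c("vote", "score", "full"), ...) {
  target <- match.arg(target); type <- match.arg(type)
  systems <- switch(target, both = c("S1", "S2"), hypo = "S1", hyper = "S2")
  out <- lapply(systems, function(s)
    predict_system_table(object$systems[[s]], object$store, newdata))
  names(out) <- systems
  if (type == "full") return(if (length(out) == 1) out[[1]] else out)
  col <- if (type == "vote") "vote" else "score"
  res <- sapply(out, function(d) d[[col]])
  if (is.null(dim(res))) res <- matrix(res, nrow = nrow(newdata),
                                       dimnames = list(NULL, systems))
  if (length(systems) == 1) drop(res) else res
}

#' Train a no-clustering baseline classifier
#'
#' A single random forest on the 13 raw features (no cluster feature) with
#' the same randomized hyperparameter search; its decision threshold
#' maximizes Youden's J on out-of-fold scores.
#'
#' @param instances training instances.
#' @param target `"hypo"` or `"hyper"`.
#' @param seed integer seed.
#' @param control a [ppg_control()].
#' @export
train_baseline <- function(instances, target = c("hypo", "hyper"), seed = 1,
                           control = ppg_control()) {
  target <- match.arg(target)
  lab <- if (target == "hypo") "label_hypo" else "label_hyper"
  x <- as.matrix(instances[, ppg_feature_names(), drop = FALSE])
  y <- instances[[lab]]
  fit <- rf_search(x, y, control, derive_seed(seed, paste0("baseline.", target)),
                   "youden")
  structure(list(target = target, model = fit$model,
                 threshold = fit$threshold, params = fit$params),
            class = "ppg_baseline")
}

predict_baseline <- function(baseline, instances) {
  x <- as.matrix(instances[, ppg_feature_names(), drop = FALSE])
  p <- predict(baseline$model, x, num.threads = 1)$predictions[, "1"]
  data.frame(vote = as.integer(p >= baseline$threshold), score = p)
}

eval_metrics <- function(y, vote, score) {
  m <- confusion_metrics(y, vote)
  auc <- if (length(unique(y)) == 2) roc_auc(score, y)$auc else NA_real_
  c(accuracy = m$accuracy, mcc = m$mcc, sensitivity = m$sensitivity,
    specificity = m$specificity, auc = auc)
}

#' Repeated stratified split evaluation protocol
#'
#' Per iteration: a stratified 90/10 train-test split; the profile index,
#' both systems and both baselines are fitted on the training split only and
#' evaluated on the held-out split. Stratification is on the joint
#' (hypo, hyper) label combination, preserving both event prevalences. If a
#' split misses a class it is resampled (max 5 retries). Summary values are
#' per-metric medians over the iterations.
#'
#' @param dataset meal-instance data.frame from [build_dataset()].
#' @param n_iter number of iterations (default 20).
#' @param test_frac held-out fraction (default 0.1).
#' @param seed integer master seed.
#' @param control a [ppg_control()].
#' @return object of class `ppg_protocol`: `per_iteration` (long data.frame
#'   of metrics per model per iteration) and `medians`.
#' @export
run_protocol <- function(dataset, n_iter = 20, test_frac = 0.1, seed = 1,
                         control = ppg_control()) {
  stopifnot(length(unique(dataset$label_hypo)) == 2,
            length(unique(dataset$label_hyper)) == 2)
  strata <- interaction(dataset$label_hypo, dataset$label_hyper, drop = TRUE)
  rows <- list()
  for (it in seq_len(n_iter)) {
    set.seed(derive_seed(seed, "split", it))
    for (retry in 1:5) {
      test_idx <- unlist(lapply(split(seq_len(nrow(dataset)), strata),
                                function(idx) {
        n_test <- max(1, round(length(idx) * test_frac))
        sample(idx, min(n_test, length(idx)))
      }))
      train <- dataset[-test_idx, , drop = FALSE]
      test <- dataset[test_idx, , drop = FALSE]
      ok <- all(vapply(c("label_hypo", "label_hyper"), function(l)
        length(unique(train[[l]])) == 2 && length(unique(test[[l]])) == 2,
        logical(1)))
      if (ok) break
      message(sprintf("iteration %d: class missing from split, resampling", it))
    }
    # leakage guard: train/test instance ids disjoint
    id <- function(d) paste(d$patient_id, format(d$meal_time))
    stopifnot(length(intersect(id(train), id(test))) == 0)

    fit <- ppg_system(train, seed = derive_seed(seed, "fit", it), control)
    b_hypo <- train_baseline(train, "hypo", derive_seed(seed, "bh", it), control)
    b_hyper <- train_baseline(train, "hyper", derive_seed(seed, "bH", it), control)

    pr <- predict(fit, test, type = "full")
    bh <- predict_baseline(b_hypo, test)
    bH <- predict_baseline(b_hyper, test)
    res <- rbind(
      data.frame(iteration = it, model = "S1",
                 t(eval_metrics(test$label_hypo, pr$S1$vote, pr$S1$score))),
      data.frame(iteration = it, model = "baseline_hypo",
                 t(eval_metrics(test$label_hypo, bh$vote, bh$score))),
      data.frame(iteration = it, model = "S2",
                 t(eval_metrics(test$label_hyper, pr$S2$vote, pr$S2$score))),
      data.frame(iteration = it, model = "baseline_hyper",
                 t(eval_metrics(test$label_hyper, bH$vote, bH$score))))
    rows[[it]] <- res
  }
  per_iter <- do.call(rbind, rows)
  med <- aggregate(per_iter[, c("accuracy", "mcc", "sensitivity",
                                "specificity", "auc")],
                   by = list(model = per_iter$model), FUN = median)
  structure(list(per_iteration = per_iter, medians = med, n_iter = n_iter,
                 seed = seed),
            class = "ppg_protocol")
}

#' @export
print.ppg_protocol <- function(x, ...) {
  cat(sprintf("Repeated-split evaluation (%d iterations), median metrics:\n",
              x$n_iter))
  print(x$medians, row.names = FALSE, digits = 3)
  invisible(x)
}
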