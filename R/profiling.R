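# Two-stage glycemic profiling: per-label-subset SOM training, k-means over
# the SOM prototypes, a 12-centroid store, and nearest-centroid assignment.

#' Train a self-organizing map
#'
#' Standard online SOM on a rectangular grid: Gaussian neighbourhood,
#' exponentially decaying learning rate and radius, weights initialised by
#' seeded uniform sampling within each dimension's data range. Sample
#' presentation order is reshuffled every epoch from the seeded stream.
#'
#' @param x numeric matrix (rows = samples) or data.frame of the clustering
#'   features.
#' @param grid_rows,grid_cols grid dimensions (default 10 x 10).
#' @param epochs number of passes over the data.
#' @param lr learning-rate schedule `c(start, end)`.
#' @param radius neighbourhood-radius schedule `c(start, end)`.
#' @param seed integer seed.
#' @return object of class `som_grid` with the `(grid_rows*grid_cols) x d`
#'   weight matrix (`weights`; unit k = row*cols + col, 0-based) and training
#'   metadata.
#' @export
train_som <- function(x, grid_rows = 10, grid_cols = 10, epochs = 500,
                      lr = c(0.5, 0.01), radius = c(5, 1), seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n == 0) stop("train_som: empty input")
  if (n < 100) warning("train_som: fewer than 100 training vectors")
  set.seed(seed)
  rng <- apply(x, 2, range)
  w0 <- matrix(runif(grid_rows * grid_cols * ncol(x)),
               grid_rows * grid_cols, ncol(x))
  w0 <- sweep(sweep(w0, 2, rng[2, ] - rng[1, ], "*"), 2, rng[1, ], "+")
  order0 <- unlist(lapply(seq_len(epochs), function(e) sample.int(n))) - 1L
  w <- cpp_som_train(x, grid_rows, grid_cols, order0, lr[1], lr[2],
                     radius[1], radius[2], w0)
  colnames(w) <- colnames(x)
  structure(list(weights = w, grid_rows = grid_rows, grid_cols = grid_cols,
                 meta = list(epochs = epochs, lr = lr, radius = radius,
                             seed = seed, n = n)),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("<som_grid> %dx%d, %d-dim, %d epochs\n", x$grid_rows,
              x$grid_cols, ncol(x$weights), x$meta$epochs))
  invisible(x)
}

#' Best-matching unit of a SOM
#'
#' @param som a `som_grid`.
#' @param v feature vector (dimension must match the map).
#' @return integer `c(row, col)`, 0-based; Euclidean argmin with ties broken
#'   by the smallest (row, col) lexicographically.
#' @export
best_matching_unit <- function(som, v) {
  if (length(v) != ncol(som$weights))
    stop("best_matching_unit: dimension mismatch")
  d2 <- rowSums(sweep(som$weights, 2, as.numeric(v))^2)
  k <- which.min(d2) - 1L   # which.min takes the first (lexicographic) min
  c(row = k %/% som$grid_cols, col = k %% som$grid_cols)
}

#' Select the number of k-means clusters over SOM prototypes
#'
#' Returns the silhouette-score argmax over `k_range`; the elbow diagnostic
#' (within-cluster SSE per k) is attached as attribute `elbow`. Degenerate
#' prototype sets (zero variance) fall back to `fallback_k` with a warning.
#' The default profiling pipeline pins k = 3 and keeps this as a diagnostic.
#'
#' @param prototypes matrix of SOM weight vectors.
#' @param k_range candidate cluster counts.
#' @param seed seed for the k-means restarts.
#' @param fallback_k value returned for degenerate input.
#' @export
choose_k <- function(prototypes, k_range = 2:8, seed = 1, fallback_k = 3) {
  prototypes <- as.matrix(prototypes)
  if (nrow(unique(prototypes)) <= max(k_range)) {
    warning("choose_k: degenerate prototypes; falling back to k = ", fallback_k)
    return(fallback_k)
  }
  d <- dist(prototypes)
  sil <- sse <- setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    set.seed(seed)
    km <- kmeans(prototypes, centers = k_range[i], nstart = 10, iter.max = 50)
    sse[i] <- km$tot.withinss
    sil[i] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }
  k <- k_range[which.max(sil)]
  attr(k, "elbow") <- data.frame(k = k_range, sse = sse, silhouette = sil)
  k
}

# z-scoring helpers shared by store and classifiers
fit_zstats <- function(x) {
  m <- colMeans(x); s <- apply(x, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(mean = m, sd = s)
}
apply_zstats <- function(x, z) {
  if (is.null(dim(x))) (x - z$mean) / z$sd
  else sweep(sweep(x, 2, z$mean), 2, z$sd, "/")
}

# fixed key order: event clusters before non-event, then cluster index
store_keys <- function(system) {
  paste0(system, ".", rep(c("event", "nonevent"), each = 3), ".", 0:2)
}

#' Build the 12-centroid glycemic profile index
#'
#' Training instances are split into four subsets by event label
#' (hypoglycemia / non-hypoglycemia for system S1, hyperglycemia /
#' non-hyperglycemia for S2). Features are z-scored (statistics fitted on the
#' full training set and stored for inference), a SOM is trained per subset,
#' k-means (seeded, 10 restarts) clusters each map's prototype weights, and
#' each cluster's centroid (the mean of its member prototypes) is stored.
#' With k = 3 this yields twelve behavioural-subgroup centroids, six per
#' system. Cluster ids within a subset are canonicalised by sorting centroids
#' lexicographically.
#'
#' @param instances data.frame from [build_dataset()].
#' @param seed integer seed.
#' @param k clusters per subset (default 3).
#' @param include_hour include the meal-hour feature in the clustering vector
#'   (default FALSE: the 12 continuous features are used).
#' @param som_epochs SOM epochs per subset.
#' @return object of class `centroid_store`: normalized-space centroid matrix
#'   (rows keyed `<system>.<event|nonevent>.<cluster>`), the z statistics, and
#'   per-instance training cluster assignments (`cluster_s1`, `cluster_s2`,
#'   each 0-5: event clusters 0-2, non-event 3-5).
#' @export
build_profile_index <- function(instances, seed = 1, k = 3,
                                include_hour = FALSE, som_epochs = 500) {
  feats <- ppg_cluster_features(include_hour)
  ord <- order(instances$patient_id, instances$meal_time)
  instances <- instances[ord, , drop = FALSE]
  x <- as.matrix(instances[, feats, drop = FALSE])
  z <- fit_zstats(x)
  xz <- apply_zstats(x, z)

  subsets <- list(S1.event = instances$label_hypo == 1,
                  S1.nonevent = instances$label_hypo == 0,
                  S2.event = instances$label_hyper == 1,
                  S2.nonevent = instances$label_hyper == 0)
  centroids <- matrix(NA_real_, 0, length(feats))
  assign_s1 <- rep(NA_integer_, nrow(instances))
  assign_s2 <- rep(NA_integer_, nrow(instances))
  for (nm in names(subsets)) {
    idx <- which(subsets[[nm]])
    if (length(idx) == 0) stop("build_profile_index: empty subset ", nm)
    som <- train_som(xz[idx, , drop = FALSE], epochs = som_epochs,
                     seed = derive_seed(seed, nm))
    set.seed(derive_seed(seed, paste0(nm, ".kmeans")))
    km <- kmeans(som$weights, centers = min(k, nrow(unique(som$weights))),
                 nstart = 10, iter.max = 100)
    cent <- km$centers
    relabel <- order(apply(cent, 1, paste, collapse = ","))
    cent <- cent[relabel, , drop = FALSE]
    # instance -> BMU prototype -> prototype's k-means cluster
    proto_cluster <- match(km$cluster, relabel) - 1L
    bmu_idx <- apply(xz[idx, , drop = FALSE], 1, function(v)
      which.min(rowSums(sweep(som$weights, 2, v)^2)))
    cl <- proto_cluster[bmu_idx]
    offset <- if (grepl("nonevent", nm)) 3L else 0L
    if (startsWith(nm, "S1")) assign_s1[idx] <- cl + offset
    else assign_s2[idx] <- cl + offset
    rownames(cent) <- paste0(nm, ".", seq_len(nrow(cent)) - 1L)
    centroids <- rbind(centroids, cent)
  }
  centroids <- centroids[c(store_keys("S1"), store_keys("S2")), , drop = FALSE]
  structure(list(centroids = centroids, zstats = z, features = feats,
                 assignments = data.frame(patient_id = instances$patient_id,
                                          meal_time = instances$meal_time,
                                          cluster_s1 = assign_s1,
                                          cluster_s2 = assign_s2),
                 k = k, seed = seed),
            class = "centroid_store")
}

#' @export
print.centroid_store <- function(x, ...) {
  cat(sprintf("<centroid_store> %d centroids over %d features (k = %d)\n",
              nrow(x$centroids), length(x$features), x$k))
  invisible(x)
}

#' Rank a system's centroids by distance to an instance
#'
#' The six centroids of the named system, ranked ascending by Euclidean
#' distance in the store's normalized feature space. Ties keep the fixed key
#' order (event clusters before non-event, then cluster index).
#'
#' @param store a `centroid_store`.
#' @param v named feature vector (raw scale; the full 13 features or at least
#'   the store's clustering features) or a 1-row data.frame.
#' @param system `"S1"` or `"S2"`.
#' @return data.frame `key`, `distance` (6 rows, non-decreasing distance).
#' @export
assign_clusters <- function(store, v, system = c("S1", "S2")) {
  system <- match.arg(system)
  v <- unlist(v)
  if (!all(store$features %in% names(v)))
    stop("assign_clusters: feature names missing from input vector")
  if (!is.na(v["cgm_at_meal"]) && v["cgm_at_meal"] < 20)
    stop("assign_clusters: input looks already normalized (cgm_at_meal < 20 mg/dL); pass raw-scale features")
  vz <- apply_zstats(as.numeric(v[store$features]),
                     list(mean = store$zstats$mean, sd = store$zstats$sd))
  keys <- store_keys(system)
  cent <- store$centroids[keys, , drop = FALSE]
  d <- sqrt(rowSums(sweep(cent, 2, vz)^2))
  ord <- order(d)  # stable: ties keep key order
  data.frame(key = keys[ord], distance = unname(d[ord]),
             stringsAsFactors = FALSE)
}
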