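test_that("a SOM trained on identical vectors collapses onto that vector", {
  v <- c(1.5, -2, 0.5)
  x <- matrix(rep(v, each = 60), 60, 3)
  som <- train_som(x, epochs = 300, seed = 4)
  expect_lt(max(abs(sweep(som$weights, 2, v))), 1e-6)
})

test_that("SOM training is deterministic under a fixed seed", {
  set.seed(10)
  x <- matrix(rnorm(150 * 4), 150, 4)
  w1 <- train_som(x, epochs = 30, seed = 8)$weights
  w2 <- train_som(x, epochs = 30, seed = 8)$weights
  expect_identical(w1, w2)
  expect_error(train_som(x[0, , drop = FALSE]), "empty")
})

test_that("best-matching unit is the Euclidean argmin with lexicographic ties", {
  som <- structure(list(weights = matrix(0, 100, 2), grid_rows = 10,
                        grid_cols = 10), class = "som_grid")
  som$weights[3 * 10 + 4 + 1, ] <- c(5, 5)     # neuron (3,4)
  expect_equal(unname(best_matching_unit(som, c(5, 5))), c(3, 4))
  # two equidistant non-zero neurons: (1,9) beats (2,0)
  som2 <- structure(list(weights = matrix(10, 100, 2), grid_rows = 10,
                         grid_cols = 10), class = "som_grid")
  som2$weights[1 * 10 + 9 + 1, ] <- c(1, 1)
  som2$weights[2 * 10 + 0 + 1, ] <- c(1, 1)
  expect_equal(unname(best_matching_unit(som2, c(0, 0))), c(1, 9))
  expect_error(best_matching_unit(som, c(1, 2, 3)), "dimension")
})

test_that("returned BMU distance is minimal over all neurons", {
  set.seed(2)
  x <- matrix(rnorm(120 * 3), 120, 3)
  som <- train_som(x, epochs = 20, seed = 2)
  for (i in 1:5) {
    v <- rnorm(3)
    bmu <- best_matching_unit(som, v)
    k <- bmu[1] * som$grid_cols + bmu[2] + 1
    d2 <- rowSums(sweep(som$weights, 2, v)^2)
    expect_equal(d2[k], min(d2))
  }
})

test_that("choose_k finds the planted blob count by silhouette", {
  set.seed(31)
  blobs <- function(k, n = 40, sep = 8)
    do.call(rbind, lapply(seq_len(k), function(g)
      matrix(rnorm(n * 2), n, 2) + sep * g))
  expect_equal(as.integer(choose_k(blobs(3), seed = 1)), 3L)
  expect_equal(as.integer(choose_k(blobs(2), seed = 1)), 2L)
  expect_warning(k <- choose_k(matrix(1, 50, 2)), "degenerate")
  expect_equal(k, 3)
  expect_true(all(c("sse", "silhouette") %in%
                    names(attr(choose_k(blobs(3), seed = 1), "elbow"))))
})

test_that("the profile index always holds 12 centroids, 3 per subset", {
  store <- memo("small_store",
                build_profile_index(small_instances(), seed = 5,
                                    som_epochs = 60))
  expect_equal(nrow(store$centroids), 12)
  keys <- rownames(store$centroids)
  for (s in c("S1", "S2")) for (cl in c("event", "nonevent"))
    expect_equal(sum(startsWith(keys, paste(s, cl, sep = "."))), 3)
  expect_false(any(is.na(store$assignments$cluster_s1)))
  expect_true(all(store$assignments$cluster_s1 %in% 0:5))
})

test_that("the profile index is reproducible and fails on an empty subset", {
  inst <- small_instances()
  s1 <- build_profile_index(inst, seed = 5, som_epochs = 30)
  s2 <- build_profile_index(inst, seed = 5, som_epochs = 30)
  expect_identical(s1$centroids, s2$centroids)
  inst_no_event <- inst[inst$label_hypo == 0, ]
  expect_error(build_profile_index(inst_no_event, seed = 5, som_epochs = 30),
               "S1.event")
})

test_that("planted subgroups are recovered by the SOM + k-means pipeline", {
  inst <- planted_instances(n_per = 30, sep = 4, seed = 21)
  store <- build_profile_index(inst, seed = 9, som_epochs = 120)
  merged <- merge(inst, store$assignments, by = c("patient_id", "meal_time"))
  # within each (system, event-class) subset, the dominant permutation of
  # planted subgroup -> cluster id must cover >= 90% of instances
  recovery <- function(cl, subgroup) {
    tab <- table(subgroup, cl)
    hit <- 0
    for (g in rownames(tab)) hit <- hit + max(tab[g, ])
    hit / length(cl)
  }
  for (lab in c("label_hypo", "label_hyper")) {
    ccol <- if (lab == "label_hypo") "cluster_s1" else "cluster_s2"
    for (y in 0:1) {
      sel <- merged[[lab]] == y
      expect_gte(recovery(merged[[ccol]][sel], merged$subgroup[sel]), 0.9)
    }
  }
})

test_that("centroid ranking is a complete, sorted permutation of the system keys", {
  store <- memo("small_store",
                build_profile_index(small_instances(), seed = 5,
                                    som_epochs = 60))
  v <- unlist(small_instances()[4, ppgs:::ppg_feature_names()])
  for (s in c("S1", "S2")) {
    rk <- assign_clusters(store, v, s)
    expect_setequal(rk$key, ppgs:::store_keys(s))
    expect_true(all(diff(rk$distance) >= 0))
  }
})

test_that("a vector equal to a stored centroid ranks first at distance zero", {
  store <- memo("small_store",
                build_profile_index(small_instances(), seed = 5,
                                    som_epochs = 60))
  cz <- store$centroids["S1.event.1", ]
  raw <- cz * store$zstats$sd + store$zstats$mean  # undo normalization
  raw <- c(raw, meal_hour = 12)
  rk <- assign_clusters(store, raw, "S1")
  expect_equal(rk$key[1], "S1.event.1")
  expect_lt(rk$distance[1], 1e-8)
})

test_that("already-normalized inputs are rejected", {
  store <- memo("small_store",
                build_profile_index(small_instances(), seed = 5,
                                    som_epochs = 60))
  vz <- setNames(rep(0, 13), ppgs:::ppg_feature_names())
  expect_error(assign_clusters(store, vz, "S1"), "normalized")
})
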