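# Model-agnostic attribution: exact Shapley values by subset enumeration,
# pairwise Shapley interaction values, LIME local surrogates, and the
# aggregation views used for reporting.

# value function table: v[mask+1] = mean_b f(x_S, b_{N\S}) over the
# background sample (marginal/interventional expectation); mask bit i-1 set
# <=> feature i comes from x
subset_value_table <- function(predict_fun, x, background, chunk = 512) {
  d <- length(x)
  background <- as.matrix(background)
  if (nrow(background) == 0) stop("background must be non-empty")
  if (ncol(background) != d) stop("background dimension mismatch")
  nb <- nrow(background)
  n_masks <- 2^d
  v <- numeric(n_masks)
  masks <- 0:(n_masks - 1)
  bit <- function(mask, i) bitwAnd(mask, bitwShiftL(1L, i - 1L)) > 0
  for (start in seq(1, n_masks, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_masks)
    big <- background[rep(seq_len(nb), length(idx)), , drop = FALSE]
    for (k in seq_along(idx)) {
      m <- masks[idx[k]]
      rows <- ((k - 1) * nb + 1):(k * nb)
      for (i in seq_len(d)) if (bit(m, i)) big[rows, i] <- x[i]
    }
    preds <- predict_fun(big)
    v[idx] <- colMeans(matrix(preds, nrow = nb))
  }
  v
}

#' Exact Shapley values
#'
#' Exhaustive subset enumeration of the Shapley value
#' \eqn{\phi_i = \sum_{S \subseteq N\setminus\{i\}}
#' \frac{|S|!(|N|-|S|-1)!}{|N|!}[f(S\cup\{i\}) - f(S)]}, where \eqn{f(S)} is
#' the model's mean prediction with off-subset features replaced by
#' background-sample values (marginal expectation). Limited to 16 features
#' in exact mode.
#'
#' @param predict_fun function taking a numeric matrix (one row per
#'   instance) and returning a numeric score per row.
#' @param x named numeric feature vector to explain.
#' @param background matrix/data.frame of reference rows (same columns).
#' @return object of class `shapley_attribution`: `phi` (named), `base`
#'   (mean background prediction), `fx` (prediction at x). Efficiency
#'   `base + sum(phi) = fx` holds to numerical precision.
mask_sizes <- function(d) {
  masks <- 0:(2^d - 1)
  vapply(masks, function(m)
    sum(bitwAnd(m, bitwShiftL(1L, 0:(d - 1))) > 0), integer(1))
}

phi_from_table <- function(v, d, feature_names = NULL) {
  wt <- factorial(0:(d - 1)) * factorial(d - 1 - 0:(d - 1)) / factorial(d)
  masks <- 0:(2^d - 1)
  sizes <- mask_sizes(d)
  phi <- numeric(d)
  for (i in seq_len(d)) {
    b <- bitwShiftL(1L, i - 1L)
    no_i <- masks[bitwAnd(masks, b) == 0]
    s <- sizes[no_i + 1]
    phi[i] <- sum(wt[s + 1] * (v[bitwOr(no_i, b) + 1] - v[no_i + 1]))
  }
  names(phi) <- feature_names
  structure(list(phi = phi, base = v[1], fx = v[2^d]),
            class = "shapley_attribution")
}

#' @export
shapley_values <- function(predict_fun, x, background) {
  d <- length(x)
  if (d > 16)
    stop("shapley_values: > 16 features; use shapley_sampling() instead")
  v <- subset_value_table(predict_fun, x, as.matrix(background))
  phi_from_table(v, d, names(x))
}

#' @export
print.shapley_attribution <- function(x, ...) {
  cat(sprintf("<shapley_attribution> f(x) = %.4f, base = %.4f\n", x$fx, x$base))
  print(round(sort(x$phi, decreasing = TRUE), 4))
  invisible(x)
}

#' Monte-Carlo permutation Shapley estimator
#'
#' Seeded permutation sampling for feature counts beyond exact enumeration;
#' also serves as an independent cross-check of the exact values.
#'
#' @inheritParams shapley_values
#' @param n_perm number of sampled permutations.
#' @param seed integer seed.
#' @export
shapley_sampling <- function(predict_fun, x, background, n_perm = 200,
                             seed = 1) {
  d <- length(x)
  background <- as.matrix(background)
  nb <- nrow(background)
  set.seed(seed)
  phi <- numeric(d)
  for (p in seq_len(n_perm)) {
    perm <- sample.int(d)
    cur <- background
    prev <- mean(predict_fun(cur))
    for (i in perm) {
      cur[, i] <- x[i]
      val <- mean(predict_fun(cur))
      phi[i] <- phi[i] + (val - prev)
      prev <- val
    }
  }
  phi <- phi / n_perm
  names(phi) <- names(x)
  structure(list(phi = phi,
                 base = mean(predict_fun(background)),
                 fx = as.numeric(predict_fun(matrix(x, 1)))),
            class = "shapley_attribution")
}

#' Exact pairwise Shapley interaction values
#'
#' The pairwise interaction of features i, j is
#' \eqn{\sum_{S \subseteq N \setminus \{i,j\}} \frac{|S|!(|N|-|S|-2)!}{|N|!}
#' [f(S\cup\{i,j\}) - f(S\cup\{i\}) - f(S\cup\{j\}) + f(S)]}. The returned
#' matrix follows the additive-decomposition convention: each pairwise
#' effect is split across its two symmetric cells and the diagonal holds the
#' main effect (the Shapley value minus the feature's interaction shares),
#' so every row sums to the feature's Shapley value.
#'
#' @inheritParams shapley_values
#' @return object of class `shapley_interactions`: `matrix` (d x d,
#'   symmetric), `pairwise` (the raw pairwise values), and the
#'   `shapley_attribution`.
#' @export
shapley_interactions <- function(predict_fun, x, background) {
  d <- length(x)
  if (d > 16) stop("shapley_interactions: > 16 features in exact mode")
  v <- subset_value_table(predict_fun, x, as.matrix(background))
  interactions_from_table(v, d, names(x))
}

interactions_from_table <- function(v, d, feature_names = NULL) {
  attr_x <- phi_from_table(v, d, feature_names)
  masks <- 0:(2^d - 1)
  sizes <- mask_sizes(d)
  wt2 <- if (d >= 2)
    factorial(0:(d - 2)) * factorial(d - 2 - 0:(d - 2)) / factorial(d)
  else numeric(0)
  eps <- matrix(0, d, d)
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    bi <- bitwShiftL(1L, i - 1L); bj <- bitwShiftL(1L, j - 1L)
    no_ij <- masks[bitwAnd(masks, bitwOr(bi, bj)) == 0]
    s <- sizes[no_ij + 1]
    term <- v[bitwOr(no_ij, bitwOr(bi, bj)) + 1] - v[bitwOr(no_ij, bi) + 1] -
      v[bitwOr(no_ij, bj) + 1] + v[no_ij + 1]
    eps[i, j] <- eps[j, i] <- sum(wt2[s + 1] * term)
  }
  m <- eps / 2
  diag(m) <- attr_x$phi - rowSums(m)
  dimnames(m) <- dimnames(eps) <- list(feature_names, feature_names)
  structure(list(matrix = m, pairwise = eps, attribution = attr_x),
            class = "shapley_interactions")
}

#' @export
print.shapley_interactions <- function(x, ...) {
  cat("<shapley_interactions>\n")
  print(round(x$matrix, 4))
  invisible(x)
}

#' LIME local surrogate explanation
#'
#' Perturbs the instance with Gaussian noise (per-feature scales, normally
#' the training-set standard deviations), weights perturbations by the
#' proximity kernel \eqn{\pi(x, z) = \exp(-d^2/w^2)} (Euclidean distance on
#' the scale-standardized features), and fits a weighted ridge regression as
#' the interpretable surrogate; the ridge penalty realizes the complexity
#' term. All features are retained (no K-sparsity) so they can be ranked.
#'
#' @inheritParams shapley_values
#' @param feature_sd per-feature perturbation scales (training sds); must be
#'   strictly positive.
#' @param n_samples number of perturbations (>= 50).
#' @param kernel_width proximity kernel width on the standardized scale
#'   (default `0.75 * sqrt(d)`).
#' @param lambda ridge penalty.
#' @param seed integer seed.
#' @return object of class `lime_surrogate`: `intercept`, `weights` (raw
#'   feature scale), `importance_rank` (1 = most important by |weight *
#'   sd|), `r2` (weighted fit quality), and the settings.
#' @export
lime_explain <- function(predict_fun, x, feature_sd, n_samples = 1000,
                         kernel_width = NULL, lambda = 1e-2, seed = 1) {
  d <- length(x)
  stopifnot(length(feature_sd) == d, n_samples >= 50)
  if (any(feature_sd <= 0 | !is.finite(feature_sd)))
    stop("lime_explain: degenerate perturbation variance")
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(d)
  set.seed(seed)
  u <- matrix(rnorm(n_samples * d), n_samples, d)    # standardized offsets
  z <- sweep(sweep(u, 2, feature_sd, "*"), 2, as.numeric(x), "+")
  colnames(z) <- names(x)
  y <- predict_fun(z)
  w <- exp(-rowSums(u^2) / kernel_width^2)
  # weighted ridge with unpenalized intercept, on the standardized scale
  um <- cbind(1, u)
  a <- crossprod(um * w, um)
  diag(a)[-1] <- diag(a)[-1] + lambda
  beta <- solve(a, crossprod(um * w, y))
  yhat <- um %*% beta
  r2 <- 1 - sum(w * (y - yhat)^2) / max(sum(w * (y - weighted.mean(y, w))^2),
                                        .Machine$double.eps)
  weights <- beta[-1] / feature_sd          # back to the raw feature scale
  names(weights) <- names(x)
  imp <- abs(beta[-1])                      # standardized-scale magnitude
  structure(list(intercept = beta[1] - sum(weights * x), weights = weights,
                 importance_rank = setNames(rank(-imp, ties.method = "first"),
                                            names(x)),
                 r2 = r2, kernel_width = kernel_width, n_samples = n_samples,
                 lambda = lambda, seed = seed),
            class = "lime_surrogate")
}

#' @export
print.lime_surrogate <- function(x, ...) {
  cat(sprintf("<lime_surrogate> local R2 %.3f (n = %d, kernel %.2f)\n",
              x$r2, x$n_samples, x$kernel_width))
  print(round(sort(x$weights, decreasing = TRUE), 4))
  invisible(x)
}

#' Aggregate attribution tables across models and iterations
#'
#' Produces the two reporting views: mean Shapley value per feature per
#' (model, iteration), and mean LIME importance rank per feature per
#' cluster.
#'
#' @param shap optional data.frame with columns `model`, `iteration`,
#'   `feature`, `phi` (one row per explained instance and feature).
#' @param lime optional data.frame with columns `cluster`, `feature`,
#'   `rank`.
#' @return list with `shap_summary` (mean phi per feature x model x
#'   iteration) and `lime_ranks` (feature x cluster matrix of mean ranks).
#' @export
aggregate_attributions <- function(shap = NULL, lime = NULL) {
  out <- list()
  if (!is.null(shap)) {
    stopifnot(all(c("model", "iteration", "feature", "phi") %in% names(shap)))
    out$shap_summary <- aggregate(phi ~ feature + model + iteration, shap,
                                  mean)
  }
  if (!is.null(lime)) {
    stopifnot(all(c("cluster", "feature", "rank") %in% names(lime)))
    agg <- aggregate(rank ~ feature + cluster, lime, mean)
    out$lime_ranks <- tapply(agg$rank, list(agg$feature, agg$cluster), mean)
  }
  out
}
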