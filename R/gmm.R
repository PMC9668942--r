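# Gaussian mixture clustering of the latent plane: full-covariance EM with
# seeded restarts, weighted per-component log-likelihoods, MAP assignment
# (ties toward the lowest component index), and BIC-based selection of the
# component count.

embedding_points <- function(embedding) {
  if (inherits(embedding, "latent_embedding")) return(embedding$points)
  if (is.matrix(embedding)) return(embedding)
  stopf("embedding must be a latent_embedding or a numeric matrix")
}

embedding_ids <- function(embedding) {
  if (inherits(embedding, "latent_embedding")) return(embedding$ids)
  rownames(embedding) %||% as.character(seq_len(nrow(embedding)))
}

# Cholesky-based multivariate normal log-density; errors on non-SPD
# covariance.
log_mvn_density <- function(X, mean, cov) {
  ch <- tryCatch(chol(cov), error = function(e)
    stopf("invalid model: covariance matrix is not positive definite"))
  d <- ncol(X)
  centered <- sweep(X, 2L, mean)
  q <- backsolve(ch, t(centered), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(q^2)
}

new_mixture <- function(K, weights, means, covariances, loglik = NA_real_,
                        trace = numeric(0), converged = NA, n = NA_integer_) {
  if (abs(sum(weights) - 1) > 1e-9) stopf("mixture weights must sum to 1")
  for (k in seq_len(K)) {
    ev <- eigen(covariances[, , k], symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0))
      stopf("invalid model: covariance of component %d is not positive definite", k)
  }
  structure(list(K = K, weights = weights, means = means,
                 covariances = covariances, loglik = loglik, trace = trace,
                 converged = converged, n = n),
            class = "ns_gmm")
}

#' @export
print.ns_gmm <- function(x, ...) {
  cat(sprintf("<ns_gmm> %d components, log-likelihood %.3f%s\n", x$K,
              x$loglik, if (isFALSE(x$converged)) " (EM not converged)" else ""))
  invisible(x)
}

# One EM run. Restarts alternate between two seeded initializations:
# "kmeans" (hard k-means partition -> means/weights) explores compact
# balanced basins, "random" (random soft responsibilities followed by an
# M-step) explores diffuse ones; the mix avoids both the spiky low-variance
# optima an unconstrained likelihood rewards and systematic under-exploration
# by repeated identical k-means partitions.
em_once <- function(X, K, reg, max_iter, tol,
                    init = c("kmeans", "random", "hclust")) {
  n <- nrow(X); d <- ncol(X)
  init <- match.arg(init)
  base_cov <- stats::cov(X) * (n - 1) / n + diag(reg, d)
  covs <- array(rep(base_cov, K), c(d, d, K))
  if (init == "hclust" && n > 2000L) init <- "kmeans"  # O(n^2) guard
  if (init == "hclust") {
    cl <- stats::cutree(stats::hclust(stats::dist(X), method = "ward.D2"), K)
    nk <- pmax(tabulate(cl, K), 1)
    w <- nk / sum(nk)
    means <- do.call(rbind, lapply(seq_len(K), function(k)
      colMeans(X[cl == k, , drop = FALSE])))
  } else if (init == "kmeans") {
    km <- tryCatch(stats::kmeans(X, centers = K, nstart = 1, iter.max = 50),
                   error = function(e) NULL)
    if (!is.null(km)) {
      means <- km$centers
      nk <- pmax(tabulate(km$cluster, K), 1)
      w <- nk / sum(nk)
    } else {
      means <- X[sample.int(n, K), , drop = FALSE]
      w <- rep(1 / K, K)
    }
  } else {
    R0 <- matrix(stats::rexp(n * K), n, K)
    R0 <- R0 / rowSums(R0)
    nk <- colSums(R0) + 1e-12
    w <- nk / sum(nk)
    means <- (t(R0) %*% X) / nk
    for (k in seq_len(K)) {
      centered <- sweep(X, 2L, means[k, ])
      covs[, , k] <- crossprod(centered * R0[, k], centered) / nk[k] +
        diag(reg, d)
    }
  }
  ll_prev <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(K), function(k)
      log(w[k]) + log_mvn_density(X, means[k, ], covs[, , k]), numeric(n))
    lse <- logsumexp_rows(logd)
    ll <- sum(lse)
    trace <- c(trace, ll)
    R <- exp(logd - lse)
    nk <- colSums(R) + 1e-12
    w <- nk / sum(nk)
    means <- (t(R) %*% X) / nk
    for (k in seq_len(K)) {
      centered <- sweep(X, 2L, means[k, ])
      covs[, , k] <- crossprod(centered * R[, k], centered) / nk[k] +
        diag(reg, d)
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  list(weights = w, means = means, covs = covs, loglik = ll, trace = trace,
       converged = converged)
}

#' Fit a Gaussian mixture to a latent embedding
#'
#' Full-covariance expectation-maximization with `n_init` seeded restarts:
#' the first restart starts from a Ward-linkage agglomerative partition, the
#' rest alternate between k-means partitions and random soft
#' responsibilities. Among restarts whose smallest component keeps at least
#' `d + 1` expected members, the best final log-likelihood wins (the guard
#' screens out near-singular "spike" components that inflate the unbounded
#' mixture likelihood). A ridge of `reg` is added to every covariance
#' diagonal at each M-step for numerical stability on (near-)degenerate
#' embeddings.
#'
#' @param embedding A `latent_embedding` (or plain n x d matrix).
#' @param K Component count, `1 <= K <= n`.
#' @param seed Integer seed (restart r uses a sub-seed derived from it).
#' @param n_init Number of EM restarts.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param reg Diagonal covariance regularization.
#' @return An `ns_gmm`: weights, means (K x d), covariances (d x d x K),
#'   best log-likelihood and its EM trace.
#' @export
fit_mixture <- function(embedding, K, seed = 1L, n_init = 10L,
                        max_iter = 500L, tol = 1e-8, reg = 1e-6) {
  X <- embedding_points(embedding)
  n <- nrow(X)
  if (!is.numeric(K) || length(K) != 1L || K < 1L)
    stopf("K must be a positive count")
  K <- as.integer(K)
  if (K > n) stopf("K (%d) cannot exceed the number of points (%d)", K, n)
  best <- best_any <- NULL
  for (r in seq_len(n_init)) {
    init_r <- if (r == 1L) "hclust" else if (r %% 2L) "kmeans" else "random"
    fit <- with_seed(derive_seed(seed, 200L + r),
                     em_once(X, K, reg, max_iter, tol, init = init_r))
    if (is.null(best_any) || fit$loglik > best_any$loglik) best_any <- fit
    # guard against near-empty (spiky) components when alternatives exist
    if (min(fit$weights) * n >= ncol(X) + 1 &&
        (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  best <- best %||% best_any
  if (!best$converged)
    warning(sprintf("EM did not converge within %d iterations; best iterate returned",
                    max_iter))
  new_mixture(K, best$weights, best$means, best$covs, best$loglik,
              best$trace, best$converged, n)
}

#' Weighted per-component log-likelihoods
#'
#' Entry k is `log(weight_k) + log N(point; mean_k, cov_k)` — the quantity
#' whose componentwise maximum defines cluster membership.
#'
#' @param model An `ns_gmm`.
#' @param point A length-d vector or an n x d matrix of points.
#' @return A K-vector for a single point, otherwise an n x K matrix.
#' @export
component_log_likelihood <- function(model, point) {
  if (!inherits(model, "ns_gmm")) stopf("model must be an ns_gmm")
  single <- is.null(dim(point))
  X <- if (single) matrix(point, nrow = 1L) else as.matrix(point)
  if (ncol(X) != ncol(model$means))
    stopf("point dimension (%d) does not match the model (%d)",
          ncol(X), ncol(model$means))
  out <- vapply(seq_len(model$K), function(k)
    log(model$weights[k]) +
      log_mvn_density(X, model$means[k, ], model$covariances[, , k]),
    numeric(nrow(X)))
  out <- matrix(out, nrow = nrow(X))
  if (single) drop(out) else out
}

#' Assign cases to mixture components
#'
#' Each case receives the label of the component with the highest weighted
#' log-likelihood (equivalently, the maximal posterior responsibility); exact
#' ties resolve to the lowest component index. Responsibilities are the
#' row-wise softmax of the weighted log-likelihoods.
#'
#' @param model An `ns_gmm`.
#' @param embedding A non-empty `latent_embedding` (or matrix).
#' @return A `cluster_assignment`: `ids`, integer `labels`, the n x K
#'   `loglik_matrix`, and n x K `responsibilities` (rows sum to 1).
#' @export
assign_clusters <- function(model, embedding) {
  X <- embedding_points(embedding)
  if (nrow(X) == 0L) stopf("embedding is empty")
  ll <- component_log_likelihood(model, X)
  ll <- matrix(ll, nrow = nrow(X))
  labels <- max.col(ll, ties.method = "first")
  resp <- exp(ll - logsumexp_rows(ll))
  ids <- embedding_ids(embedding)
  rownames(ll) <- rownames(resp) <- ids
  structure(list(ids = ids, labels = labels, loglik_matrix = ll,
                 responsibilities = resp, K = model$K),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment>\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Select the mixture component count by BIC
#'
#' Fits every K in `k_min:k_max` with [fit_mixture()] and returns the count
#' minimizing `BIC = -2 loglik + p log(n)`, where the free-parameter count is
#' `p = (K - 1) + K d + K d(d+1)/2` (weights, means, covariances). The full
#' per-K table is returned for audit.
#'
#' @inheritParams fit_mixture
#' @param k_min,k_max Range of component counts, `1 <= k_min <= k_max <= n`.
#' @return A `k_selection` list: selected `K`, the BIC `table`, and the
#'   fitted `models`.
#' @export
select_k_bic <- function(embedding, k_min = 1L, k_max = 8L, seed = 1L,
                         n_init = 10L) {
  X <- embedding_points(embedding)
  n <- nrow(X); d <- ncol(X)
  if (k_min < 1L || k_min > k_max) stopf("need 1 <= k_min <= k_max")
  if (k_max > n) stopf("k_max (%d) cannot exceed the number of points (%d)",
                       k_max, n)
  ks <- seq.int(k_min, k_max)
  models <- lapply(ks, function(K)
    fit_mixture(embedding, K, seed = derive_seed(seed, 300L + K),
                n_init = n_init))
  tab <- data.frame(
    K = ks,
    loglik = vapply(models, `[[`, numeric(1), "loglik"),
    p = (ks - 1) + ks * d + ks * d * (d + 1) / 2)
  tab$bic <- -2 * tab$loglik + tab$p * log(n)
  best <- ks[which.min(tab$bic)]
  structure(list(K = best, table = tab, models = stats::setNames(
    models, paste0("K", ks))),
    class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> selected K = %d\n", x$K))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Save / load mixture parameters as JSON
#'
#' @param model An `ns_gmm`.
#' @param path JSON file path.
#' @return `path` (save) or the restored `ns_gmm` (load).
#' @export
save_mixture <- function(model, path) {
  if (!inherits(model, "ns_gmm")) stopf("model must be an ns_gmm")
  jsonlite::write_json(
    list(K = model$K, weights = model$weights, means = model$means,
         covariances = lapply(seq_len(model$K), function(k)
           model$covariances[, , k]),
         loglik = model$loglik, n = model$n),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_mixture
#' @export
load_mixture <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- as.integer(p$K)
  d <- ncol(as.matrix(p$means))
  covs <- array(NA_real_, c(d, d, K))
  for (k in seq_len(K)) {
    covs[, , k] <- if (is.list(p$covariances)) as.matrix(p$covariances[[k]])
    else matrix(p$covariances[k, , ], d, d)
  }
  new_mixture(K, as.numeric(p$weights), as.matrix(p$means), covs,
              loglik = p$loglik %||% NA_real_, n = p$n %||% NA_integer_)
}
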