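# Gaussian mixture: density oracle, MAP assignment with tie-breaking, EM
# parameter recovery (with an mclust cross-check), monotone likelihood
# traces, and BIC component-count selection.

make_embedding <- function(points, ids = NULL) {
  ids <- if (is.null(ids)) sprintf("E%03d", seq_len(nrow(points))) else ids
  rownames(points) <- ids
  structure(list(points = points, ids = ids), class = "latent_embedding")
}

test_that("component log-likelihood matches the closed form and a brute-force scan", {
  # single standard-normal component at the mean: log(1/(2*pi))
  m <- list(K = 1L, weights = 1, means = matrix(0, 1, 2),
            covariances = array(diag(2), c(2, 2, 1)))
  class(m) <- "ns_gmm"
  expect_equal(component_log_likelihood(m, c(0, 0)), log(1 / (2 * pi)),
               tolerance = 1e-12)
  # renormalizing weights leaves the vector unchanged (weights already sum 1)
  set.seed(41)
  rm3 <- random_mixture(3)
  model <- list(K = 3L, weights = rm3$weights, means = rm3$means,
                covariances = rm3$covariances)
  class(model) <- "ns_gmm"
  pts <- matrix(rnorm(200, sd = 3), 100, 2)
  ours <- component_log_likelihood(model, pts)
  oracle <- bf_component_loglik(rm3$weights, rm3$means, rm3$covariances, pts)
  expect_equal(unname(ours), oracle, tolerance = 1e-9)
  # non-SPD covariance is an invalid model
  bad <- model
  bad$covariances[, , 1] <- matrix(c(1, 2, 2, 1), 2, 2)  # indefinite
  expect_error(component_log_likelihood(bad, c(0, 0)), "positive definite")
})

test_that("assignment is the brute-force argmax with ties to the lowest index", {
  set.seed(42)
  for (rep in 1:5) {
    rm <- random_mixture(sample(2:5, 1))
    model <- structure(list(K = length(rm$weights), weights = rm$weights,
                            means = rm$means, covariances = rm$covariances),
                       class = "ns_gmm")
    pts <- matrix(rnorm(400, sd = 4), 200, 2)
    asg <- assign_clusters(model, make_embedding(pts))
    oracle <- bf_component_loglik(rm$weights, rm$means, rm$covariances, pts)
    expect_identical(asg$labels, apply(oracle, 1, which.max))
    expect_equal(unname(rowSums(asg$responsibilities)), rep(1, 200),
                 tolerance = 1e-8)
  }
  # exact tie on the axis of symmetry resolves to component 1
  sym <- structure(list(K = 2L, weights = c(0.5, 0.5),
                        means = rbind(c(-1, 0), c(1, 0)),
                        covariances = array(rep(diag(2), 2), c(2, 2, 2))),
                   class = "ns_gmm")
  tie <- assign_clusters(sym, make_embedding(rbind(c(0, 0), c(0, 3))))
  expect_identical(tie$labels, c(1L, 1L))
  expect_error(assign_clusters(sym, make_embedding(matrix(0, 0, 2))), "empty")
})

test_that("EM recovers planted two-component structure, cross-checked with mclust", {
  set.seed(50)
  pts <- rbind(matrix(rnorm(200, mean = rep(c(-5, 0), each = 100)), 100, 2),
               matrix(rnorm(200, mean = rep(c(5, 0), each = 100)), 100, 2))
  emb <- make_embedding(pts)
  fit <- fit_mixture(emb, 2, seed = 1)
  ord <- order(fit$means[, 1])
  planted <- rbind(c(-5, 0), c(5, 0))
  expect_lt(max(abs(fit$means[ord, ] - planted)), 0.5)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  # the independent mclust fit lands on the same solution
  mc <- mclust::Mclust(pts, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_lt(max(abs(fit$means[ord, ] - t(mc$parameters$mean)[
    order(mc$parameters$mean[1, ]), ])), 0.3)
  expect_lt(abs(fit$loglik - mc$loglik), 1)
})

test_that("EM log-likelihood traces are non-decreasing", {
  set.seed(51)
  for (rep in 1:3) {
    pts <- matrix(rnorm(300, sd = c(1, 3)), 150, 2)
    fit <- fit_mixture(make_embedding(pts), 3, seed = rep)
    expect_true(all(diff(fit$trace) > -1e-6))
  }
})

test_that("degenerate and invalid inputs are handled", {
  # n identical points, K = 1: mean at the point, weight 1
  pts <- matrix(rep(c(1.5, -2), each = 20), 20, 2)
  fit <- fit_mixture(make_embedding(pts), 1, seed = 1)
  expect_equal(unname(fit$means[1, ]), c(1.5, -2), tolerance = 1e-9)
  expect_equal(fit$weights, 1)
  # K exceeding n
  expect_error(fit_mixture(make_embedding(pts[1:3, ]), 5), "exceed")
  expect_error(fit_mixture(make_embedding(pts), 0), "positive")
})

test_that("relabeling components permutes assignments consistently", {
  set.seed(52)
  rm <- random_mixture(3)
  model <- structure(list(K = 3L, weights = rm$weights, means = rm$means,
                          covariances = rm$covariances), class = "ns_gmm")
  pts <- matrix(rnorm(200, sd = 3), 100, 2)
  emb <- make_embedding(pts)
  perm <- c(3, 1, 2)
  relabeled <- structure(list(K = 3L, weights = rm$weights[perm],
                              means = rm$means[perm, ],
                              covariances = rm$covariances[, , perm]),
                         class = "ns_gmm")
  a <- assign_clusters(model, emb)
  b <- assign_clusters(relabeled, emb)
  expect_identical(order(perm)[a$labels], b$labels)
})

test_that("BIC selects the planted component count", {
  set.seed(53)
  centers <- rbind(c(-6, -6), c(6, -6), c(-6, 6), c(6, 6))
  pts <- do.call(rbind, lapply(1:4, function(k)
    matrix(rnorm(200, mean = rep(centers[k, ], each = 100)), 100, 2)))
  sel <- select_k_bic(make_embedding(pts), 1, 8, seed = 2)
  expect_equal(sel$K, 4L)
  expect_equal(nrow(sel$table), 8L)
  expect_equal(sel$table$p, (1:8 - 1) + 2 * (1:8) + 3 * (1:8))
  expect_equal(sel$table$bic,
               -2 * sel$table$loglik + sel$table$p * log(400))
  # a single Gaussian selects K = 1
  one <- matrix(rnorm(400), 200, 2)
  expect_equal(select_k_bic(make_embedding(one), 1, 4, seed = 3)$K, 1L)
  expect_error(select_k_bic(make_embedding(one), 3, 2), "k_min")
})

test_that("mixture parameters round-trip through JSON", {
  set.seed(54)
  pts <- rbind(matrix(rnorm(100, -3), 50, 2), matrix(rnorm(100, 3), 50, 2))
  fit <- fit_mixture(make_embedding(pts), 2, seed = 4)
  path <- tempfile(fileext = ".json")
  save_mixture(fit, path)
  back <- load_mixture(path)
  expect_equal(back$weights, fit$weights, tolerance = 1e-12)
  expect_equal(unname(back$means), unname(fit$means), tolerance = 1e-12)
  expect_equal(back$covariances, unname(fit$covariances), tolerance = 1e-12)
  unlink(path)
})
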