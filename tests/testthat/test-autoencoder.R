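# LSTM encoder-decoder: shape contracts, seeded determinism, agreement with
# an independent plain-R forward pass, gradient correctness against finite
# differences, training behavior and early stopping.

make_batch <- function(values, ids = NULL) {
  ids <- ids %||% sprintf("B%03d", seq_len(dim(values)[1]))
  structure(list(values = values, ids = ids, scaler = identity_scaler()),
            class = "sequence_batch")
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("configuration validation rejects bad dimensions and tolerances", {
  expect_s3_class(autoencoder_config(), "autoencoder_config")
  expect_error(autoencoder_config(latent_dim = 0), "positive")
  expect_error(autoencoder_config(early_stop_rel_tol = 1), "early_stop")
  expect_error(autoencoder_config(learning_rate = -1), "learning_rate")
})

test_that("encoding and decoding obey the shape contracts", {
  cfg <- autoencoder_config(seed = 3)
  model <- build_autoencoder(cfg)
  set.seed(1)
  batch <- make_batch(array(rnorm(25), c(1, 5, 5)))
  emb <- encode_cohort(model, batch)
  expect_equal(dim(emb$points), c(1L, 2L))
  expect_true(all(is.finite(emb$points)))
  rec <- reconstruct(model, batch)
  expect_equal(dim(rec), c(1L, 5L, 5L))
  # n = 205 in, 205 points out
  big <- make_batch(array(rnorm(205 * 25), c(205, 5, 5)))
  expect_equal(nrow(encode_cohort(model, big)$points), 205L)
})

test_that("builds are deterministic in the seed", {
  set.seed(2)
  batch <- make_batch(array(rnorm(4 * 25), c(4, 5, 5)))
  m1 <- build_autoencoder(autoencoder_config(seed = 11))
  m2 <- build_autoencoder(autoencoder_config(seed = 11))
  m3 <- build_autoencoder(autoencoder_config(seed = 12))
  expect_identical(m1$params, m2$params)
  expect_identical(reconstruction_error(m1, batch),
                   reconstruction_error(m2, batch))
  expect_false(identical(m1$params$Wx1, m3$params$Wx1))
})

test_that("compiled forward pass agrees with an independent plain-R forward pass", {
  cfg <- autoencoder_config(input_dim = 4, lstm1_dim = 6, fc_dim = 5,
                            latent_dim = 2, seed = 21)
  model <- build_autoencoder(cfg)
  set.seed(31)
  vals <- array(rnorm(3 * 5 * 4), c(3, 5, 4))  # 3 cases, 5 steps, 4 items
  batch <- make_batch(vals)
  oracle <- r_ae_forward(model$params, aperm(vals, c(1, 3, 2)))
  emb <- encode_cohort(model, batch)
  expect_equal(unname(emb$points), unname(oracle$z), tolerance = 1e-12)
  rec <- reconstruct(model, batch)
  for (t in 1:5)
    expect_equal(matrix(rec[, t, ], nrow = 3), oracle$Y[[t]],
                 tolerance = 1e-12)
  # per-case error equals the hand-computed cell-mean of squared differences
  err <- reconstruction_error(model, batch)
  hand <- sapply(1:3, function(i) mean((rec[i, , ] - vals[i, , ])^2))
  expect_equal(unname(err), hand, tolerance = 1e-12)
  expect_equal(mean(err), oracle$loss, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  ns <- asNamespace("nephroclust")
  cfg <- autoencoder_config(input_dim = 3, lstm1_dim = 4, fc_dim = 3,
                            latent_dim = 2, seed = 42)
  p <- ns$init_params(cfg)
  set.seed(7)
  X <- array(rnorm(2 * 3 * 4), c(2, 3, 4))  # (cases, items, steps) cube
  for (reverse in c(FALSE, TRUE)) {
    g <- ns$ae_grad_cpp(p, X, reverse)
    h <- 1e-5
    set.seed(8)
    for (nm in names(p)) {
      for (i in sample(seq_along(p[[nm]]), min(3, length(p[[nm]])))) {
        pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h
        pm <- p; pm[[nm]][i] <- pm[[nm]][i] - h
        num <- (ns$ae_forward_cpp(pp, X, reverse)$loss -
                  ns$ae_forward_cpp(pm, X, reverse)$loss) / (2 * h)
        expect_equal(g$grads[[nm]][i], num, tolerance = 2e-3)
      }
    }
  }
})

test_that("duplicated and permuted rows map to duplicated and permuted points", {
  model <- build_autoencoder(autoencoder_config(seed = 5))
  set.seed(13)
  vals <- array(rnorm(6 * 25), c(6, 5, 5))
  vals[4, , ] <- vals[2, , ]  # duplicate case
  batch <- make_batch(vals)
  emb <- encode_cohort(model, batch)
  expect_equal(emb$points[4, ], emb$points[2, ], ignore_attr = TRUE)
  perm <- c(3, 1, 6, 2, 5, 4)
  emb2 <- encode_cohort(model, make_batch(vals[perm, , ]))
  expect_equal(unname(emb2$points), unname(emb$points[perm, ]))
})

test_that("training reduces loss deterministically and early stopping binds", {
  coh <- generate_cohort(make_default_archetypes(), 80, seed = 14)
  batch <- apply_scaler(coh, fit_scaler(coh))
  cfg <- small_ae_config(seed = 9)
  m1 <- train_autoencoder(build_autoencoder(cfg), batch)
  m2 <- train_autoencoder(build_autoencoder(cfg), batch)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(encode_cohort(m1, batch)$points,
                   encode_cohort(m2, batch)$points)
  expect_lt(m1$loss_history[length(m1$loss_history)], m1$loss_history[1])
  expect_true(all(is.finite(m1$loss_history)))
  # reconstruction_error mean ties to the reported full-batch loss
  expect_equal(mean(reconstruction_error(m1, batch)), m1$final_loss,
               tolerance = 1e-6)
  # an extreme tolerance halts right after the first comparison
  m3 <- train_autoencoder(build_autoencoder(cfg), batch,
                          small_ae_config(seed = 9, early_stop_rel_tol = 0.99))
  expect_length(m3$loss_history, 2L)
})

test_that("an untrained model on standardized data scores near unit error", {
  model <- build_autoencoder(autoencoder_config(seed = 23))
  set.seed(15)
  batch <- make_batch(array(rnorm(50 * 25), c(50, 5, 5)))
  err <- mean(reconstruction_error(model, batch))
  expect_gt(err, 0.5)
  expect_lt(err, 1.5)
})

test_that("median loss of the first epochs exceeds the final epochs across seeds", {
  for (seed in 1:5) {
    arch <- scale_archetype_noise(make_default_archetypes(), visit_scale = 0.5)
    coh <- generate_cohort(arch, 120, seed = seed + 40)
    batch <- apply_scaler(coh, fit_scaler(coh))
    m <- train_autoencoder(build_autoencoder(small_ae_config(seed = seed)),
                           batch)
    lh <- m$loss_history
    expect_gt(stats::median(lh[1:2]),
              stats::median(lh[(length(lh) - 1):length(lh)]))
  }
})

test_that("latent clusters separate more between than within planted groups", {
  for (seed in 1:5) {
    arch <- scale_archetype_noise(make_default_archetypes(), visit_scale = 0.5)
    coh <- generate_cohort(arch, 160, seed = seed + 60)
    batch <- apply_scaler(coh, fit_scaler(coh))
    m <- train_autoencoder(build_autoencoder(small_ae_config(seed = seed)),
                           batch)
    z <- encode_cohort(m, batch)$points
    groups <- split(as.data.frame(z), coh$true_cluster)
    centroids <- t(vapply(groups, colMeans, numeric(2)))
    between <- mean(stats::dist(centroids))
    within <- mean(vapply(groups, function(g) {
      gm <- colMeans(g)
      mean(sqrt(rowSums(sweep(as.matrix(g), 2, gm)^2)))
    }, numeric(1)))
    expect_gt(between, within)
  }
})

test_that("bad batches are rejected with informative errors", {
  model <- build_autoencoder(autoencoder_config(seed = 1))
  bad <- make_batch(array(c(NA, rnorm(24)), c(1, 5, 5)))
  expect_error(encode_cohort(model, bad), "non-finite")
  wrong <- make_batch(array(rnorm(5 * 4), c(1, 5, 4)))
  expect_error(encode_cohort(model, wrong), "expects")
  expect_error(train_autoencoder(model, wrong), "expects")
})

test_that("checkpoints round-trip through JSON", {
  coh <- generate_cohort(make_default_archetypes(), 30, seed = 77)
  sc <- fit_scaler(coh)
  batch <- apply_scaler(coh, sc)
  m <- train_autoencoder(build_autoencoder(
    small_ae_config(seed = 2, iters_per_epoch = 50L)), batch)
  path <- tempfile(fileext = ".json")
  save_autoencoder(m, path, scaler = sc)
  back <- load_autoencoder(path)
  expect_equal(back$loss_history, m$loss_history, tolerance = 1e-12)
  expect_equal(encode_cohort(back, batch)$points,
               encode_cohort(m, batch)$points, tolerance = 1e-10)
  expect_equal(attr(back, "scaler")$mean, sc$mean, tolerance = 1e-12)
  unlink(path)
})

test_that("the reversed-target variant trains and reconstructs in reverse order", {
  coh <- generate_cohort(make_default_archetypes(), 40, seed = 19)
  batch <- apply_scaler(coh, fit_scaler(coh))
  cfg <- small_ae_config(seed = 3, reverse_target = TRUE,
                         iters_per_epoch = 100L)
  m <- train_autoencoder(build_autoencoder(cfg), batch)
  expect_lt(m$loss_history[length(m$loss_history)], m$loss_history[1])
  # per-case error is computed against the reversed sequence
  rec <- reconstruct(m, batch)
  err <- reconstruction_error(m, batch)
  hand <- mean((rec[1, , ] - batch$values[1, 5:1, ])^2)
  expect_equal(unname(err[1]), hand, tolerance = 1e-10)
})
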