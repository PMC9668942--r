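suppressMessages(library(mclust))  # attached: Mclust resolves mclustBIC

# Shared fixtures and independent oracles. Everything here is deliberately
# written without reusing the package's internal code paths, so that tests
# compare two independent routes to the same quantity.

items_ <- clinical_items()
months_ <- visit_months()

# Build an ns_cohort from a long data frame through the public CSV reader.
manual_cohort <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  on.exit(unlink(path))
  read_cohort(path)
}

# Complete long table for the given patients; value_fun(id, month, item).
complete_long <- function(ids, disease = "MCD", treated = TRUE,
                          value_fun = function(id, month, item) 1) {
  rows <- expand.grid(item = items_, visit_month = c(0L, months_),
                      patient_id = ids, stringsAsFactors = FALSE)
  rows$disease <- disease
  rows$treated <- treated
  rows$value <- mapply(value_fun, rows$patient_id, rows$visit_month,
                       rows$item)
  rows[, c("patient_id", "disease", "treated", "visit_month", "item",
           "value")]
}

# Archetype with (near-)deterministic output; grade means on the 0-5 grid so
# rounding is exact.
const_archetype <- function(cluster_id = "C1", weight = 1,
                            means = c(1, 3, 2, 3, 2),
                            mult = matrix(1, 5, 5), sd = 1e-12,
                            visit_sd = 1e-12,
                            disease_probs = c(1, 0, 0, 0, 0, 0)) {
  archetype_spec(cluster_id, weight, means, rep(sd, 5), mult,
                 matrix(visit_sd, 5, 5), disease_probs)
}

small_ae_config <- function(seed = 1L, sets = 2L, epochs_per_set = 2L,
                            iters_per_epoch = 300L, ...) {
  autoencoder_config(sets = sets, epochs_per_set = epochs_per_set,
                     iters_per_epoch = iters_per_epoch, seed = seed, ...)
}

# ---- independent oracles -------------------------------------------------

# Plain-R forward pass of the LSTM encoder-decoder (independent of the
# compiled implementation). X has dimensions (cases, items, timesteps).
r_ae_forward <- function(params, X) {
  sig <- function(x) 1 / (1 + exp(-x))
  addb <- function(m, b) sweep(m, 2, as.numeric(b), "+")
  run_lstm <- function(Wx, Wh, b, Xs) {
    Tn <- length(Xs); H <- nrow(Wh); B <- nrow(Xs[[1]])
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    out <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      A <- addb(Xs[[t]] %*% Wx + h %*% Wh, b)
      i <- sig(A[, 1:H, drop = FALSE])
      f <- sig(A[, H + (1:H), drop = FALSE])
      o <- sig(A[, 2 * H + (1:H), drop = FALSE])
      g <- tanh(A[, 3 * H + (1:H), drop = FALSE])
      cc <- f * cc + i * g
      h <- o * tanh(cc)
      out[[t]] <- h
    }
    out
  }
  Tn <- dim(X)[3]
  Xs <- lapply(seq_len(Tn), function(t) matrix(X[, , t], nrow = dim(X)[1]))
  h1 <- run_lstm(params$Wx1, params$Wh1, params$b1, Xs)
  E <- lapply(h1, function(h) sig(addb(h %*% params$We, params$be)))
  h2 <- run_lstm(params$Wx2, params$Wh2, params$b2, E)
  z <- h2[[Tn]]
  h3 <- run_lstm(params$Wx3, params$Wh3, params$b3, rep(list(z), Tn))
  G <- lapply(h3, function(h) sig(addb(h %*% params$Wd, params$bd)))
  h4 <- run_lstm(params$Wx4, params$Wh4, params$b4, G)
  Y <- lapply(h4, function(h) addb(h %*% params$Wo, params$bo))
  sse <- sum(mapply(function(y, x) sum((y - x)^2), Y, Xs))
  list(z = z, Y = Y,
       loss = sse / (dim(X)[1] * dim(X)[2] * Tn))
}

# Exact mean of the generator's censoring transforms, by normal-CDF algebra.
censored_mean_cont <- function(mu, sd, floor) {
  a <- (floor - mu) / sd
  floor * stats::pnorm(a) + mu * (1 - stats::pnorm(a)) +
    sd * stats::dnorm(a)
}
grade_grid_mean <- function(mu, sd) {
  g <- 0:5
  lo <- c(-Inf, g[-1] - 0.5)
  hi <- c(g[-6] + 0.5, Inf)
  sum(g * (stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd)))
}
# Mixture mean of a baseline item under the generator's value model.
generator_baseline_mean <- function(archetypes, item) {
  j <- match(item, items_)
  sum(vapply(archetypes, function(a) {
    mu <- a$baseline_mean[j]; sd <- a$baseline_sd[j]
    m <- if (item %in% c("hematuria", "proteinuria")) grade_grid_mean(mu, sd)
    else censored_mean_cont(mu, sd, if (item == "upcr") 0 else 0.01)
    a$weight * m
  }, numeric(1)))
}

# Brute-force weighted Gaussian log-likelihood scan (independent of the
# package's linear-algebra route).
bf_component_loglik <- function(weights, means, covariances, X) {
  K <- length(weights); d <- ncol(X)
  out <- matrix(NA_real_, nrow(X), K)
  for (i in seq_len(nrow(X))) {
    for (k in seq_len(K)) {
      S <- covariances[, , k]
      diffv <- as.numeric(X[i, ] - means[k, ])
      out[i, k] <- log(weights[k]) - (d / 2) * log(2 * pi) -
        0.5 * log(det(S)) -
        0.5 * as.numeric(t(diffv) %*% solve(S) %*% diffv)
    }
  }
  out
}

random_mixture <- function(K, d = 2) {
  w <- stats::rexp(K); w <- w / sum(w)
  means <- matrix(stats::rnorm(K * d, sd = 3), K, d)
  covs <- array(NA_real_, c(d, d, K))
  for (k in seq_len(K)) {
    A <- matrix(stats::rnorm(d * d), d, d)
    covs[, , k] <- A %*% t(A) + diag(0.3, d)
  }
  list(weights = w, means = means, covariances = covs)
}

# Cohort whose patients are exact copies of one generated patient.
identical_cohort <- function(n = 50, seed = 1) {
  one <- generate_cohort(make_default_archetypes(), 1, seed = seed)
  ids <- sprintf("D%03d", seq_len(n))
  df <- do.call(rbind, lapply(ids, function(id) {
    d <- merge(one$data, one$info, by = "patient_id")
    d$patient_id <- id
    d[, c("patient_id", "disease", "treated", "visit_month", "item", "value")]
  }))
  manual_cohort(df)
}
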