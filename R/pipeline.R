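# End-to-end pipeline: simulate or ingest -> complete-case filter
# (-> treated-only filter) -> standardize -> train autoencoder -> embed ->
# fit mixture (fixed K or BIC range) -> assign -> characterize, with all
# artifacts, seeds and stage counts recorded in a JSON manifest. One global
# seed fans out deterministically to per-stage sub-seeds so stages can be
# rerun in isolation.

#' Pipeline configuration
#'
#' @param input `"simulate"` (default) or a path to a cohort CSV readable by
#'   [read_cohort()].
#' @param n Cohort size when simulating.
#' @param archetypes Archetype list for simulation; defaults to
#'   [make_default_archetypes()].
#' @param visit_sd_scale Multiplier applied to the archetypes' visit-level
#'   SDs before simulating (the cluster-separation knob).
#' @param exclude_untreated Run the treated-only sensitivity filter.
#' @param scale Standardize items (pooled z-scoring) before training; when
#'   `FALSE` the model runs on raw units.
#' @param ae An [autoencoder_config()]; its seed is overridden by a sub-seed
#'   of `seed`.
#' @param K Mixture component count (default 4); ignored when `k_range` is
#'   given.
#' @param k_range Optional `c(k_min, k_max)` for BIC-based selection.
#' @param n_init EM restarts per mixture fit.
#' @param out_dir Output directory for artifacts (created if needed); `NULL`
#'   keeps everything in memory.
#' @param seed Global integer seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = "simulate", n = 205L, archetypes = NULL,
                            visit_sd_scale = 1, exclude_untreated = FALSE,
                            scale = TRUE, ae = autoencoder_config(),
                            K = 4L, k_range = NULL, n_init = 5L,
                            out_dir = NULL, seed = 1L) {
  if (!identical(input, "simulate") && !file.exists(input))
    stopf("input must be \"simulate\" or an existing CSV path")
  if (!is.null(k_range) && (length(k_range) != 2L || k_range[1] > k_range[2]))
    stopf("k_range must be c(k_min, k_max) with k_min <= k_max")
  structure(list(input = input, n = as.integer(n), archetypes = archetypes,
                 visit_sd_scale = visit_sd_scale,
                 exclude_untreated = isTRUE(exclude_untreated),
                 scale = isTRUE(scale), ae = ae, K = as.integer(K),
                 k_range = k_range, n_init = as.integer(n_init),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full clustering pipeline
#'
#' Executes every stage under derived sub-seeds of `config$seed`, logging one
#' line per stage. When `config$out_dir` is set, writes: `cohort.csv` (+ JSON
#' sidecar), `training_log.csv` (epoch, loss), `model.json` (autoencoder
#' checkpoint incl. scaler), `embedding.csv` (patient_id, z1, z2),
#' `mixture.json`, `assignments.csv` (patient_id, cluster,
#' responsibility_1..K), `trajectory_means.csv`, `baseline_table.csv`,
#' `crosstab.csv`, `contours.csv` (z1, z2, loglik), `bic.csv` (when a range
#' was searched), and `manifest.json` (seeds, stage counts and timings,
#' package version). Rerunning an identical configuration reproduces all
#' numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate object (`cohort`,
#'   `analysis_cohort`, `scaler`, `batch`, `model`, `embedding`, `mixture`,
#'   `assignment`, `profile`, `contours`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stopf("config must be a pipeline_config")
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage, t_start)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t_start, 3)
  seeds <- list(simulate = derive_seed(config$seed, 1L),
                autoencoder = derive_seed(config$seed, 2L),
                mixture = derive_seed(config$seed, 3L))

  # --- simulate / ingest ---
  ts <- proc.time()[["elapsed"]]
  if (identical(config$input, "simulate")) {
    arch <- config$archetypes %||% make_default_archetypes()
    if (config$visit_sd_scale != 1)
      arch <- scale_archetype_noise(arch, visit_scale = config$visit_sd_scale)
    cohort <- generate_cohort(arch, config$n, seeds$simulate)
    stage_log("simulate", "generated %d patients (seed %d)",
              n_patients(cohort), seeds$simulate)
  } else {
    cohort <- read_cohort(config$input)
    stage_log("ingest", "read %d patients from %s", n_patients(cohort),
              config$input)
  }
  tick("input", ts)

  # --- filter ---
  ts <- proc.time()[["elapsed"]]
  n_in <- n_patients(cohort)
  analysis <- suppressMessages(filter_complete(cohort))
  stage_log("filter", "complete cases: %d of %d", n_patients(analysis), n_in)
  if (config$exclude_untreated) {
    n_before <- n_patients(analysis)
    analysis <- suppressMessages(exclude_untreated(analysis))
    stage_log("filter", "treated only: %d of %d", n_patients(analysis),
              n_before)
  }
  if (n_patients(analysis) == 0L) stopf("pipeline stage 'filter': no patients remain")
  tick("filter", ts)

  # --- scale ---
  ts <- proc.time()[["elapsed"]]
  scaler <- if (config$scale) fit_scaler(analysis) else identity_scaler()
  batch <- apply_scaler(analysis, scaler)
  tick("scale", ts)

  # --- train ---
  ts <- proc.time()[["elapsed"]]
  ae_cfg <- config$ae
  ae_cfg$seed <- seeds$autoencoder
  model <- build_autoencoder(ae_cfg)
  model <- train_autoencoder(model, batch)
  stage_log("train", "%d epochs, first/final loss %.4f / %.4f",
            length(model$loss_history), model$loss_history[1],
            model$final_loss)
  tick("train", ts)

  # --- embed ---
  ts <- proc.time()[["elapsed"]]
  embedding <- encode_cohort(model, batch)
  tick("embed", ts)

  # --- mixture ---
  ts <- proc.time()[["elapsed"]]
  selection <- NULL
  if (!is.null(config$k_range)) {
    selection <- select_k_bic(embedding, config$k_range[1], config$k_range[2],
                              seed = seeds$mixture, n_init = config$n_init)
    mixture <- selection$models[[paste0("K", selection$K)]]
    stage_log("cluster", "BIC selected K = %d over %d..%d", selection$K,
              config$k_range[1], config$k_range[2])
  } else {
    mixture <- fit_mixture(embedding, config$K, seed = seeds$mixture,
                           n_init = config$n_init)
    stage_log("cluster", "fitted K = %d mixture (loglik %.2f)", mixture$K,
              mixture$loglik)
  }
  assignment <- assign_clusters(mixture, embedding)
  tick("cluster", ts)

  # --- characterize ---
  ts <- proc.time()[["elapsed"]]
  profile <- cluster_profile(analysis, assignment)
  pts <- embedding$points
  pad <- 0.1 * pmax(apply(pts, 2, function(x) diff(range(x))), 1e-6)
  bounds <- c(min(pts[, 1]) - pad[1], max(pts[, 1]) + pad[1],
              min(pts[, 2]) - pad[2], max(pts[, 2]) + pad[2])
  contours <- likelihood_contours(mixture, bounds, resolution = 60L)
  tick("characterize", ts)

  manifest <- list(
    package_version = as.character(utils::packageVersion("nephroclust")),
    r_version = as.character(getRversion()),
    seed = config$seed, stage_seeds = seeds,
    config = list(input = config$input, n = config$n,
                  visit_sd_scale = config$visit_sd_scale,
                  exclude_untreated = config$exclude_untreated,
                  scale = config$scale, ae = unclass(config$ae),
                  K = config$K, k_range = config$k_range,
                  n_init = config$n_init),
    counts = list(n_input = n_in, n_analyzed = n_patients(analysis),
                  cluster_sizes = as.list(table(assignment$labels))),
    K = mixture$K,
    epochs = length(model$loss_history),
    final_loss = model$final_loss,
    timings = timings,
    total_elapsed = round(proc.time()[["elapsed"]] - t0, 3))

  result <- list(cohort = cohort, analysis_cohort = analysis, scaler = scaler,
                 batch = batch, model = model, embedding = embedding,
                 mixture = mixture, selection = selection,
                 assignment = assignment, profile = profile,
                 contours = contours, manifest = manifest)
  if (!is.null(config$out_dir)) write_artifacts(result, config$out_dir)
  stage_log("done", "analyzed %d patients into %d clusters in %.1fs",
            n_patients(analysis), mixture$K, manifest$total_elapsed)
  invisible(result)
}

write_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(name) file.path(out_dir, name)
  write_cohort(result$cohort, fp("cohort.csv"))
  utils::write.csv(data.frame(epoch = seq_along(result$model$loss_history),
                              loss = result$model$loss_history),
                   fp("training_log.csv"), row.names = FALSE)
  save_autoencoder(result$model, fp("model.json"), scaler = result$scaler)
  emb <- data.frame(patient_id = result$embedding$ids,
                    result$embedding$points, check.names = FALSE)
  utils::write.csv(emb, fp("embedding.csv"), row.names = FALSE)
  save_mixture(result$mixture, fp("mixture.json"))
  resp <- result$assignment$responsibilities
  colnames(resp) <- paste0("responsibility_", seq_len(ncol(resp)))
  utils::write.csv(cbind(data.frame(patient_id = result$assignment$ids,
                                    cluster = result$assignment$labels),
                         as.data.frame(resp)),
                   fp("assignments.csv"), row.names = FALSE)
  utils::write.csv(result$profile$trajectory, fp("trajectory_means.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$profile$baseline),
                   fp("baseline_table.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$profile$crosstab),
                   fp("crosstab.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(result$contours), fp("contours.csv"),
                   row.names = FALSE)
  if (!is.null(result$selection))
    utils::write.csv(result$selection$table, fp("bic.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
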