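# Cohort container and the synthetic-cohort generator.
#
# A cohort is stored as
#   info:         one row per patient (patient_id, disease, treated)
#   data:         long table (patient_id, visit_month, item, value) with
#                 visit_month 0 denoting the at-biopsy baseline
#   true_cluster: optional planted archetype label per patient
# This long representation tolerates missing cells, which the preprocessing
# module filters out exactly as a complete-case analysis would.

new_cohort <- function(info, data, true_cluster = NULL, seed = NULL,
                       provenance = NULL) {
  stopifnot(is.data.frame(info), is.data.frame(data))
  if (anyDuplicated(info$patient_id))
    stopf("patient identifiers must be unique")
  if (!is.null(true_cluster) && length(true_cluster) != nrow(info))
    stopf("true_cluster must have one label per patient")
  if (!is.null(true_cluster)) names(true_cluster) <- info$patient_id
  structure(list(info = info, data = data, true_cluster = true_cluster,
                 seed = seed, provenance = provenance),
            class = "ns_cohort")
}

#' Number of patients in a cohort
#' @param cohort An `ns_cohort` object.
#' @return Integer count.
#' @export
n_patients <- function(cohort) {
  stopifnot(inherits(cohort, "ns_cohort"))
  nrow(cohort$info)
}

#' @export
print.ns_cohort <- function(x, ...) {
  cat(sprintf("<ns_cohort> %d patients, %d value rows%s\n",
              n_patients(x), nrow(x$data),
              if (!is.null(x$true_cluster)) ", planted labels" else ""))
  invisible(x)
}

# Keep a subset of patients, preserving order of `ids`.
subset_cohort <- function(cohort, ids) {
  keep <- cohort$info$patient_id %in% ids
  info <- cohort$info[keep, , drop = FALSE]
  info <- info[match(ids[ids %in% info$patient_id], info$patient_id), ,
               drop = FALSE]
  rownames(info) <- NULL
  data <- cohort$data[cohort$data$patient_id %in% ids, , drop = FALSE]
  rownames(data) <- NULL
  tc <- if (!is.null(cohort$true_cluster))
    cohort$true_cluster[info$patient_id] else NULL
  new_cohort(info, data, tc, cohort$seed, cohort$provenance)
}

# Valid-range censoring: continuous items are floored just above zero,
# dipstick grades are clamped to [0, 5] and rounded to the integer grid.
censor_values <- function(x, item) {
  if (item %in% grade_items()) {
    round(pmin(pmax(x, 0), 5))
  } else if (item == "upcr") {
    pmax(x, 0)
  } else {
    pmax(x, 0.01)
  }
}

#' Generate a synthetic nephrotic-syndrome cohort
#'
#' Draws `n` labeled patient trajectories from a mixture of trajectory
#' archetypes. For each patient a planted cluster is drawn from the archetype
#' weights and a disease label from that cluster's disease distribution.
#' Baseline items are drawn as `Normal(baseline_mean, baseline_sd)` censored
#' to valid ranges (continuous items floored at zero, dipstick grades clamped
#' to 0-5 and rounded to the grid). Visit values share the patient's drawn
#' baseline as a damped random intercept: with `b_j` the patient's censored,
#' pre-rounding baseline draw and
#' `b_eff = baseline_mean + intercept_strength * (b_j - baseline_mean)`,
#' the value of item j at visit t is
#' `b_eff * course_multiplier[j, t] + Normal(0, visit_sd[j, t])`, censored
#' the same way. `intercept_strength` (default 0.35) is the fraction of the
#' patient's at-biopsy deviation that persists through the treated course:
#' remission pulls values toward the cluster course regardless of where a
#' patient started, so the at-biopsy deviation only partially propagates;
#' within-patient correlation across visits comes solely from this shared
#' intercept (no additional autoregressive structure). A fixed fraction
#' 19/205 of patients is flagged untreated, independently of cluster.
#'
#' Identical `(archetypes, n, seed)` yield identical cohorts; the caller's
#' RNG stream is left untouched.
#'
#' @param archetypes List of [archetype_spec()]; weights must sum to 1.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed.
#' @param intercept_strength Fraction in `[0, 1]` of the baseline deviation
#'   carried through the visit course (see Details).
#' @return An `ns_cohort` with planted `true_cluster` labels.
#' @examples
#' coh <- generate_cohort(make_default_archetypes(), n = 50, seed = 1)
#' table(coh$true_cluster)
#' @export
generate_cohort <- function(archetypes, n, seed, intercept_strength = 0.35) {
  check_archetypes(archetypes)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stopf("n must be a positive count")
  if (!is.numeric(intercept_strength) || intercept_strength < 0 ||
      intercept_strength > 1)
    stopf("intercept_strength must lie in [0, 1]")
  n <- as.integer(n)
  K <- length(archetypes)
  items <- clinical_items()
  months <- visit_months()
  with_seed(seed, {
    w <- vapply(archetypes, `[[`, numeric(1), "weight")
    cl <- sample.int(K, n, replace = TRUE, prob = w)
    disease <- character(n)
    for (k in seq_len(K)) {
      idx <- which(cl == k)
      if (length(idx))
        disease[idx] <- sample(disease_labels(), length(idx), replace = TRUE,
                               prob = archetypes[[k]]$disease_probs)
    }
    n_untreated <- round(n * 19 / 205)
    treated <- rep(TRUE, n)
    if (n_untreated > 0) treated[sample.int(n, n_untreated)] <- FALSE

    bmean <- t(vapply(archetypes, `[[`, numeric(5), "baseline_mean"))[cl, ,
                                                                      drop = FALSE]
    bsd <- t(vapply(archetypes, `[[`, numeric(5), "baseline_sd"))[cl, ,
                                                                  drop = FALSE]
    raw_base <- matrix(stats::rnorm(n * 5L, mean = bmean, sd = bsd), n, 5L)
    colnames(raw_base) <- items
    # censored continuous baseline: the random intercept shared across visits
    b_cont <- raw_base
    for (j in items) {
      x <- raw_base[, j]
      b_cont[, j] <- if (j %in% grade_items()) pmin(pmax(x, 0), 5) else
        censor_values(x, j)
    }
    base_store <- b_cont
    for (j in grade_items()) base_store[, j] <- round(base_store[, j])

    visit_vals <- array(NA_real_, c(n, 5L, 5L),
                        dimnames = list(NULL, items, paste0("m", months)))
    for (k in seq_len(K)) {
      idx <- which(cl == k)
      if (!length(idx)) next
      a <- archetypes[[k]]
      for (j in seq_along(items)) {
        b_eff <- a$baseline_mean[j] +
          intercept_strength * (b_cont[idx, j] - a$baseline_mean[j])
        mu <- outer(b_eff, a$course_multiplier[j, ])
        eps <- matrix(stats::rnorm(length(idx) * 5L, 0,
                                   rep(a$visit_sd[j, ], each = length(idx))),
                      length(idx), 5L)
        visit_vals[idx, j, ] <- censor_values(mu + eps, items[j])
      }
    }

    ids <- sprintf("P%04d", seq_len(n))
    info <- data.frame(patient_id = ids, disease = disease, treated = treated,
                       stringsAsFactors = FALSE)
    long <- rbind(
      data.frame(patient_id = rep(ids, each = 5L),
                 visit_month = 0L,
                 item = rep(items, times = n),
                 value = as.vector(t(base_store)),
                 stringsAsFactors = FALSE),
      data.frame(patient_id = rep(ids, each = 25L),
                 visit_month = rep(rep(months, each = 5L), times = n),
                 item = rep(items, times = 5L * n),
                 value = as.vector(aperm(visit_vals, c(2L, 3L, 1L))),
                 stringsAsFactors = FALSE))
    long <- long[order(match(long$patient_id, ids), long$visit_month,
                       match(long$item, items)), , drop = FALSE]
    rownames(long) <- NULL
    tc <- vapply(archetypes, `[[`, character(1), "cluster_id")[cl]
    new_cohort(info, long, tc, seed = seed,
               provenance = list(generator = "nephroclust::generate_cohort",
                                 n = n, seed = seed,
                                 intercept_strength = intercept_strength,
                                 archetype_ids = unname(
                                   vapply(archetypes, `[[`, character(1),
                                          "cluster_id")),
                                 weights = unname(w)))
  })
}

#' Write a cohort to CSV (long format) with a JSON sidecar
#'
#' The CSV holds columns `patient_id, disease, treated, visit_month, item,
#' value` (visit_month 0 = baseline). The sidecar (same path with extension
#' `.json`) records the seed, provenance and planted labels.
#'
#' @param cohort An `ns_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ns_cohort"))
  d <- merge(cohort$data, cohort$info, by = "patient_id", sort = FALSE)
  d <- d[order(match(d$patient_id, cohort$info$patient_id), d$visit_month,
               match(d$item, clinical_items())),
         c("patient_id", "disease", "treated", "visit_month", "item", "value")]
  utils::write.csv(d, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(seed = cohort$seed, provenance = cohort$provenance,
         n = n_patients(cohort),
         true_cluster = as.list(cohort$true_cluster %||% list())),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Accepts either the long format written by [write_cohort()] (columns
#' `item` and `value` present) or a wide format with one row per patient and
#' value columns named `<item>_m<month>` (e.g. `creatinine_m0`,
#' `upcr_m24`). The dialect is detected from the header. If a JSON sidecar
#' from [write_cohort()] exists next to the file, planted labels and the seed
#' are restored.
#'
#' @param path CSV path.
#' @return An `ns_cohort`.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("item", "value") %in% names(d))) {
    cohort <- cohort_from_long(d)
  } else {
    cohort <- cohort_from_wide(d)
  }
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    cohort$seed <- meta$seed
    cohort$provenance <- meta$provenance
    if (length(meta$true_cluster)) {
      tc <- unlist(meta$true_cluster)
      cohort$true_cluster <- tc[cohort$info$patient_id]
    }
  }
  cohort
}

cohort_from_long <- function(d) {
  need <- c("patient_id", "visit_month", "item", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("long cohort CSV lacks column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- which(!d$item %in% clinical_items())
  if (length(bad))
    stopf("unknown item '%s' in row %d", d$item[bad[1]], bad[1])
  ids <- unique(d$patient_id)
  info <- d[!duplicated(d$patient_id),
            intersect(c("patient_id", "disease", "treated"), names(d)),
            drop = FALSE]
  if (is.null(info$disease)) info$disease <- NA_character_
  if (is.null(info$treated)) info$treated <- NA
  info$treated <- as.logical(info$treated)
  rownames(info) <- NULL
  data <- d[, c("patient_id", "visit_month", "item", "value")]
  data$visit_month <- as.integer(data$visit_month)
  data$value <- as.numeric(data$value)
  rownames(data) <- NULL
  new_cohort(info, data)
}

cohort_from_wide <- function(d) {
  if (!"patient_id" %in% names(d))
    stopf("wide cohort CSV lacks a patient_id column")
  pat <- sprintf("^(%s)_m(\\d+)$", paste(clinical_items(), collapse = "|"))
  vcols <- grep(pat, names(d), value = TRUE)
  if (!length(vcols))
    stopf("wide cohort CSV has no <item>_m<month> value columns")
  other <- setdiff(names(d), c("patient_id", "disease", "treated", vcols))
  if (length(other))
    stopf("unrecognized column(s) in wide cohort CSV: %s",
          paste(other, collapse = ", "))
  info <- data.frame(patient_id = as.character(d$patient_id),
                     disease = if ("disease" %in% names(d)) d$disease else NA,
                     treated = if ("treated" %in% names(d))
                       as.logical(d$treated) else NA,
                     stringsAsFactors = FALSE)
  item <- sub(pat, "\\1", vcols)
  month <- as.integer(sub(pat, "\\2", vcols))
  data <- data.frame(
    patient_id = rep(info$patient_id, times = length(vcols)),
    visit_month = rep(month, each = nrow(d)),
    item = rep(item, each = nrow(d)),
    value = as.numeric(unlist(d[vcols], use.names = FALSE)),
    stringsAsFactors = FALSE)
  new_cohort(info, data)
}
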