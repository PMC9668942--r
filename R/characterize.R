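# Cluster characterization: per-cluster item time courses, the at-biopsy
# summary table, the disease-by-cluster crosstab, a canonical severity
# ordering, and the latent-plane likelihood contour grid.

check_assignment <- function(cohort, assignment) {
  if (!inherits(cohort, "ns_cohort")) stopf("cohort must be an ns_cohort")
  if (!inherits(assignment, "cluster_assignment"))
    stopf("assignment must be a cluster_assignment")
  missing_ids <- setdiff(assignment$ids, cohort$info$patient_id)
  if (length(missing_ids))
    stopf("assigned id(s) not present in cohort: %s",
          paste(utils::head(missing_ids, 3), collapse = ", "))
  invisible(TRUE)
}

#' Planted labels as a cluster assignment
#'
#' Wraps a cohort's planted `true_cluster` labels (or any per-patient label
#' vector) in the `cluster_assignment` structure so characterization
#' functions can be driven by ground truth.
#'
#' @param cohort An `ns_cohort` with planted labels, or any cohort when
#'   `labels` is given.
#' @param labels Optional per-patient labels (character or integer), named or
#'   in cohort order.
#' @return A `cluster_assignment` with labels coded as integers in the sorted
#'   order of unique labels.
#' @export
assignment_from_labels <- function(cohort, labels = cohort$true_cluster) {
  if (!inherits(cohort, "ns_cohort")) stopf("cohort must be an ns_cohort")
  if (is.null(labels)) stopf("cohort has no planted labels")
  ids <- cohort$info$patient_id
  if (!is.null(names(labels))) labels <- labels[ids]
  lev <- sort(unique(as.character(labels)))
  structure(list(ids = ids,
                 labels = match(as.character(labels), lev),
                 loglik_matrix = NULL, responsibilities = NULL,
                 K = length(lev), label_names = lev),
            class = "cluster_assignment")
}

cluster_names <- function(assignment) {
  assignment$label_names %||% paste0("C", seq_len(assignment$K))
}

#' Per-cluster item time courses
#'
#' Mean and SD of every clinical item at every scheduled visit, within each
#' assigned cluster. Clusters with no members are simply absent from the
#' table (not reported as zeros).
#'
#' @param cohort An `ns_cohort` containing every assigned patient.
#' @param assignment A `cluster_assignment`.
#' @return A `trajectory_summary` data frame with columns `cluster`, `item`,
#'   `month`, `mean`, `sd`, `n`.
#' @export
trajectory_means <- function(cohort, assignment) {
  check_assignment(cohort, assignment)
  lab <- stats::setNames(assignment$labels, assignment$ids)
  d <- cohort$data[cohort$data$visit_month %in% visit_months() &
                     cohort$data$patient_id %in% assignment$ids, ,
                   drop = FALSE]
  d$cluster <- cluster_names(assignment)[lab[d$patient_id]]
  agg <- stats::aggregate(value ~ cluster + item + visit_month, data = d,
                          FUN = function(x) c(mean = mean(x),
                                              sd = if (length(x) > 1)
                                                stats::sd(x) else 0,
                                              n = length(x)))
  out <- data.frame(cluster = agg$cluster, item = agg$item,
                    month = agg$visit_month,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = as.integer(agg$value[, "n"]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster, match(out$item, clinical_items()),
                   out$month), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trajectory_summary", "data.frame")
  out
}

#' At-biopsy summary table by cluster
#'
#' Mean (SD) of the five items at the time of kidney biopsy, per cluster and
#' for the pooled total, formatted `"x.xx (y.yy)"`. Empty clusters are
#' omitted.
#'
#' @inheritParams trajectory_means
#' @return A `baseline_table`: formatted data frame (items x clusters +
#'   Total) with numeric matrices in attributes `mean`, `sd` and cluster
#'   sizes in `sizes`.
#' @export
baseline_table <- function(cohort, assignment) {
  check_assignment(cohort, assignment)
  base <- cohort$data[cohort$data$visit_month == 0L &
                        cohort$data$patient_id %in% assignment$ids, ,
                      drop = FALSE]
  if (!nrow(base)) stopf("cohort has no baseline (month 0) values")
  lab <- stats::setNames(assignment$labels, assignment$ids)
  base$cluster <- cluster_names(assignment)[lab[base$patient_id]]
  present <- sort(unique(base$cluster))
  cols <- c(present, "Total")
  items <- clinical_items()
  mean_m <- sd_m <- matrix(NA_real_, length(items), length(cols),
                           dimnames = list(items, cols))
  for (cl in cols) {
    rows <- if (cl == "Total") base else base[base$cluster == cl, ,
                                              drop = FALSE]
    for (j in items) {
      x <- rows$value[rows$item == j]
      mean_m[j, cl] <- mean(x)
      sd_m[j, cl] <- if (length(x) > 1) stats::sd(x) else 0
    }
  }
  fmt <- matrix(sprintf("%.2f (%.2f)", mean_m, sd_m), nrow = length(items),
                dimnames = dimnames(mean_m))
  out <- as.data.frame(fmt, stringsAsFactors = FALSE)
  out <- cbind(item = items, out)
  rownames(out) <- NULL
  sizes <- table(factor(cluster_names(assignment)[assignment$labels],
                        levels = present))
  structure(out, mean = mean_m, sd = sd_m, sizes = sizes,
            class = c("baseline_table", "data.frame"))
}

#' Disease-by-cluster crosstab
#'
#' Counts of each primary kidney disease within each assigned cluster, with
#' row and column totals; the grand total equals the assigned-cohort size.
#'
#' @inheritParams trajectory_means
#' @return A contingency `table` (diseases + Total x clusters + Total).
#' @export
disease_crosstab <- function(cohort, assignment) {
  check_assignment(cohort, assignment)
  info <- cohort$info[match(assignment$ids, cohort$info$patient_id), ,
                      drop = FALSE]
  bad <- which(!info$disease %in% disease_labels())
  if (length(bad))
    stopf("unknown disease label '%s' (patient %s)", info$disease[bad[1]],
          info$patient_id[bad[1]])
  tab <- table(disease = factor(info$disease, levels = disease_labels()),
               cluster = cluster_names(assignment)[assignment$labels])
  stats::addmargins(tab, FUN = list(Total = sum), quiet = TRUE)
}

#' Full cluster profile
#'
#' Bundles the reporting surfaces: cluster sizes, per-cluster item time
#' courses, the at-biopsy table, the disease crosstab, and the canonical
#' severity ranks.
#'
#' @inheritParams trajectory_means
#' @return A `cluster_profile` list.
#' @export
cluster_profile <- function(cohort, assignment) {
  check_assignment(cohort, assignment)
  traj <- trajectory_means(cohort, assignment)
  sizes <- table(cluster = cluster_names(assignment)[assignment$labels])
  structure(list(sizes = sizes,
                 trajectory = traj,
                 baseline = baseline_table(cohort, assignment),
                 crosstab = disease_crosstab(cohort, assignment),
                 severity = canonical_severity_order(traj)),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("<cluster_profile>\ncluster sizes:\n")
  print(x$sizes)
  cat("severity ranks (1 = mildest):\n")
  print(x$severity)
  invisible(x)
}

#' Canonical severity ordering of clusters
#'
#' Operationalizes "severity increases across clusters" with a reproducible
#' proxy: clusters are ranked by ascending mean serum creatinine at month 24
#' (the end of follow-up), ties broken by ascending month-24 UPCR mean, then
#' by original cluster label order. The returned map is a bijection
#' cluster -> rank, with rank 1 the mildest course.
#'
#' @param profile A `cluster_profile` or a `trajectory_summary` (from
#'   [trajectory_means()]) containing month-24 creatinine means.
#' @return Named integer vector of ranks.
#' @export
canonical_severity_order <- function(profile) {
  traj <- if (inherits(profile, "cluster_profile")) profile$trajectory
  else profile
  if (!is.data.frame(traj))
    stopf("profile must be a cluster_profile or trajectory_summary")
  cr <- traj[traj$item == "creatinine" & traj$month == 24L, , drop = FALSE]
  if (!nrow(cr)) stopf("profile lacks month-24 creatinine summaries")
  up <- traj[traj$item == "upcr" & traj$month == 24L, , drop = FALSE]
  clusters <- cr$cluster
  upcr24 <- up$mean[match(clusters, up$cluster)]
  upcr24[is.na(upcr24)] <- 0
  ord <- order(cr$mean, upcr24, seq_along(clusters))
  ranks <- integer(length(clusters))
  ranks[ord] <- seq_along(clusters)
  stats::setNames(ranks, clusters)
}

#' Max-component log-likelihood grid for contour plotting
#'
#' Evaluates `max_k [log w_k + log N(x; mu_k, Sigma_k)]` on a regular grid
#' over a latent-plane rectangle, the surface whose level curves are the
#' cluster contour lines; component means are returned for overlay.
#'
#' @param model An `ns_gmm` over a 2-d latent space.
#' @param bounds Numeric length-4 vector `c(z1_min, z1_max, z2_min, z2_max)`,
#'   non-degenerate.
#' @param resolution Grid nodes per axis (>= 2).
#' @return A `likelihood_contours` list: axis vectors `z1`, `z2`, the
#'   `resolution x resolution` matrix `loglik` (rows index z1), and `means`.
#' @export
likelihood_contours <- function(model, bounds, resolution = 100L) {
  if (!inherits(model, "ns_gmm")) stopf("model must be an ns_gmm")
  if (length(bounds) != 4L || !all(is.finite(bounds)) ||
      bounds[1] >= bounds[2] || bounds[3] >= bounds[4])
    stopf("bounds must be c(z1_min, z1_max, z2_min, z2_max) with min < max")
  if (resolution < 2L) stopf("resolution must be at least 2")
  z1 <- seq(bounds[1], bounds[2], length.out = resolution)
  z2 <- seq(bounds[3], bounds[4], length.out = resolution)
  nodes <- as.matrix(expand.grid(z1 = z1, z2 = z2))
  ll <- component_log_likelihood(model, nodes)
  ll <- matrix(ll, nrow = nrow(nodes))
  grid <- matrix(apply(ll, 1L, max), nrow = resolution)  # rows: z1 axis
  structure(list(z1 = z1, z2 = z2, loglik = grid, means = model$means),
            class = "likelihood_contours")
}

#' @export
as.data.frame.likelihood_contours <- function(x, ...) {
  data.frame(z1 = rep(x$z1, times = length(x$z2)),
             z2 = rep(x$z2, each = length(x$z1)),
             loglik = as.vector(x$loglik))
}
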