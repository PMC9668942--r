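# Trajectory archetypes: the generative building blocks of the synthetic
# cohort. An archetype holds the at-biopsy (baseline) means/SDs of the five
# clinical items for one planted cluster, the multiplicative course shape
# that turns baseline means into visit-level means, visit-level dispersions,
# and the distribution of histopathological diagnoses within the cluster.

#' Construct a trajectory archetype
#'
#' An archetype describes one planted cluster of clinical courses: where its
#' patients start (baseline mean/SD per item), how each item evolves over the
#' five scheduled visits (a matrix of unitless multipliers applied to the
#' baseline mean), how much visit-level noise to add, and which primary
#' kidney diseases its patients carry.
#'
#' @param cluster_id Label, e.g. `"C1"`.
#' @param weight Mixing probability in `(0, 1]`.
#' @param baseline_mean,baseline_sd Numeric length-5 vectors named (or
#'   ordered) as [clinical_items()]: creatinine (mg/dL), albumin (g/dL),
#'   hematuria grade, proteinuria grade, UPCR (g/gCr). SDs strictly positive.
#' @param course_multiplier 5 x 5 numeric matrix (items x visits): visit-level
#'   mean of item j at visit t is `baseline_mean[j] * course_multiplier[j, t]`.
#' @param visit_sd 5 x 5 matrix of strictly positive visit-level SDs, same
#'   layout.
#' @param disease_probs Probability vector over [disease_labels()], summing
#'   to 1.
#' @return An object of class `archetype_spec`.
#' @seealso [make_default_archetypes()], [generate_cohort()]
#' @export
archetype_spec <- function(cluster_id, weight, baseline_mean, baseline_sd,
                           course_multiplier, visit_sd, disease_probs) {
  items <- clinical_items()
  as_item_vec <- function(x, what) {
    if (length(x) != 5L) stopf("%s must have length 5", what)
    x <- as.numeric(if (!is.null(names(x))) x[items] else x)
    if (anyNA(x)) stopf("%s has missing or misnamed entries", what)
    names(x) <- items
    x
  }
  as_item_mat <- function(x, what) {
    x <- as.matrix(x)
    if (!all(dim(x) == c(5L, 5L))) stopf("%s must be a 5 x 5 matrix", what)
    dimnames(x) <- list(items, paste0("m", visit_months()))
    x
  }
  baseline_mean <- as_item_vec(baseline_mean, "baseline_mean")
  baseline_sd <- as_item_vec(baseline_sd, "baseline_sd")
  course_multiplier <- as_item_mat(course_multiplier, "course_multiplier")
  visit_sd <- as_item_mat(visit_sd, "visit_sd")
  if (!is.numeric(weight) || length(weight) != 1L || weight <= 0 || weight > 1)
    stopf("weight must be a single probability in (0, 1]")
  if (any(baseline_sd <= 0)) stopf("baseline_sd must be strictly positive")
  if (any(visit_sd <= 0)) stopf("visit_sd must be strictly positive")
  if (length(disease_probs) != length(disease_labels()))
    stopf("disease_probs must have length %d", length(disease_labels()))
  disease_probs <- as.numeric(disease_probs)
  if (any(disease_probs < 0) || abs(sum(disease_probs) - 1) > 1e-9)
    stopf("disease_probs must be non-negative and sum to 1")
  names(disease_probs) <- disease_labels()
  structure(
    list(cluster_id = as.character(cluster_id), weight = weight,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         course_multiplier = course_multiplier, visit_sd = visit_sd,
         disease_probs = disease_probs),
    class = "archetype_spec")
}

#' Default four-archetype configuration
#'
#' Returns the four planted clinical-course archetypes (C1-C4) used as the
#' package's reference study conditions:
#' \itemize{
#'   \item cluster weights proportional to 85:52:32:36 (the reported cluster
#'     sizes in a 205-case analysis set);
#'   \item per-cluster baseline means and SDs of the five items equal to the
#'     reported at-biopsy cluster summaries;
#'   \item per-cluster disease distributions equal to the reported
#'     disease-by-cluster crosstab;
#'   \item course multipliers chosen to realize the four described
#'     phenotypes: C1 mild disease with fast remission; C2 moderate disease
#'     with gradual remission; C3 initially high hematuria and proteinuria
#'     but a good course (brisk remission, stable creatinine); C4 initially
#'     high hematuria and proteinuria with persistent proteinuria, a
#'     non-declining UPCR and a late (months 12-24) rise in creatinine.
#' }
#' Visit-level SDs default to `0.4 * baseline_sd * pmax(multiplier, 0.25)`:
#' dispersion shrinks as an item remits but never below a tenth of the
#' baseline SD.
#'
#' @return List of four [archetype_spec()] objects named C1-C4.
#' @examples
#' arch <- make_default_archetypes()
#' arch$C1$baseline_mean["creatinine"]   # 0.99 mg/dL
#' sapply(arch, `[[`, "weight")          # 85:52:32:36 / 205
#' @export
make_default_archetypes <- function() {
  months <- paste0("m", visit_months())
  items <- clinical_items()
  base_mean <- list(
    C1 = c(0.99, 1.68, 1.58, 4.29, 7.51),
    C2 = c(1.18, 2.14, 2.37, 4.15, 7.18),
    C3 = c(1.20, 1.94, 2.28, 4.48, 8.11),
    C4 = c(1.34, 2.02, 2.89, 4.15, 10.25))
  base_sd <- list(
    C1 = c(0.57, 0.64, 1.35, 0.84, 3.83),
    C2 = c(0.71, 0.61, 1.27, 1.00, 4.23),
    C3 = c(0.98, 0.57, 1.17, 0.50, 4.73),
    C4 = c(0.79, 0.58, 1.20, 0.59, 6.46))
  sizes <- c(C1 = 85, C2 = 52, C3 = 32, C4 = 36)
  disease_counts <- list(                 #  MCD  MN FSGS MPGN IgAN MesPGN
    C1 = c(70, 9, 5, 1, 0, 0),
    C2 = c(10, 26, 5, 2, 6, 3),
    C3 = c(8, 24, 0, 0, 0, 0),
    C4 = c(2, 18, 8, 4, 3, 1))
  mk_mult <- function(creat, alb, hem, prot, upcr) {
    m <- rbind(creat, alb, hem, prot, upcr)
    dimnames(m) <- list(items, months)
    m
  }
  mult <- list(
    C1 = mk_mult(creat = c(1.00, 0.97, 0.95, 0.94, 0.94),
                 alb   = c(1.45, 1.85, 2.05, 2.10, 2.12),
                 hem   = c(0.60, 0.35, 0.20, 0.12, 0.10),
                 prot  = c(0.45, 0.18, 0.08, 0.05, 0.04),
                 upcr  = c(0.30, 0.10, 0.05, 0.03, 0.02)),
    C2 = mk_mult(creat = c(1.00, 1.00, 0.99, 0.98, 0.97),
                 alb   = c(1.10, 1.25, 1.40, 1.55, 1.65),
                 hem   = c(0.85, 0.75, 0.62, 0.50, 0.38),
                 prot  = c(0.95, 0.85, 0.70, 0.50, 0.25),
                 upcr  = c(0.90, 0.75, 0.55, 0.32, 0.15)),
    C3 = mk_mult(creat = c(1.05, 1.04, 1.02, 1.00, 0.98),
                 alb   = c(1.20, 1.55, 1.80, 1.95, 2.00),
                 hem   = c(1.05, 0.90, 0.55, 0.28, 0.15),
                 prot  = c(1.00, 0.60, 0.25, 0.10, 0.06),
                 upcr  = c(0.90, 0.45, 0.18, 0.07, 0.04)),
    C4 = mk_mult(creat = c(1.00, 1.03, 1.10, 1.28, 1.55),
                 alb   = c(1.05, 1.08, 1.12, 1.12, 1.08),
                 hem   = c(0.95, 0.92, 0.88, 0.85, 0.85),
                 prot  = c(0.98, 0.95, 0.92, 0.94, 0.96),
                 upcr  = c(0.96, 0.92, 0.94, 1.02, 1.12)))
  out <- lapply(names(sizes), function(k) {
    archetype_spec(
      cluster_id = k,
      weight = unname(sizes[k] / sum(sizes)),
      baseline_mean = base_mean[[k]],
      baseline_sd = base_sd[[k]],
      course_multiplier = mult[[k]],
      visit_sd = 0.4 * base_sd[[k]] * pmax(mult[[k]], 0.25),
      disease_probs = disease_counts[[k]] / sum(disease_counts[[k]]))
  })
  names(out) <- names(sizes)
  out
}

#' Rescale archetype noise levels
#'
#' Multiplies the baseline and/or visit-level SDs of every archetype by a
#' constant. `visit_scale < 1` is the "separation knob": it tightens
#' trajectories around their cluster course and makes planted clusters easier
#' to recover downstream.
#'
#' @param archetypes List of [archetype_spec()] objects.
#' @param baseline_scale,visit_scale Positive multipliers for the baseline
#'   and visit-level SDs.
#' @return The rescaled archetype list.
#' @export
scale_archetype_noise <- function(archetypes, baseline_scale = 1,
                                  visit_scale = 1) {
  if (baseline_scale <= 0 || visit_scale <= 0)
    stopf("noise scales must be positive")
  lapply(archetypes, function(a) {
    archetype_spec(a$cluster_id, a$weight,
                   a$baseline_mean, a$baseline_sd * baseline_scale,
                   a$course_multiplier, a$visit_sd * visit_scale,
                   a$disease_probs)
  })
}

check_archetypes <- function(archetypes) {
  if (!length(archetypes) || !all(vapply(archetypes, inherits, TRUE,
                                         "archetype_spec")))
    stopf("archetypes must be a non-empty list of archetype_spec objects")
  w <- vapply(archetypes, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-9)
    stopf("archetype weights must sum to 1 (got %.6f)", sum(w))
  ids <- vapply(archetypes, `[[`, character(1), "cluster_id")
  if (anyDuplicated(ids)) stopf("archetype cluster_ids must be unique")
  invisible(archetypes)
}
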