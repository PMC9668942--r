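# Preprocessing: dipstick encoding, complete-case filtering, the optional
# treated-only sensitivity filter, and pooled z-scoring into the fixed-shape
# (n x 5 timesteps x 5 items) block the autoencoder consumes.

#' Encode dipstick urinalysis grades on the 0-5 ordinal scale
#'
#' Maps the semi-quantitative dipstick readings to integers:
#' `-` -> 0, `+-`/`+/-` (trace) -> 1, `1+` -> 2, `2+` -> 3, `3+` -> 4,
#' `4+` -> 5. Already-numeric inputs in `[0, 5]` pass through unchanged. A
#' six-level scale is used because reported proteinuria grade means exceed
#' 4.0, which is impossible on a 0-4 coding.
#'
#' @param grade_text Character or numeric vector.
#' @return Integer vector of grades in 0-5.
#' @examples
#' encode_dipstick(c("-", "2+", "4+"))
#' @export
encode_dipstick <- function(grade_text) {
  map <- c("-" = 0L, "+-" = 1L, "+/-" = 1L,
           "1+" = 2L, "2+" = 3L, "3+" = 4L, "4+" = 5L)
  map[["\u00b1"]] <- 1L  # the plus-minus (trace) sign itself
  x <- grade_text
  out <- integer(length(x))
  for (i in seq_along(x)) {
    xi <- x[[i]]
    if (is.numeric(xi)) {
      if (is.na(xi) || xi < 0 || xi > 5)
        stopf("dipstick grade '%s' at position %d is outside [0, 5]", xi, i)
      out[i] <- as.integer(round(xi))
      next
    }
    token <- trimws(as.character(xi))
    num <- suppressWarnings(as.numeric(token))
    if (!is.na(num)) {
      if (num < 0 || num > 5)
        stopf("dipstick grade '%s' at position %d is outside [0, 5]", token, i)
      out[i] <- as.integer(round(num))
    } else if (token %in% names(map)) {
      out[i] <- map[[token]]
    } else {
      stopf("unknown dipstick token '%s' at position %d", token, i)
    }
  }
  out
}

# Per-patient completeness: baseline + each scheduled visit must carry a
# non-missing value for all five items, each exactly once.
complete_ids <- function(cohort) {
  months <- c(0L, visit_months())
  d <- cohort$data[!is.na(cohort$data$value) &
                     cohort$data$visit_month %in% months &
                     cohort$data$item %in% clinical_items(), , drop = FALSE]
  key <- paste(d$patient_id, d$visit_month, d$item)
  d <- d[!duplicated(key), , drop = FALSE]
  cnt <- table(factor(d$patient_id, levels = cohort$info$patient_id))
  names(cnt)[cnt == length(months) * 5L]
}

#' Keep complete cases only
#'
#' Retains patients whose five clinical items are all observed at baseline
#' and at every scheduled visit (months 1, 3, 6, 12, 24), mirroring a
#' complete-case analysis ("completely traceable" cases). Input order is
#' preserved; retained/dropped counts are reported via a message and exposed
#' as attributes `n_retained` / `n_dropped`.
#'
#' @param cohort An `ns_cohort`.
#' @return The filtered `ns_cohort`.
#' @export
filter_complete <- function(cohort) {
  stopifnot(inherits(cohort, "ns_cohort"))
  keep <- complete_ids(cohort)
  keep <- cohort$info$patient_id[cohort$info$patient_id %in% keep]
  out <- subset_cohort(cohort, keep)
  message(sprintf("filter_complete: retained %d of %d patients (%d dropped)",
                  length(keep), n_patients(cohort),
                  n_patients(cohort) - length(keep)))
  attr(out, "n_retained") <- length(keep)
  attr(out, "n_dropped") <- n_patients(cohort) - length(keep)
  out
}

#' Exclude untreated patients (sensitivity analysis)
#'
#' Retains only patients flagged as treated with steroids or
#' immunosuppressive drugs; used to rerun the classification on the treated
#' subset (e.g. 186 of 205 cases when 19 are untreated).
#'
#' @param cohort An `ns_cohort`; the `treated` flag must be present
#'   (non-missing) for every patient.
#' @return The filtered `ns_cohort`.
#' @export
exclude_untreated <- function(cohort) {
  stopifnot(inherits(cohort, "ns_cohort"))
  tr <- cohort$info$treated
  if (is.null(tr) || anyNA(tr))
    stopf("treated flag missing for %d patient(s)",
          if (is.null(tr)) n_patients(cohort) else sum(is.na(tr)))
  keep <- cohort$info$patient_id[tr]
  out <- subset_cohort(cohort, keep)
  if (!length(keep)) warning("exclude_untreated: no treated patients remain")
  message(sprintf("exclude_untreated: retained %d of %d patients",
                  length(keep), n_patients(cohort)))
  out
}

#' Fit per-item standardization parameters
#'
#' Computes, for each clinical item, the mean and SD pooled over all five
#' scheduled visits of all patients (baseline values are excluded from the
#' model input and hence from scaling). SDs are floored at `1e-8` so that
#' constant items standardize to zero rather than dividing by zero.
#'
#' @param cohort A complete, non-empty `ns_cohort` (see [filter_complete()]).
#' @return A `scaler_params` object: named means and SDs per item.
#' @export
fit_scaler <- function(cohort) {
  stopifnot(inherits(cohort, "ns_cohort"))
  if (n_patients(cohort) == 0L) stopf("cannot fit a scaler on an empty cohort")
  d <- cohort$data[cohort$data$visit_month %in% visit_months(), , drop = FALSE]
  if (anyNA(d$value)) stopf("cohort has missing visit values; run filter_complete first")
  items <- clinical_items()
  m <- vapply(items, function(j) mean(d$value[d$item == j]), numeric(1))
  s <- vapply(items, function(j) stats::sd(d$value[d$item == j]), numeric(1))
  s[is.na(s)] <- 0
  structure(list(mean = m, sd = pmax(s, 1e-8)), class = "scaler_params")
}

#' Identity scaler (no standardization)
#'
#' @return A `scaler_params` with zero means and unit SDs, for running the
#'   model on raw units.
#' @export
identity_scaler <- function() {
  items <- clinical_items()
  structure(list(mean = stats::setNames(rep(0, 5), items),
                 sd = stats::setNames(rep(1, 5), items)),
            class = "scaler_params")
}

#' Standardize a cohort into a sequence batch
#'
#' Produces the `(n, 5 timesteps, 5 items)` numeric block consumed by the
#' autoencoder: `values[i, t, j] = (raw - mean_j) / sd_j`, with visits in
#' chronological order (months 1, 3, 6, 12, 24).
#'
#' @param cohort A complete `ns_cohort`.
#' @param params A `scaler_params` from [fit_scaler()] (or
#'   [identity_scaler()]).
#' @return A `sequence_batch`: list with `values` (n x 5 x 5 array), `ids`,
#'   and the `scaler` used.
#' @export
apply_scaler <- function(cohort, params) {
  stopifnot(inherits(cohort, "ns_cohort"))
  if (!inherits(params, "scaler_params"))
    stopf("params must be a scaler_params object")
  items <- clinical_items()
  if (!all(items %in% names(params$mean)) ||
      !all(items %in% names(params$sd)))
    stopf("scaler params missing item(s): %s",
          paste(setdiff(items, names(params$mean)), collapse = ", "))
  months <- visit_months()
  ids <- cohort$info$patient_id
  d <- cohort$data[cohort$data$visit_month %in% months, , drop = FALSE]
  arr <- array(NA_real_, c(length(ids), 5L, 5L),
               dimnames = list(ids, paste0("m", months), items))
  arr[cbind(match(d$patient_id, ids), match(d$visit_month, months),
            match(d$item, items))] <- d$value
  if (anyNA(arr))
    stopf("cohort is not complete; run filter_complete before apply_scaler")
  for (j in items)
    arr[, , j] <- (arr[, , j] - params$mean[[j]]) / params$sd[[j]]
  structure(list(values = arr, ids = ids, scaler = params),
            class = "sequence_batch")
}

#' @export
print.sequence_batch <- function(x, ...) {
  cat(sprintf("<sequence_batch> %d cases x %d timesteps x %d items\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3]))
  invisible(x)
}
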