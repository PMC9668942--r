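# Internal helpers shared across modules.

#' Names of the five clinical items
#'
#' Item order used throughout the package: serum creatinine (mg/dL), serum
#' albumin (g/dL), dipstick hematuria grade (ordinal 0-5), dipstick
#' proteinuria grade (ordinal 0-5), and urine protein-to-creatinine ratio
#' (g/gCr).
#'
#' @return Character vector of length 5.
#' @export
clinical_items <- function() {
  c("creatinine", "albumin", "hematuria", "proteinuria", "upcr")
}

#' Scheduled post-biopsy visit months
#'
#' @return Integer vector `c(1, 3, 6, 12, 24)`; baseline (at biopsy) is
#'   coded as month 0 in long-format tables.
#' @export
visit_months <- function() {
  c(1L, 3L, 6L, 12L, 24L)
}

#' Recognized primary kidney disease labels
#'
#' Abbreviations: minimal change disease (MCD), membranous nephropathy (MN),
#' focal segmental glomerulosclerosis (FSGS), membranoproliferative
#' glomerulonephritis (MPGN), IgA nephropathy (IgAN), and mesangial
#' proliferative glomerulonephritis (MesPGN).
#'
#' @return Character vector of length 6.
#' @export
disease_labels <- function() {
  c("MCD", "MN", "FSGS", "MPGN", "IgAN", "MesPGN")
}

# Items reported on the ordinal dipstick grid.
grade_items <- function() c("hematuria", "proteinuria")

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage sub-seed, kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) * 48271 + offset * 1009) %% 2147483629) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}
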