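#' Membership-function normalization of component scores
#'
#' Rescales each component-score column to the unit interval with the
#' membership (subordinate) function `U = (x - min) / (max - min)` computed
#' across treatments, so the worst treatment maps to 0 and the best to 1 on
#' every component.
#'
#' @param scores A numeric matrix, or a data frame of component scores
#'   optionally carrying a `treatment` column (as produced in
#'   `tolerance_pca$component_scores`).
#' @return Same shape as the input, values in \[0, 1\]; each column attains
#'   both 0 and 1 exactly.
#' @export
membership_normalize <- function(scores) {
  is_df <- is.data.frame(scores)
  trt <- NULL
  if (is_df) {
    scores <- as_tibble(scores)
    if ("treatment" %in% names(scores)) {
      trt <- scores$treatment
      scores <- scores[setdiff(names(scores), "treatment")]
    }
    m <- as.matrix(scores)
  } else {
    m <- as.matrix(scores)
  }
  if (!is.numeric(m) || any(!is.finite(m))) {
    abort("Component scores must be finite numbers.")
  }
  cols <- colnames(m) %||% paste0("PC", seq_len(ncol(m)))
  for (j in seq_len(ncol(m))) {
    rng <- range(m[, j])
    if (rng[1] == rng[2]) {
      abort(paste0("Component '", cols[j],
                   "' is constant across treatments; membership is degenerate."))
    }
    m[, j] <- (m[, j] - rng[1]) / (rng[2] - rng[1])
  }
  if (is_df) {
    out <- as_tibble(m)
    if (!is.null(trt)) out <- dplyr::bind_cols(tibble(treatment = trt), out)
    out
  } else {
    m
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted composite tolerance scores and ranks
#'
#' Combines membership-normalized component scores into one composite score
#' per treatment, `CS = sum_j W_j * U_j`, and ranks treatments (rank 1 =
#' highest composite; ties keep input order).
#'
#' @param membership Membership matrix or data frame (treatments x retained
#'   components, values in \[0, 1\]), optionally with a `treatment` column.
#' @param weights Numeric weights, one per component, summing to 1.
#' @return A tibble with columns `treatment` (if supplied), `composite`, and
#'   `rank`.
#' @export
composite_scores <- function(membership, weights) {
  trt <- NULL
  if (is.data.frame(membership)) {
    membership <- as_tibble(membership)
    if ("treatment" %in% names(membership)) {
      trt <- membership$treatment
      membership <- membership[setdiff(names(membership), "treatment")]
    }
  }
  m <- as.matrix(membership)
  if (ncol(m) != length(weights)) {
    abort(paste0("Membership has ", ncol(m), " columns but ", length(weights),
                 " weights were supplied."))
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must sum to 1.")
  }
  cs <- drop(m %*% weights)
  out <- tibble(
    composite = as.numeric(cs),
    rank = rank(-cs, ties.method = "first")
  )
  if (!is.null(trt)) out <- dplyr::bind_cols(tibble(treatment = trt), out)
  out
}

#' Signed percent change between two values
#'
#' `100 * (value - reference) / reference`, rounded half-up (away from zero)
#' to two decimals -- the convention used when comparing composite tolerance
#' scores or indicator means between treatments.
#'
#' @param reference Baseline value(s); must be nonzero.
#' @param value New value(s).
#' @return Signed percent change(s), 2 decimals.
#' @examples
#' percent_change(0.61, 0.73)    #  19.67
#' percent_change(607.94, 508.73) # -16.32
#' @export
percent_change <- function(reference, value) {
  if (any(reference == 0)) abort("`reference` must be nonzero.")
  pct <- 100 * (value - reference) / reference
  round_half_up(pct, 2)
}

round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
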