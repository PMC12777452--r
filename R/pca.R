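#' Principal-component analysis of a standardized indicator table
#'
#' Column z-scores the standardized indicator values, eigendecomposes the
#' resulting correlation matrix, and retains the smallest number of leading
#' components whose cumulative variance contribution reaches
#' `cumulative_threshold`. Component scores are the projections of the
#' z-scored data onto the (sign-fixed) eigenvectors.
#'
#' Eigenvector sign is mathematically arbitrary but matters downstream
#' because membership normalization is not sign-invariant, so a fixed
#' convention is applied: each component is flipped so that its
#' largest-magnitude coefficient is positive, ties broken by the lowest
#' indicator index.
#'
#' @param std A standardized indicator table (see [standardize_indicators()]):
#'   `treatment` column plus numeric indicator columns.
#' @param cumulative_threshold Fraction in (0, 1]; retain the smallest k whose
#'   cumulative variance contribution is at least this. Default 0.85.
#' @param ddof Degrees-of-freedom correction for the z-scoring standard
#'   deviation: 1 (default) for the sample sd, 0 for the population sd. The
#'   correlation matrix, and hence the whole model, is unaffected; only the
#'   scale of the component scores changes.
#' @return An object of class `tolerance_pca`: a list with `coefficients`
#'   (components x indicators score-coefficient matrix over the full
#'   component set), `variance_contributions` (fractions summing to 1),
#'   `selected_k`, `component_scores` (treatments x selected_k tibble with a
#'   `treatment` column), `zscore_means`, `zscore_sds`, `treatments`,
#'   `indicators`, and `cumulative_threshold`.
#' @export
fit_tolerance_pca <- function(std, cumulative_threshold = 0.85, ddof = 1) {
  if (!is.numeric(cumulative_threshold) || length(cumulative_threshold) != 1L ||
      cumulative_threshold <= 0 || cumulative_threshold > 1) {
    abort("`cumulative_threshold` must be a single number in (0, 1].")
  }
  std <- as_tibble(std)
  if (!"treatment" %in% names(std)) abort("`std` must contain a `treatment` column.")
  ind <- setdiff(names(std), "treatment")
  if (nrow(std) < 2L) abort("PCA needs at least 2 treatments.")
  if (length(ind) < 2L) abort("PCA needs at least 2 indicator columns.")
  x <- as.matrix(std[ind])
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("Standardized values must all be finite numbers.")
  }

  n <- nrow(x)
  denom <- if (ddof == 1) n - 1 else n
  mu <- colMeans(x)
  sds <- sqrt(colSums(sweep(x, 2, mu)^2) / denom)
  constant <- sds <= 0 | !is.finite(sds)
  if (any(constant)) {
    abort(paste0("Indicator(s) constant across treatments (zero variance): ",
                 paste(ind[constant], collapse = ", ")))
  }
  z <- sweep(sweep(x, 2, mu), 2, sds, "/")

  r <- stats::cor(x)
  eig <- eigen(r, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # fixed sign convention: largest-|coefficient| entry positive per component
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))[1]
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  contrib <- vals / sum(vals)
  k <- which(cumsum(contrib) >= cumulative_threshold - 1e-12)[1]
  if (is.na(k)) k <- length(contrib)

  scores <- z %*% vecs[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  coef <- t(vecs)
  dimnames(coef) <- list(paste0("PC", seq_along(vals)), ind)

  structure(
    list(
      coefficients = coef,
      variance_contributions = contrib,
      selected_k = k,
      component_scores = dplyr::bind_cols(
        tibble(treatment = std$treatment),
        as_tibble(scores)
      ),
      zscore_means = setNames(mu, ind),
      zscore_sds = setNames(sds, ind),
      treatments = std$treatment,
      indicators = ind,
      cumulative_threshold = cumulative_threshold
    ),
    class = "tolerance_pca"
  )
}

#' @export
print.tolerance_pca <- function(x, ...) {
  cat("Tolerance PCA:", length(x$indicators), "indicators,",
      length(x$treatments), "treatments\n")
  cat("Variance contributions:",
      paste(sprintf("%.3f", x$variance_contributions), collapse = " "), "\n")
  cat("Retained components:", x$selected_k,
      sprintf("(cumulative %.3f >= %.2f)",
              sum(x$variance_contributions[seq_len(x$selected_k)]),
              x$cumulative_threshold), "\n")
  invisible(x)
}

#' Variance-contribution weights of the retained components
#'
#' Each retained component j receives weight
#' `W_j = PC_j / (PC_1 + ... + PC_k)`, its variance contribution divided by
#' the summed contributions of all k retained components, so the weights form
#' a convex combination (sum to 1).
#'
#' @param model A `tolerance_pca` fit from [fit_tolerance_pca()].
#' @return Numeric vector of length `selected_k`, named `PC1..PCk`.
#' @export
compute_weights <- function(model) {
  if (!inherits(model, "tolerance_pca")) {
    abort("`model` must be a `tolerance_pca` object.")
  }
  k <- model$selected_k
  if (k < 1L) abort("No retained components.")
  pc <- model$variance_contributions[seq_len(k)]
  total <- sum(pc)
  if (total <= 0) abort("Retained variance contributions sum to zero.")
  setNames(pc / total, paste0("PC", seq_len(k)))
}
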