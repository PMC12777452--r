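#' Comprehensive tolerance evaluation of a treatment panel
#'
#' Runs the full composite-scoring pipeline on a raw treatments-by-indicators
#' table: control-relative standardization with indicator polarity, PCA of
#' the z-scored standardized values, variance-contribution weighting of the
#' retained components, membership (min-max) normalization of the component
#' scores, and the weighted composite score with ranks (rank 1 = most
#' tolerant).
#'
#' @inheritParams standardize_indicators
#' @inheritParams fit_tolerance_pca
#' @return An object of class `tolerance_eval` bundling the standardized
#'   table, the `tolerance_pca` model, `weights`, the `membership` tibble,
#'   the per-treatment `scores` tibble (`treatment`, `composite`, `rank`),
#'   and a `config` echo (`control`, `cumulative_threshold`, `polarity`).
#'   Use [tidy()] for the per-treatment table, [glance()] for the one-row
#'   model summary, and [autoplot()] for a composite-score chart.
#' @examples
#' tbl <- tibble::tibble(
#'   treatment = c("W", "S100", "S300"),
#'   proline = c(160, 420, 610),
#'   sugar   = c(12, 20, 16),
#'   mda     = c(24, 30, 44)
#' )
#' fit <- evaluate_tolerance(
#'   tbl,
#'   polarity = c(proline = "positive", sugar = "positive", mda = "negative"),
#'   control = "W"
#' )
#' tidy(fit)
#' @export
evaluate_tolerance <- function(data, polarity, control,
                               cumulative_threshold = 0.85, ddof = 1) {
  std <- with_stage("standardization",
    standardize_indicators(data, polarity, control))
  model <- with_stage("pca",
    fit_tolerance_pca(std, cumulative_threshold, ddof = ddof))
  w <- with_stage("weighting", compute_weights(model))
  u <- with_stage("membership", membership_normalize(model$component_scores))
  scores <- with_stage("composite", composite_scores(u, w))

  ind <- setdiff(names(std), "treatment")
  structure(
    list(
      standardized = std,
      model = model,
      weights = w,
      membership = u,
      scores = scores,
      config = list(
        control = control,
        cumulative_threshold = cumulative_threshold,
        ddof = ddof,
        polarity = check_polarity(polarity, ind)
      )
    ),
    class = "tolerance_eval"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[", stage, "] ", conditionMessage(e)))
  })
}

#' @export
print.tolerance_eval <- function(x, ...) {
  cat("Composite tolerance evaluation\n")
  cat("  control:", x$config$control,
      " retained components:", x$model$selected_k,
      " weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n\n")
  print(x$scores[order(x$scores$rank), ])
  invisible(x)
}

#' @describeIn evaluate_tolerance Per-treatment tibble: composite score, rank,
#'   and the component score (`F_*`) and membership (`U_*`) for each retained
#'   component.
#' @param x A `tolerance_eval` object.
#' @param ... Unused.
#' @method tidy tolerance_eval
#' @export
tidy.tolerance_eval <- function(x, ...) {
  k <- x$model$selected_k
  f <- x$model$component_scores
  u <- x$membership
  names(f)[-1] <- paste0("F_PC", seq_len(k))
  names(u)[-1] <- paste0("U_PC", seq_len(k))
  x$scores |>
    dplyr::left_join(f, by = "treatment") |>
    dplyr::left_join(u, by = "treatment")
}

#' @describeIn evaluate_tolerance One-row summary: panel dimensions, retained
#'   components, cumulative contribution of the retained set, and the
#'   top-ranked treatment.
#' @method glance tolerance_eval
#' @export
glance.tolerance_eval <- function(x, ...) {
  tibble(
    n_treatments = nrow(x$scores),
    n_indicators = length(x$model$indicators),
    selected_k = x$model$selected_k,
    cumulative_contribution =
      sum(x$model$variance_contributions[seq_len(x$model$selected_k)]),
    cumulative_threshold = x$config$cumulative_threshold,
    control = x$config$control,
    top_treatment = x$scores$treatment[x$scores$rank == 1L]
  )
}

#' @describeIn evaluate_tolerance Bar chart of composite scores ordered by
#'   rank, control highlighted.
#' @param object A `tolerance_eval` object.
#' @method autoplot tolerance_eval
#' @export
autoplot.tolerance_eval <- function(object, ...) {
  d <- object$scores
  d$treatment <- stats::reorder(d$treatment, -d$rank)
  d$role <- ifelse(d$treatment == object$config$control, "control", "treated")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$treatment, y = .data$composite,
                                  fill = .data$role)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(control = "grey55", treated = "#2c7fb8")) +
    ggplot2::labs(x = NULL, y = "Composite tolerance score (CS)",
                  fill = NULL,
                  title = "Composite salt-tolerance scores by treatment") +
    ggplot2::theme_minimal()
}
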