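#' Validate a treatments-by-indicators table
#'
#' Checks the tidy indicator-table contract used throughout the scoring
#' pipeline: a `treatment` character column of unique labels followed by one
#' numeric column per physiological indicator, all values finite and strictly
#' positive (every value eventually enters a ratio against the control row,
#' and negative-polarity indicators additionally appear in a denominator).
#'
#' @param data A data frame with a `treatment` column and numeric indicator
#'   columns.
#' @param control The treatment label designated as the unstressed control.
#' @return `data` as a tibble, invisibly usable downstream.
#' @keywords internal
validate_indicator_table <- function(data, control) {
  data <- as_tibble(data)
  if (!"treatment" %in% names(data)) {
    abort("`data` must contain a `treatment` column of treatment labels.")
  }
  labels <- as.character(data$treatment)
  if (anyDuplicated(labels)) {
    dup <- unique(labels[duplicated(labels)])
    abort(paste0("Duplicated treatment label(s): ", paste(dup, collapse = ", ")))
  }
  if (!is.character(control) || length(control) != 1L || !control %in% labels) {
    abort(paste0("Control treatment '", as.character(control)[1],
                 "' not found among treatment labels."))
  }
  ind <- setdiff(names(data), "treatment")
  if (length(ind) < 1L) abort("`data` has no indicator columns.")
  for (col in ind) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      abort(paste0("Indicator column '", col, "' is not numeric."))
    }
    if (any(!is.finite(v))) {
      abort(paste0("Indicator '", col, "' contains non-finite values."))
    }
    if (any(v <= 0)) {
      bad <- labels[which(v <= 0)[1]]
      abort(paste0("Indicator '", col, "' has a non-positive value for treatment '",
                   bad, "'; all indicator measurements must be > 0."))
    }
  }
  data$treatment <- labels
  data
}

#' Standardize indicators against the control treatment
#'
#' Converts raw physiological measurements to dimensionless percent-of-control
#' scores. A *positive* indicator is standardized as
#' `100 * value / control_value`; a *negative* indicator (one whose increase
#' reflects weaker stress performance, e.g. malondialdehyde accumulation) is
#' standardized reciprocally as `100 * control_value / value`, so that larger
#' standardized scores are always the favourable direction. The control row
#' itself standardizes to 100 for every indicator under either polarity.
#'
#' @param data Indicator table: a data frame with a `treatment` column and one
#'   positive numeric column per indicator.
#' @param polarity Named character vector mapping every indicator column to
#'   `"positive"` or `"negative"`. Names must match the indicator columns
#'   exactly (no extras, none missing).
#' @param control Treatment label of the control row.
#' @return A tibble with the same shape as `data`; values are standardized
#'   percent scores.
#' @examples
#' tbl <- tibble::tibble(
#'   treatment = c("W", "S"),
#'   proline   = c(159.60, 607.94),
#'   mda       = c(24.41, 43.69)
#' )
#' standardize_indicators(
#'   tbl,
#'   polarity = c(proline = "positive", mda = "negative"),
#'   control = "W"
#' )
#' @export
standardize_indicators <- function(data, polarity, control) {
  data <- validate_indicator_table(data, control)
  ind <- setdiff(names(data), "treatment")
  polarity <- check_polarity(polarity, ind)
  ctrl_row <- which(data$treatment == control)
  out <- data
  for (col in ind) {
    v <- data[[col]]
    cv <- v[ctrl_row]
    if (cv <= 0) {
      abort(paste0("Control value for indicator '", col, "' is not positive."))
    }
    out[[col]] <- if (polarity[[col]] == "positive") 100 * v / cv else 100 * cv / v
  }
  out
}

check_polarity <- function(polarity, indicators) {
  if (is.data.frame(polarity)) {
    polarity <- setNames(as.character(polarity$polarity),
                         as.character(polarity$indicator))
  }
  if (is.null(names(polarity)) || any(names(polarity) == "")) {
    abort("`polarity` must be a named vector (indicator -> positive/negative).")
  }
  extra <- setdiff(names(polarity), indicators)
  missing <- setdiff(indicators, names(polarity))
  if (length(extra) || length(missing)) {
    abort(paste0(
      "Polarity map does not match indicator columns.",
      if (length(missing)) paste0(" Missing: ", paste(missing, collapse = ", "), "."),
      if (length(extra)) paste0(" Unknown: ", paste(extra, collapse = ", "), ".")
    ))
  }
  bad <- !polarity %in% c("positive", "negative")
  if (any(bad)) {
    abort(paste0("Polarity must be 'positive' or 'negative'; offending: ",
                 paste(names(polarity)[bad], collapse = ", ")))
  }
  polarity[indicators]
}
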