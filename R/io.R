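#' Read a treatments-by-indicators CSV
#'
#' Expects a header `treatment,<indicator1>,...`, one row per treatment,
#' UTF-8, decimal point, no thousands separators. Parsing is strict: any
#' non-numeric cell (including locale-style decimal commas) is rejected with
#' its row and column, as are duplicated treatment labels and ragged rows.
#'
#' @param path CSV file path.
#' @return An indicator tibble (`treatment` + numeric columns).
#' @export
read_indicator_csv <- function(path) {
  raw <- read_strict_csv(path)
  if (names(raw)[1] != "treatment") {
    abort(paste0("'", path, "': first column must be named 'treatment'."))
  }
  if (anyDuplicated(raw$treatment)) {
    dup <- unique(raw$treatment[duplicated(raw$treatment)])
    abort(paste0("'", path, "': duplicated treatment label(s): ",
                 paste(dup, collapse = ", ")))
  }
  out <- raw
  for (j in seq_along(raw)[-1]) {
    out[[j]] <- parse_numeric_col(raw[[j]], names(raw)[j], path)
  }
  out
}

#' Read a per-feature statistics CSV
#'
#' Columns `feature_id` plus any of `kind, fold_change, log2_fc, p_value,
#' q_value`; numeric columns parsed strictly with coordinates on failure.
#'
#' @param path CSV file path.
#' @return A tibble usable by [screen_degs()] / [screen_dams()].
#' @export
read_feature_stats_csv <- function(path) {
  raw <- read_strict_csv(path)
  require_cols(raw, "feature_id")
  if (anyDuplicated(raw$feature_id)) {
    abort(paste0("'", path, "': duplicated feature_id values."))
  }
  out <- raw
  for (col in intersect(c("fold_change", "log2_fc", "p_value", "q_value"),
                        names(raw))) {
    out[[col]] <- parse_numeric_col(raw[[col]], col, path)
  }
  out
}

#' Read a precomputed gene-metabolite pair CSV
#'
#' Columns `gene_id, metabolite_id, rho, gene_log2fc, met_log2fc`.
#'
#' @param path CSV file path.
#' @return A tibble for [classify_nine_quadrant()].
#' @export
read_pair_csv <- function(path) {
  raw <- read_strict_csv(path)
  require_cols(raw, c("gene_id", "metabolite_id", "rho",
                      "gene_log2fc", "met_log2fc"))
  out <- raw
  for (col in c("rho", "gene_log2fc", "met_log2fc")) {
    out[[col]] <- parse_numeric_col(raw[[col]], col, path, allow_na = TRUE)
  }
  out
}

#' Read a scoring configuration file (JSON or YAML)
#'
#' Fields: `control` (label), `cumulative_threshold` (fraction), and
#' `polarity` (indicator -> `positive`/`negative` map).
#'
#' @param path `.json`, `.yml`, or `.yaml` file.
#' @return A list with `control`, `cumulative_threshold`, `polarity` (named
#'   character vector).
#' @export
read_score_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$control)) abort(paste0("'", path, "': missing `control`."))
  if (is.null(cfg$polarity)) abort(paste0("'", path, "': missing `polarity`."))
  list(
    control = as.character(cfg$control),
    cumulative_threshold = as.numeric(cfg$cumulative_threshold %||% 0.85),
    polarity = unlist(cfg$polarity)
  )
}

#' Write a tibble to CSV atomically
#'
#' Writes to a temporary file in the destination directory and renames, so a
#' partial file never masquerades as a result.
#'
#' @param data Data frame to write.
#' @param path Destination path.
#' @param precision Significant digits for numeric columns. Default 6; use
#'   `NA` for full precision.
#' @return `path`, invisibly.
#' @export
write_csv_atomic <- function(data, path, precision = 6) {
  if (!is.na(precision)) {
    num <- vapply(data, is.numeric, logical(1))
    data[num] <- lapply(data[num], signif, digits = precision)
  }
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv.tmp")
  readr::write_csv(data, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Write a tolerance-evaluation report
#'
#' Emits the per-treatment CSV (treatment, composite, rank, per-component
#' score F and membership U) and a JSON summary (weights, variance
#' contributions, retained components, configuration echo). Both writes are
#' atomic.
#'
#' @param fit A `tolerance_eval` object.
#' @param csv_path,json_path Output paths.
#' @param precision Significant digits in the CSV. Default 6.
#' @return Invisibly, a list of the two paths.
#' @export
write_score_report <- function(fit, csv_path, json_path, precision = 6) {
  if (!inherits(fit, "tolerance_eval")) {
    abort("`fit` must be a `tolerance_eval` object.")
  }
  write_csv_atomic(tidy(fit), csv_path, precision)
  summary <- list(
    weights = as.list(fit$weights),
    variance_contributions = fit$model$variance_contributions,
    selected_k = fit$model$selected_k,
    config = list(
      control = fit$config$control,
      cumulative_threshold = fit$config$cumulative_threshold,
      polarity = as.list(fit$config$polarity)
    )
  )
  tmp <- tempfile(tmpdir = dirname(json_path), fileext = ".json.tmp")
  jsonlite::write_json(summary, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!file.rename(tmp, json_path)) {
    file.copy(tmp, json_path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(list(csv = csv_path, json = json_path))
}

read_strict_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: '", path, "'."))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort(paste0("'", path, "': needs a header and data rows."))
  cells <- strsplit(lines, ",", fixed = TRUE)
  width <- length(cells[[1]])
  header <- trimws(cells[[1]])
  body <- cells[-1]
  ragged <- which(lengths(body) != width)
  if (length(ragged)) {
    abort(paste0("'", path, "': ragged row ", ragged[1], " (expected ",
                 width, " fields, found ", lengths(body)[ragged[1]], ")."))
  }
  out <- lapply(seq_len(width), function(j) {
    trimws(vapply(body, `[[`, character(1), j))
  })
  names(out) <- header
  as_tibble(out)
}

parse_numeric_col <- function(chr, col, path, allow_na = FALSE) {
  v <- suppressWarnings(as.numeric(chr))
  na_ok <- allow_na & (chr %in% c("", "NA"))
  bad <- which(is.na(v) & !na_ok)
  if (length(bad)) {
    abort(paste0("'", path, "': non-numeric value '", chr[bad[1]],
                 "' in column '", col, "', data row ", bad[1],
                 " (decimal commas are not accepted)."))
  }
  v
}
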