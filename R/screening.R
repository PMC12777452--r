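#' Per-feature differential statistics from a two-group abundance matrix
#'
#' Computes, for every feature, the treatment/control mean fold change (with a
#' pseudocount), its log2, a Welch two-sample t-test p-value on
#' log2-transformed abundances, and the Benjamini-Hochberg adjusted q-value
#' across all features. This is the plumbing that feeds [screen_degs()] and
#' [screen_dams()] from raw sample matrices.
#'
#' @param abundance Data frame with a `feature_id` column and one numeric
#'   column per sample (abundances >= 0).
#' @param groups Named character vector mapping every sample column to one of
#'   exactly two group labels.
#' @param control_group The group label used as the fold-change denominator.
#' @param pseudocount Nonnegative value added to group means before the ratio
#'   and to abundances before the log2 transform. Default 1.
#' @param kind Optional feature kind tag (`"gene"` or `"metabolite"`) echoed
#'   into the output.
#' @return A tibble `feature_id, kind, fold_change, log2_fc, p_value,
#'   q_value`. Features whose test is degenerate (e.g. zero variance in both
#'   groups with equal means handled as p = 1; otherwise NA) keep `NA`
#'   p/q-values and are excluded by the screens with a logged count.
#' @export
compute_feature_stats <- function(abundance, groups, control_group,
                                  pseudocount = 1, kind = NA_character_) {
  abundance <- as_tibble(abundance)
  if (!"feature_id" %in% names(abundance)) {
    abort("`abundance` must contain a `feature_id` column.")
  }
  ids <- as.character(abundance$feature_id)
  if (anyDuplicated(ids)) abort("`feature_id` values must be unique.")
  samples <- setdiff(names(abundance), "feature_id")
  if (is.null(names(groups))) abort("`groups` must be named by sample column.")
  missing <- setdiff(samples, names(groups))
  if (length(missing)) {
    abort(paste0("Samples without a group label: ", paste(missing, collapse = ", ")))
  }
  groups <- groups[samples]
  lv <- unique(groups)
  if (length(lv) != 2L) abort("Exactly two groups are required.")
  if (!control_group %in% lv) {
    abort(paste0("Control group '", control_group, "' not found among group labels."))
  }
  treat_group <- setdiff(lv, control_group)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0) {
    abort("`pseudocount` must be a single nonnegative number.")
  }
  m <- as.matrix(abundance[samples])
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("Abundances must be finite and nonnegative.")
  }
  ctrl_cols <- which(groups == control_group)
  trt_cols <- which(groups == treat_group)
  if (length(ctrl_cols) < 2L || length(trt_cols) < 2L) {
    abort("Each group needs at least 2 samples.")
  }
  if (any(m + pseudocount <= 0)) {
    abort("All abundances plus pseudocount must be positive for the log2 transform.")
  }

  lg <- log2(m + pseudocount)
  fc <- (rowMeans(m[, trt_cols, drop = FALSE]) + pseudocount) /
        (rowMeans(m[, ctrl_cols, drop = FALSE]) + pseudocount)
  p <- vapply(seq_len(nrow(m)), function(i) {
    a <- lg[i, trt_cols]
    b <- lg[i, ctrl_cols]
    if (sd(a) == 0 && sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_)
    }
    tryCatch(stats::t.test(a, b, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))

  tibble(
    feature_id = ids,
    kind = kind,
    fold_change = as.numeric(fc),
    log2_fc = log2(as.numeric(fc)),
    p_value = p,
    q_value = p.adjust(p, method = "BH")
  )
}

#' Screen differentially expressed genes (DEGs)
#'
#' A feature is up-regulated if `fold_change > fc_threshold` and
#' `q_value <= q_max`; down-regulated if `fold_change < 1/fc_threshold` and
#' `q_value <= q_max`. The fold-change comparison is strict and the q-value
#' comparison inclusive; the q-value (BH-adjusted), not the raw p, gates
#' significance.
#'
#' @param stats A feature-statistics tibble as from [compute_feature_stats()]
#'   (needs `feature_id`, `fold_change`, `q_value`).
#' @param fc_threshold Ratio-scale fold-change cutoff (> 1). Default 1.42.
#' @param q_max Inclusive adjusted-p cutoff. Default 0.05.
#' @return A `screen_result`: the passing rows with a `direction` column
#'   (`"up"`/`"down"`), plus attributes `thresholds`, `counts`, and
#'   `n_missing` (features dropped for missing fold change or q).
#' @export
screen_degs <- function(stats, fc_threshold = 1.42, q_max = 0.05) {
  if (!is.numeric(fc_threshold) || fc_threshold <= 1) {
    abort("`fc_threshold` must be > 1 (ratio scale).")
  }
  stats <- as_tibble(stats)
  require_cols(stats, c("feature_id", "fold_change", "q_value"))
  ok <- is.finite(stats$fold_change) & is.finite(stats$q_value)
  n_missing <- sum(!ok)
  if (n_missing > 0) {
    rlang::inform(paste0("screen_degs: excluded ", n_missing,
                         " feature(s) with missing fold change or q-value."))
  }
  s <- stats[ok, ]
  dir <- dplyr::case_when(
    s$fold_change > fc_threshold & s$q_value <= q_max ~ "up",
    s$fold_change < 1 / fc_threshold & s$q_value <= q_max ~ "down",
    TRUE ~ NA_character_
  )
  new_screen_result(
    s[!is.na(dir), ], dir[!is.na(dir)],
    thresholds = list(fc_threshold = fc_threshold, q_max = q_max),
    n_missing = n_missing
  )
}

#' Screen differentially accumulated metabolites (DAMs)
#'
#' A metabolite is up-accumulated if `fold_change >= fc_up` and
#' `p_value < p_max`; down-accumulated if `fold_change <= fc_down` and
#' `p_value < p_max`. Fold-change bounds are inclusive and the p comparison
#' strict, and the raw p-value (not the BH q) gates significance -- the
#' deliberate asymmetry with [screen_degs()].
#'
#' @param stats A feature-statistics tibble (needs `feature_id`,
#'   `fold_change`, `p_value`).
#' @param fc_up Inclusive upper fold-change bound (> 1). Default 1.2.
#' @param fc_down Inclusive lower fold-change bound (< 1). Default 0.83.
#' @param p_max Strict raw-p cutoff. Default 0.05.
#' @return A `screen_result` (see [screen_degs()]).
#' @export
screen_dams <- function(stats, fc_up = 1.2, fc_down = 0.83, p_max = 0.05) {
  if (!(fc_down < 1 && 1 < fc_up)) {
    abort("Fold-change bounds must satisfy fc_down < 1 < fc_up.")
  }
  stats <- as_tibble(stats)
  require_cols(stats, c("feature_id", "fold_change", "p_value"))
  ok <- is.finite(stats$fold_change) & is.finite(stats$p_value)
  n_missing <- sum(!ok)
  if (n_missing > 0) {
    rlang::inform(paste0("screen_dams: excluded ", n_missing,
                         " feature(s) with missing fold change or p-value."))
  }
  s <- stats[ok, ]
  dir <- dplyr::case_when(
    s$fold_change >= fc_up & s$p_value < p_max ~ "up",
    s$fold_change <= fc_down & s$p_value < p_max ~ "down",
    TRUE ~ NA_character_
  )
  new_screen_result(
    s[!is.na(dir), ], dir[!is.na(dir)],
    thresholds = list(fc_up = fc_up, fc_down = fc_down, p_max = p_max),
    n_missing = n_missing
  )
}

new_screen_result <- function(rows, direction, thresholds, n_missing) {
  out <- dplyr::bind_cols(rows, tibble(direction = direction))
  structure(
    out,
    thresholds = thresholds,
    counts = c(up = sum(direction == "up"), down = sum(direction == "down")),
    n_missing = n_missing,
    class = c("screen_result", class(out))
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cnt <- attr(x, "counts")
  thr <- attr(x, "thresholds")
  cat("Differential screen:", cnt[["up"]], "up,", cnt[["down"]], "down",
      sprintf("(%d excluded for missing stats)\n", attr(x, "n_missing")))
  cat("Thresholds:",
      paste(names(thr), unlist(thr), sep = " = ", collapse = ", "), "\n")
  NextMethod()
}

require_cols <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", ")))
  }
  invisible(df)
}
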