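#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive mean ranks);
#' the monotone-association measure used to gate gene-metabolite pairs.
#'
#' @param x,y Numeric vectors of equal length >= 3, all values finite.
#' @return The correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("Spearman correlation needs at least 3 observations.")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite.")
  }
  if (sd(rank(x)) == 0 || sd(rank(y)) == 0) {
    abort("Zero rank variance: a constant vector has no defined correlation.")
  }
  stats::cor(x, y, method = "spearman")
}

#' Build gene-metabolite pair associations from abundance matrices
#'
#' For each candidate (gene, metabolite) pair, computes the Spearman
#' correlation of their abundances across the shared samples and attaches the
#' two log2 fold changes from the supplied per-feature statistics, yielding
#' the pair table that [classify_nine_quadrant()] consumes.
#'
#' @param gene_abund,met_abund Data frames with a `feature_id` column and the
#'   same sample columns (same names, same order not required).
#' @param gene_stats,met_stats Feature-statistics tables (as from
#'   [compute_feature_stats()]) providing `log2_fc` per `feature_id`.
#' @param pairs Optional tibble `gene_id, metabolite_id` restricting which
#'   pairs are formed; by default all genes x all metabolites (quadratic --
#'   supply candidates for large panels).
#' @return A tibble `gene_id, metabolite_id, rho, gene_log2fc, met_log2fc`.
#' @export
pair_associations <- function(gene_abund, met_abund, gene_stats, met_stats,
                              pairs = NULL) {
  gene_abund <- as_tibble(gene_abund)
  met_abund <- as_tibble(met_abund)
  require_cols(gene_abund, "feature_id")
  require_cols(met_abund, "feature_id")
  samples <- intersect(setdiff(names(gene_abund), "feature_id"),
                       setdiff(names(met_abund), "feature_id"))
  if (length(samples) < 3L) {
    abort("Gene and metabolite matrices share fewer than 3 sample columns.")
  }
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(
      gene_id = as.character(gene_abund$feature_id),
      metabolite_id = as.character(met_abund$feature_id)
    )
  }
  pairs <- as_tibble(pairs)
  require_cols(pairs, c("gene_id", "metabolite_id"))

  gm <- as.matrix(gene_abund[samples])
  rownames(gm) <- as.character(gene_abund$feature_id)
  mm <- as.matrix(met_abund[samples])
  rownames(mm) <- as.character(met_abund$feature_id)

  rho <- purrr::map2_dbl(pairs$gene_id, pairs$metabolite_id, function(g, m) {
    if (!g %in% rownames(gm) || !m %in% rownames(mm)) return(NA_real_)
    x <- gm[g, ]
    y <- mm[m, ]
    if (sd(rank(x)) == 0 || sd(rank(y)) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  })

  glfc <- setNames(gene_stats$log2_fc, as.character(gene_stats$feature_id))
  mlfc <- setNames(met_stats$log2_fc, as.character(met_stats$feature_id))
  tibble(
    gene_id = pairs$gene_id,
    metabolite_id = pairs$metabolite_id,
    rho = rho,
    gene_log2fc = unname(glfc[pairs$gene_id]),
    met_log2fc = unname(mlfc[pairs$metabolite_id])
  )
}

#' Nine-quadrant classification of gene-metabolite pairs
#'
#' Pairs passing the Spearman gate (`|rho| > rho_min` by default) are placed
#' on a 3x3 grid by the sign class of each member's log2 fold change --
#' down (`< -lfc_min`), unchanged (within `[-lfc_min, +lfc_min]`), or up
#' (`> +lfc_min`); all threshold comparisons are strict. The grid is numbered
#' with the gene class on the horizontal axis (down, unchanged, up, left to
#' right) and the metabolite class on the vertical axis (up on top):
#'
#' \preformatted{
#'   met up        | Q1 Q2 Q3
#'   met unchanged | Q4 Q5 Q6
#'   met down      | Q7 Q8 Q9
#'                   gene: down / unchanged / up
#' }
#'
#' So Q3 and Q7 are the concordant cells, Q1 and Q9 the discordant ones, and
#' Q5 holds pairs where neither member responds.
#'
#' @param pairs Tibble with `rho`, `gene_log2fc`, `met_log2fc` columns (e.g.
#'   from [pair_associations()]).
#' @param rho_min Strict Spearman gate. Default 0.8.
#' @param lfc_min Strict log2-fold-change magnitude needed to call a member
#'   up or down. Default 0.5.
#' @param gate `"absolute"` (default) gates on `|rho| > rho_min`; `"signed"`
#'   on `rho > rho_min`.
#' @return The input with a `quadrant` factor column (levels `"1"`..`"9"`,
#'   `"filtered"`, `"missing"`); pairs with missing rho or fold change are
#'   tallied as `"missing"`, never dropped. Attribute `counts` holds the
#'   per-level tally (see [quadrant_counts()]).
#' @export
classify_nine_quadrant <- function(pairs, rho_min = 0.8, lfc_min = 0.5,
                                   gate = c("absolute", "signed")) {
  gate <- match.arg(gate)
  if (!is.numeric(rho_min) || rho_min < 0 || rho_min >= 1) {
    abort("`rho_min` must be in [0, 1).")
  }
  if (!is.numeric(lfc_min) || lfc_min < 0) abort("`lfc_min` must be >= 0.")
  pairs <- as_tibble(pairs)
  require_cols(pairs, c("rho", "gene_log2fc", "met_log2fc"))

  miss <- !is.finite(pairs$rho) | !is.finite(pairs$gene_log2fc) |
          !is.finite(pairs$met_log2fc)
  gated <- if (gate == "absolute") abs(pairs$rho) > rho_min else pairs$rho > rho_min
  gated[miss] <- FALSE

  axis_class <- function(lfc) {
    dplyr::case_when(lfc < -lfc_min ~ 1L, lfc > lfc_min ~ 3L, TRUE ~ 2L)
  }
  gx <- axis_class(pairs$gene_log2fc)      # 1 down, 2 unchanged, 3 up
  myrow <- 4L - axis_class(pairs$met_log2fc) # row 1 = met up, 3 = met down
  q <- (myrow - 1L) * 3L + gx

  lev <- c(as.character(1:9), "filtered", "missing")
  lab <- dplyr::case_when(
    miss ~ "missing",
    !gated ~ "filtered",
    TRUE ~ as.character(q)
  )
  out <- pairs
  out$quadrant <- factor(lab, levels = lev)
  structure(out,
            counts = table(out$quadrant),
            gate = gate, rho_min = rho_min, lfc_min = lfc_min,
            class = c("nine_quadrant", class(out)))
}

#' Per-quadrant counts of a nine-quadrant classification
#'
#' @param x Result of [classify_nine_quadrant()].
#' @return A tibble `quadrant, n` covering quadrants 1-9 plus the `filtered`
#'   and `missing` tallies; `n` sums to the number of input pairs.
#' @export
quadrant_counts <- function(x) {
  if (!inherits(x, "nine_quadrant")) {
    abort("`x` must come from classify_nine_quadrant().")
  }
  tb <- table(x$quadrant)
  tibble(quadrant = names(tb), n = as.integer(tb))
}

#' @export
print.nine_quadrant <- function(x, ...) {
  cat("Nine-quadrant classification (gate:", attr(x, "gate"),
      "rho >", attr(x, "rho_min"), ", |log2FC| >", attr(x, "lfc_min"), ")\n")
  tb <- table(x$quadrant)
  cat(paste0("Q", names(tb)[1:9], "=", as.integer(tb)[1:9], collapse = " "),
      "| filtered:", tb[["filtered"]], "missing:", tb[["missing"]], "\n")
  NextMethod()
}

#' @describeIn classify_nine_quadrant Scatter of gene vs metabolite log2 fold
#'   change, coloured by quadrant; filtered/missing pairs in grey.
#' @param object A `nine_quadrant` object.
#' @param ... Unused.
#' @method autoplot nine_quadrant
#' @export
autoplot.nine_quadrant <- function(object, ...) {
  lfc <- attr(object, "lfc_min")
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene_log2fc, y = .data$met_log2fc,
                                  colour = .data$quadrant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(-lfc, lfc), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Gene log2 fold change", y = "Metabolite log2 fold change",
                  colour = "Quadrant",
                  title = "Nine-quadrant transcript-metabolite classification") +
    ggplot2::theme_minimal()
}
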