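#' Specify a synthetic treatment-by-indicator panel design
#'
#' Describes the ground truth from which [generate_indicator_table()] draws:
#' per-indicator control means and polarities, a per-treatment effect
#' multiplier for every indicator (the designed dose-response), a replicate
#' count, and a multiplicative noise coefficient of variation.
#'
#' @param multipliers Tibble with a `treatment` column and one positive
#'   numeric column per indicator; the control row must be exactly 1
#'   everywhere.
#' @param polarity Named character vector (`"positive"`/`"negative"`) over
#'   the indicator columns.
#' @param control_mean Named positive numeric vector of control-level means,
#'   one per indicator, in the indicator's own units.
#' @param control Treatment label of the control row.
#' @param cv Replicate noise coefficient of variation (single nonnegative
#'   number). Default 0.05.
#' @param n_reps Biological replicates averaged per emitted value. Default 3.
#' @return An `indicator_design` object.
#' @seealso [default_indicator_design()] for the built-in panel emulating a
#'   two-series (water vs NaHS) NaCl dose-response experiment.
#' @export
indicator_design <- function(multipliers, polarity, control_mean, control,
                             cv = 0.05, n_reps = 3) {
  multipliers <- validate_indicator_table(multipliers, control)
  ind <- setdiff(names(multipliers), "treatment")
  polarity <- check_polarity(polarity, ind)
  if (is.null(names(control_mean)) ||
      !setequal(names(control_mean), ind)) {
    abort("`control_mean` must be named and cover exactly the indicator columns.")
  }
  control_mean <- control_mean[ind]
  if (any(!is.finite(control_mean)) || any(control_mean <= 0)) {
    abort("`control_mean` values must be positive and finite.")
  }
  ctrl <- which(multipliers$treatment == control)
  if (any(abs(as.matrix(multipliers[ctrl, ind]) - 1) > 1e-12)) {
    abort("The control row of `multipliers` must be exactly 1 for every indicator.")
  }
  if (!is.numeric(cv) || length(cv) != 1L || cv < 0) {
    abort("`cv` must be a single nonnegative number.")
  }
  if (!is.numeric(n_reps) || n_reps < 1L) abort("`n_reps` must be >= 1.")
  structure(
    list(multipliers = multipliers, polarity = polarity,
         control_mean = control_mean, control = control,
         cv = cv, n_reps = as.integer(n_reps)),
    class = "indicator_design"
  )
}

#' Generate a synthetic indicator table from a design
#'
#' Each emitted value is the mean over `n_reps` simulated replicates of
#' `control_mean * multiplier * (1 + noise)`, with
#' `noise ~ Normal(0, cv)` truncated below at -0.9 so values stay positive.
#' At `cv = 0` the table equals the design means exactly; the output is
#' deterministic given the seed.
#'
#' @param design An [indicator_design()].
#' @param seed Integer seed (required; no global RNG state is consumed).
#' @return A tibble ready for [evaluate_tolerance()]: `treatment` column plus
#'   one column per indicator.
#' @export
generate_indicator_table <- function(design, seed) {
  if (!inherits(design, "indicator_design")) {
    abort("`design` must be an `indicator_design` object.")
  }
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is required.")
  ind <- setdiff(names(design$multipliers), "treatment")
  mult <- as.matrix(design$multipliers[ind])
  n_t <- nrow(mult)
  withr::with_seed(as.integer(seed), {
    out <- design$multipliers
    for (j in seq_along(ind)) {
      mean_j <- design$control_mean[[ind[j]]]
      vals <- numeric(n_t)
      for (i in seq_len(n_t)) {
        noise <- if (design$cv > 0) {
          pmax(rnorm(design$n_reps, 0, design$cv), -0.9)
        } else {
          rep(0, design$n_reps)
        }
        vals[i] <- mean(mean_j * mult[i, j] * (1 + noise))
      }
      out[[ind[j]]] <- vals
    }
    out
  })
}

#' Built-in indicator panel design
#'
#' A ready-made [indicator_design()] emulating a tray-seedling salt-stress
#' experiment with two irrigation series (water vs an H2S donor) crossed with
#' NaCl doses of 0/50/100/200/300 mM: ten treatments (`W`, `WS50`..`WS300`,
#' `H`, `HS50`..`HS300`), control `W`, three replicates, and a twelve-
#' indicator physiological panel (antioxidant enzymes, osmolytes, membrane
#' damage, ion balance, root architecture, water content). Effect multipliers
#' encode the canonical response shapes: enzyme activities peaking at
#' moderate salt, monotone proline and malondialdehyde accumulation, starch
#' decline, K+ loss and Na+/K+ rise with dose, and an attenuation of the
#' damage indicators in the donor-treated series. Malondialdehyde and the
#' Na+/K+ ratio carry negative polarity; all other indicators positive.
#'
#' @param cv Replicate noise CV. Default 0.05.
#' @param n_reps Replicates per value. Default 3.
#' @return An `indicator_design`.
#' @export
default_indicator_design <- function(cv = 0.05, n_reps = 3) {
  trt <- c("W", "WS50", "WS100", "WS200", "WS300",
           "H", "HS50", "HS100", "HS200", "HS300")
  m <- tibble(
    treatment = trt,
    sod       = c(1, 1.25, 1.485, 1.35, 1.20, 1.02, 1.30, 1.53, 1.42, 1.25),
    pod       = c(1, 1.50, 2.00, 2.80, 3.42, 1.05, 1.90, 2.50, 3.10, 3.60),
    cat       = c(1, 1.20, 1.50, 1.80, 1.60, 1.02, 1.30, 1.60, 1.90, 1.99),
    protein   = c(1, 1.175, 1.10, 1.05, 0.95, 1.00, 1.05, 1.00, 0.95, 0.90),
    proline   = c(1, 1.40, 2.00, 2.90, 3.81, 1.00, 1.30, 1.80, 2.50, 3.19),
    sugar     = c(1, 1.20, 1.35, 1.544, 1.40, 1.00, 1.483, 1.40, 1.45, 1.35),
    starch    = c(1, 0.95, 0.90, 0.883, 0.745, 1.00, 0.97, 0.94, 0.90, 0.83),
    mda       = c(1, 1.20, 1.40, 1.65, 1.79, 1.00, 1.10, 1.25, 1.40, 1.55),
    potassium = c(1, 0.95, 0.90, 0.82, 0.737, 1.00, 0.97, 0.94, 0.90, 0.85),
    na_k      = c(1, 1.60, 2.30, 3.10, 3.856, 0.98, 1.40, 2.00, 2.60, 3.30),
    srl       = c(1, 0.85, 0.65, 0.45, 0.319, 1.00, 0.90, 0.75, 0.79, 0.50),
    water     = c(1, 0.98, 0.95, 0.90, 0.838, 1.00, 0.99, 0.97, 0.94, 0.88)
  )
  indicator_design(
    multipliers = m,
    polarity = c(sod = "positive", pod = "positive", cat = "positive",
                 protein = "positive", proline = "positive",
                 sugar = "positive", starch = "positive",
                 mda = "negative", potassium = "positive",
                 na_k = "negative", srl = "positive", water = "positive"),
    control_mean = c(sod = 137.2, pod = 36.09, cat = 250, protein = 4.0,
                     proline = 159.60, sugar = 13.0, starch = 39.57,
                     mda = 24.41, potassium = 8.81, na_k = 2.01,
                     srl = 4457.49, water = 71.69),
    control = "W", cv = cv, n_reps = n_reps
  )
}

#' Specify a paired gene-metabolite simulation design
#'
#' Two-group (control vs treatment) paired omics matrices: background
#' features are independent log-normal abundances with true fold change 1;
#' each planted (gene, metabolite) pair shares a per-sample latent factor
#' inducing a monotone association of the designed sign, plus group mean
#' shifts implementing the designed log2 fold changes.
#'
#' @param n_genes,n_metabolites Total feature counts (planted pairs index
#'   into these).
#' @param n_per_group Samples per group (>= 3). Default 12.
#' @param planted Tibble `gene, metabolite, rho_sign, gene_log2fc,
#'   met_log2fc` (indices into the feature ranges; `rho_sign` is +1 or -1).
#'   May be empty.
#' @param base_abundance Background mean abundance. Default 1000.
#' @param noise_sd Log2-scale noise standard deviation. Default 0.5.
#' @param latent_cor Target correlation induced by the shared latent factor
#'   within a planted pair. Default 0.95.
#' @return An `omics_design` object.
#' @export
omics_design <- function(n_genes, n_metabolites, n_per_group = 12,
                         planted = NULL, base_abundance = 1000,
                         noise_sd = 0.5, latent_cor = 0.95) {
  if (n_per_group < 3L) abort("`n_per_group` must be >= 3.")
  if (n_genes < 1L || n_metabolites < 1L) {
    abort("Feature counts must be positive.")
  }
  if (base_abundance <= 0) abort("`base_abundance` must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  if (latent_cor <= 0 || latent_cor >= 1) abort("`latent_cor` must be in (0, 1).")
  if (is.null(planted)) {
    planted <- tibble(gene = integer(), metabolite = integer(),
                      rho_sign = numeric(), gene_log2fc = numeric(),
                      met_log2fc = numeric())
  }
  planted <- as_tibble(planted)
  if (nrow(planted) > 0) {
    require_cols(planted, c("gene", "metabolite", "rho_sign",
                            "gene_log2fc", "met_log2fc"))
    if (any(planted$gene < 1 | planted$gene > n_genes) ||
        any(planted$metabolite < 1 | planted$metabolite > n_metabolites)) {
      abort("Planted indices out of range.")
    }
    if (anyDuplicated(planted$gene) || anyDuplicated(planted$metabolite)) {
      abort("Each feature may be planted in at most one pair.")
    }
    if (!all(planted$rho_sign %in% c(-1, 1))) {
      abort("`rho_sign` must be +1 or -1.")
    }
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_metabolites = as.integer(n_metabolites),
         n_per_group = as.integer(n_per_group),
         planted = planted, base_abundance = base_abundance,
         noise_sd = noise_sd, latent_cor = latent_cor),
    class = "omics_design"
  )
}

#' Built-in paired-omics design
#'
#' 200 genes and 50 metabolites, 12 samples per group, five planted pairs
#' with |log2FC| = 2 spanning the concordant (Q3, Q7) and discordant
#' (Q1, Q9) quadrants, latent correlation target 0.95, log2 noise sd 0.5.
#'
#' @return An `omics_design`.
#' @export
default_omics_design <- function() {
  omics_design(
    n_genes = 200, n_metabolites = 50, n_per_group = 12,
    planted = tibble(
      gene        = 1:5,
      metabolite  = 1:5,
      rho_sign    = c(1, 1, -1, -1, 1),
      gene_log2fc = c(2, -2, 2, -2, 2),
      met_log2fc  = c(2, -2, -2, 2, 2)
    )
  )
}

#' Generate paired gene/metabolite matrices with planted associations
#'
#' @param design An [omics_design()].
#' @param seed Integer seed; identical design + seed gives identical output.
#' @return A list: `genes` and `metabolites` (tibbles with `feature_id` and
#'   sample columns `C1..Cn`, `T1..Tn`), `groups` (named sample -> group
#'   vector, groups `"control"` and `"treatment"`), and `truth` (planted
#'   pairs with ids and the `designed_quadrant` implied by the designed log2
#'   fold changes at the default 0.5 gate).
#' @export
generate_paired_omics <- function(design, seed) {
  if (!inherits(design, "omics_design")) {
    abort("`design` must be an `omics_design` object.")
  }
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is required.")
  n <- design$n_per_group
  samples <- c(paste0("C", seq_len(n)), paste0("T", seq_len(n)))
  groups <- setNames(rep(c("control", "treatment"), each = n), samples)
  is_trt <- groups == "treatment"
  mu <- log2(design$base_abundance)
  sdn <- design$noise_sd
  # planted features keep the background noise level: the log2-scale sd is
  # split into a shared latent component and an independent residual so the
  # within-pair correlation hits latent_cor; at sd 0 the pair is purely
  # latent and the association is exact
  if (sdn > 0) {
    amp <- sdn * sqrt(design$latent_cor)
    resid_sd <- sdn * sqrt(1 - design$latent_cor)
  } else {
    amp <- 1
    resid_sd <- 0
  }

  withr::with_seed(as.integer(seed), {
    gmat <- matrix(mu + sdn * rnorm(design$n_genes * 2 * n),
                   nrow = design$n_genes)
    mmat <- matrix(mu + sdn * rnorm(design$n_metabolites * 2 * n),
                   nrow = design$n_metabolites)
    if (nrow(design$planted) > 0) {
      for (i in seq_len(nrow(design$planted))) {
        p <- design$planted[i, ]
        latent <- rnorm(2 * n)
        gmat[p$gene, ] <- mu + p$gene_log2fc * is_trt + amp * latent +
          resid_sd * rnorm(2 * n)
        mmat[p$metabolite, ] <- mu + p$met_log2fc * is_trt +
          p$rho_sign * amp * latent + resid_sd * rnorm(2 * n)
      }
    }
    gene_ids <- sprintf("gene_%03d", seq_len(design$n_genes))
    met_ids <- sprintf("met_%03d", seq_len(design$n_metabolites))
    genes <- dplyr::bind_cols(tibble(feature_id = gene_ids),
                              as_tibble(2^gmat, .name_repair = ~samples))
    mets <- dplyr::bind_cols(tibble(feature_id = met_ids),
                             as_tibble(2^mmat, .name_repair = ~samples))
    truth <- design$planted
    if (nrow(truth) > 0) {
      truth$gene_id <- gene_ids[truth$gene]
      truth$metabolite_id <- met_ids[truth$metabolite]
      truth$designed_quadrant <- designed_quadrant(
        truth$gene_log2fc, truth$met_log2fc, lfc_min = 0.5)
    }
    list(genes = genes, metabolites = mets, groups = groups, truth = truth)
  })
}

designed_quadrant <- function(gene_lfc, met_lfc, lfc_min = 0.5) {
  cls <- function(v) dplyr::case_when(v < -lfc_min ~ 1L, v > lfc_min ~ 3L,
                                      TRUE ~ 2L)
  gx <- cls(gene_lfc)
  myrow <- 4L - cls(met_lfc)
  (myrow - 1L) * 3L + gx
}
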