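make_stats <- function(fc, p = NULL, q = NULL) {
  tibble::tibble(
    feature_id = paste0("f", seq_along(fc)),
    fold_change = fc,
    log2_fc = log2(fc),
    p_value = p %||% rep(0.01, length(fc)),
    q_value = q %||% rep(0.01, length(fc))
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("feature stats: fold changes, identical means, and BH q-values", {
  ab <- tibble::tibble(
    feature_id = c("a", "b", "c"),
    s1 = c(8, 10, 42), s2 = c(12, 10, 38),
    s3 = c(18, 10, 11), s4 = c(22, 10, 9)
  )
  groups <- c(s1 = "ctrl", s2 = "ctrl", s3 = "trt", s4 = "trt")
  st <- compute_feature_stats(ab, groups, "ctrl", pseudocount = 0)
  expect_equal(st$fold_change, c(2, 1, 0.25))  # group means (10,20),(10,10),(40,10)
  expect_equal(st$log2_fc, log2(st$fold_change), tolerance = 1e-9)
  expect_equal(st$fold_change[2], 1)
  expect_equal(st$log2_fc[2], 0)
  expect_equal(st$q_value, bh_stepup_oracle(st$p_value), tolerance = 1e-12)
})

test_that("BH adjustment equals the hand-coded step-up on random small lists", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))  # classic equal-spacing case, by hand
  withr::with_seed(5, {
    for (i in 1:50) {
      m <- sample(1:20, 1)
      p <- stats::runif(m)
      expect_equal(stats::p.adjust(p, "BH"), bh_stepup_oracle(p),
                   tolerance = 1e-14)
    }
  })
})

test_that("DEG rule: strict fold-change boundary, inclusive q boundary", {
  st <- make_stats(fc = c(1.50, 1.42, 0.70, 1 / 1.42, 2.0),
                   q = c(0.01, 0.001, 0.05, 0.01, 0.051))
  res <- screen_degs(st)
  dir <- setNames(res$direction, res$feature_id)
  expect_equal(unname(dir["f1"]), "up")        # 1.50 > 1.42, q small
  expect_false("f2" %in% names(dir))           # FC exactly 1.42 excluded
  expect_equal(unname(dir["f3"]), "down")      # 0.70 < 1/1.42, q = 0.05 included
  expect_false("f4" %in% names(dir))           # FC exactly 1/1.42 excluded
  expect_false("f5" %in% names(dir))           # q just above the cutoff
})

test_that("DEG boundary grid: every FC x q combination behaves as specified", {
  fc_vals <- c(1.41, 1.42, 1.43)
  q_vals <- c(0.049, 0.05, 0.051)
  grid <- expand.grid(fc = fc_vals, q = q_vals)
  res <- screen_degs(make_stats(fc = grid$fc, q = grid$q))
  got_up <- make_stats(grid$fc)$feature_id %in%
    res$feature_id[res$direction == "up"]
  expect_equal(got_up, grid$fc > 1.42 & grid$q <= 0.05)
  # mirrored grid on the down side
  grid_dn <- expand.grid(fc = 1 / fc_vals, q = q_vals)
  res_dn <- screen_degs(make_stats(fc = grid_dn$fc, q = grid_dn$q))
  got_dn <- make_stats(grid_dn$fc)$feature_id %in%
    res_dn$feature_id[res_dn$direction == "down"]
  expect_equal(got_dn, grid_dn$fc < 1 / 1.42 & grid_dn$q <= 0.05)
})

test_that("DAM rule: inclusive fold-change bounds, strict p boundary", {
  st <- make_stats(fc = c(1.20, 0.83, 1.50, 1.19, 0.84),
                   p = c(0.01, 0.049, 0.05, 0.01, 0.01))
  res <- screen_dams(st)
  dir <- setNames(res$direction, res$feature_id)
  expect_equal(unname(dir["f1"]), "up")     # FC = 1.2 inclusive
  expect_equal(unname(dir["f2"]), "down")   # FC = 0.83 inclusive
  expect_false("f3" %in% names(dir))        # p = 0.05 strict
  expect_false("f4" %in% names(dir))        # inside the unchanged band
  expect_false("f5" %in% names(dir))

  grid <- expand.grid(fc = c(1.19, 1.20, 1.21, 0.82, 0.83, 0.84),
                      p = c(0.049, 0.05, 0.051))
  res_g <- screen_dams(make_stats(fc = grid$fc, p = grid$p))
  passing <- make_stats(grid$fc)$feature_id %in% res_g$feature_id
  expect_equal(passing,
               (grid$fc >= 1.2 | grid$fc <= 0.83) & grid$p < 0.05)
})

test_that("screens are disjoint, monotone in thresholds, and symmetric", {
  withr::with_seed(9, {
    for (i in 1:20) {
      m <- 50
      st <- make_stats(fc = stats::rlnorm(m, 0, 0.6),
                       p = stats::runif(m), q = stats::runif(m))
      deg <- screen_degs(st)
      expect_equal(sum(deg$direction == "up" & deg$direction == "down"), 0)
      expect_lte(length(intersect(deg$feature_id[deg$direction == "up"],
                                  deg$feature_id[deg$direction == "down"])), 0)
      # loosening thresholds never loses a passing feature
      looser <- screen_degs(st, fc_threshold = 1.2, q_max = 0.10)
      expect_true(all(deg$feature_id %in% looser$feature_id))
      dam <- screen_dams(st)
      dam_loose <- screen_dams(st, fc_up = 1.1, fc_down = 0.9, p_max = 0.10)
      expect_true(all(dam$feature_id %in% dam_loose$feature_id))
      # DEG symmetry: f passes up iff 1/f (same q) passes down
      mirror <- st
      mirror$fold_change <- 1 / st$fold_change
      mirror$log2_fc <- -st$log2_fc
      deg_m <- screen_degs(mirror)
      expect_setequal(deg$feature_id[deg$direction == "up"],
                      deg_m$feature_id[deg_m$direction == "down"])
      expect_setequal(deg$feature_id[deg$direction == "down"],
                      deg_m$feature_id[deg_m$direction == "up"])
    }
  })
})

test_that("invalid thresholds and missing stats are handled explicitly", {
  st <- make_stats(fc = c(2, NA, 0.5), q = c(0.01, 0.01, NA))
  expect_error(screen_degs(st, fc_threshold = 1), "> 1")
  expect_error(screen_dams(st, fc_up = 0.9), "fc_down < 1 < fc_up")
  expect_message(res <- screen_degs(st), "excluded 2")
  expect_equal(attr(res, "n_missing"), 2L)
  expect_equal(res$feature_id, "f1")
})

test_that("realized FDR of the DEG screen stays within twice nominal", {
  des <- omics_design(
    n_genes = 60, n_metabolites = 5, n_per_group = 6,
    planted = tibble::tibble(gene = 1:5, metabolite = 1:5,
                             rho_sign = 1,
                             gene_log2fc = c(2, -2, 2, -2, 2),
                             met_log2fc = c(2, -2, 2, -2, 2)))
  fp <- 0L
  disc <- 0L
  for (s in 1:200) {
    om <- generate_paired_omics(des, seed = 5000 + s)
    st <- compute_feature_stats(om$genes, om$groups, "control")
    res <- suppressMessages(screen_degs(st))
    hits <- res$feature_id
    fp <- fp + sum(!hits %in% om$truth$gene_id)
    disc <- disc + length(hits)
  }
  realized_fdr <- if (disc > 0) fp / disc else 0
  expect_lte(realized_fdr, 2 * 0.05)
})
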