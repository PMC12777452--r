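test_that("indicator generation is deterministic and exact at zero noise", {
  des <- ladder_design(cv = 0)
  t1 <- generate_indicator_table(des, seed = 3)
  t2 <- generate_indicator_table(des, seed = 3)
  expect_identical(t1, t2)

  expected <- des$multipliers
  for (col in names(des$control_mean)) {
    expected[[col]] <- expected[[col]] * des$control_mean[[col]]
  }
  expect_equal(t1, expected, tolerance = 1e-12)

  noisy <- ladder_design(cv = 0.05)
  n1 <- generate_indicator_table(noisy, seed = 3)
  n2 <- generate_indicator_table(noisy, seed = 4)
  expect_identical(generate_indicator_table(noisy, seed = 3), n1)
  expect_false(isTRUE(all.equal(n1, n2)))
  expect_true(all(as.matrix(n1[-1]) > 0))
})

test_that("design validation rejects malformed inputs", {
  m <- tibble::tibble(treatment = c("C", "T"), a = c(1, 2), b = c(1, 0.5))
  pol <- c(a = "positive", b = "negative")
  cm <- c(a = 10, b = 5)
  expect_s3_class(indicator_design(m, pol, cm, "C"), "indicator_design")
  bad <- m
  bad$a[1] <- 1.5  # control multiplier must be exactly 1
  expect_error(indicator_design(bad, pol, cm, "C"), "control row")
  expect_error(indicator_design(m, pol, c(a = 10), "C"), "control_mean")
  expect_error(indicator_design(m, pol, cm, "C", cv = -0.1), "cv")
  expect_error(generate_indicator_table(ladder_design(), seed = NULL), "seed")
})

test_that("a noise-free dominance ladder is ranked exactly as designed", {
  des <- ladder_design(cv = 0)
  tbl <- generate_indicator_table(des, seed = 1)
  fit <- evaluate_tolerance(tbl, des$polarity, "CTRL")
  # the last treatment dominates every favourable direction -> rank 1,
  # and the whole ladder is recovered in designed order
  expect_equal(fit$scores$rank, rev(seq_len(nrow(tbl))))
})

test_that("composite ranks track the designed order under replicate noise", {
  des <- ladder_design(cv = 0.05)
  designed <- rev(seq_len(nrow(des$multipliers)))
  rhos <- vapply(1:100, function(s) {
    tbl <- generate_indicator_table(des, seed = 200 + s)
    fit <- evaluate_tolerance(tbl, des$polarity, "CTRL")
    stats::cor(fit$scores$rank, designed, method = "spearman")
  }, numeric(1))
  expect_gte(mean(rhos), 0.9)
})

test_that("paired omics: determinism, null exactness, and monotone limit", {
  des <- default_omics_design()
  o1 <- generate_paired_omics(des, seed = 11)
  o2 <- generate_paired_omics(des, seed = 11)
  expect_identical(o1, o2)
  expect_false(identical(o1$genes,
                         generate_paired_omics(des, seed = 12)$genes))

  # zero noise, no planted pairs: every fold change is exactly 1
  null_des <- omics_design(n_genes = 10, n_metabolites = 5, n_per_group = 3,
                           noise_sd = 0)
  om <- generate_paired_omics(null_des, seed = 1)
  st <- compute_feature_stats(om$genes, om$groups, "control")
  expect_equal(st$fold_change, rep(1, 10))

  # zero noise, planted positive pair with equal shifts: rho exactly 1
  planted <- omics_design(
    n_genes = 3, n_metabolites = 3, n_per_group = 4, noise_sd = 0,
    planted = tibble::tibble(gene = 1, metabolite = 1, rho_sign = 1,
                             gene_log2fc = 2, met_log2fc = 2))
  om2 <- generate_paired_omics(planted, seed = 2)
  x <- as.numeric(om2$genes[1, -1])
  y <- as.numeric(om2$metabolites[1, -1])
  expect_equal(spearman_rho(x, y), 1)
})

test_that("omics design validation catches bad planted specifications", {
  expect_error(omics_design(10, 5, n_per_group = 2), "n_per_group")
  expect_error(
    omics_design(10, 5, planted = tibble::tibble(
      gene = 11, metabolite = 1, rho_sign = 1,
      gene_log2fc = 2, met_log2fc = 2)),
    "out of range")
  expect_error(
    omics_design(10, 5, planted = tibble::tibble(
      gene = c(1, 1), metabolite = 1:2, rho_sign = 1,
      gene_log2fc = 2, met_log2fc = 2)),
    "at most one pair")
  expect_error(
    omics_design(10, 5, planted = tibble::tibble(
      gene = 1, metabolite = 1, rho_sign = 0.5,
      gene_log2fc = 2, met_log2fc = 2)),
    "rho_sign")
})

test_that("truth table records ids and the designed quadrants", {
  om <- generate_paired_omics(default_omics_design(), seed = 7)
  expect_equal(om$truth$designed_quadrant, c(3L, 7L, 9L, 1L, 3L))
  expect_true(all(om$truth$gene_id %in% om$genes$feature_id))
  expect_true(all(om$truth$metabolite_id %in% om$metabolites$feature_id))
})

test_that("null designs keep the DEG false-positive proportion near nominal", {
  des <- omics_design(n_genes = 40, n_metabolites = 5, n_per_group = 6)
  total <- 0L
  hits <- 0L
  for (s in 1:200) {
    om <- generate_paired_omics(des, seed = 9000 + s)
    st <- compute_feature_stats(om$genes, om$groups, "control")
    res <- suppressMessages(screen_degs(st))
    hits <- hits + nrow(res)
    total <- total + nrow(st)
  }
  expect_lte(hits / total, 2 * 0.05)
})

test_that("planted pairs are recovered into their designed quadrant", {
  des <- default_omics_design()
  recovered <- 0L
  planted_total <- 0L
  for (s in 1:200) {
    om <- generate_paired_omics(des, seed = 100 + s)
    gs <- compute_feature_stats(om$genes, om$groups, "control")
    ms <- compute_feature_stats(om$metabolites, om$groups, "control")
    pa <- pair_associations(
      om$genes, om$metabolites, gs, ms,
      pairs = tibble::tibble(gene_id = om$truth$gene_id,
                             metabolite_id = om$truth$metabolite_id))
    cls <- classify_nine_quadrant(pa)
    recovered <- recovered +
      sum(as.character(cls$quadrant) == as.character(om$truth$designed_quadrant))
    planted_total <- planted_total + nrow(om$truth)
  }
  expect_gte(recovered / planted_total, 0.9)
})
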