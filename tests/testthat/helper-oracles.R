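# Independent oracles and small fixture builders used across the suite.

# Benjamini-Hochberg step-up, written from the definition: sort p ascending,
# q_(i) = min over j >= i of p_(j) * m / j, capped at 1, mapped back.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Spearman rho from the definition: average ranks, then the explicit
# covariance / sd ratio (no call to cor()).
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  n <- length(x)
  cov_xy <- sum((rx - mean(rx)) * (ry - mean(ry))) / (n - 1)
  sx <- sqrt(sum((rx - mean(rx))^2) / (n - 1))
  sy <- sqrt(sum((ry - mean(ry))^2) / (n - 1))
  cov_xy / (sx * sy)
}

# Correlation matrix computed explicitly from centred cross-products, then
# eigendecomposed: the brute-force reference for the PCA stage.
pca_oracle <- function(x) {
  n <- nrow(x)
  z <- sweep(x, 2, colMeans(x))
  z <- sweep(z, 2, apply(x, 2, stats::sd), "/")
  r <- crossprod(z) / (n - 1)
  eig <- eigen(r, symmetric = TRUE)
  list(values = pmax(eig$values, 0),
       contributions = pmax(eig$values, 0) / sum(pmax(eig$values, 0)),
       vectors = eig$vectors,
       scores = z %*% eig$vectors)
}

# A small strictly positive indicator table with distinct column behaviours.
toy_indicator_table <- function() {
  tibble::tibble(
    treatment = c("W", "S50", "S100", "S200"),
    enzyme  = c(100, 140, 180, 150),
    osmolyte = c(50, 70, 120, 160),
    damage  = c(10, 14, 20, 30)
  )
}

toy_polarity <- c(enzyme = "positive", osmolyte = "positive",
                  damage = "negative")

# A dominance ladder: treatment i+1 beats treatment i on every indicator in
# the tolerance-favourable direction (positive up, negative down).
ladder_design <- function(cv = 0, n_treat = 6) {
  trt <- c("CTRL", paste0("T", seq_len(n_treat - 1)))
  up <- seq(1, 2, length.out = n_treat)      # favourable for positive
  down <- seq(1, 0.5, length.out = n_treat)  # favourable for negative
  m <- tibble::tibble(
    treatment = trt,
    a = up, b = up^1.3, c = up^0.7,
    d = down, e = down^1.2
  )
  salttol::indicator_design(
    multipliers = m,
    polarity = c(a = "positive", b = "positive", c = "positive",
                 d = "negative", e = "negative"),
    control_mean = c(a = 100, b = 30, c = 800, d = 25, e = 4),
    control = "CTRL", cv = cv, n_reps = 3
  )
}
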