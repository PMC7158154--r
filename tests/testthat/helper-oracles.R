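# Independent oracles and small fixture builders used across the suite.
# Each oracle is written from the defining formula, not from the package's
# code path, so the two routes stay independent.

# Pearson correlation from the covariance / sd formula.
pearson_oracle <- function(a, b) {
  ca <- a - mean(a); cb <- b - mean(b)
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

# Sort-based median: middle order statistic, or the mean of the two central
# ones for even counts.
median_oracle <- function(x) {
  s <- sort(x); n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Exhaustive pairwise interior-intersection check on axis-aligned squares,
# via interval overlap on each axis (strict, with the shared-edge slack).
overlap_pairs_oracle <- function(bricks, eps = 1e-9) {
  b <- bricks[!bricks$zeroed, , drop = FALSE]
  n <- nrow(b); bad <- 0L
  if (n < 2) return(bad)
  l <- b$x - b$side / 2; r <- b$x + b$side / 2
  d <- b$y - b$side / 2; u <- b$y + b$side / 2
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ox <- min(r[i], r[j]) - max(l[i], l[j])
    oy <- min(u[i], u[j]) - max(d[i], d[j])
    if (ox > eps && oy > eps) bad <- bad + 1L
  }
  bad
}

# Arbitrary small arcsinh-state table with distinct labels.
make_table <- function(values, transform_state = "arcsinh", cofactor = 5) {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("c", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("m", seq_len(ncol(values)))
  cluster_table(values, transform_state = transform_state,
                cofactor = if (transform_state == "arcsinh") cofactor else NULL)
}

# Random arcsinh-state table (values in a realistic 0-6 range).
random_table <- function(n_clusters, n_markers, seed) {
  set.seed(seed)
  make_table(matrix(runif(n_clusters * n_markers, 0, 6), nrow = n_clusters))
}

# Random brick configurations for geometry stress tests: uniform centers,
# log-uniform sides.
random_bricks <- function(n, seed) {
  set.seed(seed)
  side <- exp(runif(n, log(0.05), log(1.2)))
  data.frame(marker = sprintf("m%03d", seq_len(n)),
             x = runif(n, 0, 4), y = runif(n, 0, 4),
             side = side, area = side^2,
             group = rep(1L, n), zeroed = FALSE, displaced = FALSE,
             stringsAsFactors = FALSE)
}

# CSV writer for raw tables fed to read_cluster_table.
write_fixture_csv <- function(values, path) {
  df <- data.frame(cluster = rownames(values), values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
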