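test_that("correlation matrix matches the direct-formula Pearson oracle", {
  for (s in 1:100) {
    tab <- random_table(n_clusters = 6, n_markers = 8, seed = 1000 + s)
    cm <- correlation_matrix(tab)
    v <- tab$values
    for (i in 1:8) for (j in i:8) {
      expect_lt(abs(cm$values[i, j] - pearson_oracle(v[, i], v[, j])), 1e-10)
    }
    expect_true(all(abs(cm$values - t(cm$values)) < 1e-12))
    expect_true(all(cm$values >= -1 - 1e-12 & cm$values <= 1 + 1e-12))
    expect_identical(unname(diag(cm$values)), rep(1, 8))
  }
})

test_that("perfect co- and anti-correlation hit the +/-1 endpoints", {
  base <- c(1, 2, 4, 3, 5)
  v <- cbind(m1 = base, m2 = base, m3 = -base + 10, m4 = c(2, 2, 7, 1, 4))
  cm <- correlation_matrix(make_table(v))
  expect_equal(cm$values["m1", "m2"], 1, tolerance = 1e-12)
  expect_equal(cm$values["m1", "m3"], -1, tolerance = 1e-12)
})

test_that("zero-variance markers get correlation 0 with a warning, not dropped", {
  v <- cbind(m1 = c(1, 2, 3, 4), m2 = c(2, 2, 2, 2), m3 = c(4, 1, 3, 2))
  expect_warning(cm <- correlation_matrix(make_table(v)),
                 class = "bp_degenerate_marker_warning")
  expect_identical(cm$marker_names, c("m1", "m2", "m3"))
  expect_identical(unname(cm$values["m2", c("m1", "m3")]), c(0, 0))
  expect_identical(unname(cm$values["m2", "m2"]), 1)
})

test_that("correlations are computed on the arcsinh scale only", {
  v <- matrix(1:12, nrow = 4, dimnames = list(paste0("c", 1:4), paste0("m", 1:3)))
  raw <- cluster_table(v, transform_state = "raw_counts")
  expect_error(correlation_matrix(raw), class = "bp_state_error")
})

test_that("PCA places markers by their centered correlation rows", {
  # two perfect 3-marker blocks, within r = 1, between r = -1: the centered
  # row matrix has rank 1, so PC1 carries 100% of the variance and each
  # block collapses to a single point
  r <- rbind(c(1, 1, 1, -1, -1, -1))
  cm <- structure(list(marker_names = paste0("m", 1:6),
                       values = rbind(r, r, r, -r, -r, -r) * 1),
                  class = "correlation_matrix")
  dimnames(cm$values) <- list(cm$marker_names, cm$marker_names)
  p <- pca_coordinates(cm)
  expect_equal(p$pc1_var_pct, 100, tolerance = 1e-9)
  expect_lt(max(abs(p$pc1[1:3] - p$pc1[1])), 1e-9)   # block 1 coincides
  expect_lt(max(abs(p$pc1[4:6] - p$pc1[4])), 1e-9)   # block 2 coincides
  expect_gt(abs(p$pc1[1] - p$pc1[4]), 1)             # blocks separated on PC1
  expect_lt(max(abs(p$pc2)), 1e-9)                   # nothing left for PC2

  # identical rows always coincide; variance percentages sum to 100;
  # the 2-D projection never stretches centered-row distances
  for (s in 1:25) {
    tab <- random_table(n_clusters = 7, n_markers = 9, seed = 2000 + s)
    cm <- correlation_matrix(tab)
    p <- pca_coordinates(cm)
    expect_equal(sum(p$var_pct), 100, tolerance = 1e-9)
    expect_true(all(diff(p$var_pct) < 1e-12))  # sorted non-increasing
    centered <- scale(cm$values, center = TRUE, scale = FALSE)
    for (pair in list(c(1, 2), c(3, 9), c(5, 6))) {
      full <- sum((centered[pair[1], ] - centered[pair[2], ])^2)
      proj <- (p$pc1[pair[1]] - p$pc1[pair[2]])^2 +
              (p$pc2[pair[1]] - p$pc2[pair[2]])^2
      expect_lte(proj, full + 1e-9)
      # full-space scores preserve centered-row distances exactly
      expect_equal(sum((p$scores[pair[1], ] - p$scores[pair[2], ])^2), full,
                   tolerance = 1e-9)
    }
  }

  # rank-0 input (all rows identical after centering) is an error
  cm0 <- structure(list(marker_names = paste0("m", 1:3),
                        values = matrix(1, 3, 3)),
                   class = "correlation_matrix")
  expect_error(pca_coordinates(cm0), class = "bp_degenerate_layout_error")
})

test_that("elbow-validated K-means recovers separated clouds and degenerate cases", {
  # all markers at one coordinate: k = 1, a single group
  co <- matrix(rep(c(2, 3), each = 6), ncol = 2)
  expect_warning(r <- kmeans_elbow_groups(co, seed = 5),
                 class = "bp_kmax_reduced_warning")
  expect_identical(r$elbow$k_selected, 1L)
  expect_identical(r$group_id, rep(1L, 6))

  # three tight clouds, centers >= 10 apart, 5 markers each
  set.seed(99)
  centers <- rbind(c(0, 0), c(10, 0), c(5, 12))
  co <- do.call(rbind, lapply(1:3, function(b)
    sweep(matrix(rnorm(10, sd = 0.01), ncol = 2), 2, centers[b, ], "+")))
  r <- kmeans_elbow_groups(co, seed = 7)
  expect_identical(r$elbow$k_selected, 3L)
  expect_identical(r$group_id, rep(1:3, each = 5))  # first-appearance numbering
  # WCSS is non-increasing in k (multi-restart tolerance)
  expect_true(all(diff(r$elbow$wcss) <= 1e-9))
  expect_true(r$elbow$k_selected %in% r$elbow$k_values)
})

test_that("the dataset layout is deterministic and row-order invariant", {
  ds <- generate_table(synthetic_spec(seed = 7))
  lay1 <- build_layout(ds$table, seed = 3)
  lay2 <- build_layout(ds$table, seed = 3)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_layout_json(lay1, p1); write_layout_json(lay2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  # permuting cluster rows cannot change a correlation-based layout
  perm <- rev(seq_len(nrow(ds$table$values)))
  tab_perm <- cluster_table(ds$table$values[perm, ],
                            transform_state = "arcsinh", cofactor = 5)
  lay3 <- build_layout(tab_perm, seed = 3)
  expect_equal(lay3$markers, lay1$markers, tolerance = 1e-12)

  # layout JSON round-trips losslessly
  back <- read_layout_json(p1)
  expect_equal(back$markers, lay1$markers, tolerance = 0)
  expect_identical(back$k_selected, lay1$k_selected)
  expect_identical(back$seed, lay1$seed)

  # invariant structure of the layout itself
  expect_identical(sort(unique(lay1$markers$group)), seq_len(lay1$k_selected))
  expect_gte(lay1$pc1_var_pct, lay1$pc2_var_pct)
  expect_lte(lay1$pc1_var_pct + lay1$pc2_var_pct, 100 + 1e-9)
})

test_that("synthetic co-expression blocks are recovered as layout groups", {
  ds <- generate_table(synthetic_spec(n_clusters = 40, within_block_corr = 0.9,
                                      noise_sd = 0.1, seed = 7))
  lay <- build_layout(ds$table, seed = 7)
  expect_identical(lay$k_selected, 3L)
  expect_equal(mclust::adjustedRandIndex(lay$markers$group, ds$truth_groups), 1)
  # markers of one block share a group id and sit close together
  for (b in 1:3) {
    g <- lay$markers$group[ds$truth_groups == b]
    expect_identical(g, rep(g[1], 5))
  }
})
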