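make_layout_stub <- function(pc1, pc2, group = rep(1L, length(pc1)),
                             names = sprintf("m%02d", seq_along(pc1))) {
  structure(list(
    markers = data.frame(name = names, pc1 = pc1, pc2 = pc2, group = group,
                         stringsAsFactors = FALSE),
    pc1_var_pct = 60, pc2_var_pct = 25, k_selected = max(group),
    seed = 1L, config = list(zero_cutoff = 1, cofactor = 5), elbow = NULL
  ), class = "marker_layout")
}

test_that("the dataset scale factor inverts the largest-brick definition", {
  v <- rbind(c(2, 1, 0), c(4, 0, 1), c(1, 1, 1))
  tab <- make_table(v)
  lay <- make_layout_stub(pc1 = c(0, 3, 6), pc2 = c(0, 2, 1))  # span L = 6
  s <- compute_scale_factor(tab, lay, max_area_fraction = 0.25)
  expect_equal(s, (0.25 * 6)^2 / 4, tolerance = 1e-12)  # s = (f L)^2 / v_max
  # doubling every value halves s: rendered sides are scale-invariant
  tab2 <- make_table(2 * v)
  expect_equal(compute_scale_factor(tab2, lay, 0.25), s / 2, tolerance = 1e-12)
  expect_equal(sqrt(s * v[2, 1]), sqrt((s / 2) * 2 * v[2, 1]), tolerance = 1e-12)
  # an all-zero table has nothing to scale
  expect_error(compute_scale_factor(make_table(matrix(0, 3, 3)), lay, 0.25),
               class = "bp_all_zero_error")
  expect_error(compute_scale_factor(tab, lay, 0), class = "bp_value_error")
})

test_that("brick areas are exactly proportional to expression", {
  lay <- make_layout_stub(pc1 = c(0, 3, 6), pc2 = c(0, 2, 1))
  v <- rbind(A = c(1.2, 1, 0), B = c(2.4, 2, 1.5), C = c(0, 0.5, 3))
  colnames(v) <- lay$markers$name
  tab <- make_table(v)
  s <- compute_scale_factor(tab, lay, 0.2)
  bA <- size_bricks(lay, v["A", ], s)
  bB <- size_bricks(lay, v["B", ], s)
  # same marker, value 1.2 vs 2.4: B has exactly twice the area (sqrt(2) side)
  expect_equal(bB$area[1] / bA$area[1], 2, tolerance = 1e-12)
  expect_equal(bB$side[1] / bA$side[1], sqrt(2), tolerance = 1e-12)
  # cross-marker, cross-cluster proportionality under the shared scale
  expect_equal(bA$area[2] / bB$area[3], 1 / 1.5, tolerance = 1e-9)
  # zero value: a zeroed brick, flagged but kept
  expect_true(bA$zeroed[3]); expect_identical(bA$area[3], 0)
  expect_identical(nrow(bA), 3L)
  # area = side^2 bookkeeping
  expect_true(all(abs(bA$area - bA$side^2) < 1e-12))
  # equal values give congruent squares
  bC <- size_bricks(lay, c(m01 = 2, m02 = 2, m03 = 2), s)
  expect_identical(length(unique(bC$side)), 1L)
  # misaligned rows are refused
  expect_error(size_bricks(lay, c(1, 2), s), class = "bp_alignment_error")
  expect_error(size_bricks(lay, c(x = 1, y = 2, z = 3), s),
               class = "bp_alignment_error")
})

test_that("overlap-free inputs pass through resolution untouched", {
  b <- data.frame(marker = c("a", "b", "c"),
                  x = c(0, 5, 10), y = c(0, 0, 0),
                  side = c(1, 2, 1), area = c(1, 4, 1),
                  group = 1L, zeroed = FALSE, displaced = FALSE,
                  stringsAsFactors = FALSE)
  r <- resolve_overlaps(b)
  expect_identical(r, b)
  expect_false(any(r$displaced))
})

test_that("coincident bricks end edge-adjacent along the +x fallback ray", {
  b <- data.frame(marker = c("a", "b"),
                  x = c(2, 2), y = c(3, 3),
                  side = c(1, 1), area = c(1, 1),
                  group = 1L, zeroed = FALSE, displaced = FALSE,
                  stringsAsFactors = FALSE)
  r <- resolve_overlaps(b)
  # equal areas: tie broken by marker name, so "a" is placed first and stays
  expect_identical(r$x[1], 2); expect_identical(r$y[1], 3)
  expect_false(r$displaced[1]); expect_true(r$displaced[2])
  # "b" pushed along +x until edge contact: center distance = 1
  expect_equal(r$x[2], 3, tolerance = 1e-12)
  expect_equal(r$y[2], 3, tolerance = 1e-12)
  expect_identical(overlap_pairs_oracle(r), 0L)
})

test_that("resolution yields interior-disjoint bricks on random configurations", {
  for (s in 1:100) {
    n <- sample(5:25, 1)
    b <- random_bricks(n, seed = 3000 + s)
    r <- resolve_overlaps(b)
    expect_identical(overlap_pairs_oracle(r), 0L)
    # bricks that never collided are bit-identical in position
    clean <- !r$displaced
    expect_identical(r$x[clean], b$x[clean])
    expect_identical(r$y[clean], b$y[clean])
    # resolution only translates: sides and areas untouched, order preserved
    expect_identical(r$side, b$side)
    expect_identical(r$marker, b$marker)
    # determinism: same input, same displacements
    expect_identical(resolve_overlaps(b), r)
  }
})

test_that("per-cluster plots share dataset-level positions and scale", {
  ds <- generate_table(synthetic_spec(seed = 21, negative_marker_count = 2))
  tab <- apply_zero_threshold(ds$table)
  lay <- build_layout(ds$table, seed = 21)
  ids <- cluster_ids(tab)[1:2]
  s <- compute_scale_factor(tab, lay, 0.25)
  for (id in ids) {
    sized <- size_bricks(lay, tab$values[id, ], s)
    # pre-displacement positions are the layout coordinates for every cluster
    expect_identical(sized$x, lay$markers$pc1)
    expect_identical(sized$y, lay$markers$pc2)
  }
  pA <- build_brick_plot(tab, lay, ids[1])
  pB <- build_brick_plot(tab, lay, ids[2])
  expect_equal(pA$scale_factor, pB$scale_factor, tolerance = 0)
  expect_identical(count_overlapping_pairs(pA$bricks), 0L)
  # one brick per layout marker, zeroed ones flagged not dropped
  expect_identical(pA$bricks$marker, lay$markers$name)
  # negative markers are zeroed in every cluster
  expect_true(all(pA$bricks$zeroed[ds$truth_groups == 4]))

  expect_error(build_brick_plot(tab, lay, "no_such_cluster"),
               class = "bp_lookup_error")

  # determinism of the serialized plot
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_brick_plot_json(pA, f1)
  write_brick_plot_json(build_brick_plot(tab, lay, ids[1]), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_brick_plot_json(f1)
  expect_equal(back$bricks[, c("marker", "x", "y", "side")],
               pA$bricks[, c("marker", "x", "y", "side")], tolerance = 0)
})

test_that("raising the zeroing cutoff never adds bricks", {
  ds <- generate_table(synthetic_spec(seed = 4, negative_marker_count = 3))
  lay <- build_layout(ds$table, seed = 4)
  counts <- vapply(c(0, 0.5, 1, 1.5, 2, 3, 4.5), function(cut) {
    thr <- apply_zero_threshold(ds$table, threshold_config(zero_cutoff = cut))
    if (all(thr$values == 0)) return(0L)
    p <- build_brick_plot(thr, lay, cluster_ids(thr)[1])
    sum(!p$bricks$zeroed)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})
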