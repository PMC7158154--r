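#' Specification for a synthetic cluster-expression dataset
#'
#' Describes a dataset with known marker co-expression structure: groups
#' (blocks) of markers sharing a per-cluster latent signal, plus optional
#' "negative" markers whose values sit below the zeroing threshold in every
#' cluster. Used to test layout recovery, thresholding, and geometry without
#' external data.
#'
#' @param n_clusters number of cell clusters (rows); >= 3.
#' @param blocks list of `c(size, base_level)` pairs, or a data.frame with
#'   columns `size` and `base_level`: each block is a set of co-expressed
#'   markers around a mean arcsinh level.
#' @param within_block_corr target Pearson correlation between markers of the
#'   same block, in [0, 1].
#' @param noise_sd standard deviation of the marker-specific noise relative
#'   to the unit-variance shared latent signal.
#' @param negative_marker_count markers drawn uniformly in
#'   `[0, 0.5 * zero_cutoff]`, i.e. always sub-threshold.
#' @param zero_cutoff the zeroing threshold the negative markers must stay
#'   under (default 1, the method's default cutoff).
#' @param seed integer seed; generation is fully reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_clusters = 40L,
                           blocks = list(c(5, 2.5), c(5, 3.5), c(5, 4.5)),
                           within_block_corr = 0.9,
                           noise_sd = 0.1,
                           negative_marker_count = 0L,
                           zero_cutoff = 1.0,
                           seed = 1L) {
  if (is.data.frame(blocks))
    blocks <- lapply(seq_len(nrow(blocks)),
                     function(i) c(blocks$size[i], blocks$base_level[i]))
  sizes <- vapply(blocks, `[`, numeric(1), 1)
  bases <- vapply(blocks, `[`, numeric(1), 2)
  if (any(sizes < 1) || any(bases <= 0))
    bp_stop("each block needs a positive size and base level", "bp_value_error")
  if (within_block_corr < 0 || within_block_corr > 1)
    bp_stop("within_block_corr must lie in [0, 1]", "bp_value_error")
  if (noise_sd < 0) bp_stop("noise_sd must be non-negative", "bp_value_error")
  n_markers <- sum(sizes) + negative_marker_count
  if (n_markers < 3 || n_clusters < 3)
    bp_stop("need >= 3 markers and >= 3 clusters in total", "bp_value_error")
  structure(list(n_clusters = as.integer(n_clusters),
                 block_sizes = as.integer(sizes),
                 base_levels = bases,
                 within_block_corr = within_block_corr,
                 noise_sd = noise_sd,
                 negative_marker_count = as.integer(negative_marker_count),
                 zero_cutoff = zero_cutoff,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic cluster table with known block structure
#'
#' Correlation is induced by a shared latent factor: per block a per-cluster
#' standard-normal latent signal L is drawn, and each member marker's value is
#'
#'   value = base_level + sqrt(rho) * L + sqrt(1 - rho) * noise_sd * eps
#'
#' with eps ~ N(0, 1) independent per marker, clipped at 0 (expression is
#' non-negative). With `noise_sd = 1` the within-block correlation is exactly
#' `rho` in expectation; smaller noise tightens it toward 1. The latent
#' signals of different blocks are orthogonalized across clusters (and
#' re-standardized), so the empirical between-block correlation of the signal
#' part is exactly 0 — the generated fixtures actually exhibit the negligible
#' between-block co-expression they are defined to have, rather than sampling
#' noise of order 1/sqrt(n_clusters). Negative markers are uniform in
#' `[0, 0.5 * zero_cutoff]` so thresholding removes them entirely.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_dataset`: `table` (arcsinh-state
#'   [cluster_table()]), `truth_groups` (integer ground-truth group per
#'   marker; negative markers share one extra group), `spec`.
#' @export
generate_table <- function(spec) {
  n_blocks <- length(spec$block_sizes)
  rho <- spec$within_block_corr
  with_seed(spec$seed, {
    ## latent block signals: iid normal, then centered, orthogonalized (QR)
    ## and re-standardized so between-block signal correlation is exactly 0
    L <- matrix(stats::rnorm(spec$n_clusters * n_blocks), ncol = n_blocks)
    if (spec$n_clusters > n_blocks + 1) {
      L <- scale(L, center = TRUE, scale = FALSE)
      L <- qr.Q(qr(L)) * sqrt(spec$n_clusters - 1)
      # QR signs are arbitrary; fix them for cross-platform determinism
      for (b in seq_len(n_blocks)) if (L[1, b] < 0) L[, b] <- -L[, b]
    }
    cols <- list(); truth <- integer(0); nms <- character(0)
    for (b in seq_len(n_blocks)) {
      latent <- L[, b]
      for (m in seq_len(spec$block_sizes[b])) {
        eps <- stats::rnorm(spec$n_clusters)
        val <- spec$base_levels[b] + sqrt(rho) * latent +
          sqrt(1 - rho) * spec$noise_sd * eps
        cols[[length(cols) + 1]] <- pmax(val, 0)
        truth <- c(truth, b)
        nms <- c(nms, sprintf("M%02d_B%d", length(cols), b))
      }
    }
    if (spec$negative_marker_count > 0) {
      for (m in seq_len(spec$negative_marker_count)) {
        cols[[length(cols) + 1]] <- stats::runif(spec$n_clusters,
                                                 0, 0.5 * spec$zero_cutoff)
        truth <- c(truth, n_blocks + 1L)
        nms <- c(nms, sprintf("M%02d_neg", length(cols)))
      }
    }
    values <- do.call(cbind, cols)
    dimnames(values) <- list(sprintf("cluster_%02d", seq_len(spec$n_clusters)), nms)
    structure(list(
      table = cluster_table(values, transform_state = "arcsinh", cofactor = 5),
      truth_groups = truth,
      spec = spec
    ), class = "synthetic_dataset")
  })
}

#' Generate per-event data around synthetic cluster medians
#'
#' Draws `events_per_cluster` events per cluster with symmetric Gaussian
#' noise around the cluster-level values of [generate_table()], so
#' [median_by_cluster()] recovers the table within sampling error (exactly,
#' when `event_noise_sd = 0`).
#'
#' @param spec a [synthetic_spec()].
#' @param events_per_cluster events drawn per cluster.
#' @param event_noise_sd per-event noise standard deviation (arcsinh units).
#' @return list: `events` (an [event_matrix()]), `table` (the generating
#'   [cluster_table()]), `truth_groups`.
#' @export
generate_events <- function(spec, events_per_cluster = 200L,
                            event_noise_sd = 0.2) {
  ds <- generate_table(spec)
  tab <- ds$table$values
  n_mk <- ncol(tab)
  with_seed(derive_seed(spec$seed, 104729L), {
    ev <- matrix(NA_real_, nrow = nrow(tab) * events_per_cluster, ncol = n_mk,
                 dimnames = list(NULL, colnames(tab)))
    labs <- character(nrow(ev))
    r <- 0L
    for (cl in rownames(tab)) {
      idx <- r + seq_len(events_per_cluster)
      noise <- matrix(stats::rnorm(events_per_cluster * n_mk, sd = event_noise_sd),
                      nrow = events_per_cluster)
      ev[idx, ] <- rep(tab[cl, ], each = events_per_cluster) + noise
      labs[idx] <- cl
      r <- r + events_per_cluster
    }
    list(events = event_matrix(ev, labs), table = ds$table,
         truth_groups = ds$truth_groups)
  })
}

#' Round-trip a synthetic spec through YAML
#'
#' @param spec a [synthetic_spec()].
#' @param path YAML file path.
#' @export
write_spec_yaml <- function(spec, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    bp_stop("the 'yaml' package is required for YAML specs", "bp_io_error")
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_spec_yaml
#' @export
read_spec_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    bp_stop("the 'yaml' package is required for YAML specs", "bp_io_error")
  d <- yaml::read_yaml(path)
  synthetic_spec(
    n_clusters = d$n_clusters,
    blocks = lapply(seq_along(d$block_sizes),
                    function(i) c(d$block_sizes[i], d$base_levels[i])),
    within_block_corr = d$within_block_corr,
    noise_sd = d$noise_sd,
    negative_marker_count = d$negative_marker_count,
    zero_cutoff = d$zero_cutoff,
    seed = d$seed
  )
}
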