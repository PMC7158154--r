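#' Marker co-expression correlation matrix
#'
#' Pearson correlation between the across-cluster expression vectors of every
#' marker pair, computed on arcsinh-transformed medians (before zeroing, which
#' is a display rule applied downstream). Entries lie in [-1, 1]. A marker
#' with zero variance across clusters carries no co-expression information:
#' it gets 0 off-diagonal and 1 on the diagonal, with a warning, rather than
#' being dropped (keeps table and layout aligned; such markers are usually
#' zeroed anyway).
#'
#' @param table an arcsinh-state [cluster_table()] with >= 3 clusters.
#' @param method `"pearson"` (default, the method's convention) or
#'   `"spearman"`.
#' @return An object of class `correlation_matrix`: list with `marker_names`
#'   and the square `values` matrix.
#' @export
correlation_matrix <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (table$transform_state != "arcsinh")
    bp_stop("correlations are computed on arcsinh-transformed medians; transform first",
            "bp_state_error")
  v <- table$values
  if (nrow(v) < 3)
    bp_stop("need >= 3 clusters: correlation on 2 points is always +/-1, uninformative",
            "bp_dimension_error")
  sds <- apply(v, 2, stats::sd)
  degenerate <- sds == 0
  cm <- suppressWarnings(stats::cor(v, method = method))
  if (any(degenerate)) {
    bp_warn(sprintf("marker(s) with zero variance across clusters get correlation 0: %s",
                    paste(colnames(v)[degenerate], collapse = ", ")),
            "bp_degenerate_marker_warning")
    cm[degenerate, ] <- 0
    cm[, degenerate] <- 0
  }
  diag(cm) <- 1
  cm <- (cm + t(cm)) / 2  # enforce exact symmetry against rounding
  structure(list(marker_names = colnames(v), values = cm),
            class = "correlation_matrix")
}

#' PCA coordinates of markers from their correlation rows
#'
#' Markers are the observations; each marker's feature vector is its row of
#' correlations to all markers. Rows are column-centered (no re-scaling:
#' correlations already share the [-1, 1] scale) and projected onto the top
#' two principal axes. Perfectly co-expressed markers have identical rows and
#' therefore coincide in the plot. The sign of each component is fixed so
#' that its largest-magnitude loading is positive, making the embedding
#' deterministic.
#'
#' @param corr a [correlation_matrix()].
#' @return A list with per-marker `pc1`, `pc2`, the variance percentages
#'   `pc1_var_pct`, `pc2_var_pct`, full `var_pct` over all components, and the
#'   full score matrix `scores` (used by distance-contraction checks).
#' @export
pca_coordinates <- function(corr) {
  x <- corr$values
  centered <- scale(x, center = TRUE, scale = FALSE)
  if (max(abs(centered)) < 1e-12)
    bp_stop("all markers have identical correlation rows after centering; the layout is undefined",
            "bp_degenerate_layout_error")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  # sign convention: largest-|loading| entry of each rotation column positive
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  ev <- p$sdev^2
  var_pct <- 100 * ev / sum(ev)
  scores <- p$x
  pc2 <- if (ncol(scores) >= 2) scores[, 2] else rep(0, nrow(scores))
  list(pc1 = unname(scores[, 1]),
       pc2 = unname(pc2),
       pc1_var_pct = var_pct[1],
       pc2_var_pct = if (length(var_pct) >= 2) var_pct[2] else 0,
       var_pct = var_pct,
       scores = scores)
}

#' Group markers by K-means with elbow-point model selection
#'
#' Runs multi-restart K-means (squared Euclidean, on the 2-D PC coordinates)
#' for `n_k` integer K values evenly spaced in `[k_min, k_max]` (all of them
#' when the range is short). The elbow point is the tested K maximizing the
#' discrete second difference of the within-cluster sum of squares,
#' `wcss[i-1] - 2 wcss[i] + wcss[i+1]`, over interior indices; ties go to the
#' smallest K. With fewer than three tested K values there is no curvature to
#' measure and the smallest K is kept. Group labels are renumbered 1..K by
#' order of first appearance in marker order.
#'
#' @param coords numeric matrix (markers x 2) of PC1/PC2 coordinates.
#' @param k_min,k_max,n_k K range and number of K values tested; defaults
#'   follow the method (`1` to the number of markers, 30 values).
#' @param seed integer seed; the grouping is a pure function of
#'   (coords, K range, seed).
#' @param nstart K-means restarts per K (protects the non-increasing WCSS
#'   invariant).
#' @return list(group_id = integer per marker, elbow = `elbow_result` with
#'   `k_values`, `wcss`, `k_selected`).
#' @export
kmeans_elbow_groups <- function(coords, k_min = 1L, k_max = nrow(coords),
                                n_k = 30L, seed = 42L, nstart = 10L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k_min < 1) bp_stop("k_min must be >= 1", "bp_value_error")
  if (k_max > n) bp_stop("k_max cannot exceed the number of markers", "bp_value_error")
  n_distinct <- nrow(unique(round(coords, 12)))
  if (k_max > n_distinct) {
    bp_warn(sprintf("only %d distinct coordinate points; reducing k_max from %d",
                    n_distinct, k_max),
            "bp_kmax_reduced_warning")
    k_max <- n_distinct
    if (k_min > k_max) k_min <- k_max
  }
  span <- k_max - k_min + 1L
  ks <- if (span <= n_k) seq.int(k_min, k_max)
        else unique(round(seq(k_min, k_max, length.out = n_k)))
  ## k = 1 and k = number of distinct points have closed-form optima that
  ## stats::kmeans (Hartigan-Wong) does not accept; handle them directly.
  fit_k <- function(k, i) {
    if (k == 1) {
      ctr <- colMeans(coords)
      list(cluster = rep(1L, n), tot.withinss = sum(sweep(coords, 2, ctr)^2),
           centers = matrix(ctr, nrow = 1))
    } else if (k == n_distinct) {
      key <- apply(round(coords, 12), 1, paste, collapse = ",")
      cl <- match(key, unique(key))
      ctr <- do.call(rbind, lapply(split(seq_len(n), cl), function(ix)
        colMeans(coords[ix, , drop = FALSE])))
      w <- sum(vapply(split(seq_len(n), cl), function(ix) {
        sub <- coords[ix, , drop = FALSE]
        sum(sweep(sub, 2, colMeans(sub))^2)
      }, numeric(1)))
      list(cluster = cl, tot.withinss = w, centers = ctr)
    } else {
      with_seed(derive_seed(seed, i), {
        stats::kmeans(coords, centers = k, nstart = nstart, iter.max = 100L)
      })
    }
  }
  ## Fit the K values in order; besides the seeded multi-restart fit, try a
  ## warm start that extends the previous K's centers with the points
  ## farthest from them. K-means iterations never worsen their own
  ## initialization, so the best of the two keeps the WCSS curve
  ## non-increasing in K.
  fits <- vector("list", length(ks))
  prev_ctr <- NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    fit <- fit_k(k, i)
    if (!is.null(prev_ctr) && k > nrow(prev_ctr) && k > 1 && k < n_distinct) {
      ctr <- prev_ctr
      ok <- TRUE
      for (add in seq_len(k - nrow(ctr))) {
        d2 <- vapply(seq_len(n), function(r)
          min(rowSums(sweep(ctr, 2, coords[r, ])^2)), numeric(1))
        if (max(d2) < 1e-24) { ok <- FALSE; break }
        ctr <- rbind(ctr, coords[which.max(d2), ])
      }
      if (ok && !anyDuplicated(round(ctr, 12))) {
        warm <- tryCatch(stats::kmeans(coords, centers = ctr, iter.max = 100L),
                         error = function(e) NULL)
        if (!is.null(warm) && warm$tot.withinss < fit$tot.withinss) fit <- warm
      }
    }
    fits[[i]] <- fit
    prev_ctr <- fit$centers
  }
  wcss <- vapply(fits, `[[`, numeric(1), "tot.withinss")
  k_selected <- if (length(ks) < 3) ks[1] else {
    interior <- 2:(length(ks) - 1)
    curv <- wcss[interior - 1] - 2 * wcss[interior] + wcss[interior + 1]
    ks[interior[which.max(curv)]]  # which.max takes the first max = smallest k
  }
  group_raw <- fits[[match(k_selected, ks)]]$cluster
  # renumber by first appearance in marker order
  group_id <- match(group_raw, unique(group_raw))
  elbow <- structure(list(k_values = as.integer(ks), wcss = wcss,
                          k_selected = as.integer(k_selected)),
                     class = "elbow_result")
  list(group_id = as.integer(group_id), elbow = elbow)
}

#' Build the dataset-level marker layout
#'
#' Orchestrates [correlation_matrix()] -> [pca_coordinates()] ->
#' [kmeans_elbow_groups()]. The result is computed once per dataset and
#' reused unchanged for every cluster's Brick plot, so all plots share one
#' marker map.
#'
#' @param table an arcsinh-state [cluster_table()] (pre-threshold values:
#'   zeroing is a display rule and does not feed the correlations).
#' @param config a [threshold_config()] (recorded in the layout for the
#'   manifest; not used by the embedding itself).
#' @param seed integer seed for the K-means restarts.
#' @param k_min,k_max,n_k passed to [kmeans_elbow_groups()]; `k_max = NULL`
#'   means the number of markers.
#' @param kmeans_on `"pc2"` (default: group on the plotted 2-D coordinates)
#'   or `"rows"` (group on full centered correlation rows).
#' @param cor_method passed to [correlation_matrix()].
#' @return An object of class `marker_layout`: `markers` data.frame
#'   (name, pc1, pc2, group), `pc1_var_pct`, `pc2_var_pct`, `k_selected`,
#'   `seed`, `config`, `elbow`.
#' @export
build_layout <- function(table, config = threshold_config(), seed = 42L,
                         k_min = 1L, k_max = NULL, n_k = 30L,
                         kmeans_on = c("pc2", "rows"),
                         cor_method = c("pearson", "spearman")) {
  kmeans_on <- match.arg(kmeans_on)
  corr <- correlation_matrix(table, method = match.arg(cor_method))
  pca <- pca_coordinates(corr)
  if (is.null(k_max)) k_max <- length(corr$marker_names)
  feat <- if (kmeans_on == "pc2") cbind(pca$pc1, pca$pc2)
          else scale(corr$values, center = TRUE, scale = FALSE)
  km <- kmeans_elbow_groups(feat, k_min = k_min, k_max = k_max, n_k = n_k,
                            seed = seed)
  structure(list(
    markers = data.frame(name = corr$marker_names, pc1 = pca$pc1,
                         pc2 = pca$pc2, group = km$group_id,
                         stringsAsFactors = FALSE),
    pc1_var_pct = pca$pc1_var_pct,
    pc2_var_pct = pca$pc2_var_pct,
    k_selected = km$elbow$k_selected,
    seed = as.integer(seed),
    config = list(zero_cutoff = config$zero_cutoff, cofactor = config$cofactor),
    elbow = km$elbow
  ), class = "marker_layout")
}

#' @export
print.marker_layout <- function(x, ...) {
  cat(sprintf("<marker_layout> %d markers, %d groups (elbow-selected), PC1 %.1f%% / PC2 %.1f%% variance, seed %d\n",
              nrow(x$markers), x$k_selected, x$pc1_var_pct, x$pc2_var_pct, x$seed))
  invisible(x)
}

#' Serialize / deserialize a marker layout as JSON
#'
#' The layout JSON is the contract between the dataset-level layout stage and
#' per-cluster rendering; field order is stable and numbers are written at
#' full precision so identical layouts serialize byte-identically.
#'
#' @param layout a `marker_layout`.
#' @param path output file path.
#' @export
write_layout_json <- function(layout, path) {
  doc <- list(
    markers = lapply(seq_len(nrow(layout$markers)), function(i) {
      m <- layout$markers[i, ]
      list(name = m$name, pc1 = m$pc1, pc2 = m$pc2, group = m$group)
    }),
    pc1_var_pct = layout$pc1_var_pct,
    pc2_var_pct = layout$pc2_var_pct,
    k_selected = layout$k_selected,
    seed = layout$seed,
    config = layout$config
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  mk <- doc$markers
  structure(list(
    markers = data.frame(
      name = vapply(mk, `[[`, character(1), "name"),
      pc1 = vapply(mk, `[[`, numeric(1), "pc1"),
      pc2 = vapply(mk, `[[`, numeric(1), "pc2"),
      group = vapply(mk, function(m) as.integer(m$group), integer(1)),
      stringsAsFactors = FALSE),
    pc1_var_pct = doc$pc1_var_pct,
    pc2_var_pct = doc$pc2_var_pct,
    k_selected = as.integer(doc$k_selected),
    seed = as.integer(doc$seed),
    config = doc$config,
    elbow = NULL
  ), class = "marker_layout")
}
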