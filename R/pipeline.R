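#' Read a per-event matrix from CSV/TSV
#'
#' Events in rows, markers in columns, plus one named column holding the
#' cluster label of each event.
#'
#' @inheritParams read_cluster_table
#' @param label_col name of the cluster-label column.
#' @return An [event_matrix()].
#' @export
read_event_matrix <- function(path, label_col = "cluster",
                              dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    bp_stop(sprintf("input file not found: %s", path), "bp_io_error")
  sep <- switch(dialect, csv = ",", tsv = "\t", auto = {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  })
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!label_col %in% colnames(df))
    bp_stop(sprintf("label column '%s' not found; columns: %s", label_col,
                    paste(colnames(df), collapse = ", ")),
            "bp_lookup_error")
  labs <- as.character(df[[label_col]])
  mat <- as.matrix(df[, setdiff(colnames(df), label_col), drop = FALSE])
  if (!is.numeric(mat))
    bp_stop("all marker columns of the event matrix must be numeric", "bp_parse_error")
  event_matrix(mat, labs)
}

#' Run the full Brick plot pipeline
#'
#' Read -> (median by cluster) -> arcsinh transform -> zero threshold ->
#' dataset layout -> one Brick plot per cluster. Writes, under `out_dir`:
#' `layout.json`, `elbow.json` (K vs WCSS diagnostic), one
#' `plot_<cluster>.json` + image per cluster, and `manifest.json` (seed,
#' configuration, package version, input checksum). Rerunning with the same
#' inputs and seed reproduces every JSON byte-identically.
#'
#' @param input_path CSV/TSV input: a clusters-by-markers median table, or a
#'   per-event matrix when `events = TRUE`.
#' @param out_dir output directory (created if needed).
#' @param events treat the input as events x markers with a label column.
#' @param label_col cluster-label column name for event input.
#' @param dialect input delimiter handling, see [read_cluster_table()].
#' @param pre_transformed declare the input already arcsinh-transformed; the
#'   transform step is then skipped.
#' @param cofactor,zero_cutoff see [threshold_config()].
#' @param k_min,k_max,n_k K-means range, see [kmeans_elbow_groups()];
#'   `k_max = NULL` means the number of markers.
#' @param seed master seed for the seeded stages.
#' @param scale_mode `"global"` (default: one area scale for the whole
#'   dataset, so brick sizes compare across clusters) or `"per_marker"`
#'   (each marker scaled to its own dataset maximum first).
#' @param max_area_fraction see [compute_scale_factor()].
#' @param cluster_id render only this cluster (default: all).
#' @param render_cfg a [render_config()].
#' @param quiet suppress stage logging.
#' @return Invisibly, a list with the layout, plots, and written file paths.
#' @export
run_pipeline <- function(input_path, out_dir,
                         events = FALSE, label_col = "cluster",
                         dialect = "auto", pre_transformed = FALSE,
                         cofactor = 5.0, zero_cutoff = 1.0,
                         k_min = 1L, k_max = NULL, n_k = 30L, seed = 42L,
                         scale_mode = c("global", "per_marker"),
                         max_area_fraction = 0.25,
                         cluster_id = NULL,
                         render_cfg = render_config(),
                         quiet = FALSE) {
  scale_mode <- match.arg(scale_mode)
  log_info <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      bp_stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
              "bp_stage_error")
    })
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- threshold_config(zero_cutoff = zero_cutoff, cofactor = cofactor)
  state <- if (pre_transformed) "arcsinh" else "raw_counts"

  log_info("[read] %s", input_path)
  table <- stage("read", {
    if (events) {
      em <- read_event_matrix(input_path, label_col = label_col, dialect = dialect)
      log_info("[median] %d events -> %d clusters",
               nrow(em$events), length(unique(em$cluster_labels)))
      median_by_cluster(em, transform_state = state, cofactor = cofactor)
    } else {
      read_cluster_table(input_path, dialect = dialect,
                         transform_state = state, cofactor = cofactor)
    }
  })
  if (!pre_transformed) {
    log_info("[transform] arcsinh, cofactor %g", cofactor)
    table <- stage("transform", arcsinh_transform(table, cfg))
  }
  log_info("[layout] correlation + PCA + K-means elbow (seed %d)", seed)
  layout <- stage("layout", build_layout(table, cfg, seed = seed, k_min = k_min,
                                         k_max = k_max, n_k = n_k))
  log_info("[layout] k_selected = %d, PC1 %.1f%% / PC2 %.1f%%",
           layout$k_selected, layout$pc1_var_pct, layout$pc2_var_pct)
  log_info("[threshold] zeroing values below %g", zero_cutoff)
  thresholded <- stage("threshold", apply_zero_threshold(table, cfg))

  sized_table <- thresholded
  if (scale_mode == "per_marker") {
    v <- thresholded$values
    mx <- apply(v, 2, max)
    mx[mx == 0] <- 1
    sized_table <- cluster_table(sweep(v, 2, mx, "/"),
                                 transform_state = "arcsinh",
                                 cofactor = thresholded$cofactor)
  }
  scale_factor <- stage("scale", compute_scale_factor(sized_table, layout,
                                                      max_area_fraction))

  layout_path <- file.path(out_dir, "layout.json")
  write_layout_json(layout, layout_path)
  elbow_path <- file.path(out_dir, "elbow.json")
  jsonlite::write_json(
    list(k_values = layout$elbow$k_values, wcss = layout$elbow$wcss,
         k_selected = layout$elbow$k_selected),
    elbow_path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)

  ids <- if (is.null(cluster_id)) cluster_ids(sized_table) else {
    if (!cluster_id %in% cluster_ids(sized_table))
      bp_stop(sprintf("[stage plots] unknown cluster id '%s'", cluster_id),
              "bp_stage_error")
    cluster_id
  }
  safe <- function(s) gsub("[^A-Za-z0-9._-]", "_", s)
  plots <- list(); files <- c(layout_path, elbow_path)
  for (id in ids) {
    bp <- stage("plots", build_brick_plot(sized_table, layout, id,
                                          scale_factor = scale_factor))
    jp <- file.path(out_dir, sprintf("plot_%s.json", safe(id)))
    write_brick_plot_json(bp, jp)
    ip <- file.path(out_dir, sprintf("plot_%s.%s", safe(id),
                                     render_cfg$output_format))
    stage("render", render_plot(bp, layout, render_cfg, ip))
    log_info("[plots] cluster %s: %d bricks rendered, %d displaced",
             id, sum(!bp$bricks$zeroed), sum(bp$bricks$displaced))
    plots[[id]] <- bp
    files <- c(files, jp, ip)
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(
    tool = "brickplot",
    version = as.character(utils::packageVersion("brickplot")),
    input = basename(input_path),
    input_md5 = unname(tools::md5sum(input_path)),
    seed = as.integer(seed),
    config = list(events = events, pre_transformed = pre_transformed,
                  cofactor = cofactor, zero_cutoff = zero_cutoff,
                  k_min = k_min, k_max = k_max, n_k = n_k,
                  scale_mode = scale_mode,
                  max_area_fraction = max_area_fraction,
                  output_format = render_cfg$output_format),
    clusters = ids
  ), manifest_path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  files <- c(files, manifest_path)
  log_info("[done] %d files in %s", length(files), out_dir)
  invisible(list(table = thresholded, layout = layout, plots = plots,
                 scale_factor = scale_factor, files = files))
}
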