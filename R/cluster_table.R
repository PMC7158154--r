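#' Cluster-by-marker expression table
#'
#' The sole data input of the Brick plot method: a matrix of median marker
#' expression with one row per cell cluster and one column per marker.
#' Values are either raw ion counts (`transform_state = "raw_counts"`) or
#' already arcsinh-transformed (`transform_state = "arcsinh"`), in which case
#' the cofactor used is recorded.
#'
#' @param values numeric matrix, clusters in rows, markers in columns; must
#'   carry rownames (cluster ids) and colnames (marker names).
#' @param transform_state `"raw_counts"` or `"arcsinh"`.
#' @param cofactor positive cofactor (ion counts) used for the arcsinh
#'   transform; required when `transform_state = "arcsinh"`.
#' @return An object of class `cluster_table`.
#' @export
cluster_table <- function(values, transform_state = c("raw_counts", "arcsinh"),
                          cofactor = NULL) {
  transform_state <- match.arg(transform_state)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  x <- structure(
    list(values = values, transform_state = transform_state,
         cofactor = if (transform_state == "arcsinh") cofactor else NULL),
    class = "cluster_table"
  )
  validate_cluster_table(x)
}

validate_cluster_table <- function(x) {
  v <- x$values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    bp_stop("cluster_table values must have cluster ids as rownames and marker names as colnames",
            "bp_dimension_error")
  if (anyDuplicated(colnames(v)))
    bp_stop(sprintf("duplicate marker name: '%s'",
                    colnames(v)[duplicated(colnames(v))][1]),
            "bp_duplicate_label_error")
  if (anyDuplicated(rownames(v)))
    bp_stop(sprintf("duplicate cluster id: '%s'",
                    rownames(v)[duplicated(rownames(v))][1]),
            "bp_duplicate_label_error")
  if (nrow(v) < 3 || ncol(v) < 3)
    bp_stop(sprintf("need at least 3 clusters and 3 markers (got %d x %d); correlation and PCA are degenerate below this",
                    nrow(v), ncol(v)),
            "bp_dimension_error")
  if (!all(is.finite(v)))
    bp_stop("all expression values must be finite (no NA/NaN/Inf); missing values are rejected, not imputed",
            "bp_value_error")
  if (x$transform_state == "raw_counts" && any(v < 0))
    bp_stop("raw ion counts must be non-negative", "bp_value_error")
  if (x$transform_state == "arcsinh") {
    if (is.null(x$cofactor) || !is.numeric(x$cofactor) || x$cofactor <= 0)
      bp_stop("arcsinh tables must record a positive cofactor", "bp_value_error")
  }
  x
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("<cluster_table> %d clusters x %d markers [%s%s]\n",
              nrow(x$values), ncol(x$values), x$transform_state,
              if (x$transform_state == "arcsinh")
                sprintf(", cofactor %g", x$cofactor) else ""))
  cat("markers:", paste(utils::head(marker_names(x), 8), collapse = ", "),
      if (ncol(x$values) > 8) "..." else "", "\n")
  invisible(x)
}

#' @rdname cluster_table
#' @param x a `cluster_table`.
#' @export
marker_names <- function(x) colnames(x$values)

#' @rdname cluster_table
#' @export
cluster_ids <- function(x) rownames(x$values)

#' Zeroing-threshold and cofactor configuration
#'
#' @param zero_cutoff non-negative cutoff on the arcsinh scale below which a
#'   marker's value in a cluster is zeroed (default 1: background signal tops
#'   out near one for most markers, and the cutoff is user-adjustable).
#' @param cofactor positive arcsinh cofactor in ion counts (default 5, the
#'   usual CyTOF choice).
#' @return A list of class `threshold_config`.
#' @export
threshold_config <- function(zero_cutoff = 1.0, cofactor = 5.0) {
  if (!is.numeric(zero_cutoff) || length(zero_cutoff) != 1 || zero_cutoff < 0)
    bp_stop("zero_cutoff must be a single non-negative number", "bp_value_error")
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0)
    bp_stop("cofactor must be a single positive number", "bp_value_error")
  structure(list(zero_cutoff = zero_cutoff, cofactor = cofactor),
            class = "threshold_config")
}

#' Read a cluster-by-marker table from CSV/TSV
#'
#' Expects a header row of marker names and a first column of cluster ids;
#' every remaining cell must be numeric. Row and column order are preserved.
#'
#' @param path file path.
#' @param dialect `"auto"` (sniff the delimiter from the header line),
#'   `"csv"`, or `"tsv"`.
#' @param transform_state declare the file's provenance: `"raw_counts"`
#'   (default) or `"arcsinh"` for tables exported already transformed.
#' @param cofactor cofactor to record when `transform_state = "arcsinh"`.
#' @return A [cluster_table()].
#' @export
read_cluster_table <- function(path, dialect = c("auto", "csv", "tsv"),
                               transform_state = c("raw_counts", "arcsinh"),
                               cofactor = 5.0) {
  dialect <- match.arg(dialect)
  transform_state <- match.arg(transform_state)
  if (!file.exists(path))
    bp_stop(sprintf("input file not found: %s", path), "bp_io_error")
  sep <- switch(dialect, csv = ",", tsv = "\t", auto = {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  })
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    bp_stop("table must have a cluster-id column plus marker columns", "bp_dimension_error")
  ids <- df[[1]]
  markers <- colnames(df)[-1]
  raw <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
  if (length(bad)) {
    bp_stop(sprintf("non-numeric cell '%s' at data row %d, marker column %d ('%s')",
                    raw[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2],
                    markers[bad[1, 2]]),
            "bp_parse_error")
  }
  if (anyNA(num)) {
    miss <- which(is.na(num), arr.ind = TRUE)
    bp_stop(sprintf("missing value at data row %d, marker column %d ('%s')",
                    miss[1, 1], miss[1, 2], markers[miss[1, 2]]),
            "bp_parse_error")
  }
  dimnames(num) <- list(ids, markers)
  cluster_table(num, transform_state = transform_state,
                cofactor = if (transform_state == "arcsinh") cofactor else NULL)
}

#' Write a cluster table back to CSV/TSV
#'
#' Inverse of [read_cluster_table()]; labels and values round-trip to within
#' formatting precision (15 significant digits).
#'
#' @inheritParams read_cluster_table
#' @param table a [cluster_table()].
#' @export
write_cluster_table <- function(table, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- data.frame(cluster = cluster_ids(table),
                   format(table$values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("cluster", marker_names(table))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-event expression matrix
#'
#' Upstream input from which per-cluster medians are computed: one row per
#' cell event, one column per marker, plus a cluster label per event.
#'
#' @param events numeric matrix (events x markers) with marker colnames.
#' @param cluster_labels character/factor vector, one label per event row.
#' @return An object of class `event_matrix`.
#' @export
event_matrix <- function(events, cluster_labels) {
  events <- as.matrix(events)
  storage.mode(events) <- "double"
  if (is.null(colnames(events)))
    bp_stop("event matrix must carry marker names as colnames", "bp_dimension_error")
  if (anyDuplicated(colnames(events)))
    bp_stop("duplicate marker name in event matrix", "bp_duplicate_label_error")
  cluster_labels <- as.character(cluster_labels)
  if (length(cluster_labels) != nrow(events))
    bp_stop(sprintf("cluster label count (%d) must equal event row count (%d)",
                    length(cluster_labels), nrow(events)),
            "bp_dimension_error")
  structure(list(events = events, cluster_labels = cluster_labels),
            class = "event_matrix")
}

#' Median marker expression per cluster
#'
#' Collapses an event matrix to one row per distinct cluster label (ordered by
#' first appearance); each cell is the median over that cluster's events.
#' Even event counts use the conventional mean of the two central order
#' statistics.
#'
#' @param events an [event_matrix()].
#' @param transform_state,cofactor provenance declaration inherited by the
#'   resulting table (medians of raw counts are still raw counts).
#' @return A [cluster_table()].
#' @export
median_by_cluster <- function(events, transform_state = c("raw_counts", "arcsinh"),
                              cofactor = 5.0) {
  transform_state <- match.arg(transform_state)
  labs <- events$cluster_labels
  ids <- unique(labs)
  med <- matrix(NA_real_, nrow = length(ids), ncol = ncol(events$events),
                dimnames = list(ids, colnames(events$events)))
  for (id in ids) {
    sub <- events$events[labs == id, , drop = FALSE]
    med[id, ] <- apply(sub, 2, stats::median)
  }
  cluster_table(med, transform_state = transform_state,
                cofactor = if (transform_state == "arcsinh") cofactor else NULL)
}

#' Arcsinh-transform raw ion counts
#'
#' Replaces every value x with asinh(x / cofactor). The transform is log-like
#' at high counts and linear near zero; the cofactor sets the linear range
#' (counts are divided by it to de-emphasize noise around 0).
#'
#' @param table a raw-counts [cluster_table()].
#' @param config a [threshold_config()] carrying the cofactor.
#' @return The transformed `cluster_table` (`transform_state = "arcsinh"`).
#' @export
arcsinh_transform <- function(table, config = threshold_config()) {
  if (table$transform_state != "raw_counts")
    bp_stop("table is already arcsinh-transformed; refusing to transform twice",
            "bp_state_error")
  v <- asinh(table$values / config$cofactor)
  cluster_table(v, transform_state = "arcsinh", cofactor = config$cofactor)
}

#' Zero sub-threshold values
#'
#' Every arcsinh value strictly below `zero_cutoff` is set to exactly 0
#' (cell-wise: a marker may be zeroed in one cluster and kept in another).
#' A zeroed cell yields no brick, suppressing background noise. Values equal
#' to the cutoff survive. Idempotent.
#'
#' @inheritParams arcsinh_transform
#' @return The thresholded `cluster_table`.
#' @export
apply_zero_threshold <- function(table, config = threshold_config()) {
  if (table$transform_state != "arcsinh")
    bp_stop("zeroing applies to arcsinh-transformed tables only", "bp_state_error")
  v <- table$values
  v[v < config$zero_cutoff] <- 0
  cluster_table(v, transform_state = "arcsinh", cofactor = table$cofactor)
}
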