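## Numeric slack for "interiors disjoint": shared edges/corners are allowed,
## so two bricks overlap only if they interpenetrate by more than EPS.
BP_EPS <- 1e-9

#' Dataset-level area scale factor
#'
#' Brick area is proportional to the thresholded arcsinh value:
#' `area = s * value` with one constant `s` per dataset, so brick sizes are
#' comparable across every cluster plot. `s` is chosen so that the single
#' largest brick in the whole dataset has side `max_area_fraction` times the
#' span of the layout coordinates.
#'
#' @param table thresholded arcsinh [cluster_table()] (the whole dataset).
#' @param layout the dataset [build_layout()] result (its coordinate span
#'   fixes the geometry scale).
#' @param max_area_fraction side of the largest brick as a fraction of the
#'   layout span, in (0, 1]; default 0.25 keeps even the largest brick well
#'   inside the marker map.
#' @return Positive scale factor `s` (area units per expression unit).
#' @export
compute_scale_factor <- function(table, layout, max_area_fraction = 0.25) {
  if (!is.numeric(max_area_fraction) || max_area_fraction <= 0 || max_area_fraction > 1)
    bp_stop("max_area_fraction must lie in (0, 1]", "bp_value_error")
  v_max <- max(table$values)
  if (v_max <= 0)
    bp_stop("no bricks to scale: every value in the table is zero", "bp_all_zero_error")
  L <- layout_span(layout)
  (max_area_fraction * L)^2 / v_max
}

layout_span <- function(layout) {
  sx <- diff(range(layout$markers$pc1))
  sy <- diff(range(layout$markers$pc2))
  L <- max(sx, sy)
  if (L <= 0) 1 else L
}

#' Size bricks for one cluster
#'
#' One brick per layout marker, centered at the marker's PC1/PC2 coordinate,
#' with `area = scale_factor * value` and `side = sqrt(area)` (bricks are
#' squares). A zero value yields a zeroed brick: flagged, never rendered,
#' never considered by overlap resolution.
#'
#' @param layout a `marker_layout`.
#' @param cluster_row named numeric vector of thresholded values, aligned
#'   with the layout marker order.
#' @param scale_factor from [compute_scale_factor()].
#' @return data.frame of bricks: marker, x, y, side, area, group, zeroed,
#'   displaced.
#' @export
size_bricks <- function(layout, cluster_row, scale_factor) {
  mk <- layout$markers
  if (length(cluster_row) != nrow(mk))
    bp_stop(sprintf("cluster row has %d values but layout has %d markers",
                    length(cluster_row), nrow(mk)),
            "bp_alignment_error")
  if (!is.null(names(cluster_row)) && !identical(names(cluster_row), mk$name))
    bp_stop("cluster row marker names do not match layout marker order",
            "bp_alignment_error")
  area <- scale_factor * as.numeric(cluster_row)
  data.frame(
    marker = mk$name,
    x = mk$pc1, y = mk$pc2,
    side = sqrt(area), area = area,
    group = mk$group,
    zeroed = area == 0,
    displaced = FALSE,
    stringsAsFactors = FALSE
  )
}

## TRUE iff the open interiors of two axis-aligned squares intersect
## (by more than the shared-edge slack).
interiors_overlap <- function(x1, y1, s1, x2, y2, s2) {
  hx <- (s1 + s2) / 2
  abs(x1 - x2) < hx - BP_EPS && abs(y1 - y2) < hx - BP_EPS
}

## Minimal t > 0 so that a square of side s1 whose center moves to
## B + t*u is interior-disjoint from the placed square (center B, side s2).
## u is a unit direction. Disjointness needs separation >= h on x OR y.
push_distance <- function(ux, uy, h) {
  tx <- if (abs(ux) > BP_EPS) h / abs(ux) else Inf
  ty <- if (abs(uy) > BP_EPS) h / abs(uy) else Inf
  min(tx, ty)
}

#' Resolve brick overlaps by deterministic adjacent placement
#'
#' Bricks are placed one at a time in descending area (ties broken by marker
#' name). A brick that overlaps an already-placed brick is moved outward
#' along the ray from the overlapped brick's center through the moving
#' brick's original center, by the minimal distance that makes the two
#' interiors disjoint (edge contact allowed) — i.e. the new brick is placed
#' adjacent to the existing one. If the pushed position collides with another
#' placed brick, the push repeats against that brick up to a bounded number
#' of iterations, after which a fully deterministic outward spiral search
#' (fixed angular step, fixed radial increment, centered on the original
#' position) finds the nearest collision-free spot. Bricks that never collide
#' are never moved; output row order equals input order.
#'
#' @param bricks data.frame from [size_bricks()]; zeroed bricks pass through
#'   untouched.
#' @param max_push_iter bound on chained pushes per brick before falling back
#'   to the spiral.
#' @param spiral_steps bound on spiral probes; exhausting it means the total
#'   brick area exceeds the available canvas — reduce `max_area_fraction`.
#' @return The bricks data.frame with updated x/y and `displaced` flags.
#' @export
resolve_overlaps <- function(bricks, max_push_iter = 64L, spiral_steps = 20000L) {
  active <- which(!bricks$zeroed)
  if (length(active) < 2) return(bricks)
  ord <- active[order(-bricks$area[active], bricks$marker[active], method = "radix")]
  span <- max(diff(range(bricks$x[active])), diff(range(bricks$y[active])),
              max(bricks$side[active]))
  placed <- integer(0)
  for (i in ord) {
    ox <- bricks$x[i]; oy <- bricks$y[i]   # original center fixes the ray
    cx <- ox; cy <- oy
    si <- bricks$side[i]
    moved <- FALSE
    iter <- 0L
    repeat {
      hit <- 0L
      for (j in placed) {
        if (interiors_overlap(cx, cy, si, bricks$x[j], bricks$y[j], bricks$side[j])) {
          hit <- j; break
        }
      }
      if (hit == 0L) break
      iter <- iter + 1L
      if (iter > max_push_iter) {
        sp <- spiral_search(ox, oy, si, bricks, placed,
                            step = span / 64, n_steps = spiral_steps)
        cx <- sp[1]; cy <- sp[2]; moved <- TRUE
        break
      }
      dx <- ox - bricks$x[hit]; dy <- oy - bricks$y[hit]
      nrm <- sqrt(dx^2 + dy^2)
      if (nrm < BP_EPS) { dx <- 1; dy <- 0; nrm <- 1 }  # coincident centers: push +x
      ux <- dx / nrm; uy <- dy / nrm
      h <- (si + bricks$side[hit]) / 2
      t <- push_distance(ux, uy, h)
      cx <- bricks$x[hit] + t * ux
      cy <- bricks$y[hit] + t * uy
      moved <- TRUE
    }
    bricks$x[i] <- cx; bricks$y[i] <- cy
    bricks$displaced[i] <- moved
    placed <- c(placed, i)
  }
  bricks
}

## Deterministic Archimedean spiral probe around (ox, oy): radius grows by
## `step` per turn, 16 probes per turn. First collision-free center wins.
spiral_search <- function(ox, oy, side, bricks, placed, step, n_steps) {
  golden <- pi * (3 - sqrt(5))
  for (k in seq_len(n_steps)) {
    r <- step * (1 + k / 16)
    th <- k * golden
    cx <- ox + r * cos(th); cy <- oy + r * sin(th)
    free <- TRUE
    for (j in placed) {
      if (interiors_overlap(cx, cy, side, bricks$x[j], bricks$y[j], bricks$side[j])) {
        free <- FALSE; break
      }
    }
    if (free) return(c(cx, cy))
  }
  bp_stop("overlap resolution budget exhausted: total brick area exceeds the canvas; reduce max_area_fraction",
          "bp_layout_budget_error")
}

#' Build the Brick plot for one cluster
#'
#' Sizes the cluster's bricks on the shared dataset layout, resolves
#' overlaps, and bundles the result with the dataset scale factor and the
#' bounding rectangle of the rendered bricks. Positions before overlap
#' resolution are dataset-level: every cluster's plot starts from the same
#' marker map.
#'
#' @param table the full thresholded [cluster_table()] (the scale factor is a
#'   dataset property).
#' @param layout [build_layout()] result for the same marker set.
#' @param cluster_id which cluster (row) to plot.
#' @param max_area_fraction see [compute_scale_factor()].
#' @param scale_factor override the computed scale factor (used by the
#'   pipeline to compute it once).
#' @return An object of class `brick_plot`.
#' @export
build_brick_plot <- function(table, layout, cluster_id,
                             max_area_fraction = 0.25, scale_factor = NULL) {
  if (!identical(marker_names(table), layout$markers$name))
    bp_stop("table and layout marker sets differ", "bp_alignment_error")
  if (!cluster_id %in% cluster_ids(table))
    bp_stop(sprintf("unknown cluster id '%s'; available: %s", cluster_id,
                    paste(cluster_ids(table), collapse = ", ")),
            "bp_lookup_error")
  if (is.null(scale_factor))
    scale_factor <- compute_scale_factor(table, layout, max_area_fraction)
  row <- table$values[cluster_id, ]
  bricks <- size_bricks(layout, row, scale_factor)
  bricks <- resolve_overlaps(bricks)
  shown <- bricks[!bricks$zeroed, , drop = FALSE]
  bounds <- if (nrow(shown)) {
    c(xmin = min(shown$x - shown$side / 2), xmax = max(shown$x + shown$side / 2),
      ymin = min(shown$y - shown$side / 2), ymax = max(shown$y + shown$side / 2))
  } else {
    c(xmin = min(layout$markers$pc1), xmax = max(layout$markers$pc1),
      ymin = min(layout$markers$pc2), ymax = max(layout$markers$pc2))
  }
  structure(list(cluster_id = cluster_id, bricks = bricks,
                 scale_factor = scale_factor, bounds = bounds),
            class = "brick_plot")
}

#' @export
print.brick_plot <- function(x, ...) {
  cat(sprintf("<brick_plot> cluster '%s': %d bricks rendered (%d zeroed, %d displaced), scale %.4g\n",
              x$cluster_id, sum(!x$bricks$zeroed), sum(x$bricks$zeroed),
              sum(x$bricks$displaced), x$scale_factor))
  invisible(x)
}

#' Serialize / deserialize a Brick plot as JSON
#'
#' The renderer's sole input. Field order is stable and numbers are written
#' at full precision, so the same plot always serializes byte-identically.
#'
#' @param plot a `brick_plot`.
#' @param path output file path.
#' @export
write_brick_plot_json <- function(plot, path) {
  doc <- list(
    cluster_id = plot$cluster_id,
    scale_factor = plot$scale_factor,
    bricks = lapply(seq_len(nrow(plot$bricks)), function(i) {
      b <- plot$bricks[i, ]
      list(marker = b$marker, x = b$x, y = b$y, side = b$side,
           group = b$group, zeroed = b$zeroed, displaced = b$displaced)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_brick_plot_json
#' @export
read_brick_plot_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  bk <- doc$bricks
  bricks <- data.frame(
    marker = vapply(bk, `[[`, character(1), "marker"),
    x = vapply(bk, `[[`, numeric(1), "x"),
    y = vapply(bk, `[[`, numeric(1), "y"),
    side = vapply(bk, `[[`, numeric(1), "side"),
    group = vapply(bk, function(b) as.integer(b$group), integer(1)),
    zeroed = vapply(bk, `[[`, logical(1), "zeroed"),
    displaced = vapply(bk, `[[`, logical(1), "displaced"),
    stringsAsFactors = FALSE
  )
  bricks$area <- bricks$side^2
  structure(list(cluster_id = doc$cluster_id, bricks = bricks,
                 scale_factor = doc$scale_factor, bounds = NULL),
            class = "brick_plot")
}

#' Count pairwise interior overlaps among rendered bricks
#'
#' Exhaustive O(n^2) check used as the geometric soundness oracle: returns
#' the number of brick pairs whose open interiors intersect. Zero after
#' [resolve_overlaps()].
#'
#' @param bricks a bricks data.frame.
#' @return Integer count of overlapping pairs.
#' @export
count_overlapping_pairs <- function(bricks) {
  idx <- which(!bricks$zeroed)
  n_bad <- 0L
  if (length(idx) < 2) return(n_bad)
  for (a in seq_along(idx)[-length(idx)]) {
    for (b in (a + 1):length(idx)) {
      i <- idx[a]; j <- idx[b]
      if (interiors_overlap(bricks$x[i], bricks$y[i], bricks$side[i],
                            bricks$x[j], bricks$y[j], bricks$side[j]))
        n_bad <- n_bad + 1L
    }
  }
  n_bad
}
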