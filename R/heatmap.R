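#' Hierarchically cluster one axis of a signal matrix
#'
#' Agglomerative clustering of the axis vectors with Euclidean distance and
#' complete linkage. The leaf order is a deterministic left-first traversal
#' of the merge tree in which, at every internal node, the subtree
#' containing the smaller original index is visited first — so identical
#' inputs always yield identical orders regardless of platform heuristics.
#'
#' @param matrix numeric matrix (log-PRR values)
#' @param axis \code{"row"} or \code{"column"}
#' @return list with \code{merge} and \code{height} (as in
#'   \code{\link[stats]{hclust}}), \code{order} (leaf permutation) and
#'   \code{labels}
#' @export
cluster_axis <- function(matrix, axis = c("row", "column")) {
  axis <- match.arg(axis)
  x <- if (axis == "row") matrix else t(matrix)
  labels <- rownames(x)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
  n <- nrow(x)
  if (n == 0L) stop("cannot cluster an empty axis")
  if (n == 1L)
    return(list(merge = matrix(numeric(0), 0, 2), height = numeric(0),
                order = 1L, labels = labels))
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "complete")
  list(merge = hc$merge, height = hc$height,
       order = deterministic_leaf_order(hc$merge, n), labels = labels)
}

# left-first traversal; at each node the child subtree with the smaller
# minimal original leaf index is visited first
deterministic_leaf_order <- function(merge, n) {
  if (nrow(merge) == 0L) return(1L)
  leaves <- vector("list", nrow(merge))
  mins <- numeric(nrow(merge))
  side <- function(v, k) {
    if (v < 0) list(leaves = -v, min = -v) else
      list(leaves = leaves[[v]], min = mins[v])
  }
  for (k in seq_len(nrow(merge))) {
    l <- side(merge[k, 1L])
    r <- side(merge[k, 2L])
    if (l$min <= r$min) {
      leaves[[k]] <- c(l$leaves, r$leaves)
    } else {
      leaves[[k]] <- c(r$leaves, l$leaves)
    }
    mins[k] <- min(l$min, r$min)
  }
  as.integer(leaves[[nrow(merge)]])
}

#' Build a clustered heat-map matrix at one of the three resolutions
#'
#' Assembles the dense log-PRR matrix from signal records, optionally
#' restricted to a focal drug class's members (drill-down level 2) and/or a
#' set of ADE columns (drill-down level 3), and clusters both axes. The
#' three resolutions of exploration are: all drug classes x ADE classes
#' (class-level records), the drugs of one class x ADE classes (drug-level
#' records, \code{rows =} the class members), and those drugs x the
#' individual ADE terms of selected ADE classes (\code{rows} and
#' \code{cols} both set).
#'
#' @param records signal records at a single resolution from
#'   \code{\link{signal_scan}}
#' @param rows optional row filter (e.g. member ingredients of a focal
#'   class)
#' @param cols optional column filter (e.g. ADE terms of selected classes)
#' @param prr_min optional: keep only columns whose maximum PRR over the
#'   selected rows reaches this value (the usual way to focus a drill-down
#'   on strong signals)
#' @return an object of class \code{classfx_heatmap}: the matrix in
#'   original order plus row/column orders and linkage trees
#' @export
build_heatmap <- function(records, rows = NULL, cols = NULL, prr_min = NULL) {
  if (nrow(records) == 0L) stop("no signal records to plot")
  if (!is.null(rows)) records <- records[records$row_id %in% rows, ]
  if (!is.null(cols)) records <- records[records$col_id %in% cols, ]
  if (nrow(records) == 0L) stop("empty selection: no records match filters")
  m <- to_matrix(records, row_ids = if (is.null(rows)) NULL else rows,
                 col_ids = if (is.null(cols)) NULL else cols)
  if (!is.null(prr_min)) {
    keep <- apply(m, 2L, max) >= log(prr_min)
    if (!any(keep)) stop("empty selection: no column reaches prr_min")
    m <- m[, keep, drop = FALSE]
  }
  rowc <- cluster_axis(m, "row")
  colc <- cluster_axis(m, "column")
  structure(list(matrix = m, row_order = rowc$order, col_order = colc$order,
                 row_linkage = rowc[c("merge", "height")],
                 col_linkage = colc[c("merge", "height")]),
            class = "classfx_heatmap")
}

#' @export
print.classfx_heatmap <- function(x, ...) {
  cat("<classfx_heatmap> ", nrow(x$matrix), " x ", ncol(x$matrix),
      " (clustered)\n", sep = "")
  invisible(x)
}

#' Permuted matrix of a clustered heat map
#' @param x a \code{classfx_heatmap}
#' @return the log-PRR matrix with rows and columns in dendrogram order
#' @export
permuted_matrix <- function(x) {
  stopifnot(inherits(x, "classfx_heatmap"))
  x$matrix[x$row_order, x$col_order, drop = FALSE]
}

#' Export a clustered heat map as TSV
#'
#' Writes the permuted matrix with row and column headers; reading the file
#' back with \code{\link{read_table}} reproduces the values.
#'
#' @param x a \code{classfx_heatmap}
#' @param path output path
#' @export
export_heatmap <- function(x, path) {
  m <- permuted_matrix(x)
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, path)
  invisible(path)
}

#' Render a clustered heat map to a PNG file
#'
#' Low values draw in red, intermediate in yellow, high in white — strong
#' signals stand out bright against a red background.
#'
#' @param x a \code{classfx_heatmap}
#' @param path output PNG path
#' @param width,height image size in pixels
#' @export
render_heatmap <- function(x, path, width = 900, height = 700) {
  m <- permuted_matrix(x)
  if (any(!is.finite(m))) stop("matrix contains non-finite values")
  ramp <- grDevices::colorRampPalette(c("red", "yellow", "white"))(256)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(6, 6, 2, 2))   # device-local; dies with dev.off()
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = z,
                  col = ramp, axes = FALSE, xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 2, cex.axis = 0.7)
  invisible(path)
}
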