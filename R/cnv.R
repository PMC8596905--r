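#' Call integer copy numbers from a segmentation
#'
#' For every segment and cell, the copy number is the rounded ratio
#' \eqn{\lfloor 2X/\hat X\rceil} of the segment-level mean raw depth to the
#' mean normalised (expected-diploid) depth, clamped to `[0, cn_cap]` and
#' broadcast to all bins of the segment. Calling uses segment-level means,
#' matching the segmentation objective, never per-bin ratios.
#'
#' @param raw,norm matched `read_depth_matrix` objects (may span several
#'   chromosomes).
#' @param segs a [segmentation()] or list of them; together they must cover
#'   every bin of `raw` exactly once.
#' @param params an [mbic_params()]; supplies `cn_cap`.
#' @return An object of class `cnv_matrix`: list with integer `values`
#'   (bins x cells), `bins`, `cell_ids`, `segments`, and a logical
#'   `overflow` mask marking entries clamped at `cn_cap`.
#' @export
call_copy_number <- function(raw, norm, segs, params = NULL) {
  if (is.null(params)) params <- default_mbic_params(ncol(raw$values))
  if (inherits(segs, "segmentation")) segs <- list(segs)
  m <- nrow(raw$values)
  n <- ncol(raw$values)
  covered <- integer(m)
  values <- matrix(NA_integer_, m, n)
  overflow <- matrix(FALSE, m, n)
  for (s in segs) {
    idx <- which(raw$bins$chrom == s$chrom)
    if (length(idx) != s$m) {
      stop("segmentation of ", s$chrom, " expects ", s$m, " bins; matrix has ",
           length(idx), call. = FALSE)
    }
    bounds <- segment_bounds(s)
    for (k in seq_len(nrow(bounds))) {
      rows <- idx[bounds[k, "start"]:bounds[k, "end"]]
      covered[rows] <- covered[rows] + 1L
      X <- colMeans(raw$values[rows, , drop = FALSE])
      Xhat <- colMeans(norm$values[rows, , drop = FALSE])
      cn_raw <- rounded_cn(X, Xhat)
      cn <- pmin(pmax(cn_raw, 0L), params$cn_cap)
      values[rows, ] <- matrix(cn, length(rows), n, byrow = TRUE)
      overflow[rows, ] <- matrix(cn_raw > params$cn_cap, length(rows), n,
                                 byrow = TRUE)
    }
  }
  if (any(covered != 1L)) {
    bad <- which(covered != 1L)[1]
    stop("bin ", bad, " is covered ", covered[bad],
         " times by the segmentations; need exactly once", call. = FALSE)
  }
  colnames(values) <- raw$cell_ids
  structure(list(values = values, bins = raw$bins, cell_ids = raw$cell_ids,
                 segments = segs, overflow = overflow),
            class = "cnv_matrix")
}

#' @export
print.cnv_matrix <- function(x, ...) {
  cat(sprintf("<cnv_matrix> %d bins x %d cells, CN range [%d, %d]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Aggregate a copy-number matrix by cell group
#'
#' Per-group per-bin mean copy number, e.g. for clone-level heatmap or
#' stairstep displays.
#'
#' @param cnv a `cnv_matrix`.
#' @param labels group label per cell: named vector (names = cell ids) or
#'   vector in column order.
#' @return Numeric matrix, groups x bins.
#' @export
aggregate_by_group <- function(cnv, labels) {
  stopifnot(inherits(cnv, "cnv_matrix"))
  if (!is.null(names(labels))) {
    idx <- match(cnv$cell_ids, names(labels))
    if (anyNA(idx)) {
      stop("unlabeled cell(s): ",
           paste(cnv$cell_ids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    labels <- labels[idx]
  } else if (length(labels) != length(cnv$cell_ids)) {
    stop("need one label per cell (", length(cnv$cell_ids), ")", call. = FALSE)
  }
  labels <- as.character(labels)
  groups <- unique(labels)
  out <- t(vapply(groups, function(g) {
    rowMeans(cnv$values[, labels == g, drop = FALSE])
  }, numeric(nrow(cnv$values))))
  rownames(out) <- groups
  out
}

#' Long-format copy-number table
#'
#' @param cnv a `cnv_matrix`.
#' @return data.frame with columns cell, chrom, start, end, cn (one row per
#'   cell per bin).
#' @export
cnv_long <- function(cnv) {
  stopifnot(inherits(cnv, "cnv_matrix"))
  m <- nrow(cnv$values)
  n <- ncol(cnv$values)
  data.frame(cell = rep(cnv$cell_ids, each = m),
             chrom = rep(cnv$bins$chrom, n),
             start = rep(cnv$bins$start, n),
             end = rep(cnv$bins$end, n),
             cn = as.vector(cnv$values))
}

#' Write a copy-number matrix as TSV
#'
#' @param cnv a `cnv_matrix`.
#' @param path output path (bins x cells of integers, cell-id header).
#' @return `path`, invisibly.
#' @export
write_cnv <- function(cnv, path) {
  d <- as.data.frame(cnv$values)
  colnames(d) <- cnv$cell_ids
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}
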