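#' Cell-by-bin read-depth matrices
#'
#' A `read_depth_matrix` bundles a bins x cells matrix of read counts with
#' its genomic bin annotations and a flag saying whether the counts are raw
#' (non-negative integers) or normalised (non-negative reals, typically the
#' expected diploid depth per bin per cell). Rows are genomic bins, columns
#' are cells; bins within a chromosome are sorted, non-overlapping and --
#' except possibly the last one -- of equal width.
#'
#' @param values numeric matrix, bins in rows, cells in columns.
#' @param bins data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive coordinates), one row per matrix row.
#' @param cell_ids character vector of cell identifiers, one per column.
#' @param kind `"raw"` or `"normalized"`.
#' @return An object of class `read_depth_matrix`: a list with elements
#'   `values`, `bins`, `cell_ids`, `kind`.
#' @examples
#' bins <- data.frame(chrom = "chr1", start = c(1, 11), end = c(10, 20))
#' m <- read_depth_matrix(matrix(0:3, 2, 2), bins, c("c1", "c2"), "raw")
#' dim(m)
#' @export
read_depth_matrix <- function(values, bins, cell_ids, kind = c("raw", "normalized")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  bins <- validate_bins(bins)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != nrow(bins)) {
    stop("matrix has ", nrow(values), " rows but bin annotation has ",
         nrow(bins), " rows", call. = FALSE)
  }
  if (ncol(values) != length(cell_ids)) {
    stop("matrix has ", ncol(values), " columns but ", length(cell_ids),
         " cell ids were given", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("matrix contains missing or non-finite entries", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("matrix contains negative entries; read depths must be non-negative",
         call. = FALSE)
  }
  if (kind == "raw" && any(values != floor(values))) {
    stop("raw count matrix contains non-integer entries", call. = FALSE)
  }
  colnames(values) <- cell_ids
  structure(list(values = values, bins = bins, cell_ids = cell_ids, kind = kind),
            class = "read_depth_matrix")
}

validate_bins <- function(bins) {
  bins <- as.data.frame(bins)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(bins))) {
    stop("bin annotation must have columns chrom, start, end", call. = FALSE)
  }
  bins <- bins[need]
  bins$chrom <- as.character(bins$chrom)
  bins$start <- as.numeric(bins$start)
  bins$end <- as.numeric(bins$end)
  if (any(bins$start > bins$end)) {
    stop("bin annotation has start > end", call. = FALSE)
  }
  for (chr in unique(bins$chrom)) {
    b <- bins[bins$chrom == chr, ]
    if (is.unsorted(b$start, strictly = TRUE) && nrow(b) > 1) {
      stop("bins on ", chr, " are not sorted by start", call. = FALSE)
    }
    if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)])) {
      stop("bins on ", chr, " overlap", call. = FALSE)
    }
  }
  rownames(bins) <- NULL
  bins
}

#' @export
dim.read_depth_matrix <- function(x) dim(x$values)

#' @export
print.read_depth_matrix <- function(x, ...) {
  cat(sprintf("<read_depth_matrix> %s: %d bins x %d cells, %d chromosome(s)\n",
              x$kind, nrow(x$values), ncol(x$values),
              length(unique(x$bins$chrom))))
  invisible(x)
}

#' Chromosomes present in a read-depth matrix
#'
#' @param mat a `read_depth_matrix`.
#' @return Character vector of chromosome names in bin order.
#' @export
chromosomes <- function(mat) unique(mat$bins$chrom)

#' Read bin annotations from a BED file
#'
#' BED coordinates on disk are 0-based half-open; they are converted to the
#' 1-based inclusive convention used internally.
#'
#' @param path path to a 3-column BED file (chrom, start, end), no header.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bins <- function(path) {
  if (!file.exists(path)) stop("bins file not found: ", path, call. = FALSE)
  b <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(b) < 3) stop("bins file must have at least 3 columns", call. = FALSE)
  data.frame(chrom = as.character(b[[1]]), start = as.numeric(b[[2]]) + 1,
             end = as.numeric(b[[3]]))
}

#' Write bin annotations to a BED file
#'
#' @param bins data.frame with 1-based inclusive `chrom`, `start`, `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bins <- function(bins, path) {
  bins <- validate_bins(bins)
  out <- data.frame(chrom = bins$chrom, start = format(bins$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(bins$end, scientific = FALSE, trim = TRUE))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a cell-by-bin count matrix from disk
#'
#' Two dialects are supported: dense TSV (header row of cell ids, one row
#' per bin) and MatrixMarket coordinate format (`.mtx`, bins as rows) with a
#' companion one-id-per-line cells file.
#'
#' @param path matrix file (`.tsv`/`.txt` dense, or `.mtx` sparse).
#' @param bins_path BED file of bin coordinates, one row per matrix row.
#' @param kind `"raw"` or `"normalized"`.
#' @param cells_path required for `.mtx` input: text file of cell ids.
#' @return A [read_depth_matrix()].
#' @export
read_matrix <- function(path, bins_path, kind = c("raw", "normalized"),
                        cells_path = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  bins <- read_bins(bins_path)
  if (grepl("\\.mtx$", path)) {
    if (is.null(cells_path)) {
      stop("sparse .mtx input needs a cells_path file of cell ids", call. = FALSE)
    }
    values <- as.matrix(Matrix::readMM(path))
    cell_ids <- readLines(cells_path)
  } else {
    d <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
    cell_ids <- colnames(d)
    values <- as.matrix(d)
  }
  read_depth_matrix(values, bins, cell_ids, kind)
}

#' Write a read-depth matrix (and its bins) to disk
#'
#' @param mat a `read_depth_matrix`.
#' @param path output matrix path; `.mtx` suffix selects sparse output.
#' @param bins_path optional BED output path for the bin annotations.
#' @param cells_path cells-file path, required when writing `.mtx`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, bins_path = NULL, cells_path = NULL) {
  stopifnot(inherits(mat, "read_depth_matrix"))
  if (grepl("\\.mtx$", path)) {
    if (is.null(cells_path)) {
      stop("sparse .mtx output needs a cells_path for the cell ids", call. = FALSE)
    }
    Matrix::writeMM(Matrix::Matrix(mat$values, sparse = TRUE), path)
    writeLines(mat$cell_ids, cells_path)
  } else {
    d <- as.data.frame(mat$values)
    colnames(d) <- mat$cell_ids
    data.table::fwrite(d, path, sep = "\t")
  }
  if (!is.null(bins_path)) write_bins(mat$bins, bins_path)
  invisible(path)
}

#' Extract one chromosome's contiguous block of bins
#'
#' Segmentation is per-chromosome: this returns the row block of `mat`
#' annotated to `chrom`, preserving bin order and cell ids.
#'
#' @param mat a `read_depth_matrix`.
#' @param chrom chromosome name.
#' @return A `read_depth_matrix` restricted to `chrom`.
#' @export
slice_chromosome <- function(mat, chrom) {
  stopifnot(inherits(mat, "read_depth_matrix"))
  keep <- mat$bins$chrom == chrom
  if (!any(keep)) {
    stop("chromosome '", chrom, "' not found; available: ",
         paste(chromosomes(mat), collapse = ", "), call. = FALSE)
  }
  read_depth_matrix(mat$values[keep, , drop = FALSE], mat$bins[keep, ],
                    mat$cell_ids, mat$kind)
}

#' Rank-one baseline normalisation
#'
#' Builds the expected diploid depth matrix as the outer product of a
#' per-bin baseline `b_i` (mean raw count over the baseline cells) and a
#' per-cell library-size factor `s_j` (cell total over the mean total of
#' baseline cells). This is a deliberately simple stand-in for model-based
#' cross-cell normalisation: externally normalised matrices can be supplied
#' directly to the segmentation functions instead.
#'
#' @param raw a raw `read_depth_matrix`.
#' @param normal_cells optional character vector of cell ids to use as the
#'   diploid baseline; defaults to all cells.
#' @param eps positive floor applied to the result so downstream ratios
#'   \eqn{2X/\hat X} are always defined.
#' @return A `read_depth_matrix` with `kind = "normalized"`.
#' @export
normalize_baseline <- function(raw, normal_cells = NULL, eps = 1e-8) {
  stopifnot(inherits(raw, "read_depth_matrix"))
  if (raw$kind != "raw") stop("normalize_baseline expects a raw matrix", call. = FALSE)
  Y <- raw$values
  zero_bin <- which(rowSums(Y) == 0)
  if (length(zero_bin)) {
    stop("bin ", zero_bin[1], " (", raw$bins$chrom[zero_bin[1]], ":",
         raw$bins$start[zero_bin[1]], "-", raw$bins$end[zero_bin[1]],
         ") has zero count in every cell", call. = FALSE)
  }
  zero_cell <- which(colSums(Y) == 0)
  if (length(zero_cell)) {
    stop("cell '", raw$cell_ids[zero_cell[1]], "' has zero total count", call. = FALSE)
  }
  if (is.null(normal_cells)) {
    base_idx <- seq_along(raw$cell_ids)
  } else {
    base_idx <- match(normal_cells, raw$cell_ids)
    if (anyNA(base_idx)) {
      stop("unknown baseline cell id(s): ",
           paste(normal_cells[is.na(base_idx)], collapse = ", "), call. = FALSE)
    }
  }
  b <- rowMeans(Y[, base_idx, drop = FALSE])
  totals <- colSums(Y)
  s <- totals / mean(totals[base_idx])
  Yhat <- pmax(outer(b, s), eps)
  read_depth_matrix(Yhat, raw$bins, raw$cell_ids, "normalized")
}
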