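#' Single-segment log-likelihood table
#'
#' Fills the upper-triangular m x m table `l[i, j]` with the generalized
#' log-likelihood ratio of the single segment spanning bins i..j. Prefix
#' sums over bins make each entry O(n), the whole table O(m^2 n).
#'
#' @param raw,norm matched single-chromosome `read_depth_matrix` objects;
#'   `norm` must be strictly positive.
#' @param params an [mbic_params()].
#' @return m x m numeric matrix, `NA` below the diagonal.
#' @export
build_l_table <- function(raw, norm, params = mbic_params()) {
  stopifnot(inherits(raw, "read_depth_matrix"), inherits(norm, "read_depth_matrix"))
  if (!identical(dim(raw$values), dim(norm$values))) {
    stop("raw and normalized matrices differ in shape", call. = FALSE)
  }
  m <- nrow(raw$values)
  if (m == 0) stop("empty chromosome: no bins", call. = FALSE)
  if (any(norm$values <= 0)) {
    stop("normalized matrix must be strictly positive (apply the epsilon floor)",
         call. = FALSE)
  }
  Y <- raw$values
  Yhat <- norm$values
  n <- ncol(Y)
  cumY <- rbind(0, apply(Y, 2, cumsum))
  cumYhat <- rbind(0, apply(Yhat, 2, cumsum))
  dim(cumY) <- dim(cumYhat) <- c(m + 1L, n)
  l <- matrix(NA_real_, m, m)
  lf <- params$log_floor
  for (i in seq_len(m)) {
    lens <- seq_len(m - i + 1)                       # segment lengths for j = i..m
    SX <- cumY[(i:m) + 1L, , drop = FALSE] -
      matrix(cumY[i, ], m - i + 1, n, byrow = TRUE)
    SXh <- cumYhat[(i:m) + 1L, , drop = FALSE] -
      matrix(cumYhat[i, ], m - i + 1, n, byrow = TRUE)
    X <- SX / lens
    Xh <- SXh / lens
    cn <- floor(2 * X / Xh + 0.5)
    log_arg <- cn
    log_arg[cn == 0] <- lf
    contrib <- Xh * (1 - cn / 2) + X * log(log_arg / 2)
    l[i, i:m] <- lens * rowSums(contrib)
  }
  l
}

#' Fill the dynamic-programming tables
#'
#' Computes, for k = 1..K segments and every prefix of bins 1..i, the best
#' achievable likelihood `L[k, i]`, the argmax backpointer `T[k, i]` (the
#' last bin of the penultimate segment; ties broken towards the smallest
#' index), and the penalised objective `beta[k, i] = L[k, i] -
#' log C(m, k-1) - (k-1)(kappa1-kappa2)`. The penalty depends on k only, so
#' it is applied per layer and never disturbs the inner argmax.
#'
#' @param l_table output of [build_l_table()].
#' @param params an [mbic_params()].
#' @param K maximum number of segments to explore; default `min(m, 15)`.
#' @return A list of class `dp_tables` with `l`, `L`, `beta`, `T`, `K`, `m`.
#' @export
dp_fill <- function(l_table, params = mbic_params(), K = NULL) {
  m <- nrow(l_table)
  if (is.null(K)) K <- min(m, 15L)
  K <- as.integer(K)
  if (K < 1 || K > m) stop("need 1 <= K <= m (K = ", K, ", m = ", m, ")",
                           call. = FALSE)
  L <- matrix(-Inf, K, m)
  TT <- matrix(0L, K, m)
  L[1, ] <- l_table[1, ]
  if (K >= 2) {
    for (k in 2:K) {
      for (i in k:m) {
        cand <- (k - 1):(i - 1)                  # last bin of the (k-1)-segment prefix
        vals <- L[k - 1, cand] + l_table[cbind(cand + 1L, i)]
        best <- which.max(vals)                  # first max = smallest i'
        L[k, i] <- vals[best]
        TT[k, i] <- cand[best]
      }
    }
  }
  ks <- seq_len(K)
  beta <- L - lchoose(m, ks - 1) - (ks - 1) * (params$kappa1 - params$kappa2)
  structure(list(l = l_table, L = L, beta = beta, T = TT, K = K, m = m),
            class = "dp_tables")
}

#' Backtrack the optimal turning points
#'
#' Selects the segment count k* maximising `beta[k, m]` (smallest k on
#' ties) and walks the backpointer table to recover the turning points.
#'
#' @param tables a `dp_tables` object from [dp_fill()].
#' @param chrom chromosome name to stamp on the result.
#' @param bins optional bin annotations for coordinate export.
#' @return A [segmentation()].
#' @export
backtrack <- function(tables, chrom = "chr", bins = NULL) {
  stopifnot(inherits(tables, "dp_tables"))
  m <- tables$m
  bvec <- tables$beta[, m]
  kstar <- which.max(bvec)
  tps <- integer(0)
  k <- kstar
  i <- m
  while (k >= 2) {
    t <- tables$T[k, i]
    tps <- c(t, tps)
    i <- t
    k <- k - 1L
  }
  segmentation(chrom, tps, m, mbic = bvec[kstar], loglik = tables$L[kstar, m],
               bins = bins)
}

#' Segment one chromosome
#'
#' Composition of [build_l_table()], [dp_fill()] and [backtrack()] on a
#' single-chromosome pair of matrices.
#'
#' @param raw,norm matched `read_depth_matrix` objects covering exactly one
#'   chromosome.
#' @param params an [mbic_params()]; `NULL` (default) uses
#'   [default_mbic_params()] scaled to the cell count.
#' @param K maximum segment count; default `min(m, 15)`.
#' @return A [segmentation()].
#' @export
segment_chromosome <- function(raw, norm, params = NULL, K = NULL) {
  if (is.null(params)) params <- default_mbic_params(ncol(raw$values))
  chroms <- chromosomes(raw)
  if (length(chroms) != 1) {
    stop("segment_chromosome expects a single chromosome; got ",
         paste(chroms, collapse = ", "), "; use segment_genome()", call. = FALSE)
  }
  l <- build_l_table(raw, norm, params)
  tables <- dp_fill(l, params, K)
  backtrack(tables, chrom = chroms, bins = raw$bins)
}

#' Segment every chromosome independently
#'
#' @param raw,norm matched multi-chromosome matrices.
#' @param params an [mbic_params()]; `NULL` uses [default_mbic_params()].
#' @param K maximum segment count per chromosome.
#' @return Named list of [segmentation()] objects, in bin-annotation order.
#' @export
segment_genome <- function(raw, norm, params = NULL, K = NULL) {
  if (is.null(params)) params <- default_mbic_params(ncol(raw$values))
  chroms <- chromosomes(raw)
  res <- lapply(chroms, function(chr) {
    segment_chromosome(slice_chromosome(raw, chr), slice_chromosome(norm, chr),
                       params, K)
  })
  names(res) <- chroms
  res
}

#' Export segments as a table
#'
#' @param segs a [segmentation()] or list of them.
#' @return data.frame with columns chrom, segment_index, start_bin, end_bin,
#'   start_bp, end_bp, mbic_of_chrom (bin indices 1-based inclusive).
#' @export
segments_table <- function(segs) {
  if (inherits(segs, "segmentation")) segs <- list(segs)
  do.call(rbind, lapply(segs, function(s) {
    bounds <- segment_bounds(s)
    data.frame(chrom = s$chrom, segment_index = seq_len(nrow(bounds)),
               start_bin = bounds[, "start"], end_bin = bounds[, "end"],
               start_bp = if (!is.null(s$bins)) s$bins$start[bounds[, "start"]] else NA,
               end_bp = if (!is.null(s$bins)) s$bins$end[bounds[, "end"]] else NA,
               mbic_of_chrom = s$mbic)
  }))
}

#' Export turning points as a BED track
#'
#' Each turning point becomes one BED line covering the last bin of its
#' left segment (0-based half-open on disk).
#'
#' @param segs a [segmentation()] or list of them (with bin annotations).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_turning_points_bed <- function(segs, path) {
  if (inherits(segs, "segmentation")) segs <- list(segs)
  rows <- do.call(rbind, lapply(segs, function(s) {
    if (!length(s$turning_points)) return(NULL)
    if (is.null(s$bins)) stop("segmentation lacks bin annotations", call. = FALSE)
    data.frame(chrom = s$chrom,
               start = format(s$bins$start[s$turning_points] - 1,
                              scientific = FALSE, trim = TRUE),
               end = format(s$bins$end[s$turning_points],
                            scientific = FALSE, trim = TRUE),
               name = paste0("tp_", s$chrom, "_", s$turning_points))
  }))
  if (is.null(rows)) {
    writeLines(character(0), path)
  } else {
    data.table::fwrite(rows, path, sep = "\t", col.names = FALSE)
  }
  invisible(path)
}
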