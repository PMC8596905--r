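#' Parameters of the simplified mBIC objective
#'
#' The segmentation objective is a simplified modified Bayesian information
#' criterion: the generalized log-likelihood ratio of the segmented model
#' against the unsegmented diploid null, minus a combinatorial penalty
#' \eqn{\log \binom{m}{\ell-1}} on the number of segments and a linear term
#' \eqn{(\ell-1)(\kappa_1-\kappa_2)}.
#'
#' @param kappa1,kappa2 penalty constants; only their difference enters the
#'   objective. Defaults 1 and 0.
#' @param cn_cap maximum reportable integer copy number (reported calls are
#'   clamped to `[0, cn_cap]`; the likelihood always uses the uncapped
#'   rounded value).
#' @param log_floor effective copy number substituted inside the log term
#'   when the rounded copy number is 0, keeping homozygous deletions
#'   finitely but strongly penalised.
#' @return A list of class `mbic_params`.
#' @export
mbic_params <- function(kappa1 = 1, kappa2 = 0, cn_cap = 10L, log_floor = 1e-4) {
  stopifnot(is.finite(kappa1), is.finite(kappa2), cn_cap >= 2, log_floor > 0)
  structure(list(kappa1 = kappa1, kappa2 = kappa2,
                 cn_cap = as.integer(cn_cap), log_floor = log_floor),
            class = "mbic_params")
}

#' Default objective parameters scaled to the data
#'
#' The likelihood side of the objective grows with the number of cells:
#' every extra changepoint frees one copy-number level per cell, and under
#' count noise that slack is worth a fraction of a nat of spurious
#' likelihood per aberrant cell. The default changepoint cost therefore
#' scales with the cell count: \eqn{\kappa_1 - \kappa_2 = n \log 2} -- one
#' bit per cell per changepoint, a minimum-description-length reading of
#' "did this cell's copy number change here?". The high-level segmentation
#' functions use this default when no explicit [mbic_params()] is given.
#'
#' @param n_cells number of cells in the matrix to be segmented.
#' @return An [mbic_params()] with `kappa1 = n_cells * log(2)`, `kappa2 = 0`.
#' @export
default_mbic_params <- function(n_cells) {
  mbic_params(kappa1 = n_cells * log(2), kappa2 = 0)
}

#' Per-cell segment means of raw and normalised depth
#'
#' For a candidate segment (inclusive bin range), computes for every cell j
#' the arithmetic means \eqn{X_j} (raw) and \eqn{\hat X_j} (normalised) over
#' the segment's bins.
#'
#' @param raw,norm matched raw and normalised `read_depth_matrix` objects
#'   (same shape).
#' @param start_bin,end_bin 1-based inclusive bin indices.
#' @return A list of class `segment_stat` with `start_bin`, `end_bin`,
#'   `n_bins`, `X_row`, `Xhat_row`.
#' @export
segment_stat <- function(raw, norm, start_bin, end_bin) {
  stopifnot(inherits(raw, "read_depth_matrix"), inherits(norm, "read_depth_matrix"))
  m <- nrow(raw$values)
  if (!identical(dim(raw$values), dim(norm$values))) {
    stop("raw and normalized matrices differ in shape", call. = FALSE)
  }
  if (start_bin < 1 || end_bin > m || start_bin > end_bin) {
    stop("invalid bin range [", start_bin, ", ", end_bin, "] for ", m, " bins",
         call. = FALSE)
  }
  idx <- start_bin:end_bin
  structure(list(start_bin = start_bin, end_bin = end_bin,
                 n_bins = length(idx),
                 X_row = colMeans(raw$values[idx, , drop = FALSE]),
                 Xhat_row = colMeans(norm$values[idx, , drop = FALSE])),
            class = "segment_stat")
}

#' Rounded integer copy number
#'
#' Copy number is the ratio of observed to expected-diploid depth scaled to
#' ploidy 2, \eqn{2X/\hat X}, rounded half-away-from-zero (so 2.5 rounds to
#' 3). Optionally clamped to `[0, cn_cap]`.
#'
#' @param X,Xhat numeric vectors of per-cell segment means (raw and
#'   normalised); `Xhat` must be strictly positive.
#' @param cn_cap optional clamp; `NULL` (default) leaves values uncapped as
#'   required inside the likelihood.
#' @return Integer vector of copy numbers.
#' @export
rounded_cn <- function(X, Xhat, cn_cap = NULL) {
  if (any(Xhat <= 0)) {
    stop("normalized segment mean must be strictly positive", call. = FALSE)
  }
  cn <- floor(2 * X / Xhat + 0.5)  # half-away-from-zero for non-negative input
  if (!is.null(cn_cap)) cn <- pmin(pmax(cn, 0), cn_cap)
  as.integer(cn)
}

#' Generalized log-likelihood ratio of one segment
#'
#' The contribution of segment s with per-cell means \eqn{X_j, \hat X_j} and
#' rounded copy number \eqn{c_j} is the Poisson log-likelihood ratio of the
#' copy-number model against the diploid null, summed over the segment's
#' bins and cells:
#' \deqn{|s| \sum_j \hat X_j (1 - c_j/2) + X_j \log(c_j/2).}
#' A purely diploid cell (c = 2) contributes exactly 0. When \eqn{c_j = 0}
#' the log argument is replaced by `log_floor / 2`.
#'
#' @param stat a [segment_stat()].
#' @param params an [mbic_params()].
#' @return The segment's log-likelihood ratio (scalar).
#' @export
segment_loglik <- function(stat, params = mbic_params()) {
  stopifnot(inherits(stat, "segment_stat"))
  X <- stat$X_row
  Xhat <- stat$Xhat_row
  cn <- floor(2 * X / Xhat + 0.5)
  log_arg <- ifelse(cn == 0, params$log_floor, cn)
  stat$n_bins * sum(Xhat * (1 - cn / 2) + X * log(log_arg / 2))
}

#' Model-complexity penalty of the simplified mBIC
#'
#' @param m number of bins on the chromosome.
#' @param ell number of segments (`1 <= ell <= m`).
#' @param params an [mbic_params()].
#' @return \eqn{-\log\binom{m}{\ell-1} - (\ell-1)(\kappa_1-\kappa_2)}.
#' @export
mbic_penalty <- function(m, ell, params = mbic_params()) {
  if (ell < 1 || ell > m) stop("need 1 <= ell <= m", call. = FALSE)
  -lchoose(m, ell - 1) - (ell - 1) * (params$kappa1 - params$kappa2)
}

#' Segmentation objects
#'
#' A `segmentation` records, for one chromosome of m bins, the sorted
#' turning points (1-based index of the last bin of each non-final segment),
#' the segment count, the maximised objective `mbic` and its likelihood part
#' `loglik`.
#'
#' @param chrom chromosome name.
#' @param turning_points strictly increasing integer vector, all `< m`.
#' @param m number of bins.
#' @param mbic,loglik objective value and its log-likelihood-ratio part.
#' @param bins optional bin annotation data.frame for coordinate export.
#' @return A list of class `segmentation`.
#' @export
segmentation <- function(chrom, turning_points, m, mbic = NA_real_,
                         loglik = NA_real_, bins = NULL) {
  turning_points <- as.integer(turning_points)
  if (length(turning_points)) {
    if (is.unsorted(turning_points, strictly = TRUE) ||
        any(turning_points < 1) || any(turning_points >= m)) {
      stop("turning points must be strictly increasing and in [1, m-1]",
           call. = FALSE)
    }
  }
  structure(list(chrom = chrom, turning_points = turning_points,
                 n_segments = length(turning_points) + 1L, m = as.integer(m),
                 mbic = mbic, loglik = loglik, bins = bins),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %s: %d bins, %d segment(s), mBIC = %.4f\n",
              x$chrom, x$m, x$n_segments, x$mbic))
  if (length(x$turning_points)) {
    cat("  turning points (last bin of left segment):",
        paste(x$turning_points, collapse = ", "), "\n")
  }
  invisible(x)
}

segment_bounds <- function(seg) {
  starts <- c(1L, seg$turning_points + 1L)
  ends <- c(seg$turning_points, seg$m)
  cbind(start = starts, end = ends)
}

#' Score a segmentation by the simplified mBIC
#'
#' Evaluates the objective explicitly (sum of per-segment log-likelihood
#' ratios plus the complexity penalty) for an arbitrary segmentation. This
#' is the reference scorer used to validate the dynamic-programming engine.
#'
#' @param raw,norm matched single-chromosome matrices.
#' @param seg a [segmentation()].
#' @param params an [mbic_params()].
#' @return The objective value \eqn{\beta(S)}.
#' @export
score_segmentation <- function(raw, norm, seg, params = mbic_params()) {
  stopifnot(inherits(seg, "segmentation"))
  m <- nrow(raw$values)
  if (seg$m != m) stop("segmentation is for ", seg$m, " bins, matrix has ", m,
                       call. = FALSE)
  bounds <- segment_bounds(seg)
  ll <- sum(vapply(seq_len(nrow(bounds)), function(k) {
    segment_loglik(segment_stat(raw, norm, bounds[k, 1], bounds[k, 2]), params)
  }, numeric(1)))
  ll + mbic_penalty(m, seg$n_segments, params)
}
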