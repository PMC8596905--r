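#' Turning-point precision and recall
#'
#' Matches each found turning point to an as-yet-unmatched planted one
#' within `tolerance` bins (greedy, left to right). Precision is the matched
#' fraction of found points, recall the matched fraction of planted points;
#' an empty side is scored 1 vacuously.
#'
#' @param found,planted sorted integer vectors of turning-point bin indices.
#' @param tolerance maximum |found - planted| counted as a match (default 0,
#'   exact).
#' @return Named numeric vector `c(precision, recall)`.
#' @export
turning_point_accuracy <- function(found, planted, tolerance = 0) {
  found <- sort(as.integer(found))
  planted <- sort(as.integer(planted))
  used <- logical(length(planted))
  matched <- 0L
  for (f in found) {
    ok <- which(!used & abs(planted - f) <= tolerance)
    if (length(ok)) {
      used[ok[1]] <- TRUE
      matched <- matched + 1L
    }
  }
  precision <- if (length(found)) matched / length(found) else 1
  recall <- if (length(planted)) matched / length(planted) else 1
  c(precision = precision, recall = recall)
}

#' Pearson correlation and RMSE between copy-number profiles
#'
#' @param est,ref numeric vectors over shared bins (pairs with `NA` in
#'   either are dropped).
#' @return List with `pearson` (NA with `constant = TRUE` if either vector
#'   is constant), `rmse`, `n` (bins compared), `constant` flag.
#' @export
cnv_agreement <- function(est, ref) {
  if (length(est) != length(ref)) {
    stop("profiles differ in length (", length(est), " vs ", length(ref), ")",
         call. = FALSE)
  }
  keep <- !(is.na(est) | is.na(ref))
  est <- est[keep]
  ref <- ref[keep]
  if (!length(est)) stop("no shared bins to compare", call. = FALSE)
  constant <- stats::sd(est) == 0 || stats::sd(ref) == 0
  pearson <- if (constant) NA_real_ else stats::cor(est, ref)
  list(pearson = pearson, rmse = sqrt(mean((est - ref)^2)),
       n = length(est), constant = constant)
}

#' Hierarchical clustering of cells on their copy-number profiles
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage via
#' `ward.D2`) of the cells of a copy-number matrix, cut to `k` clusters.
#' Deterministic for fixed input.
#'
#' @param cnv a `cnv_matrix` or a bins x cells numeric matrix.
#' @param k number of clusters, `1 <= k <= n`.
#' @param method linkage method passed to [stats::hclust()].
#' @return Named integer vector of cluster labels, one per cell.
#' @export
cluster_cells <- function(cnv, k, method = "ward.D2") {
  values <- if (inherits(cnv, "cnv_matrix")) cnv$values else as.matrix(cnv)
  n <- ncol(values)
  if (k < 1 || k > n) stop("need 1 <= k <= ", n, " cells (k = ", k, ")",
                           call. = FALSE)
  hc <- stats::hclust(stats::dist(t(values)), method = method)
  stats::cutree(hc, k = k)
}

#' External clustering agreement indices
#'
#' Adjusted Rand index, normalized mutual information (arithmetic-mean
#' normalisation) and the pair-counting Jaccard index between two labelings
#' of the same cells. Values near 0 indicate random assignment, 1 perfect
#' agreement. When both labelings are single-cluster (zero entropy) NMI is
#' defined as 1.
#'
#' @param labels,truth_labels vectors of equal length (any label type).
#' @return Named numeric vector `c(ari, nmi, ji)`.
#' @export
clustering_indices <- function(labels, truth_labels) {
  if (length(labels) != length(truth_labels)) {
    stop("label vectors differ in length (", length(labels), " vs ",
         length(truth_labels), ")", call. = FALSE)
  }
  tab <- table(labels, truth_labels)
  N <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)

  # ARI from the pair-counting contingency formula
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(a, 2))
  sum_b <- sum(choose(b, 2))
  tot <- choose(N, 2)
  expected <- sum_a * sum_b / tot
  max_idx <- (sum_a + sum_b) / 2
  ari <- if (max_idx == expected) 1 else (sum_ij - expected) / (max_idx - expected)

  # NMI, arithmetic-mean normalisation
  p <- tab / N
  pa <- a / N
  pb <- b / N
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  nmi <- if (ha == 0 && hb == 0) 1 else if (mi == 0 && min(ha, hb) == 0) 0 else
    mi / ((ha + hb) / 2)

  # pair-counting Jaccard: co-clustered pairs in both / in either
  ji <- if (sum_a + sum_b - sum_ij == 0) 1 else sum_ij / (sum_a + sum_b - sum_ij)
  c(ari = ari, nmi = min(max(nmi, 0), 1), ji = ji)
}

#' Per-cell Gini coefficient of a coverage profile
#'
#' Inequality of a cell's bin-level profile, computed on the sum-normalised
#' vector via the mean-absolute-difference definition. A uniform profile
#' has Gini 0; concentrating all reads in one of B bins approaches
#' (B-1)/B. Invariant to uniform scaling of the vector.
#'
#' @param x non-negative numeric vector (one cell's bin profile).
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini_coefficient <- function(x) {
  if (any(x < 0)) stop("profile must be non-negative", call. = FALSE)
  if (sum(x) == 0) stop("all-zero profile: Gini undefined", call. = FALSE)
  x <- sort(x / sum(x))
  B <- length(x)
  2 * sum(seq_len(B) * x) / B - (B + 1) / B
}

#' Flag putative tumour cells by coverage Gini coefficient
#'
#' Aneuploid cells have unequal coverage across bins; cells whose Gini
#' coefficient exceeds `cutoff` (default 0.12) are flagged `"tumor"`, the
#' rest `"normal"`.
#'
#' @param x a `read_depth_matrix`, `cnv_matrix`, or bins x cells matrix.
#' @param cutoff Gini threshold.
#' @return List with `gini` (named numeric per cell) and `flag` (named
#'   character, `"tumor"`/`"normal"`).
#' @export
gini_flag <- function(x, cutoff = 0.12) {
  values <- if (inherits(x, c("read_depth_matrix", "cnv_matrix"))) x$values else
    as.matrix(x)
  g <- apply(values, 2, gini_coefficient)
  list(gini = g, flag = ifelse(g > cutoff, "tumor", "normal"))
}

#' Full evaluation report against a known truth
#'
#' Convenience wrapper bundling turning-point accuracy, profile agreement
#' and clustering indices into one flat list.
#'
#' @param found,planted turning-point vectors.
#' @param est_profile,ref_profile optional profiles for [cnv_agreement()].
#' @param labels,truth_labels optional labelings for [clustering_indices()].
#' @param tolerance turning-point matching tolerance in bins.
#' @return Flat named list (class `eval_report`).
#' @export
eval_report <- function(found, planted, est_profile = NULL, ref_profile = NULL,
                        labels = NULL, truth_labels = NULL, tolerance = 0) {
  acc <- turning_point_accuracy(found, planted, tolerance)
  out <- list(tp_precision = unname(acc["precision"]),
              tp_recall = unname(acc["recall"]))
  if (!is.null(est_profile) && !is.null(ref_profile)) {
    agr <- cnv_agreement(est_profile, ref_profile)
    out$pearson <- agr$pearson
    out$rmse <- agr$rmse
  }
  if (!is.null(labels) && !is.null(truth_labels)) {
    ci <- clustering_indices(labels, truth_labels)
    out$ari <- unname(ci["ari"])
    out$nmi <- unname(ci["nmi"])
    out$ji <- unname(ci["ji"])
  }
  structure(out, class = c("eval_report", "list"))
}
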