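# Shared fixtures: small matrices built in code, plus the brute-force
# enumeration scorer used as the independent oracle for the DP engine.

make_bins <- function(m, chrom = "chr1", width = 10) {
  data.frame(chrom = chrom,
             start = seq(1, by = width, length.out = m),
             end = seq(width, by = width, length.out = m))
}

# matched raw/norm pair with given per-cell copy-number matrix and flat depth
make_pair <- function(cn, depth = 100, chrom = "chr1") {
  m <- nrow(cn)
  n <- ncol(cn)
  raw <- read_depth_matrix((cn / 2) * depth, make_bins(m, chrom),
                           sprintf("c%02d", 1:n), "raw")
  norm <- read_depth_matrix(matrix(depth, m, n), make_bins(m, chrom),
                            sprintf("c%02d", 1:n), "normalized")
  list(raw = raw, norm = norm)
}

random_pair <- function(m, n, depth = 20, chrom = "chr1") {
  raw <- read_depth_matrix(matrix(rpois(m * n, depth), m, n), make_bins(m, chrom),
                           sprintf("c%02d", 1:n), "raw")
  norm <- read_depth_matrix(matrix(rgamma(m * n, depth, 1), m, n),
                            make_bins(m, chrom), sprintf("c%02d", 1:n),
                            "normalized")
  list(raw = raw, norm = norm)
}

# independent scorer: naive per-segment log-likelihoods (no prefix sums) and
# explicit enumeration of all segmentations with k segments
naive_ll_table <- function(raw, norm, params) {
  m <- nrow(raw$values)
  ll <- matrix(NA_real_, m, m)
  for (i in 1:m) for (j in i:m) {
    ll[i, j] <- segment_loglik(segment_stat(raw, norm, i, j), params)
  }
  ll
}

enumerate_best_beta <- function(raw, norm, params, K) {
  m <- nrow(raw$values)
  ll <- naive_ll_table(raw, norm, params)
  vapply(seq_len(K), function(k) {
    if (k == 1) return(ll[1, m] + mbic_penalty(m, 1, params))
    combos <- utils::combn(m - 1, k - 1)
    best <- -Inf
    for (ci in seq_len(ncol(combos))) {
      tp <- combos[, ci]
      bnd <- cbind(c(1, tp + 1), c(tp, m))
      v <- sum(ll[bnd]) + mbic_penalty(m, k, params)
      if (v > best) best <- v
    }
    best
  }, numeric(1))
}
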