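#' Simulation parameters for clone-structured count data
#'
#' Defaults reproduce the reference in-silico design: 100 cells and 70 bins
#' on one chromosome, a large normal (diploid) population plus 4 tumour
#' subclones sharing 7 segments (6 turning points), and 10% random noise on
#' the expected depth.
#'
#' @param n_cells,n_bins matrix dimensions.
#' @param n_clones number of tumour subclones (excluding normals).
#' @param normal_fraction fraction of cells that are diploid normals.
#' @param n_segments number of planted segments shared by all clones.
#' @param noise_rate noise level in `[0, 1]`; see `noise_model`.
#' @param noise_model `"multiplicative"` (default): every entry's expected
#'   depth is scaled by `1 + e`, `e ~ U(-noise_rate, noise_rate)` —
#'   measurement noise that leaves the planted boundaries the only true
#'   ones. `"replace"`: `noise_rate` of entries have their copy number
#'   replaced by a random different value in `{0..cn_cap}` — this plants
#'   genuine single-cell, single-bin CNVs which an optimal segmenter will
#'   legitimately fence off with extra boundaries.
#' @param mean_depth_per_bin expected reads per bin for a diploid cell of
#'   average library size.
#' @param dispersion negative-binomial overdispersion (variance
#'   \eqn{\mu + \phi\mu^2}); used when `count_model = "nbinom"`.
#' @param count_model `"poisson"` (default), `"nbinom"`, or
#'   `"deterministic"` (counts = rounded expectation, the zero-variance
#'   limit used for exact round-trip checks).
#' @param cn_states integer copy numbers available to aberrant clone
#'   segments (2 = diploid is always available for non-aberrant segments).
#' @param cn_cap maximum copy number used by `"replace"` noise.
#' @param chrom chromosome name stamped on the bins.
#' @param bin_width bin width in bp (annotation only; the algorithm sees
#'   bin counts, not widths).
#' @param seed integer seed; every generated object is a deterministic
#'   function of the parameters.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_cells = 100L, n_bins = 70L, n_clones = 4L,
                       normal_fraction = 0.5, n_segments = 7L,
                       noise_rate = 0.1,
                       noise_model = c("multiplicative", "replace"),
                       mean_depth_per_bin = 200, dispersion = 0,
                       count_model = c("poisson", "nbinom", "deterministic"),
                       cn_states = c(1L, 3L, 4L, 5L), cn_cap = 10L,
                       chrom = "chr22", bin_width = 5e5, seed = 1L) {
  noise_model <- match.arg(noise_model)
  count_model <- match.arg(count_model)
  stopifnot(n_cells >= 1, n_bins >= 1, n_clones >= 0,
            normal_fraction >= 0, normal_fraction <= 1,
            noise_rate >= 0, noise_rate <= 1,
            mean_depth_per_bin > 0, dispersion >= 0, bin_width >= 1)
  if (n_segments > n_bins) {
    stop("n_segments (", n_segments, ") cannot exceed n_bins (", n_bins, ")",
         call. = FALSE)
  }
  if (count_model == "nbinom" && dispersion <= 0) {
    stop("count_model = 'nbinom' needs dispersion > 0", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells), n_bins = as.integer(n_bins),
                 n_clones = as.integer(n_clones),
                 normal_fraction = normal_fraction,
                 n_segments = as.integer(n_segments),
                 noise_rate = noise_rate, noise_model = noise_model,
                 mean_depth_per_bin = mean_depth_per_bin,
                 dispersion = dispersion, count_model = count_model,
                 cn_states = as.integer(cn_states), cn_cap = as.integer(cn_cap),
                 chrom = chrom, bin_width = bin_width, seed = as.integer(seed)),
            class = "sim_params")
}

# segment lengths: a guaranteed minimum plus a random multinomial remainder;
# clone-level CNAs span megabases, so planted segments are >= 5 bins when room allows
planted_segment_lengths <- function(m, ell) {
  min_len <- max(1L, min(5L, m %/% ell))
  extra <- stats::rmultinom(1, m - ell * min_len, rep(1, ell))[, 1]
  min_len + extra
}

#' Generate a ground-truth clone CNV profile
#'
#' Normal cells are diploid everywhere. Each tumour clone receives a
#' piecewise-constant integer profile over the shared planted segments:
#' aberrant segments draw from `cn_states`, the rest stay at 2; every clone
#' carries at least one aberration, and every planted boundary separates
#' different copy numbers for at least one clone (so all turning points are
#' recoverable in principle).
#'
#' @param params a [sim_params()].
#' @return Object of class `synthetic_truth`: list with integer `cnv`
#'   (bins x cells), `clone_of` (named character vector), `turning_points`,
#'   `profiles` (clones x segments), `segment_lengths`, `bins`, `params`.
#' @export
generate_truth <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  m <- params$n_bins
  n <- params$n_cells
  ell <- params$n_segments
  lengths <- planted_segment_lengths(m, ell)
  tps <- if (ell > 1) cumsum(lengths)[seq_len(ell - 1)] else integer(0)

  n_normal <- if (params$n_clones == 0) n else round(params$normal_fraction * n)
  n_tumor <- n - n_normal
  clone_of <- c(rep("normal", n_normal),
                if (n_tumor > 0 && params$n_clones > 0)
                  paste0("clone", rep(seq_len(params$n_clones),
                                      length.out = n_tumor)))
  cell_ids <- sprintf("cell_%03d", seq_len(n))
  names(clone_of) <- cell_ids

  nc <- params$n_clones
  profiles <- matrix(2L, max(nc, 0L), ell)
  if (nc > 0 && n_tumor > 0) {
    states <- setdiff(params$cn_states, 2L)
    aberrant <- matrix(stats::runif(nc * ell) < 0.6, nc, ell)
    profiles[aberrant] <- sample(states, sum(aberrant), replace = TRUE)
    # every clone must be aberrant somewhere
    for (cl in seq_len(nc)) {
      if (all(profiles[cl, ] == 2L)) {
        profiles[cl, sample.int(ell, 1)] <- sample(states, 1)
      }
    }
    # every boundary must separate different CN for at least one clone
    if (ell > 1) {
      for (b in seq_len(ell - 1)) {
        if (all(profiles[, b] == profiles[, b + 1])) {
          cl <- ((b - 1) %% nc) + 1
          choices <- setdiff(c(2L, states), profiles[cl, b])
          profiles[cl, b + 1] <- sample(choices, 1)
        }
      }
    }
  }

  cnv <- matrix(2L, m, n)
  seg_of_bin <- rep(seq_len(ell), times = lengths)
  tumor_idx <- which(clone_of != "normal")
  for (j in tumor_idx) {
    cl <- as.integer(sub("clone", "", clone_of[j]))
    cnv[, j] <- profiles[cl, seg_of_bin]
  }
  colnames(cnv) <- cell_ids
  bins <- data.frame(chrom = params$chrom,
                     start = (seq_len(m) - 1) * params$bin_width + 1,
                     end = seq_len(m) * params$bin_width)
  structure(list(cnv = cnv, clone_of = clone_of, turning_points = tps,
                 profiles = profiles, segment_lengths = lengths, bins = bins,
                 params = params),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d bins x %d cells, %d clone(s), %d planted segment(s)\n",
              nrow(x$cnv), ncol(x$cnv), nrow(x$profiles),
              length(x$turning_points) + 1L))
  invisible(x)
}

#' Simulate matched raw and normalised count matrices from a truth
#'
#' Each cell j draws a log-normal library-size factor `s_j`; the expected
#' raw count of entry (i, j) is `(cn_ij / 2) * mean_depth_per_bin * s_j`,
#' perturbed by the configured noise, and counts are drawn from the
#' configured model. The normalised matrix is the matching noiseless
#' diploid baseline `mean_depth_per_bin * s_j`, so `E[2 * raw / norm]`
#' equals the planted copy number entry-wise.
#'
#' @param truth a [generate_truth()] result.
#' @return List with elements `raw` and `norm` ([read_depth_matrix()]s).
#' @export
simulate_counts <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- truth$params
  set.seed(p$seed + 1L)
  m <- p$n_bins
  n <- p$n_cells
  sdlog <- 0.1
  s <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  muhat <- matrix(p$mean_depth_per_bin, m, n) *
    matrix(s, m, n, byrow = TRUE)

  cn <- truth$cnv
  if (p$noise_model == "replace" && p$noise_rate > 0) {
    k <- round(p$noise_rate * m * n)
    idx <- sample.int(m * n, k)
    cn[idx] <- vapply(cn[idx], function(v) {
      sample(setdiff(0:p$cn_cap, v), 1)
    }, integer(1))
  }
  lambda <- (cn / 2) * muhat
  if (p$noise_model == "multiplicative" && p$noise_rate > 0) {
    lambda <- lambda * (1 + stats::runif(m * n, -p$noise_rate, p$noise_rate))
  }
  raw_vals <- switch(p$count_model,
    poisson = matrix(stats::rpois(m * n, lambda), m, n),
    nbinom = matrix(stats::rnbinom(m * n, mu = lambda, size = 1 / p$dispersion),
                    m, n),
    deterministic = round(lambda))
  cell_ids <- colnames(truth$cnv)
  list(raw = read_depth_matrix(raw_vals, truth$bins, cell_ids, "raw"),
       norm = read_depth_matrix(muhat, truth$bins, cell_ids, "normalized"))
}

#' Scenario grid along one simulation axis
#'
#' Produces one truth per value of the chosen axis, keeping all other
#' parameters at `base` and deriving each scenario's seed deterministically
#' from the base seed.
#'
#' @param base a [sim_params()].
#' @param axis one of `"normal_fraction"`, `"n_clones"`, `"n_segments"`.
#' @param values vector of axis values (non-empty).
#' @return List of lists, each with elements `params` and `truth`.
#' @export
scenario_grid <- function(base,
                          axis = c("normal_fraction", "n_clones", "n_segments"),
                          values) {
  stopifnot(inherits(base, "sim_params"))
  axis <- match.arg(axis)
  if (!length(values)) stop("values must be non-empty", call. = FALSE)
  lapply(seq_along(values), function(i) {
    args <- unclass(base)
    args[[axis]] <- values[[i]]
    args$seed <- base$seed + 1000L * i
    p <- do.call(sim_params, args)
    list(params = p, truth = generate_truth(p))
  })
}

#' Write a synthetic truth (and optionally its counts) to disk
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created if needed).
#' @param counts optional result of [simulate_counts()] to write alongside.
#' @return Named character vector of the files written, invisibly.
#' @export
write_truth <- function(truth, dir, counts = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(truth_cnv = file.path(dir, "truth_cnv.tsv"),
             clones = file.path(dir, "clones.tsv"),
             turning_points = file.path(dir, "truth_turning_points.tsv"),
             bins = file.path(dir, "bins.bed"))
  d <- as.data.frame(truth$cnv)
  data.table::fwrite(d, files["truth_cnv"], sep = "\t")
  data.table::fwrite(data.frame(cell_id = names(truth$clone_of),
                                clone = unname(truth$clone_of)),
                     files["clones"], sep = "\t")
  data.table::fwrite(data.frame(turning_point_bin = truth$turning_points),
                     files["turning_points"], sep = "\t")
  write_bins(truth$bins, files["bins"])
  if (!is.null(counts)) {
    files <- c(files, raw = file.path(dir, "raw.tsv"),
               norm = file.path(dir, "norm.tsv"))
    write_matrix(counts$raw, files["raw"])
    write_matrix(counts$norm, files["norm"])
  }
  invisible(files)
}
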