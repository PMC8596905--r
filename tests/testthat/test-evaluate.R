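test_that("turning-point matching computes precision and recall", {
  expect_equal(turning_point_accuracy(c(3, 9), c(3, 9)),
               c(precision = 1, recall = 1))
  # one extra call over six true points
  expect_equal(turning_point_accuracy(1:7 * 10, 1:6 * 10),
               c(precision = 6 / 7, recall = 1))
  # off-by-one miss at zero tolerance, rescued at tolerance 1
  expect_equal(turning_point_accuracy(c(3, 9), c(3, 10)),
               c(precision = 0.5, recall = 0.5))
  expect_equal(turning_point_accuracy(c(3, 9), c(3, 10), tolerance = 1),
               c(precision = 1, recall = 1))
  # a planted point can only be matched once
  expect_equal(turning_point_accuracy(c(5, 5), 5),
               c(precision = 0.5, recall = 1))
  expect_equal(turning_point_accuracy(integer(0), integer(0)),
               c(precision = 1, recall = 1))
  expect_equal(turning_point_accuracy(integer(0), c(4)),
               c(precision = 1, recall = 0))
})

test_that("profile agreement matches the textbook formulas", {
  expect_equal(cnv_agreement(c(2, 3, 4), c(2, 3, 4))[c("pearson", "rmse")],
               list(pearson = 1, rmse = 0))
  sh <- cnv_agreement(c(2, 3, 4), c(3, 4, 5))
  expect_equal(sh$pearson, 1)
  expect_equal(sh$rmse, 1)

  set.seed(51)
  a <- rpois(10, 5)
  b <- rpois(10, 5)
  got <- cnv_agreement(a, b)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$pearson, r_hand)
  expect_equal(got$rmse, sqrt(sum((a - b)^2) / 10))

  const <- cnv_agreement(rep(2, 5), c(1, 2, 3, 2, 1))
  expect_true(const$constant)
  expect_true(is.na(const$pearson))
  expect_false(is.na(const$rmse))
  expect_error(cnv_agreement(1:3, 1:4), "differ in length")

  # Pearson is scale-invariant, RMSE is not
  expect_equal(cnv_agreement(2 * a + 1, b)$pearson, got$pearson)
  expect_false(isTRUE(all.equal(cnv_agreement(2 * a + 1, b)$rmse, got$rmse)))
})

test_that("hierarchical clustering separates planted clones deterministically", {
  cn <- matrix(2L, 20, 12)
  cn[1:10, 1:6] <- 5L
  pair <- make_pair(cn)
  cnv <- call_copy_number(pair$raw, pair$norm,
                          segment_chromosome(pair$raw, pair$norm))
  lab <- cluster_cells(cnv, 2)
  expect_length(unique(lab[1:6]), 1)
  expect_length(unique(lab[7:12]), 1)
  expect_false(lab[1] == lab[7])

  expect_length(unique(cluster_cells(cnv, 12)), 12)
  expect_identical(cluster_cells(cnv, 3), cluster_cells(cnv, 3))
  expect_error(cluster_cells(cnv, 13), "cells")
})

test_that("clustering indices agree with pair-counting by hand and with
           reference implementations", {
  expect_equal(clustering_indices(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               c(ari = 1, nmi = 1, ji = 1))
  expect_equal(clustering_indices(rep(1, 6), rep("x", 6)),
               c(ari = 1, nmi = 1, ji = 1))

  # hand-counted 8-item example: labels {1,1,1,1,2,2,2,2}, truth {a,a,a,b,b,b,c,c}
  lab <- c(1, 1, 1, 1, 2, 2, 2, 2)
  tru <- c("a", "a", "a", "b", "b", "b", "c", "c")
  # pairs co-clustered in both: C(3,2) + C(2,2) + C(2,2) = 5
  # pairs co-clustered in labels: 2*C(4,2) = 12; in truth: 3+3+1 = 7
  got <- clustering_indices(lab, tru)
  expect_equal(got[["ji"]], 5 / (12 + 7 - 5))
  n_pairs <- choose(8, 2)
  expected <- 12 * 7 / n_pairs
  expect_equal(got[["ari"]], (5 - expected) / ((12 + 7) / 2 - expected))

  skip_if_not_installed("mclust")
  skip_if_not_installed("igraph")
  set.seed(53)
  for (rep in 1:5) {
    l1 <- sample(1:3, 12, replace = TRUE)
    l2 <- sample(1:4, 12, replace = TRUE)
    ours <- clustering_indices(l1, l2)
    expect_equal(ours[["ari"]], mclust::adjustedRandIndex(l1, l2))
    expect_equal(ours[["nmi"]], igraph::compare(l1, l2, method = "nmi"))
  }

  # symmetry under relabeling either argument
  expect_equal(clustering_indices(c(2, 2, 1, 1, 3), c(1, 1, 2, 2, 3)),
               clustering_indices(c(9, 9, 5, 5, 7), c(1, 1, 2, 2, 3)))
  expect_error(clustering_indices(1:3, 1:4), "differ in length")
})

test_that("Gini coefficient matches its mean-absolute-difference definition", {
  expect_equal(gini_coefficient(rep(4, 10)), 0)
  # all mass in one of B bins -> (B-1)/B
  for (B in c(4, 10)) {
    expect_equal(gini_coefficient(c(rep(0, B - 1), 7)), (B - 1) / B)
  }
  set.seed(55)
  x <- rgamma(5, 2)
  mad_gini <- sum(outer(x, x, function(a, b) abs(a - b))) / (2 * 5^2 * mean(x))
  expect_equal(gini_coefficient(x), mad_gini)
  # scale invariance
  expect_equal(gini_coefficient(13 * x), gini_coefficient(x))
  expect_error(gini_coefficient(rep(0, 4)), "all-zero")
  expect_error(gini_coefficient(c(-1, 2)), "non-negative")
})

test_that("Gini flagging separates aneuploid from euploid coverage profiles", {
  set.seed(56)
  p <- sim_params(normal_fraction = 0.5, seed = 56)
  tr <- generate_truth(p)
  cc <- simulate_counts(tr)
  fl <- gini_flag(cc$raw, cutoff = 0.12)
  is_tumor <- tr$clone_of != "normal"
  # tumour cells have unequal coverage across bins, normals near-uniform
  expect_gt(mean(fl$gini[is_tumor]), mean(fl$gini[!is_tumor]))
  expect_true(all(fl$flag[!is_tumor] == "normal"))
  expect_gt(mean(fl$flag[is_tumor] == "tumor"), 0.9)
})
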