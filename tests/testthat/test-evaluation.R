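test_that("mean absolute connection difference matches hand arithmetic", {
  c1 <- conn_from_edges(c(2, 3, 5), 3)
  c2 <- conn_from_edges(c(4, 3, 1), 3)
  expect_equal(mean_abs_difference(c1, c2), 2)   # (2 + 0 + 4) / 3
  expect_equal(mean_abs_difference(c2, c1), 2)   # symmetric in arguments
  expect_equal(mean_abs_difference(c1, c1), 0)
  c3 <- conn_from_edges(rep(0, 6), 4)
  expect_error(mean_abs_difference(c1, c3), "parcellation")
})

test_that("cross distance matrices hold all pairwise mean-L1 values", {
  a1 <- conn_from_edges(c(2, 3, 5), 3, subject = "A")
  a2 <- conn_from_edges(c(0, 0, 0), 3, subject = "B")
  b1 <- conn_from_edges(c(4, 3, 1), 3, subject = "A")
  b2 <- conn_from_edges(c(2, 3, 5), 3, subject = "B")
  D <- cross_distance_matrix(list(a1, a2), list(b1, b2))
  expect_equal(unname(D),
               matrix(c(mean_abs_difference(a1, b1), mean_abs_difference(a2, b1),
                        mean_abs_difference(a1, b2), mean_abs_difference(a2, b2)),
                      2))
  expect_equal(rownames(D), c("A", "B"))

  # same set on both sides: zero diagonal; permuting B permutes columns
  DD <- cross_distance_matrix(list(a1, a2), list(a1, a2))
  expect_equal(unname(diag(DD)), c(0, 0))
  Dp <- cross_distance_matrix(list(a1, a2), list(b2, b1))
  expect_equal(unname(Dp), unname(D[, c(2, 1)]))
  expect_error(cross_distance_matrix(list(), list(a1)), "nonempty")
})

test_that("intra/inter distance samples have the right size and values", {
  sA <- acq_setting(1.25, 3000); sB <- acq_setting(2.3, 1000)
  mk <- function(sub, st, edges) conn_from_edges(edges, 3, subject = sub,
                                                 res = st$res, bval = st$bval)
  coh <- cohort(list(mk("s1", sA, c(1, 2, 3)), mk("s1", sB, c(1, 2, 7)),
                     mk("s2", sA, c(4, 2, 3)), mk("s2", sB, c(4, 2, 3)),
                     mk("s3", sA, c(1, 8, 3)), mk("s3", sB, c(0, 8, 3))))
  d <- intra_inter_distributions(coh, sA, sB)
  expect_length(d$intra, 3L)
  expect_length(d$inter, 3L)
  expect_equal(unname(d$intra), c(4 / 3, 0, 1 / 3))
  expect_equal(unname(d$inter["s1-s2"]), 1)  # |1-4|/3

  # identical scans at both settings: all-zero intra sample
  coh0 <- cohort(list(mk("s1", sA, c(1, 2, 3)), mk("s1", sB, c(1, 2, 3)),
                      mk("s2", sA, c(5, 0, 1)), mk("s2", sB, c(5, 0, 1))))
  expect_equal(unname(intra_inter_distributions(coh0, sA, sB)$intra), c(0, 0))

  # a subject missing one setting is an error
  coh_miss <- cohort(list(mk("s1", sA, c(1, 2, 3)), mk("s1", sB, c(1, 2, 3)),
                          mk("s2", sA, c(5, 0, 1))))
  expect_error(intra_inter_distributions(coh_miss, sA, sB), "no connectome")
})

test_that("identification accuracy and I_diff follow the printed definitions", {
  fp <- identification_accuracy(matrix(c(1, 4, 3, 2), 2))
  expect_equal(fp$accuracy, 1)
  expect_equal(fp$i_diff, (3 + 4) / 2 - (1 + 2) / 2)

  expect_equal(identification_accuracy(matrix(c(3, 2, 1, 4), 2))$accuracy, 0)

  # strictly minimal diagonal identifies everyone
  set.seed(8)
  D <- matrix(runif(25, 2, 5), 5); diag(D) <- 1
  expect_equal(identification_accuracy(D)$accuracy, 1)

  # ties count as failure
  Dt <- matrix(2, 3, 3)
  expect_equal(identification_accuracy(Dt)$accuracy, 0)
  expect_equal(identification_accuracy(Dt)$i_diff, 0)

  # direction flag transposes the matching
  Da <- matrix(c(1, 0, 5, 2), 2)  # row-wise: row 1 fails (0 < 1 off-diag?)
  expect_equal(identification_accuracy(Da, "row")$accuracy,
               identification_accuracy(t(Da), "column")$accuracy)
  expect_error(identification_accuracy(matrix(0, 2, 3)), "square")
})

test_that("I_diff shifts and scales as a distance gap should", {
  set.seed(3)
  D <- matrix(runif(36, 1, 4), 6)
  base <- identification_accuracy(D)$i_diff
  expect_equal(identification_accuracy(matrix(5, 6, 6))$i_diff, 0)
  expect_equal(identification_accuracy(D + 2.5)$i_diff, base, tolerance = 1e-12)
  expect_equal(identification_accuracy(D * 3)$i_diff, 3 * base, tolerance = 1e-12)
})

test_that("KS statistic matches the pooled-ECDF oracle for all small samples", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ks_two_sample(c(1, 2), c(10, 11, 12))$statistic, 1)
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(2:20, 1); m <- sample(2:20, 1)
    a <- round(rnorm(n), 1)  # coarse values force ties across samples
    b <- round(rnorm(m, sample(c(0, 1), 1)), 1)
    expect_equal(ks_two_sample(a, b)$statistic, oracle_ks_statistic(a, b),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1), "nonempty")
})

test_that("train-fitted PCA embeds both sets with the stated conventions", {
  set.seed(13)
  # rank-1 training covariance: one latent drives two edges, two edges constant
  x <- rnorm(10, 0, 5)
  train <- cbind(x, 3 * x - 1, 7, 2)
  test <- cbind(c(0, 1), c(-1, 2), 7, 2)
  emb <- pca_embed(train, test)
  expect_equal(sum(emb$feature_mask), 2L)  # the two constant edges are excluded
  expect_equal(emb$explained_variance[1], 1, tolerance = 1e-10)
  # after z-scoring the two correlated edges load equally, positive by the
  # sign convention (dominant loading positive)
  expect_equal(unname(emb$rotation[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-8)
  expect_gt(emb$rotation[which.max(abs(emb$rotation[, 1])), 1], 0)

  # the training mean projects to the origin
  train2 <- matrix(rnorm(40), 8, 5)
  emb2 <- pca_embed(train2, matrix(colMeans(train2), 1))
  expect_equal(unname(emb2$test_coords[1, ]), c(0, 0), tolerance = 1e-10)

  expect_error(pca_embed(train[1:2, ], test), "at least 3")
  expect_error(pca_embed(matrix(1, 5, 3), matrix(1, 2, 3)), "non-degenerate")
})

test_that("outlier screening flags inter-subject-like repeat scans without dropping them", {
  D <- matrix(c(0.1, 3, 3,
                3, 5, 3,
                3, 3, 0.2), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  rep_ <- screen_outlier_subjects(D)
  expect_equal(rep_$flagged, c(FALSE, TRUE, FALSE))
  expect_equal(nrow(rep_), 3L)
})
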