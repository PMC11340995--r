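#' Mean absolute connection difference between two connectomes
#'
#' The mean, over the n(n-1)/2 distinct connections, of the absolute
#' difference in fiber counts — the L1 distance averaged across
#' connections used throughout the harmonization quality analyses.
#'
#' @param c1,c2 Two [connectome()]s on the same parcellation.
#' @return Non-negative scalar (fibers).
#' @export
#' @examples
#' # 3 regions, edge vectors (2, 3, 5) vs (4, 3, 1): (2 + 0 + 4) / 3 = 2
mean_abs_difference <- function(c1, c2) {
  if (!identical(c1$parcellation$region_labels, c2$parcellation$region_labels)) {
    stop("connectomes are on different parcellations", call. = FALSE)
  }
  idx <- upper_triangle_index(c1$parcellation$n_regions)
  mean(abs(vectorize(c1, idx) - vectorize(c2, idx)))
}

#' Pairwise mean-L1 distance matrix between two connectome sets
#'
#' Computes the mean absolute connection difference between every
#' connectome of `setA` (rows) and every connectome of `setB` (columns).
#' When both sets hold the same subjects in the same order the diagonal
#' contains the within-subject distances and the off-diagonal the
#' between-subject distances — the matrix underlying fingerprinting and
#' differential identifiability.
#'
#' @param setA,setB Lists of [connectome()]s (or cohorts; cohort order is
#'   used).
#' @return Numeric matrix with subject ids as dimnames.
#' @export
cross_distance_matrix <- function(setA, setB) {
  as_list <- function(x) if (inherits(x, "cohort")) unname(x$connectomes) else x
  setA <- as_list(setA); setB <- as_list(setB)
  if (length(setA) == 0 || length(setB) == 0) {
    stop("connectome sets must be nonempty", call. = FALSE)
  }
  idx <- upper_triangle_index(setA[[1L]]$parcellation$n_regions)
  va <- vapply(setA, vectorize, numeric(idx$n_edges), index = idx)
  vb <- vapply(setB, vectorize, numeric(idx$n_edges), index = idx)
  D <- matrix(0, length(setA), length(setB),
              dimnames = list(vapply(setA, function(c) c$subject_id, character(1)),
                              vapply(setB, function(c) c$subject_id, character(1))))
  for (r in seq_along(setA)) {
    D[r, ] <- colMeans(abs(vb - va[, r]))
  }
  D
}

#' Within- and between-subject distance distributions
#'
#' For a cohort observed at two acquisition settings, computes the
#' intra-subject (IS) sample — one distance per subject between their scan
#' at `setting_a` and at `setting_b` — and the inter-subject (InterS)
#' sample — one distance per unordered subject pair, both scans taken at
#' the reference `setting_a`.  Comparing the two distributions (e.g. with
#' [ks_two_sample()]) quantifies whether acquisition differences swamp
#' identity differences.
#'
#' @param cohort A [cohort()]; every subject must be present at both
#'   settings.
#' @param setting_a Reference [acq_setting()] (inter-subject distances are
#'   computed here).
#' @param setting_b Second [acq_setting()].
#' @param session Session to use (default "1").
#' @return List with numeric vectors `intra` (length n_subjects, named by
#'   subject) and `inter` (length n(n-1)/2, named by subject pair).
#' @export
intra_inter_distributions <- function(cohort, setting_a, setting_b, session = "1") {
  subs <- cohort_subjects(cohort)
  at_a <- lapply(subs, function(s) cohort_get(cohort, s, setting_a, session))
  at_b <- lapply(subs, function(s) cohort_get(cohort, s, setting_b, session))
  intra <- vapply(seq_along(subs), function(k) {
    mean_abs_difference(at_a[[k]], at_b[[k]])
  }, numeric(1))
  names(intra) <- subs
  n <- length(subs)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  inter <- vapply(seq_len(nrow(pairs)), function(k) {
    mean_abs_difference(at_a[[pairs[k, 1L]]], at_a[[pairs[k, 2L]]])
  }, numeric(1))
  names(inter) <- paste(subs[pairs[, 1L]], subs[pairs[, 2L]], sep = "-")
  list(intra = intra, inter = inter)
}

#' Fingerprinting accuracy and differential identifiability
#'
#' Given a square cross-scan distance matrix with aligned subjects, a
#' subject is correctly identified when the diagonal entry is the strict
#' minimum of its row (row-wise matching of each query scan against the
#' gallery; ties count as failure).  Differential identifiability I_diff is
#' the mean of the off-diagonal elements minus the mean of the diagonal
#' elements — the gap between average between-subject and within-subject
#' distances; larger values mean identities separate more easily.
#'
#' @param D Square distance matrix with identical row/column subject order.
#' @param direction `"row"` (default) or `"column"` matching.
#' @return Object of class `fingerprint_result`: `accuracy` in \[0, 1\],
#'   `i_diff`, `direction`, `n_subjects`.
#' @export
#' @examples
#' identification_accuracy(matrix(c(1, 4, 3, 2), 2))  # accuracy 1, I_diff 2
identification_accuracy <- function(D, direction = c("row", "column")) {
  direction <- match.arg(direction)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square", call. = FALSE)
  if (!is.null(rownames(D)) && !is.null(colnames(D)) &&
      !identical(rownames(D), colnames(D))) {
    stop("row and column subjects are not aligned", call. = FALSE)
  }
  M <- if (direction == "row") D else t(D)
  n <- nrow(M)
  hits <- vapply(seq_len(n), function(i) {
    M[i, i] < min(M[i, -i])
  }, logical(1))
  structure(
    list(accuracy = mean(hits),
         i_diff = mean(D[row(D) != col(D)]) - mean(diag(D)),
         direction = direction,
         n_subjects = n),
    class = "fingerprint_result"
  )
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat(sprintf("<fingerprint_result> accuracy = %.3f, I_diff = %.4g (%s-wise, n = %d)\n",
              x$accuracy, x$i_diff, x$direction, x$n_subjects))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided sup-distance between the empirical CDFs of two samples with
#' the asymptotic p-value, used to compare within- and between-subject
#' distance distributions.
#'
#' @param sample_a,sample_b Nonempty numeric vectors.
#' @return List with `statistic` (D in \[0, 1\]) and `p_value`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Train/test PCA embedding of edge vectors
#'
#' Edge features are z-scored with respect to the training set (per-edge
#' training mean and standard deviation; edges with zero training variance
#' are excluded), a PCA is fitted on the training set only, and both sets
#' are projected onto the first two principal components.  Component signs
#' are fixed by making each component's largest-magnitude loading positive.
#' The low-dimensional view shows whether connectomes cluster by
#' acquisition setting (before harmonization) or mix (after).
#'
#' @param train,test Matrices with one row per connectome and one column
#'   per edge in canonical order (e.g. `cohort_edge_matrix()$edges`);
#'   `train` needs at least 3 rows.
#' @return Object of class `embedding_result`: `train_coords`,
#'   `test_coords` (n x 2), `feature_mask` (logical per input edge),
#'   `explained_variance` (all components), `rotation` (masked edges x 2).
#' @export
pca_embed <- function(train, test) {
  train <- as.matrix(train); test <- as.matrix(test)
  if (nrow(train) < 3) stop("training set must contain at least 3 connectomes",
                            call. = FALSE)
  if (ncol(test) != ncol(train)) stop("train and test edge dimensions differ",
                                      call. = FALSE)
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  mask <- sd > 0
  if (sum(mask) < 2) stop("fewer than 2 non-degenerate features", call. = FALSE)
  zt <- sweep(sweep(train[, mask, drop = FALSE], 2, mu[mask]), 2, sd[mask], "/")
  zs <- sweep(sweep(test[, mask, drop = FALSE], 2, mu[mask]), 2, sd[mask], "/")
  pc <- stats::prcomp(zt, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, 1:2, drop = FALSE]
  for (k in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, k])), k] < 0) rot[, k] <- -rot[, k]
  }
  structure(
    list(train_coords = zt %*% rot,
         test_coords = zs %*% rot,
         feature_mask = mask,
         explained_variance = pc$sdev^2 / sum(pc$sdev^2),
         rotation = rot),
    class = "embedding_result"
  )
}

#' Screen subjects whose repeat-scan distance looks inter-subject-like
#'
#' For quality control: flags subjects whose within-subject distance (same
#' setting, two sessions, or across settings) is at or above the median
#' between-subject distance — the pattern that motivates excluding
#' unreliable repeat scans.  Subjects are only reported, never dropped.
#'
#' @param D Square aligned distance matrix (within-subject on diagonal).
#' @return data.frame with `subject_id`, `within`, `median_between`,
#'   `flagged`.
#' @export
screen_outlier_subjects <- function(D) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D))
  med_between <- stats::median(D[row(D) != col(D)])
  data.frame(
    subject_id = rownames(D) %||% as.character(seq_len(nrow(D))),
    within = diag(D),
    median_between = med_between,
    flagged = diag(D) >= med_between,
    row.names = NULL
  )
}
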