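# Independent brute-force oracles.  These deliberately avoid the package's
# computational paths (igraph, vectorized sums of squares, ks.test): shortest
# paths by Floyd-Warshall triple loop, metrics by explicit pair sums, ANOVA
# by direct enumeration of group means, KS by pooled-ECDF sup.

oracle_shortest_paths <- function(lengths) {
  n <- nrow(lengths)
  d <- lengths
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        via <- d[i, k] + d[k, j]
        if (via < d[i, j]) d[i, j] <- via
      }
    }
  }
  d
}

oracle_length_matrix <- function(w) {
  n <- nrow(w)
  l <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) l[i, j] <- 0 else if (w[i, j] != 0) l[i, j] <- 1 / w[i, j]
  }
  l
}

oracle_strength <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) sum(w[i, -i]))
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    k <- sum(w[i, ] > 0)
    if (k < 2) return(0)
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        acc <- acc + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
      }
    }
    acc / (k * (k - 1))
  })
}

oracle_closeness <- function(w) {
  d <- oracle_shortest_paths(oracle_length_matrix(w))
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    reach <- setdiff(which(is.finite(d[i, ])), i)
    if (length(reach) == 0) return(0)
    length(reach) / sum(d[i, reach])
  })
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    dsub <- oracle_shortest_paths(oracle_length_matrix(w[nb, nb, drop = FALSE]))
    acc <- 0
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a != b && is.finite(dsub[a, b]) && dsub[a, b] > 0) {
        acc <- acc + (w[i, nb[a]] * w[i, nb[b]] / dsub[a, b])^(1 / 3)
      }
    }
    acc / (k * (k - 1))
  })
}

# direct-enumeration sums of squares for a balanced two-way layout
oracle_anova_ss <- function(y, a, b) {
  a <- as.character(a); b <- as.character(b)
  grand <- mean(y)
  ss_a <- 0
  for (lv in unique(a)) ss_a <- ss_a + sum(a == lv) * (mean(y[a == lv]) - grand)^2
  ss_b <- 0
  for (lv in unique(b)) ss_b <- ss_b + sum(b == lv) * (mean(y[b == lv]) - grand)^2
  ss_cells <- 0; ss_within <- 0
  for (la in unique(a)) for (lb in unique(b)) {
    sel <- a == la & b == lb
    cm <- mean(y[sel])
    ss_cells <- ss_cells + sum(sel) * (cm - grand)^2
    ss_within <- ss_within + sum((y[sel] - cm)^2)
  }
  c(a = ss_a, b = ss_b, ab = ss_cells - ss_a - ss_b,
    within = ss_within, total = sum((y - grand)^2))
}

oracle_ks_statistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(sapply(pts, function(t) mean(a <= t) - mean(b <= t))))
}

# random symmetric integer connectome matrix for property tests
random_connectome_matrix <- function(n, density = 0.5, max_count = 20) {
  m <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < density) {
      m[i, j] <- m[j, i] <- sample.int(max_count, 1)
    }
  }
  m
}

toy_connectome <- function(m, subject = "s1", res = 1.25, bval = 3000,
                           session = "1", integer = TRUE) {
  connectome(m, subject_id = subject, session = session,
             setting = acq_setting(res, bval), integer = integer)
}

# connectome from upper-triangle edge values, row-major
conn_from_edges <- function(edges, n, ...) {
  toy_connectome(devectorize(edges, upper_triangle_index(n)), ...)
}
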