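#' Balanced two-way fixed-effects ANOVA with interaction
#'
#' Decomposes a balanced 2 x 2 factorial (factor A = b-value level, factor
#' B = resolution level, S >= 2 observations per cell) into sums of squares
#' on 1 df each for A, B, and the A x B interaction, with the residual on
#' 4(S - 1) df; F = MS_effect / MS_within with upper-tail p from the F
#' distribution.  Degenerate inputs follow fixed conventions: if the total
#' sum of squares is zero, every F is 0 and every p is 1; if the within-cell
#' variance is zero but an effect sum of squares is positive, that effect's
#' F is `Inf` and p is 0.
#'
#' @param values Numeric observations.
#' @param a,b Factor labels (2 levels each) parallel to `values`.
#' @return List with `F`, `p` (each named `a`, `b`, `ab`), `ss` (named
#'   `a`, `b`, `ab`, `within`, `total`), and `df`.
#' @export
#' @examples
#' y <- c(10, 11, 10, 11, 20, 21, 20, 21)
#' a <- rep(c("b1000", "b3000"), each = 4)
#' b <- rep(c("lo", "hi", "lo", "hi"), each = 2)
#' two_way_anova_2x2(y, a, b)$p
two_way_anova_2x2 <- function(values, a, b) {
  res <- anova_2x2_matrix(matrix(values, ncol = 1), a, b)
  list(F = c(a = res$F_a[1], b = res$F_b[1], ab = res$F_ab[1]),
       p = c(a = res$p_a[1], b = res$p_b[1], ab = res$p_ab[1]),
       ss = c(a = res$ss_a[1], b = res$ss_b[1], ab = res$ss_ab[1],
              within = res$ss_within[1], total = res$ss_total[1]),
       df = res$df)
}

# Vectorized 2x2 balanced ANOVA over the columns of Y (one unit per
# column).  This is the mass-univariate workhorse: sums of squares are
# computed from cell means in closed form so 37k edges run in one pass.
anova_2x2_matrix <- function(Y, a, b) {
  a <- as.factor(a); b <- as.factor(b)
  if (nlevels(a) != 2 || nlevels(b) != 2) {
    stop("both factors must have exactly two levels", call. = FALSE)
  }
  cell <- interaction(a, b, drop = FALSE)
  counts <- table(cell)
  if (length(unique(as.integer(counts))) != 1L) {
    stop("unbalanced design: cell counts ", paste(counts, collapse = ", "),
         "; equal counts per cell are required", call. = FALSE)
  }
  S <- as.integer(counts[1L])
  if (S < 2) stop("at least 2 observations per cell are required", call. = FALSE)
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == length(a))

  grand <- colMeans(Y)
  mean_by <- function(f) rowsum(Y, f, reorder = TRUE) / as.vector(table(f))
  ma <- mean_by(a)      # 2 x units
  mb <- mean_by(b)
  mc <- mean_by(cell)   # 4 x units
  n <- nrow(Y)
  ss_a <- (n / 2) * colSums((ma - rep(grand, each = 2))^2)
  ss_b <- (n / 2) * colSums((mb - rep(grand, each = 2))^2)
  ss_cells <- S * colSums((mc - rep(grand, each = 4))^2)
  ss_ab <- pmax(ss_cells - ss_a - ss_b, 0)
  fitted <- mc[as.integer(cell), , drop = FALSE]
  ss_within <- colSums((Y - fitted)^2)
  ss_total <- colSums((Y - rep(grand, each = n))^2)

  df_within <- 4L * (S - 1L)
  msw <- ss_within / df_within
  # zero tolerance scaled to the data so exact-zero conventions fire only
  # on genuinely constant input
  tol <- 1e-12 * pmax(ss_total, 1)

  f_of <- function(ss_eff) {
    f <- ss_eff / msw
    f[ss_eff <= tol] <- 0
    f[msw <= tol & ss_eff > tol] <- Inf
    f
  }
  p_of <- function(f) {
    p <- stats::pf(f, 1, df_within, lower.tail = FALSE)
    p[f == 0] <- 1
    p[is.infinite(f)] <- 0
    p
  }
  F_a <- f_of(ss_a); F_b <- f_of(ss_b); F_ab <- f_of(ss_ab)
  list(F_a = F_a, F_b = F_b, F_ab = F_ab,
       p_a = p_of(F_a), p_b = p_of(F_b), p_ab = p_of(F_ab),
       ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab,
       ss_within = ss_within, ss_total = ss_total,
       degenerate = ss_total <= tol,
       df = c(a = 1L, b = 1L, ab = 1L, within = df_within))
}

# shared post-processing: Bonferroni correction, significance, -log10 maps
finish_anova_result <- function(raw, unit_ids, m, alpha, unit_type) {
  out <- data.frame(unit_ids, stringsAsFactors = FALSE)
  for (fac in c("bval", "res", "interaction")) {
    key <- c(bval = "a", res = "b", interaction = "ab")[[fac]]
    p <- raw[[paste0("p_", key)]]
    p[raw$degenerate] <- 1
    f <- raw[[paste0("F_", key)]]
    f[raw$degenerate] <- 0
    corrected <- pmin(1, p * m)
    out[[paste0("F_", fac)]] <- f
    out[[paste0("p_", fac)]] <- p
    out[[paste0("corrected_p_", fac)]] <- corrected
    out[[paste0("significant_", fac)]] <- p < alpha / m
    out[[paste0("neglog_", fac)]] <- -log10(corrected)
  }
  out$degenerate <- raw$degenerate
  structure(out,
            m = m, alpha = alpha, unit_type = unit_type,
            log_base = 10,
            class = c("anova_result", "data.frame"))
}

# requires the cohort's settings to form a complete 2x2 grid and returns
# (bval factor, res factor) per observation row
check_2x2_grid <- function(tab) {
  res_lv <- sort(unique(tab$res_mm))
  bval_lv <- sort(unique(tab$bval))
  if (length(res_lv) != 2 || length(bval_lv) != 2) {
    stop("acquisition settings must form a 2 x 2 grid; observed ",
         length(res_lv), " resolution level(s) and ", length(bval_lv),
         " b-value level(s)", call. = FALSE)
  }
  combos <- table(factor(tab$bval, bval_lv), factor(tab$res_mm, res_lv))
  if (any(combos == 0)) {
    stop("acquisition settings must cover all four cells of the 2 x 2 grid",
         call. = FALSE)
  }
  list(a = factor(tab$bval, bval_lv), b = factor(tab$res_mm, res_lv))
}

#' Edgewise two-way ANOVA of acquisition effects
#'
#' Applies the balanced 2 x 2 two-way ANOVA (factors: b-value and spatial
#' resolution, with interaction) independently to every connection of the
#' cohort's connectomes, then Bonferroni-corrects over the number of
#' possible connections m = n(n-1)/2 — 37,401 for the 274-region
#' parcellation.  An edge is significant for a factor when its raw p-value
#' is strictly below `alpha / m`.  Edges with zero variance across all
#' observations (e.g. absent connections) are flagged degenerate and
#' reported non-significant with corrected p = 1.  The `neglog_*` columns
#' hold -log10 of the corrected p-values, the scale used for significance
#' maps (threshold -log10(0.05)).
#'
#' @param cohort A [cohort()] whose settings form a complete 2 x 2 grid
#'   with equal numbers of observations per setting (>= 2).
#' @param alpha Family-wise error level (default 0.05).
#' @return An `anova_result` data.frame with one row per edge (`region_i`,
#'   `region_j`, F/p/corrected p/significance/neglog per factor) and
#'   attributes `m`, `alpha`, `unit_type`, `log_base`.
#' @export
edgewise_anova <- function(cohort, alpha = 0.05) {
  em <- cohort_edge_matrix(cohort)
  fac <- check_2x2_grid(em$table)
  raw <- anova_2x2_matrix(em$edges, fac$a, fac$b)
  labs <- cohort$parcellation$region_labels
  ids <- data.frame(region_i = labs[em$index$i], region_j = labs[em$index$j],
                    stringsAsFactors = FALSE)
  finish_anova_result(raw, ids, m = em$index$n_edges, alpha = alpha,
                      unit_type = "edge")
}

#' Nodal two-way ANOVA of acquisition effects
#'
#' Same mass-univariate two-way ANOVA applied to one weighted nodal metric
#' across the 2 x 2 acquisition grid, Bonferroni-corrected over the number
#' of nodes (0.05/274 at the scale-3 parcellation).
#'
#' @param metric_table The `nodal` data.frame from [cohort_metric_table()].
#' @param metric One of `"strength"`, `"closeness"`, `"clustering"`,
#'   `"local_efficiency"`.
#' @param alpha Family-wise error level (default 0.05).
#' @return An `anova_result` data.frame with one row per node.
#' @export
nodal_anova <- function(metric_table, metric, alpha = 0.05) {
  valid <- c("strength", "closeness", "clustering", "local_efficiency")
  if (!metric %in% valid) {
    stop("unknown metric '", metric, "'; expected one of ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  nodes <- unique(metric_table$node_label)
  # wide: one column per node, one row per connectome observation
  obs_key <- interaction(metric_table$subject_id, metric_table$session,
                         metric_table$res_mm, metric_table$bval, drop = TRUE)
  first <- !duplicated(obs_key)
  tab <- metric_table[first, c("subject_id", "session", "res_mm", "bval")]
  Y <- matrix(NA_real_, nrow = sum(first), ncol = length(nodes),
              dimnames = list(NULL, nodes))
  Y[cbind(match(obs_key, obs_key[first]), match(metric_table$node_label, nodes))] <-
    metric_table[[metric]]
  if (anyNA(Y)) stop("metric table is incomplete: missing node values", call. = FALSE)
  fac <- check_2x2_grid(tab)
  raw <- anova_2x2_matrix(Y, fac$a, fac$b)
  finish_anova_result(raw, data.frame(node_label = nodes, stringsAsFactors = FALSE),
                      m = length(nodes), alpha = alpha, unit_type = "node")
}

#' Summarize significant units per factor
#'
#' Counts significant units for each factor and formats the percentage the
#' way the significance tables print it: rounded to the nearest integer, or
#' to two decimals when below 1 percent.
#'
#' @param result An `anova_result` from [edgewise_anova()] or
#'   [nodal_anova()].
#' @return data.frame with columns `factor`, `n_significant`, `m`,
#'   `percent` (character).
#' @export
anova_summary <- function(result) {
  m <- attr(result, "m")
  rows <- lapply(c("bval", "res", "interaction"), function(fac) {
    n_sig <- sum(result[[paste0("significant_", fac)]])
    data.frame(factor = fac, n_significant = n_sig, m = m,
               percent = format_percentage(n_sig, m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an ANOVA result (and its summary) to CSV
#'
#' @param result An `anova_result`.
#' @param path Output CSV path; the summary goes to
#'   `<path minus .csv>_summary.csv`.
#' @return `path`, invisibly.
#' @export
write_anova_result <- function(result, path) {
  df <- as.data.frame(result)
  utils::write.csv(df, path, row.names = FALSE)
  spath <- sub("\\.csv$", "", path)
  utils::write.csv(anova_summary(result), paste0(spath, "_summary.csv"),
                   row.names = FALSE)
  invisible(path)
}
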