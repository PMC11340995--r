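#' Weighted nodal graph metrics for structural connectomes
#'
#' The four weighted metrics analyzed for acquisition-parameter effects:
#' nodal strength and closeness centrality (integration), clustering
#' coefficient and local efficiency (segregation).  All are computed on the
#' raw fiber-count weights by the literal formulas
#'
#' \deqn{k_i^w = \sum_{j \ne i} w_{ij}}
#' \deqn{C_i^w = \frac{1}{k_i (k_i - 1)} \sum_{j \ne h} (w_{ij} w_{ih} w_{jh})^{1/3}}
#' \deqn{L_i^{w^{-1}} = \frac{n_i - 1}{\sum_j d_{ij}^w}}
#' \deqn{E_{loc,i}^w = \frac{1}{k_i (k_i - 1)} \sum_{j \ne h}
#'   \left(w_{ij} w_{ih} \, [d_{jh}^w(N_{-i})]^{-1}\right)^{1/3}}
#'
#' where path lengths are reciprocal weights (\eqn{l_{ij} = 1/w_{ij}}),
#' \eqn{n_i - 1} is the number of nodes reachable from node i, sums run over
#' ordered neighbor pairs, and \eqn{d_{jh}^w(N_{-i})} is the shortest
#' distance between j and h inside the subgraph induced by i's neighbors
#' (excluding i).  Nodes of degree < 2 get clustering and local efficiency
#' 0; unreachable pairs contribute 0 in local efficiency.
#'
#' Because the weights are raw counts, clustering and local efficiency are
#' not bounded by 1 and scale linearly with a uniform weight rescaling.
#' Some toolkits instead normalize weights by the graph maximum before the
#' cube root; set `normalize = TRUE` to reproduce that convention for
#' cross-checking.  The default is the literal formula.
#'
#' @param connectome A [connectome()] (a bare symmetric matrix also works).
#' @param normalize Divide weights by the graph-wide maximum before
#'   computing clustering and local efficiency (default `FALSE`).
#' @return `nodal_metrics()`: data.frame with columns `node_label`,
#'   `strength`, `closeness`, `clustering`, `local_efficiency`; the
#'   single-metric functions return named numeric vectors.
#' @name graph_metrics
NULL

conn_matrix <- function(connectome) {
  if (inherits(connectome, "connectome")) connectome$matrix else as.matrix(connectome)
}

#' @rdname graph_metrics
#' @export
nodal_strength <- function(connectome) {
  w <- conn_matrix(connectome)
  rowSums(w)   # diagonal is zero by invariant
}

#' Reciprocal-weight length matrix
#'
#' Converts connection weights into lengths: `l_ij = 1/w_ij` for nonzero
#' off-diagonal weights, 0 on the diagonal, and `Inf` (absent) where
#' `w_ij = 0` — a zero count means no direct edge, not a zero-length one.
#'
#' @inheritParams graph_metrics
#' @return Symmetric numeric matrix of lengths with `Inf` marking absent
#'   direct connections.
#' @export
length_matrix <- function(connectome) {
  w <- conn_matrix(connectome)
  l <- ifelse(w > 0, 1 / w, Inf)
  diag(l) <- 0
  l
}

#' All-pairs shortest path distances on a length matrix
#'
#' Exact shortest paths (Dijkstra, via igraph) over the weighted graph whose
#' edge lengths are the finite off-diagonal entries of `lengths`.
#' Unreachable pairs are `Inf`.
#'
#' @param lengths A length matrix as from [length_matrix()].
#' @return Symmetric matrix of shortest-path distances (zero diagonal,
#'   `Inf` for unreachable pairs).
#' @export
shortest_paths <- function(lengths) {
  l <- as.matrix(lengths)
  adj <- ifelse(is.finite(l), l, 0)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- dimnames(l)
  d
}

#' @rdname graph_metrics
#' @export
closeness_centrality <- function(connectome) {
  w <- conn_matrix(connectome)
  d <- shortest_paths(length_matrix(w))
  n <- nrow(w)
  out <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di)
    if (!any(reach)) return(0)
    sum(reach) / sum(di[reach])
  }, numeric(1))
  names(out) <- rownames(w)
  out
}

#' @rdname graph_metrics
#' @export
clustering_coefficient <- function(connectome, normalize = FALSE) {
  w <- conn_matrix(connectome)
  if (normalize && max(w) > 0) w <- w / max(w)
  w3 <- w^(1 / 3)
  k <- rowSums(w > 0)
  num <- diag(w3 %*% w3 %*% w3)  # ordered (j, h) pairs; zero diagonal kills j = h and j,h = i
  out <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  names(out) <- rownames(w)
  out
}

#' @rdname graph_metrics
#' @export
local_efficiency <- function(connectome, normalize = FALSE) {
  w <- conn_matrix(connectome)
  if (normalize && max(w) > 0) w <- w / max(w)
  n <- nrow(w)
  out <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    dsub <- shortest_paths(length_matrix(w[nb, nb, drop = FALSE]))
    inv <- ifelse(is.finite(dsub) & dsub > 0, 1 / dsub, 0)  # unreachable -> 0
    wi <- w[i, nb]
    terms <- (outer(wi, wi) * inv)^(1 / 3)
    diag(terms) <- 0
    sum(terms) / (k * (k - 1))
  }, numeric(1))
  names(out) <- rownames(w)
  out
}

#' @rdname graph_metrics
#' @export
nodal_metrics <- function(connectome, normalize = FALSE) {
  w <- conn_matrix(connectome)
  data.frame(
    node_label = rownames(w) %||% sprintf("region_%03d", seq_len(nrow(w))),
    strength = unname(nodal_strength(w)),
    closeness = unname(closeness_centrality(w)),
    clustering = unname(clustering_coefficient(w, normalize = normalize)),
    local_efficiency = unname(local_efficiency(w, normalize = normalize)),
    row.names = NULL
  )
}

#' Nodal metrics for every connectome in a cohort
#'
#' Computes the four weighted nodal metrics for each connectome and, as a
#' companion table, the mean of each metric across regions per connectome
#' (the summary used to compare acquisition settings at the whole-brain
#' level).
#'
#' @param cohort A [cohort()].
#' @param normalize Passed to the metric functions.
#' @return List with `nodal` (one row per connectome x node:
#'   subject_id, session, res_mm, bval, node_label, strength, closeness,
#'   clustering, local_efficiency) and `means` (one row per connectome with
#'   the across-region mean of each metric).
#' @export
cohort_metric_table <- function(cohort, normalize = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  tabs <- lapply(cohort$connectomes, function(cn) {
    nm <- nodal_metrics(cn, normalize = normalize)
    cbind(data.frame(subject_id = cn$subject_id, session = cn$session,
                     res_mm = cn$setting$res, bval = cn$setting$bval,
                     stringsAsFactors = FALSE),
          nm)
  })
  nodal <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  means <- do.call(rbind, c(lapply(tabs, function(t) {
    data.frame(subject_id = t$subject_id[1L], session = t$session[1L],
               res_mm = t$res_mm[1L], bval = t$bval[1L],
               strength = mean(t$strength), closeness = mean(t$closeness),
               clustering = mean(t$clustering),
               local_efficiency = mean(t$local_efficiency),
               stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  list(nodal = nodal, means = means)
}
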