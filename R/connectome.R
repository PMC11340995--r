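#' Parcellation of gray matter into labeled regions
#'
#' A parcellation is an ordered set of unique region labels; its size fixes
#' the node set of every connectome built on it.  The scale-3 Lausanne
#' parcellation used throughout the validation analyses has 274 regions.
#'
#' @param region_labels Character vector of unique, non-empty region labels.
#' @return An object of class `parcellation` with fields `region_labels`
#'   and `n_regions`.
#' @export
#' @examples
#' p <- parcellation(c("lh.precentral", "rh.precentral", "brainstem"))
#' p$n_regions
parcellation <- function(region_labels) {
  region_labels <- as.character(region_labels)
  if (length(region_labels) < 1 || anyNA(region_labels) || any(!nzchar(region_labels))) {
    stop("region labels must be non-empty strings", call. = FALSE)
  }
  if (anyDuplicated(region_labels)) {
    stop("region labels must be unique; duplicated: ",
         paste(unique(region_labels[duplicated(region_labels)]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(region_labels = region_labels, n_regions = length(region_labels)),
    class = "parcellation"
  )
}

# default labels for simulated / unlabeled data
default_parcellation <- function(n_regions) {
  parcellation(sprintf("region_%03d", seq_len(n_regions)))
}

#' @export
print.parcellation <- function(x, ...) {
  cat("<parcellation>", x$n_regions, "regions:",
      paste(utils::head(x$region_labels, 3), collapse = ", "),
      if (x$n_regions > 3) "..." else "", "\n")
  invisible(x)
}

#' Acquisition setting (spatial resolution, b-value)
#'
#' The two diffusion-MRI acquisition parameters the harmonization model
#' covaries on: spatial resolution `res` in mm, defined as the cube root of
#' the voxel volume (so anisotropic voxels get a scalar resolution), and the
#' maximal diffusion weighting `bval` in s/mm^2.  Settings are experiment
#' keys: equality is exact numeric equality on both fields, with no
#' tolerance.
#'
#' @param res Positive scalar, mm (cube root of voxel volume).
#' @param bval Positive scalar, s/mm^2.
#' @return An object of class `acq_setting`.
#' @export
#' @examples
#' hbhr <- acq_setting(res = 1.25, bval = 3000)  # higher-bval higher-res
#' lblr <- acq_setting(res = 2.3, bval = 1000)   # lower-bval lower-res
acq_setting <- function(res, bval) {
  if (!is.numeric(res) || length(res) != 1L || !is.finite(res) || res <= 0) {
    stop("res must be a positive finite scalar (mm)", call. = FALSE)
  }
  if (!is.numeric(bval) || length(bval) != 1L || !is.finite(bval) || bval <= 0) {
    stop("bval must be a positive finite scalar (s/mm^2)", call. = FALSE)
  }
  structure(list(res = as.numeric(res), bval = as.numeric(bval)),
            class = "acq_setting")
}

#' @export
print.acq_setting <- function(x, ...) {
  cat(sprintf("<acq_setting> res = %g mm, bval = %g s/mm^2\n", x$res, x$bval))
  invisible(x)
}

#' @export
`==.acq_setting` <- function(e1, e2) {
  identical(e1$res, e2$res) && identical(e1$bval, e2$bval)
}

setting_equal <- function(a, b) {
  a$res == b$res && a$bval == b$bval
}

setting_key <- function(s) {
  paste0(format_full(s$res), "|", format_full(s$bval))
}

#' Row-major strict upper-triangle edge index
#'
#' Fixes the canonical ordering of the n(n-1)/2 undirected edges of an
#' n-region connectome: row-major over the strict upper triangle, i.e.
#' (1,2), (1,3), ..., (1,n), (2,3), ...  Every operation that vectorizes a
#' connectome (model fitting, edgewise ANOVA, PCA features, model files)
#' uses this one ordering, so position k always refers to the same region
#' pair.  For the 274-region parcellation this gives 37,401 possible
#' connections.
#'
#' @param n_regions Integer >= 2.
#' @return An object of class `edge_index` with fields `n_regions`, `i`,
#'   `j` (parallel integer vectors with `i < j`) and `n_edges`.
#' @export
#' @examples
#' upper_triangle_index(274)$n_edges  # 37401
upper_triangle_index <- function(n_regions) {
  if (!is.numeric(n_regions) || length(n_regions) != 1L ||
      n_regions != floor(n_regions) || n_regions < 2) {
    stop("invalid parcellation: n_regions must be an integer >= 2", call. = FALSE)
  }
  n <- as.integer(n_regions)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  structure(
    list(n_regions = n, i = i, j = j, n_edges = as.integer(n * (n - 1L) / 2L)),
    class = "edge_index"
  )
}

#' @export
print.edge_index <- function(x, ...) {
  cat("<edge_index>", x$n_regions, "regions,", x$n_edges, "edges (row-major upper triangle)\n")
  invisible(x)
}

#' Structural connectome
#'
#' A structural connectome (SC) is a symmetric matrix of fiber (streamline)
#' counts between parcellated gray-matter regions, with zero diagonal
#' (self-connections are set to zero), annotated with the subject, session,
#' and acquisition setting it was reconstructed under.
#'
#' @param matrix Square numeric matrix of non-negative counts; must be
#'   symmetric with zero diagonal.  Integer-valued unless
#'   `integer = FALSE` (continuous connectomes arise internally from
#'   pre-rounding harmonization output and simulation).
#' @param subject_id Subject identifier string.
#' @param session Session identifier string; defaults to `"1"`.
#' @param setting An [acq_setting()].
#' @param parcellation A [parcellation()], or `NULL` to take labels from
#'   `dimnames(matrix)` (or generate defaults).
#' @param integer Require integer entries (default `TRUE`).
#' @return An object of class `connectome`.
#' @export
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 5; m[2, 3] <- m[3, 2] <- 2
#' connectome(m, "sub-001", setting = acq_setting(1.25, 3000))
connectome <- function(matrix, subject_id, session = "1", setting,
                       parcellation = NULL, integer = TRUE) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) {
    stop("connectome matrix must be square; got ", nrow(m), " x ", ncol(m),
         call. = FALSE)
  }
  if (is.null(parcellation)) {
    labs <- rownames(m) %||% colnames(m)
    parcellation <- if (is.null(labs)) default_parcellation(nrow(m)) else parcellation(labs)
  }
  if (!inherits(parcellation, "parcellation")) {
    stop("parcellation must be a parcellation object", call. = FALSE)
  }
  if (parcellation$n_regions != nrow(m)) {
    stop("matrix size ", nrow(m), " does not match parcellation size ",
         parcellation$n_regions, call. = FALSE)
  }
  if (!inherits(setting, "acq_setting")) {
    stop("setting must be an acq_setting", call. = FALSE)
  }
  validate_connectome_matrix(m, integer = integer)
  dimnames(m) <- list(parcellation$region_labels, parcellation$region_labels)
  structure(
    list(matrix = m,
         subject_id = as.character(subject_id),
         session = as.character(session),
         setting = setting,
         parcellation = parcellation,
         continuous = !integer),
    class = "connectome"
  )
}

# Checks all matrix invariants, reporting the first offending cell by
# position so malformed files are easy to fix.
validate_connectome_matrix <- function(m, integer = TRUE) {
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite entry at cell (%d, %d)", bad[1L], bad[2L]), call. = FALSE)
  }
  if (integer && any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative entry %g at cell (%d, %d); fiber counts must be >= 0",
                 m[bad[1L], bad[2L]], bad[1L], bad[2L]), call. = FALSE)
  }
  if (integer && any(m != floor(m))) {
    bad <- which(m != floor(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer entry %g at cell (%d, %d)", m[bad[1L], bad[2L]],
                 bad[1L], bad[2L]), call. = FALSE)
  }
  asym <- m != t(m)
  if (any(asym)) {
    bad <- which(asym, arr.ind = TRUE)[1L, ]
    stop(sprintf("matrix not symmetric: cell (%d, %d) = %g but (%d, %d) = %g",
                 bad[1L], bad[2L], m[bad[1L], bad[2L]],
                 bad[2L], bad[1L], m[bad[2L], bad[1L]]), call. = FALSE)
  }
  if (any(diag(m) != 0)) {
    bad <- which(diag(m) != 0)[1L]
    stop(sprintf("nonzero diagonal at cell (%d, %d); self-connections must be zero",
                 bad, bad), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> subject %s session %s, %d regions, res = %g mm, bval = %g s/mm^2%s\n",
              x$subject_id, x$session, x$parcellation$n_regions,
              x$setting$res, x$setting$bval,
              if (isTRUE(x$continuous)) " (continuous)" else ""))
  invisible(x)
}

#' Vectorize a connectome along the canonical edge order
#'
#' Extracts the strict upper triangle of the connectivity matrix in the
#' row-major order fixed by [upper_triangle_index()].  `devectorize()` is
#' the exact inverse: it rebuilds the symmetric, zero-diagonal matrix.
#'
#' @param connectome A [connectome()] (or a bare symmetric matrix).
#' @param index An [upper_triangle_index()] of matching size; built
#'   automatically when omitted.
#' @return Numeric vector of length `index$n_edges`.
#' @export
vectorize <- function(connectome, index = NULL) {
  m <- if (inherits(connectome, "connectome")) connectome$matrix else as.matrix(connectome)
  if (is.null(index)) index <- upper_triangle_index(nrow(m))
  if (index$n_regions != nrow(m)) {
    stop("edge index size ", index$n_regions,
         " does not match connectome size ", nrow(m), call. = FALSE)
  }
  m[cbind(index$i, index$j)]
}

#' @rdname vectorize
#' @param edges Numeric vector of length `index$n_edges`.
#' @export
devectorize <- function(edges, index) {
  if (length(edges) != index$n_edges) {
    stop("edge vector length ", length(edges), " does not match index n_edges ",
         index$n_edges, call. = FALSE)
  }
  m <- matrix(0, index$n_regions, index$n_regions)
  m[cbind(index$i, index$j)] <- edges
  m[cbind(index$j, index$i)] <- edges
  m
}

#' Cohort of connectomes
#'
#' A cohort collects connectomes sharing one parcellation, indexed by the
#' (subject, session, setting) triple.  Duplicate keys and mixed
#' parcellations are rejected.
#'
#' @param connectomes List of [connectome()] objects.
#' @return An object of class `cohort`.
#' @export
cohort <- function(connectomes) {
  if (length(connectomes) == 0) stop("cohort must contain at least one connectome", call. = FALSE)
  if (!all(vapply(connectomes, inherits, logical(1), "connectome"))) {
    stop("all elements must be connectome objects", call. = FALSE)
  }
  labs <- connectomes[[1L]]$parcellation$region_labels
  for (k in seq_along(connectomes)) {
    if (!identical(connectomes[[k]]$parcellation$region_labels, labs)) {
      stop("mixed parcellations: connectome ", k,
           " uses different region labels than the first", call. = FALSE)
    }
  }
  keys <- vapply(connectomes, function(cn) {
    paste(cn$subject_id, cn$session, setting_key(cn$setting), sep = "\r")
  }, character(1))
  if (anyDuplicated(keys)) {
    dup <- connectomes[[which(duplicated(keys))[1L]]]
    stop(sprintf("duplicate (subject, session, setting) key: %s / %s / (%g, %g)",
                 dup$subject_id, dup$session, dup$setting$res, dup$setting$bval),
         call. = FALSE)
  }
  names(connectomes) <- keys
  structure(list(connectomes = connectomes,
                 parcellation = connectomes[[1L]]$parcellation),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", length(x$connectomes), "connectomes,",
      x$parcellation$n_regions, "regions,",
      length(cohort_subjects(x)), "subjects,",
      length(cohort_settings(x)), "settings\n")
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$connectomes)

#' Cohort accessors
#'
#' `cohort_subjects()` and `cohort_settings()` list the distinct subjects
#' and acquisition settings; `cohort_get()` retrieves one connectome by
#' key; `cohort_subset()` filters by subject and/or setting.
#'
#' @param x A [cohort()].
#' @return `cohort_subjects()`: character vector; `cohort_settings()`: list
#'   of [acq_setting()]; `cohort_get()`: a connectome or error;
#'   `cohort_subset()`: a cohort.
#' @export
cohort_subjects <- function(x) {
  unique(vapply(x$connectomes, function(cn) cn$subject_id, character(1)))
}

#' @rdname cohort_subjects
#' @export
cohort_settings <- function(x) {
  keys <- vapply(x$connectomes, function(cn) setting_key(cn$setting), character(1))
  x$connectomes[!duplicated(keys)] |>
    lapply(function(cn) cn$setting)
}

#' @rdname cohort_subjects
#' @param subject_id,session,setting Key of the connectome to retrieve.
#' @export
cohort_get <- function(x, subject_id, setting, session = "1") {
  key <- paste(subject_id, session, setting_key(setting), sep = "\r")
  cn <- x$connectomes[[key]]
  if (is.null(cn)) {
    stop(sprintf("no connectome for subject %s session %s at (%g, %g)",
                 subject_id, session, setting$res, setting$bval), call. = FALSE)
  }
  cn
}

#' @rdname cohort_subjects
#' @param subjects Character vector of subject ids to keep (NULL = all).
#' @param settings List of [acq_setting()] to keep (NULL = all).
#' @export
cohort_subset <- function(x, subjects = NULL, settings = NULL) {
  keep <- vapply(x$connectomes, function(cn) {
    ok <- TRUE
    if (!is.null(subjects)) ok <- cn$subject_id %in% subjects
    if (ok && !is.null(settings)) {
      ok <- any(vapply(settings, setting_equal, logical(1), b = cn$setting))
    }
    ok
  }, logical(1))
  if (!any(keep)) stop("subset matches no connectomes", call. = FALSE)
  cohort(unname(x$connectomes[keep]))
}

# observation table: one row per connectome, in cohort order
cohort_table <- function(x) {
  data.frame(
    subject_id = vapply(x$connectomes, function(cn) cn$subject_id, character(1)),
    session = vapply(x$connectomes, function(cn) cn$session, character(1)),
    res_mm = vapply(x$connectomes, function(cn) cn$setting$res, numeric(1)),
    bval = vapply(x$connectomes, function(cn) cn$setting$bval, numeric(1)),
    row.names = NULL
  )
}

#' Stack a cohort into an observation-by-edge matrix
#'
#' Vectorizes every connectome along the canonical edge order and stacks the
#' results into one matrix with one row per connectome (in cohort order).
#' This is the common input to model fitting, edgewise ANOVA, and PCA.
#'
#' @param x A [cohort()].
#' @return List with `edges` (matrix n_obs x n_edges), `table` (data.frame
#'   of subject_id, session, res_mm, bval per row) and `index` (the shared
#'   [upper_triangle_index()]).
#' @export
cohort_edge_matrix <- function(x) {
  idx <- upper_triangle_index(x$parcellation$n_regions)
  edges <- t(vapply(x$connectomes, vectorize, numeric(idx$n_edges), index = idx))
  rownames(edges) <- NULL
  list(edges = edges, table = cohort_table(x), index = idx)
}
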