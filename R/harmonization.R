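#' Build the acquisition design matrix
#'
#' One row per observation with columns (1, X_r, X_b, X_r * X_b): intercept,
#' spatial resolution in mm, b-value in s/mm^2, and their product.
#' Covariates enter in raw physical units with no centering or scaling; the
#' model space spanned by {1, X_r, X_b, X_r X_b} is invariant under affine
#' reparameterization of either covariate, so predictions do not depend on
#' the units (only the individual coefficient values do).
#'
#' @param settings List of [acq_setting()] (one per observation).
#' @return List with `X` (n x 4 matrix, columns `intercept`, `res`, `bval`,
#'   `res_bval`) and `rank` (numerical rank of `X`).
#' @export
#' @examples
#' grid <- list(acq_setting(1.25, 1000), acq_setting(1.25, 3000),
#'              acq_setting(2.3, 1000), acq_setting(2.3, 3000))
#' build_design(grid)$rank  # 4: the full 2 x 2 grid identifies the model
build_design <- function(settings) {
  if (length(settings) == 0) stop("settings list must be nonempty", call. = FALSE)
  stopifnot(all(vapply(settings, inherits, logical(1), "acq_setting")))
  xr <- vapply(settings, function(s) s$res, numeric(1))
  xb <- vapply(settings, function(s) s$bval, numeric(1))
  X <- cbind(intercept = 1, res = xr, bval = xb, res_bval = xr * xb)
  list(X = X, rank = qr(X)$rank)
}

#' Fit the per-connection acquisition harmonization model
#'
#' For every connection i the fiber count is modeled as a linear function
#' of the acquisition parameters,
#' \deqn{y_i = \beta_{0i} + \beta_{1i} X_r + \beta_{2i} X_b +
#'   \beta_{3i} X_r X_b + \varepsilon_i,}
#' fitted by ordinary least squares over all training connectomes (every
#' (subject, session, setting) observation contributes one row per edge).
#' Subject identity is deliberately not a covariate, so the fitted model
#' can correct connectomes of subjects never seen in training; with
#' traveling subjects, subject baselines are orthogonal to the acquisition
#' columns and land in the intercept.  The shared design is factorized once
#' (QR) and solved simultaneously for all edges.  The four distinct
#' settings must identify the model: a design of rank < 4 is an error, not
#' a pseudo-inverse fallback.
#'
#' @param cohort Training [cohort()].
#' @return An object of class `harmonization_model`: `betas` (n_edges x 4,
#'   columns `beta0`..`beta3`), `edge_index`, `region_labels`,
#'   `training_settings` (data.frame res, bval, count), `n_obs`,
#'   `resid_var` (per-edge residual variance on n - 4 df), `rounding`.
#' @export
fit_harmonization <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  em <- cohort_edge_matrix(cohort)
  settings <- lapply(cohort$connectomes, function(cn) cn$setting)
  des <- build_design(settings)
  if (nrow(des$X) < 4) {
    stop("at least 4 observations are required to fit the model; got ",
         nrow(des$X), call. = FALSE)
  }
  if (des$rank < 4) {
    uniq <- unique(data.frame(res = des$X[, "res"], bval = des$X[, "bval"]))
    stop("rank-deficient design (rank ", des$rank, " < 4): the distinct ",
         "training settings (res, bval) = ",
         paste(sprintf("(%g, %g)", uniq$res, uniq$bval), collapse = ", "),
         " cannot identify intercept, res, bval and interaction effects",
         call. = FALSE)
  }
  qrX <- qr(des$X)
  coefs <- qr.coef(qrX, em$edges)          # 4 x n_edges
  resid <- em$edges - des$X %*% coefs
  dfres <- nrow(des$X) - 4L
  resid_var <- if (dfres > 0) colSums(resid^2) / dfres else rep(NA_real_, ncol(resid))
  betas <- t(coefs)
  colnames(betas) <- c("beta0", "beta1", "beta2", "beta3")
  tr <- stats::aggregate(
    list(count = seq_len(nrow(em$table))),
    by = list(res = em$table$res_mm, bval = em$table$bval),
    FUN = length
  )
  structure(
    list(betas = betas,
         edge_index = em$index,
         region_labels = cohort$parcellation$region_labels,
         training_settings = tr[order(tr$res, tr$bval), ],
         n_obs = nrow(des$X),
         resid_var = unname(resid_var),
         rounding = "half-away-from-zero"),
    class = "harmonization_model"
  )
}

#' @export
print.harmonization_model <- function(x, ...) {
  cat("<harmonization_model>", x$edge_index$n_regions, "regions,",
      x$edge_index$n_edges, "edges, fitted on", x$n_obs, "observations at",
      nrow(x$training_settings), "settings\n")
  invisible(x)
}

#' Harmonize a connectome to a target acquisition setting
#'
#' Applies the fitted per-connection correction
#' \deqn{y_i^{AP_2} = y_i^{AP_1} + \hat\beta_{1i}(X_r^{AP_2} - X_r^{AP_1})
#'   + \hat\beta_{2i}(X_b^{AP_2} - X_b^{AP_1})
#'   + \hat\beta_{3i}(X_r^{AP_2} X_b^{AP_2} - X_r^{AP_1} X_b^{AP_1}),}
#' then — because fiber counts are non-negative integers — rounds to the
#' nearest integer (half away from zero) and sets negative values to zero,
#' in that order.  Harmonizing to the source setting is the identity.
#' Targets outside the convex hull of the training settings trigger an
#' extrapolation warning but proceed: near extrapolation can work, while
#' far extrapolation fails when the true acquisition response is nonlinear
#' (the high-b-value regime).
#'
#' @param connectome A [connectome()] whose source setting is read from its
#'   metadata.
#' @param model A fitted [fit_harmonization()] model on the same
#'   parcellation.
#' @param target Target [acq_setting()].
#' @param integer_output Round and clamp to integer counts (default
#'   `TRUE`).  `FALSE` returns the continuous corrected values (negative
#'   values retained), used for path-consistency and exact-recovery
#'   analyses.
#' @return A [connectome()] at the target setting; `$provenance` records
#'   the source setting.
#' @export
harmonize <- function(connectome, model, target, integer_output = TRUE) {
  stopifnot(inherits(connectome, "connectome"),
            inherits(model, "harmonization_model"),
            inherits(target, "acq_setting"))
  if (!identical(connectome$parcellation$region_labels, model$region_labels)) {
    stop("connectome parcellation does not match the model's region labels",
         call. = FALSE)
  }
  src <- connectome$setting
  if (!in_training_hull(model, target)) {
    warning(sprintf(paste0("target setting (%g, %g) lies outside the convex hull ",
                           "of the training settings: extrapolating"),
                    target$res, target$bval), call. = FALSE)
  }
  y <- vectorize(connectome, model$edge_index)
  delta <- model$betas[, "beta1"] * (target$res - src$res) +
    model$betas[, "beta2"] * (target$bval - src$bval) +
    model$betas[, "beta3"] * (target$res * target$bval - src$res * src$bval)
  corrected <- y + delta
  if (any(!is.finite(corrected))) {
    stop("non-finite corrected values; model coefficients may be degenerate",
         call. = FALSE)
  }
  if (integer_output) {
    corrected <- pmax(round_half_away(corrected), 0)
  }
  out <- connectome(devectorize(corrected, model$edge_index),
                    subject_id = connectome$subject_id,
                    session = connectome$session,
                    setting = target,
                    parcellation = connectome$parcellation,
                    integer = integer_output)
  out$provenance <- list(source_setting = src, harmonized = TRUE)
  out
}

# 2D point-in-convex-hull test on the (res, bval) plane, with graceful
# handling of degenerate hulls (single point, collinear settings)
in_training_hull <- function(model, target, tol = 1e-9) {
  pts <- unique(model$training_settings[, c("res", "bval")])
  p <- c(target$res, target$bval)
  scale <- max(abs(as.matrix(pts)), abs(p), 1)
  eps <- tol * scale
  if (nrow(pts) == 1L) {
    return(all(abs(p - as.numeric(pts[1L, ])) <= eps))
  }
  h <- grDevices::chull(pts$res, pts$bval)
  poly <- as.matrix(pts[h, ])
  if (nrow(poly) < 3L) {
    # collinear settings: point must lie on the segment between extremes
    a <- poly[1L, ]; b <- poly[2L, ]
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (abs(cross) > eps * scale) return(FALSE)
    t <- sum((p - a) * (b - a)) / sum((b - a)^2)
    return(t >= -tol && t <= 1 + tol)
  }
  # chull returns vertices clockwise; point is inside iff every edge cross
  # product has the same (non-positive) sign
  nv <- nrow(poly)
  for (k in seq_len(nv)) {
    a <- poly[k, ]; b <- poly[k %% nv + 1L, ]
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (cross > eps * scale) return(FALSE)
  }
  TRUE
}

#' Save or load a harmonization model as tab-delimited text
#'
#' The model file is self-describing plain text: `#`-prefixed header lines
#' carry the region count, observation count, rounding rule and the
#' training settings with their multiplicities, followed by one row per
#' edge with columns `region_i`, `region_j`, `beta0`..`beta3`, `resid_var`
#' in full decimal precision, in canonical edge order.  `load_model()`
#' reproduces the coefficients bit-exactly.
#'
#' @param model A `harmonization_model`.
#' @param path File path.
#' @return `save_model()`: `path` invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "harmonization_model"))
  idx <- model$edge_index
  header <- c(
    "# connharmony harmonization model v1",
    paste0("# n_regions: ", idx$n_regions),
    paste0("# n_obs: ", model$n_obs),
    paste0("# rounding: ", model$rounding),
    sprintf("# training_setting: %s %s %d",
            format_full(model$training_settings$res),
            format_full(model$training_settings$bval),
            model$training_settings$count)
  )
  labs <- model$region_labels
  rv <- model$resid_var
  if (length(rv) != idx$n_edges) rv <- rep(NA_real_, idx$n_edges)
  body <- paste(labs[idx$i], labs[idx$j],
                format_full(model$betas[, "beta0"]),
                format_full(model$betas[, "beta1"]),
                format_full(model$betas[, "beta2"]),
                format_full(model$betas[, "beta3"]),
                format_full(rv),
                sep = "\t")
  writeLines(c(header,
               "region_i\tregion_j\tbeta0\tbeta1\tbeta2\tbeta3\tresid_var",
               body), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  comments <- lines[startsWith(lines, "#")]
  if (!any(grepl("^# connharmony harmonization model v1", comments))) {
    stop("not a connharmony model file (missing version line): ", path,
         call. = FALSE)
  }
  get_field <- function(name) {
    hit <- grep(paste0("^# ", name, ": "), comments, value = TRUE)
    if (length(hit) != 1L) stop("model file missing header field '", name, "'",
                                call. = FALSE)
    sub(paste0("^# ", name, ": "), "", hit)
  }
  n_regions <- as.integer(get_field("n_regions"))
  n_obs <- as.integer(get_field("n_obs"))
  rounding <- get_field("rounding")
  tr_lines <- grep("^# training_setting: ", comments, value = TRUE)
  tr <- do.call(rbind, lapply(strsplit(sub("^# training_setting: ", "", tr_lines), " "),
                              function(p) data.frame(res = as.numeric(p[1]),
                                                     bval = as.numeric(p[2]),
                                                     count = as.integer(p[3]))))
  content <- lines[!startsWith(lines, "#") & nzchar(lines)]
  cols <- strsplit(content[1L], "\t", fixed = TRUE)[[1L]]
  needed <- c("region_i", "region_j", "beta0", "beta1", "beta2", "beta3")
  missing <- setdiff(needed, cols)
  if (length(missing)) {
    stop("model file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- utils::read.table(text = content[-1L], sep = "\t",
                          col.names = cols, colClasses = "character")
  idx <- upper_triangle_index(n_regions)
  if (nrow(df) != idx$n_edges) {
    stop("model file has ", nrow(df), " edge rows but n_regions ", n_regions,
         " implies ", idx$n_edges, call. = FALSE)
  }
  labs <- unique(c(df$region_i, df$region_j))
  betas <- cbind(beta0 = as.numeric(df$beta0), beta1 = as.numeric(df$beta1),
                 beta2 = as.numeric(df$beta2), beta3 = as.numeric(df$beta3))
  if (any(!is.finite(betas))) stop("model file contains non-finite coefficients",
                                   call. = FALSE)
  rv <- if ("resid_var" %in% names(df)) as.numeric(df$resid_var) else rep(NA_real_, nrow(df))
  structure(
    list(betas = betas, edge_index = idx, region_labels = labs,
         training_settings = tr, n_obs = n_obs, resid_var = rv,
         rounding = rounding),
    class = "harmonization_model"
  )
}
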