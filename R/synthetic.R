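#' Configuration for synthetic connectome cohorts
#'
#' Defines the generative model for simulated structural connectomes.  A
#' cohort shares a group skeleton (a fixed fraction of present edges) with
#' log-normal group-mean fiber counts; each subject adds a Gaussian
#' fingerprint (stable subject-specific edge offsets); acquisition settings
#' shift a configurable fraction of skeleton edges through per-edge linear
#' effects in resolution, b-value, and their interaction (relative to a
#' reference setting), optionally plus a quadratic b-value term to emulate
#' the nonlinear high-b-value regime; finally Gaussian observation noise is
#' added and counts are rounded half away from zero and clamped at zero —
#' the same observation rule the harmonization corrector uses.
#'
#' Defaults emulate the validation cohorts: the 2 x 2 acquisition grid
#' (res 1.25/2.3 mm x bval 1000/3000 s/mm^2) with the higher-bval
#' higher-res setting as reference, traveling subjects, heavy-tailed group
#' counts around 50 fibers, subject fingerprint SD 5 fibers, acquisition
#' effects on 30% of skeleton edges sized so that cross-setting shifts are
#' several times the observation noise (SD 2 fibers).
#'
#' @param n_regions Number of parcellation regions.
#' @param n_subjects Number of subjects.
#' @param density Fraction of present edges (the skeleton), in (0, 1].
#' @param settings_grid List of [acq_setting()].
#' @param design `"traveling"` (every subject at every setting) or
#'   `"single"` (each subject at exactly one setting, assigned round-robin
#'   so the design is balanced when `n_subjects` is a multiple of the grid
#'   size).
#' @param reference_setting [acq_setting()] at which group means are
#'   defined (acquisition effects vanish there).
#' @param mean_count_scale Median group-mean fiber count on the skeleton.
#' @param mean_count_sdlog Log-scale SD of the group means (heavy tail).
#' @param subject_sd SD of subject fingerprints (fibers); 0 removes all
#'   identity signal.
#' @param effect_sd_res,effect_sd_bval,effect_sd_interaction SDs of the
#'   per-edge true effects beta1 (fibers/mm), beta2 (fibers per s/mm^2),
#'   beta3 (fibers per mm * s/mm^2) on affected edges.
#' @param effect_edge_fraction Fraction of skeleton edges carrying
#'   acquisition effects (the rest are null, so false-positive control is
#'   testable in the same cohort).
#' @param nonlinearity `"none"` or `"quadratic"`; `nonlin_coef` is the
#'   quadratic coefficient gamma in fibers/(s/mm^2)^2 applied as
#'   gamma * (X_b - X_b0)^2 on affected edges.
#' @param nonlin_coef See `nonlinearity`.
#' @param noise_sd Observation noise SD (fibers).
#' @param integer_counts Apply the round/clamp observation rule (default
#'   `TRUE`); `FALSE` yields continuous connectomes for exact-recovery
#'   analyses.
#' @param seed Integer seed; all draws derive from it in a fixed order.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_regions = 60,
                       n_subjects = 30,
                       density = 0.35,
                       settings_grid = hcp_settings_grid(),
                       design = c("traveling", "single"),
                       reference_setting = acq_setting(1.25, 3000),
                       mean_count_scale = 50,
                       mean_count_sdlog = 0.75,
                       subject_sd = 5,
                       effect_sd_res = 10,
                       effect_sd_bval = 0.01,
                       effect_sd_interaction = 0.002,
                       effect_edge_fraction = 0.3,
                       nonlinearity = c("none", "quadratic"),
                       nonlin_coef = 0,
                       noise_sd = 2,
                       integer_counts = TRUE,
                       seed = 1L) {
  design <- match.arg(design)
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(n_regions >= 2, n_subjects >= 1,
            density > 0, density <= 1,
            length(settings_grid) >= 1,
            subject_sd >= 0, noise_sd >= 0,
            effect_sd_res >= 0, effect_sd_bval >= 0, effect_sd_interaction >= 0,
            effect_edge_fraction >= 0, effect_edge_fraction <= 1,
            mean_count_scale > 0)
  stopifnot(all(vapply(settings_grid, inherits, logical(1), "acq_setting")))
  if (nonlinearity == "quadratic" && nonlin_coef == 0) {
    warning("quadratic nonlinearity requested with coefficient 0", call. = FALSE)
  }
  structure(
    list(n_regions = as.integer(n_regions), n_subjects = as.integer(n_subjects),
         density = density, settings_grid = settings_grid, design = design,
         reference_setting = reference_setting,
         mean_count_scale = mean_count_scale, mean_count_sdlog = mean_count_sdlog,
         subject_sd = subject_sd,
         effect_sd_res = effect_sd_res, effect_sd_bval = effect_sd_bval,
         effect_sd_interaction = effect_sd_interaction,
         effect_edge_fraction = effect_edge_fraction,
         nonlinearity = nonlinearity, nonlin_coef = nonlin_coef,
         noise_sd = noise_sd, integer_counts = integer_counts,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' The 2 x 2 acquisition grid of the resampled young-adult dataset
#'
#' Settings (res, bval) = (1.25, 1000), (1.25, 3000), (2.3, 1000),
#' (2.3, 3000): the four combinations of 1.25/2.3 mm isotropic resolution
#' and 1000/3000 s/mm^2 b-value.
#'
#' @return List of four [acq_setting()]s.
#' @export
hcp_settings_grid <- function() {
  list(acq_setting(1.25, 1000), acq_setting(1.25, 3000),
       acq_setting(2.3, 1000), acq_setting(2.3, 3000))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws (in a fixed order under the config seed) the skeleton, group
#' means, effect-edge subset, true per-edge effects, subject fingerprints,
#' and observation noise, then assembles one connectome per (subject,
#' assigned setting):
#'
#' `y = group_mean + subject_effect + beta1 (X_r - X_r0) + beta2 (X_b -
#' X_b0) + beta3 (X_r X_b - X_r0 X_b0) [+ gamma (X_b - X_b0)^2] + noise`,
#'
#' rounded half away from zero and clamped at zero (unless
#' `integer_counts = FALSE`).  Edges outside the skeleton are exactly zero
#' at every setting.  Identical configs give bit-identical cohorts.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (a [cohort()]) and `truth` (class
#'   `synthetic_truth`: `skeleton_mask`, `group_means`, `subject_effects`
#'   (subjects x edges), `true_betas` (edges x 3, beta1..beta3),
#'   `nonlin_coef`, `config`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  idx <- upper_triangle_index(cfg$n_regions)
  parc <- default_parcellation(cfg$n_regions)
  subjects <- sprintf("sub-%03d", seq_len(cfg$n_subjects))

  set.seed(cfg$seed)
  # draw order: skeleton, group means, effect edges, betas, fingerprints, noise
  n_skel <- max(1L, round(cfg$density * idx$n_edges))
  skeleton <- sort(sample.int(idx$n_edges, n_skel))
  gm <- numeric(idx$n_edges)
  gm[skeleton] <- stats::rlnorm(n_skel, meanlog = log(cfg$mean_count_scale),
                                sdlog = cfg$mean_count_sdlog)
  n_eff <- round(cfg$effect_edge_fraction * n_skel)
  effect_edges <- if (n_eff > 0) sort(sample(skeleton, n_eff)) else integer(0)
  betas <- matrix(0, idx$n_edges, 3,
                  dimnames = list(NULL, c("beta1", "beta2", "beta3")))
  if (n_eff > 0) {
    betas[effect_edges, "beta1"] <- stats::rnorm(n_eff, 0, cfg$effect_sd_res)
    betas[effect_edges, "beta2"] <- stats::rnorm(n_eff, 0, cfg$effect_sd_bval)
    betas[effect_edges, "beta3"] <- stats::rnorm(n_eff, 0, cfg$effect_sd_interaction)
  }
  subj_eff <- matrix(0, cfg$n_subjects, idx$n_edges)
  if (cfg$subject_sd > 0) {
    subj_eff[, skeleton] <- stats::rnorm(cfg$n_subjects * n_skel, 0, cfg$subject_sd)
  }

  ref <- cfg$reference_setting
  assignments <- if (cfg$design == "traveling") {
    lapply(seq_len(cfg$n_subjects), function(s) seq_along(cfg$settings_grid))
  } else {
    lapply(seq_len(cfg$n_subjects),
           function(s) ((s - 1L) %% length(cfg$settings_grid)) + 1L)
  }

  conns <- list()
  for (s in seq_len(cfg$n_subjects)) {
    for (g in assignments[[s]]) {
      st <- cfg$settings_grid[[g]]
      y <- gm + subj_eff[s, ] +
        betas[, "beta1"] * (st$res - ref$res) +
        betas[, "beta2"] * (st$bval - ref$bval) +
        betas[, "beta3"] * (st$res * st$bval - ref$res * ref$bval)
      if (cfg$nonlinearity == "quadratic" && length(effect_edges)) {
        y[effect_edges] <- y[effect_edges] +
          cfg$nonlin_coef * (st$bval - ref$bval)^2
      }
      if (cfg$noise_sd > 0) {
        y[skeleton] <- y[skeleton] + stats::rnorm(n_skel, 0, cfg$noise_sd)
      }
      off <- setdiff(seq_len(idx$n_edges), skeleton)
      y[off] <- 0
      if (cfg$integer_counts) {
        y <- pmax(round_half_away(y), 0)
      }
      conns[[length(conns) + 1L]] <- connectome(
        devectorize(y, idx), subject_id = subjects[s], session = "1",
        setting = st, parcellation = parc, integer = cfg$integer_counts)
    }
  }
  truth <- structure(
    list(skeleton_mask = seq_len(idx$n_edges) %in% skeleton,
         group_means = gm,
         subject_effects = subj_eff,
         true_betas = betas,
         effect_edges = effect_edges,
         nonlin_coef = if (cfg$nonlinearity == "quadratic") cfg$nonlin_coef else 0,
         config = cfg),
    class = "synthetic_truth"
  )
  list(cohort = cohort(conns), truth = truth)
}

#' Preset: traveling-subject cohort on the 2 x 2 acquisition grid
#'
#' Convenience wrapper for [generate_cohort()] with the four-setting grid
#' (1.25/2.3 mm x 1000/3000 s/mm^2), traveling design and reference
#' (1.25, 3000); any [sim_config()] argument can be overridden.  150
#' traveling subjects yield the 600-observation training design; the
#' `"single"` design with 150 subjects yields 150 independent
#' observations.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return As [generate_cohort()].
#' @export
make_2x2_cohort <- function(...) {
  args <- list(...)
  args$settings_grid <- args$settings_grid %||% hcp_settings_grid()
  args$reference_setting <- args$reference_setting %||% acq_setting(1.25, 3000)
  generate_cohort(do.call(sim_config, args))
}

#' Preset: extrapolation scenario with quadratic b-value misspecification
#'
#' Emulates transferring a linearly-fitted model to acquisitions far
#' outside its b-value training range, where a nonlinear b-value response
#' makes far extrapolation fail.  Subjects travel over the 2 x 2 training
#' grid (bval <= 3000) plus two held-out targets at the training
#' resolution floor: a near b-value (default 2000, inside the hull) and a
#' far one (default 8000).  A quadratic term gamma (X_b - X_b0)^2 acts on
#' the effect edges, so the linear model is correct on the training grid
#' span but increasingly wrong with distance in b-value.
#'
#' @param near_bval,far_bval Held-out target b-values (s/mm^2).
#' @param target_res Resolution of the held-out targets (mm).
#' @param nonlin_coef Quadratic coefficient gamma (default 2e-6
#'   fibers/(s/mm^2)^2: about 50 fibers at 5000 s/mm^2 from the reference,
#'   2 at 1000).
#' @param ... Further [sim_config()] overrides.
#' @return List with `cohort` (all settings), `truth`, `train_settings`
#'   (the 2 x 2 grid), `source_setting` (2.3, 1000), `near_setting`,
#'   `far_setting`.
#' @export
make_extrapolation_scenario <- function(near_bval = 2000, far_bval = 8000,
                                        target_res = 2.3, nonlin_coef = 2e-6,
                                        ...) {
  train_grid <- hcp_settings_grid()
  near <- acq_setting(target_res, near_bval)
  far <- acq_setting(target_res, far_bval)
  args <- list(...)
  args$settings_grid <- c(train_grid, list(near, far))
  args$reference_setting <- args$reference_setting %||% acq_setting(1.25, 3000)
  args$nonlinearity <- "quadratic"
  args$nonlin_coef <- nonlin_coef
  out <- generate_cohort(do.call(sim_config, args))
  c(out, list(train_settings = train_grid,
              source_setting = acq_setting(2.3, 1000),
              near_setting = near, far_setting = far))
}

#' Write the ground truth of a synthetic cohort as TSV
#'
#' One row per edge: regions, skeleton flag, group mean, true beta1..beta3.
#'
#' @param truth A `synthetic_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  idx <- upper_triangle_index(truth$config$n_regions)
  labs <- default_parcellation(truth$config$n_regions)$region_labels
  df <- data.frame(
    region_i = labs[idx$i], region_j = labs[idx$j],
    skeleton = as.integer(truth$skeleton_mask),
    group_mean = format_full(truth$group_means),
    beta1 = format_full(truth$true_betas[, "beta1"]),
    beta2 = format_full(truth$true_betas[, "beta2"]),
    beta3 = format_full(truth$true_betas[, "beta3"]),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
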