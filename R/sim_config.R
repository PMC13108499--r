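#' Configuration for the synthetic cohort generator
#'
#' Defaults are the study conditions the pipeline is designed around: a
#' 360-parcel cortex with 12 networks and 8 CCC parcels, 48 subjects, 150-TR
#' resting scans at TR = 2 s with two sessions, a distributed mixing weight of
#' 0.75 and a planted vergence specificity ratio of 1.5. The reduced test
#' scale (P = 60, n = 8) is available via [sim_config_small].
#'
#' @param P Number of parcels (even, >= 24).
#' @param n_subjects Cohort size.
#' @param T_rest Resting frames per session.
#' @param tr Repetition time, seconds.
#' @param sessions Resting sessions per subject (1 or 2).
#' @param density_within,strength_within Edge probability and magnitude of
#'   within-network ground-truth precision entries (entries are negative, so
#'   true partial correlations are positive).
#' @param density_between,strength_between Same for cross-network edges.
#' @param ccc_vis2_density,ccc_vis2_strength Planted edges from each CCC parcel
#'   to same-hemisphere secondary-visual (VIS2) parcels: the dominant
#'   distributed pathway.
#' @param ccc_dan_density,ccc_dan_strength Planted edges to same-hemisphere
#'   dorsal-attention (DAN) parcels: the second pathway.
#' @param ar Temporal AR(1) coefficient of the latent resting signal.
#' @param noise_sd Observation noise sd added to the resting series.
#' @param lambda_distributed Mixing weight of the distributed (activity-flow)
#'   component in CCC activations, in `[0, 1]`.
#' @param specificity_ratio Planted VM/VS specificity ratio of the actual CCC
#'   activations (> 0).
#' @param network_gains Named vector over the 12 networks of source activation
#'   gains; VIS2 > DAN > VIS1 > rest by default, planting the expected network
#'   contribution ordering.
#' @param source_beta_sd Subject-level i.i.d. noise sd on source-parcel betas.
#' @param local_noise_sd Sd of the i.i.d. local noise (orthogonalized against
#'   the flow profile) added to CCC local components.
#' @param ccc_beta_sd Sd of residual noise on CCC betas.
#' @param task_noise_sd,task_ar Sd and AR(1) coefficient of task-run noise.
#' @param confound_load_sd Sd of per-parcel loadings on the base confound
#'   regressors.
#' @param motion_step_sd Sd of the motion random-walk increments (mm).
#' @param spike_rate Expected fraction of frames with frame-wise displacement
#'   above 0.25 mm.
#' @param seed Master seed for the cohort.
#' @return A `sim_config` list.
#' @export
sim_config <- function(P = 360, n_subjects = 48, T_rest = 150, tr = 2,
                       sessions = 2,
                       density_within = 0.20, strength_within = 1.00,
                       density_between = 0.01, strength_between = 0.40,
                       ccc_vis2_density = 1.0, ccc_vis2_strength = 0.70,
                       ccc_dan_density = 1.0, ccc_dan_strength = 0.50,
                       ar = 0.3, noise_sd = 0.2,
                       lambda_distributed = 0.75, specificity_ratio = 1.5,
                       network_gains = c(VIS1 = 0.8, VIS2 = 1.8, SMN = 0.4,
                                         CON = 0.5, DAN = 1.0, LAN = 0.4,
                                         FPN = 0.4, AUD = 0.4, DMN = 0.4,
                                         PMM = 0.4, VMM = 0.4, ORA = 0.4),
                       source_beta_sd = 0.10, local_noise_sd = 0.10,
                       ccc_beta_sd = 0.05,
                       task_noise_sd = 0.35, task_ar = 0.3,
                       confound_load_sd = 0.10, motion_step_sd = 0.02,
                       spike_rate = 0.03, seed = 1L) {
  cfg <- list(P = P, n_subjects = n_subjects, T_rest = T_rest, tr = tr,
              sessions = sessions,
              density_within = density_within, strength_within = strength_within,
              density_between = density_between, strength_between = strength_between,
              ccc_vis2_density = ccc_vis2_density, ccc_vis2_strength = ccc_vis2_strength,
              ccc_dan_density = ccc_dan_density, ccc_dan_strength = ccc_dan_strength,
              ar = ar, noise_sd = noise_sd,
              lambda_distributed = lambda_distributed,
              specificity_ratio = specificity_ratio,
              network_gains = network_gains,
              source_beta_sd = source_beta_sd, local_noise_sd = local_noise_sd,
              ccc_beta_sd = ccc_beta_sd,
              task_noise_sd = task_noise_sd, task_ar = task_ar,
              confound_load_sd = confound_load_sd, motion_step_sd = motion_step_sd,
              spike_rate = spike_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param ... Overrides passed on to [sim_config].
#' @export
sim_config_small <- function(...) {
  args <- list(...)
  defaults <- list(P = 60, n_subjects = 8)
  do.call(sim_config, utils::modifyList(defaults, args))
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$P) || cfg$P < 24 || cfg$P %% 2 != 0)
    stop_vf("P must be an even count >= 24")
  if (cfg$P / 2 < 12) stop_vf("P too small: need at least one parcel per network per hemisphere")
  if (!is_count(cfg$n_subjects) || cfg$n_subjects < 1)
    stop_vf("n_subjects must be a positive count")
  if (cfg$T_rest < 50) stop_vf("T_rest must be >= 50")
  if (cfg$tr <= 0) stop_vf("tr must be positive")
  if (!cfg$sessions %in% c(1, 2)) stop_vf("sessions must be 1 or 2")
  for (f in c("density_within", "density_between", "ccc_vis2_density",
              "ccc_dan_density")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop_vf("%s must be in [0, 1]", f)
  }
  if (cfg$lambda_distributed < 0 || cfg$lambda_distributed > 1)
    stop_vf("lambda_distributed must be in [0, 1]")
  if (cfg$specificity_ratio <= 0) stop_vf("specificity_ratio must be > 0")
  if (abs(cfg$ar) >= 1 || abs(cfg$task_ar) >= 1)
    stop_vf("AR coefficients must lie in (-1, 1)")
  if (!setequal(names(cfg$network_gains), NETWORKS))
    stop_vf("network_gains must name all 12 networks")
  if (any(cfg$network_gains <= 0)) stop_vf("network_gains must be positive")
  invisible(cfg)
}
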