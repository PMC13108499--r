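#' The study's block designs for the four tasks
#'
#' VM (vergence motor) runs have five 19-s VM-many blocks and five 18-s VM-few
#' blocks in 208 TRs; VS (vergence sensory) five 22-s VS-many and five 18-s
#' VS-few blocks in 208 TRs; SM (saccadic motor) five 24-s blocks of each
#' condition in 208 TRs; FT (finger tapping) three 20-s blocks of each
#' condition in 92 TRs. TR is 2 s throughout. Blocks alternate conditions and
#' are separated by evenly spread rest gaps that fill the run to its printed
#' frame count (gap placement is a reproducibility choice; the task seconds
#' are fixed).
#'
#' @return Named list of [task_design] objects: `VM` (used for both VM runs),
#'   `VS`, `SM`, `FT`.
#' @export
make_designs <- function() {
  build <- function(cond_a, dur_a, cond_b, dur_b, n_blocks_each, n_tr, tr = 2) {
    durs <- rep(c(dur_a, dur_b), n_blocks_each)
    conds <- rep(c(cond_a, cond_b), n_blocks_each)
    n_blocks <- length(durs)
    gap_total <- n_tr * tr - sum(durs)
    if (gap_total < 0) stop_vf("blocks exceed run length")
    # n_blocks + 1 gaps (before, between, after), spread as equal integers
    n_gaps <- n_blocks + 1
    gaps <- rep(gap_total %/% n_gaps, n_gaps)
    rem <- gap_total - sum(gaps)
    if (rem > 0) gaps[seq_len(rem)] <- gaps[seq_len(rem)] + 1
    onsets <- cumsum(gaps[-n_gaps] + c(0, durs[-n_blocks]))
    task_design(data.frame(condition = conds, onset_s = onsets,
                           duration_s = durs),
                n_timepoints = n_tr, tr = tr,
                condition_set = c(cond_a, cond_b))
  }
  list(VM = build("VM-many", 19, "VM-few", 18, 5, 208),
       VS = build("VS-many", 22, "VS-few", 18, 5, 208),
       SM = build("SM-fast", 24, "SM-slow", 24, 5, 208),
       FT = build("FT-fast", 20, "FT-slow", 20, 3, 92))
}

#' Plant per-subject true activations
#'
#' Source (non-CCC) parcels get condition betas `gain * source_profile` plus
#' i.i.d. subject noise. Each CCC parcel's beta vector is the planted mixture
#' `lambda * flow + (1 - lambda) * local + noise`, where `flow` is the exact
#' activity-flow sum of the realized source betas through the true partial
#' correlations (all eight CCC parcels excluded as sources), and `local` is the
#' parcel's flow gain times the local condition profile plus i.i.d. noise
#' orthogonalized against the realized flow profile. The calibration in
#' [make_ground_truth_fc] makes the expected actual VM/VS ratio equal the
#' planted `specificity_ratio` and the distributed share of it equal
#' `lambda_distributed`.
#'
#' @param gt A [make_ground_truth_fc] result.
#' @param parcels The [parcel_table].
#' @param cfg A [sim_config].
#' @param subject_seed Seed for this subject's draws.
#' @return An [activation_matrix] (P x 8) of true betas.
#' @export
make_task_activations <- function(gt, parcels, cfg,
                                  subject_seed = cfg$seed) {
  P <- nrow(parcels)
  ccc <- parcels$is_ccc
  gains <- cfg$network_gains[parcels$network]
  with_seed(derive_seed(subject_seed, "activations"), {
    act <- outer(gains, gt$source_profile) +
      matrix(rnorm(P * 8, sd = cfg$source_beta_sd), P, 8)
    act[ccc, ] <- 0
    lambda <- gt$lambda_distributed
    wbar <- mean(abs(gt$flow_gain[ccc]))
    for (j in which(ccc)) {
      flow <- as.numeric(crossprod(act[!ccc, , drop = FALSE],
                                   gt$true_partial_corr[!ccc, j]))
      eta <- rnorm(8, sd = cfg$local_noise_sd * wbar)
      if (sum(flow^2) > 0)
        eta <- eta - sum(eta * flow) / sum(flow^2) * flow
      local <- gt$flow_gain[j] * gt$local_profile + eta
      act[j, ] <- lambda * flow + (1 - lambda) * local +
        rnorm(8, sd = cfg$ccc_beta_sd * wbar)
    }
    activation_matrix(act, CONDITIONS)
  })
}

#' Simulate a task run from planted betas
#'
#' The clean signal is the HRF-convolved design times the planted betas (the
#' same design-matrix builder the GLM stage uses, so noiseless runs are
#' recovered exactly); confound-coupled signal and AR(1) noise are added on
#' top, and the generated confound table includes motion with occasional
#' displacement spikes.
#'
#' @param design A [task_design].
#' @param true_betas P x C matrix of betas for `design$condition_set` (columns
#'   matched by name from a full [activation_matrix]).
#' @param cfg A [sim_config].
#' @param seed Seed for this run.
#' @param run_id,state Identifiers stored on the series.
#' @return List with `ts` (a [time_series_matrix]) and `confounds`
#'   (a `confound_table`).
#' @export
simulate_task_runs <- function(design, true_betas, cfg, seed,
                               run_id = NA_character_, state = "task") {
  X <- build_design_matrix(design, tr = design$tr)
  B <- true_betas[, design$condition_set, drop = FALSE]
  vals <- B %*% t(X)
  P <- nrow(vals); Tn <- ncol(vals)
  confounds <- simulate_confounds(Tn, cfg, derive_seed(seed, "confounds"))
  vals <- add_confound_signal(vals, confounds, cfg, derive_seed(seed, "loads"))
  noise <- with_seed(derive_seed(seed, "noise"), {
    E <- matrix(rnorm(P * Tn, sd = cfg$task_noise_sd), P, Tn)
    if (cfg$task_ar != 0 && Tn > 1) {
      scale <- sqrt(1 - cfg$task_ar^2)
      for (t in 2:Tn) E[, t] <- cfg$task_ar * E[, t - 1] + scale * E[, t]
    }
    E
  })
  ts <- time_series_matrix(vals + noise, tr = design$tr, run_id = run_id,
                           state = state)
  list(ts = ts, confounds = confounds)
}
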