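#' Simulate a resting-state run from the ground truth
#'
#' Draws a stationary AR(1) latent process whose marginal covariance equals
#' the ground-truth covariance (innovations are scaled by
#' \eqn{\sqrt{1-\phi^2}}), then adds white observation noise, so the observed
#' series has covariance \eqn{\Sigma + \sigma^2 I}. The two sessions of the
#' repeated-scan workflow use independent noise streams derived from the same
#' ground truth.
#'
#' @param gt A [make_ground_truth_fc] result.
#' @param cfg A [sim_config].
#' @param session Session index (1 or 2).
#' @param seed Seed for this run's noise stream.
#' @return A [time_series_matrix] (P x T_rest, state `"rest"`).
#' @export
simulate_rest <- function(gt, cfg, session = 1L, seed = cfg$seed) {
  if (cfg$T_rest < 50) stop_vf("T_rest must be >= 50")
  P <- nrow(gt$precision)
  Tn <- cfg$T_rest
  phi <- cfg$ar
  L <- chol(gt$covariance)
  vals <- with_seed(derive_seed(seed, "rest", session), {
    E <- matrix(rnorm(Tn * P), Tn, P) %*% L   # rows ~ N(0, Sigma)
    Z <- matrix(0, Tn, P)
    Z[1, ] <- E[1, ]
    scale <- sqrt(1 - phi^2)
    for (t in 2:Tn) Z[t, ] <- phi * Z[t - 1, ] + scale * E[t, ]
    t(Z) + cfg$noise_sd * matrix(rnorm(Tn * P), P, Tn)
  })
  time_series_matrix(vals, tr = cfg$tr, run_id = sprintf("rest%d", session),
                     state = "rest")
}

# simulate base motion + compcor regressors and expand to a confound table;
# spike frames are level shifts in one translation so that exactly those
# frames exceed the 0.25-mm displacement threshold
simulate_confounds <- function(n_frames, cfg, seed) {
  with_seed(seed, {
    # translations step in mm; rotations in radians, scaled so their
    # displacement contribution on a 50-mm sphere matches the translations
    step_sd <- cfg$motion_step_sd * rep(c(1, 1 / 50), each = 3)
    motion <- apply(matrix(rnorm(n_frames * 6) *
                             rep(step_sd, each = n_frames),
                           n_frames, 6), 2, cumsum)
    spikes <- runif(n_frames) < cfg$spike_rate
    spikes[1] <- FALSE
    if (any(spikes)) {
      jump <- sample(c(-0.6, 0.6), sum(spikes), replace = TRUE)
      shift <- numeric(n_frames)
      shift[spikes] <- jump
      motion[, 1] <- motion[, 1] + cumsum(shift)
    }
    compcor <- matrix(0, n_frames, 5)
    compcor[1, ] <- rnorm(5)
    for (t in 2:n_frames)
      compcor[t, ] <- 0.5 * compcor[t - 1, ] + rnorm(5, sd = sqrt(0.75))
    confound_table(motion, compcor)
  })
}

# add confound-coupled signal to a parcels x frames matrix: per-parcel
# loadings on the 11 base regressors (6 motion + 5 compcor)
add_confound_signal <- function(vals, confounds, cfg, seed) {
  base <- as.matrix(confounds[, c(MOTION_COLS, COMPCOR_COLS)])
  loads <- with_seed(seed, matrix(rnorm(nrow(vals) * ncol(base),
                                        sd = cfg$confound_load_sd),
                                  nrow(vals), ncol(base)))
  vals + loads %*% t(base)
}
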