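#' Canonical double-gamma haemodynamic response function
#'
#' The SPM-style canonical HRF: a gamma response with 6-s delay minus a 16-s
#' undershoot at 1/6 amplitude (both with unit dispersion), sampled on a
#' 32-s support and normalized to peak 1.
#'
#' @param tr Sampling interval in seconds.
#' @param duration Kernel support in seconds (default 32).
#' @return Numeric vector `h(t)` at `t = 0, tr, 2*tr, ...`.
#' @export
canonical_hrf <- function(tr, duration = 32) {
  if (tr <= 0) stop_vf("tr must be positive")
  t <- seq(0, duration, by = tr)
  h <- dgamma(t, shape = 6, scale = 1) - dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

#' Build an HRF-convolved design matrix for one run
#'
#' One column per condition: the block boxcar is built on a fine time grid
#' (0.1 s), convolved with the canonical HRF, and sampled at frame acquisition
#' times. Condition columns only; intercept/drift terms are added by
#' [estimate_betas] per run.
#'
#' @param design A [task_design].
#' @param tr Repetition time in seconds.
#' @param dt Microtime resolution for the convolution grid.
#' @return T x C numeric matrix with condition column names.
#' @export
build_design_matrix <- function(design, tr = design$tr, dt = 0.1) {
  conds <- design$condition_set
  if (length(conds) == 0L) stop_vf("design has no conditions")
  run_s <- design$n_timepoints * tr
  grid <- seq(0, run_s, by = dt)
  h <- canonical_hrf(dt)
  X <- matrix(0, design$n_timepoints, length(conds),
              dimnames = list(NULL, conds))
  frame_t <- (seq_len(design$n_timepoints) - 1) * tr
  for (k in seq_along(conds)) {
    u <- numeric(length(grid))
    b <- design$blocks[design$blocks$condition == conds[k], , drop = FALSE]
    for (r in seq_len(nrow(b)))
      u[grid >= b$onset_s[r] & grid < b$onset_s[r] + b$duration_s[r]] <- 1
    conv <- stats::convolve(u, rev(h), type = "open")[seq_along(grid)] * dt
    X[, k] <- conv[round(frame_t / dt) + 1]
  }
  X
}

#' Denoise a parcel time series by nuisance regression
#'
#' Drops the initial frames (five for resting scans, none for task runs),
#' then regresses out, per parcel: an intercept, a linear trend, the 44
#' motion/physiological nuisance columns, and (for resting data) one indicator
#' column per spike frame. Residuals are returned; they have zero mean, are
#' orthogonal to every nuisance column, and spike-frame rows are exactly zero.
#'
#' @param ts A [time_series_matrix] (P x T).
#' @param confounds A `confound_table` with T rows.
#' @param spikes Optional logical mask of spike frames (length T); supply
#'   `compute_fd(...)$spikes` for resting data, `NULL` for task runs.
#' @param drop_initial Number of initial frames to discard (rest: 5; task: 0).
#' @return A [time_series_matrix] of residuals with `T - drop_initial` frames.
#' @export
denoise <- function(ts, confounds, spikes = NULL, drop_initial = 0) {
  Tn <- ncol(ts)
  validate_confounds(confounds, Tn)
  if (!is.null(spikes) && length(spikes) != Tn)
    stop_vf("spike mask length %d does not match %d frames", length(spikes), Tn)
  keep <- seq_len(Tn) > drop_initial
  Y <- t(unclass(ts)[, keep, drop = FALSE])
  nuis <- as.matrix(confounds[keep, nuisance_columns(confounds), drop = FALSE])
  n <- nrow(Y)
  X <- cbind(intercept = 1, trend = seq_len(n) - (n + 1) / 2, nuis)
  if (!is.null(spikes)) {
    sp <- which(spikes[keep])
    if (length(sp)) {
      S <- matrix(0, n, length(sp),
                  dimnames = list(NULL, paste0("spike_", sp)))
      S[cbind(sp, seq_along(sp))] <- 1
      X <- cbind(X, S)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_vf("nuisance matrix is rank deficient (collinear columns: %s)",
            paste(dropped, collapse = ", "))
  }
  resid <- Y - X %*% qr.coef(qrX, Y)
  time_series_matrix(t(resid), tr = attr(ts, "tr"),
                     subject_id = attr(ts, "subject_id"),
                     run_id = attr(ts, "run_id"), state = attr(ts, "state"))
}

#' Estimate condition betas by ordinary least squares
#'
#' Fits, per parcel, the HRF-convolved condition regressors plus a per-run
#' intercept and linear drift. Multiple runs of the same task are concatenated:
#' condition columns are shared across runs, intercept/drift columns are
#' per-run. Only the condition betas are returned.
#'
#' @param ts_list List of (denoised) [time_series_matrix] runs.
#' @param design_list List of matching [task_design]s (conditions must agree).
#' @return P x C matrix of betas with condition column names.
#' @export
estimate_betas <- function(ts_list, design_list) {
  if (!is.list(ts_list) || inherits(ts_list, "time_series_matrix"))
    ts_list <- list(ts_list)
  if (inherits(design_list, "task_design")) design_list <- list(design_list)
  if (length(ts_list) != length(design_list))
    stop_vf("need one design per run")
  conds <- design_list[[1]]$condition_set
  Xs <- list(); Ys <- list()
  for (r in seq_along(ts_list)) {
    d <- design_list[[r]]
    if (!identical(d$condition_set, conds))
      stop_vf("runs have differing condition sets")
    if (d$n_timepoints != ncol(ts_list[[r]]))
      stop_vf("design has %d frames but run %d has %d",
              d$n_timepoints, r, ncol(ts_list[[r]]))
    Xs[[r]] <- build_design_matrix(d)
    Ys[[r]] <- t(unclass(ts_list[[r]]))
  }
  n_runs <- length(Xs)
  Xcond <- do.call(rbind, Xs)
  run_lens <- vapply(Xs, nrow, integer(1))
  run_id <- rep(seq_len(n_runs), run_lens)
  Xnuis <- matrix(0, sum(run_lens), 2 * n_runs)
  for (r in seq_len(n_runs)) {
    idx <- run_id == r
    Xnuis[idx, 2 * r - 1] <- 1
    Xnuis[idx, 2 * r] <- seq_len(sum(idx)) - (sum(idx) + 1) / 2
  }
  X <- cbind(Xcond, Xnuis)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_vf("GLM design matrix is rank deficient")
  beta <- qr.coef(qrX, do.call(rbind, Ys))
  out <- t(beta[seq_along(conds), , drop = FALSE])
  colnames(out) <- conds
  out
}

#' Denoise all runs of a subject and estimate the P x 8 activation matrix
#'
#' Applies [denoise] to each task run (no spike regressors, no dropped frames;
#' spike handling is a resting-state step), concatenates the two VM runs, fits
#' the per-task GLMs, and assembles the activation matrix over the eight
#' conditions in canonical order.
#'
#' @param ds A validated [subject_dataset].
#' @return An [activation_matrix] (P x 8).
#' @export
subject_activations <- function(ds) {
  betas <- list()
  for (task in c("VM", "VS", "SM", "FT")) {
    runs <- ds$tasks[[task]]$runs
    ts_list <- lapply(runs, function(r) denoise(r$ts, r$confounds))
    design_list <- lapply(runs, `[[`, "design")
    betas[[task]] <- estimate_betas(ts_list, design_list)
  }
  all_b <- do.call(cbind, betas)
  colnames(all_b) <- unlist(lapply(betas, colnames), use.names = FALSE)
  activation_matrix(all_b[, CONDITIONS, drop = FALSE], CONDITIONS)
}

#' Denoise a resting run with spike regressors
#'
#' Convenience wrapper: computes frame-wise displacement from the confounds'
#' motion columns, drops the first `drop_initial` frames, and runs [denoise]
#' with spike indicator columns for frames exceeding 0.25 mm.
#'
#' @param ts A resting [time_series_matrix].
#' @param confounds Matching `confound_table`.
#' @param drop_initial Initial frames to discard (default 5).
#' @return A denoised [time_series_matrix].
#' @export
denoise_rest <- function(ts, confounds, drop_initial = 5) {
  spikes <- compute_fd(as.matrix(confounds[, MOTION_COLS]))$spikes
  denoise(ts, confounds, spikes = spikes, drop_initial = drop_initial)
}
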