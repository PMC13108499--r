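MOTION_COLS <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
COMPCOR_COLS <- paste0("a_comp_cor_", 1:5)

# derivative (backward difference, first frame 0) and quadratic expansions
expand_nuisance <- function(base) {
  d <- apply(base, 2, function(v) c(0, diff(v)))
  out <- cbind(base, d, base^2, d^2)
  colnames(out) <- c(colnames(base), paste0(colnames(base), "_derivative1"),
                     paste0(colnames(base), "_power2"),
                     paste0(colnames(base), "_derivative1_power2"))
  out
}

#' Construct a confound table from base regressors
#'
#' Expands 6 rigid-body motion parameters and 5 anatomical-CompCor components
#' into the standard 44-column nuisance set (each base column plus its
#' temporal derivative, square, and squared derivative: 24 motion + 20
#' physiological regressors), and appends frame-wise displacement computed
#' from the motion parameters.
#'
#' @param motion T x 6 matrix of motion parameters (translations in mm,
#'   rotations in radians), columns ordered `trans_x..rot_z`.
#' @param compcor T x 5 matrix of aCompCor component time series.
#' @return A `confound_table` data.frame with 44 nuisance columns plus `fd`.
#' @export
confound_table <- function(motion, compcor) {
  motion <- as.matrix(motion); compcor <- as.matrix(compcor)
  if (ncol(motion) != 6L) stop_vf("motion must have 6 columns")
  if (ncol(compcor) != 5L) stop_vf("compcor must have 5 columns")
  if (nrow(motion) != nrow(compcor))
    stop_vf("motion and compcor must have the same number of frames")
  colnames(motion) <- MOTION_COLS
  colnames(compcor) <- COMPCOR_COLS
  out <- as.data.frame(cbind(expand_nuisance(motion), expand_nuisance(compcor)))
  out$fd <- compute_fd(motion)$fd
  class(out) <- c("confound_table", "data.frame")
  out
}

# names of the 44 nuisance columns (everything but fd)
nuisance_columns <- function(confounds) setdiff(names(confounds), "fd")

validate_confounds <- function(confounds, n_frames) {
  if (!inherits(confounds, "data.frame"))
    stop_vf("confounds must be a data.frame")
  if (nrow(confounds) != n_frames)
    stop_vf("confounds have %d rows but the run has %d frames",
            nrow(confounds), n_frames)
  if (length(nuisance_columns(confounds)) != 44L)
    stop_vf("expected exactly 44 nuisance columns, found %d",
            length(nuisance_columns(confounds)))
  invisible(confounds)
}

#' Frame-wise displacement and spike mask from motion parameters
#'
#' Relative (frame-to-frame) root-mean-square displacement: the RMS of the six
#' motion-parameter differences, with rotations (radians) converted to mm of
#' arc on a 50-mm sphere. The first frame has displacement 0 by convention.
#' Frames are flagged as spikes where displacement strictly exceeds the
#' threshold.
#'
#' @param motion T x 6 matrix (translations mm, rotations radians).
#' @param threshold_mm Spike threshold in mm; the field-standard 0.25 by
#'   default. Flagging is strict (`> threshold`, not `>=`).
#' @param head_radius_mm Sphere radius for rotation-to-mm conversion.
#' @return List with `fd` (length-T numeric) and `spikes` (logical mask).
#' @export
compute_fd <- function(motion, threshold_mm = 0.25, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop_vf("motion must have 6 columns")
  if (nrow(motion) < 2L) stop_vf("need at least 2 frames")
  d <- diff(motion)
  d[, 4:6] <- d[, 4:6] * head_radius_mm
  fd <- c(0, sqrt(rowSums(d^2)))
  list(fd = fd, spikes = fd > threshold_mm)
}
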