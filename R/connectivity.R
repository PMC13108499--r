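#' Resting-state functional connectivity by cross-validated graphical lasso
#'
#' Standardizes each parcel series (mean 0, sd 1, so the L1 penalty is
#' scale-free), splits the timepoints into contiguous blocks (respecting
#' temporal autocorrelation), and selects the lasso penalty from a log-spaced
#' grid by held-out Gaussian log-likelihood
#' \eqn{\log\det\Theta - \mathrm{tr}(S_{test}\Theta)}. The final model is
#' refit on all frames at the selected penalty and the precision matrix is
#' converted to partial correlations \eqn{-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}}.
#'
#' @param rest A denoised resting [time_series_matrix] (P x T).
#' @param folds Number of contiguous cross-validation blocks (default 5).
#' @param alphas Optional penalty grid; by default 20 log-spaced values from
#'   the maximum absolute off-diagonal covariance down to 1% of it.
#' @param n_alpha Grid size when `alphas` is NULL.
#' @param standardize Standardize parcel series before estimation.
#' @param session_id Stored on the result for provenance.
#' @return An [fc_matrix] (method `"glasso"`) with attributes `alpha`
#'   (selected penalty) and `cv` (per-penalty mean held-out log-likelihood).
#' @export
fc_glasso <- function(rest, folds = 5, alphas = NULL, n_alpha = 20,
                      standardize = TRUE, session_id = NA_character_) {
  X <- t(unclass(rest))
  Tn <- nrow(X); P <- ncol(X)
  if (folds < 2 || folds > Tn - 1)
    stop_vf("folds must satisfy 2 <= folds <= T - 1")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop_vf("constant parcel series: parcel %s",
            paste(which(sds == 0), collapse = ", "))
  if (standardize) X <- scale(X)
  if (is.null(alphas)) {
    S_all <- crossprod(X) / Tn
    a_max <- max(abs(S_all - diag(diag(S_all))))
    alphas <- exp(seq(log(a_max), log(a_max * 0.01), length.out = n_alpha))
  }
  alphas <- sort(alphas, decreasing = TRUE) # warm-start path, dense last
  fold_id <- cut(seq_len(Tn), breaks = folds, labels = FALSE)
  cv_ll <- matrix(NA_real_, folds, length(alphas))
  any_converged <- logical(length(alphas))
  for (f in seq_len(folds)) {
    tr_idx <- fold_id != f
    S_tr <- crossprod(X[tr_idx, , drop = FALSE]) / sum(tr_idx)
    S_te <- crossprod(X[!tr_idx, , drop = FALSE]) / sum(!tr_idx)
    W <- NULL
    for (a in seq_along(alphas)) {
      fit <- glasso_fit(S_tr, alphas[a], W_init = W)
      W <- fit$W
      if (!fit$converged) next
      any_converged[a] <- TRUE
      ev <- determinant(fit$Theta, logarithm = TRUE)
      if (ev$sign <= 0) next
      cv_ll[f, a] <- as.numeric(ev$modulus) - sum(S_te * fit$Theta)
    }
  }
  if (!any(any_converged))
    stop_vf("graphical lasso failed to converge at every penalty (grid %s)",
            paste(signif(alphas, 3), collapse = ", "))
  mean_ll <- colMeans(cv_ll)
  best <- which.max(mean_ll)
  S_all <- crossprod(X) / Tn
  final <- glasso_fit(S_all, alphas[best])
  if (!final$converged)
    stop_vf("graphical lasso failed to converge at the selected penalty %.4g",
            alphas[best])
  pc <- precision_to_partial(final$Theta)
  out <- fc_matrix(pc, method = "glasso",
                   subject_id = attr(rest, "subject_id"),
                   session_id = session_id)
  attr(out, "alpha") <- alphas[best]
  attr(out, "cv") <- data.frame(alpha = alphas, mean_loglik = mean_ll)
  out
}

# precision matrix -> partial correlations with zero diagonal
precision_to_partial <- function(Theta) {
  pc <- -Theta / sqrt(tcrossprod(diag(Theta)))
  diag(pc) <- 0
  pc <- (pc + t(pc)) / 2
  pc[pc > 1] <- 1
  pc[pc < -1] <- -1
  pc
}

#' Pairwise Pearson correlation FC (comparison method)
#'
#' @param rest A denoised resting [time_series_matrix] (P x T, T >= 3).
#' @param session_id Stored for provenance.
#' @return An [fc_matrix] (method `"pearson"`).
#' @export
fc_pearson <- function(rest, session_id = NA_character_) {
  X <- t(unclass(rest))
  if (nrow(X) < 3) stop_vf("need at least 3 timepoints")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop_vf("constant parcel series: parcel %s",
            paste(which(sds == 0), collapse = ", "))
  r <- cor(X)
  diag(r) <- 0
  fc_matrix(r, method = "pearson", subject_id = attr(rest, "subject_id"),
            session_id = session_id)
}

#' Seed-ensemble FC map
#'
#' For every parcel, the mean connectivity to a seed set (self-connections
#' excluded); with the eight CCC parcels as seeds this gives the overall FC of
#' the circuitry to the rest of cortex.
#'
#' @param fc An [fc_matrix].
#' @param seeds Non-empty vector of seed parcel ids.
#' @return Numeric vector over parcels.
#' @export
seed_fc_map <- function(fc, seeds) {
  if (length(seeds) == 0L) stop_vf("seed set is empty")
  P <- nrow(fc)
  vapply(seq_len(P), function(p) {
    use <- setdiff(seeds, p)
    if (length(use) == 0L) 0 else mean(fc[use, p])
  }, numeric(1))
}
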