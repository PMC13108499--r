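#' General dominance analysis over all predictor subsets
#'
#' Decomposes the R-squared of the regression of an actual response profile on
#' the 12 network-partitioned generated activations into per-network shares.
#' Every nonempty predictor subset (4,095 models for 12 predictors) is fit by
#' least squares with an intercept; each predictor's general-dominance partial
#' R-squared is the average over subset sizes of its mean incremental
#' R-squared when added to subsets lacking it. With this size-conditional
#' averaging the partial values sum exactly to the full-model R-squared.
#'
#' @param y Response vector (e.g. the 32 pooled observations: 4 CCC parcels x
#'   8 conditions for one hemisphere of one subject).
#' @param X Observations x K predictor matrix (K <= 20; the reference use is
#'   K = 12 network components).
#' @return A `dominance_result`: list with `partial_r2` (named per predictor),
#'   `full_r2`, `n_subsets`, and `subset_r2` (vector indexed by bitmask + 1).
#' @export
dominance <- function(y, X) {
  X <- as.matrix(X)
  K <- ncol(X)
  if (K < 1 || K > 20) stop_vf("need 1..20 predictors")
  n <- length(y)
  if (nrow(X) != n) stop_vf("y and X disagree on observations")
  labels <- colnames(X) %||% paste0("x", seq_len(K))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop_vf("response has zero variance")
  n_models <- bitwShiftL(1L, K)
  r2 <- numeric(n_models) # r2[mask + 1]; empty model = 0
  warned <- FALSE
  for (mask in seq_len(n_models - 1L)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(K) - 1L)) != 0L)
    Xm <- cbind(1, X[, cols, drop = FALSE])
    qrX <- qr(Xm)
    if (qrX$rank < ncol(Xm) && !warned) {
      warn_vf("rank-deficient subset model; least-norm fit used")
      warned <- TRUE
    }
    res <- qr.resid(qrX, y)
    r2[mask + 1L] <- 1 - sum(res^2) / sst
  }
  full_r2 <- r2[n_models]
  sizes <- vapply(0:(n_models - 1L), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(K - 1L))) != 0L), numeric(1))
  partial <- numeric(K)
  for (k in seq_len(K)) {
    bit <- bitwShiftL(1L, k - 1L)
    inc_by_size <- numeric(K) # mean increment when added to subsets of size s-1
    cnt_by_size <- numeric(K)
    for (mask in 0:(n_models - 1L)) {
      if (bitwAnd(mask, bit) != 0L) next
      s <- sizes[mask + 1L] + 1L # size of the model after adding k
      inc_by_size[s] <- inc_by_size[s] + (r2[bitwOr(mask, bit) + 1L] - r2[mask + 1L])
      cnt_by_size[s] <- cnt_by_size[s] + 1
    }
    partial[k] <- mean(inc_by_size / cnt_by_size)
  }
  names(partial) <- labels
  structure(list(partial_r2 = partial, full_r2 = full_r2,
                 n_subsets = n_models - 1L, subset_r2 = r2),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("dominance: %d predictors, %d subset models, full R^2 = %.3f\n",
              length(x$partial_r2), x$n_subsets, x$full_r2))
  print(round(sort(x$partial_r2, decreasing = TRUE), 4))
  invisible(x)
}

#' Dominance analysis of network components for one hemisphere of a cohort
#'
#' For each subject, pools the hemisphere's 4 CCC parcels x 8 conditions into
#' 32 observations, regresses the actual activations on the 12
#' network-partitioned generated activations, runs [dominance], and averages
#' partial R-squared across subjects.
#'
#' @param actual_list Per-subject activation matrices.
#' @param net_flow_list Per-subject results of [network_partitioned_generate]
#'   over the CCC targets.
#' @param parcels The [parcel_table].
#' @param hemisphere `"L"` or `"R"`.
#' @return List with `partial_r2` (mean over subjects, named by network),
#'   `full_r2` (mean), and `per_subject` (subjects x 12 matrix).
#' @export
cohort_dominance <- function(actual_list, net_flow_list, parcels,
                             hemisphere = "L") {
  ids <- ccc_parcels(parcels, hemisphere)
  per <- matrix(NA_real_, length(actual_list), length(NETWORKS),
                dimnames = list(NULL, NETWORKS))
  fulls <- numeric(length(actual_list))
  for (s in seq_along(actual_list)) {
    y <- as.numeric(t(unclass(as.matrix(actual_list[[s]]))[ids, , drop = FALSE]))
    X <- vapply(NETWORKS, function(net) {
      g <- net_flow_list[[s]][[net]]$generated
      as.numeric(t(g[as.character(ids), , drop = FALSE]))
    }, numeric(length(y)))
    d <- dominance(y, X)
    per[s, ] <- d$partial_r2
    fulls[s] <- d$full_r2
  }
  list(partial_r2 = colMeans(per), full_r2 = mean(fulls), per_subject = per)
}
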