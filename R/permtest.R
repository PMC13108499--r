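#' One-sample max-T sign-flip permutation test
#'
#' Computes the one-sample t statistic for each variable against `mu0` and
#' builds the family-wise null by randomly sign-flipping the centered rows,
#' recording the maximum t across variables on each permutation. The corrected
#' p-value for variable v is `(b + 1) / (n_perm + 1)` where b counts
#' permutation maxima at or above the observed t (valid convention; the
#' classic `b / n_perm` is also reported as `p_classic`, whose floor at
#' 100,000 permutations is 0.00001). The critical threshold is the
#' `(1 - alpha)` quantile of the max-null; a variable is significant iff its
#' observed t exceeds it.
#'
#' @param x Subjects x variables matrix (>= 3 subjects, finite).
#' @param mu0 Null mean.
#' @param n_perm Number of permutations (the reference analyses use 100,000;
#'   smaller values are appropriate in simulation suites).
#' @param seed Integer seed (fixed seed gives identical p-values).
#' @param alpha Family-wise level for the reported threshold.
#' @param tail Only `"upper"` is implemented (the analyses are one-sided).
#' @return A `maxt_result`: list with `t` (observed t per variable), `df`,
#'   `p_corrected`, `p_classic`, `threshold`, `significant`, `max_null`
#'   summary, `n_perm`, `seed`, `tail`.
#' @export
maxt_one_sample <- function(x, mu0 = 0, n_perm = 100000, seed = 1L,
                            alpha = 0.05, tail = "upper") {
  x <- as.matrix(x)
  n <- nrow(x); V <- ncol(x)
  if (n < 3) stop_vf("need at least 3 subjects")
  check_finite(x, "permutation test data")
  if (!identical(tail, "upper")) stop_vf("only the upper tail is implemented")
  d <- x - mu0
  sds <- apply(d, 2, sd)
  zero_var <- sds == 0
  if (any(zero_var & colMeans(d) != 0))
    stop_vf("zero variance in variable %s",
            paste(which(zero_var & colMeans(d) != 0), collapse = ", "))
  # a variable identically at the null contributes t = 0 by convention
  t_obs <- ifelse(zero_var, 0, colMeans(d) / (sds / sqrt(n)))
  ssq <- colSums(d^2)
  max_null <- with_seed(derive_seed(seed, "maxt"), {
    E <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    M <- (E %*% d) / n
    Vn <- sweep(-n * M^2, 2, ssq, `+`) / (n - 1)
    Tm <- M / sqrt(pmax(Vn, 0) / n)
    Tm[!is.finite(Tm)] <- 0
    apply(Tm, 1, max)
  })
  b <- vapply(t_obs, function(t0) sum(max_null >= t0), numeric(1))
  thr_idx <- ceiling((1 - alpha) * n_perm)
  threshold <- sort(max_null, partial = thr_idx)[thr_idx]
  structure(list(t = t_obs, df = n - 1L,
                 p_corrected = (b + 1) / (n_perm + 1),
                 p_classic = b / n_perm,
                 threshold = threshold,
                 significant = t_obs > threshold,
                 max_null = stats::quantile(max_null, c(.5, .9, .95, .99)),
                 n_perm = n_perm, seed = seed, tail = tail),
            class = "maxt_result")
}

#' Paired max-T permutation test (upper-tailed)
#'
#' A one-sample sign-flip test on the paired differences `a - b` against zero;
#' swapping `a` and `b` flips the t statistics exactly.
#'
#' @param a,b Subjects x variables matrices of equal shape.
#' @inheritParams maxt_one_sample
#' @return A `maxt_result`.
#' @export
maxt_paired <- function(a, b, n_perm = 100000, seed = 1L, alpha = 0.05) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop_vf("a and b must have the same shape")
  maxt_one_sample(a - b, mu0 = 0, n_perm = n_perm, seed = seed, alpha = alpha)
}

#' @export
print.maxt_result <- function(x, ...) {
  cat(sprintf(
    "max-T permutation test: %d variable(s), df = %d, %d permutations\n",
    length(x$t), x$df, x$n_perm))
  cat(sprintf("  threshold (alpha level): %.3f; %d significant\n",
              x$threshold, sum(x$significant)))
  invisible(x)
}
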