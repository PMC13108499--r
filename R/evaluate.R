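#' Accuracy of generated versus actual activations
#'
#' The three comparison metrics used throughout: Pearson r, the coefficient of
#' determination \eqn{R^2 = 1 - \sum(a-g)^2 / \sum(a-\bar a)^2} (which can be
#' negative when the generated values explain less variance than the actual
#' mean), and mean absolute error. Matrices are flattened parcels-major.
#'
#' @param actual,generated Numeric matrices or vectors of the same shape.
#' @return List with `r`, `r_squared`, `mae`, and `degenerate` (TRUE when the
#'   actual values have zero variance, leaving r and R^2 undefined).
#' @export
accuracy <- function(actual, generated) {
  a <- as.numeric(t(as.matrix(actual)))
  g <- as.numeric(t(as.matrix(generated)))
  if (length(a) != length(g)) stop_vf("shapes differ")
  sst <- sum((a - mean(a))^2)
  if (sst == 0)
    return(list(r = NA_real_, r_squared = NA_real_,
                mae = mean(abs(a - g)), degenerate = TRUE))
  r <- if (sd(g) == 0) NA_real_ else cor(a, g)
  list(r = r,
       r_squared = 1 - sum((a - g)^2) / sst,
       mae = mean(abs(a - g)),
       degenerate = FALSE)
}

#' Per-subject accuracy averaged to a group (random-effects) estimate
#'
#' @param actual_list,generated_list Lists of per-subject matrices.
#' @param level Label recorded on the report (`"whole_model"`, `"task"`, or
#'   `"response_profile"`).
#' @return An `accuracy_report`: list with `level`, `per_subject` (data frame)
#'   and group means `r`, `r_squared`, `mae`.
#' @export
accuracy_report <- function(actual_list, generated_list,
                            level = c("whole_model", "task",
                                      "response_profile")) {
  level <- match.arg(level)
  per <- do.call(rbind, Map(function(a, g) {
    acc <- accuracy(a, g)
    data.frame(r = acc$r, r_squared = acc$r_squared, mae = acc$mae)
  }, actual_list, generated_list))
  structure(list(level = level, per_subject = per,
                 r = mean(per$r), r_squared = mean(per$r_squared),
                 mae = mean(per$mae)),
            class = "accuracy_report")
}

#' Min-max normalization of a parcel's 8-condition profiles
#'
#' The actual profile is rescaled to `[0, 1]` by its own minimum and maximum;
#' the generated profile is rescaled with the *same* actual minimum and
#' maximum (so generated values may fall outside `[0, 1]` and are not
#' clamped). A constant actual profile makes the rescaling undefined; the
#' parcel is flagged degenerate and excluded from specificity.
#'
#' @param actual_profile,generated_profile Numeric vectors of length 8.
#' @return List with `actual`, `generated`, `degenerate`.
#' @export
minmax_normalize <- function(actual_profile, generated_profile) {
  if (length(actual_profile) != 8L || length(generated_profile) != 8L)
    stop_vf("profiles must have length 8")
  lo <- min(actual_profile); hi <- max(actual_profile)
  if (hi == lo)
    return(list(actual = rep(NA_real_, 8), generated = rep(NA_real_, 8),
                degenerate = TRUE))
  list(actual = (actual_profile - lo) / (hi - lo),
       generated = (generated_profile - lo) / (hi - lo),
       degenerate = FALSE)
}

#' Vergence specificity index for one hemisphere of the CCC
#'
#' After per-parcel min-max normalization, the index is the ratio of the mean
#' normalized activation over the two VM conditions (across the hemisphere's
#' four CCC parcels) to the mean over the two VS conditions:
#' \eqn{\mathrm{VSI} = \bar{VM}/\bar{VS}}; 1 is the null value. Computed
#' separately for actual and generated profiles (both normalized with the
#' actual min/max). A non-positive \eqn{\bar{VS}} makes the ratio
#' uninterpretable; the record is flagged non-finite and excluded downstream
#' with a warning.
#'
#' @param actual An [activation_matrix] (or P x 8 matrix) of actual betas.
#' @param generated Generated activations covering the CCC (a `flow_result`
#'   `generated` matrix or P x 8 matrix with parcel-id rownames).
#' @param parcels The [parcel_table].
#' @param hemisphere `"L"` or `"R"`.
#' @param conditions Column labels (defaults to [CONDITIONS]).
#' @return List with `spec_actual`, `spec_generated`, `contribution_pct`,
#'   `n_parcels_used`, `flagged`.
#' @export
vergence_specificity <- function(actual, generated, parcels, hemisphere,
                                 conditions = CONDITIONS) {
  ids <- ccc_parcels(parcels, hemisphere)
  if (length(ids) == 0L) stop_vf("no CCC parcels in hemisphere %s", hemisphere)
  vm <- match(VM_CONDITIONS, conditions)
  vs <- match(VS_CONDITIONS, conditions)
  if (anyNA(vm) || anyNA(vs)) stop_vf("VM/VS conditions missing")
  gen <- as.matrix(generated)
  if (!is.null(rownames(gen))) {
    gen <- gen[as.character(ids), , drop = FALSE]
  } else {
    gen <- gen[ids, , drop = FALSE]
  }
  act <- unclass(as.matrix(actual))[ids, , drop = FALSE]
  na <- ng <- matrix(NA_real_, length(ids), length(conditions))
  used <- logical(length(ids))
  for (k in seq_along(ids)) {
    nm <- minmax_normalize(act[k, ], gen[k, ])
    if (!nm$degenerate) {
      na[k, ] <- nm$actual
      ng[k, ] <- nm$generated
      used[k] <- TRUE
    }
  }
  if (!any(used))
    return(list(spec_actual = NA_real_, spec_generated = NA_real_,
                contribution_pct = NA_real_, n_parcels_used = 0L,
                flagged = TRUE))
  vm_a <- mean(na[used, vm]); vs_a <- mean(na[used, vs])
  vm_g <- mean(ng[used, vm]); vs_g <- mean(ng[used, vs])
  flagged <- vs_a <= 0 || vs_g <= 0
  if (flagged) {
    warn_vf("non-positive VS mean in hemisphere %s; record flagged", hemisphere)
    return(list(spec_actual = NA_real_, spec_generated = NA_real_,
                contribution_pct = NA_real_, n_parcels_used = sum(used),
                flagged = TRUE))
  }
  sa <- vm_a / vs_a
  sg <- vm_g / vs_g
  list(spec_actual = sa, spec_generated = sg,
       contribution_pct = distributed_contribution(sg, sa),
       n_parcels_used = sum(used), flagged = FALSE)
}

#' Distributed contribution percentage
#'
#' The share of the actual vergence specificity accounted for by the
#' flow-generated specificity: `100 * spec_generated / spec_actual`, uncapped.
#' Values are tested against the 50% null downstream (above 50% means the
#' specificity is primarily supported by distributed processes).
#'
#' @param spec_generated,spec_actual Finite specificity indices;
#'   `spec_actual` must be positive.
#' @return Percentage.
#' @export
distributed_contribution <- function(spec_generated, spec_actual) {
  if (!is.finite(spec_generated) || !is.finite(spec_actual))
    stop_vf("specificity indices must be finite")
  if (spec_actual <= 0) stop_vf("spec_actual must be positive")
  100 * spec_generated / spec_actual
}

#' Median-absolute-deviation outlier flagging
#'
#' Flags values farther than `k` scaled MADs from the median, using the
#' 1.4826 consistency constant (so the threshold is `k * 1.4826 * MAD_raw`).
#' The conservative default is k = 5. If the MAD is zero the rule is
#' uninformative: nothing is flagged and a warning is raised.
#'
#' @param values Numeric vector (length >= 3).
#' @param k Deviation threshold (default 5).
#' @return List with `outlier` (logical mask) and `n_kept`.
#' @export
mad_outliers <- function(values, k = 5) {
  if (length(values) < 3L) stop_vf("need at least 3 values")
  med <- median(values)
  mad_raw <- median(abs(values - med))
  if (mad_raw == 0) {
    warn_vf("MAD is zero; no outliers flagged")
    return(list(outlier = rep(FALSE, length(values)), n_kept = length(values)))
  }
  out <- abs(values - med) > k * 1.4826 * mad_raw
  list(outlier = out, n_kept = sum(!out))
}

#' Per-subject, per-hemisphere specificity records for a cohort
#'
#' Applies [vergence_specificity] to every subject and hemisphere and flags
#' outliers with [mad_outliers]: within each hemisphere, a subject flagged in
#' either the actual or the generated specificity is removed from both (the
#' hemispheres are treated independently, so their degrees of freedom can
#' differ).
#'
#' @param actual_list Per-subject activation matrices.
#' @param generated_list Per-subject generated matrices covering the CCC.
#' @param parcels The [parcel_table].
#' @param k MAD threshold (default 5); `Inf` disables outlier removal.
#' @return Data frame with one row per subject x hemisphere: `subject`,
#'   `hemisphere`, `spec_actual`, `spec_generated`, `contribution_pct`,
#'   `outlier`.
#' @export
specificity_records <- function(actual_list, generated_list, parcels, k = 5) {
  rows <- list()
  for (s in seq_along(actual_list)) {
    for (h in c("L", "R")) {
      rec <- vergence_specificity(actual_list[[s]], generated_list[[s]],
                                  parcels, h)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, hemisphere = h, spec_actual = rec$spec_actual,
        spec_generated = rec$spec_generated,
        contribution_pct = rec$contribution_pct, flagged = rec$flagged)
    }
  }
  df <- do.call(rbind, rows)
  df$outlier <- FALSE
  if (is.finite(k)) {
    for (h in c("L", "R")) {
      idx <- which(df$hemisphere == h & !df$flagged)
      if (length(idx) >= 3) {
        oa <- mad_outliers(df$spec_actual[idx], k)$outlier
        og <- mad_outliers(df$spec_generated[idx], k)$outlier
        df$outlier[idx] <- oa | og
      }
    }
  }
  df
}
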