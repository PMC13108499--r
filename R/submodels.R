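SUBMODEL_NETWORKS <- list(
  "full"         = NULL,
  "VIS-CON-DAN"  = c("VIS1", "VIS2", "CON", "DAN"),
  "VIS-CON"      = c("VIS1", "VIS2", "CON"),
  "VIS-DAN"      = c("VIS1", "VIS2", "DAN"),
  "VIS-Only"     = c("VIS1", "VIS2"),
  "DAN-Only"     = "DAN",
  "V1-initiated" = "V1"
)

# response-profile R^2 for one hemisphere: pooled over the 4 CCC parcels and
# 8 conditions, per subject, then averaged
profile_r2 <- function(actual_list, generated_list, parcels, hemisphere) {
  ids <- ccc_parcels(parcels, hemisphere)
  vals <- vapply(seq_along(actual_list), function(s) {
    a <- unclass(as.matrix(actual_list[[s]]))[ids, , drop = FALSE]
    g <- as.matrix(generated_list[[s]])
    g <- g[as.character(ids), , drop = FALSE]
    accuracy(a, g)$r_squared
  }, numeric(1))
  mean(vals)
}

#' Evaluate condensed cortical submodels against the full model
#'
#' Generates CCC activations under each submodel: the full whole-cortex model
#' and network-restricted variants (`VIS-CON-DAN`, `VIS-CON`, `VIS-DAN`,
#' `VIS-Only`, `DAN-Only`; all with every CCC parcel held out) plus the
#' `V1-initiated` model (mean-centered V1 activations as the only sources).
#' For each submodel it reports the response-profile R-squared per hemisphere
#' and the generated-specificity t statistic against 1, and optionally the
#' R-squared distribution over matched-size random subnetworks (parcels drawn
#' outside the submodel's networks and the CCC).
#'
#' @param act_list Per-subject [activation_matrix] objects.
#' @param fc_list Per-subject [fc_matrix] objects.
#' @param parcels The [parcel_table].
#' @param dist Optional [distance_matrix].
#' @param submodels Character vector naming submodels (default: all).
#' @param n_random Random matched-size subnetwork draws per submodel (the
#'   reference control uses 1000; 0 disables).
#' @param n_perm,seed Permutation settings for the specificity tests.
#' @return Data frame with one row per submodel x hemisphere: `submodel`,
#'   `hemisphere`, `r_squared`, `spec_t`, `spec_p`,
#'   `random_r2_mean`, `random_r2_q95`, `n_sources_median`.
#' @export
compare_submodels <- function(act_list, fc_list, parcels, dist = NULL,
                              submodels = names(SUBMODEL_NETWORKS),
                              n_random = 0, n_perm = 1000, seed = 1L) {
  ccc <- ccc_parcels(parcels)
  n_sub <- length(act_list)
  rows <- list()
  for (m in submodels) {
    nets <- SUBMODEL_NETWORKS[[m]]
    gen_list <- vector("list", n_sub)
    n_src <- integer(n_sub)
    for (s in seq_len(n_sub)) {
      if (identical(m, "V1-initiated")) {
        fr <- v1_initiated(act_list[[s]], fc_list[[s]], parcels)
        n_src[s] <- 2L
      } else {
        pol <- source_policy("exclude_ccc", allowed_networks = nets)
        fr <- actflow_generate(act_list[[s]], fc_list[[s]], targets = ccc,
                               policy = pol, parcels = parcels, dist = dist)
        n_src[s] <- nrow(fr$flow_terms[[1]])
      }
      gen_list[[s]] <- fr$generated
    }
    spec <- specificity_records(act_list, gen_list, parcels, k = 5)
    for (h in c("L", "R")) {
      r2 <- profile_r2(act_list, gen_list, parcels, h)
      sh <- spec[spec$hemisphere == h & !spec$flagged & !spec$outlier, ]
      spec_t <- spec_p <- NA_real_
      if (nrow(sh) >= 3 && sd(sh$spec_generated) > 0) {
        mt <- maxt_one_sample(matrix(sh$spec_generated, ncol = 1), mu0 = 1,
                              n_perm = n_perm, seed = derive_seed(seed, m, h))
        spec_t <- unname(mt$t)
        spec_p <- unname(mt$p_corrected)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        submodel = m, hemisphere = h, r_squared = r2, spec_t = spec_t,
        spec_p = spec_p, random_r2_mean = NA_real_, random_r2_q95 = NA_real_,
        n_sources_median = stats::median(n_src))
    }
    # matched-size random-subnetwork control (not for full / V1-initiated)
    if (n_random > 0 && !m %in% c("full", "V1-initiated")) {
      size <- as.integer(stats::median(n_src))
      draws <- random_subnetwork_draws(size, excluded_networks = nets,
                                       n_draws = n_random, parcels = parcels,
                                       seed = derive_seed(seed, "rand", m))
      for (h in c("L", "R")) {
        r2d <- vapply(draws, function(src) {
          pol <- source_policy("exclude_ccc", explicit_sources = src)
          gl <- lapply(seq_len(n_sub), function(s)
            actflow_generate(act_list[[s]], fc_list[[s]], targets = ccc,
                             policy = pol, parcels = parcels)$generated)
          profile_r2(act_list, gl, parcels, h)
        }, numeric(1))
        idx <- which(vapply(rows, function(r)
          r$submodel == m && r$hemisphere == h, logical(1)))
        rows[[idx]]$random_r2_mean <- mean(r2d)
        rows[[idx]]$random_r2_q95 <- unname(quantile(r2d, 0.95))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
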