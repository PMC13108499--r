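#' Build the ground-truth precision matrix and derived quantities
#'
#' Constructs a sparse symmetric precision matrix with denser, stronger
#' within-network blocks, sparser cross-network edges, and planted edges from
#' each CCC parcel to same-hemisphere VIS2 and DAN parcels (the distributed
#' pathways the analysis is meant to recover). All off-diagonal precision
#' entries are negative, so every true partial correlation
#' (\eqn{-P_{ij}/\sqrt{P_{ii}P_{jj}}}) is positive and flow weights do not
#' cancel in sign. Positive definiteness is enforced by diagonal dominance:
#' each diagonal entry is 1 plus the absolute row sum.
#'
#' Also derives the condition-profile calibration used to plant activations:
#' a shared 8-condition source profile whose VM/VS ratio is
#' `lambda * specificity_ratio`, and a CCC-local profile whose VM/VS ratio is
#' `specificity_ratio * (1 + lambda)`, so that the mixed actual activations
#' have VM/VS ratio `specificity_ratio` and the distributed (flow) share of
#' the specificity is exactly `lambda` in the noiseless limit.
#'
#' @param parcels A [parcel_table].
#' @param cfg A [sim_config].
#' @return A `ground_truth` list: `precision`, `true_partial_corr`,
#'   `covariance`, `flow_gain` (per-parcel expected flow gain from non-CCC
#'   sources), `source_profile`, `local_profile`, `lambda_distributed`,
#'   `specificity_ratio`, `seed`.
#' @export
make_ground_truth_fc <- function(parcels, cfg) {
  P <- nrow(parcels)
  if (P != cfg$P) stop_vf("parcel table has %d parcels but cfg$P = %d", P, cfg$P)
  net <- parcels$network
  hemi <- parcels$hemisphere
  ccc <- parcels$is_ccc
  Omega <- with_seed(derive_seed(cfg$seed, "ground_truth"), {
    O <- matrix(0, P, P)
    pairs <- which(upper.tri(O), arr.ind = TRUE)
    same_net <- net[pairs[, 1]] == net[pairs[, 2]]
    u <- runif(nrow(pairs))
    w <- runif(nrow(pairs), 0.5, 1)
    val <- numeric(nrow(pairs))
    sel_w <- same_net & u < cfg$density_within
    sel_b <- !same_net & u < cfg$density_between
    val[sel_w] <- -cfg$strength_within * w[sel_w]
    val[sel_b] <- -cfg$strength_between * w[sel_b]
    # background edges touching a CCC parcel are damped so the circuit's
    # connectivity fingerprint is dominated by the planted pathways below
    touches_ccc <- ccc[pairs[, 1]] | ccc[pairs[, 2]]
    val[touches_ccc] <- val[touches_ccc] * 0.4
    O[pairs] <- val
    # planted CCC pathways: bilateral VIS2 sources (early visual cortex is
    # strongly callosally connected) and same-hemisphere DAN sources
    for (j in which(ccc)) {
      cand <- which(net == "VIS2" & !ccc)
      take <- cand[runif(length(cand)) < cfg$ccc_vis2_density]
      O[cbind(pmin(j, take), pmax(j, take))] <-
        -cfg$ccc_vis2_strength * runif(length(take), 0.75, 1)
      cand <- which(net == "DAN" & hemi == hemi[j] & !ccc)
      take <- cand[runif(length(cand)) < cfg$ccc_dan_density]
      O[cbind(pmin(j, take), pmax(j, take))] <-
        -cfg$ccc_dan_strength * runif(length(take), 0.75, 1)
    }
    O[lower.tri(O)] <- 0
    O <- O + t(O)
    diag(O) <- 1 + rowSums(abs(O))
    O
  })
  pc <- -Omega / sqrt(tcrossprod(diag(Omega)))
  diag(pc) <- 0
  Sigma <- solve(Omega)
  Sigma <- (Sigma + t(Sigma)) / 2
  lambda <- cfg$lambda_distributed
  rho <- cfg$specificity_ratio
  shape <- c(1.05, 0.95, 1.05, 0.95, 0.5, 0.5, 0, 0) # many/few asymmetry
  source_profile <- shape * rep(c(lambda * rho, 1, 1, 1), each = 2)
  local_profile <- shape * rep(c(rho * (1 + lambda), 1, 1, 1), each = 2)
  names(source_profile) <- names(local_profile) <- CONDITIONS
  gains <- cfg$network_gains[net]
  gains[ccc] <- 0
  flow_gain <- as.numeric(crossprod(pc, gains)) # sum_i g_i * pc_ij over non-CCC i
  structure(list(precision = Omega, true_partial_corr = pc, covariance = Sigma,
                 flow_gain = flow_gain, source_profile = source_profile,
                 local_profile = local_profile,
                 lambda_distributed = lambda, specificity_ratio = rho,
                 parcels = parcels, seed = cfg$seed),
            class = "ground_truth")
}
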