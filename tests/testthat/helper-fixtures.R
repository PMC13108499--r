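# Shared fixtures and independent oracles, all built in code at test time.

# a hand-built 10-parcel table: hemispheres L (1:5) / R (6:10), a V1 pair,
# CCC = {1, 2, 6} (VIS1+CON left, VIS1 right)
tiny_parcels <- function() {
  parcel_table(data.frame(
    parcel_id = 1:10,
    name = c("L_V1", "L_FEF", "L_x1", "L_x2", "L_x3",
             "R_V1", "R_x1", "R_x2", "R_x3", "R_x4"),
    hemisphere = rep(c("L", "R"), each = 5),
    network = c("VIS1", "CON", "VIS2", "DAN", "DMN",
                "VIS1", "VIS2", "DAN", "SMN", "FPN"),
    is_ccc = c(TRUE, TRUE, FALSE, FALSE, FALSE,
               TRUE, FALSE, FALSE, FALSE, FALSE)))
}

# symmetric zero-diagonal random FC in [-1, 1]
random_fc <- function(P, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(P * P, -0.5, 0.5), P)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  fc_matrix(m, method = "glasso")
}

random_dist <- function(P, seed = 1) {
  set.seed(seed)
  xyz <- matrix(rnorm(P * 3, sd = 20), ncol = 3)
  d <- as.matrix(dist(xyz))
  dimnames(d) <- NULL
  distance_matrix(d)
}

# independent looped reference for activity flow under any policy: no matrix
# algebra, no shared code path with actflow_generate
oracle_actflow <- function(act, fc, targets, policy, parcels, dist = NULL) {
  gen <- matrix(0, length(targets), ncol(act))
  for (k in seq_along(targets)) {
    j <- targets[k]
    for (c in seq_len(ncol(act))) {
      s <- 0
      for (i in parcels$parcel_id) {
        if (i == j) next
        if (policy$mode %in% c("exclude_ccc", "exclude_ccc_radius") &&
            parcels$is_ccc[i]) next
        if (policy$mode == "exclude_ccc_radius" &&
            dist[j, i] < policy$radius_mm) next
        if (!is.null(policy$allowed_networks) &&
            !parcels$network[i] %in% policy$allowed_networks) next
        if (!is.null(policy$explicit_sources) &&
            !i %in% policy$explicit_sources) next
        s <- s + act[i, c] * fc[i, j]
      }
      gen[k, c] <- s
    }
  }
  gen
}

# a small cohort shared by several expensive tests (built once per session)
shared_small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(sim_config_small(n_subjects = 4, seed = 42))
    cache
  }
})

# per-subject glasso FC + GLM activations for a cohort (session 1)
analyze_cohort <- function(cohort, folds = 5, n_alpha = 20) {
  n <- length(cohort$subjects)
  fc <- vector("list", n); act <- vector("list", n)
  for (s in seq_len(n)) {
    ds <- cohort$subjects[[s]]
    fc[[s]] <- fc_glasso(denoise_rest(ds$rest$session1$ts,
                                      ds$rest$session1$confounds),
                         folds = folds, n_alpha = n_alpha)
    act[[s]] <- subject_activations(ds)
  }
  list(fc = fc, act = act)
}
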