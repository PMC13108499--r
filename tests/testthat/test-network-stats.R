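test_that("network contributions match a brute-force triple loop", {
  cfg <- sim_config(P = 26, n_subjects = 2, seed = 6)
  parc <- make_parcellation(26, 6)
  gt <- make_ground_truth_fc(parc$parcels, cfg)
  act <- make_task_activations(gt, parc$parcels, cfg, subject_seed = 1)
  fc <- fc_matrix(gt$true_partial_corr, "glasso")
  ccc <- vergeflow:::ccc_parcels(parc$parcels)
  fr <- actflow_generate(act, fc, targets = ccc,
                         policy = source_policy("exclude_ccc"),
                         parcels = parc$parcels)
  contrib <- network_flow_contributions(fr, parc$parcels, VM_CONDITIONS, "L")

  # independent loop oracle: target x network x condition
  ccc_l <- vergeflow:::ccc_parcels(parc$parcels, "L")
  oracle <- setNames(numeric(12), NETWORKS)
  for (net in NETWORKS) {
    per_target <- numeric(length(ccc_l))
    for (k in seq_along(ccc_l)) {
      j <- ccc_l[k]
      src <- parc$parcels$parcel_id[parc$parcels$network == net &
                                    !parc$parcels$is_ccc]
      src <- setdiff(src, j)
      if (length(src) == 0) { per_target[k] <- 0; next }
      vals <- numeric(0)
      for (i in src)
        for (cond in VM_CONDITIONS)
          vals <- c(vals, act[i, cond] * fc[i, j])
      per_target[k] <- mean(vals)
    }
    oracle[net] <- mean(per_target)
  }
  expect_equal(contrib, oracle, tolerance = 1e-12)

  # linearity: doubling flow terms doubles contributions
  act2 <- activation_matrix(unclass(act) * 2, CONDITIONS)
  fr2 <- actflow_generate(act2, fc, targets = ccc,
                          policy = source_policy("exclude_ccc"),
                          parcels = parc$parcels)
  expect_equal(network_flow_contributions(fr2, parc$parcels, VM_CONDITIONS, "L"),
               2 * contrib, tolerance = 1e-12)
})

test_that("network contributions are invariant to parcel reordering", {
  co <- shared_small_cohort()
  parc <- co$parcels
  fc <- fc_matrix(co$ground_truth$true_partial_corr, "glasso")
  act <- co$true_betas[[1]]
  ccc <- vergeflow:::ccc_parcels(parc)
  fr <- actflow_generate(act, fc, targets = ccc,
                         policy = source_policy("exclude_ccc"), parcels = parc)
  base <- network_flow_contributions(fr, parc, CONDITIONS, "R")

  set.seed(60)
  perm <- sample(nrow(parc))
  df <- as.data.frame(parc)[perm, ]
  df$parcel_id <- seq_len(nrow(df))
  parc_p <- parcel_table(df)
  fc_p <- fc_matrix(unclass(fc)[perm, perm], "glasso")
  act_p <- activation_matrix(unclass(act)[perm, ], CONDITIONS)
  fr_p <- actflow_generate(act_p, fc_p,
                           targets = vergeflow:::ccc_parcels(parc_p),
                           policy = source_policy("exclude_ccc"),
                           parcels = parc_p)
  expect_equal(network_flow_contributions(fr_p, parc_p, CONDITIONS, "R"),
               base, tolerance = 1e-12)
})

test_that("each network faces 11 comparisons and exchangeable nulls stay flat", {
  set.seed(61)
  contrib <- matrix(rnorm(24 * 12), 24, 12) # exchangeable null
  rk <- rank_networks(contrib, n_perm = 500, seed = 62)
  expect_equal(nrow(rk$pairs), 132L)
  expect_true(all(table(rk$pairs$a) == 11))
  expect_lte(sum(rk$ranking$wins), 2) # max-T holds the family error down
})

test_that("VM-vs-VS contrasts flag only truly different variables", {
  set.seed(63)
  vm <- matrix(rnorm(24 * 12, mean = 1), 24, 12)
  ct0 <- contrast_flows(vm, vm, "network", labels = NETWORKS,
                        n_perm = 500, seed = 64)
  expect_length(ct0$significant_labels, 0L)

  vs <- vm; vm2 <- vm
  vm2[, 2] <- vm2[, 2] + 1 # planted VIS2-like VM loading
  ct1 <- contrast_flows(vm2, vs, "network", labels = NETWORKS,
                        n_perm = 1000, seed = 65)
  expect_true("VIS2" %in% ct1$significant_labels)

  # parcel-level family excludes the CCC (no flow terms into themselves)
  co <- shared_small_cohort()
  fr <- actflow_generate(co$true_betas[[1]],
                         fc_matrix(co$ground_truth$true_partial_corr, "glasso"),
                         targets = vergeflow:::ccc_parcels(co$parcels),
                         policy = source_policy("exclude_ccc"),
                         parcels = co$parcels)
  pf <- vergeflow:::parcel_flows_into_ccc(fr, co$parcels, VM_CONDITIONS, "L")
  expect_length(pf, nrow(co$parcels) - 8L)
})

test_that("dominance enumerates 4095 subsets and sums to the full R^2", {
  set.seed(66)
  n <- 32
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, NETWORKS))
  y <- X %*% runif(12, 0, 1) + rnorm(n, sd = 0.5)
  d <- dominance(as.numeric(y), X)
  expect_equal(d$n_subsets, 4095L)
  expect_lt(abs(sum(d$partial_r2) - d$full_r2), 1e-8)
  expect_equal(unname(d$full_r2), summary(lm(y ~ X))$r.squared,
               tolerance = 1e-10)

  # single predictor: its partial equals the full R^2
  d1 <- dominance(as.numeric(y), X[, 1, drop = FALSE])
  expect_equal(unname(d1$partial_r2), d1$full_r2)

  # exchangeable predictors share their partials symmetrically
  z <- rnorm(n)
  Xs <- cbind(a = z + rnorm(n, sd = 1), b = z + rnorm(n, sd = 1))
  ys <- z + rnorm(n, sd = 0.3)
  ds <- dominance(ys, Xs)
  # both predictors are draws from the same joint law; partials are close
  expect_lt(abs(ds$partial_r2["a"] - ds$partial_r2["b"]),
            0.5 * ds$full_r2)
})

test_that("dominance partials order predictors by their signal share", {
  set.seed(67)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  y <- 2 * x1 + 0.5 * x2 + 0 * x3 + rnorm(n, sd = 0.5)
  d <- dominance(y, cbind(x1 = x1, x2 = x2, x3 = x3))
  expect_gt(d$partial_r2["x1"], d$partial_r2["x2"])
  expect_gt(d$partial_r2["x2"], d$partial_r2["x3"])
})

test_that("submodel comparison ranks full above restricted models", {
  co <- shared_small_cohort()
  parc <- co$parcels
  fcT <- fc_matrix(co$ground_truth$true_partial_corr, "glasso")
  fc_list <- rep(list(fcT), length(co$subjects))
  # V1-initiated generated profiles can legitimately flag non-positive VS
  tbl <- suppressWarnings(
    compare_submodels(co$true_betas, fc_list, parc, co$dist,
                      submodels = c("full", "VIS-Only", "V1-initiated"),
                      n_random = 10, n_perm = 200, seed = 3))
  for (h in c("L", "R")) {
    th <- tbl[tbl$hemisphere == h, ]
    full_r2 <- th$r_squared[th$submodel == "full"]
    expect_gt(full_r2, th$r_squared[th$submodel == "VIS-Only"])
    expect_gt(full_r2, th$r_squared[th$submodel == "V1-initiated"])
    expect_lt(th$r_squared[th$submodel == "V1-initiated"], 0)
    # the labeled submodel beats matched-size random subnetworks on average
    vis <- th[th$submodel == "VIS-Only", ]
    expect_gt(vis$r_squared, vis$random_r2_mean)
  }
})
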