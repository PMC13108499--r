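test_that("parcellation has 12 networks, 8 CCC parcels, and is deterministic", {
  parc <- make_parcellation(360, seed = 1)
  expect_equal(nrow(parc$parcels), 360L)
  expect_setequal(unique(parc$parcels$network), NETWORKS)
  expect_equal(sum(parc$parcels$is_ccc), 8L)
  for (h in c("L", "R")) {
    ccc_net <- sort(parc$parcels$network[parc$parcels$is_ccc &
                                         parc$parcels$hemisphere == h])
    expect_equal(ccc_net, sort(c("VIS1", "CON", "CON", "DAN")))
  }
  expect_equal(as.vector(table(parc$parcels$hemisphere)), c(180L, 180L))

  a <- make_parcellation(60, seed = 1)
  b <- make_parcellation(60, seed = 1)
  expect_identical(a$parcels, b$parcels)
  expect_identical(unclass(a$dist)[, ], unclass(b$dist)[, ])

  d <- unclass(a$dist)
  expect_true(all(d[upper.tri(d)] > 0))
  expect_true(all(diag(d) == 0))
  expect_error(make_parcellation(23), "even count")
})

test_that("ground-truth precision is SPD with positive partial correlations", {
  cfg <- sim_config_small(seed = 3)
  parc <- make_parcellation(cfg$P, cfg$seed)
  gt <- make_ground_truth_fc(parc$parcels, cfg)
  ev <- eigen(gt$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  pc <- gt$true_partial_corr
  expect_equal(pc, t(pc))
  expect_true(all(diag(pc) == 0))
  expect_true(all(pc >= 0)) # negative precision entries only
  expect_true(all(abs(pc) <= 1))

  # diagonal-only request: independence
  cfg0 <- sim_config_small(density_within = 0, density_between = 0,
                           ccc_vis2_density = 0, ccc_dan_density = 0, seed = 3)
  gt0 <- make_ground_truth_fc(parc$parcels, cfg0)
  expect_true(all(gt0$true_partial_corr == 0))
})

test_that("3-parcel chain: zero partial but nonzero marginal correlation", {
  # analytic oracle: invert the chain precision directly
  Om <- matrix(c(1.5, -0.4, 0,
                 -0.4, 1.5, -0.4,
                 0, -0.4, 1.5), 3, 3)
  Sigma <- solve(Om)
  pc <- -Om / sqrt(tcrossprod(diag(Om)))
  diag(pc) <- 0
  expect_equal(pc[1, 3], 0)
  marg13 <- Sigma[1, 3] / sqrt(Sigma[1, 1] * Sigma[3, 3])
  expect_gt(marg13, 0.05)
  # the package's converter agrees with the analytic form
  expect_equal(vergeflow:::precision_to_partial(Om), pc)
})

test_that("resting simulation matches its stated covariance and AR structure", {
  cfg <- sim_config(P = 36, n_subjects = 2, T_rest = 50000, ar = 0,
                    noise_sd = 0.2, seed = 2)
  parc <- make_parcellation(36, 2)
  gt <- make_ground_truth_fc(parc$parcels, cfg)
  ts <- simulate_rest(gt, cfg, session = 1, seed = 3)
  expect_equal(dim(ts), c(36L, 50000L))
  emp <- tcrossprod(unclass(ts) - rowMeans(ts)) / (ncol(ts) - 1)
  target <- gt$covariance + diag(cfg$noise_sd^2, 36)
  expect_lt(max(abs(emp - target)), 0.02)
  # AR coefficient 0: consecutive-frame autocorrelation ~ 0
  ac <- mean(vapply(1:36, function(p)
    cor(ts[p, -1], ts[p, -ncol(ts)]), numeric(1)))
  expect_lt(abs(ac), 0.02)
  # default rest length and TR
  cfg_def <- sim_config_small()
  expect_equal(cfg_def$T_rest, 150)
  expect_equal(cfg_def$tr, 2)
  # sessions draw independent noise from the same ground truth
  s1 <- simulate_rest(gt, cfg_def, session = 1, seed = 5)
  s2 <- simulate_rest(gt, cfg_def, session = 2, seed = 5)
  expect_false(isTRUE(all.equal(unclass(s1)[, ], unclass(s2)[, ])))
})

test_that("block designs reproduce the study's timing", {
  d <- make_designs()
  vm_secs <- sum(d$VM$blocks$duration_s)
  expect_equal(vm_secs, 5 * 19 + 5 * 18) # 185 s of task
  expect_equal(d$VM$n_timepoints, 208L)
  expect_equal(d$VS$n_timepoints, 208L)
  expect_equal(sum(d$VS$blocks$duration_s), 5 * 22 + 5 * 18)
  expect_equal(d$SM$n_timepoints, 208L)
  expect_equal(sum(d$SM$blocks$duration_s), 10 * 24)
  expect_equal(d$FT$n_timepoints, 92L) # 3 min 4 s at TR 2
  expect_equal(sum(d$FT$blocks$duration_s), 6 * 20)
  all_conds <- unlist(lapply(d, `[[`, "condition_set"), use.names = FALSE)
  expect_equal(sort(all_conds), sort(CONDITIONS)) # eight conditions in total
  for (x in d) expect_equal(x$tr, 2)
})

test_that("planted activations obey the distributed/local mixture limits", {
  parc <- make_parcellation(60, 11)
  ccc <- parc$parcels$is_ccc

  # pure-distributed limit: CCC betas equal the flow sum exactly
  cfg1 <- sim_config_small(lambda_distributed = 1, ccc_beta_sd = 0, seed = 11)
  gt1 <- make_ground_truth_fc(parc$parcels, cfg1)
  act1 <- make_task_activations(gt1, parc$parcels, cfg1, subject_seed = 9)
  flow <- crossprod(unclass(act1)[!ccc, ], gt1$true_partial_corr[!ccc, ccc])
  expect_equal(unclass(act1)[ccc, ], t(flow), tolerance = 1e-12,
               ignore_attr = TRUE)

  # pure-local limit: CCC betas equal the local component
  cfg0 <- sim_config_small(lambda_distributed = 0, ccc_beta_sd = 0,
                           local_noise_sd = 0, seed = 11)
  gt0 <- make_ground_truth_fc(parc$parcels, cfg0)
  act0 <- make_task_activations(gt0, parc$parcels, cfg0, subject_seed = 9)
  local_expect <- outer(gt0$flow_gain[ccc], gt0$local_profile)
  expect_equal(unclass(act0)[ccc, ], local_expect, tolerance = 1e-12,
               ignore_attr = TRUE)

  # null planting: specificity_ratio 1 gives equal expected VM and VS betas
  cfg_null <- sim_config_small(specificity_ratio = 1, seed = 11)
  gt_null <- make_ground_truth_fc(parc$parcels, cfg_null)
  sp <- gt_null$source_profile
  lp <- gt_null$local_profile
  lam <- cfg_null$lambda_distributed
  mixed <- lam * sp + (1 - lam) * lp
  expect_equal(mean(mixed[VM_CONDITIONS]), mean(mixed[VS_CONDITIONS]))
})

test_that("planted specificity is recoverable from many subjects' true betas", {
  cfg <- sim_config_small(seed = 21) # rho = 1.5
  parc <- make_parcellation(cfg$P, cfg$seed)
  gt <- make_ground_truth_fc(parc$parcels, cfg)
  ccc <- vergeflow:::ccc_parcels(parc$parcels)
  ratios <- vapply(1:100, function(s) {
    act <- make_task_activations(gt, parc$parcels, cfg,
                                 subject_seed = derive_seed(21, "subj", s))
    a <- unclass(act)[ccc, ]
    mean(a[, VM_CONDITIONS]) / mean(a[, VS_CONDITIONS])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - cfg$specificity_ratio),
            0.05 * cfg$specificity_ratio)
})

test_that("task runs recover planted betas noiselessly and are deterministic", {
  cfg <- sim_config_small(task_noise_sd = 0, confound_load_sd = 0, seed = 13)
  parc <- make_parcellation(cfg$P, cfg$seed)
  gt <- make_ground_truth_fc(parc$parcels, cfg)
  act <- make_task_activations(gt, parc$parcels, cfg, subject_seed = 2)
  d <- make_designs()
  run <- simulate_task_runs(d$VM, unclass(act), cfg, seed = 5)
  est <- estimate_betas(run$ts, d$VM)
  expect_lt(max(abs(est - unclass(act)[, d$VM$condition_set])), 1e-8)

  run2 <- simulate_task_runs(d$VM, unclass(act), cfg, seed = 5)
  expect_identical(unclass(run$ts)[, ], unclass(run2$ts)[, ])
  expect_identical(run$confounds, run2$confounds)
})

test_that("confound simulation hits the configured spike rate", {
  cfg <- sim_config_small(spike_rate = 0.03, seed = 1)
  conf <- vergeflow:::simulate_confounds(20000, cfg, seed = 7)
  fd <- compute_fd(as.matrix(conf[, vergeflow:::MOTION_COLS]))
  expect_lt(abs(mean(fd$spikes) - cfg$spike_rate), 0.01)
})

test_that("identical seed and config give a byte-identical on-disk cohort", {
  cfg <- sim_config(P = 26, n_subjects = 2, T_rest = 60, sessions = 1,
                    seed = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, out_dir = d1)
  simulate_cohort(cfg, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(manifest$tasks$VM, 2L) # two VM runs per subject
})
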