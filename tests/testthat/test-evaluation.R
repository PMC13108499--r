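test_that("accuracy metrics match hand arithmetic and edge cases", {
  a <- c(1, 2, 3); g <- c(1, 1, 1)
  acc <- accuracy(a, g)
  expect_equal(acc$mae, 1)
  # SSE = 0 + 1 + 4 = 5, SST = 2, R^2 = 1 - 5/2
  expect_equal(acc$r_squared, 1 - 5 / 2)

  perfect <- accuracy(a, a)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$mae, 0)

  opposite <- accuracy(a, -a)
  expect_lt(opposite$r_squared, 0) # worse than the mean predictor

  degen <- accuracy(c(2, 2, 2), c(1, 2, 3))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$r_squared))
})

test_that("R^2 never exceeds 1 and equals 1 only for identity", {
  set.seed(51)
  for (r in 1:20) {
    a <- rnorm(30)
    g <- a + rnorm(30, sd = runif(1, 0, 2))
    acc <- accuracy(a, g)
    expect_lte(acc$r_squared, 1)
    if (acc$r_squared == 1) expect_equal(a, g)
  }
})

test_that("min-max normalization uses the actual range without clamping", {
  actual <- c(2, 4, 6, 8, 10, 12, 14, 16)
  generated <- c(0, 4, 8, 12, 16, 20, 18, 17)
  nm <- minmax_normalize(actual, generated)
  expect_equal(nm$actual, (actual - 2) / 14)
  expect_equal(nm$actual[1], 0)
  expect_equal(nm$actual[8], 1)
  expect_equal(nm$generated, (generated - 2) / 14)
  expect_gt(max(nm$generated), 1) # values beyond the actual max are retained
  expect_lt(min(nm$generated), 0)

  expect_true(minmax_normalize(rep(1, 8), generated)$degenerate)
})

test_that("vergence specificity matches its defining ratio", {
  parc <- tiny_parcels()
  # build profiles where the normalized VM and VS means are known:
  # CCC left parcels 1 and 2; conditions span [0, 1] after normalization
  act <- matrix(0, 10, 8, dimnames = list(NULL, CONDITIONS))
  act[1, ] <- c(0.8, 0.8, 0.4, 0.4, 0.2, 0.2, 0, 1)
  act[2, ] <- c(0.8, 0.8, 0.4, 0.4, 0.2, 0.2, 0, 1)
  gen <- act / 2
  rec <- vergence_specificity(activation_matrix(act, CONDITIONS), gen,
                              parc, "L")
  expect_equal(rec$spec_actual, 2.0) # 0.8 / 0.4
  expect_equal(rec$spec_generated, 2.0) # ratio invariant to halving: min 0
  expect_equal(rec$contribution_pct, 100)

  # VM mean = VS mean > 0 gives the null value 1
  act1 <- act
  act1[1:2, 1:2] <- 0.4
  rec1 <- vergence_specificity(activation_matrix(act1, CONDITIONS), act1,
                               parc, "L")
  expect_equal(rec1$spec_actual, 1.0)

  # non-positive VS mean flags the record
  act2 <- act
  gen2 <- act2
  gen2[1:2, 3:4] <- -5 # generated VS below the actual minimum
  expect_warning(
    rec2 <- vergence_specificity(activation_matrix(act2, CONDITIONS), gen2,
                                 parc, "L"),
    "non-positive VS")
  expect_true(rec2$flagged)
})

test_that("specificity is invariant to common positive rescaling", {
  co <- shared_small_cohort()
  parc <- co$parcels
  ccc <- vergeflow:::ccc_parcels(parc)
  act <- co$true_betas[[1]]
  gen <- unclass(act)[ccc, ] * 0.6
  rownames(gen) <- ccc
  r1 <- vergence_specificity(act, gen, parc, "L")
  act_scaled <- activation_matrix(unclass(act) * 3.7, CONDITIONS)
  gen_scaled <- gen * 3.7
  r2 <- vergence_specificity(act_scaled, gen_scaled, parc, "L")
  expect_equal(r1$spec_actual, r2$spec_actual, tolerance = 1e-12)
  expect_equal(r1$spec_generated, r2$spec_generated, tolerance = 1e-12)
})

test_that("distributed contribution is the uncapped percentage ratio", {
  expect_equal(distributed_contribution(1.2, 1.2), 100)
  expect_equal(distributed_contribution(1.0, 2.0), 50)
  expect_equal(distributed_contribution(3.0, 2.0), 150) # no cap
  expect_error(distributed_contribution(1, -0.5), "positive")
  expect_error(distributed_contribution(NaN, 1), "finite")
})

test_that("MAD outlier rule matches the hand-computed example", {
  v <- c(10, 12, 11, 13, 12, 50)
  # median 12, raw MAD 1, threshold 5 * 1.4826 = 7.413: only 50 flagged
  out <- mad_outliers(v, k = 5)
  expect_equal(which(out$outlier), 6L)
  expect_equal(out$n_kept, 5L)

  expect_warning(same <- mad_outliers(rep(4, 6)), "MAD is zero")
  expect_false(any(same$outlier))
  expect_error(mad_outliers(c(1, 2)), "at least 3")
})

test_that("specificity recovery: planted ratio and lambda are recovered", {
  # large-sample mean of the actual index approaches the planted 1.5 and the
  # contribution approaches 100 * lambda under the true FC
  cfg <- sim_config_small(n_subjects = 2, seed = 23)
  parc <- make_parcellation(cfg$P, cfg$seed)
  gt <- make_ground_truth_fc(parc$parcels, cfg)
  ccc <- vergeflow:::ccc_parcels(parc$parcels)
  fcT <- fc_matrix(gt$true_partial_corr, "glasso")
  acts <- lapply(1:40, function(s)
    make_task_activations(gt, parc$parcels, cfg,
                          subject_seed = derive_seed(23, "rs", s)))
  gens <- lapply(acts, function(a)
    actflow_generate(a, fcT, targets = ccc,
                     policy = source_policy("exclude_ccc"),
                     parcels = parc$parcels)$generated)
  sp <- specificity_records(acts, gens, parc$parcels)
  keep <- !sp$flagged & !sp$outlier
  expect_lt(abs(mean(sp$spec_actual[keep]) - 1.5), 0.1)
  expect_lt(abs(mean(sp$contribution_pct[keep]) - 75), 5)
})
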