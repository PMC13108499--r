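test_that("source resolution implements every policy exactly", {
  parc <- make_parcellation(360, seed = 2)
  pol <- source_policy("exclude_ccc")
  non_ccc_target <- parc$parcels$parcel_id[!parc$parcels$is_ccc][1]
  ccc_target <- vergeflow:::ccc_parcels(parc$parcels)[1]
  expect_length(resolve_sources(non_ccc_target, pol, parc$parcels), 351L)
  expect_length(resolve_sources(ccc_target, pol, parc$parcels), 352L)

  # radius mode with all distances > radius degenerates to exclude_ccc
  far <- distance_matrix({d <- matrix(50, 20, 20); diag(d) <- 0; d})
  tp <- tiny_parcels()
  tp20 <- parcel_table(data.frame(parcel_id = 1:20,
                                  name = paste0("p", 1:20),
                                  hemisphere = rep(c("L", "R"), each = 10),
                                  network = rep(NETWORKS[1:10], 2),
                                  is_ccc = rep(c(TRUE, rep(FALSE, 9)), 2)))
  polr <- source_policy("exclude_ccc_radius", radius_mm = 10)
  expect_equal(resolve_sources(5, polr, tp20, far),
               resolve_sources(5, source_policy("exclude_ccc"), tp20))
  # strictly-less-than exclusion at the radius boundary
  at_edge <- far; at_edge[5, 7] <- at_edge[7, 5] <- 10
  expect_true(7 %in% resolve_sources(5, polr, tp20, distance_matrix(at_edge)))

  expect_error(source_policy("exclude_ccc_radius"), "radius_mm")
  expect_error(source_policy("exclude_ccc", radius_mm = 5), "radius_mm")
  expect_error(resolve_sources(5, source_policy("exclude_ccc",
                                                allowed_networks = "ORA"),
                               tp20), "empty source set")
})

test_that("activity flow reproduces a hand-computed 3-parcel example", {
  tp3 <- parcel_table(data.frame(parcel_id = 1:3, name = c("a", "b", "c"),
                                 hemisphere = c("L", "L", "R"),
                                 network = c("VIS1", "VIS2", "DAN"),
                                 is_ccc = FALSE))
  fcv <- matrix(0, 3, 3); fcv[1, 2] <- fcv[2, 1] <- 0.5
  fc <- fc_matrix(fcv, "glasso")
  act <- activation_matrix(matrix(c(1, 2, 3), 3, 1), "VM-many")
  fr <- actflow_generate(act, fc, targets = 1:3,
                         policy = source_policy("target_only"), parcels = tp3)
  expect_equal(as.numeric(fr$generated), c(1.0, 0.5, 0.0))

  # all-zero FC generates all zeros
  fr0 <- actflow_generate(act, fc_matrix(matrix(0, 3, 3), "glasso"),
                          targets = 1:3,
                          policy = source_policy("target_only"), parcels = tp3)
  expect_true(all(fr0$generated == 0))
})

test_that("flow terms sum to the generated value and respect linearity", {
  parc <- tiny_parcels()
  fc <- random_fc(10, seed = 5)
  set.seed(6)
  a1 <- activation_matrix(matrix(rnorm(80), 10), CONDITIONS)
  a2 <- activation_matrix(matrix(rnorm(80), 10), CONDITIONS)
  pol <- source_policy("exclude_ccc")
  f1 <- actflow_generate(a1, fc, targets = 1:10, policy = pol, parcels = parc)
  for (k in seq_along(f1$targets))
    expect_lt(max(abs(colSums(f1$flow_terms[[k]]) - f1$generated[k, ])), 1e-10)

  f2 <- actflow_generate(a2, fc, targets = 1:10, policy = pol, parcels = parc)
  mix <- activation_matrix(2 * unclass(a1) - 3 * unclass(a2), CONDITIONS)
  fmix <- actflow_generate(mix, fc, targets = 1:10, policy = pol,
                           parcels = parc)
  expect_equal(fmix$generated, 2 * f1$generated - 3 * f2$generated,
               tolerance = 1e-12)
})

test_that("network-partitioned components sum exactly to the full model", {
  co <- shared_small_cohort()
  parc <- co$parcels
  ccc <- vergeflow:::ccc_parcels(parc)
  fc <- fc_matrix(co$ground_truth$true_partial_corr, "glasso")
  act <- co$true_betas[[1]]
  pol <- source_policy("exclude_ccc")
  full <- actflow_generate(act, fc, targets = ccc, policy = pol,
                           parcels = parc, dist = co$dist)
  parts <- network_partitioned_generate(act, fc, targets = ccc, policy = pol,
                                        parcels = parc, dist = co$dist)
  expect_named(parts, NETWORKS)
  total <- Reduce(`+`, lapply(parts, `[[`, "generated"))
  expect_lt(max(abs(total - full$generated)), 1e-10)

  # a network emptied by the policy contributes exactly zeros
  pol_ora <- source_policy("exclude_ccc", allowed_networks = "VIS2")
  parts2 <- network_partitioned_generate(act, fc, targets = ccc,
                                         policy = pol_ora, parcels = parc)
  expect_true(all(parts2$ORA$generated == 0))
  expect_equal(parts2$VIS2$generated,
               actflow_generate(act, fc, targets = ccc, policy = pol_ora,
                                parcels = parc)$generated)
})

test_that("secondary circulation matches hand and loop computations", {
  co <- shared_small_cohort()
  parc <- co$parcels
  ccc <- vergeflow:::ccc_parcels(parc)
  fc <- fc_matrix(co$ground_truth$true_partial_corr, "glasso")
  gen1 <- actflow_generate(co$true_betas[[1]], fc, targets = ccc,
                           policy = source_policy("exclude_ccc"),
                           parcels = parc)
  gen2 <- secondary_circulation(gen1, fc, parc)
  # independent 8x8 loop oracle
  g1 <- gen1$generated
  for (k in seq_along(ccc)) {
    for (cc in seq_len(ncol(g1))) {
      s <- 0
      for (i in seq_along(ccc)) {
        if (ccc[i] == ccc[k]) next
        s <- s + g1[i, cc] * fc[ccc[i], ccc[k]]
      }
      expect_equal(gen2$generated[k, cc], s, tolerance = 1e-12)
    }
  }
  # zeros propagate to zeros
  zero1 <- gen1; zero1$generated[] <- 0
  expect_true(all(secondary_circulation(zero1, fc, parc)$generated == 0))

  # two-region circuit: gen2 swaps and halves gen1
  tp2 <- parcel_table(data.frame(parcel_id = 1:2, name = c("L_V1", "R_V1"),
                                 hemisphere = c("L", "R"), network = "VIS1",
                                 is_ccc = TRUE))
  fc2v <- matrix(c(0, .5, .5, 0), 2)
  g1_2 <- list(generated = matrix(c(4, 2), 2, 1,
                                  dimnames = list(1:2, "VM-many")),
               targets = 1:2)
  class(g1_2) <- "flow_result"
  out2 <- secondary_circulation(g1_2, fc_matrix(fc2v, "glasso"), tp2)
  expect_equal(as.numeric(out2$generated), c(1, 2)) # swapped and halved
})

test_that("V1-initiated model centers V1 and uses only V1 sources", {
  parc <- tiny_parcels()
  fc <- random_fc(10, seed = 9)
  set.seed(10)
  act <- activation_matrix(matrix(rnorm(80), 10), CONDITIONS)
  out <- v1_initiated(act, fc, parc)
  v1 <- c(1, 6)
  centered <- unclass(act)[v1, ] - rowMeans(unclass(act)[v1, ])
  expect_lt(max(abs(rowMeans(centered))), 1e-12)
  # left V1 (target 1) is generated from right V1 (parcel 6) only
  expect_equal(out$generated["1", ], centered[2, ] * fc[6, 1])
  # a non-V1 CCC target uses both centered V1 activations
  expect_equal(out$generated["2", ],
               centered[1, ] * fc[1, 2] + centered[2, ] * fc[6, 2])
  # constant V1 profiles are annihilated by centering
  act_const <- act
  act_const[1, ] <- 3; act_const[6, ] <- -2
  out_const <- v1_initiated(activation_matrix(unclass(act_const), CONDITIONS),
                            fc, parc)
  expect_true(all(abs(out_const$generated) < 1e-12))
})

test_that("random subnetwork draws are reproducible and respect exclusions", {
  parc <- make_parcellation(60, seed = 3)
  draws <- random_subnetwork_draws(10, excluded_networks = c("VIS1", "VIS2"),
                                   n_draws = 50, parcels = parc$parcels,
                                   seed = 4)
  draws2 <- random_subnetwork_draws(10, excluded_networks = c("VIS1", "VIS2"),
                                    n_draws = 50, parcels = parc$parcels,
                                    seed = 4)
  expect_identical(draws, draws2)
  expect_length(draws, 50L)
  all_ids <- unlist(draws)
  bad_nets <- parc$parcels$network[all_ids] %in% c("VIS1", "VIS2")
  expect_false(any(bad_nets))
  expect_false(any(parc$parcels$is_ccc[all_ids]))
  expect_true(all(vapply(draws, function(d) !anyDuplicated(d), logical(1))))
  expect_error(random_subnetwork_draws(1000, parcels = parc$parcels,
                                       n_draws = 2, seed = 1),
               "exceeds eligible pool")
})
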