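#' Run the full activity-flow experiment on a cohort
#'
#' End-to-end orchestration mirroring the analysis sequence: per-subject
#' resting denoising and graphical-lasso FC, task denoising and GLM betas,
#' whole-cortex activity flow with all CCC parcels excluded as sources,
#' accuracy at the whole-model / VM-task / CCC-response-profile levels,
#' vergence specificity with max-T tests against 1, distributed contribution
#' against the 50% null, network-level contributions with pairwise ranking,
#' dominance analysis, VM-versus-VS flow contrasts, condensed submodels, and
#' (when the cohort has two resting sessions) the repeated-scan rerun in
#' which session-2 FC generates the session-1 activations. All group
#' statistics are computed subject-first (per-subject estimate, then group
#' mean), and one master seed drives every stochastic step.
#'
#' @param cohort A [simulate_cohort] result (or an equivalent list of
#'   validated datasets).
#' @param n_perm Permutations for every max-T test.
#' @param seed Master seed for analysis-stage randomness.
#' @param folds,n_alpha Cross-validation settings for [fc_glasso].
#' @param n_random Random-subnetwork draws in [compare_submodels] (0 skips).
#' @param run_submodels,run_session2 Stage toggles.
#' @param alpha Family-wise level.
#' @param progress Print stage progress.
#' @return An `experiment_report` (nested list; see [report_render]).
#' @export
run_experiment <- function(cohort, n_perm = 1000, seed = cohort$cfg$seed,
                           folds = 5, n_alpha = 20, n_random = 0,
                           run_submodels = TRUE, run_session2 = TRUE,
                           alpha = 0.05, progress = FALSE) {
  parcels <- cohort$parcels
  dist <- cohort$dist
  n_sub <- length(cohort$subjects)
  ccc <- ccc_parcels(parcels)
  say <- function(...) if (progress) message(sprintf(...))

  say("stage 1/7: denoising + FC + GLM (%d subjects)", n_sub)
  fc1 <- vector("list", n_sub); fc2 <- vector("list", n_sub)
  act <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    ds <- cohort$subjects[[s]]
    assert_valid_dataset(ds)
    r1 <- denoise_rest(ds$rest$session1$ts, ds$rest$session1$confounds)
    fc1[[s]] <- fc_glasso(r1, folds = folds, n_alpha = n_alpha,
                          session_id = "session1")
    if (run_session2 && !is.null(ds$rest$session2)) {
      r2 <- denoise_rest(ds$rest$session2$ts, ds$rest$session2$confounds)
      fc2[[s]] <- fc_glasso(r2, folds = folds, n_alpha = n_alpha,
                            session_id = "session2")
    }
    act[[s]] <- subject_activations(ds)
  }
  have_s2 <- run_session2 && !any(vapply(fc2, is.null, logical(1)))

  say("stage 2/7: whole-cortex activity flow")
  policy <- source_policy("exclude_ccc")
  flows <- lapply(seq_len(n_sub), function(s)
    actflow_generate(act[[s]], fc1[[s]], targets = parcels$parcel_id,
                     policy = policy, parcels = parcels, dist = dist))
  gen <- lapply(flows, `[[`, "generated")

  say("stage 3/7: accuracy")
  vm_cols <- match(VM_CONDITIONS, CONDITIONS)
  accuracy_tbl <- list(
    whole_model = accuracy_report(act, gen, "whole_model"),
    vm_task = accuracy_report(lapply(act, function(a) a[, vm_cols]),
                              lapply(gen, function(g) g[, vm_cols]), "task"),
    response_profile = lapply(setNames(c("L", "R"), c("L", "R")), function(h) {
      ids <- ccc_parcels(parcels, h)
      accuracy_report(lapply(act, function(a) unclass(a)[ids, , drop = FALSE]),
                      lapply(gen, function(g) g[as.character(ids), , drop = FALSE]),
                      "response_profile")
    }))

  say("stage 4/7: specificity + contribution")
  spec <- specificity_records(act, gen, parcels, k = 5)
  spec_tests <- list(); contrib_tests <- list()
  for (h in c("L", "R")) {
    sh <- spec[spec$hemisphere == h & !spec$flagged & !spec$outlier, ]
    spec_tests[[h]] <- maxt_one_sample(
      cbind(actual = sh$spec_actual, generated = sh$spec_generated),
      mu0 = 1, n_perm = n_perm, seed = derive_seed(seed, "spec", h),
      alpha = alpha)
    contrib_tests[[h]] <- maxt_one_sample(
      matrix(sh$contribution_pct, ncol = 1, dimnames = list(NULL, "contribution")),
      mu0 = 50, n_perm = n_perm, seed = derive_seed(seed, "contrib", h),
      alpha = alpha)
  }

  say("stage 5/7: network contributions, ranking, dominance, contrasts")
  net_flows <- lapply(seq_len(n_sub), function(s)
    network_partitioned_generate(act[[s]], fc1[[s]], targets = ccc,
                                 policy = policy, parcels = parcels,
                                 dist = dist))
  networks <- list(); dominance_tbl <- list(); vm_vs <- list()
  for (h in c("L", "R")) {
    contrib_vm <- cohort_network_contributions(flows, parcels,
                                               VM_CONDITIONS, h)
    networks[[h]] <- rank_networks(contrib_vm, n_perm = n_perm,
                                   seed = derive_seed(seed, "rank", h),
                                   alpha = alpha)
    dominance_tbl[[h]] <- cohort_dominance(act, net_flows, parcels, h)
    contrib_vs <- cohort_network_contributions(flows, parcels,
                                               VS_CONDITIONS, h)
    net_ct <- contrast_flows(contrib_vm, contrib_vs, "network",
                             labels = NETWORKS, n_perm = n_perm,
                             seed = derive_seed(seed, "ctnet", h),
                             alpha = alpha)
    pf_vm <- do.call(rbind, lapply(flows, parcel_flows_into_ccc,
                                   parcels = parcels,
                                   conditions = VM_CONDITIONS, hemisphere = h))
    pf_vs <- do.call(rbind, lapply(flows, parcel_flows_into_ccc,
                                   parcels = parcels,
                                   conditions = VS_CONDITIONS, hemisphere = h))
    keep <- apply(pf_vm - pf_vs, 2, sd) > 0
    par_ct <- contrast_flows(pf_vm[, keep, drop = FALSE],
                             pf_vs[, keep, drop = FALSE], "parcel",
                             labels = colnames(pf_vm)[keep], n_perm = n_perm,
                             seed = derive_seed(seed, "ctpar", h),
                             alpha = alpha)
    vm_vs[[h]] <- list(network = net_ct, parcel = par_ct)
  }

  submodels <- NULL
  if (run_submodels) {
    say("stage 6/7: condensed submodels")
    submodels <- compare_submodels(act, fc1, parcels, dist,
                                   n_random = n_random, n_perm = n_perm,
                                   seed = derive_seed(seed, "submodels"))
  }

  session2 <- NULL
  if (have_s2) {
    say("stage 7/7: repeated-session rerun")
    flows2 <- lapply(seq_len(n_sub), function(s)
      actflow_generate(act[[s]], fc2[[s]], targets = parcels$parcel_id,
                       policy = policy, parcels = parcels, dist = dist))
    gen2 <- lapply(flows2, `[[`, "generated")
    spec2 <- specificity_records(act, gen2, parcels, k = 5)
    contrib2 <- list()
    for (h in c("L", "R")) {
      sh <- spec2[spec2$hemisphere == h & !spec2$flagged & !spec2$outlier, ]
      contrib2[[h]] <- maxt_one_sample(
        matrix(sh$contribution_pct, ncol = 1,
               dimnames = list(NULL, "contribution")),
        mu0 = 50, n_perm = n_perm, seed = derive_seed(seed, "contrib2", h),
        alpha = alpha)
    }
    session2 <- list(
      accuracy = list(
        whole_model = accuracy_report(act, gen2, "whole_model"),
        response_profile = lapply(setNames(c("L", "R"), c("L", "R")),
          function(h) {
            ids <- ccc_parcels(parcels, h)
            accuracy_report(
              lapply(act, function(a) unclass(a)[ids, , drop = FALSE]),
              lapply(gen2, function(g) g[as.character(ids), , drop = FALSE]),
              "response_profile")
          })),
      specificity = spec2, contribution_tests = contrib2)
  }

  cfg_str <- paste(deparse(cohort$cfg[setdiff(names(cohort$cfg), "network_gains")]),
                   collapse = "")
  structure(list(
    provenance = list(package_version = as.character(utils::packageVersion("vergeflow")),
                      config_hash = config_hash(cfg_str),
                      seed = seed, n_perm = n_perm, n_subjects = n_sub,
                      P = nrow(parcels)),
    accuracy = accuracy_tbl, specificity = spec, spec_tests = spec_tests,
    contribution_tests = contrib_tests, networks = networks,
    dominance = dominance_tbl, vm_vs = vm_vs, submodels = submodels,
    session2 = session2,
    fc = fc1, fc_session2 = if (have_s2) fc2 else NULL,
    activations = act, generated = gen),
    class = "experiment_report")
}

#' Render an experiment report as a human-readable markdown summary
#'
#' @param report An `experiment_report` from [run_experiment].
#' @return Character vector of markdown lines (also printed invisibly by
#'   `print`).
#' @export
report_render <- function(report) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  pv <- report$provenance
  add("# Activity-flow experiment report")
  add("")
  add("- config hash: %s | seed: %d | n = %d subjects | P = %d | %d permutations",
      pv$config_hash, pv$seed, pv$n_subjects, pv$P, pv$n_perm)
  add("")
  add("## Model accuracy (per subject, then group mean)")
  wm <- report$accuracy$whole_model
  add("- whole model: r = %.3f, R^2 = %.3f, MAE = %.3f",
      wm$r, wm$r_squared, wm$mae)
  vm <- report$accuracy$vm_task
  add("- VM task only: r = %.3f, R^2 = %.3f, MAE = %.3f",
      vm$r, vm$r_squared, vm$mae)
  for (h in c("L", "R")) {
    rp <- report$accuracy$response_profile[[h]]
    add("- %s CCC response profile: r = %.3f, R^2 = %.3f, MAE = %.3f",
        h, rp$r, rp$r_squared, rp$mae)
  }
  add("")
  add("## Vergence specificity (null value 1)")
  for (h in c("L", "R")) {
    st <- report$spec_tests[[h]]
    sh <- report$specificity[report$specificity$hemisphere == h, ]
    used <- sum(!sh$flagged & !sh$outlier)
    add("- %s hemisphere (df = %d after outlier removal): actual %.3f (t = %.2f, p = %.4g%s), generated %.3f (t = %.2f, p = %.4g%s)",
        h, st$df, mean(sh$spec_actual[!sh$flagged & !sh$outlier]),
        st$t["actual"], st$p_corrected[1],
        if (st$significant["actual"]) ", significant" else "",
        mean(sh$spec_generated[!sh$flagged & !sh$outlier]),
        st$t["generated"], st$p_corrected[2],
        if (st$significant["generated"]) ", significant" else "")
    if (used < nrow(sh)) add("  (%d of %d subjects removed as outliers)",
                             nrow(sh) - used, nrow(sh))
  }
  add("")
  add("## Distributed contribution (reference line: 50%%)")
  for (h in c("L", "R")) {
    ct <- report$contribution_tests[[h]]
    sh <- report$specificity[report$specificity$hemisphere == h, ]
    m <- mean(sh$contribution_pct[!sh$flagged & !sh$outlier])
    add("- %s hemisphere: %.2f%% vs 50%% (t(%d) = %.2f, p = %.4g%s)",
        h, m, ct$df, ct$t[1], ct$p_corrected[1],
        if (ct$significant[1]) ", significant" else "")
  }
  add("")
  add("## Network contributions (VM conditions)")
  for (h in c("L", "R")) {
    rk <- report$networks[[h]]$ranking
    n_sig <- sum(rk$wins > 0)
    if (n_sig == 0) {
      add("- %s hemisphere: no network is significantly dominant.", h)
    } else {
      top <- head(rk, 3)
      add("- %s hemisphere ranking: %s", h,
          paste(sprintf("%s (%d/11 wins)", top$network, top$wins),
                collapse = " > "))
    }
    dom <- report$dominance[[h]]
    topd <- sort(dom$partial_r2, decreasing = TRUE)[1:3]
    add("  dominance (full R^2 = %.3f): %s", dom$full_r2,
        paste(sprintf("%s %.3f", names(topd), topd), collapse = ", "))
    sigs <- report$vm_vs[[h]]$network$significant_labels
    add("  VM > VS network flows: %s",
        if (length(sigs)) paste(sigs, collapse = ", ") else "none significant")
  }
  if (!is.null(report$submodels)) {
    add("")
    add("## Condensed submodels (response-profile R^2)")
    for (h in c("L", "R")) {
      sm <- report$submodels[report$submodels$hemisphere == h, ]
      add("- %s: %s", h,
          paste(sprintf("%s %.2f", sm$submodel, sm$r_squared), collapse = "; "))
    }
  }
  if (!is.null(report$session2)) {
    add("")
    add("## Repeated-session rerun (session-2 FC, session-1 activations)")
    wm2 <- report$session2$accuracy$whole_model
    add("- whole model: r = %.3f, R^2 = %.3f, MAE = %.3f",
        wm2$r, wm2$r_squared, wm2$mae)
    for (h in c("L", "R")) {
      ct <- report$session2$contribution_tests[[h]]
      sh <- report$session2$specificity[
        report$session2$specificity$hemisphere == h, ]
      add("- %s contribution: %.2f%% (t(%d) = %.2f)", h,
          mean(sh$contribution_pct[!sh$flagged & !sh$outlier]), ct$df, ct$t[1])
    }
  }
  ln
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(paste(report_render(x), collapse = "\n"), "\n")
  invisible(x)
}
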