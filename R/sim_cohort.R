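#' Simulate a complete synthetic cohort
#'
#' Builds the parcellation and ground truth, then for every subject: one or
#' two resting sessions (series + confounds), the five task runs (VM twice,
#' VS, SM, FT) simulated from that subject's planted activations, and the
#' true activation matrix. Identical seed and configuration give a
#' byte-identical cohort. If `out_dir` is given the cohort is also written to
#' disk in the package's delimited-text formats together with a JSON manifest
#' and the ground-truth partial correlations / per-subject true betas (for
#' recovery tests).
#'
#' @param cfg A [sim_config].
#' @param out_dir Optional output directory.
#' @return A `cohort`: list with `cfg`, `parcels`, `dist`, `ground_truth`,
#'   `subjects` (list of [subject_dataset]), `true_betas` (list of
#'   [activation_matrix]), and `manifest`.
#' @export
simulate_cohort <- function(cfg, out_dir = NULL) {
  validate_sim_config(cfg)
  if (cfg$n_subjects < 2) stop_vf("a cohort needs n_subjects >= 2")
  parc <- make_parcellation(cfg$P, seed = cfg$seed)
  gt <- make_ground_truth_fc(parc$parcels, cfg)
  designs <- make_designs()
  subjects <- vector("list", cfg$n_subjects)
  true_betas <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("sub-%03d", s)
    sseed <- derive_seed(cfg$seed, "subject", s)
    betas <- make_task_activations(gt, parc$parcels, cfg, subject_seed = sseed)
    true_betas[[s]] <- betas
    rest <- list()
    for (session in seq_len(cfg$sessions)) {
      ts <- simulate_rest(gt, cfg, session = session, seed = sseed)
      conf <- simulate_confounds(cfg$T_rest, cfg,
                                 derive_seed(sseed, "restconf", session))
      vals <- add_confound_signal(unclass(ts), conf, cfg,
                                  derive_seed(sseed, "restload", session))
      rest[[sprintf("session%d", session)]] <-
        list(ts = time_series_matrix(vals, tr = cfg$tr, subject_id = sid,
                                     run_id = sprintf("rest%d", session),
                                     state = "rest"),
             confounds = conf)
    }
    tasks <- list()
    for (task in c("VM", "VS", "SM", "FT")) {
      n_runs <- if (task == "VM") 2L else 1L
      runs <- vector("list", n_runs)
      for (r in seq_len(n_runs)) {
        sim <- simulate_task_runs(designs[[task]], unclass(betas), cfg,
                                  seed = derive_seed(sseed, task, r),
                                  run_id = sprintf("%s_run%d", task, r),
                                  state = task)
        runs[[r]] <- list(ts = sim$ts, confounds = sim$confounds,
                          design = designs[[task]])
      }
      tasks[[task]] <- list(runs = runs)
    }
    subjects[[s]] <- subject_dataset(sid, rest, tasks, parc$parcels)
  }
  manifest <- list(
    package = "vergeflow",
    n_subjects = cfg$n_subjects, P = cfg$P, sessions = cfg$sessions,
    tasks = list(VM = 2L, VS = 1L, SM = 1L, FT = 1L),
    tr = cfg$tr, T_rest = cfg$T_rest, seed = cfg$seed,
    lambda_distributed = cfg$lambda_distributed,
    specificity_ratio = cfg$specificity_ratio)
  cohort <- structure(list(cfg = cfg, parcels = parc$parcels,
                           dist = parc$dist, ground_truth = gt,
                           subjects = subjects, true_betas = true_betas,
                           manifest = manifest),
                      class = "cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d subjects, P = %d, lambda = %.2f, rho = %.2f, seed %d\n",
              x$cfg$n_subjects, x$cfg$P, x$cfg$lambda_distributed,
              x$cfg$specificity_ratio, x$cfg$seed))
  invisible(x)
}

# write the cohort to disk in the delimited-text formats + JSON manifest
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_parcel_table(cohort$parcels, file.path(out_dir, "parcels.tsv"))
  write_matrix(cohort$dist, file.path(out_dir, "distances.tsv"), "distance")
  write_matrix(fc_matrix(cohort$ground_truth$true_partial_corr, "glasso"),
               file.path(out_dir, "true_partial_corr.tsv"), "fc")
  designs <- make_designs()
  for (task in names(designs))
    write_design(designs[[task]], file.path(out_dir, sprintf("design_%s.tsv", task)))
  for (s in seq_along(cohort$subjects)) {
    ds <- cohort$subjects[[s]]
    sd_dir <- file.path(out_dir, ds$subject_id)
    dir.create(sd_dir, showWarnings = FALSE)
    for (session in names(ds$rest)) {
      write_matrix(ds$rest[[session]]$ts,
                   file.path(sd_dir, sprintf("%s_bold.tsv", session)), "timeseries")
      write.table(ds$rest[[session]]$confounds,
                  file.path(sd_dir, sprintf("%s_confounds.tsv", session)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (task in names(ds$tasks)) {
      for (r in seq_along(ds$tasks[[task]]$runs)) {
        run <- ds$tasks[[task]]$runs[[r]]
        write_matrix(run$ts,
                     file.path(sd_dir, sprintf("%s_run%d_bold.tsv", task, r)),
                     "timeseries")
        write.table(run$confounds,
                    file.path(sd_dir, sprintf("%s_run%d_confounds.tsv", task, r)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    write_matrix(cohort$true_betas[[s]],
                 file.path(sd_dir, "true_betas.tsv"), "activation")
  }
  jsonlite::write_json(cohort$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
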