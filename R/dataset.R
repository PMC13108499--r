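#' Assemble a per-subject dataset
#'
#' Bundles everything one subject contributes to the analysis: one or two
#' resting sessions (each a time series + confound table), the five task runs
#' (VM twice, VS, SM, FT once each) with their designs and confounds, and a
#' reference to the cohort parcel table.
#'
#' @param subject_id Subject identifier.
#' @param rest Named list of sessions (`session1`, optionally `session2`),
#'   each `list(ts = , confounds = )`.
#' @param tasks Named list over tasks (`VM`, `VS`, `SM`, `FT`); each element is
#'   `list(runs = list(list(ts=, confounds=, design=), ...))`. VM must have two
#'   runs, the others one.
#' @param parcels The cohort [parcel_table].
#' @return A `subject_dataset` object.
#' @export
subject_dataset <- function(subject_id, rest, tasks, parcels) {
  structure(list(subject_id = subject_id, rest = rest, tasks = tasks,
                 parcels = parcels),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("subject_dataset %s: %d rest session(s), tasks: %s\n",
              x$subject_id, length(x$rest),
              paste(names(x$tasks), collapse = ", ")))
  invisible(x)
}

#' Validate a subject dataset against the pipeline's invariants
#'
#' Returns a report (one row per check) rather than raising; downstream
#' stages refuse datasets whose report contains failures.
#'
#' @param ds A [subject_dataset].
#' @return Data frame with columns `check`, `pass`, `detail`.
#' @export
validate_dataset <- function(ds) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(check = check, pass = pass,
                                                 detail = detail)
  }
  P <- nrow(ds$parcels)
  ok_p <- TRUE
  for (s in names(ds$rest)) {
    ts <- ds$rest[[s]]$ts
    if (nrow(ts) != P) ok_p <- FALSE
    add(sprintf("rest %s length >= 10 frames", s), ncol(ts) >= 10,
        sprintf("%d frames", ncol(ts)))
    conf_ok <- tryCatch({
      validate_confounds(ds$rest[[s]]$confounds, ncol(ts)); TRUE
    }, error = function(e) FALSE)
    add(sprintf("rest %s confounds valid", s), conf_ok)
  }
  for (task in names(ds$tasks)) {
    runs <- ds$tasks[[task]]$runs
    for (r in seq_along(runs)) {
      ts <- runs[[r]]$ts
      if (nrow(ts) != P) ok_p <- FALSE
      design_ok <- tryCatch({
        d <- runs[[r]]$design
        inherits(d, "task_design") && d$n_timepoints == ncol(ts)
      }, error = function(e) FALSE)
      add(sprintf("%s run %d design matches frames", task, r), design_ok)
      conf_ok <- tryCatch({
        validate_confounds(runs[[r]]$confounds, ncol(ts)); TRUE
      }, error = function(e) FALSE)
      add(sprintf("%s run %d confounds valid", task, r), conf_ok)
    }
  }
  add("all matrices share parcel count", ok_p, sprintf("P = %d", P))
  add("VM requires two runs",
      !is.null(ds$tasks$VM) && length(ds$tasks$VM$runs) == 2L,
      sprintf("%d run(s)", length(ds$tasks$VM$runs)))
  do.call(rbind, checks)
}

# refuse datasets whose validation report contains failures
assert_valid_dataset <- function(ds) {
  rep <- validate_dataset(ds)
  if (!all(rep$pass))
    stop_vf("dataset failed validation: %s",
            paste(rep$check[!rep$pass], collapse = "; "))
  invisible(ds)
}
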