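#' Construct and validate a block task design
#'
#' A design is a set of non-overlapping blocks (condition label, onset and
#' duration in seconds) within a run of `n_timepoints` frames at repetition
#' time `tr`.
#'
#' @param blocks Data frame with columns `condition`, `onset_s`, `duration_s`.
#' @param n_timepoints Number of frames in the run.
#' @param tr Repetition time in seconds.
#' @param condition_set Ordered labels covering all block conditions; defaults
#'   to the order of first appearance.
#' @return A `task_design` object.
#' @export
task_design <- function(blocks, n_timepoints, tr,
                        condition_set = unique(blocks$condition)) {
  required <- c("condition", "onset_s", "duration_s")
  if (!all(required %in% names(blocks)))
    stop_vf("design blocks need columns %s", paste(required, collapse = ", "))
  if (!is_count(n_timepoints) || n_timepoints < 1)
    stop_vf("n_timepoints must be a positive count")
  run_s <- n_timepoints * tr
  if (any(blocks$onset_s < 0) ||
      any(blocks$onset_s + blocks$duration_s > run_s + 1e-9))
    stop_vf("block outside run bounds (run is %g s)", run_s)
  ord <- order(blocks$onset_s)
  b <- blocks[ord, , drop = FALSE]
  if (nrow(b) > 1L) {
    ends <- b$onset_s[-nrow(b)] + b$duration_s[-nrow(b)]
    if (any(ends > b$onset_s[-1] + 1e-9)) stop_vf("overlapping blocks")
  }
  if (!all(blocks$condition %in% condition_set))
    stop_vf("condition_set does not cover all block labels")
  structure(list(blocks = b, n_timepoints = as.integer(n_timepoints),
                 tr = tr, condition_set = condition_set),
            class = "task_design")
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf("task_design: %d blocks, %d conditions, %d frames @ TR %gs\n",
              nrow(x$blocks), length(x$condition_set), x$n_timepoints, x$tr))
  invisible(x)
}

#' Read / write a task design as TSV
#'
#' Columns `condition`, `onset_s`, `duration_s`, with `#n_timepoints`, `#tr`
#' and `#condition_set` metadata lines.
#'
#' @param design A [task_design].
#' @param path File path.
#' @return `write_design` returns `path` invisibly; `read_design` a
#'   [task_design].
#' @export
write_design <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#n_timepoints\t%d", design$n_timepoints), con)
  writeLines(sprintf("#tr\t%.17g", design$tr), con)
  writeLines(sprintf("#condition_set\t%s",
                     paste(design$condition_set, collapse = ",")), con)
  writeLines("condition\tonset_s\tduration_s", con)
  writeLines(sprintf("%s\t%.17g\t%.17g", design$blocks$condition,
                     design$blocks$onset_s, design$blocks$duration_s), con)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    kv <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  body <- lines[-meta_idx]
  df <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                   stringsAsFactors = FALSE)
  task_design(df, n_timepoints = as.integer(meta$n_timepoints),
              tr = as.numeric(meta$tr),
              condition_set = strsplit(meta$condition_set, ",", fixed = TRUE)[[1]])
}
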