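#' Typed matrix containers
#'
#' Light S3 wrappers around base matrices that enforce the invariants each
#' pipeline stage relies on: BOLD time series (parcels x timepoints, with TR),
#' functional connectivity (symmetric, zero diagonal; partial correlations in
#' \code{[-1, 1]} for the graphical-lasso method), inter-parcel distances
#' (symmetric, non-negative, zero diagonal), and activation matrices
#' (parcels x conditions GLM coefficients).
#'
#' @param values Numeric matrix of the stated shape.
#' @param tr Repetition time in seconds (> 0).
#' @param subject_id,run_id,session_id Optional identifiers carried as
#'   attributes.
#' @param state `"rest"` or a task name.
#' @name containers
NULL

#' @rdname containers
#' @export
time_series_matrix <- function(values, tr, subject_id = NA_character_,
                               run_id = NA_character_, state = "rest") {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop_vf("time series needs at least 2 timepoints")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop_vf("tr must be a positive scalar (seconds)")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    stop_vf("time series contains non-finite values (parcel %d, frame %d)",
            bad[1, 1], bad[1, 2])
  }
  structure(values, tr = tr, subject_id = subject_id, run_id = run_id,
            state = state, class = c("time_series_matrix", "matrix", "array"))
}

#' @rdname containers
#' @param method FC estimation method, `"glasso"` or `"pearson"`.
#' @export
fc_matrix <- function(values, method = c("glasso", "pearson"),
                      subject_id = NA_character_, session_id = NA_character_) {
  method <- match.arg(method)
  values <- as.matrix(values)
  check_symmetric(values, "FC matrix")
  check_finite(values, "FC matrix")
  if (max(abs(diag(values))) > 1e-12)
    stop_vf("FC matrix must have zero diagonal")
  if (method == "glasso" && (max(values) > 1 + 1e-8 || min(values) < -1 - 1e-8))
    stop_vf("glasso FC (partial correlations) must lie in [-1, 1]")
  structure(values, method = method, subject_id = subject_id,
            session_id = session_id,
            class = c("fc_matrix", "matrix", "array"))
}

#' @rdname containers
#' @export
distance_matrix <- function(values) {
  values <- as.matrix(values)
  check_symmetric(values, "distance matrix")
  check_finite(values, "distance matrix")
  if (any(values < 0)) stop_vf("distances must be non-negative")
  if (max(abs(diag(values))) > 1e-12)
    stop_vf("distance matrix must have zero diagonal")
  structure(values, class = c("distance_matrix", "matrix", "array"))
}

#' @rdname containers
#' @param betas Numeric parcels x conditions matrix of GLM coefficients.
#' @param conditions Ordered condition labels (one per column).
#' @export
activation_matrix <- function(betas, conditions = colnames(betas)) {
  betas <- as.matrix(betas)
  if (is.null(conditions) || length(conditions) != ncol(betas))
    stop_vf("activation matrix needs one condition label per column")
  check_finite(betas, "activation matrix")
  colnames(betas) <- conditions
  structure(betas, conditions = conditions,
            class = c("activation_matrix", "matrix", "array"))
}

matrix_kind_attrs <- list(
  timeseries = c("tr", "subject_id", "run_id", "state"),
  fc         = c("method", "subject_id", "session_id"),
  distance   = character(0),
  activation = c("conditions")
)

#' Write a typed matrix to delimited text
#'
#' Row-major TSV with full double precision (`%.17g`, so write/read round-trips
#' are bitwise exact) preceded by `#key<TAB>value` metadata lines recording the
#' kind and the container attributes (tr, subject_id, method, conditions, ...).
#'
#' @param x A container from [containers] (or a bare matrix for
#'   `kind = "distance"`).
#' @param path Output path.
#' @param kind One of `"timeseries"`, `"fc"`, `"distance"`, `"activation"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path,
                         kind = c("timeseries", "fc", "distance", "activation")) {
  kind <- match.arg(kind)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#kind\t%s", kind), con)
  writeLines(sprintf("#nrow\t%d", nrow(x)), con)
  writeLines(sprintf("#ncol\t%d", ncol(x)), con)
  for (a in matrix_kind_attrs[[kind]]) {
    v <- attr(x, a)
    if (!is.null(v) && !all(is.na(v)))
      writeLines(sprintf("#%s\t%s", a, paste(as.character(v), collapse = ",")), con)
  }
  vals <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  writeLines(apply(vals, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a typed matrix written by [write_matrix]
#'
#' Validates the container invariants for the requested kind; mismatch between
#' the requested and stored kind, asymmetry (fc/distance), non-finite entries,
#' or a parcel-count mismatch against `parcels` are errors.
#'
#' @param path Path to a file written by [write_matrix].
#' @param kind One of `"timeseries"`, `"fc"`, `"distance"`, `"activation"`.
#' @param parcels Optional [parcel_table]; if given, the parcel dimension must
#'   match its row count.
#' @return The corresponding typed container.
#' @export
read_matrix <- function(path,
                        kind = c("timeseries", "fc", "distance", "activation"),
                        parcels = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    kv <- strsplit(sub("^#", "", ln), "\t", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  if (!identical(meta$kind, kind))
    stop_vf("file stores kind '%s' but '%s' was requested", meta$kind %||% "?", kind)
  body <- lines[-meta_idx]
  vals <- matrix(as.numeric(unlist(strsplit(body, "\t", fixed = TRUE))),
                 nrow = length(body), byrow = TRUE)
  if (nrow(vals) != as.integer(meta$nrow) || ncol(vals) != as.integer(meta$ncol))
    stop_vf("matrix shape %dx%d does not match stored metadata %sx%s",
            nrow(vals), ncol(vals), meta$nrow, meta$ncol)
  if (!is.null(parcels)) {
    p_expect <- nrow(parcels)
    p_have <- if (kind == "timeseries" || kind == "activation") nrow(vals) else nrow(vals)
    if (p_have != p_expect)
      stop_vf("matrix has %d parcels but parcel table has %d", p_have, p_expect)
  }
  switch(kind,
    timeseries = time_series_matrix(vals, tr = as.numeric(meta$tr %||% "2"),
                                    subject_id = meta$subject_id %||% NA_character_,
                                    run_id = meta$run_id %||% NA_character_,
                                    state = meta$state %||% "rest"),
    fc = fc_matrix(vals, method = meta$method %||% "glasso",
                   subject_id = meta$subject_id %||% NA_character_,
                   session_id = meta$session_id %||% NA_character_),
    distance = distance_matrix(vals),
    activation = activation_matrix(vals,
      conditions = strsplit(meta$conditions, ",", fixed = TRUE)[[1]])
  )
}
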