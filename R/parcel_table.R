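#' Construct and validate a parcel table
#'
#' The parcel table defines the analysis space: one row per cortical parcel
#' with its hemisphere, functional network assignment (one of the 12 labels in
#' [NETWORKS]), membership in the cortical circuitry of convergence (CCC), and
#' optional MNI coordinates (metadata only; no geometry is computed from them).
#'
#' @param df Data frame with columns `parcel_id`, `name`, `hemisphere`,
#'   `network`, `is_ccc` and optionally `mni_x`, `mni_y`, `mni_z`.
#' @return A validated `parcel_table` (a data.frame subclass).
#' @export
parcel_table <- function(df) {
  required <- c("parcel_id", "name", "hemisphere", "network", "is_ccc")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_vf("parcel table missing column(s): %s", paste(missing, collapse = ", "))
  df$parcel_id <- as.integer(df$parcel_id)
  if (anyDuplicated(df$parcel_id))
    stop_vf("duplicate parcel_id: %s",
            paste(unique(df$parcel_id[duplicated(df$parcel_id)]), collapse = ", "))
  if (!identical(sort(df$parcel_id), seq_len(nrow(df))))
    stop_vf("parcel_id must be contiguous 1..%d", nrow(df))
  df <- df[order(df$parcel_id), , drop = FALSE]
  if (!all(df$hemisphere %in% c("L", "R")))
    stop_vf("hemisphere must be 'L' or 'R'")
  bad <- setdiff(unique(df$network), NETWORKS)
  if (length(bad))
    stop_vf("unknown network label(s): %s", paste(bad, collapse = ", "))
  df$is_ccc <- as.logical(df$is_ccc)
  if (anyNA(df$is_ccc)) stop_vf("is_ccc must be TRUE/FALSE")
  rownames(df) <- NULL
  class(df) <- c("parcel_table", "data.frame")
  df
}

#' Read a parcel table from a tab-delimited file
#'
#' Expected header columns: `parcel_id`, `name`, `hemisphere`, `network`,
#' `is_ccc`, and optionally `mni_x`, `mni_y`, `mni_z`.
#'
#' @param path Path to a TSV file.
#' @return A validated [parcel_table].
#' @export
read_parcel_table <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, comment.char = "#")
  parcel_table(df)
}

#' Write a parcel table to a tab-delimited file
#'
#' @param parcels A [parcel_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parcel_table <- function(parcels, path) {
  write.table(as.data.frame(parcels), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.parcel_table <- function(x, ...) {
  cat(sprintf("parcel_table: %d parcels, %d networks, %d CCC members\n",
              nrow(x), length(unique(x$network)), sum(x$is_ccc)))
  NextMethod()
}

# parcel ids of CCC members, optionally one hemisphere
ccc_parcels <- function(parcels, hemisphere = NULL) {
  keep <- parcels$is_ccc
  if (!is.null(hemisphere)) keep <- keep & parcels$hemisphere == hemisphere
  parcels$parcel_id[keep]
}

# the V1 parcels: CCC members assigned to VIS1 (one per hemisphere)
v1_parcels <- function(parcels) {
  ids <- parcels$parcel_id[parcels$is_ccc & parcels$network == "VIS1"]
  if (length(ids) < 1L)
    stop_vf("no V1 parcels flagged (CCC members with network VIS1)")
  ids
}
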