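#' Network-level flow contributions into the CCC
#'
#' Attributes the flow of activity arriving at the held-out CCC parcels to the
#' 12 source networks: for each target, the *mean* of the flow terms over the
#' source parcels belonging to each network (the mean, not the sum, so large
#' networks are not favored by size), then the mean over the hemisphere's CCC
#' targets, then the mean over the scoped conditions.
#'
#' @param flows A `flow_result` whose targets include the CCC parcels and
#'   whose flow terms are present.
#' @param parcels The [parcel_table].
#' @param conditions Condition scope: e.g. [VM_CONDITIONS], [VS_CONDITIONS],
#'   or all eight (default).
#' @param hemisphere `"L"` or `"R"`.
#' @return Named numeric vector over [NETWORKS] (0 where a network
#'   contributes no sources).
#' @export
network_flow_contributions <- function(flows, parcels,
                                       conditions = CONDITIONS,
                                       hemisphere = "L") {
  targets <- intersect(flows$targets, ccc_parcels(parcels, hemisphere))
  if (length(targets) == 0L)
    stop_vf("flow result contains no CCC targets for hemisphere %s", hemisphere)
  net_of <- setNames(parcels$network, as.character(parcels$parcel_id))
  acc <- matrix(0, length(targets), length(NETWORKS),
                dimnames = list(NULL, NETWORKS))
  for (k in seq_along(targets)) {
    ft <- flows$flow_terms[[as.character(targets[k])]]
    cols <- match(conditions, colnames(ft))
    if (anyNA(cols)) stop_vf("condition scope not present in flow terms")
    src_net <- net_of[rownames(ft)]
    per_source <- rowMeans(ft[, cols, drop = FALSE])
    means <- tapply(per_source, factor(src_net, levels = NETWORKS), mean)
    means[is.na(means)] <- 0
    acc[k, ] <- means
  }
  colMeans(acc)
}

# subjects x 12 contribution matrix for one hemisphere
cohort_network_contributions <- function(flow_list, parcels,
                                         conditions = CONDITIONS,
                                         hemisphere = "L") {
  do.call(rbind, lapply(flow_list, network_flow_contributions,
                        parcels = parcels, conditions = conditions,
                        hemisphere = hemisphere))
}

#' Rank networks by pairwise flow-contribution comparisons
#'
#' For every ordered pair of networks, tests whether the first's contribution
#' exceeds the second's with a paired upper-tailed max-T test over all 132
#' ordered pairs as the comparison family. Each network's score is its number
#' of significant wins out of 11; ranking is by wins, ties broken by mean t.
#'
#' @param contrib Subjects x 12 matrix of network contributions (columns in
#'   [NETWORKS] order).
#' @param n_perm,seed,alpha Passed to [maxt_paired].
#' @return List with `ranking` (data frame: network, wins, mean_t, rank) and
#'   the underlying `maxt` result plus the `pairs` index.
#' @export
rank_networks <- function(contrib, n_perm = 1000, seed = 1L, alpha = 0.05) {
  contrib <- as.matrix(contrib)
  if (ncol(contrib) != length(NETWORKS))
    stop_vf("contribution matrix must have 12 columns")
  colnames(contrib) <- NETWORKS
  pairs <- expand.grid(a = NETWORKS, b = NETWORKS,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  D <- contrib[, pairs$a, drop = FALSE] - contrib[, pairs$b, drop = FALSE]
  colnames(D) <- paste(pairs$a, ">", pairs$b)
  res <- maxt_one_sample(D, mu0 = 0, n_perm = n_perm, seed = seed,
                         alpha = alpha)
  wins <- tapply(res$significant, pairs$a, sum)[NETWORKS]
  mean_t <- tapply(res$t, pairs$a, mean)[NETWORKS]
  ranking <- data.frame(network = NETWORKS, wins = as.integer(wins),
                        mean_t = as.numeric(mean_t))
  ord <- order(-ranking$wins, -ranking$mean_t)
  ranking <- ranking[ord, ]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  list(ranking = ranking, maxt = res, pairs = pairs)
}

#' Contrast VM against VS flows at the network or parcel level
#'
#' Computes subject-wise differences in flows into the CCC between the VM and
#' VS conditions and applies a paired upper-tailed max-T test, either across
#' the 12 networks or across all source parcels (family size P minus the CCC,
#' whose parcels carry no flow terms into the circuit).
#'
#' @param flows_vm,flows_vs Subjects x variables matrices of VM- and VS-scoped
#'   flows (networks or source parcels as variables).
#' @param level `"network"` or `"parcel"` (recorded on the result).
#' @param labels Optional variable labels used to report significant entries.
#' @param n_perm,seed,alpha Passed to [maxt_paired].
#' @return List with the `maxt` result, `level`, and `significant_labels`.
#' @export
contrast_flows <- function(flows_vm, flows_vs, level = c("network", "parcel"),
                           labels = colnames(as.matrix(flows_vm)),
                           n_perm = 1000, seed = 1L, alpha = 0.05) {
  level <- match.arg(level)
  res <- maxt_paired(as.matrix(flows_vm), as.matrix(flows_vs),
                     n_perm = n_perm, seed = seed, alpha = alpha)
  sig <- if (is.null(labels)) which(res$significant) else labels[res$significant]
  list(maxt = res, level = level, significant_labels = sig)
}

# per-subject mean flow per source parcel into one hemisphere's CCC, scoped
# to a condition set; returns named vector over source parcel ids
parcel_flows_into_ccc <- function(flows, parcels, conditions, hemisphere) {
  targets <- intersect(flows$targets, ccc_parcels(parcels, hemisphere))
  src_ids <- setdiff(parcels$parcel_id, ccc_parcels(parcels))
  acc <- matrix(0, length(targets), length(src_ids),
                dimnames = list(NULL, src_ids))
  for (k in seq_along(targets)) {
    ft <- flows$flow_terms[[as.character(targets[k])]]
    cols <- match(conditions, colnames(ft))
    v <- rowMeans(ft[, cols, drop = FALSE])
    hit <- intersect(rownames(ft), colnames(acc))
    acc[k, hit] <- v[hit]
  }
  colMeans(acc)
}
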