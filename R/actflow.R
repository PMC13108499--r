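#' Source-selection policy for activity flow mapping
#'
#' Controls which parcels may serve as sources for a given target. The target
#' itself is always excluded. `exclude_ccc` (the default used for every result
#' in the pipeline) additionally removes all eight CCC parcels from the source
#' set; `exclude_ccc_radius` further removes every parcel within `radius_mm`
#' of the target (strictly less than), guarding against spatial signal
#' leakage; `target_only` keeps all other parcels. An optional
#' `allowed_networks` set restricts sources to the named networks (the
#' condensed submodels), and `explicit_sources` restricts to a fixed parcel
#' set (random matched-size subnetworks).
#'
#' @param mode One of `"exclude_ccc"`, `"target_only"`, `"exclude_ccc_radius"`.
#' @param radius_mm Exclusion radius; required iff mode is
#'   `"exclude_ccc_radius"`.
#' @param allowed_networks Optional subset of [NETWORKS].
#' @param explicit_sources Optional parcel-id vector.
#' @return A `source_policy` object.
#' @export
source_policy <- function(mode = c("exclude_ccc", "target_only",
                                   "exclude_ccc_radius"),
                          radius_mm = NULL, allowed_networks = NULL,
                          explicit_sources = NULL) {
  mode <- match.arg(mode)
  if (mode == "exclude_ccc_radius" && is.null(radius_mm))
    stop_vf("radius_mm is required for mode 'exclude_ccc_radius'")
  if (mode != "exclude_ccc_radius" && !is.null(radius_mm))
    stop_vf("radius_mm only applies to mode 'exclude_ccc_radius'")
  if (!is.null(allowed_networks)) {
    bad <- setdiff(allowed_networks, NETWORKS)
    if (length(bad)) stop_vf("unknown network(s): %s", paste(bad, collapse = ", "))
  }
  structure(list(mode = mode, radius_mm = radius_mm,
                 allowed_networks = allowed_networks,
                 explicit_sources = explicit_sources),
            class = "source_policy")
}

#' Resolve the source parcel set for one target
#'
#' @param target Target parcel id.
#' @param policy A [source_policy].
#' @param parcels The [parcel_table].
#' @param dist A [distance_matrix]; required for the radius mode.
#' @return Integer vector of source parcel ids.
#' @export
resolve_sources <- function(target, policy, parcels, dist = NULL) {
  P <- nrow(parcels)
  if (!target %in% parcels$parcel_id) stop_vf("unknown target parcel %s", target)
  keep <- rep(TRUE, P)
  keep[target] <- FALSE
  if (policy$mode %in% c("exclude_ccc", "exclude_ccc_radius"))
    keep[parcels$is_ccc] <- FALSE
  if (policy$mode == "exclude_ccc_radius") {
    if (is.null(dist)) stop_vf("radius mode needs a distance matrix")
    keep[dist[target, ] < policy$radius_mm] <- FALSE
    keep[target] <- FALSE
  }
  if (!is.null(policy$allowed_networks))
    keep[!parcels$network %in% policy$allowed_networks] <- FALSE
  if (!is.null(policy$explicit_sources))
    keep[!parcels$parcel_id %in% policy$explicit_sources] <- FALSE
  src <- parcels$parcel_id[keep]
  if (length(src) == 0L)
    stop_vf("empty source set for target %d under policy '%s'", target,
            policy$mode)
  src
}

#' Generate held-out activations by activity flow
#'
#' For each target j and condition c, the generated activation is the sum over
#' the resolved source set of the source's actual activation times its
#' connectivity with the target:
#' \eqn{\mathrm{FlowAct}_{jc} = \sum_{i \in \mathrm{src}(j)} \mathrm{Act}_{ic}\,\mathrm{FC}_{ij}}.
#' The per-source flow terms \eqn{\mathrm{Act}_{ic}\,\mathrm{FC}_{ij}} are
#' retained so that network-level contributions can be aggregated; by
#' construction they sum exactly to the generated value.
#'
#' @param act An [activation_matrix] (P x C).
#' @param fc An [fc_matrix] (P x P) on the same parcel space.
#' @param targets Parcel ids to generate (default: all parcels).
#' @param policy A [source_policy].
#' @param parcels The [parcel_table].
#' @param dist Optional [distance_matrix] (needed for the radius mode).
#' @return A `flow_result`: list with `generated` (targets x C, rownames =
#'   parcel ids), `flow_terms` (one sources x C matrix per target, rownames =
#'   source parcel ids), `targets`, and the `policy`.
#' @export
actflow_generate <- function(act, fc, targets = parcels$parcel_id,
                             policy = source_policy("exclude_ccc"),
                             parcels, dist = NULL) {
  if (nrow(act) != nrow(fc) || nrow(act) != nrow(parcels))
    stop_vf("activations, FC and parcel table must share the parcel space")
  C <- ncol(act)
  gen <- matrix(0, length(targets), C,
                dimnames = list(targets, colnames(act)))
  terms <- vector("list", length(targets))
  names(terms) <- as.character(targets)
  for (k in seq_along(targets)) {
    j <- targets[k]
    src <- resolve_sources(j, policy, parcels, dist)
    ft <- unclass(act)[src, , drop = FALSE] * fc[src, j]
    rownames(ft) <- src
    terms[[k]] <- ft
    gen[k, ] <- colSums(ft)
  }
  structure(list(generated = gen, flow_terms = terms, targets = targets,
                 policy = policy),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("flow_result: %d targets x %d conditions (policy %s)\n",
              nrow(x$generated), ncol(x$generated), x$policy$mode))
  invisible(x)
}

#' Network-partitioned activity flow
#'
#' Repeats [actflow_generate] with sources restricted to each of the 12
#' networks in turn (after the policy's exclusions). Because the networks
#' partition the source set, the element-wise sum of the 12 components equals
#' the unrestricted result exactly; a network with no parcels left after
#' exclusion contributes zeros.
#'
#' @inheritParams actflow_generate
#' @return Named list over [NETWORKS] of `flow_result`s.
#' @export
network_partitioned_generate <- function(act, fc, targets, policy, parcels,
                                         dist = NULL) {
  out <- vector("list", length(NETWORKS))
  names(out) <- NETWORKS
  for (net in NETWORKS) {
    pol <- policy
    pol$allowed_networks <- net
    gen <- matrix(0, length(targets), ncol(act),
                  dimnames = list(targets, colnames(act)))
    terms <- stats::setNames(vector("list", length(targets)),
                             as.character(targets))
    for (k in seq_along(targets)) {
      j <- targets[k]
      src <- tryCatch(resolve_sources(j, pol, parcels, dist),
                      error = function(e) integer(0))
      if (length(src)) {
        ft <- unclass(act)[src, , drop = FALSE] * fc[src, j]
        rownames(ft) <- src
        terms[[k]] <- ft
        gen[k, ] <- colSums(ft)
      } else {
        terms[[k]] <- matrix(0, 0, ncol(act))
      }
    }
    out[[net]] <- structure(list(generated = gen, flow_terms = terms,
                                 targets = targets, policy = pol),
                            class = "flow_result")
  }
  out
}

#' Secondary activity-flow circulation within the CCC
#'
#' One round of within-circuit propagation: each CCC region's activation is
#' regenerated from the primary flow-generated activations of the other seven
#' CCC regions, weighted by their connectivity. Only the target is held out
#' (holding out all eight would leave no sources inside the circuit).
#'
#' @param gen1 A `flow_result` whose targets are the eight CCC parcels.
#' @param fc An [fc_matrix].
#' @param parcels The [parcel_table].
#' @return A `flow_result` over the same CCC targets.
#' @export
secondary_circulation <- function(gen1, fc, parcels) {
  ccc <- ccc_parcels(parcels)
  if (!all(ccc %in% gen1$targets))
    stop_vf("gen1 must cover all %d CCC parcels", length(ccc))
  g1 <- gen1$generated[as.character(ccc), , drop = FALSE]
  C <- ncol(g1)
  gen <- matrix(0, length(ccc), C, dimnames = list(ccc, colnames(g1)))
  terms <- stats::setNames(vector("list", length(ccc)), as.character(ccc))
  for (k in seq_along(ccc)) {
    j <- ccc[k]
    src <- setdiff(ccc, j)
    ft <- g1[as.character(src), , drop = FALSE] * fc[src, j]
    rownames(ft) <- src
    terms[[k]] <- ft
    gen[k, ] <- colSums(ft)
  }
  structure(list(generated = gen, flow_terms = terms, targets = ccc,
                 policy = source_policy("target_only")),
            class = "flow_result")
}

#' V1-initiated propagation model
#'
#' A deliberately restricted model in which signal can only originate in
#' primary visual cortex: each V1's 8-condition activation vector is
#' mean-centered (removing any standing offset), the six non-V1 CCC targets
#' are generated from the two centered V1 activations, and each V1 target is
#' generated from the contralateral V1 alone.
#'
#' @param act An [activation_matrix].
#' @param fc An [fc_matrix].
#' @param parcels The [parcel_table] (V1 = CCC member with network VIS1).
#' @return A `flow_result` over the eight CCC parcels.
#' @export
v1_initiated <- function(act, fc, parcels) {
  v1 <- v1_parcels(parcels)
  if (length(v1) != 2L)
    stop_vf("expected exactly 2 V1 parcels (one per hemisphere), found %d",
            length(v1))
  ccc <- ccc_parcels(parcels)
  v1_act <- unclass(act)[v1, , drop = FALSE]
  v1_act <- v1_act - rowMeans(v1_act)
  rownames(v1_act) <- v1
  C <- ncol(act)
  gen <- matrix(0, length(ccc), C, dimnames = list(ccc, colnames(act)))
  terms <- stats::setNames(vector("list", length(ccc)), as.character(ccc))
  hemi_of <- setNames(parcels$hemisphere, parcels$parcel_id)
  for (k in seq_along(ccc)) {
    j <- ccc[k]
    src <- if (j %in% v1) v1[hemi_of[as.character(v1)] != hemi_of[as.character(j)]]
           else v1
    ft <- v1_act[as.character(src), , drop = FALSE] * fc[src, j]
    rownames(ft) <- src
    terms[[k]] <- ft
    gen[k, ] <- colSums(ft)
  }
  structure(list(generated = gen, flow_terms = terms, targets = ccc,
                 policy = source_policy("target_only",
                                        explicit_sources = v1)),
            class = "flow_result")
}

#' Random matched-size source subnetworks
#'
#' Draws `n_draws` source sets of a given size, sampled without replacement
#' from parcels outside the excluded networks and outside the CCC (which is
#' never eligible), reproducibly by seed. Used as the size-matched null
#' control for the condensed submodels.
#'
#' @param size Parcels per draw.
#' @param excluded_networks Networks whose parcels are ineligible.
#' @param n_draws Number of draws (the reference control uses 1000).
#' @param parcels The [parcel_table].
#' @param seed Integer seed.
#' @return List of integer parcel-id vectors.
#' @export
random_subnetwork_draws <- function(size, excluded_networks = character(0),
                                    n_draws = 1000, parcels, seed = 1L) {
  eligible <- parcels$parcel_id[!parcels$is_ccc &
                                !parcels$network %in% excluded_networks]
  if (size > length(eligible))
    stop_vf("requested size %d exceeds eligible pool of %d", size,
            length(eligible))
  with_seed(derive_seed(seed, "subnetworks", size),
            lapply(seq_len(n_draws),
                   function(i) sort(sample(eligible, size))))
}
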