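#' Generate a synthetic parcellation with 12 networks and 8 CCC parcels
#'
#' Splits `P` parcels evenly between hemispheres, assigns each hemisphere's
#' parcels to the 12 networks in near-equal contiguous runs, and designates
#' the CCC as four parcels per hemisphere mirroring the convergence circuitry:
#' one primary-visual parcel (V1, network VIS1), two cingulo-opercular parcels
#' (FEF and SCEF, network CON), and one dorsal-attention parcel (AIP, network
#' DAN). Inter-parcel distances come from a random 3-D embedding per
#' hemisphere (coordinates stored as pseudo-MNI metadata); hemispheres are
#' offset laterally so cross-hemisphere distances are large.
#'
#' @param P Number of parcels (even, >= 24).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return List with `parcels` (a [parcel_table]) and `dist`
#'   (a [distance_matrix], mm).
#' @export
make_parcellation <- function(P, seed = 1L) {
  if (!is_count(P) || P < 24 || P %% 2 != 0)
    stop_vf("P must be an even count >= 24 (got %s)", P)
  half <- P / 2
  if (half < 12) stop_vf("P too small for one parcel per network per hemisphere")
  # near-equal contiguous network runs within each hemisphere; CON gets the
  # remainder first so it always has >= 2 parcels for the two CCC members
  base <- rep(half %/% 12, 12)
  extra <- half %% 12
  order_pref <- match(c("CON", "VIS1", "DAN", "VIS2", "SMN", "LAN", "FPN",
                        "AUD", "DMN", "PMM", "VMM", "ORA"), NETWORKS)
  base[order_pref[seq_len(extra)]] <- base[order_pref[seq_len(extra)]] + 1L
  if (base[match("CON", NETWORKS)] < 2)
    stop_vf("P too small: CON needs >= 2 parcels per hemisphere")
  rows <- list()
  for (hemi in c("L", "R")) {
    offset <- if (hemi == "L") 0L else half
    net <- rep(NETWORKS, times = base)
    id <- offset + seq_len(half)
    name <- sprintf("%s_%s_%02d", hemi, net, stats::ave(id, net, FUN = seq_along))
    is_ccc <- rep(FALSE, half)
    # V1: first VIS1 parcel; FEF, SCEF: first two CON; AIP: first DAN
    vis1_idx <- which(net == "VIS1")[1]
    con_idx <- which(net == "CON")[1:2]
    dan_idx <- which(net == "DAN")[1]
    is_ccc[c(vis1_idx, con_idx, dan_idx)] <- TRUE
    name[vis1_idx] <- paste0(hemi, "_V1")
    name[con_idx] <- paste0(hemi, c("_FEF", "_SCEF"))
    name[dan_idx] <- paste0(hemi, "_AIP")
    rows[[hemi]] <- data.frame(parcel_id = id, name = name, hemisphere = hemi,
                               network = net, is_ccc = is_ccc)
  }
  df <- rbind(rows$L, rows$R)
  coords <- with_seed(derive_seed(seed, "parcellation", P), {
    xyz <- matrix(rnorm(P * 3, sd = 25), ncol = 3)
    xyz[, 1] <- xyz[, 1] + ifelse(df$hemisphere == "L", -70, 70)
    xyz
  })
  df$mni_x <- round(coords[, 1], 1)
  df$mni_y <- round(coords[, 2], 1)
  df$mni_z <- round(coords[, 3], 1)
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  list(parcels = parcel_table(df), dist = distance_matrix(d))
}
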