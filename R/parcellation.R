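#' Generate a synthetic cortical parcellation
#'
#' Builds a bilateral parcellation table with node positions, resting-state
#' network (RSN) labels and homotopic (mirror-hemisphere) partners. The
#' default layout has 324 parcels split 159 left / 165 right, matching the
#' hemispheric asymmetry of widely used cortical parcellations; only the
#' first `min(n_L, n_R)` nodes of each hemisphere are homotopically paired,
#' so some right-hemisphere parcels have no partner.
#'
#' Left-hemisphere positions are sampled inside a unit hemisphere shell and
#' mirrored (x -> -x) to place the homotopic right partners; unpaired right
#' nodes get fresh positions. Networks are assigned as spatially contiguous
#' angular sectors, identically on both hemispheres, so every network is
#' bilateral.
#'
#' @param n_nodes total number of parcels (default 324).
#' @param n_networks number of RSN labels (default 10).
#' @param seed integer seed; the output is deterministic given the seed.
#' @return A `data.frame` of class `parcellation` with columns `node_id`,
#'   `hemisphere` ("L"/"R"), `network`, `homotope` (partner node id or `NA`)
#'   and positions `x`, `y`, `z` (arbitrary units, brain radius ~1).
#' @export
#' @examples
#' p <- generate_parcellation(40, n_networks = 4, seed = 1)
#' table(p$hemisphere)
generate_parcellation <- function(n_nodes = 324L, n_networks = 10L, seed = 1L) {
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  if (n_networks < 1 || n_networks > n_nodes)
    stop("n_networks must be in [1, n_nodes]")
  rsn_names <- c("VIS", "DMN", "SMM", "AUD", "COP",
                 "SAL", "VAT", "DAN", "FPN", "CPA")
  labels <- if (n_networks <= length(rsn_names)) rsn_names[seq_len(n_networks)]
            else c(rsn_names, paste0("NET", seq_len(n_networks - length(rsn_names))))

  # hemispheric split with the mild L/R asymmetry of real parcellations
  asym <- round(n_nodes / 54)
  n_L <- max(1L, as.integer(floor((n_nodes - asym) / 2)))
  n_R <- n_nodes - n_L
  n_pair <- min(n_L, n_R)

  set.seed(derive_seed(seed, 11L))
  sample_hemi <- function(n) {
    # points in a half-shell: lateral offset in [0.15, 1], y/z on a disc
    r <- sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    cbind(x = runif(n, 0.15, 1), y = r * cos(th), z = r * sin(th))
  }
  pos_L <- sample_hemi(n_L)
  pos_L[, "x"] <- -pos_L[, "x"]
  pos_R <- sample_hemi(n_R)
  # mirror the paired right nodes onto the left layout
  pos_R[seq_len(n_pair), ] <- pos_L[seq_len(n_pair), ]
  pos_R[seq_len(n_pair), "x"] <- -pos_L[seq_len(n_pair), "x"]

  # contiguous angular sectors (in the y-z plane) define the networks;
  # paired nodes inherit the partner's sector so networks are bilateral
  sector <- function(pos) {
    ang <- atan2(pos[, "z"], pos[, "y"])
    cut(rank(ang, ties.method = "first"), breaks = n_networks, labels = FALSE)
  }
  net_L <- sector(pos_L)
  net_R <- integer(n_R)
  net_R[seq_len(n_pair)] <- net_L[seq_len(n_pair)]
  if (n_R > n_pair)
    net_R[(n_pair + 1L):n_R] <- sector(pos_R)[(n_pair + 1L):n_R] %% n_networks + 1L

  id_L <- seq_len(n_L)
  id_R <- n_L + seq_len(n_R)
  homo_L <- c(id_R[seq_len(n_pair)], rep(NA_integer_, n_L - n_pair))
  homo_R <- c(id_L[seq_len(n_pair)], rep(NA_integer_, n_R - n_pair))

  out <- data.frame(
    node_id = c(id_L, id_R),
    hemisphere = rep(c("L", "R"), c(n_L, n_R)),
    network = labels[c(net_L, net_R)],
    homotope = c(homo_L, homo_R),
    x = c(pos_L[, "x"], pos_R[, "x"]),
    y = c(pos_L[, "y"], pos_R[, "y"]),
    z = c(pos_L[, "z"], pos_R[, "z"]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("parcellation", "data.frame")
  out
}

#' Homotopic node pairs of a parcellation
#'
#' @param parcellation a [generate_parcellation()] table.
#' @return two-column integer matrix of node-id pairs, each pair once.
#' @export
homotopic_pairs <- function(parcellation) {
  i <- which(!is.na(parcellation$homotope) &
               parcellation$node_id < parcellation$homotope)
  cbind(parcellation$node_id[i], parcellation$homotope[i])
}

# Euclidean inter-node distance matrix from parcel positions.
parcellation_distances <- function(parcellation) {
  as.matrix(dist(parcellation[, c("x", "y", "z")]))
}
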