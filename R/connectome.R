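#' Remove the weakest connections of a streamline-count matrix
#'
#' Sets entries with at most `min_streamlines` streamlines to zero (the
#' threshold is inclusive: an entry of exactly 3 is removed under the
#' default). Unthresholded tractography matrices contain many spurious weak
#' connections that push the excitable dynamics away from criticality.
#'
#' @param raw a `raw_connectome`.
#' @param min_streamlines inclusive removal threshold (default 3).
#' @return a thresholded `raw_connectome`; warns if the result has no edges.
#' @export
threshold_connectome <- function(raw, min_streamlines = 3) {
  W <- raw$W
  W[W <= min_streamlines] <- 0
  if (all(W == 0)) warning("thresholding removed every connection")
  new_raw_connectome(W, raw$parcellation, raw$subject_id, raw$timepoint)
}

#' Homeostatic (row) normalization of structural weights
#'
#' Divides each row of the count matrix by its row sum, so every
#' non-isolated node receives unit total incoming weight. This homeostatic
#' plasticity rule collapses the critical point of the excitable dynamics
#' onto a common value across individuals. The result is asymmetric even
#' though the input is symmetric.
#'
#' @param raw a (thresholded) `raw_connectome`.
#' @return A `normalized_connectome`: list with `W_tilde` (rows sum to 1 or
#'   are all-zero), the undirected binary `adjacency`, the indices of
#'   `isolated_nodes` (zero row sum), plus the carried-over metadata.
#' @export
homeostatic_normalize <- function(raw) {
  W <- raw$W
  rs <- rowSums(W)
  isolated <- which(rs == 0)
  denom <- ifelse(rs == 0, 1, rs)
  W_tilde <- W / denom
  adjacency <- (W > 0) * 1L
  structure(list(W_tilde = W_tilde, adjacency = adjacency,
                 isolated_nodes = isolated,
                 parcellation = raw$parcellation,
                 subject_id = raw$subject_id, timepoint = raw$timepoint),
            class = "normalized_connectome")
}

#' Structural graph metrics
#'
#' Computes the four whole-network summaries used throughout the analysis,
#' all on the undirected binary adjacency except the connectivity disorder:
#' \describe{
#'   \item{K}{average binary degree, `sum(k_v)/N`.}
#'   \item{Q}{Newman modularity of the best of `n_restarts` Louvain
#'     partitions.}
#'   \item{E_global}{global efficiency, the mean of `1/d_ij` over ordered
#'     node pairs; disconnected pairs contribute 0.}
#'   \item{H_SC}{connectivity disorder: Shannon entropy of all `N^2` entries
#'     of the row-normalized matrix, binned into `bins` equal bins on
#'     \[0,1\] (zeros included), normalized by `log(bins)`.}
#' }
#'
#' @param norm a `normalized_connectome`.
#' @param bins number of entropy bins (default 100).
#' @param louvain_seed seed for the stochastic Louvain restarts.
#' @param n_restarts Louvain restarts; the max-modularity partition is kept.
#' @return list with elements `K`, `Q`, `E_global`, `H_SC`.
#' @export
graph_metrics <- function(norm, bins = 100L, louvain_seed = 1L,
                          n_restarts = 20L) {
  A <- norm$adjacency
  N <- nrow(A)
  K <- sum(A) / N
  H_SC <- binned_entropy(as.vector(norm$W_tilde), bins)
  if (sum(A) == 0)
    return(list(K = 0, Q = NA_real_, E_global = 0, H_SC = H_SC))

  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  D <- igraph::distances(g)
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  E_global <- sum(inv) / (N * (N - 1))

  Q <- -Inf
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(louvain_seed, r))
    cl <- igraph::cluster_louvain(g)
    Q <- max(Q, igraph::modularity(g, igraph::membership(cl)))
  }
  list(K = K, Q = Q, E_global = E_global, H_SC = H_SC)
}

# Normalized Shannon entropy of values binned into `bins` equal bins on
# [0, 1]. Shared by the structural (m = 100) and functional (m = 20)
# disorder measures.
binned_entropy <- function(values, bins) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  counts <- tabulate(pmin(bins, floor(values * bins) + 1L), nbins = bins)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p)) / log(bins)
}

#' Newman modularity of a fixed partition (direct formula)
#'
#' Literal evaluation of `Q = (1/2m) * sum_vw [A_vw - k_v k_w / 2m]
#' delta(c_v, c_w)` on a binary undirected adjacency. Used as the reference
#' implementation against which the Louvain-based value is validated.
#'
#' @param A binary symmetric adjacency matrix.
#' @param membership integer community label per node.
#' @return modularity Q.
#' @export
modularity_direct <- function(A, membership) {
  m <- sum(A) / 2
  if (m == 0) return(NA_real_)
  k <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / (2 * m)) * same) / (2 * m)
}

#' Recovery index of a metric between two timepoints
#'
#' @param metric_t2,metric_t1 scalar metric values at the late and early
#'   timepoint.
#' @return `metric_t2 - metric_t1`.
#' @export
recovery_index <- function(metric_t2, metric_t1) {
  stopifnot(is.finite(metric_t2), is.finite(metric_t1))
  metric_t2 - metric_t1
}
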