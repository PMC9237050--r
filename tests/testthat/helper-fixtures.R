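# Shared fixtures: everything is generated in code, no files.

# Small parcellation + calibration scaled down for fast tests.
tiny_parcellation <- function(n = 40, seed = 7) {
  generate_parcellation(n, n_networks = 4, seed = seed)
}

tiny_calibration <- function() {
  healthy_calibration(k_core = 8L, p_far = 0.02, mu_core = 120,
                      mu_far = 7, mu_homotopic = 120, dispersion = 50)
}

tiny_connectome <- function(parc = tiny_parcellation(), seed = 1) {
  generate_healthy_connectome(parc, tiny_calibration(), seed = seed)
}

# Reduced model parameters for fast sweeps in unit tests.
tiny_params <- function(N, ...) {
  model_params(N, T_grid = seq(0, 0.2, by = 0.02), t_s = 400L,
               burn_in = 50L, n_reps = 3L, seed = 99L, ...)
}

# Hand-built normalized connectome from an explicit weight matrix.
norm_from_matrix <- function(W, parc = NULL) {
  raw <- neurocrit:::new_raw_connectome(W, parc, "fixture", "t1")
  homeostatic_normalize(raw)
}

# Undirected ring adjacency (each node linked to its two neighbors).
ring_matrix <- function(n, weight = 10) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    W[i, j] <- W[j, i] <- weight
  }
  W
}

# Planted-signal cohort with the correlated, low-rank feature structure of
# real connectome samples: a shared low-rank background plus three planted
# edges that each carry a strong independent factor driving the outcome.
# (With fully independent features and p >> n no method recovers a sparse
# linear signal, so recoverability requires this structure.)
make_planted_cohort <- function(n = 30, nodes = 15, noise_sd = 0, seed = 3) {
  set.seed(seed)
  p <- nodes * (nodes - 1) / 2
  planted <- c(4, 17, 60)
  Z <- matrix(rnorm(n * 5), n, 5)
  G <- matrix(rnorm(2 * p), 2, p)
  X <- Z[, 4:5] %*% G + matrix(rnorm(n * p, 0, 0.5), n, p) + 20
  for (k in 1:3) X[, planted[k]] <- 6 * Z[, k] + 20
  signal <- X[, planted] %*% c(1.5, -2, 1)
  y <- drop(signal) + rnorm(n, 0, noise_sd * stats::sd(signal))
  list(X = X, y = y, planted = planted)
}

# Brute-force global efficiency via BFS on the binary adjacency.
bfs_efficiency <- function(A) {
  n <- nrow(A)
  total <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (v in frontier) {
        nb <- which(A[v, ] > 0 & is.infinite(dist))
        dist[nb] <- d
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    total <- total + sum(1 / dist[-s][is.finite(dist[-s])])
  }
  total / (n * (n - 1))
}

# Brute-force connected components of the active-induced subgraph.
bf_components <- function(mask, A) {
  act <- which(as.logical(mask))
  comp <- integer(0)
  seen <- logical(length(mask))
  sizes <- integer(0)
  for (s in act) {
    if (seen[s]) next
    stack <- s
    seen[s] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1
      nb <- which(A[v, ] > 0)
      nb <- nb[nb %in% act & !seen[nb]]
      seen[nb] <- TRUE
      stack <- c(stack, nb)
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}
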