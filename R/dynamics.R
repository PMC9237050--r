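#' Parameters of the three-state excitable model
#'
#' Defaults follow the standard whole-brain setup: spontaneous activation
#' `r1 = 2/N`, refractory release `r2 = r1^(1/5)`, activation threshold grid
#' over \[0, 0.2\] in steps of 0.002 (fine enough to localize the critical
#' point to the third decimal), 2000 synchronous steps per run with the
#' first 100 discarded, and 10 independent random initial configurations.
#'
#' @param N number of nodes (sets the `r1` default).
#' @param r1 spontaneous I -> A probability.
#' @param r2 R -> I release probability.
#' @param T_grid strictly increasing activation thresholds.
#' @param t_s total steps per trajectory.
#' @param burn_in discarded initial steps.
#' @param n_reps independent random initial configurations.
#' @param seed master seed; one independent stream is derived per
#'   (threshold, replicate), so results do not depend on evaluation order.
#' @return a `model_params` list.
#' @export
model_params <- function(N = 324L, r1 = 2 / N, r2 = r1^(1 / 5),
                         T_grid = seq(0, 0.2, by = 0.002),
                         t_s = 2000L, burn_in = 100L, n_reps = 10L,
                         seed = 1L) {
  stopifnot(r1 >= 0, r1 <= 1, r2 >= 0, r2 <= 1,
            burn_in < t_s, all(diff(T_grid) > 0))
  structure(list(r1 = r1, r2 = r2, T_grid = T_grid, t_s = as.integer(t_s),
                 burn_in = as.integer(burn_in), n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "model_params")
}

# state coding shared with the C++ engine
STATE_I <- 0L
STATE_A <- 1L
STATE_R <- 2L

#' One synchronous update of the excitable dynamics (reference version)
#'
#' Pure-R implementation of the update rule, used as the readable reference
#' for the compiled sweep engine. All transitions read the previous step's
#' states: an inactive node activates with probability 1 when the summed
#' normalized weights of its active neighbors exceed `T` (strict
#' inequality), otherwise with probability `r1`; an active node always
#' becomes refractory; a refractory node recovers with probability `r2`.
#' Uses R's global RNG stream.
#'
#' @param states integer vector, 0 = I, 1 = A, 2 = R.
#' @param norm a `normalized_connectome`.
#' @param T_act activation threshold.
#' @param params a [model_params()] list (only `r1`, `r2` are used).
#' @return updated integer state vector.
#' @export
step_network <- function(states, norm, T_act, params) {
  input <- as.vector(norm$W_tilde %*% (states == STATE_A))
  new <- states
  inact <- states == STATE_I
  fire <- inact & input > T_act
  spont <- inact & !fire & runif(length(states)) < params$r1
  new[fire | spont] <- STATE_A
  new[states == STATE_A] <- STATE_R
  release <- states == STATE_R & runif(length(states)) < params$r2
  new[release] <- STATE_I
  new
}

#' Cluster sizes of the active subgraph
#'
#' Sizes of the connected components of the structural adjacency restricted
#' to simultaneously active nodes.
#'
#' @param active_mask logical/0-1 vector of active nodes.
#' @param adjacency undirected binary adjacency matrix.
#' @return `c(S1, S2)`: largest and second-largest component size (0 when
#'   fewer than one or two components exist).
#' @export
cluster_sizes <- function(active_mask, adjacency) {
  active <- which(as.logical(active_mask))
  if (!length(active)) return(c(S1 = 0, S2 = 0))
  g <- igraph::graph_from_adjacency_matrix(
    adjacency[active, active, drop = FALSE], mode = "undirected")
  cs <- sort(igraph::components(g)$csize, decreasing = TRUE)
  c(S1 = cs[1], S2 = if (length(cs) > 1) cs[2] else 0)
}

#' Threshold sweep of the excitable dynamics
#'
#' For each threshold in `params$T_grid`, runs `n_reps` trajectories from
#' independent random initial configurations, discards the burn-in, and
#' records the time-averaged network activity `<A>`, its standard deviation
#' `sigma_A`, and the time-averaged largest / second-largest active-cluster
#' sizes `S1`, `S2`; all four are then averaged across replicates.
#' Propagation uses the asymmetric row-normalized weights, cluster
#' membership the undirected binary adjacency.
#'
#' @param norm a `normalized_connectome`.
#' @param params a [model_params()] list.
#' @return A `criticality_profile`: list with the four per-threshold curves,
#'   their replicate SDs, the critical point `T_c` (argmax of S2), the curve
#'   integrals `I1`, `I2` (trapezoid rule), and the `monotonic_S2` flag.
#' @export
simulate_sweep <- function(norm, params = model_params(nrow(norm$W_tilde))) {
  prop <- as_push_csr(norm$W_tilde)
  adj <- as_push_csr(norm$adjacency)
  res <- gh_sweep_cpp(prop$ptr, prop$idx, prop$w, adj$ptr, adj$idx,
                      params$T_grid, params$r1, params$r2,
                      params$t_s, params$burn_in, params$n_reps,
                      params$seed)
  prof <- structure(list(T_grid = params$T_grid,
                         mean_A = res$mean_A, sd_A = res$sd_A,
                         S1 = res$S1, S2 = res$S2,
                         rep_sd_S1 = res$rep_sd_S1,
                         rep_sd_S2 = res$rep_sd_S2,
                         params = params,
                         subject_id = norm$subject_id,
                         timepoint = norm$timepoint),
                    class = "criticality_profile")
  prof$T_c <- if (all(res$S2 == 0)) NA_real_ else find_critical_point(prof)
  ints <- integrate_profile(prof)
  prof$I1 <- ints[["I1"]]
  prof$I2 <- ints[["I2"]]
  prof$monotonic_S2 <- if (length(params$T_grid) >= 3)
    classify_s2_monotonic(prof) else NA
  prof
}

#' @export
print.criticality_profile <- function(x, ...) {
  cat(sprintf(
    "criticality_profile: %s/%s  T_c = %s  I1 = %.3f  I2 = %.3f  %s\n",
    x$subject_id %||% "?", x$timepoint %||% "?",
    ifelse(is.na(x$T_c), "NA", sprintf("%.3f", x$T_c)), x$I1, x$I2,
    if (isTRUE(x$monotonic_S2)) "monotonic S2 (criticality lost)"
    else "peaked S2 (critical)"))
  invisible(x)
}

#' Critical point of a threshold profile
#'
#' The grid threshold maximizing the replicate-averaged second-largest
#' cluster size; ties break toward the smallest threshold.
#'
#' @param profile a `criticality_profile`.
#' @return `T_c`, or `NA` (with a warning) when S2 is identically zero.
#' @export
find_critical_point <- function(profile) {
  S2 <- profile$S2
  if (all(S2 == 0)) {
    warning("S2 is identically zero; no critical point")
    return(NA_real_)
  }
  profile$T_grid[which.max(S2)]
}

#' Classify the S2 curve as monotonic (loss of criticality)
#'
#' Forward finite differences of S2 are computed on the threshold grid; the
#' curve is monotonic when their sign is constant for thresholds at or above
#' `noise_cutoff` (sign changes below the cutoff are attributed to noise).
#'
#' Because the curves are Monte-Carlo averages, the derivative sign is only
#' counted where it is statistically meaningful: differences are taken over
#' a short lag (~0.01 in T, so 5 grid steps on the default grid) and must
#' exceed `z_crit` times their standard error, computed from the stored
#' per-threshold replicate SDs (for hand-built curves without replicate
#' information the rule degenerates to the strict sign criterion with
#' lag 1). The curve is monotonic when the significant differences do not
#' include both signs.
#'
#' @param profile a `criticality_profile` (or list with `T_grid`, `S2`).
#' @param noise_cutoff thresholds below this value are ignored
#'   (default 0.07).
#' @param z_crit significance multiple for a lagged difference (default 3,
#'   a guard against false sign changes across the ~60 tested lags).
#' @return `TRUE` when S2 is monotonic, i.e. the critical phase transition
#'   is lost.
#' @export
classify_s2_monotonic <- function(profile, noise_cutoff = 0.07, z_crit = 3) {
  S2 <- profile$S2
  Tg <- profile$T_grid
  if (length(S2) < 3) stop("S2 curve must have at least 3 points")
  step <- stats::median(diff(Tg))
  has_se <- !is.null(profile$rep_sd_S2) &&
    is.finite(profile$params$n_reps %||% NA_integer_)
  m <- if (has_se) max(1L, round(0.01 / step)) else 1L
  m <- min(m, length(S2) - 1L)
  k <- which(Tg >= noise_cutoff & seq_along(Tg) + m <= length(Tg))
  if (!length(k)) return(TRUE)
  d <- S2[k + m] - S2[k]
  tol <- if (has_se) {
    se <- profile$rep_sd_S2 / sqrt(profile$params$n_reps)
    z_crit * sqrt(se[k]^2 + se[k + m]^2)
  } else 0
  s <- sign(d)
  s[abs(d) <= tol] <- 0
  !(any(s > 0) && any(s < 0))
}

#' Integrals of the cluster-size curves
#'
#' Trapezoidal quadrature of S1 and S2 over the threshold grid; these are
#' the threshold-independent criticality indexes `I1` and `I2`.
#'
#' @param profile a `criticality_profile`.
#' @return named vector `c(I1, I2)`.
#' @export
integrate_profile <- function(profile) {
  c(I1 = trapz(profile$T_grid, profile$S1),
    I2 = trapz(profile$T_grid, profile$S2))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Euclidean distance of a profile curve from a reference curve
#'
#' `d = sqrt(sum_T (<X> - X(T))^2)` across the threshold grid, the summary
#' used to quantify how far an individual's neural profile sits from the
#' control-group average.
#'
#' @param profile a `criticality_profile`.
#' @param reference_curve reference values on the same threshold grid.
#' @param curve which profile curve to compare
#'   ("S1", "S2", "mean_A", "sd_A").
#' @return nonnegative distance.
#' @export
profile_distance <- function(profile, reference_curve,
                             curve = c("S2", "S1", "mean_A", "sd_A")) {
  curve <- match.arg(curve)
  x <- profile[[curve]]
  if (length(x) != length(reference_curve))
    stop("reference curve is not on the profile's threshold grid")
  sqrt(sum((reference_curve - x)^2))
}

#' Avalanche (cluster-size) exponent near a threshold
#'
#' Pools every per-step active-cluster size across replicates at threshold
#' `T_act` and fits a discrete truncated power law by maximum likelihood,
#' with the lower cutoff chosen by Kolmogorov-Smirnov distance
#' minimization (see [fit_power_law()]). Near the critical point the
#' exponent is expected around the avalanche hallmark 3/2.
#'
#' @param norm a `normalized_connectome`.
#' @param params a [model_params()] list.
#' @param T_act threshold at which to pool cluster sizes (use the detected
#'   `T_c` for meaningful output).
#' @return list with `alpha`, `xmin`, `n_tail`, `n_pooled`; `alpha` is `NA`
#'   (with a warning) when fewer than 100 clusters were pooled.
#' @export
cluster_exponent <- function(norm, params, T_act) {
  prop <- as_push_csr(norm$W_tilde)
  adj <- as_push_csr(norm$adjacency)
  res <- gh_sweep_cpp(prop$ptr, prop$idx, prop$w, adj$ptr, adj$idx,
                      T_act, params$r1, params$r2,
                      params$t_s, params$burn_in, params$n_reps,
                      params$seed, collect_t = 1L)
  sizes <- res$pooled_sizes
  if (length(sizes) < 100) {
    warning("fewer than 100 pooled clusters; exponent not estimated")
    return(list(alpha = NA_real_, xmin = NA_real_, n_tail = 0L,
                n_pooled = length(sizes)))
  }
  fit <- fit_power_law(sizes)
  c(fit, list(n_pooled = length(sizes)))
}
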