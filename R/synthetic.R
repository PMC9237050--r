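#' Generator calibration for synthetic healthy connectomes
#'
#' Parameters of the streamline-count generator. Connectivity has two
#' spatial scales: a short-range core (each node is linked to the mutual
#' set of its `k_core` nearest neighbors, carrying large streamline counts)
#' and a sparse uniform long-range floor of weak connections, plus always
#' present, elevated homotopic inter-hemispheric edges. Edge probability is
#' therefore a steeply decaying function of inter-node distance
#' (1 inside the neighborhood core, `p_far` outside).
#'
#' The defaults are calibrated once so that, after the usual <=3-streamline
#' threshold, a default cohort has mean binary degree inside the healthy
#' band K = 18 +/- 3 and connectivity disorder inside
#' H_SC = 0.059 +/- 0.004; with row normalization the ~15 comparable core
#' weights per node (~0.06-0.08 each) make the supra-threshold percolation
#' of the excitable dynamics break down near T ~ 0.12 for every subject,
#' which is what produces the universal critical point.
#'
#' @param k_core nearest-neighbor count of the short-range core (mutual
#'   kNN, so the realized core degree is somewhat below `k_core`).
#' @param p_far probability of a weak long-range edge between non-core
#'   pairs.
#' @param mu_core mean excess streamline count on core edges.
#' @param mu_far mean excess count on long-range edges (chosen so a fair
#'   share falls at or below the <=3 threshold).
#' @param mu_homotopic minimum mean excess count on homotopic edges (always
#'   present, elevated above the long-range floor).
#' @param dispersion negative-binomial size of the count draw; large values
#'   concentrate core counts near their mean (the pooled count distribution
#'   across edge classes remains heavy-tailed).
#' @return named list of generator parameters.
#' @export
healthy_calibration <- function(k_core = 19L, p_far = 0.006,
                                mu_core = 200, mu_far = 7,
                                mu_homotopic = 200, dispersion = 200) {
  list(k_core = as.integer(k_core), p_far = p_far, mu_core = mu_core,
       mu_far = mu_far, mu_homotopic = mu_homotopic, dispersion = dispersion)
}

#' Generate a synthetic healthy structural connectome
#'
#' Streamline-count matrix with short-range dominance (mutual
#' nearest-neighbor core with large counts), a sparse weak long-range
#' floor, and elevated homotopic inter-hemispheric edges; see
#' [healthy_calibration()] for the generator model.
#'
#' @param parcellation a [generate_parcellation()] table.
#' @param calibration a [healthy_calibration()] list.
#' @param seed integer seed.
#' @param subject_id,timepoint identifiers stored on the result.
#' @return A `raw_connectome`: list with the symmetric integer count matrix
#'   `W` (zero diagonal), the `parcellation`, `subject_id` and `timepoint`.
#' @export
generate_healthy_connectome <- function(parcellation,
                                        calibration = healthy_calibration(),
                                        seed = 1L,
                                        subject_id = "synthetic",
                                        timepoint = "t1") {
  cal <- calibration
  N <- nrow(parcellation)
  if (cal$k_core > N - 2)
    stop("infeasible calibration: k_core exceeds the parcellation size")
  if (cal$p_far < 0 || cal$p_far > 1)
    stop("infeasible calibration: p_far outside [0, 1]")
  d <- parcellation_distances(parcellation)
  set.seed(derive_seed(seed, 29L))

  nn <- matrix(FALSE, N, N)
  for (i in seq_len(N))
    nn[i, order(d[i, ])[2:(cal$k_core + 1L)]] <- TRUE
  core <- nn & t(nn)

  up <- which(upper.tri(d))
  p_edge <- ifelse(core[up], 1, cal$p_far)
  mu <- ifelse(core[up], cal$mu_core, cal$mu_far)

  hp <- homotopic_pairs(parcellation)
  if (nrow(hp)) {
    hidx <- (hp[, 2] - 1L) * N + hp[, 1]   # upper-triangle linear index (i < j)
    pos <- match(hidx, up)
    p_edge[pos] <- 1
    mu[pos] <- pmax(mu[pos], cal$mu_homotopic)
  }

  present <- runif(length(up)) < p_edge
  counts <- numeric(length(up))
  ne <- sum(present)
  counts[present] <- 1 + stats::rnbinom(ne, size = cal$dispersion %||% 1,
                                        mu = mu[present])

  W <- matrix(0, N, N)
  W[up] <- counts
  W <- W + t(W)
  new_raw_connectome(W, parcellation, subject_id, timepoint)
}

new_raw_connectome <- function(W, parcellation, subject_id, timepoint) {
  structure(list(W = W, parcellation = parcellation,
                 subject_id = subject_id, timepoint = timepoint),
            class = "raw_connectome")
}

#' @export
print.raw_connectome <- function(x, ...) {
  N <- nrow(x$W)
  cat(sprintf("raw_connectome: %s/%s, %d nodes, %d edges, total streamlines %.0f\n",
              x$subject_id, x$timepoint, N, sum(x$W[upper.tri(x$W)] > 0),
              sum(x$W) / 2))
  invisible(x)
}

#' Lesion specification
#'
#' @param lesioned_nodes integer node ids whose rows/columns are zeroed.
#' @param interhemispheric_scale factor in \[0,1\] applied to all surviving
#'   cross-hemisphere edge weights (stroke preferentially disrupts
#'   inter-hemispheric connectivity).
#' @param edge_dropout fraction of surviving edges removed at random.
#' @param seed integer seed for the dropout draw.
#' @return a `lesion_spec` list.
#' @export
lesion_spec <- function(lesioned_nodes = integer(), interhemispheric_scale = 1,
                        edge_dropout = 0, seed = 1L) {
  if (interhemispheric_scale < 0 || interhemispheric_scale > 1)
    stop("interhemispheric_scale must be in [0, 1]")
  if (edge_dropout < 0 || edge_dropout > 1)
    stop("edge_dropout must be in [0, 1]")
  structure(list(lesioned_nodes = as.integer(lesioned_nodes),
                 interhemispheric_scale = interhemispheric_scale,
                 edge_dropout = edge_dropout, seed = as.integer(seed)),
            class = "lesion_spec")
}

#' Sample a focal (spatially contiguous) lesion node set
#'
#' Picks a random seed parcel in one hemisphere and returns it together with
#' its `size - 1` nearest same-hemisphere neighbors, emulating a focal
#' stroke.
#'
#' @param parcellation a parcellation table.
#' @param size number of lesioned nodes.
#' @param hemisphere "L" or "R".
#' @param seed integer seed.
#' @return integer vector of node ids.
#' @export
sample_lesion_nodes <- function(parcellation, size, hemisphere = "L", seed = 1L) {
  ids <- parcellation$node_id[parcellation$hemisphere == hemisphere]
  if (size > length(ids)) stop("lesion larger than the hemisphere")
  set.seed(derive_seed(seed, 43L))
  centre <- sample(ids, 1L)
  pos <- as.matrix(parcellation[match(ids, parcellation$node_id),
                                c("x", "y", "z")])
  d <- sqrt(rowSums((pos - matrix(
    as.numeric(parcellation[parcellation$node_id == centre, c("x", "y", "z")]),
    nrow(pos), 3, byrow = TRUE))^2))
  ids[order(d)][seq_len(size)]
}

#' Apply a focal lesion to a connectome
#'
#' Zeroes the rows/columns of lesioned nodes, scales surviving
#' cross-hemisphere weights, and randomly drops a fraction of the surviving
#' edges. Degree and connectivity disorder are non-increasing in lesion
#' severity in expectation.
#'
#' @param connectome a `raw_connectome`.
#' @param spec a [lesion_spec()].
#' @return a lesioned `raw_connectome` (counts remain nonnegative integers).
#' @export
apply_lesion <- function(connectome, spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  W <- connectome$W
  parc <- connectome$parcellation
  if (length(spec$lesioned_nodes) &&
      !all(spec$lesioned_nodes %in% parc$node_id))
    stop("lesioned nodes not in the parcellation")
  if (length(spec$lesioned_nodes)) {
    W[spec$lesioned_nodes, ] <- 0
    W[, spec$lesioned_nodes] <- 0
  }
  if (spec$interhemispheric_scale < 1) {
    cross <- outer(parc$hemisphere, parc$hemisphere, "!=")
    W[cross] <- round(W[cross] * spec$interhemispheric_scale)
  }
  if (spec$edge_dropout > 0) {
    set.seed(derive_seed(spec$seed, 61L))
    up <- which(upper.tri(W) & W > 0)
    drop <- up[runif(length(up)) < spec$edge_dropout]
    W[drop] <- 0
    W[lower.tri(W)] <- t(W)[lower.tri(W)]   # mirror to keep exact symmetry
  }
  new_raw_connectome(W, parc, connectome$subject_id, connectome$timepoint)
}

#' Stroke-typical lesion specification along a severity axis
#'
#' Maps a scalar severity in \[0, 1\] to a [lesion_spec()] following the
#' dominant structural signature of stroke: progressive loss of
#' inter-hemispheric connectivity (complete disconnection at maximal
#' severity), a growing focal node lesion, and mild diffuse edge dropout.
#' This is the severity path used by the cohort generator and by the
#' criticality-loss boundary analysis.
#'
#' @param parcellation the parcellation.
#' @param severity scalar in \[0, 1\].
#' @param seed integer seed (lesion placement and dropout).
#' @param max_lesion_nodes focal lesion size at severity 1.
#' @param dropout_rate diffuse edge dropout at severity 1.
#' @param hemisphere lesioned hemisphere.
#' @return a [lesion_spec()].
#' @export
stroke_severity_spec <- function(parcellation, severity, seed = 1L,
                                 max_lesion_nodes = 12L, dropout_rate = 0.15,
                                 hemisphere = "L") {
  stopifnot(severity >= 0, severity <= 1)
  n_les <- round(max_lesion_nodes * severity)
  lesion_spec(
    lesioned_nodes = if (n_les > 0)
      sample_lesion_nodes(parcellation, n_les, hemisphere, seed) else integer(),
    interhemispheric_scale = max(0, 1 - 1.02 * severity),
    edge_dropout = dropout_rate * severity,
    seed = seed)
}

#' Partial longitudinal remodeling toward a healthy template
#'
#' Moves the surviving-node submatrix a fraction of the way back toward the
#' healthy template (restoration) and adds a fraction of new edges absent
#' from the template (rewiring), emulating white-matter remodeling between
#' the 3-month and 12-month scans. `recovery_fraction = 1,
#' rewire_fraction = 0` reproduces the template exactly on non-lesioned
#' nodes.
#'
#' @param lesioned,healthy_template `raw_connectome`s on the same
#'   parcellation.
#' @param recovery_fraction fraction in \[0,1\] of the template/lesioned
#'   difference restored.
#' @param rewire_fraction new edges added, as a fraction of the template's
#'   surviving-node edge count.
#' @param seed integer seed.
#' @return a remodeled `raw_connectome` (timepoint set to "t2").
#' @export
remodel_recovery <- function(lesioned, healthy_template, recovery_fraction,
                             rewire_fraction = 0, seed = 1L) {
  if (recovery_fraction < 0 || recovery_fraction > 1 ||
      rewire_fraction < 0 || rewire_fraction > 1)
    stop("fractions must be in [0, 1]")
  if (!identical(dim(lesioned$W), dim(healthy_template$W)))
    stop("connectomes must share a parcellation")
  W <- lesioned$W
  Wt <- healthy_template$W
  dead <- which(rowSums(W) == 0 & rowSums(Wt) > 0)  # lesioned nodes stay dead
  alive <- setdiff(seq_len(nrow(W)), dead)
  sub <- W[alive, alive, drop = FALSE]
  sub <- round(sub + recovery_fraction * (Wt[alive, alive, drop = FALSE] - sub))
  W[alive, alive] <- sub

  if (rewire_fraction > 0 && length(alive) > 1) {
    set.seed(derive_seed(seed, 83L))
    Wa <- W[alive, alive, drop = FALSE]
    Ta <- Wt[alive, alive, drop = FALSE]
    cand <- which(upper.tri(Wa) & Ta == 0 & Wa == 0)
    n_new <- min(length(cand),
                 round(rewire_fraction * sum(Ta[upper.tri(Ta)] > 0)))
    if (n_new > 0) {
      add <- sample(cand, n_new)
      Wa[add] <- 4 + rgeom(n_new, prob = 1 / 9)  # counts surviving the threshold
      Wa[lower.tri(Wa)] <- t(Wa)[lower.tri(Wa)]
      W[alive, alive] <- Wa
    }
  }
  new_raw_connectome(W, lesioned$parcellation, lesioned$subject_id, "t2")
}

#' Synthetic composite behavior score
#'
#' Linear-Gaussian stand-in for a multi-domain neuropsychological composite:
#' `B_raw = intercept + c1 * I1 - c2 * I2 + N(0, noise_sd)`, standardized to
#' mean 0 / SD 1 on the control subset (so patient scores read as SD units
#' below the control average).
#'
#' @param I1,I2 criticality integrals per subject.
#' @param coefficients named vector `c(intercept, c1, c2)`. The defaults are
#'   scaled to the typical cohort spread of I1 (~ SD 3) and I2 (~ SD 0.4) so
#'   that with the default noise the sample correlation of B with I1 lands in
#'   the moderate band reported for real behavior composites (~0.4-0.5).
#' @param noise_sd Gaussian noise SD (raw score units).
#' @param seed integer seed.
#' @param controls logical vector marking the standardization subset
#'   (default: all subjects).
#' @return numeric vector of standardized composite scores.
#' @export
generate_behavior <- function(I1, I2,
                              coefficients = c(intercept = 0, c1 = 0.3, c2 = 2),
                              noise_sd = 1.5, seed = 1L,
                              controls = rep(TRUE, length(I1))) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  stopifnot(length(I1) == length(I2), all(is.finite(I1)), all(is.finite(I2)))
  set.seed(derive_seed(seed, 97L))
  b <- coefficients[["intercept"]] + coefficients[["c1"]] * I1 -
    coefficients[["c2"]] * I2 + rnorm(length(I1), 0, noise_sd)
  mu <- mean(b[controls])
  s <- sd(b[controls])
  if (!is.finite(s) || s == 0) s <- 1
  (b - mu) / s
}
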