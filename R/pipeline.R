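#' Generate a synthetic longitudinal cohort
#'
#' Builds control and patient subject records on a shared parcellation.
#' Controls are scanned twice: the second scan re-samples a small fraction
#' of edge counts (measurement jitter) but leaves the topology intact.
#' Patients carry a focal lesion plus inter-hemispheric weight loss and
#' edge dropout at `t1`, and are partially remodeled toward their own
#' pre-lesion connectome at `t2`.
#'
#' @param n_controls,n_patients cohort sizes.
#' @param parcellation shared parcellation (default 324 nodes).
#' @param seed master seed.
#' @param lesion_size nodes in each patient's focal lesion (scalar or
#'   per-patient vector; default 12).
#' @param interhemispheric_scale,edge_dropout lesion severity parameters
#'   (scalars or per-patient vectors).
#' @param recovery_fraction,rewire_fraction remodeling parameters for `t2`
#'   (scalars or per-patient vectors; defaults 0.6 and 0.1).
#' @param calibration generator calibration for the healthy base
#'   connectomes.
#' @return list of subject records, each a list with `subject_id`, `group`,
#'   `timepoint` and `connectome`.
#' @export
generate_cohort <- function(n_controls = 14, n_patients = 14,
                            parcellation = generate_parcellation(),
                            seed = 1L,
                            lesion_size = 12,
                            interhemispheric_scale = 0.55,
                            edge_dropout = 0.25,
                            recovery_fraction = 0.6,
                            rewire_fraction = 0.1,
                            calibration = healthy_calibration()) {
  rec <- function(id, group, tp, con) {
    con$subject_id <- id
    con$timepoint <- tp
    list(subject_id = id, group = group, timepoint = tp, connectome = con)
  }
  expand <- function(x, n) if (length(x) == 1) rep(x, n) else x
  lesion_size <- expand(lesion_size, n_patients)
  interhemispheric_scale <- expand(interhemispheric_scale, n_patients)
  edge_dropout <- expand(edge_dropout, n_patients)
  recovery_fraction <- expand(recovery_fraction, n_patients)
  rewire_fraction <- expand(rewire_fraction, n_patients)

  cohort <- list()
  for (i in seq_len(n_controls)) {
    id <- sprintf("con%02d", i)
    base <- generate_healthy_connectome(parcellation, calibration,
                                        seed = derive_seed(seed, 1000 + i),
                                        subject_id = id)
    cohort[[length(cohort) + 1L]] <- rec(id, "control", "t1", base)
    cohort[[length(cohort) + 1L]] <-
      rec(id, "control", "t2",
          rescan_connectome(base, seed = derive_seed(seed, 2000 + i)))
  }
  for (i in seq_len(n_patients)) {
    id <- sprintf("pat%02d", i)
    base <- generate_healthy_connectome(parcellation, calibration,
                                        seed = derive_seed(seed, 3000 + i),
                                        subject_id = id)
    spec <- lesion_spec(
      sample_lesion_nodes(parcellation, lesion_size[i],
                          hemisphere = c("L", "R")[1 + i %% 2],
                          seed = derive_seed(seed, 4000 + i)),
      interhemispheric_scale = interhemispheric_scale[i],
      edge_dropout = edge_dropout[i],
      seed = derive_seed(seed, 5000 + i))
    t1 <- apply_lesion(base, spec)
    t2 <- remodel_recovery(t1, base, recovery_fraction[i], rewire_fraction[i],
                           seed = derive_seed(seed, 6000 + i))
    cohort[[length(cohort) + 1L]] <- rec(id, "patient", "t1", t1)
    cohort[[length(cohort) + 1L]] <- rec(id, "patient", "t2", t2)
  }
  cohort
}

# Second healthy scan: re-draw the counts of a small fraction of existing
# edges (tractography repeat-measurement noise), topology unchanged.
rescan_connectome <- function(connectome, refresh = 0.05, seed = 1L) {
  W <- connectome$W
  set.seed(derive_seed(seed, 7L))
  up <- which(upper.tri(W) & W > 0)
  pick <- up[runif(length(up)) < refresh]
  W[pick] <- pmax(1, round(W[pick] * exp(rnorm(length(pick), 0, 0.2))))
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  new_raw_connectome(W, connectome$parcellation, connectome$subject_id, "t2")
}

#' Run the cohort-level criticality analysis end to end
#'
#' For every subject and timepoint: streamline threshold, homeostatic
#' normalization, threshold sweep, criticality profile, structural graph
#' metrics, and (optionally) BOLD synthesis with FC summaries at the
#' subject's critical point. Control-group average curves define the
#' reference against which per-subject Euclidean profile distances are
#' computed; paired patients get recovery indexes.
#'
#' @param cohort list of subject records from [generate_cohort()].
#' @param params a [model_params()] list (per-subject seeds are derived
#'   from `params$seed`).
#' @param min_streamlines streamline threshold.
#' @param compute_fc also synthesize BOLD and FC summaries (slower).
#' @param behavior optional named numeric vector of composite scores keyed
#'   by subject id (merged into the subject table).
#' @return list of data frames: `subjects` (one row per subject x
#'   timepoint: T_c, I1, I2, monotonic flag, K, Q, E_global, H_SC,
#'   distances, FC summaries), `recovery` (per patient: recovery indexes
#'   and distance change), and `reference` (control-average curves).
#' @export
run_cohort_analysis <- function(cohort, params = model_params(),
                                min_streamlines = 3, compute_fc = FALSE,
                                behavior = NULL) {
  profiles <- list()
  rows <- list()
  for (s in seq_along(cohort)) {
    rec <- cohort[[s]]
    thr <- threshold_connectome(rec$connectome, min_streamlines)
    norm <- homeostatic_normalize(thr)
    p_s <- params
    p_s$seed <- derive_seed(params$seed, 100000 + s)
    prof <- simulate_sweep(norm, p_s)
    gm <- graph_metrics(norm, louvain_seed = derive_seed(params$seed, s))
    key <- paste(rec$subject_id, rec$timepoint, sep = ".")
    profiles[[key]] <- prof
    row <- data.frame(subject_id = rec$subject_id, group = rec$group,
                      timepoint = rec$timepoint,
                      T_c = prof$T_c, I1 = prof$I1, I2 = prof$I2,
                      monotonic_S2 = prof$monotonic_S2,
                      K = gm$K, Q = gm$Q, E_global = gm$E_global,
                      H_SC = gm$H_SC, stringsAsFactors = FALSE)
    if (compute_fc) {
      fc <- subject_fc(norm, prof, p_s)
      row$mean_FC <- fc$mean_FC
      row$homotopic_FC <- fc$homotopic_FC
      row$H_FC <- fc$H
    }
    rows[[s]] <- row
  }
  subjects <- do.call(rbind, rows)

  # control-average reference curves and per-subject distances
  con_keys <- subjects$group == "control"
  reference <- list(T_grid = params$T_grid)
  for (curve in c("S1", "S2", "mean_A", "sd_A")) {
    mat <- vapply(profiles[con_keys], `[[`, numeric(length(params$T_grid)),
                  curve)
    reference[[curve]] <- rowMeans(mat)
    subjects[[paste0("d_", curve)]] <-
      vapply(profiles, profile_distance, numeric(1),
             reference_curve = reference[[curve]], curve = curve)
  }

  if (!is.null(behavior))
    subjects$B <- unname(behavior[subjects$subject_id])

  recovery <- cohort_recovery_table(subjects)
  list(subjects = subjects, recovery = recovery, reference = reference,
       profiles = profiles)
}

# BOLD/FC summaries at the subject's critical point (grid midpoint when the
# critical point is undefined).
subject_fc <- function(norm, prof, params, hrf = hrf_params()) {
  T_use <- if (is.na(prof$T_c)) stats::median(prof$T_grid) else prof$T_c
  prop <- as_push_csr(norm$W_tilde)
  traj <- gh_trajectory_cpp(prop$ptr, prop$idx, prop$w, T_use,
                            params$r1, params$r2, params$t_s, params$seed)
  bold <- states_to_bold(traj, hrf)
  fc_summaries(fc_pearson(bold), norm$parcellation)
}

cohort_recovery_table <- function(subjects) {
  pat <- subjects[subjects$group == "patient", ]
  ids <- unique(pat$subject_id)
  out <- list()
  for (id in ids) {
    a <- pat[pat$subject_id == id & pat$timepoint == "t1", ]
    b <- pat[pat$subject_id == id & pat$timepoint == "t2", ]
    if (nrow(a) != 1 || nrow(b) != 1) {
      warning("subject ", id, " lacks a paired timepoint; excluded")
      next
    }
    out[[id]] <- data.frame(
      subject_id = id,
      dK = recovery_index(b$K, a$K),
      dH_SC = recovery_index(b$H_SC, a$H_SC),
      dE_global = recovery_index(b$E_global, a$E_global),
      dQ = recovery_index(b$Q, a$Q),
      dI2 = recovery_index(b$I2, a$I2),
      d_S2_t1 = a$d_S2, d_S2_t2 = b$d_S2,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Correlation table with FDR adjustment
#'
#' Pearson correlation, R-squared and two-tailed p-value for each requested
#' pair of columns of a results table, with Benjamini-Hochberg adjustment
#' across the requested family.
#'
#' @param results data frame (e.g. the `subjects` table of
#'   [run_cohort_analysis()]).
#' @param pairs list of character vectors `c(var_x, var_y)`.
#' @return data frame with `var_x`, `var_y`, `rho`, `r_squared`, `p`,
#'   `p_adj`, `n`.
#' @export
correlate_outputs <- function(results, pairs) {
  rows <- lapply(pairs, function(pr) {
    x <- results[[pr[1]]]
    y <- results[[pr[2]]]
    ok <- complete.cases(x, y)
    if (sum(ok) < 3)
      return(data.frame(var_x = pr[1], var_y = pr[2], rho = NA_real_,
                        r_squared = NA_real_, p = NA_real_, n = sum(ok)))
    ct <- cor.test(x[ok], y[ok])
    data.frame(var_x = pr[1], var_y = pr[2], rho = unname(ct$estimate),
               r_squared = unname(ct$estimate)^2, p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
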