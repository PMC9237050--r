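#' Double-gamma hemodynamic response parameters
#'
#' Canonical double-gamma HRF constants: shape exponents `a1 = 6`,
#' `a2 = 12`, scales `b1 = b2 = 0.9` s, undershoot ratio `c = 0.35`, with
#' delays `d_i = a_i * b_i` (5.4 s peak, 10.8 s undershoot). `dt` is the
#' wall-clock duration of one model step; the default 0.45 s makes a
#' 2000-step run span 15 minutes, the length of a typical resting-state
#' fMRI acquisition.
#'
#' @param a1,a2 shape exponents.
#' @param b1,b2 scale constants (seconds).
#' @param c undershoot ratio.
#' @param dt seconds per model step.
#' @return an `hrf_params` list (with derived `d1`, `d2`).
#' @export
hrf_params <- function(a1 = 6, a2 = 12, b1 = 0.9, b2 = 0.9, c = 0.35,
                       dt = 0.45) {
  stopifnot(a1 > 0, a2 > 0, b1 > 0, b2 > 0, c > 0, dt > 0)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c = c,
       d1 = a1 * b1, d2 = a2 * b2, dt = dt)
}

#' Sampled double-gamma hemodynamic response kernel
#'
#' Evaluates
#' `h(tau) = (tau/d1)^a1 exp(-(tau-d1)/b1) - c (tau/d2)^a2 exp(-(tau-d2)/b2)`
#' on the `dt` grid over `[0, duration]`. The kernel rises to a peak near
#' 5 s and has a late negative undershoot.
#'
#' @param params an [hrf_params()] list.
#' @param duration kernel length in seconds (default 30).
#' @return numeric kernel sampled every `dt` seconds.
#' @export
hrf_kernel <- function(params = hrf_params(), duration = 30) {
  if (duration <= 0) stop("duration must be positive")
  if (params$dt <= 0) stop("dt must be positive")
  tau <- seq(0, duration, by = params$dt)
  (tau / params$d1)^params$a1 * exp(-(tau - params$d1) / params$b1) -
    params$c * (tau / params$d2)^params$a2 * exp(-(tau - params$d2) / params$b2)
}

# Symmetric windowed-sinc FIR band-pass kernel (Hamming window). Normalized
# frequencies f = f_Hz * dt; the number of taps covers ~4 periods of the
# low edge so the 0.01 Hz transition is resolved.
fir_bandpass_kernel <- function(low, high, dt, n_taps = NULL) {
  nyq <- 1 / (2 * dt)
  if (low <= 0 || high >= nyq || low >= high)
    stop("band must satisfy 0 < low < high < Nyquist for this dt")
  if (is.null(n_taps)) n_taps <- 2L * floor(2 / (low * dt)) + 1L
  m <- (n_taps - 1) / 2
  n <- seq(-m, m)
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  f1 <- low * dt
  f2 <- high * dt
  h <- 2 * f2 * sinc(2 * f2 * n) - 2 * f1 * sinc(2 * f1 * n)
  w <- 0.54 + 0.46 * cos(pi * n / m)
  h * w
}

# Zero-lag FIR filtering: the symmetric (linear-phase) kernel is applied by
# full convolution and the group delay removed, which leaves exactly zero
# phase shift at every frequency.
apply_fir <- function(x, kernel) {
  m <- (length(kernel) - 1) / 2
  y <- stats::convolve(x, rev(kernel), type = "open")
  y[(m + 1):(m + length(x))]
}

#' Transform simulated node activity into BOLD-like signals
#'
#' Convolves each node's binary activity indicator with the double-gamma
#' kernel (causal convolution), discards a kernel-length warm-up, and
#' band-pass filters the result with a zero-lag linear-phase FIR filter
#' (default band 0.01-0.1 Hz). A half-filter-length segment at each end is
#' trimmed after filtering to suppress edge transients.
#'
#' @param traj integer state matrix (steps x nodes; 0/1/2 coding, only
#'   state 1 counts as activity) or an already-binary activity matrix.
#' @param params an [hrf_params()] list.
#' @param band band-pass edges in Hz.
#' @param kernel_duration HRF kernel length in seconds.
#' @return numeric matrix (time x nodes) of filtered BOLD-like signals.
#' @export
states_to_bold <- function(traj, params = hrf_params(), band = c(0.01, 0.1),
                           kernel_duration = 30) {
  act <- (traj == 1) * 1
  k <- hrf_kernel(params, kernel_duration)
  L <- length(k)
  if (nrow(act) <= 2 * L) stop("trajectory shorter than the kernel warm-up")
  conv_causal <- function(x) {
    y <- stats::convolve(x, rev(k), type = "open")
    y[seq_along(x)]
  }
  bold <- apply(act, 2, conv_causal)
  bold <- bold[-seq_len(L), , drop = FALSE]           # convolution warm-up
  fk <- fir_bandpass_kernel(band[1], band[2], params$dt)
  filt <- apply(bold, 2, apply_fir, kernel = fk)
  trim <- min((length(fk) - 1) %/% 4, (nrow(filt) - 2) %/% 2)
  filt[(trim + 1):(nrow(filt) - trim), , drop = FALSE]
}

#' Functional connectivity by Pearson correlation
#'
#' Pairwise Pearson correlation of node signals; zero-variance nodes yield
#' `NA` rows/columns (excluded from downstream summaries). The diagonal is
#' set to 1.
#'
#' @param signals time x nodes matrix.
#' @return symmetric correlation matrix of class `fc_matrix`.
#' @export
fc_pearson <- function(signals) {
  if (nrow(signals) < 2) stop("need at least 2 time points")
  v <- apply(signals, 2, var)
  FC <- suppressWarnings(cor(signals))
  FC[v == 0, ] <- NA_real_
  FC[, v == 0] <- NA_real_
  diag(FC) <- 1
  structure(FC, class = c("fc_matrix", "matrix", "array"))
}

#' Summaries of a functional connectivity matrix
#'
#' \describe{
#'   \item{mean_FC}{mean of the upper-triangular absolute correlations.}
#'   \item{homotopic_FC}{mean signed correlation over the parcellation's
#'     homotopic pairs (`NA` when no pairs are defined).}
#'   \item{H}{normalized Shannon entropy of the upper-triangular `|FC|`
#'     values, `bins` equal bins on \[0,1\] (default 20).}
#' }
#'
#' @param fc an [fc_pearson()] matrix.
#' @param parcellation the parcellation (for homotopic pairs).
#' @param bins entropy bin count.
#' @return list with `mean_FC`, `homotopic_FC`, `H`.
#' @export
fc_summaries <- function(fc, parcellation, bins = 20L) {
  a <- abs(fc[upper.tri(fc)])
  a <- a[!is.na(a)]
  mean_FC <- mean(a)
  H <- binned_entropy(pmin(a, 1), bins)
  hp <- homotopic_pairs(parcellation)
  homotopic_FC <- if (nrow(hp)) mean(fc[hp], na.rm = TRUE) else NA_real_
  list(mean_FC = mean_FC, homotopic_FC = homotopic_FC, H = H)
}
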