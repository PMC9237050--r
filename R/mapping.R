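#' Vectorize the upper triangle of a symmetric connectome
#'
#' Stacks the off-diagonal upper-triangular entries in row-major pair order
#' (1,2), (1,3), ..., (1,N), (2,3), ... — a stable ordering shared by all
#' subjects, of length `N(N-1)/2` (52,326 for the default 324-node
#' parcellation).
#'
#' @param W symmetric matrix (or a `raw_connectome`).
#' @param tol asymmetry tolerance.
#' @return numeric edge vector with attributes `n_nodes` and `pair_index`
#'   (two-column matrix of node pairs).
#' @export
edge_vectorize <- function(W, tol = 1e-8) {
  if (inherits(W, "raw_connectome")) W <- W$W
  if (nrow(W) != ncol(W) || max(abs(W - t(W))) > tol)
    stop("connectome must be symmetric")
  N <- nrow(W)
  lt <- lower.tri(W)
  v <- W[lt]   # column-major lower triangle == row-major upper-pair order
  idx <- which(lt, arr.ind = TRUE)
  structure(v, n_nodes = N, pair_index = cbind(i = idx[, 2L], j = idx[, 1L]))
}

#' Back-project an edge vector to a symmetric matrix
#'
#' Inverse of [edge_vectorize()]: rebuilds the symmetric zero-diagonal
#' matrix.
#'
#' @param values edge vector of length `N(N-1)/2`.
#' @param n_nodes N (taken from the vector's attribute when absent).
#' @return symmetric `n_nodes x n_nodes` matrix.
#' @export
edge_unvectorize <- function(values, n_nodes = attr(values, "n_nodes")) {
  if (is.null(n_nodes)) stop("n_nodes not supplied")
  if (length(values) != n_nodes * (n_nodes - 1) / 2)
    stop("edge vector has the wrong length")
  M <- matrix(0, n_nodes, n_nodes)
  M[lower.tri(M)] <- as.numeric(values)
  M + t(M)
}

#' Closed-form ridge regression weights
#'
#' `W = (X'X + lambda I)^(-1) X'Y` on already-standardized inputs.
#'
#' @param X predictor matrix (n x p).
#' @param Y outcome vector.
#' @param lambda nonnegative regularization strength.
#' @return weight vector of length p.
#' @export
ridge_closed_form <- function(X, Y, lambda) {
  X <- as.matrix(X)
  G <- crossprod(X) + diag(lambda, ncol(X))
  w <- tryCatch(solve(G, crossprod(X, Y)),
                error = function(e)
                  stop("singular system; use lambda > 0 for collinear X"))
  drop(w)
}

# Exact leave-one-out mean squared error of ridge regression for each
# lambda, via the SVD hat-matrix identity e_loo = e / (1 - h_ii).
ridge_loo_mse <- function(X, y, lambdas) {
  sv <- svd(X)
  d2 <- sv$d^2
  uy <- crossprod(sv$u, y)
  vapply(lambdas, function(l) {
    shrink <- d2 / (d2 + l)
    fitted <- sv$u %*% (shrink * uy)
    h <- rowSums(sweep(sv$u^2, 2, shrink, `*`))
    mean(((y - fitted) / (1 - pmin(h, 1 - 1e-10)))^2)
  }, numeric(1))
}

#' Coefficient of determination, printed form
#'
#' `R^2 = 1 - sum((Y - Y')^2) / sum((Y - Ybar)^2)` where, in the printed
#' convention used for the LOOCV maps, `Ybar` is the mean of the
#' *predicted* values; `center = "observed"` switches to the conventional
#' observed-mean denominator.
#'
#' @param Y observed values.
#' @param Y_pred predicted values.
#' @param center "predicted" (printed form, default) or "observed".
#' @return R-squared (may be negative); `NA` on a zero denominator.
#' @export
r_squared_printed <- function(Y, Y_pred,
                              center = c("predicted", "observed")) {
  center <- match.arg(center)
  stopifnot(length(Y) == length(Y_pred), length(Y) >= 2)
  mu <- if (center == "predicted") mean(Y_pred) else mean(Y)
  denom <- sum((Y - mu)^2)
  if (denom == 0) return(NA_real_)
  1 - sum((Y - Y_pred)^2) / denom
}

#' PCA + ridge regression with leave-one-out cross-validation
#'
#' The connectome-predictive mapping: principal components of the
#' subject x edge feature matrix are used as ridge predictors of a
#' criticality index, in an outer leave-one-subject-out loop. Within each
#' fold the PCA basis, component standardization and outcome
#' standardization are estimated on the training subjects only (no
#' leakage); the ridge penalty is tuned on a logarithmic grid by exact
#' inner leave-one-out error; components explaining `var_frac` of the
#' training variance are retained. Fold weights are back-projected through
#' the PCA basis and the standardization to edge space, so they are
#' comparable and averageable across folds.
#'
#' @param features n x p matrix (rows: subjects; columns: edges from
#'   [edge_vectorize()]).
#' @param outcome length-n criticality values (e.g. I2).
#' @param var_frac PCA explained-variance fraction retained (default 0.95).
#' @param lambda_grid ridge penalties (default decades from 1e-5 to 1e5).
#' @param pca_scope "fold" (leakage-safe, default) or "global".
#' @return list with `predictions`, `r_squared` (printed form),
#'   `r_squared_observed` (conventional centering), `fold_weights`
#'   (n x p edge-space matrix), `lambda` (per fold), `n_pc` (per fold).
#' @export
ridge_loocv <- function(features, outcome, var_frac = 0.95,
                        lambda_grid = 10^seq(-5, 5),
                        pca_scope = c("fold", "global")) {
  pca_scope <- match.arg(pca_scope)
  X <- as.matrix(features)
  y <- as.numeric(outcome)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 subjects")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite inputs")
  if (sd(y) == 0) {
    warning("constant outcome; R^2 undefined")
    return(list(predictions = rep(mean(y), n), r_squared = NA_real_,
                r_squared_observed = NA_real_,
                fold_weights = matrix(0, n, ncol(X)),
                lambda = rep(NA_real_, n), n_pc = rep(0L, n)))
  }

  global_pca <- if (pca_scope == "global") prcomp(X, center = TRUE) else NULL

  preds <- numeric(n)
  lambdas <- numeric(n)
  n_pcs <- integer(n)
  fold_w <- matrix(0, n, ncol(X))
  for (k in seq_len(n)) {
    tr <- setdiff(seq_len(n), k)
    if (is.null(global_pca)) {
      pc <- prcomp(X[tr, , drop = FALSE], center = TRUE)
      ctr <- pc$center
      rot <- pc$rotation
      scores_tr <- pc$x
    } else {
      ctr <- global_pca$center
      rot <- global_pca$rotation
      scores_tr <- sweep(X[tr, , drop = FALSE], 2, ctr) %*% rot
    }
    ev <- apply(scores_tr, 2, var)
    m <- max(1L, which(cumsum(ev) / sum(ev) >= var_frac)[1])
    rot <- rot[, seq_len(m), drop = FALSE]
    scores_tr <- scores_tr[, seq_len(m), drop = FALSE]

    s_mu <- colMeans(scores_tr)
    s_sd <- apply(scores_tr, 2, sd)
    s_sd[s_sd == 0] <- 1
    Z <- sweep(sweep(scores_tr, 2, s_mu), 2, s_sd, `/`)
    y_mu <- mean(y[tr])
    y_sd <- sd(y[tr])
    if (y_sd == 0) y_sd <- 1
    yz <- (y[tr] - y_mu) / y_sd

    lam <- lambda_grid[which.min(ridge_loo_mse(Z, yz, lambda_grid))]
    beta <- ridge_closed_form(Z, yz, lam)

    z_new <- (drop((X[k, ] - ctr) %*% rot) - s_mu) / s_sd
    preds[k] <- y_mu + y_sd * sum(z_new * beta)
    lambdas[k] <- lam
    n_pcs[k] <- m
    # edge-space weights in outcome units per raw edge unit
    fold_w[k, ] <- drop(rot %*% (beta / s_sd)) * y_sd
  }
  list(predictions = preds,
       r_squared = r_squared_printed(y, preds),
       r_squared_observed = r_squared_printed(y, preds, center = "observed"),
       fold_weights = fold_w, lambda = lambdas, n_pc = n_pcs)
}

#' Permutation test of the LOOCV R-squared
#'
#' Permutes the outcome across subjects `n_perm` times, reruns the full
#' LOOCV per permutation, and reports
#' `p = #(null R^2 > observed R^2) / n_perm` (strict inequality as
#' printed; `p = 0` is possible). `add_one = TRUE` switches to the
#' (obs+1)/(n+1) convention.
#'
#' @param observed_r2 the unpermuted R-squared.
#' @param features,outcome as in [ridge_loocv()].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param store_weights keep each permutation's consensus edge weights
#'   (rows of the returned `null_weights`), needed for the edge
#'   reliability test.
#' @param add_one use the add-one permutation p-value convention.
#' @param ... passed to [ridge_loocv()].
#' @return list with `p`, `null_r2`, and optionally `null_weights`.
#' @export
permutation_pvalue <- function(observed_r2, features, outcome,
                               n_perm = 10000L, seed = 1L,
                               store_weights = FALSE, add_one = FALSE, ...) {
  stopifnot(n_perm >= 1)
  null_r2 <- numeric(n_perm)
  null_w <- if (store_weights)
    matrix(0, n_perm, ncol(as.matrix(features))) else NULL
  for (b in seq_len(n_perm)) {
    set.seed(derive_seed(seed, b))
    fit <- ridge_loocv(features, sample(outcome), ...)
    null_r2[b] <- fit$r_squared
    if (store_weights) null_w[b, ] <- colMeans(fit$fold_weights)
  }
  p <- if (add_one) (sum(null_r2 > observed_r2) + 1) / (n_perm + 1)
       else sum(null_r2 > observed_r2) / n_perm
  out <- list(p = p, null_r2 = null_r2)
  if (store_weights) out$null_weights <- null_w
  out
}

#' Consensus predictive edge map
#'
#' Averages the fold weights into a single consensus edge-weight vector,
#' flags statistically reliable edges by a per-edge Welch t-test of the
#' fold-weight distribution against the pooled permutation-null weights
#' (Benjamini-Hochberg corrected), aggregates the back-projected symmetric
#' weight matrix into network-pair averages
#' `<W>_(X,Y) = sum_(i in X) sum_(j in Y) W_ij / (N_X * N_Y)`, and ranks
#' the top edges by absolute consensus weight.
#'
#' @param fold_weights n_folds x p matrix from [ridge_loocv()].
#' @param null_weights n_perm x p matrix from [permutation_pvalue()] with
#'   `store_weights = TRUE`, or `NULL` (reliability mask omitted with a
#'   warning).
#' @param parcellation the parcellation (for network labels).
#' @param fdr_alpha FDR level of the reliability test.
#' @param top_k number of top edges returned.
#' @return list with `consensus_edge_weights`, `reliability_mask`,
#'   `network_averages` (RSN x RSN matrix), `top_edges` (data frame
#'   `i`, `j`, `weight`, `reliable`).
#' @export
consensus_map <- function(fold_weights, null_weights = NULL, parcellation,
                          fdr_alpha = 0.05, top_k = 200L) {
  consensus <- colMeans(fold_weights)
  p_edges <- length(consensus)

  reliability <- rep(NA, p_edges)
  if (is.null(null_weights)) {
    warning("no null weight distributions; reliability mask omitted")
  } else {
    reliability <- welch_bh_mask(fold_weights, null_weights, fdr_alpha)
  }

  N <- nrow(parcellation)
  Wmat <- edge_unvectorize(consensus, N)
  nets <- sort(unique(parcellation$network))
  net_avg <- matrix(0, length(nets), length(nets),
                    dimnames = list(nets, nets))
  for (a in seq_along(nets)) for (b in seq_along(nets)) {
    ia <- which(parcellation$network == nets[a])
    ib <- which(parcellation$network == nets[b])
    net_avg[a, b] <- sum(Wmat[ia, ib]) / (length(ia) * length(ib))
  }

  pi <- attr(edge_vectorize(Wmat), "pair_index")
  ord <- order(abs(consensus), decreasing = TRUE)[seq_len(min(top_k, p_edges))]
  top <- data.frame(i = pi[ord, 1], j = pi[ord, 2],
                    weight = consensus[ord], reliable = reliability[ord])
  list(consensus_edge_weights = consensus, reliability_mask = reliability,
       network_averages = net_avg, top_edges = top)
}

# Vectorized per-edge Welch t-test (fold weights vs null weights) with BH
# correction; returns the logical reliability mask.
welch_bh_mask <- function(fold_weights, null_weights, fdr_alpha) {
  n1 <- nrow(fold_weights)
  n2 <- nrow(null_weights)
  m1 <- colMeans(fold_weights)
  m2 <- colMeans(null_weights)
  v1 <- apply(fold_weights, 2, var)
  v2 <- apply(null_weights, 2, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(pmax(se2, .Machine$double.xmin))
  df <- se2^2 / pmax(v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)),
                     .Machine$double.xmin)
  pv <- 2 * pt(-abs(tstat), df)
  pv[!is.finite(pv)] <- 1
  p.adjust(pv, method = "BH") < fdr_alpha
}
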