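test_that("parcellation layout matches the 324-node default and is valid", {
  p <- generate_parcellation(seed = 3)
  expect_equal(sum(p$hemisphere == "L"), 159)
  expect_equal(sum(p$hemisphere == "R"), 165)
  expect_equal(nrow(p), 324)
  # homotopy is symmetric and crosses hemispheres
  paired <- which(!is.na(p$homotope))
  expect_equal(p$homotope[p$homotope[paired]], p$node_id[paired])
  expect_true(all(p$hemisphere[paired] != p$hemisphere[p$homotope[paired]]))
  # every network is bilateral
  expect_true(all(table(p$network, p$hemisphere) > 0))
})

test_that("small parcellations are fully labeled and deterministic", {
  p <- generate_parcellation(4, n_networks = 2, seed = 5)
  expect_equal(nrow(p), 4)
  expect_false(any(is.na(p$network)))
  paired <- which(!is.na(p$homotope))
  expect_equal(p$homotope[p$homotope[paired]], p$node_id[paired])
  expect_identical(generate_parcellation(40, 4, seed = 11),
                   generate_parcellation(40, 4, seed = 11))
  expect_error(generate_parcellation(4, n_networks = 9), "n_networks")
})

test_that("healthy connectomes are symmetric integer count matrices", {
  con <- tiny_connectome(seed = 2)
  expect_identical(con$W, t(con$W))
  expect_true(all(diag(con$W) == 0))
  expect_true(all(con$W >= 0))
  expect_equal(con$W, round(con$W))
  # determinism
  expect_identical(con$W, tiny_connectome(seed = 2)$W)
  expect_error(
    generate_healthy_connectome(tiny_parcellation(),
                                healthy_calibration(k_core = 60)),
    "infeasible")
})

test_that("homotopic edges are elevated over other inter-hemispheric edges", {
  parc <- tiny_parcellation()
  hp <- homotopic_pairs(parc)
  cross <- outer(parc$hemisphere, parc$hemisphere, "!=")
  homo_w <- other_w <- numeric(0)
  for (s in 1:20) {
    W <- tiny_connectome(parc, seed = 100 + s)$W
    hmask <- matrix(FALSE, nrow(W), ncol(W))
    hmask[hp] <- TRUE
    hmask <- hmask | t(hmask)
    homo_w <- c(homo_w, W[hmask & cross])
    ow <- W[!hmask & cross & upper.tri(W)]
    other_w <- c(other_w, ow[ow > 0])
  }
  expect_gt(mean(homo_w), mean(other_w))
})

test_that("empty lesion spec is the identity", {
  con <- tiny_connectome()
  out <- apply_lesion(con, lesion_spec())
  expect_identical(out$W, con$W)
})

test_that("lesions zero node rows, reduce degree, and keep symmetry", {
  parc <- tiny_parcellation()
  con <- tiny_connectome(parc)
  nodes <- sample_lesion_nodes(parc, 10, "L", seed = 3)
  out <- apply_lesion(con, lesion_spec(nodes, interhemispheric_scale = 0.5,
                                       edge_dropout = 0.2, seed = 1))
  expect_true(all(out$W[nodes, ] == 0))
  expect_true(all(out$W[, nodes] == 0))
  expect_identical(out$W, t(out$W))
  K0 <- mean(rowSums(threshold_connectome(con)$W > 0))
  K1 <- mean(rowSums(threshold_connectome(out)$W > 0))
  expect_lt(K1, K0)
  expect_error(lesion_spec(edge_dropout = 1.5), "edge_dropout")
  expect_error(apply_lesion(con, lesion_spec(lesioned_nodes = 999L)),
               "not in the parcellation")
})

test_that("full recovery with no rewiring reproduces the template", {
  parc <- tiny_parcellation()
  base <- tiny_connectome(parc)
  nodes <- sample_lesion_nodes(parc, 6, "L", seed = 9)
  les <- apply_lesion(base, lesion_spec(nodes, 0.6, 0.3, seed = 2))
  rec <- remodel_recovery(les, base, recovery_fraction = 1, rewire_fraction = 0)
  alive <- setdiff(seq_len(nrow(base$W)), nodes)
  expect_identical(rec$W[alive, alive], base$W[alive, alive])
  expect_true(all(rec$W[nodes, ] == 0))
  expect_error(remodel_recovery(les, base, 1.5), "fractions")
})

test_that("degree is non-decreasing along the recovery grid (ensemble)", {
  parc <- tiny_parcellation()
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  Kbar <- rep(0, length(grid))
  for (s in 1:10) {
    base <- tiny_connectome(parc, seed = 200 + s)
    nodes <- sample_lesion_nodes(parc, 6, "L", seed = s)
    les <- apply_lesion(base, lesion_spec(nodes, 0.5, 0.4, seed = s))
    Kbar <- Kbar + vapply(grid, function(f) {
      rec <- remodel_recovery(les, base, f, 0, seed = s)
      mean(rowSums(threshold_connectome(rec)$W > 0))
    }, numeric(1))
  }
  expect_true(all(diff(Kbar / 10) >= 0))
})

test_that("paired recovery indexes of K and H_SC correlate positively", {
  parc <- tiny_parcellation()
  dK <- dH <- numeric(12)
  for (s in 1:12) {
    base <- tiny_connectome(parc, seed = 300 + s)
    nodes <- sample_lesion_nodes(parc, 4 + (s %% 5), "L", seed = s)
    les <- apply_lesion(base, lesion_spec(nodes, 0.6, 0.1 + 0.04 * (s %% 6),
                                          seed = s))
    rec <- remodel_recovery(les, base, 0.3 + 0.06 * (s %% 8), 0.05, seed = s)
    m1 <- graph_metrics(homeostatic_normalize(threshold_connectome(les)))
    m2 <- graph_metrics(homeostatic_normalize(threshold_connectome(rec)))
    dK[s] <- recovery_index(m2$K, m1$K)
    dH[s] <- recovery_index(m2$H_SC, m1$H_SC)
  }
  expect_gt(cor(dK, dH), 0)
})

test_that("behavior scores are linear, standardized and reproducible", {
  I1 <- c(30, 32, 28, 31, 29, 27, 33, 30.5)
  I2 <- c(0.4, 0.5, 0.3, 0.45, 0.35, 0.32, 0.52, 0.41)
  b0 <- generate_behavior(I1, I2, noise_sd = 0, seed = 1)
  co <- c(intercept = 0, c1 = 0.3, c2 = 2)
  raw <- co[["c1"]] * I1 - co[["c2"]] * I2
  expect_equal(b0, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)
  expect_equal(mean(b0), 0, tolerance = 1e-12)
  expect_equal(sd(b0), 1, tolerance = 1e-12)
  expect_identical(generate_behavior(I1, I2, seed = 4),
                   generate_behavior(I1, I2, seed = 4))
  expect_error(generate_behavior(I1, I2, noise_sd = -1), "noise_sd")
  # control-subset standardization
  ctrl <- c(rep(TRUE, 4), rep(FALSE, 4))
  b <- generate_behavior(I1, I2, noise_sd = 0.1, seed = 2, controls = ctrl)
  expect_equal(mean(b[ctrl]), 0, tolerance = 1e-12)
  expect_equal(sd(b[ctrl]), 1, tolerance = 1e-12)
})
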