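test_that("across-cluster scaling follows the weight-balance identity", {
  expect_equal(cluster_scaling(20, 1), 1)
  expect_equal(cluster_scaling(20, 20), 0)
  expect_equal(cluster_scaling(20, 2), 18 / 19)
  expect_error(cluster_scaling(1, 1), "Q")
  expect_warning(v <- cluster_scaling(20, 25), "negative")
  expect_equal(v, -5 / 19)
  # EI multiplier relation
  cl <- cluster_spec(network_spec(N_E = 400L, N_I = 100L,
                                  clustering_mode = "EI_weights",
                                  J_Eplus = 4, R_J = 0.75))
  expect_equal(cl$J_Iplus, 3.25)
  expect_equal(cl$J_Iminus, (20 - 3.25) / 19)
})

test_that("unclustered matrices have the right signs, weights and density", {
  spec <- small_spec()
  w <- derive_weights(spec)
  wm <- build_matrix(spec, seed = 5)
  J <- wm$J
  expect_equal(dim(J), c(500, 500))
  expect_true(all(Matrix::diag(J) == 0))
  # E columns carry only J_EE / J_IE, I columns only J_EI / J_II
  EE <- J[1:400, 1:400]
  expect_true(all(EE@x == w$J_EE))
  II <- J[401:500, 401:500]
  expect_true(all(II@x == w$J_II))
  # realized densities within 5 standard errors
  for (blk in list(list(r = 1:400, c = 1:400, p = spec$p_EE),
                   list(r = 1:400, c = 401:500, p = spec$p_EI),
                   list(r = 401:500, c = 1:400, p = spec$p_IE),
                   list(r = 401:500, c = 401:500, p = spec$p_II))) {
    n <- length(blk$r) * length(blk$c)
    se <- sqrt(blk$p * (1 - blk$p) / n)
    expect_lt(abs(block_density(J, blk$r, blk$c) - blk$p), 5 * se + 5 / n)
  }
  # reproducibility
  wm2 <- build_matrix(spec, seed = 5)
  expect_identical(wm$J@x, wm2$J@x)
  expect_identical(wm$J@i, wm2$J@i)
})

test_that("weight clustering scales within/across blocks and decouples at J+=Q", {
  spec <- small_spec(clustering_mode = "E_weights", J_Eplus = 20)
  w <- derive_weights(spec)
  wm <- build_matrix(spec, seed = 6)
  # across-cluster EE entries all exactly zero at J+ = Q (structural zeros
  # are dropped, so every stored EE entry lies within a cluster)
  EE <- wm$J[1:400, 1:400]
  trip <- Matrix::summary(EE)
  a <- wm$cluster$assignment_E
  expect_true(all(a[trip$i] == a[trip$j]))
  expect_true(all(abs(trip$x - 20 * w$J_EE) < 1e-14))

  # EI mode: within-cluster II entries equal J_I+ * J_II
  specEI <- small_spec(clustering_mode = "EI_weights", J_Eplus = 4,
                       R_J = 0.75)
  wmEI <- build_matrix(specEI, seed = 7)
  aI <- wmEI$cluster$assignment_I
  II <- wmEI$J[401:500, 401:500]
  tII <- Matrix::summary(II)
  within <- aI[tII$i] == aI[tII$j]
  expect_true(all(abs(tII$x[within] - 3.25 * w$J_II) < 1e-14))
  expect_true(all(abs(tII$x[!within] -
                        cluster_scaling(20, 3.25) * w$J_II) < 1e-14))
})

test_that("expected row sums are independent of the clustering strength", {
  # balance of weights: E-input and I-input row sums should not depend on
  # J_+ beyond sampling noise, pooled over realizations
  spec1 <- small_spec(clustering_mode = "E_weights", J_Eplus = 1)
  spec5 <- small_spec(clustering_mode = "E_weights", J_Eplus = 5)
  sums <- function(spec, seeds) {
    rowsum_E <- rowsum_I <- 0
    for (s in seeds) {
      J <- build_matrix(spec, seed = s)$J
      rowsum_E <- rowsum_E + mean(Matrix::rowSums(J[1:400, 1:400]))
      rowsum_I <- rowsum_I + mean(Matrix::rowSums(J[1:400, 401:500]))
    }
    c(rowsum_E, rowsum_I) / length(seeds)
  }
  s1 <- sums(spec1, 1:20)
  s5 <- sums(spec5, 21:40)
  w <- derive_weights(spec1)
  expected_E <- spec1$N_E * spec1$p_EE * w$J_EE
  # per-realization SE of the mean E row sum, conservative bound
  se <- w$J_EE * sqrt(spec1$N_E * spec1$p_EE) / sqrt(400 * 20) * 5
  expect_lt(abs(s1[1] - expected_E), se * 5)
  expect_lt(abs(s5[1] - expected_E), se * 5)
  expect_lt(abs(s1[2] - s5[2]), abs(expected_E) * 0.05)
})

test_that("probability clustering preserves the mean connection probability", {
  pp <- clusternet:::.probability_cluster_probs(0.2, 20, 2)
  expect_equal(pp$p_out, 0.2 * 20 / 21, tolerance = 1e-12)
  expect_equal(pp$p_in, 2 * pp$p_out, tolerance = 1e-12)
  pp1 <- clusternet:::.probability_cluster_probs(0.2, 20, 1)
  expect_equal(pp1$p_in, 0.2)
  expect_equal(pp1$p_out, 0.2)
  expect_error(clusternet:::.probability_cluster_probs(0.6, 2, 11), "exceeds")

  spec <- small_spec(clustering_mode = "E_probability", R_EE = 2)
  wm <- build_probability_clustered(spec, seed = 8)
  d <- block_density(wm$J, 1:400, 1:400)
  n <- 400 * 400
  se <- sqrt(0.2 * 0.8 / n)
  expect_lt(abs(d - 0.2), 5 * se + 5 / n)
  # within-cluster density roughly doubled
  a <- wm$cluster$assignment_E
  din <- block_density(wm$J, which(a == 1), which(a == 1))
  expect_gt(din, 0.3)
})

test_that("background variant sizes and input statistics are correct", {
  spec <- network_spec(N_E = 4000L, N_I = 1000L,
                       clustering_mode = "E_weights_background",
                       background_fraction = 0.1, J_Eplus = 3)
  cl <- cluster_spec(spec)
  expect_equal(sum(is.na(cl$assignment_E)), 400)
  expect_equal(sum(cl$assignment_E == 1, na.rm = TRUE), 180)

  sp <- small_spec(clustering_mode = "E_weights_background",
                   background_fraction = 0.1, J_Eplus = 3)
  w <- derive_weights(sp)
  # background rows: expected E-input sum equals N_E * p_EE * J_EE
  tot <- 0
  nreal <- 10
  for (s in 1:nreal) {
    J <- build_matrix(sp, seed = 100 + s)$J
    bg <- which(is.na(cluster_spec(sp)$assignment_E))
    tot <- tot + mean(Matrix::rowSums(J[bg, 1:400]))
  }
  expected <- sp$N_E * sp$p_EE * w$J_EE
  se <- w$J_EE * sqrt(sp$N_E * sp$p_EE) / sqrt(length(bg) * nreal)
  expect_lt(abs(tot / nreal - expected), 5 * se * 3)
})

test_that("cluster moments are permutation symmetric across clusters", {
  spec <- small_spec(clustering_mode = "E_weights", J_Eplus = 4)
  J <- build_matrix(spec, seed = 9)$J
  a <- cluster_spec(spec)$assignment_E
  wm_means <- vapply(1:20, function(q) {
    idx <- which(a == q)
    mean(Matrix::rowSums(J[idx, idx]))
  }, numeric(1))
  # within-cluster input means agree across clusters (5 SE)
  w <- derive_weights(spec)
  se <- 4 * w$J_EE * sqrt(20 * spec$p_EE) / sqrt(20)
  expect_lt(max(abs(wm_means - mean(wm_means))), 5 * se)
})

test_that("triplet export round-trips the matrix", {
  spec <- small_spec(clustering_mode = "E_weights", J_Eplus = 2)
  wm <- build_matrix(spec, seed = 10)
  f <- tempfile(fileext = ".tsv")
  fa <- tempfile(fileext = ".tsv")
  write_weight_matrix(wm, f, fa)
  J2 <- read_weight_matrix(f)
  expect_equal(Matrix::norm(wm$J - J2, "M"), 0)
  assign <- utils::read.table(fa, header = TRUE, sep = "\t")
  expect_equal(nrow(assign), 500)
  expect_equal(assign$cluster_id[1], 1L)
  unlink(c(f, fa))
})
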