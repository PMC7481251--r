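test_that("double centering zeroes row and column sums", {
  expect_equal(double_center(matrix(c(1, 3, 2, 4), 2)),
               matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(double_center(diag(2)),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2), ignore_attr = TRUE)
  expect_equal(double_center(matrix(5, 3, 4)), matrix(0, 3, 4),
               ignore_attr = TRUE)

  set.seed(1)
  x <- matrix(rnorm(60, 5), 12, 5)
  G <- double_center(x)
  expect_lt(max(abs(rowSums(G)), abs(colSums(G))), 1e-10)
  # sequential column-then-row subtraction gives the identical matrix
  seq_centered <- sweep(x, 2, colMeans(x))
  seq_centered <- sweep(seq_centered, 1, rowMeans(seq_centered))
  expect_equal(G, seq_centered, tolerance = 1e-12)
})

test_that("decomposition matches the covariance eigendecomposition oracle", {
  set.seed(101)
  for (i in 1:8) {
    n <- sample(20:200, 1)
    m <- sample(3:12, 1)
    G <- random_centered_matrix(n, m)
    fit <- pc_decompose(G)
    oracle <- oracle_decompose(G)
    expect_equal(fit$lambda, oracle$lambda, tolerance = 1e-8)
    expect_equal(abs(unname(fit$P)), abs(oracle$P), tolerance = 1e-6)
    expect_equal(unname(fit$z * fit$cosine), oracle$z * oracle$cosine,
                 tolerance = 1e-6)
    aligned <- abs(fit$z) >= 1.96 & abs(fit$cosine) >= 0.4
    expect_identical(unname(aligned), oracle$aligned)
  }
})

test_that("the factorization reconstructs G and projections equal G V", {
  set.seed(2)
  G <- random_centered_matrix(80, 6)
  fit <- pc_decompose(G)
  recon <- fit$U %*% diag(fit$d) %*% t(fit$V)
  expect_lt(norm(G - recon, "F"), 1e-8 * norm(G, "F"))
  expect_equal(unname(fit$P), unname(G %*% fit$V), tolerance = 1e-8)
  # column norms of U are 1, so gene-wise squared projections sum to d^2
  expect_equal(unname(colSums(fit$P^2)), fit$d^2, tolerance = 1e-8)
  # variance fractions sum to 1 and are non-increasing
  expect_equal(sum(fit$lambda), 1, tolerance = 1e-12)
  expect_true(all(diff(fit$d) <= 1e-12))
})

test_that("the sign convention makes decompositions platform-stable", {
  set.seed(3)
  G <- random_centered_matrix(40, 5)
  fit <- pc_decompose(G)
  for (j in seq_along(fit$d)) {
    expect_gt(fit$V[which.max(abs(fit$V[, j])), j], 0)
  }
  # rank-1 matrix concentrates all variance on PC1
  r1 <- double_center(outer(rnorm(30), c(rep(0, 3), 1)))
  expect_equal(pc_decompose(r1)$lambda[1], 1, tolerance = 1e-12)
})

test_that("projection z-scores standardize per PC and ignore location", {
  P <- matrix(c(sqrt(2), -sqrt(2)), 2, 1)
  expect_equal(unname(projection_zscores(P)),
               matrix(c(1, -1) / sqrt(2), 2, 1), tolerance = 1e-12)
  set.seed(4)
  P2 <- matrix(rnorm(60), 20, 3)
  z <- projection_zscores(P2)
  expect_equal(unname(colMeans(z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(projection_zscores(P2 + 5), z, tolerance = 1e-10)
  expect_warning(z0 <- projection_zscores(matrix(1, 4, 1)), "zero")
  expect_equal(unname(z0), matrix(0, 4, 1))
})

test_that("cosines are unit-normalized gene directions", {
  set.seed(5)
  G <- random_centered_matrix(50, 6)
  fit <- pc_decompose(G)
  expect_true(all(abs(fit$cosine) <= 1 + 1e-12))
  expect_equal(unname(rowSums(fit$cosine^2)), rep(1, 50), tolerance = 1e-10)
  # sign coherence with the projection
  nz <- fit$P != 0
  expect_true(all(sign(fit$cosine[nz]) == sign(fit$P[nz])))
  # a gene parallel to a PC has |cosine| 1 on it and 0 elsewhere
  Gp <- rbind(G, parallel = fit$V[, 2] * 3)
  fit2 <- pc_decompose(double_center(Gp))
  # (re-centering perturbs slightly; check on the raw projection identity)
  cosv <- (Gp %*% fit$V)["parallel", ] / sqrt(sum(Gp["parallel", ]^2))
  expect_equal(unname(abs(cosv)), c(0, 1, 0, 0, 0, 0), tolerance = 1e-10)
  expect_warning(projection_cosines(matrix(c(0, 1, 0, 2), 2, 2)), "zero-norm")
})

test_that("the alignment rule needs both thresholds and respects the sign", {
  toy <- simulate_toy()
  fit <- pc_decompose(toy$data)
  tab <- alignment_table(fit)
  expect_identical(nrow(tab), 26L * 3L)
  on1 <- dplyr::filter(tab, pc == 1)
  expect_identical(on1$aligned,
                   abs(on1$z) >= 1.96 & abs(on1$cosine) >= 0.4)
  expect_true(all(on1$sign[on1$projection > 0] == 1))
  # a strong |z| with weak cosine (or vice versa) must not align
  expect_false(any(on1$aligned & (abs(on1$z) < 1.96 | abs(on1$cosine) < 0.4)))
  expect_error(aligned_genes(fit, 7), "out of range")
  sets <- aligned_genes(fit, 1)
  expect_setequal(union(sets$up, sets$down), on1$gene_id[on1$aligned])
})

test_that("permuting gene rows permutes the alignment table identically", {
  set.seed(6)
  G <- random_centered_matrix(30, 4)
  perm <- sample(nrow(G))
  fit <- pc_decompose(G)
  # the last PC of a double-centered matrix is the exact null sample
  # direction; restrict to the components carrying variance
  real <- which(fit$d > 1e-10 * fit$d[1])
  t1 <- alignment_table(fit)
  t2 <- alignment_table(pc_decompose(G[perm, ]))
  t1s <- dplyr::arrange(dplyr::filter(t1, pc %in% real), .data$pc, .data$gene_id)
  t2s <- dplyr::arrange(dplyr::filter(t2, pc %in% real), .data$pc, .data$gene_id)
  expect_equal(t1s, t2s, tolerance = 1e-8)
})

test_that("find_condition_pc locates the axis separating two conditions", {
  sim <- simulate_expression(design_multimuscle(reversal = -1),
                             n_genes = 600, seed = 8,
                             signature = planted_signature(20, 20))
  fit <- sim$data |> filter_expressed() |> log_transform() |> pc_decompose()
  pc <- find_condition_pc(fit, "30mCON", "10mCON")
  cond <- fit$design$condition
  sep <- abs(mean(fit$V[cond == "30mCON", pc]) -
               mean(fit$V[cond == "10mCON", pc]))
  expect_gt(sep, abs(mean(fit$V[cond == "30mCON", 1]) -
                       mean(fit$V[cond == "10mCON", 1])))
  expect_error(find_condition_pc(fit, "30mCON", "nope"), "not found")
})
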