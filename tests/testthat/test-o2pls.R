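test_that("o2pls refuses orthogonal blocks (zero covariance)", {
  set.seed(50)
  t1 <- qr.Q(qr(matrix(rnorm(20 * 2), 20)))  # orthonormal scores
  x1 <- tcrossprod(t1[, 1], rnorm(6))
  x2 <- tcrossprod(t1[, 2], rnorm(5))        # exactly orthogonal column spaces
  mb <- multiblock(block(x1, 1L), block(x2, 2L))
  expect_error(o2pls_decompose(mb, model_spec(1, c(0, 0))),
               "no-common-variation")
  expect_error(o2pls_decompose(planted(seed = 50)$data,
                               model_spec(0, c(1, 1))), "invalid-spec")
})

test_that("o2pls invariants: within-block orthogonality, reconstruction,
           column spaces", {
  for (seed in c(51L, 52L)) {
    sim <- planted(i = 30, j = c(14, 9), n_common = 1, n_distinct = c(2, 1),
                   common_frac = 0.4, distinct_frac = 0.4,
                   error_frac = 0.2, seed = seed)
    dec <- o2pls_decompose(sim$data, model_spec(1, c(2, 1)))
    xs <- lapply(sim$data$blocks, `[[`, "values")
    for (k in 1:2) {
      recon <- dec$common[[k]] + dec$distinct[[k]] + dec$residual[[k]]
      expect_lt(sqrt(frob2(xs[[k]] - recon) / frob2(xs[[k]])), 1e-10)
      # C_k' D_k = 0 exactly (deflation makes scores orthogonal)
      nc <- sqrt(frob2(dec$common[[k]])) * sqrt(frob2(dec$distinct[[k]]))
      expect_lt(sqrt(frob2(crossprod(dec$common[[k]],
                                     dec$distinct[[k]]))) / nc, 1e-8)
      # E_k' D_k = 0 (distinctive estimated before the final update)
      ne <- sqrt(frob2(dec$residual[[k]])) * sqrt(frob2(dec$distinct[[k]]))
      expect_lt(sqrt(frob2(crossprod(dec$residual[[k]],
                                     dec$distinct[[k]]))) / ne, 1e-8)
      # no cross-block leakage: parts stay in the block's column space
      expect_lt(columnspace_residual(dec$common[[k]],
                                     sim$data$blocks[[k]]), 1e-16)
      expect_lt(columnspace_residual(dec$distinct[[k]],
                                     sim$data$blocks[[k]]), 1e-16)
    }
    # per-block common scores highly correlated across blocks
    expect_gt(abs(cor(dec$common_scores[[1]][, 1],
                      dec$common_scores[[2]][, 1])), 0.9)
  }
})

test_that("o2pls recovers scenario-1 style planted scores", {
  sim <- scenario1(6)
  dec <- o2pls_decompose(sim$data, model_spec(1, c(1, 1)))
  for (k in 1:2) {
    expect_gt(abs(cor(dec$common_scores[[k]][, 1],
                      sim$truth$scores$common[, 1])), 0.99)
    expect_gt(abs(cor(dec$distinct_scores[[k]][, 1],
                      sim$truth$scores$distinct[[k]][, 1])), 0.99)
  }
})

test_that("global_common_scores spans the shared space with SVD-truncation
           residual", {
  sim <- scenario1(7)
  dec <- o2pls_decompose(sim$data, model_spec(1, c(1, 1)))
  gl <- global_common_scores(dec)
  expect_gt(abs(cor(gl$scores[, 1], sim$truth$scores$common[, 1])), 0.99)
  # reconstruction residual equals the SCA truncation error (full-SVD oracle)
  c_cat <- cbind(dec$common[[1]], dec$common[[2]])
  resid <- frob2(c_cat - cbind(gl$common[[1]], gl$common[[2]]))
  d_full <- svd(c_cat, nu = 0, nv = 0)$d
  expect_equal(resid, sum(d_full[-1]^2), tolerance = 1e-8)
  # identical per-block scores => global scores span the same space
  dec2 <- dec
  dec2$common_scores[[2]] <- dec2$common_scores[[1]]
  dec2$common[[2]] <- dec2$common_scores[[1]] %*% t(dec2$common_loadings[[2]])
  gl2 <- global_common_scores(dec2)
  expect_lt(max_principal_angle(gl2$scores, dec2$common_scores[[1]]), 1e-8)
})

test_that("element-wise PCA CV matches the naive leave-variable-out oracle", {
  set.seed(53)
  m <- matrix(rnorm(12 * 6), 12)
  m <- sweep(m, 2, colMeans(m))
  tr <- m[1:9, ]; te <- m[10:12, ]
  v <- svd(tr)$v[, 1:2]
  press_naive <- 0
  for (i in 1:3) {
    for (j in 1:6) {
      vj <- v[-j, , drop = FALSE]
      t_mj <- solve(crossprod(vj), crossprod(vj, te[i, -j]))
      press_naive <- press_naive + (te[i, j] - sum(v[j, ] * t_mj))^2
    }
  }
  tf <- te %*% v
  pj2 <- rowSums(v^2)
  xhat <- sweep(tf %*% t(v) - sweep(te, 2, pj2, "*"), 2, 1 - pj2, "/")
  expect_equal(sum((te - xhat)^2), press_naive, tolerance = 1e-10)
})

test_that("o2pls_select_model finds planted models and rejects noise", {
  sim <- scenario1(8)
  sel <- o2pls_select_model(sim$data, seed = 9L)
  expect_equal(sel$spec$n_common, 1L)
  expect_equal(sel$spec$n_distinct, c(1L, 1L))
  expect_true(all(diff(sel$press[[1]][1:2]) < 0))  # rank 1 beats rank 0
  sel0 <- o2pls_select_model(pure_noise_mb(seed = 54L), seed = 10L)
  expect_equal(sel0$spec$n_common, 0L)
})
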