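test_that("orthogonality_table flags method patterns and extremes", {
  sim <- planted(i = 30, j = c(14, 9), common_frac = 0.4,
                 distinct_frac = 0.4, error_frac = 0.2, seed = 60)
  dec <- jive_decompose(sim$data, model_spec(1, c(1, 1)))
  ot <- orthogonality_table(dec)
  expect_equal(nrow(ot), 14L)
  expect_true(all(ot$magnitude >= 0))
  # JIVE forces CkDk, EkDk, CkDl to zero
  expect_true(all(ot$pass[ot$pair %in% c("CkDk", "EkDk", "CkDl")]))
  expect_false(any(ot$expected_zero[ot$pair %in% c("DkDl", "EkCk")]))

  # maximal non-orthogonality: a hand-built decomposition whose (rank-1)
  # common and distinctive parts coincide
  m <- tcrossprod(sim$data$blocks[[1]]$values[, 1],
                  rnorm(ncol(sim$data$blocks[[1]]$values)))
  fake <- dec
  fake$common <- list(m, dec$common[[2]])
  fake$distinct <- list(m, dec$distinct[[2]])
  fake$residual <- list(m * 0, dec$residual[[2]])
  ot2 <- orthogonality_table(fake)
  expect_equal(ot2$magnitude[ot2$pair == "CkDk" & ot2$block == 1], 1,
               tolerance = 1e-12)
})

test_that("explained_variance is exact, additive, and type-III bounded", {
  sim <- planted(i = 25, j = c(10, 8), common_frac = 0.5,
                 distinct_frac = 0.4, error_frac = 0.1, seed = 61)
  fits <- fit_all_methods(sim$data, model_spec(1, c(1, 1)))
  for (dec in fits) {
    ev <- explained_variance(dec, type3 = TRUE)
    expect_true(all(ev$fraction_common >= 0 & ev$fraction_error >= 0))
    # type-III corrected error never exceeds the raw error
    expect_true(all(ev$fraction_error_type3 <= ev$fraction_error + 1e-15))
  }
  # DISCO fractions add to one
  ev <- explained_variance(fits$disco)
  sums <- ev$fraction_common + ev$fraction_distinct + ev$fraction_error
  expect_equal(sums, c(1, 1), tolerance = 1e-10)
  # noiseless full-rank model: zero error
  sim0 <- planted(i = 25, j = c(10, 8), common_frac = 0.5,
                  distinct_frac = 0.5, error_frac = 0, seed = 62)
  ev0 <- explained_variance(disco_decompose(sim0$data, model_spec(1, c(1, 1)),
                                            seed = 1))
  expect_lt(max(ev0$fraction_error), 1e-12)
})

test_that("crossover_variance matches the explicit projector oracle", {
  sim <- planted(i = 30, j = c(14, 9), common_frac = 0.35,
                 distinct_frac = 0.45, error_frac = 0.2, seed = 63)
  dec <- disco_decompose(sim$data, model_spec(1, c(1, 1)), seed = 1)
  co <- crossover_variance(dec)
  for (k in 1:2) {
    t_d <- dec$distinct_scores[[3 - k]]
    x_k <- sim$data$blocks[[k]]$values
    proj <- t_d %*% solve(crossprod(t_d), crossprod(t_d, x_k))
    expect_equal(co[[k]], frob2(proj) / frob2(x_k), tolerance = 1e-8)
  }
  # no foreign distinctive components -> zero
  dec2 <- disco_decompose(sim$data, model_spec(1, c(1, 0)), seed = 1)
  expect_equal(unname(crossover_variance(dec2)[1]), 0)
  # O2-PLS parts never leave their block -> zero by construction
  dec3 <- o2pls_decompose(sim$data, model_spec(1, c(1, 1)))
  expect_equal(unname(crossover_variance(dec3)), c(0, 0))
})

test_that("columnspace_residual agrees with an orthonormal-basis oracle", {
  set.seed(64)
  x <- matrix(rnorm(70 * 5), 70)
  blk <- block(x, 1L)
  # anything built from X's columns lies in its column space
  expect_lt(columnspace_residual(x %*% matrix(rnorm(15), 5), blk), 1e-10)
  # wide full-row-rank block spans everything
  wide <- block(matrix(rnorm(6 * 10), 6), 1L)
  expect_lt(columnspace_residual(matrix(rnorm(6 * 3), 6), wide), 1e-16)
  # a direction orthogonal to X's columns contributes its squared norm
  q <- qr.Q(qr(cbind(x, rnorm(70))))
  ortho <- q[, 6] * 3  # norm 3, orthogonal to col(X)
  part <- x %*% matrix(rnorm(10), 5, 2)
  part <- cbind(part, part[, 1] + ortho)
  # QR-based oracle
  qx <- qr.Q(qr(x))
  oracle <- frob2(part - qx %*% crossprod(qx, part))
  expect_equal(columnspace_residual(part, blk), oracle, tolerance = 1e-8)
  expect_equal(columnspace_residual(part, blk), 9, tolerance = 1e-6)
})

test_that("swiss matches hand-computed sums of squares and invariances", {
  expect_equal(swiss(matrix(c(0, 2, 10, 12), 4), c("a", "a", "b", "b")),
               4 / 104)
  # each object its own subtype -> 0; a single subtype -> 1
  s <- matrix(rnorm(12), 6)
  expect_equal(swiss(s, letters[1:6]), 0)
  expect_equal(swiss(s, rep("x", 6)), 1)
  # invariant to score rotation and label renaming
  labs <- rep(c("u", "v"), each = 3)
  r <- random_orthogonal(2, seed = 65)
  expect_equal(swiss(s %*% r, labs), swiss(s, labs), tolerance = 1e-12)
  expect_equal(swiss(s, c(2, 2, 2, 7, 7, 7)), swiss(s, labs))
  expect_error(swiss(matrix(1, 1, 1), "a"), "single object")
})

test_that("rv_modified behaves like a matrix correlation", {
  set.seed(66)
  a <- scale(matrix(rnorm(40 * 3), 40), scale = FALSE)
  expect_equal(rv_modified(a, a), 1, tolerance = 1e-12)
  # invariance under orthogonal rotation and positive scaling
  r <- random_orthogonal(3, seed = 67)
  expect_equal(rv_modified(a %*% r * 3.7, a), rv_modified(a, a),
               tolerance = 1e-10)
  # near zero for independent configurations (simulation oracle)
  vals <- vapply(1:100, function(i) {
    b1 <- scale(matrix(rnorm(40 * 2), 40), scale = FALSE)
    b2 <- scale(matrix(rnorm(40 * 2), 40), scale = FALSE)
    rv_modified(b1, b2)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
  expect_error(rv_modified(a * 0, a), "degenerate")
})
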