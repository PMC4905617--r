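test_that("jive_decompose converges immediately on orthogonal truth", {
  # noiseless data with exactly orthogonal scores AND loadings (built by
  # direct SVD construction): the second sweep reproduces the first, so
  # the loop stops right away
  set.seed(40)
  tsc <- orthonormal_scores(25, 3, center = TRUE)
  p1 <- qr.Q(qr(matrix(rnorm(20), 10)))
  p2 <- qr.Q(qr(matrix(rnorm(16), 8)))
  x1 <- sqrt(0.5) * (tcrossprod(tsc[, 1], p1[, 1]) +
                       tcrossprod(tsc[, 2], p1[, 2]))
  x2 <- sqrt(0.5) * (tcrossprod(tsc[, 1], p2[, 1]) +
                       tcrossprod(tsc[, 3], p2[, 2]))
  mb <- preprocess(multiblock(block(x1, 1L), block(x2, 2L)))
  dec <- jive_decompose(mb, model_spec(1, c(1, 1)))
  expect_lte(dec$iterations, 3L)
  expect_lt(frob2(dec$residual[[1]]) + frob2(dec$residual[[2]]), 1e-16)
})

test_that("jive invariants hold across specs (property-style)", {
  cases <- list(list(cc = 1L, ck = c(1L, 1L)),
                list(cc = 2L, ck = c(2L, 1L)),
                list(cc = 0L, ck = c(2L, 2L)),
                list(cc = 2L, ck = c(0L, 1L)))
  for (seed in c(41L, 42L)) {
    sim <- planted(i = 30, j = c(14, 9), n_common = 2, n_distinct = c(2, 2),
                   common_frac = 0.4, distinct_frac = 0.4,
                   error_frac = 0.2, seed = seed)
    xs <- lapply(sim$data$blocks, `[[`, "values")
    for (cs in cases) {
      spec <- model_spec(cs$cc, cs$ck)
      dec <- suppressWarnings(jive_decompose(sim$data, spec))
      for (k in 1:2) {
        # reconstruction
        recon <- dec$common[[k]] + dec$distinct[[k]] + dec$residual[[k]]
        expect_lt(sqrt(frob2(xs[[k]] - recon) / frob2(xs[[k]])), 1e-10)
        # distinctive scores orthogonal to common scores by construction
        if (cs$cc > 0 && cs$ck[k] > 0) {
          expect_lt(max(abs(crossprod(dec$common_scores,
                                      dec$distinct_scores[[k]]))), 1e-8)
        }
        # Eq. 7 per-block additivity of common and distinctive
        lhs <- frob2(dec$common[[k]]) + frob2(dec$distinct[[k]])
        rhs <- frob2(dec$common[[k]] + dec$distinct[[k]])
        expect_lt(abs(lhs - rhs) / max(rhs, 1e-12), 1e-10)
        # residual orthogonal to the distinctive part (estimated last)
        if (cs$ck[k] > 0) {
          nc <- sqrt(frob2(dec$residual[[k]])) *
            sqrt(frob2(dec$distinct[[k]]))
          if (nc > 0) {
            expect_lt(sqrt(frob2(crossprod(dec$residual[[k]],
                                           dec$distinct[[k]]))) / nc, 1e-8)
          }
        }
      }
    }
  }
})

test_that("jive recovers scenario-1 style planted scores", {
  sim <- scenario1(5)
  dec <- jive_decompose(sim$data, model_spec(1, c(1, 1)))
  expect_gt(abs(cor(dec$common_scores[, 1],
                    sim$truth$scores$common[, 1])), 0.99)
  for (k in 1:2) {
    expect_gt(abs(cor(dec$distinct_scores[[k]][, 1],
                      sim$truth$scores$distinct[[k]][, 1])), 0.99)
  }
})

test_that("jive_select_model returns (0,0,0) on pure noise", {
  # each test has a ~alpha false-positive rate by construction, so ask for
  # the all-zero model in the large majority of independent noise draws
  specs <- vapply(1:6, function(s) {
    sel <- jive_select_model(pure_noise_mb(seed = 42L + s), seed = 5L + s)
    c(sel$spec$n_common, sel$spec$n_distinct)
  }, integer(3))
  expect_gte(sum(colSums(specs) == 0L), 5L)
})

test_that("jive_select_model recovers planted ranks", {
  sim <- planted(i = 40, j = c(30, 20), n_common = 1, n_distinct = c(1, 1),
                 common_frac = 0.5, distinct_frac = 0.3, error_frac = 0.2,
                 seed = 43)
  sel <- jive_select_model(sim$data, seed = 6L)
  expect_equal(sel$spec$n_common, 1L)
  expect_equal(sel$spec$n_distinct, c(1L, 1L))
})

test_that("identification sweep flips across the common/distinctive ratio", {
  sw <- jive_identification_sweep(common_grid = c(0.2, 0.8),
                                  replicates = 2L, seed = 7L)
  expect_equal(sw$fraction_correct[1], 0)
  expect_equal(sw$fraction_correct[2], 1)
  expect_error(jive_identification_sweep(common_grid = c(0, 0.5)),
               "invalid-input")
})
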