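test_that("build_target reproduces the worked 5x3 pattern and edge cases", {
  tg <- build_target(2, 3, model_spec(1, c(1, 1)))
  expect_equal(tg$pattern,
               matrix(c(1, 0, 1,
                        1, 0, 1,
                        0, 1, 1,
                        0, 1, 1,
                        0, 1, 1), 5, 3, byrow = TRUE))
  expect_equal(tg$weight, 1 - tg$pattern)
  expect_equal(tg$column_roles, c("distinct1", "distinct2", "common"))

  tg <- build_target(1, 1, model_spec(0, c(1, 1)))
  expect_equal(tg$pattern, diag(2))
  tg <- build_target(2, 2, model_spec(1, c(0, 0)))
  expect_equal(tg$pattern, matrix(1, 4, 1))
  expect_error(build_target(1, 3, model_spec(0, c(2, 1))), "invalid-spec")
})

test_that("find_rotation recovers planted rotations and stays monotone", {
  set.seed(20)
  tg <- build_target(5, 4, model_spec(1, c(2, 1)))
  # a loading matrix already conforming to the pattern
  p0 <- tg$pattern * matrix(rnorm(nrow(tg$pattern) * 4), ncol = 4)
  rot <- find_rotation(p0, tg, n_restarts = 5, seed = 1)
  expect_lt(rot$objective, 1e-12)

  # plant-and-recover: rotate a conforming matrix by a random orthogonal B
  b0 <- random_orthogonal(4, seed = 21)
  rot <- find_rotation(p0 %*% b0, tg, n_restarts = 10, seed = 2)
  expect_lt(rot$objective, 1e-12)
  expect_lt(max(abs(tg$weight * ((p0 %*% b0) %*% rot$b_opt))), 1e-6)
  # B stays orthogonal and the objective history never increases
  expect_equal(crossprod(rot$b_opt), diag(4), tolerance = 1e-10)
  expect_true(all(diff(rot$history) <= 1e-12))
})

test_that("find_rotation matches the 1-parameter grid oracle for c_t = 2", {
  set.seed(22)
  tg <- build_target(3, 2, model_spec(0, c(1, 1)))
  p <- matrix(rnorm(10), 5, 2)
  rot <- find_rotation(p, tg, n_restarts = 10, seed = 3)
  # exhaustive search over rotations and reflections
  theta <- seq(0, 2 * pi, by = 1e-4)
  obj_at <- function(b) sum((tg$weight * (p %*% b))^2)
  grid_best <- Inf
  for (refl in c(1, -1)) {
    objs <- vapply(theta, function(a) {
      obj_at(matrix(c(cos(a), sin(a), -refl * sin(a), refl * cos(a)), 2))
    }, numeric(1))
    grid_best <- min(grid_best, min(objs))
  }
  expect_equal(rot$objective, grid_best, tolerance = 1e-8)
})

test_that("disco_decompose recovers noiseless planted structure exactly", {
  sim <- planted(i = 25, j = c(10, 8), n_common = 1, n_distinct = c(1, 1),
                 common_frac = 0.5, distinct_frac = 0.5, error_frac = 0,
                 seed = 30)
  dec <- disco_decompose(sim$data, model_spec(1, c(1, 1)), seed = 1)
  for (k in 1:2) expect_lt(frob2(dec$residual[[k]]), 1e-10)
  expect_lt(max_principal_angle(dec$common_scores,
                                sim$truth$scores$common), 1e-6)
  for (k in 1:2) {
    expect_lt(max_principal_angle(dec$distinct_scores[[k]],
                                  sim$truth$scores$distinct[[k]]), 1e-6)
  }
})

test_that("disco decomposition is exact, additive and rotation-invariant", {
  sim <- planted(i = 30, j = c(14, 9), n_common = 2, n_distinct = c(2, 1),
                 common_frac = 0.4, distinct_frac = 0.4, error_frac = 0.2,
                 seed = 31)
  spec <- model_spec(2, c(2, 1))
  dec <- disco_decompose(sim$data, spec, seed = 1)
  xs <- lapply(sim$data$blocks, `[[`, "values")
  for (k in 1:2) {
    recon <- dec$common[[k]] + dec$distinct[[k]] + dec$residual[[k]]
    expect_lt(sqrt(frob2(xs[[k]] - recon) / frob2(xs[[k]])), 1e-10)
  }
  # Eq. 5 additivity of the combined model
  tot <- sum(vapply(xs, frob2, numeric(1)))
  parts <- sum(vapply(1:2, function(k) {
    frob2(dec$common[[k]]) + frob2(dec$distinct[[k]]) +
      frob2(dec$residual[[k]])
  }, numeric(1)))
  expect_lt(abs(tot - parts) / tot, 1e-10)
  # the partitioned parts differ from the (rotation-invariant) SCA fit by
  # exactly the pattern-zero mass, i.e. the rotation objective
  fit_sca <- dec$sca$scores %*% t(dec$sca$loadings)
  cd <- cbind(dec$common[[1]] + dec$distinct[[1]],
              dec$common[[2]] + dec$distinct[[2]])
  expect_equal(frob2(fit_sca - cd), dec$rotation$objective,
               tolerance = 1e-8)
})

test_that("disco_select_model finds planted structure (exhaustive step 2)", {
  sim <- planted(i = 25, j = c(10, 8), n_common = 1, n_distinct = c(1, 1),
                 common_frac = 0.5, distinct_frac = 0.5, error_frac = 0,
                 seed = 32)
  sel <- disco_select_model(sim$data, seed = 4)
  expect_equal(sel$spec$n_common, 1L)
  expect_equal(sel$spec$n_distinct, c(1L, 1L))
  cand <- sel$candidates
  true_row <- cand[cand$c_c == 1 & cand$c_1 == 1 & cand$c_2 == 1, ]
  expect_lt(true_row$total_crossover, 1e-10)
  # every 0-common split must pay the planted common component's mass
  expect_gt(min(cand$total_crossover[cand$c_c == 0]), 0.05)
})
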