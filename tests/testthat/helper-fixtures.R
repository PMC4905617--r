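# Shared fixture builders. Everything is generated in code at test time.

# Planted two-block data set through the public generator; error = 0 gives
# exactly low-rank blocks.
planted <- function(i = 30L, j = c(12L, 9L), n_common = 1L,
                    n_distinct = c(1L, 1L), common_frac = 0.5,
                    distinct_frac = 0.4, error_frac = 0.1, seed = 1L) {
  stopifnot(abs(common_frac + distinct_frac + error_frac - 1) < 1e-9)
  frac_block <- function(ck) {
    d <- if (ck > 0) rep(distinct_frac / ck, ck) else numeric(0)
    list(common = rep(common_frac / max(n_common, 1L), n_common),
         distinct = d, error = 1 - common_frac - sum(d))
  }
  generate_scenario(scenario_config(
    i = i, j = j, n_common = n_common, n_distinct = n_distinct,
    fractions = list(frac_block(n_distinct[1L]), frac_block(n_distinct[2L])),
    loading_style = "spectral", seed = seed))
}

# Generic correlated data: shared latent rows, dense loadings, no planted
# orthogonality -- the "generic data" for nonzero orthogonality checks.
generic_correlated <- function(seed = 3L, i = 70L, j = c(100L, 50L)) {
  set.seed(seed)
  s <- matrix(rnorm(i * 4L), i, 4L)
  x1 <- s %*% matrix(rnorm(4L * j[1L]), 4L) + 2 * matrix(rnorm(i * j[1L]), i)
  x2 <- s %*% matrix(rnorm(4L * j[2L]), 4L) + 2 * matrix(rnorm(i * j[2L]), i)
  preprocess(multiblock(block(x1, 1L), block(x2, 2L)))
}

pure_noise_mb <- function(seed = 42L, i = 40L, j = c(30L, 20L)) {
  set.seed(seed)
  preprocess(multiblock(block(matrix(rnorm(i * j[1L]), i), 1L),
                        block(matrix(rnorm(i * j[2L]), i), 2L)))
}

random_orthogonal <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * n), n)))
}

# Largest principal angle (radians) between the column spaces of a and b.
max_principal_angle <- function(a, b) {
  qa <- qr.Q(qr(a)); qb <- qr.Q(qr(b))
  s <- svd(crossprod(qa, qb), nu = 0, nv = 0)$d
  acos(min(1, max(0, min(s))))
}

frob2 <- function(m) sum(m * m)

fit_all_methods <- function(data, spec, seed = 1L) {
  list(disco = disco_decompose(data, spec, seed = seed),
       jive = suppressWarnings(jive_decompose(data, spec)),
       o2pls = o2pls_decompose(data, spec))
}

# Minimum |cor| between fitted and generating score vectors over all
# methods and components (common + per-block distinctive).
min_score_recovery <- function(sim, spec, seed = 1L) {
  tr <- sim$truth$scores
  fits <- fit_all_methods(sim$data, spec, seed = seed)
  min(vapply(fits, function(m) {
    cs <- if (is.list(m$common_scores)) m$common_scores else
      list(m$common_scores)
    vals <- c(
      unlist(lapply(cs, function(s)
        vapply(seq_len(ncol(s)), function(c)
          abs(cor(s[, c], tr$common[, c])), numeric(1)))),
      unlist(lapply(1:2, function(k) {
        s <- m$distinct_scores[[k]]
        vapply(seq_len(ncol(s)), function(c)
          abs(cor(s[, c], tr$distinct[[k]][, c])), numeric(1))
      })))
    min(vals)
  }, numeric(1)))
}
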