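#' Build the binary target pattern for DISCO rotation
#'
#' The target `P*` is a `(J_1 + J_2) x c_t` binary matrix. A column that is
#' distinctive for block k carries 1s exactly on block k's rows (its loading
#' is free there and constrained to zero elsewhere); a common column is all
#' 1s. The complementary weight matrix `W = 1 - P*` marks the entries whose
#' squared sum the rotation minimizes. Column order is: distinctive block 1,
#' distinctive block 2, common.
#'
#' @param j1,j2 Numbers of variables in blocks 1 and 2.
#' @param spec A [model_spec()].
#' @return An object of class `codivar_target`: list with `pattern`,
#'   `weight` and `column_roles` (one of `"distinct1"`, `"distinct2"`,
#'   `"common"` per column).
#' @export
build_target <- function(j1, j2, spec) {
  stopifnot(inherits(spec, "codivar_model_spec"))
  j1 <- as.integer(j1); j2 <- as.integer(j2)
  if (j1 < 1L || j2 < 1L) stop("invalid-input: blocks need >= 1 variable")
  if (length(spec$n_distinct) != 2L) {
    stop("invalid-spec: the target pattern is defined for two blocks")
  }
  c1 <- spec$n_distinct[1L]; c2 <- spec$n_distinct[2L]; cc <- spec$n_common
  if (c1 > j1 || c2 > j2) {
    stop("invalid-spec: more distinctive components than block variables")
  }
  roles <- c(rep("distinct1", c1), rep("distinct2", c2), rep("common", cc))
  pattern <- matrix(0, j1 + j2, spec$n_total)
  rows1 <- seq_len(j1)
  rows2 <- j1 + seq_len(j2)
  for (j in seq_along(roles)) {
    pattern[, j] <- switch(roles[j],
      distinct1 = as.numeric(seq_len(j1 + j2) %in% rows1),
      distinct2 = as.numeric(seq_len(j1 + j2) %in% rows2),
      common = 1)
  }
  structure(list(pattern = pattern, weight = 1 - pattern,
                 column_roles = roles),
            class = "codivar_target")
}

#' Orthogonal rotation towards a zero-pattern target
#'
#' Finds an orthogonal matrix `B` minimizing `sum((W * (P %*% B))^2)`, the
#' squared sum of the rotated loadings on the pattern's zero positions.
#' Because `B` is orthogonal, `||P B||^2` is constant, so minimizing the
#' mass on the zeros equals maximizing the mass on the free (pattern-one)
#' positions; the latter is a convex function of `B` and is maximized by a
#' monotone majorize-minimize iteration: linearize at the current `B` and
#' project the gradient onto the orthogonal group via its polar
#' factor (SVD). Multi-start: the identity plus `n_restarts` random
#' orthogonal starts guard against local optima.
#'
#' @param p_sca SCA loading matrix (`J x c_t`).
#' @param target A `codivar_target` from [build_target()].
#' @param n_restarts Number of random orthogonal starts besides the
#'   identity (default 20).
#' @param tol Stop when the objective decreases by less than `tol` between
#'   sweeps (default 1e-12).
#' @param max_iter Maximum sweeps per start (default 5000); reaching it
#'   raises a convergence warning carrying the last iterate.
#' @param seed Optional integer seed for the random starts.
#' @return An object of class `codivar_rotation`: list with `b_opt`
#'   (orthogonal `c_t x c_t`), `objective` (minimized squared sum on the
#'   zeros), `n_restarts_used` and `history` (objective per sweep of the
#'   winning start).
#' @export
find_rotation <- function(p_sca, target, n_restarts = 20L, tol = 1e-12,
                          max_iter = 5000L, seed = NULL) {
  stopifnot(inherits(target, "codivar_target"))
  p_sca <- as.matrix(p_sca)
  ct <- ncol(p_sca)
  if (nrow(p_sca) != nrow(target$pattern) || ct != ncol(target$pattern)) {
    stop("invalid-input: loading matrix does not conform to the target")
  }
  if (ct == 0L) {
    return(structure(list(b_opt = diag(0), objective = 0,
                          n_restarts_used = 0L, history = numeric(0)),
                     class = "codivar_rotation"))
  }
  w <- target$weight
  pstar <- target$pattern
  objective <- function(b) sum((w * (p_sca %*% b))^2)
  if (sum(w) == 0) {  # no zero constraints: any rotation is optimal
    return(structure(list(b_opt = diag(ct), objective = 0,
                          n_restarts_used = 0L, history = numeric(0)),
                     class = "codivar_rotation"))
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- c(list(diag(ct)),
              replicate(n_restarts,
                        qr.Q(qr(matrix(stats::rnorm(ct * ct), ct, ct))),
                        simplify = FALSE))
  best <- NULL
  for (b0 in starts) {
    b <- b0
    f <- objective(b)
    hist <- f
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      grad <- crossprod(p_sca, pstar * (p_sca %*% b))
      sv <- svd(grad)
      b_new <- sv$u %*% t(sv$v)
      f_new <- objective(b_new)
      hist <- c(hist, f_new)
      if (f - f_new < tol) {
        b <- b_new; f <- f_new; converged <- TRUE
        break
      }
      b <- b_new; f <- f_new
    }
    if (!converged) {
      warning("find_rotation: maximum iterations reached before ",
              "stationarity; returning last iterate")
    }
    if (is.null(best) || f < best$objective) {
      best <- list(b_opt = b, objective = f, history = hist)
    }
  }
  structure(c(best, list(n_restarts_used = length(starts) - 1L)),
            class = "codivar_rotation")
}

#' DISCO-SCA decomposition
#'
#' Simultaneous component analysis of the concatenated matrix
#' `X = [X_1 | X_2]` with `c_t = c_c + c_1 + c_2` components, followed by an
#' orthogonal rotation of scores and loadings towards the zero-pattern
#' target from [build_target()]. Rotated components are partitioned by their
#' target role: common components share one score matrix `T_c` across
#' blocks; distinctive components get per-block scores and loadings. The
#' part of the fit that falls on pattern zeros (an imperfect rotation's
#' cross-over variation) is left in the residual, so `C_k + D_k + E_k`
#' always reconstructs `X_k` exactly.
#'
#' @param data A preprocessed `codivar_multiblock` with two blocks.
#' @param spec A [model_spec()].
#' @param n_restarts,tol,max_iter,seed Passed to [find_rotation()].
#' @return A `codivar_decomposition` (method `"disco"`) with extra fields
#'   `rotation` (the [find_rotation()] result) and `sca` (unrotated scores
#'   and loadings).
#' @export
disco_decompose <- function(data, spec, n_restarts = 20L, tol = 1e-12,
                            max_iter = 5000L, seed = NULL) {
  check_spec_feasible(data, spec)
  xs <- mb_values(data)
  if (length(xs) != 2L) stop("invalid-input: DISCO expects two blocks")
  x <- mb_concat(data)
  idx <- mb_col_index(data)
  ct <- spec$n_total

  sv <- truncated_svd(x, ct)
  t_sca <- sv$u
  p_sca <- sv$v %*% diag(sv$d, nrow = ct)

  target <- build_target(ncol(xs[[1L]]), ncol(xs[[2L]]), spec)
  rot <- find_rotation(p_sca, target, n_restarts = n_restarts, tol = tol,
                       max_iter = max_iter, seed = seed)
  t_r <- t_sca %*% rot$b_opt
  p_r <- p_sca %*% rot$b_opt
  fx <- fix_score_signs(t_r, p_r)
  t_r <- fx$scores; p_r <- fx$loadings

  roles <- target$column_roles
  ccol <- which(roles == "common")
  dcol <- list(which(roles == "distinct1"), which(roles == "distinct2"))

  t_c <- t_r[, ccol, drop = FALSE]
  common <- distinct <- residual <- vector("list", 2L)
  common_loadings <- distinct_scores <- distinct_loadings <-
    vector("list", 2L)
  for (k in 1:2) {
    p_ck <- p_r[idx[[k]], ccol, drop = FALSE]
    t_dk <- t_r[, dcol[[k]], drop = FALSE]
    p_dk <- p_r[idx[[k]], dcol[[k]], drop = FALSE]
    common[[k]] <- t_c %*% t(p_ck)
    distinct[[k]] <- t_dk %*% t(p_dk)
    residual[[k]] <- xs[[k]] - common[[k]] - distinct[[k]]
    common_loadings[[k]] <- p_ck
    distinct_scores[[k]] <- t_dk
    distinct_loadings[[k]] <- p_dk
  }
  names(common) <- names(distinct) <- names(residual) <- names(xs)
  new_decomposition("disco", spec, data, common, distinct, residual,
                    common_scores = t_c,
                    common_loadings = common_loadings,
                    distinct_scores = distinct_scores,
                    distinct_loadings = distinct_loadings,
                    extras = list(rotation = rot,
                                  sca = list(scores = t_sca,
                                             loadings = p_sca),
                                  target = target))
}

#' DISCO two-step model selection
#'
#' Step 1 chooses the total number of components `c_t` as the smallest
#' count for which the SCA of the concatenated matrix explains at least
#' `variance_threshold` of **each** block's variance. Step 2 enumerates
#' every split `(c_c, c_1, c_2)` of `c_t`, fits each candidate and scores
#' it by the total cross-over variance (variation of each block explained
#' by the other block's distinctive scores, see [crossover_variance()]).
#' Because a common column of the target pattern is unconstrained, adding
#' common components can never increase the cross-over -- the all-common
#' model trivially scores zero -- so the minimizer alone is degenerate.
#' The selected model is therefore the most parsimonious adequate one: the
#' smallest `c_c` whose best split keeps the total cross-over below
#' `crossover_tol`, with the distinctive counts at that `c_c` chosen to
#' minimize the cross-over (ties within `1e-9` broken deterministically
#' towards a larger `c_1`). Forcing a genuinely common component into a
#' distinctive slot costs its full loading mass on the other block, far
#' above `crossover_tol`, which is what pins `c_c` from below.
#'
#' @param data A preprocessed two-block `codivar_multiblock`.
#' @param variance_threshold Per-block explained-variance threshold for
#'   step 1 (default 0.9).
#' @param max_components Largest `c_t` to consider (default 10).
#' @param crossover_tol Acceptable total cross-over variance fraction
#'   (default 0.01).
#' @param n_restarts,seed Passed to [disco_decompose()] for each candidate.
#' @return List with `spec` (the selected [model_spec()]), `c_t`,
#'   `step1` (per-`c_t` per-block explained fractions) and `candidates`
#'   (data frame of all step-2 splits with their cross-over variance).
#' @export
disco_select_model <- function(data, variance_threshold = 0.9,
                               max_components = 10L, crossover_tol = 0.01,
                               n_restarts = 20L, seed = NULL) {
  xs <- mb_values(data)
  if (length(xs) != 2L) stop("invalid-input: DISCO expects two blocks")
  x <- mb_concat(data)
  idx <- mb_col_index(data)
  cmax <- min(max_components, nrow(x) - 1L, ncol(x))

  sv <- svd(x, nu = 0, nv = cmax)
  ## Explained fraction of block k after c components:
  ## sum_{i<=c} d_i^2 * ||v_i restricted to block k||^2 / ||X_k||^2
  expl <- vapply(1:2, function(k) {
    per_comp <- sv$d[seq_len(cmax)]^2 *
      colSums(sv$v[idx[[k]], , drop = FALSE]^2)
    cumsum(per_comp) / fnorm2(xs[[k]])
  }, numeric(cmax))
  step1 <- data.frame(c_t = seq_len(cmax),
                      block1 = expl[, 1L], block2 = expl[, 2L])
  reached <- which(pmin(expl[, 1L], expl[, 2L]) >= variance_threshold)
  if (length(reached) == 0L) {
    warning("disco_select_model: no c_t <= ", cmax, " reaches the ",
            "variance threshold; using the best available")
    ct <- cmax
  } else {
    ct <- min(reached)
  }

  js <- vapply(xs, ncol, integer(1))
  cand <- expand.grid(c_c = 0:ct, c_1 = 0:ct, c_2 = 0:ct)
  cand <- cand[cand$c_c + cand$c_1 + cand$c_2 == ct &
                 cand$c_1 <= js[1L] & cand$c_2 <= js[2L], , drop = FALSE]
  cand$crossover1 <- cand$crossover2 <- NA_real_
  for (i in seq_len(nrow(cand))) {
    sp <- model_spec(cand$c_c[i], c(cand$c_1[i], cand$c_2[i]))
    dec <- disco_decompose(data, sp, n_restarts = n_restarts, seed = seed)
    co <- crossover_variance(dec)
    cand$crossover1[i] <- co[1L]
    cand$crossover2[i] <- co[2L]
  }
  cand$total_crossover <- cand$crossover1 + cand$crossover2
  ## smallest c_c that keeps the cross-over below tolerance; within that
  ## c_c, the split with minimal cross-over (ties towards larger c_1)
  best_by_cc <- vapply(sort(unique(cand$c_c)), function(cc) {
    min(cand$total_crossover[cand$c_c == cc])
  }, numeric(1))
  ccs <- sort(unique(cand$c_c))
  adequate <- ccs[best_by_cc <= crossover_tol]
  if (length(adequate) == 0L) {
    warning("disco_select_model: no split keeps the cross-over below ",
            crossover_tol, "; returning the global minimizer")
    cc_pick <- cand$c_c[which.min(cand$total_crossover)]
  } else {
    cc_pick <- min(adequate)
  }
  sub <- cand[cand$c_c == cc_pick, , drop = FALSE]
  sub <- sub[sub$total_crossover <= min(sub$total_crossover) + 1e-9, ,
             drop = FALSE]
  pick <- which(cand$c_c == cc_pick &
                  cand$c_1 == sub$c_1[which.max(sub$c_1)] &
                  cand$c_2 == sub$c_2[which.max(sub$c_1)])[1L]
  rownames(cand) <- NULL
  list(spec = model_spec(cand$c_c[pick], c(cand$c_1[pick], cand$c_2[pick])),
       c_t = ct, step1 = step1, candidates = cand)
}
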