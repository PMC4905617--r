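#' O2-PLS decomposition
#'
#' Estimates the common variation of two blocks from the SVD of their
#' cross-block covariance matrix `X_1' X_2` (left singular vectors become
#' the block-1 common loadings, right vectors the block-2 loadings). Each
#' block then has its orthogonal (distinctive) variation removed one
#' component at a time: the dominant left singular vector of
#' `R_k' T_ck` (with `R_k = X_k - T_ck P_ck'`) gives a weight vector `w`,
#' the distinctive score is `t = X_k w`, its loading the regression
#' `p = X_k' t / (t' t)`, and `X_k` is deflated by `t p'`. After all
#' `c_k` components are removed the common scores are updated once
#' (`T_ck = X_k P_ck`). Unlike DISCO and JIVE the common scores are
#' per-block: `T_c1` and `T_c2` are highly correlated but not identical,
#' and no variation crosses from one block into the other.
#'
#' @param data A preprocessed two-block `codivar_multiblock`.
#' @param spec A [model_spec()] with `n_common >= 1`.
#' @param cov_tol Relative Frobenius threshold below which the covariance
#'   matrix counts as zero (orthogonal blocks carry no common variation);
#'   default 1e-12.
#' @return A `codivar_decomposition` (method `"o2pls"`) whose
#'   `common_scores` is a list of per-block score matrices; extra field
#'   `cov_svd` holds the singular values of the covariance SVD.
#' @export
o2pls_decompose <- function(data, spec, cov_tol = 1e-12) {
  check_spec_feasible(data, spec)
  xs <- mb_values(data)
  if (length(xs) != 2L) stop("invalid-input: O2-PLS expects two blocks")
  cc <- spec$n_common
  if (cc < 1L) {
    stop("invalid-spec: O2-PLS needs at least one common component")
  }
  cov <- crossprod(xs[[1L]], xs[[2L]])
  if (sqrt(fnorm2(cov)) <=
      cov_tol * sqrt(fnorm2(xs[[1L]])) * sqrt(fnorm2(xs[[2L]]))) {
    stop("no-common-variation: the cross-block covariance matrix is zero; ",
         "orthogonal blocks share no common variation")
  }
  svc <- truncated_svd(cov, cc)
  p_c <- list(svc$u, svc$v)

  deflated <- xs
  distinct <- common <- residual <- vector("list", 2L)
  t_c <- distinct_scores <- distinct_loadings <- vector("list", 2L)
  for (k in 1:2) {
    xk <- deflated[[k]]
    ck <- spec$n_distinct[k]
    t_d <- matrix(0, nrow(xk), 0L)
    p_d <- matrix(0, ncol(xk), 0L)
    for (l in seq_len(ck)) {
      t_ck <- xk %*% p_c[[k]]
      r_k <- xk - t_ck %*% t(p_c[[k]])
      w <- svd(crossprod(r_k, t_ck), nu = 1L, nv = 0L)$u[, 1L]
      t_l <- xk %*% w
      tt <- drop(crossprod(t_l))
      if (tt < .Machine$double.eps) {
        warning("o2pls_decompose: degenerate distinctive component ", l,
                " in block ", k, "; stopping extraction early")
        break
      }
      p_l <- crossprod(xk, t_l) / tt
      xk <- xk - t_l %*% t(p_l)
      t_d <- cbind(t_d, t_l)
      p_d <- cbind(p_d, p_l)
    }
    fx <- fix_score_signs(t_d, p_d)
    t_ck <- xk %*% p_c[[k]]
    deflated[[k]] <- xk
    t_c[[k]] <- t_ck
    distinct_scores[[k]] <- fx$scores
    distinct_loadings[[k]] <- fx$loadings
    common[[k]] <- t_ck %*% t(p_c[[k]])
    distinct[[k]] <- fx$scores %*% t(fx$loadings)
    residual[[k]] <- xk - common[[k]]
  }
  names(common) <- names(distinct) <- names(residual) <- names(xs)
  new_decomposition("o2pls", spec, data, common, distinct, residual,
                    common_scores = t_c,
                    common_loadings = p_c,
                    distinct_scores = distinct_scores,
                    distinct_loadings = distinct_loadings,
                    extras = list(cov_svd = svc$d))
}

#' Global common scores for an O2-PLS decomposition
#'
#' O2-PLS leaves each block with its own common scores. This post-processing
#' step combines them into one shared score matrix `T_c` via an SCA
#' (rank-`c_c` SVD) of the concatenated common parts `[C_1 | C_2]`, and
#' recomputes the loadings by least-squares regression of each `C_k` on
#' `T_c`. The globalized common part of a block then contains variation
#' from the other block, so the column-space projection residual of each
#' new `C_k` against its `X_k` is returned as a diagnostic.
#'
#' @param dec A `codivar_decomposition` from [o2pls_decompose()].
#' @param c_c Number of global common components (defaults to the model's
#'   common count).
#' @return List with `scores` (shared `I x c_c`), `loadings` (per-block),
#'   `common` (per-block globalized common parts) and
#'   `columnspace_residuals` (per-block, see [columnspace_residual()]).
#' @export
global_common_scores <- function(dec, c_c = dec$model$n_common) {
  stopifnot(inherits(dec, "codivar_decomposition"))
  if (dec$method != "o2pls") {
    stop("invalid-input: global common scores apply to O2-PLS results")
  }
  c_cat <- do.call(cbind, unname(dec$common))
  sv <- truncated_svd(c_cat, c_c)
  t_c <- sv$u
  xs <- mb_values(dec$data)
  loadings <- common <- resid <- vector("list", length(xs))
  for (k in seq_along(xs)) {
    loadings[[k]] <- crossprod(dec$common[[k]], t_c)  # T_c orthonormal
    common[[k]] <- t_c %*% t(loadings[[k]])
    resid[[k]] <- columnspace_residual(common[[k]], dec$data$blocks[[k]])
  }
  names(common) <- names(resid) <- names(xs)
  list(scores = t_c, loadings = loadings, common = common,
       columnspace_residuals = unlist(resid))
}

## Element-wise (leave-variable-out) PCA cross-validation PRESS for ranks
## 0..max_rank. Rows are split into folds; loadings come from the training
## rows; each held-out element is predicted from its row's other variables
## via the rank-one downdate of the orthonormal-loading projection
## (Sherman-Morrison), which avoids refitting per element.
#' @keywords internal
#' @noRd
pca_cv_press <- function(m, max_rank, folds = 7L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(m)
  folds <- min(folds, n)
  fold_id <- sample(rep_len(seq_len(folds), n))
  max_rank <- min(max_rank, ncol(m), n - ceiling(n / folds) - 1L)
  press <- numeric(max_rank + 1L)
  for (f in seq_len(folds)) {
    test <- m[fold_id == f, , drop = FALSE]
    train <- m[fold_id != f, , drop = FALSE]
    press[1L] <- press[1L] + fnorm2(test)  # rank 0 predicts zero (centered)
    v <- svd(train, nu = 0, nv = max_rank)$v
    for (r in seq_len(max_rank)) {
      p <- v[, seq_len(r), drop = FALSE]
      tf <- test %*% p                       # full scores per held-out row
      pj2 <- rowSums(p^2)                    # ||p_j||^2 per variable row
      ## prediction of element (i, j) without using x_ij:
      ## x_hat_ij = (t_i . p_j - x_ij ||p_j||^2) / (1 - ||p_j||^2)
      num <- tf %*% t(p) - sweep(test, 2L, pj2, "*")
      xhat <- sweep(num, 2L, pmax(1 - pj2, 1e-12), "/")
      press[r + 1L] <- press[r + 1L] + fnorm2(test - xhat)
    }
  }
  press
}

## First local minimum of a PRESS curve over ranks 0..length-1.
#' @keywords internal
#' @noRd
first_press_minimum <- function(press) {
  for (r in seq_len(length(press) - 1L)) {
    if (press[r + 1L] >= press[r]) return(r - 1L)
  }
  length(press) - 1L
}

#' O2-PLS model selection
#'
#' The number of common components is chosen by a permutation test on the
#' singular values of the cross-block covariance matrix `X_1' X_2`:
#' permuting whole rows of block 2 destroys the object link, and `c_c` is
#' the number of leading observed squared singular values exceeding the
#' `(1 - alpha)` null quantile. The common parts are then projected out of
#' each block and the number of distinctive components per block is chosen
#' by element-wise PCA cross-validation (row folds, leave-variable-out
#' predictions), taking the first minimum of the PRESS curve.
#'
#' @param data A preprocessed two-block `codivar_multiblock`.
#' @param cv_folds Row folds for the PCA cross-validation (default 7).
#' @param max_common,max_distinct Largest candidate counts (defaults 5).
#' @param n_perm Permutations for the common-component test (default 100).
#' @param alpha Test level (default 0.05).
#' @param seed Optional integer seed (permutations and fold assignment).
#' @return List with `spec` (selected [model_spec()]), `common_test`
#'   (observed squared singular values and null thresholds) and `press`
#'   (per-block PRESS curves over ranks `0..max_distinct`).
#' @export
o2pls_select_model <- function(data, cv_folds = 7L, max_common = 5L,
                               max_distinct = 5L, n_perm = 100L,
                               alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xs <- mb_values(data)
  if (length(xs) != 2L) stop("invalid-input: O2-PLS expects two blocks")
  i_n <- nrow(xs[[1L]])
  cov <- crossprod(xs[[1L]], xs[[2L]])
  obs <- sv_only(cov)^2
  null_m <- t(replicate(n_perm, {
    sv_only(crossprod(xs[[1L]], xs[[2L]][sample.int(i_n), ,
                                         drop = FALSE]))^2
  }))
  res <- leading_exceedances(obs, null_m, alpha)
  cc <- min(res$rank, max_common)

  ## remove the common subspace per block, then pick c_k by PCA CV
  press <- vector("list", 2L)
  cks <- integer(2L)
  for (k in 1:2) {
    if (cc > 0L) {
      svc <- truncated_svd(cov, cc)
      p_ck <- if (k == 1L) svc$u else svc$v
      r_k <- xs[[k]] - (xs[[k]] %*% p_ck) %*% t(p_ck)
    } else {
      r_k <- xs[[k]]
    }
    press[[k]] <- pca_cv_press(r_k, max_distinct, folds = cv_folds)
    cks[k] <- first_press_minimum(press[[k]])
  }
  list(spec = model_spec(cc, cks),
       common_test = list(observed = obs, thresholds = res$thresholds,
                          alpha = alpha, n_perm = n_perm),
       press = press)
}
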