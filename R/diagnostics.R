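## Which cross-products each method forces to zero. DISCO's rotation keeps
## every pair orthogonal; JIVE frees D_k'D_l and everything involving E
## except E_k'D_k; O2-PLS only constrains within-block C/D and E/D.
#' @keywords internal
#' @noRd
expected_zero_pattern <- function(method) {
  pairs <- c("CkDk", "EkCk", "EkDk", "CkDl", "DkDl", "EkCl", "EkDl")
  zero <- switch(method,
    disco = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    jive  = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    o2pls = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stop("unknown method: ", method))
  stats::setNames(zero, pairs)
}

## ||A' B||_F / (||A||_F ||B||_F); zero when either factor vanishes.
#' @keywords internal
#' @noRd
normalized_crossprod <- function(a, b) {
  na <- sqrt(fnorm2(a)); nb <- sqrt(fnorm2(b))
  if (na == 0 || nb == 0) return(0)
  sqrt(fnorm2(crossprod(a, b))) / (na * nb)
}

#' Orthogonality audit of a decomposition
#'
#' Computes the normalized magnitude `||A'B||_F / (||A||_F ||B||_F)` for
#' the seven cross-products that distinguish the three methods
#' (`C_k'D_k`, `E_k'C_k`, `E_k'D_k`, `C_k'D_l`, `D_k'D_l`, `E_k'C_l`,
#' `E_k'D_l`, for both blocks k with l the other block), flags which of
#' them the fitted method forces to zero, and reports pass/fail of each
#' expected zero against a tolerance. DISCO constrains all seven; JIVE
#' frees the distinctive-distinctive and most residual products; O2-PLS is
#' the most lenient.
#'
#' @param dec A `codivar_decomposition`.
#' @param tol Tolerance for an expected-zero entry (default 1e-8).
#' @return Data frame of class `codivar_orthogonality` with columns
#'   `pair`, `block`, `magnitude`, `expected_zero`, `pass`.
#' @export
orthogonality_table <- function(dec, tol = 1e-8) {
  stopifnot(inherits(dec, "codivar_decomposition"))
  zero <- expected_zero_pattern(dec$method)
  rows <- list()
  for (k in 1:2) {
    l <- 3L - k
    c_k <- dec$common[[k]]; d_k <- dec$distinct[[k]]
    e_k <- dec$residual[[k]]
    c_l <- dec$common[[l]]; d_l <- dec$distinct[[l]]
    mags <- c(CkDk = normalized_crossprod(c_k, d_k),
              EkCk = normalized_crossprod(e_k, c_k),
              EkDk = normalized_crossprod(e_k, d_k),
              CkDl = normalized_crossprod(c_k, d_l),
              DkDl = normalized_crossprod(d_k, d_l),
              EkCl = normalized_crossprod(e_k, c_l),
              EkDl = normalized_crossprod(e_k, d_l))
    rows[[k]] <- data.frame(pair = names(mags), block = k,
                            magnitude = unname(mags),
                            expected_zero = unname(zero[names(mags)]))
  }
  out <- do.call(rbind, rows)
  out$pass <- !out$expected_zero | out$magnitude < tol
  rownames(out) <- NULL
  class(out) <- c("codivar_orthogonality", "data.frame")
  out
}

#' Explained-variance report
#'
#' Per-block fractions of total variance captured by the common,
#' distinctive and residual parts (squared Frobenius norms over
#' `||X_k||^2`), plus the additivity defect
#' `||X||^2 - (||C||^2 + ||D||^2 + ||E||^2)`. For DISCO all parts are
#' mutually orthogonal and the fractions add to one; for JIVE and O2-PLS
#' only `||C_k||^2 + ||D_k||^2 = ||C_k + D_k||^2` holds and the residual
#' may overlap the common column space. Setting `type3 = TRUE` applies the
#' type-III correction: only the component of `E_k` orthogonal to the
#' column space of `C_k` counts as error, the projected remainder being
#' reattributed to the common part.
#'
#' @param dec A `codivar_decomposition`.
#' @param type3 Apply the type-III residual correction (default `FALSE`;
#'   corrected columns are reported alongside the raw ones when `TRUE`).
#' @return Data frame of class `codivar_variance` with one row per block:
#'   `fraction_common`, `fraction_distinct`, `fraction_error`, optionally
#'   `fraction_common_type3` / `fraction_error_type3`, and attribute
#'   `additivity_defect`.
#' @export
explained_variance <- function(dec, type3 = FALSE) {
  stopifnot(inherits(dec, "codivar_decomposition"))
  xs <- mb_values(dec$data)
  out <- lapply(seq_along(xs), function(k) {
    tot <- fnorm2(xs[[k]])
    row <- data.frame(block = names(xs)[k],
                      fraction_common = fnorm2(dec$common[[k]]) / tot,
                      fraction_distinct = fnorm2(dec$distinct[[k]]) / tot,
                      fraction_error = fnorm2(dec$residual[[k]]) / tot)
    if (type3) {
      proj <- project_on_colspace(dec$common[[k]], dec$residual[[k]])
      row$fraction_common_type3 <- row$fraction_common + fnorm2(proj) / tot
      row$fraction_error_type3 <-
        fnorm2(dec$residual[[k]] - proj) / tot
    }
    row
  })
  out <- do.call(rbind, out)
  defect <- sum(vapply(seq_along(xs), function(k) {
    fnorm2(xs[[k]]) - fnorm2(dec$common[[k]]) - fnorm2(dec$distinct[[k]]) -
      fnorm2(dec$residual[[k]])
  }, numeric(1)))
  attr(out, "additivity_defect") <- defect
  class(out) <- c("codivar_variance", "data.frame")
  out
}

## Orthogonal projection of the columns of m onto the column space of a,
## with singular values below tol * s_max treated as zero.
#' @keywords internal
#' @noRd
project_on_colspace <- function(a, m, tol = 1e-12) {
  if (fnorm2(a) == 0) return(matrix(0, nrow(m), ncol(m)))
  sv <- svd(a, nv = 0)
  keep <- sv$d > tol * sv$d[1L]
  u <- sv$u[, keep, drop = FALSE]
  u %*% crossprod(u, m)
}

#' Cross-over variance of a shared-score decomposition
#'
#' The variation in block k explained by the **other** block's distinctive
#' scores: `||T_d(l) B_k||^2 / ||X_k||^2`, where `B_k` is the least-squares
#' regression of `X_k` on `T_d(l)`. A perfect DISCO rotation makes this
#' zero; its size measures how much the blocks contaminate each other's
#' distinctive components. For O2-PLS, whose parts never leave their own
#' block, the cross-over is zero by construction.
#'
#' @param dec A `codivar_decomposition`.
#' @return Named numeric vector, one fraction per block.
#' @export
crossover_variance <- function(dec) {
  stopifnot(inherits(dec, "codivar_decomposition"))
  xs <- mb_values(dec$data)
  out <- stats::setNames(numeric(length(xs)), names(xs))
  if (dec$method == "o2pls") return(out)
  for (k in seq_along(xs)) {
    l <- 3L - k
    t_d <- dec$distinct_scores[[l]]
    if (is.null(t_d) || ncol(t_d) == 0L) next
    beta <- solve(crossprod(t_d), crossprod(t_d, xs[[k]]))
    out[k] <- fnorm2(t_d %*% beta) / fnorm2(xs[[k]])
  }
  out
}

#' Column-space projection residual
#'
#' `||P - X_k X_k^+ P||^2` for a fitted part `P`: zero when `P` lies in the
#' column space of the block, positive when the part carries variation that
#' is not present in `X_k` (which happens for DISCO/JIVE blocks with fewer
#' variables than objects, because the shared scores are estimated from the
#' concatenation). Singular values below `pinv_tol * s_max` are treated as
#' zero when forming the pseudoinverse projector.
#'
#' @param part Numeric matrix (`I x J_k` or `I x c`).
#' @param blk A `codivar_block` (or numeric matrix) with the same number
#'   of rows.
#' @param pinv_tol Relative singular-value cutoff (default 1e-12).
#' @return Non-negative scalar.
#' @export
columnspace_residual <- function(part, blk, pinv_tol = 1e-12) {
  x <- if (inherits(blk, "codivar_block")) blk$values else as.matrix(blk)
  part <- as.matrix(part)
  if (nrow(part) != nrow(x)) {
    stop("invalid-input: part and block must have the same number of rows")
  }
  proj <- project_on_colspace(x, part, tol = pinv_tol)
  fnorm2(part - proj)
}

#' SWISS score (standardized within-class sum of squares)
#'
#' The variability of a score matrix within subtypes as a proportion of its
#' total variability: the sum over score columns of within-subtype squared
#' deviations from the subtype means, divided by the squared deviations
#' from the grand mean. Lower values mean better subtype separation; a
#' single subtype gives 1, one object per subtype gives 0.
#'
#' @param scores Numeric matrix (`I x c`).
#' @param labels Subtype label per object (length `I`).
#' @return Scalar in `[0, 1]`.
#' @export
swiss <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.factor(labels)
  if (length(labels) != nrow(scores)) {
    stop("invalid-input: one label per object is required")
  }
  if (nrow(scores) < 2L) {
    stop("invalid-input: SWISS is undefined for a single object")
  }
  if (any(table(labels) == 0L)) labels <- droplevels(labels)
  grand <- colMeans(scores)
  total <- sum(sweep(scores, 2L, grand, "-")^2)
  if (total == 0) stop("degenerate-input: scores have no variability")
  within <- 0
  for (g in levels(labels)) {
    sub <- scores[labels == g, , drop = FALSE]
    within <- within + sum(sweep(sub, 2L, colMeans(sub), "-")^2)
  }
  within / total
}

#' Modified RV coefficient
#'
#' Matrix correlation between two configurations sharing their rows,
#' computed from the object-by-object cross-product matrices `A A'` and
#' `B B'` with their diagonals set to zero (the modification that removes
#' the upward bias of the plain RV coefficient for high-dimensional data):
#' the trace inner product of the two zero-diagonal matrices divided by the
#' product of their Frobenius norms.
#'
#' @param a,b Column-centered numeric matrices with the same number of
#'   rows.
#' @return Scalar in `[-1, 1]`; `rv_modified(a, a)` is 1.
#' @export
rv_modified <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) {
    stop("invalid-input: configurations must share their rows")
  }
  sa <- tcrossprod(a); diag(sa) <- 0
  sb <- tcrossprod(b); diag(sb) <- 0
  den <- sqrt(sum(sa^2)) * sqrt(sum(sb^2))
  if (den == 0) {
    stop("degenerate-input: modified RV undefined for a zero configuration")
  }
  sum(sa * sb) / den
}
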