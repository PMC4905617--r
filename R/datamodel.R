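#' Construct a data block
#'
#' A block is one numeric data matrix of `I` objects (rows) by `J_k`
#' variables (columns), together with its labels and an identifier. Blocks
#' are the unit that every decomposition method in this package consumes;
#' two blocks sharing their object mode form a [multiblock()].
#'
#' @param values Numeric matrix (`I x J_k`), all entries finite, `I >= 2`.
#' @param block_id Identifier for the block (e.g. `1`, `2`, `"mrna"`).
#' @param object_labels Character vector of length `I`. Defaults to the
#'   rownames of `values`, or `obj1..objI` when absent.
#' @param variable_labels Character vector of length `J_k`. Defaults to the
#'   colnames of `values`, or `var1..varJ` when absent.
#'
#' @return An object of class `codivar_block`: a list with elements
#'   `values`, `block_id`, `object_labels`, `variable_labels` and
#'   `preprocessing` (character vector recording applied steps).
#' @export
block <- function(values, block_id = 1L, object_labels = NULL,
                  variable_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("invalid-input: block values must be numeric")
  }
  if (any(!is.finite(values))) {
    stop("invalid-input: block contains missing or non-finite entries")
  }
  if (nrow(values) < 2L) {
    stop("invalid-input: a block needs at least 2 objects (rows)")
  }
  if (ncol(values) < 1L) {
    stop("invalid-input: a block needs at least 1 variable (column)")
  }
  if (is.null(object_labels)) {
    object_labels <- rownames(values)
    if (is.null(object_labels)) {
      object_labels <- paste0("obj", seq_len(nrow(values)))
    }
  }
  if (is.null(variable_labels)) {
    variable_labels <- colnames(values)
    if (is.null(variable_labels)) {
      variable_labels <- paste0("var", seq_len(ncol(values)))
    }
  }
  if (length(object_labels) != nrow(values)) {
    stop("invalid-input: object_labels length does not match row count")
  }
  if (length(variable_labels) != ncol(values)) {
    stop("invalid-input: variable_labels length does not match column count")
  }
  dimnames(values) <- list(object_labels, variable_labels)
  structure(
    list(values = values, block_id = block_id,
         object_labels = as.character(object_labels),
         variable_labels = as.character(variable_labels),
         preprocessing = character(0)),
    class = "codivar_block")
}

#' @export
print.codivar_block <- function(x, ...) {
  cat(sprintf("<codivar_block '%s'> %d objects x %d variables", x$block_id,
              nrow(x$values), ncol(x$values)))
  if (length(x$preprocessing)) {
    cat(" [", paste(x$preprocessing, collapse = ", "), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Construct a multi-block data set
#'
#' Bundles two (or more) blocks that share an identical object mode: all
#' blocks must have the same object labels in the same order. All
#' decomposition methods in this package operate on a two-block multiblock.
#'
#' @param ... Objects of class `codivar_block` (or a single list of them).
#'
#' @return An object of class `codivar_multiblock` with elements `blocks`
#'   (named list) and `preprocessing` (record of steps applied to all
#'   blocks).
#' @export
multiblock <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1L && !inherits(blocks[[1L]], "codivar_block")) {
    blocks <- blocks[[1L]]
  }
  if (length(blocks) < 2L) {
    stop("invalid-input: a multiblock needs at least two blocks")
  }
  if (!all(vapply(blocks, inherits, logical(1), "codivar_block"))) {
    stop("invalid-input: all elements must be codivar_block objects")
  }
  ref <- blocks[[1L]]$object_labels
  for (b in blocks[-1L]) {
    if (!identical(b$object_labels, ref)) {
      stop("invalid-input: all blocks must share identical object labels ",
           "in identical order")
    }
  }
  names(blocks) <- vapply(blocks, function(b) as.character(b$block_id),
                          character(1))
  structure(list(blocks = blocks, preprocessing = character(0)),
            class = "codivar_multiblock")
}

#' @export
print.codivar_multiblock <- function(x, ...) {
  cat(sprintf("<codivar_multiblock> %d blocks, %d shared objects\n",
              length(x$blocks), nrow(x$blocks[[1L]]$values)))
  for (b in x$blocks) print(b)
  invisible(x)
}

## Internal helpers used throughout -----------------------------------------

#' @keywords internal
#' @noRd
mb_values <- function(data) lapply(data$blocks, function(b) b$values)

#' @keywords internal
#' @noRd
mb_concat <- function(data) do.call(cbind, unname(mb_values(data)))

#' @keywords internal
#' @noRd
mb_col_index <- function(data) {
  js <- vapply(data$blocks, function(b) ncol(b$values), integer(1))
  ends <- cumsum(js)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

#' @keywords internal
#' @noRd
fnorm2 <- function(m) sum(m * m)

#' Model specification: numbers of common and distinctive components
#'
#' @param n_common Non-negative integer, the number of common components
#'   shared across blocks.
#' @param n_distinct Integer vector of per-block numbers of distinctive
#'   components (length 2 for the two-block case).
#'
#' @return An object of class `codivar_model_spec` with elements `n_common`,
#'   `n_distinct` and `n_total`.
#' @export
model_spec <- function(n_common, n_distinct) {
  n_common <- as.integer(n_common)
  n_distinct <- as.integer(n_distinct)
  if (length(n_common) != 1L || is.na(n_common) || n_common < 0L) {
    stop("invalid-spec: n_common must be a single non-negative integer")
  }
  if (any(is.na(n_distinct)) || any(n_distinct < 0L)) {
    stop("invalid-spec: n_distinct must be non-negative integers")
  }
  structure(list(n_common = n_common, n_distinct = n_distinct,
                 n_total = n_common + sum(n_distinct)),
            class = "codivar_model_spec")
}

#' @export
print.codivar_model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> common = %d, distinctive = (%s), total = %d\n",
              x$n_common, paste(x$n_distinct, collapse = ", "), x$n_total))
  invisible(x)
}

## Validate a spec against the dimensions of a multiblock. Centered data
## have row rank at most I - 1, hence the I - 1 bound on the total count.
#' @keywords internal
#' @noRd
check_spec_feasible <- function(data, spec) {
  stopifnot(inherits(data, "codivar_multiblock"),
            inherits(spec, "codivar_model_spec"))
  js <- vapply(data$blocks, function(b) ncol(b$values), integer(1))
  if (length(spec$n_distinct) != length(js)) {
    stop("invalid-spec: n_distinct length must match the number of blocks")
  }
  i <- nrow(data$blocks[[1L]]$values)
  if (spec$n_total > min(i - 1L, sum(js))) {
    stop("invalid-spec: total component count exceeds min(I-1, sum(J_k))")
  }
  if (any(spec$n_distinct > js)) {
    stop("invalid-spec: a block cannot host more distinctive components ",
         "than it has variables")
  }
  invisible(TRUE)
}

## Preprocessing --------------------------------------------------------------

#' Column-center a block
#'
#' Removes the column means so that every variable has mean zero over the
#' objects. Centering is idempotent and is always applied before block
#' scaling so that the block's total sum of squares is interpretable as
#' variance.
#'
#' @param blk A `codivar_block`.
#' @return The centered block, with `"centered"` appended to its
#'   preprocessing record.
#' @export
center_columns <- function(blk) {
  stopifnot(inherits(blk, "codivar_block"))
  if (nrow(blk$values) < 2L) {
    stop("invalid-input: centering requires at least 2 rows")
  }
  blk$values <- sweep(blk$values, 2L, colMeans(blk$values), "-")
  if (!"centered" %in% blk$preprocessing) {
    blk$preprocessing <- c(blk$preprocessing, "centered")
  }
  blk
}

#' Scale a block to unit total variance
#'
#' Divides the block by its Frobenius norm so that its total sum of squares
#' is exactly 1. Equal block scaling gives every block the same weight in a
#' joint fit regardless of its number of variables.
#'
#' @param blk A `codivar_block`.
#' @return The scaled block, with `"scaled"` appended to its preprocessing
#'   record.
#' @export
scale_block_unit_variance <- function(blk) {
  stopifnot(inherits(blk, "codivar_block"))
  ss <- fnorm2(blk$values)
  if (ss == 0) {
    stop("degenerate-input: cannot scale an all-zero block")
  }
  blk$values <- blk$values / sqrt(ss)
  if (!"scaled" %in% blk$preprocessing) {
    blk$preprocessing <- c(blk$preprocessing, "scaled")
  }
  blk
}

#' Preprocess a multiblock (column centering, block scaling)
#'
#' Applies [center_columns()] and then [scale_block_unit_variance()] to each
#' block. All decomposition methods expect preprocessed input: centering
#' makes sums of squares read as variances, and unit block scaling stops a
#' large block from dominating the joint fit.
#'
#' @param data A `codivar_multiblock`.
#' @param center Apply column centering (default `TRUE`).
#' @param scale Apply unit-variance block scaling (default `TRUE`).
#' @return The preprocessed multiblock with an updated preprocessing record.
#' @export
preprocess <- function(data, center = TRUE, scale = TRUE) {
  stopifnot(inherits(data, "codivar_multiblock"))
  data$blocks <- lapply(data$blocks, function(b) {
    if (center) b <- center_columns(b)
    if (scale) b <- scale_block_unit_variance(b)
    b
  })
  data$preprocessing <- unique(c(data$preprocessing,
                                 c("centered", "scaled")[c(center, scale)]))
  data
}

## Truncated SVD --------------------------------------------------------------

#' Rank-truncated singular value decomposition
#'
#' Best rank-`c` least-squares approximation of a matrix, with a fixed sign
#' convention (the largest-magnitude entry of every left singular vector is
#' positive) so that repeated runs and downstream decompositions are
#' reproducible.
#'
#' @param m Numeric matrix.
#' @param c Number of components to retain, `0 <= c <= min(dim(m))`.
#' @return An object of class `codivar_svd`: list with `u` (left vectors),
#'   `d` (non-increasing singular values) and `v` (right vectors).
#' @export
truncated_svd <- function(m, c) {
  m <- as.matrix(m)
  c <- as.integer(c)
  if (is.na(c) || c < 0L || c > min(dim(m))) {
    stop("invalid-spec: component count must lie in [0, min(dim(m))]")
  }
  if (c == 0L) {
    return(structure(list(u = matrix(0, nrow(m), 0L), d = numeric(0),
                          v = matrix(0, ncol(m), 0L)),
                     class = "codivar_svd"))
  }
  ## Fast path for wide matrices: eigendecompose the I x I Gram matrix and
  ## recover the right vectors by projection. Falls back to the full SVD
  ## when a requested singular value is too small for a stable division.
  out <- NULL
  if (nrow(m) < ncol(m)) {
    eg <- eigen(tcrossprod(m), symmetric = TRUE)
    d <- sqrt(pmax(eg$values[seq_len(c)], 0))
    if (min(d) > 1e-5 * max(d)) {
      u <- eg$vectors[, seq_len(c), drop = FALSE]
      v <- crossprod(m, u) %*% diag(1 / d, nrow = c)
      out <- list(u = u, d = d, v = v)
    }
  }
  if (is.null(out)) {
    sv <- svd(m, nu = c, nv = c)
    out <- list(u = sv$u, d = sv$d[seq_len(c)], v = sv$v)
  }
  svd_fix_signs(out)
}

## Flip signs so the largest-|.| entry of each left vector is positive.
#' @keywords internal
#' @noRd
svd_fix_signs <- function(sv) {
  for (j in seq_len(ncol(sv$u))) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  structure(sv, class = "codivar_svd")
}

## Apply the same convention to an arbitrary score/loading column pair.
#' @keywords internal
#' @noRd
fix_score_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, j]))
    if (length(i) && scores[i, j] < 0) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}
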