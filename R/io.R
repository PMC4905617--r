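#' Read a labeled matrix from delimited text
#'
#' Expects a rectangular table whose first row holds the variable labels
#' and whose first column holds the object labels. Parsing is
#' locale-independent (decimal point). Ragged rows, non-numeric cells and
#' duplicated labels are reported with the offending line.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @param block_id Identifier for the returned block (default the file
#'   name without extension).
#' @return A `codivar_block`.
#' @export
read_labeled_matrix <- function(path, sep = "\t", block_id = NULL) {
  if (!file.exists(path)) stop("invalid-input: file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("invalid-input: ", path, " has an empty data region")
  }
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  var_labels <- header[-1L]
  ncols <- length(var_labels)
  if (ncols < 1L) stop("invalid-input: ", path, " has no variable columns")
  n <- length(lines) - 1L
  values <- matrix(NA_real_, n, ncols)
  obj_labels <- character(n)
  for (r in seq_len(n)) {
    cells <- strsplit(lines[r + 1L], sep, fixed = TRUE)[[1L]]
    if (length(cells) != ncols + 1L) {
      stop("parse error in ", path, ": row ", r, " has ",
           length(cells) - 1L, " data cells, expected ", ncols)
    }
    obj_labels[r] <- cells[1L]
    num <- suppressWarnings(as.numeric(cells[-1L]))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1L]
      stop("parse error in ", path, ": non-numeric cell at row ", r,
           ", column ", bad, " ('", cells[bad + 1L], "')")
    }
    values[r, ] <- num
  }
  if (anyDuplicated(obj_labels)) {
    stop("parse error in ", path, ": duplicate object label '",
         obj_labels[anyDuplicated(obj_labels)], "'")
  }
  if (anyDuplicated(var_labels)) {
    stop("parse error in ", path, ": duplicate variable label '",
         var_labels[anyDuplicated(var_labels)], "'")
  }
  if (is.null(block_id)) block_id <- sub("\\.[^.]*$", "", basename(path))
  block(values, block_id = block_id, object_labels = obj_labels,
        variable_labels = var_labels)
}

#' Write a labeled matrix as delimited text
#'
#' Inverse of [read_labeled_matrix()]: first row variable labels, first
#' column object labels, full double precision.
#'
#' @param m Numeric matrix with dimnames, or a `codivar_block`.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(m, path, sep = "\t") {
  if (inherits(m, "codivar_block")) m <- m$values
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("obj", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("var", seq_len(ncol(m)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(m)), collapse = sep), con)
  body <- apply(m, 1L, function(r) paste(format(r, digits = 17,
                                                trim = TRUE,
                                                scientific = TRUE),
                                         collapse = sep))
  writeLines(paste(rownames(m), body, sep = sep), con)
  invisible(path)
}

#' Export a decomposition to a directory
#'
#' Writes one labeled TSV per part (`C_k`, `D_k`, `E_k`), the score and
#' loading matrices, and a machine-readable `summary.json` holding the
#' method, model specification, explained-variance report and
#' orthogonality audit.
#'
#' @param dec A `codivar_decomposition`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_decomposition <- function(dec, dir) {
  stopifnot(inherits(dec, "codivar_decomposition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ks <- names(dec$common)
  for (k in seq_along(ks)) {
    lab <- dec$data$blocks[[k]]
    part <- function(m) {
      dimnames(m) <- list(lab$object_labels, lab$variable_labels)
      m
    }
    write_labeled_matrix(part(dec$common[[k]]),
                         file.path(dir, paste0("common_", ks[k], ".tsv")))
    write_labeled_matrix(part(dec$distinct[[k]]),
                         file.path(dir, paste0("distinct_", ks[k], ".tsv")))
    write_labeled_matrix(part(dec$residual[[k]]),
                         file.path(dir, paste0("residual_", ks[k], ".tsv")))
    ds <- dec$distinct_scores[[k]]
    if (!is.null(ds) && ncol(ds) > 0L) {
      rownames(ds) <- lab$object_labels
      write_labeled_matrix(ds, file.path(dir,
                                         paste0("distinct_scores_", ks[k],
                                                ".tsv")))
    }
    dl <- dec$distinct_loadings[[k]]
    if (!is.null(dl) && ncol(dl) > 0L) {
      rownames(dl) <- lab$variable_labels
      write_labeled_matrix(dl, file.path(dir,
                                         paste0("distinct_loadings_", ks[k],
                                                ".tsv")))
    }
    cl <- dec$common_loadings[[k]]
    if (!is.null(cl) && ncol(cl) > 0L) {
      rownames(cl) <- lab$variable_labels
      write_labeled_matrix(cl, file.path(dir,
                                         paste0("common_loadings_", ks[k],
                                                ".tsv")))
    }
  }
  cs <- dec$common_scores
  if (is.list(cs)) {
    for (k in seq_along(cs)) {
      if (ncol(cs[[k]]) > 0L) {
        rownames(cs[[k]]) <- dec$data$blocks[[k]]$object_labels
        write_labeled_matrix(cs[[k]],
                             file.path(dir, paste0("common_scores_", ks[k],
                                                   ".tsv")))
      }
    }
  } else if (ncol(cs) > 0L) {
    rownames(cs) <- dec$data$blocks[[1L]]$object_labels
    write_labeled_matrix(cs, file.path(dir, "common_scores.tsv"))
  }
  ev <- explained_variance(dec, type3 = TRUE)
  ortho <- orthogonality_table(dec)
  summary <- list(
    method = dec$method,
    model = list(n_common = dec$model$n_common,
                 n_distinct = dec$model$n_distinct),
    explained_variance = ev,
    additivity_defect = attr(ev, "additivity_defect"),
    orthogonality = ortho,
    crossover = as.list(crossover_variance(dec)),
    version = as.character(utils::packageVersion("codivar")))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
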