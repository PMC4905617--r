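#' Decomposition container
#'
#' Internal constructor for the object returned by [disco_decompose()],
#' [jive_decompose()] and [o2pls_decompose()]. Per block k it stores the
#' common part `C_k`, distinctive part `D_k` and residual `E_k`
#' (all `I x J_k`, summing to the preprocessed `X_k`), the common scores
#' (one shared `I x c_c` matrix for DISCO/JIVE, a per-block list for
#' O2-PLS), common loadings, and per-block distinctive scores/loadings.
#'
#' @keywords internal
#' @noRd
new_decomposition <- function(method, model, data, common, distinct,
                              residual, common_scores, common_loadings,
                              distinct_scores, distinct_loadings,
                              extras = list()) {
  structure(
    c(list(method = method, model = model, data = data,
           common = common, distinct = distinct, residual = residual,
           common_scores = common_scores,
           common_loadings = common_loadings,
           distinct_scores = distinct_scores,
           distinct_loadings = distinct_loadings),
      extras),
    class = "codivar_decomposition")
}

#' @export
print.codivar_decomposition <- function(x, ...) {
  cat(sprintf("<codivar_decomposition: %s>\n", x$method))
  print(x$model)
  xs <- mb_values(x$data)
  for (k in seq_along(xs)) {
    cat(sprintf("  block %s: common %.3f, distinctive %.3f, residual %.3f\n",
                names(xs)[k],
                fnorm2(x$common[[k]]) / fnorm2(xs[[k]]),
                fnorm2(x$distinct[[k]]) / fnorm2(xs[[k]]),
                fnorm2(x$residual[[k]]) / fnorm2(xs[[k]])))
  }
  invisible(x)
}

## Reconstruction defect max_k ||X_k - (C_k + D_k + E_k)|| / ||X_k||.
#' @keywords internal
#' @noRd
reconstruction_error <- function(dec) {
  xs <- mb_values(dec$data)
  max(vapply(seq_along(xs), function(k) {
    sqrt(fnorm2(xs[[k]] - dec$common[[k]] - dec$distinct[[k]] -
                  dec$residual[[k]]) / fnorm2(xs[[k]]))
  }, numeric(1)))
}
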