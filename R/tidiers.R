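# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sparse-subspace-clustering fit
#'
#' @param x A `mihc_ssc` object.
#' @param ... Unused.
#' @return One row per clustered cell: `cell_id`, `roi_id`, `group`, and
#'   the coding diagnostics `n_nonzero` (support size of the cell's sparse
#'   code) and `converged`.
#' @export
tidy.mihc_ssc <- function(x, ...) {
  tibble(
    cell_id = x$cells$cell_id,
    roi_id = x$cells$roi_id,
    group = x$labels,
    n_nonzero = colSums(x$codes$C != 0),
    converged = x$codes$converged
  )
}

#' Glance at a sparse-subspace-clustering fit
#'
#' @param x A `mihc_ssc` object.
#' @param ... Unused.
#' @return One-row tibble: `n_cells`, `k`, `n_landmarks`, `alpha`,
#'   `mean_support` (mean nonzeros per code), `prop_converged`,
#'   `normalization`.
#' @export
glance.mihc_ssc <- function(x, ...) {
  tibble(
    n_cells = ncol(x$codes$C),
    k = x$k,
    n_landmarks = length(x$landmarks),
    alpha = x$parameters$alpha,
    mean_support = mean(colSums(x$codes$C != 0)),
    prop_converged = mean(x$codes$converged),
    normalization = x$parameters$normalization
  )
}
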