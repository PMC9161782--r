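# Spatial statistics between phenotypes: nearest-neighbour distances,
# proximity fractions, and the knn permutation neighbourhood-enrichment test
# (observed mean neighbour counts versus a null built by shuffling phenotype
# labels over fixed positions).

# k nearest neighbours by brute-force Euclidean distance, ties at the kth
# distance broken by cell order for determinism. Returns an n x k index
# matrix. Chunked over query points to bound memory.
knn_index <- function(x, y, k) {
  n <- length(x)
  k <- min(k, n - 1)
  if (k < 1) return(matrix(integer(0), n, 0))
  nb <- matrix(0L, n, k)
  chunk <- max(1, floor(2e6 / n))
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf # no self-edges
    for (r in seq_along(idx)) {
      ord <- order(d2[r, ], seq_len(n))[seq_len(k)]
      nb[idx[r], ] <- ord
    }
  }
  nb
}

#' Build the per-ROI k-nearest-neighbour graph
#'
#' @param cells Cell table for one ROI (`x_um`, `y_um`).
#' @param k Neighbour count (default 10); cells get `min(k, N - 1)`
#'   neighbours, no self-edges.
#' @return A `mihc_graph`: `neighbors` (n x k index matrix), `k`, `cell_id`,
#'   and the coordinates.
#' @export
spatial_graph <- function(cells, k = 10) {
  check_cell_table(cells, coords = TRUE)
  nb <- knn_index(cells$x_um, cells$y_um, k)
  structure(list(neighbors = nb, k = k, cell_id = cells$cell_id,
                 x_um = cells$x_um, y_um = cells$y_um,
                 roi_id = if (nrow(cells) > 0) cells$roi_id[1] else NA),
            class = "mihc_graph")
}

#' @export
print.mihc_graph <- function(x, ...) {
  cat("<mihc_graph> ", length(x$cell_id), " cells, k=", x$k, "\n", sep = "")
  invisible(x)
}

#' Mean shortest distance from a reference to a target phenotype
#'
#' For every reference cell, the Euclidean distance (um) to its nearest
#' target cell (self excluded when the phenotypes coincide); returns the mean
#' and the per-reference-cell distance vector. An empty reference or target
#' set yields a flagged undefined result (`defined = FALSE`), never zero.
#'
#' @param cells Cell table with coordinates and a `phenotype` column (or the
#'   column named in `label_col`).
#' @param reference,target Phenotype labels.
#' @param label_col Name of the label column.
#' @return List: `mean_um`, `distances` (per reference cell), `defined`.
#' @export
#' @examples
#' cells <- tibble::tibble(cell_id = 1:3, roi_id = "r",
#'                         x_um = c(0, 3, 10), y_um = c(0, 4, 0),
#'                         phenotype = c("A", "B", "B"))
#' mean_shortest_distance(cells, "A", "B")$mean_um # 3-4-5 triangle: 5
mean_shortest_distance <- function(cells, reference, target,
                                   label_col = "phenotype") {
  check_cell_table(cells, coords = TRUE)
  lab <- cells[[label_col]]
  ref_i <- which(lab == reference)
  tgt_i <- which(lab == target)
  undefined <- list(mean_um = NA_real_, distances = numeric(0),
                    defined = FALSE)
  if (length(ref_i) == 0 || length(tgt_i) == 0) return(undefined)
  same <- identical(reference, target)
  if (same && length(tgt_i) < 2) return(undefined)
  tx <- cells$x_um[tgt_i]; ty <- cells$y_um[tgt_i]
  d <- vapply(ref_i, function(i) {
    d2 <- (tx - cells$x_um[i])^2 + (ty - cells$y_um[i])^2
    if (same) d2[tgt_i == i] <- Inf
    sqrt(min(d2))
  }, numeric(1))
  list(mean_um = mean(d), distances = d, defined = TRUE)
}

#' Fraction of reference cells within proximity thresholds
#'
#' @param distances Nearest-target distance vector (um), e.g. from
#'   [mean_shortest_distance()].
#' @param thresholds_um Proximity thresholds (default 30 and 50 um).
#' @return Tibble: `threshold_um`, `fraction` (of reference cells whose
#'   nearest target lies within the threshold).
#' @export
proximity_fractions <- function(distances, thresholds_um = c(30, 50)) {
  if (length(distances) == 0) abort("empty distance vector")
  if (any(distances < 0)) abort("distances must be non-negative")
  tibble(
    threshold_um = thresholds_um,
    fraction = vapply(thresholds_um,
                      function(t) mean(distances <= t), numeric(1))
  )
}

#' Neighbourhood enrichment by label permutation
#'
#' For every ordered phenotype pair (reference, target): the observed mean
#' number of target cells among each reference cell's k nearest neighbours,
#' compared against a null built by shuffling the labels over the fixed
#' positions `n_perm` times. Reports the permutation z-score and the
#' empirical two-sided p-value with the add-one correction
#' `p = (#{|perm - mean| >= |obs - mean|} + 1) / (n_perm + 1)`, and
#' classifies each pair as enriched / depleted / ns at level `alpha`.
#' Results are directional: (ref, tgt) and (tgt, ref) are distinct tests.
#'
#' @param graph A `mihc_graph` from [spatial_graph()].
#' @param labels Phenotype label per graph node.
#' @param n_perm Number of permutations (default 1000).
#' @param alpha Significance level for the class calls.
#' @param seed Integer seed of the permutation generator.
#' @return Tibble per ordered pair: `roi_id`, `reference`, `target`,
#'   `observed`, `perm_mean`, `perm_sd`, `z`, `p`, `class` (enriched /
#'   depleted / ns / not_evaluable).
#' @export
neighborhood_enrichment <- function(graph, labels, n_perm = 1000,
                                    alpha = 0.05, seed = 1) {
  nb <- graph$neighbors
  n <- nrow(nb)
  if (length(labels) != n) abort("labels must cover all graph nodes")
  k <- ncol(nb)
  levs <- sort(unique(as.character(labels)))
  L <- length(levs)
  lab_i <- match(as.character(labels), levs)

  # mean target-neighbour count per (ref, tgt), as an L x L matrix
  pair_stat <- function(li) {
    ref_of_edge <- rep(li, times = k)
    tgt_of_edge <- li[as.vector(nb)]
    counts <- matrix(tabulate((ref_of_edge - 1L) * L + tgt_of_edge, L * L),
                     L, L, byrow = TRUE)
    n_ref <- tabulate(li, L)
    counts / pmax(n_ref, 1)
  }

  obs <- pair_stat(lab_i)
  perm_sum <- matrix(0, L, L)
  perm_sumsq <- matrix(0, L, L)
  exceed <- matrix(0, L, L) # filled after the mean is known: store perms
  perm_store <- array(0, c(L, L, n_perm))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pl <- lab_i[sample.int(n)]
      ps <- pair_stat(pl)
      perm_store[, , b] <- ps
      perm_sum <- perm_sum + ps
      perm_sumsq <- perm_sumsq + ps^2
    }
  })
  perm_mean <- perm_sum / n_perm
  perm_sd <- sqrt(pmax(perm_sumsq / n_perm - perm_mean^2, 0) *
                    n_perm / max(n_perm - 1, 1))
  for (b in seq_len(n_perm)) {
    exceed <- exceed +
      (abs(perm_store[, , b] - perm_mean) >= abs(obs - perm_mean) - 1e-12)
  }
  p <- (exceed + 1) / (n_perm + 1)
  z <- ifelse(perm_sd > 0, (obs - perm_mean) / perm_sd, 0)

  n_ref <- tabulate(lab_i, L)
  out <- tidyr::expand_grid(reference = levs, target = levs)
  ri <- match(out$reference, levs)
  ti <- match(out$target, levs)
  idx <- cbind(ri, ti)
  out$observed <- obs[idx]
  out$perm_mean <- perm_mean[idx]
  out$perm_sd <- perm_sd[idx]
  out$z <- z[idx]
  out$p <- p[idx]
  evaluable <- n_ref[ri] > 0 & n_ref[ti] > 0
  out$class <- dplyr::case_when(
    !evaluable ~ "not_evaluable",
    out$p < alpha & out$observed > out$perm_mean ~ "enriched",
    out$p < alpha & out$observed < out$perm_mean ~ "depleted",
    TRUE ~ "ns"
  )
  out <- dplyr::bind_cols(tibble(roi_id = graph$roi_id %||% NA_character_),
                          out)
  class(out) <- c("mihc_enrichment", class(out))
  out
}

#' Aggregate per-ROI enrichment into stage-level matrices
#'
#' Element-wise mean z per (reference, target) across the ROIs of each
#' stage, skipping non-evaluable entries; the count of contributing ROIs is
#' attached per pair.
#'
#' @param results List of (or row-bound) [neighborhood_enrichment()]
#'   tibbles.
#' @param roi_stage Tibble with `roi_id`, `stage`.
#' @return Tibble: `stage`, `reference`, `target`, `mean_z`, `n_roi`.
#' @export
aggregate_enrichment <- function(results, roi_stage) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- bind_rows(results)
  }
  merged <- left_join(results, roi_stage, by = "roi_id")
  if (anyNA(merged$stage)) abort("ROI(s) missing from the stage map")
  merged %>%
    filter(.data$class != "not_evaluable") %>%
    group_by(.data$stage, .data$reference, .data$target) %>%
    summarise(mean_z = mean(.data$z), n_roi = dplyr::n(),
              .groups = "drop")
}
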