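# Landmark sparse subspace clustering (SSC) over the marker-by-cell matrix.
# Each cell's marker vector is coded as a sparse linear combination of a
# landmark dictionary (the self-expressiveness property: points in a union
# of subspaces reconstruct from points of their own subspace); the l1-
# penalized codes define an affinity graph that is partitioned by spectral
# clustering. The solver is FISTA on the lasso relaxation
#   min 1/2 ||x_i - D c_i||^2 + lambda_i ||c_i||_1,   c_ii = 0,
# vectorized over all cells.

#' Filter to immune cells by the CD45 cut-off
#'
#' Retains cells whose mean CD45 intensity is strictly greater than the
#' cut-off (default 0.07 on the unit intensity scale), the pan-immune
#' pre-filter applied before clustering.
#'
#' @param cells Cell table with a `CD45` column.
#' @param cd45_cutoff Strict lower cut-off.
#' @return The filtered tibble.
#' @export
#' @examples
#' filter_immune(tibble::tibble(cell_id = 1:3, roi_id = "r",
#'                              CD45 = c(0.06, 0.07, 0.08)))$CD45
filter_immune <- function(cells, cd45_cutoff = 0.07) {
  if (!"CD45" %in% names(cells)) abort("cell table lacks a CD45 column")
  cells[cells$CD45 > cd45_cutoff, , drop = FALSE]
}

#' Build the marker-by-cell feature matrix
#'
#' @param cells Cell table containing every panel marker.
#' @param markers Feature rows (default the 10-marker panel).
#' @param normalization `"none"` (raw intensities), `"max"` (each marker
#'   scaled by its maximum) or `"zscore"` (each marker centred/scaled).
#' @return A `mihc_features` object: `X` (m x N matrix, rows = markers,
#'   columns = cells), `cell_id`, `normalization` and the scaling record
#'   (`center`, `scale`) needed to invert it.
#' @export
build_feature_matrix <- function(cells, markers = mihc_panel(),
                                 normalization = c("none", "max",
                                                   "zscore")) {
  normalization <- match.arg(normalization)
  missing <- setdiff(markers, names(cells))
  if (length(missing) > 0) {
    abort(paste0("cell table lacks marker column(s): ",
                 paste(missing, collapse = ", ")))
  }
  X <- t(as.matrix(cells[, markers, drop = FALSE]))
  if (anyNA(X)) abort("feature matrix contains missing values")
  center <- rep(0, length(markers)); scale_ <- rep(1, length(markers))
  if (normalization == "max") {
    scale_ <- apply(X, 1, max)
    if (any(scale_ <= 0)) abort("marker with non-positive maximum")
    X <- X / scale_
  } else if (normalization == "zscore") {
    center <- rowMeans(X)
    scale_ <- apply(X, 1, sd)
    if (any(scale_ < 1e-12)) {
      abort("zero-variance marker under z-score normalization")
    }
    X <- (X - center) / scale_
  }
  names(center) <- names(scale_) <- markers
  structure(list(X = X, cell_id = cells$cell_id, markers = markers,
                 normalization = normalization, center = center,
                 scale = scale_),
            class = "mihc_features")
}

#' Select landmark cells
#'
#' Landmarks are the representative points the sparse coder uses as its
#' dictionary. `"kmeans"` runs k-means with `n_landmarks` centres and picks
#' the cell nearest each centre; `"random"` samples uniformly.
#'
#' @param features A `mihc_features`.
#' @param n_landmarks Number of landmarks (1..N).
#' @param method `"kmeans"` or `"random"`.
#' @param seed Integer seed (selection is deterministic given the seed).
#' @return Integer vector of landmark column indices (sorted).
#' @export
select_landmarks <- function(features, n_landmarks = 2000,
                             method = c("kmeans", "random"), seed = 1) {
  method <- match.arg(method)
  N <- ncol(features$X)
  if (n_landmarks < 1 || n_landmarks > N) {
    abort("n_landmarks must be between 1 and the number of cells")
  }
  if (n_landmarks == N) return(seq_len(N))
  with_seed(seed, {
    if (method == "random") {
      sort(sample.int(N, n_landmarks))
    } else {
      pts <- t(features$X)
      km <- suppressWarnings(
        kmeans(pts, centers = n_landmarks, iter.max = 50, nstart = 1))
      idx <- vapply(seq_len(n_landmarks), function(j) {
        d2 <- colSums((features$X - km$centers[j, ])^2)
        which.min(d2)
      }, numeric(1))
      sort(unique(idx))
    }
  })
}

#' Sparse-code all cells against the landmark dictionary
#'
#' Solves, for every cell i, the noise-tolerant l1 program
#' `min 1/2 ||x_i - D c_i||^2 + lambda_i ||c_i||_1` over the landmark
#' dictionary D, with the self-coefficient pinned to zero when cell i is a
#' landmark (excluding the trivial self-representation). `lambda_i` scales
#' with the per-cell maximal correlation: `lambda_i = alpha *
#' ||D^T x_i||_inf`, so `alpha` in (0, 1) spans the whole lasso path.
#' Solved by FISTA, vectorized over cells.
#'
#' @param features A `mihc_features`.
#' @param landmarks Landmark column indices.
#' @param alpha Sparsity level in (0, 1); `lambda_i = alpha *
#'   ||D^T x_i||_inf`.
#' @param max_iter FISTA iteration cap.
#' @param tol Relative KKT-violation tolerance (per cell, relative to its
#'   `lambda_i`); optimality is checked periodically and drives the stop.
#' @param unit_norm Scale every cell vector (and hence the dictionary) to
#'   unit Euclidean norm before coding. Phenotype structure in stain
#'   intensities is angular — cells of one type share a marker direction at
#'   varying overall brightness — so coding on the unit sphere keeps the
#'   codes from fragmenting a phenotype by staining strength.
#' @return A `mihc_codes`: `C` (L x N coefficient matrix), `landmarks`,
#'   `lambda` (per cell), `converged` (per cell), `iterations`.
#' @export
sparse_code <- function(features, landmarks, alpha = 0.05,
                        max_iter = 1000, tol = 1e-3, unit_norm = FALSE) {
  if (length(landmarks) == 0) abort("landmarks must be non-empty")
  if (alpha < 0) abort("alpha must be non-negative")
  X <- features$X
  if (unit_norm) {
    nrm <- sqrt(colSums(X^2))
    X <- sweep(X, 2, pmax(nrm, 1e-12), "/")
  }
  D <- X[, landmarks, drop = FALSE] # m x L
  N <- ncol(X); L <- length(landmarks)

  # the Gram matrix D'D has rank <= m, so all products go through D:
  # D'(D Z) costs O(m L N) instead of O(L^2 N)
  gram_mul <- function(Z) crossprod(D, D %*% Z)
  DtX <- crossprod(D, X) # L x N
  lambda <- alpha * apply(abs(DtX), 2, max)
  lambda[lambda == 0] <- max(alpha, 1e-8) # degenerate all-zero cell
  lip <- svd(D, nu = 0, nv = 0)$d[1]^2
  if (!is.finite(lip) || lip <= 0) lip <- 1
  step <- 1 / lip

  # pin self-coefficients of landmark cells to zero
  self_idx <- cbind(seq_len(L), landmarks) # (row in C, column in C)
  LAM <- matrix(lambda, L, N, byrow = TRUE)
  thr <- step * LAM

  kkt_violation <- function(C) {
    R <- DtX - gram_mul(C) # = D^T (x - D c)
    V <- pmax(abs(R) - LAM, 0) # inactive-coefficient violation
    act <- C != 0
    V[act] <- abs(R[act] - LAM[act] * sign(C[act]))
    V[self_idx] <- 0 # pinned coefficients carry no condition
    apply(V, 2, max)
  }

  C <- matrix(0, L, N)
  Z <- C
  t_acc <- 1
  iters <- max_iter
  viol <- rep(Inf, N)
  for (it in seq_len(max_iter)) {
    grad <- gram_mul(Z) - DtX
    C_new <- Z - step * grad
    C_new <- sign(C_new) * pmax(abs(C_new) - thr, 0)
    C_new[self_idx] <- 0
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    Z <- C_new + ((t_acc - 1) / t_new) * (C_new - C)
    C <- C_new
    t_acc <- t_new
    if (it %% 25 == 0 || it == max_iter) {
      viol <- kkt_violation(C)
      if (max(viol / pmax(lambda, 1e-12)) <= tol) {
        iters <- it
        break
      }
    }
  }

  # exact active-set polish for cells FISTA left short of optimality:
  # coordinate descent on the restricted support (support + KKT violators),
  # growing the support until the full KKT conditions hold. The restricted
  # problems are tiny (tens of coordinates), so this is cheap and robust.
  forbid_of <- integer(N)
  forbid_of[landmarks] <- seq_len(L)
  need <- which(viol / pmax(lambda, 1e-12) > tol)
  col_norm2 <- colSums(D^2)
  for (i in need) {
    ci <- C[, i]
    lam_i <- lambda[i]
    fb <- forbid_of[i]
    for (outer_it in 1:30) {
      g <- DtX[, i] - crossprod(D, D %*% ci)[, 1]
      viol_g <- abs(g) - lam_i * (1 + 1e-10)
      if (fb > 0) viol_g[fb] <- -Inf
      cand <- which(viol_g > 0)
      # grow the working set by the worst violators only, so coordinate
      # descent always runs on a small, relevant subproblem
      if (length(cand) > 10) {
        cand <- cand[order(viol_g[cand], decreasing = TRUE)[1:10]]
      }
      S <- union(which(ci != 0), cand)
      if (fb > 0) S <- setdiff(S, fb)
      if (length(S) == 0) break
      DS <- D[, S, drop = FALSE]
      cS <- ci[S]
      r <- X[, i] - DS %*% cS
      # coordinate descent on the restricted problem (globally convergent
      # for the lasso); a periodic KKT check on the restricted set exits
      # as soon as the declared tolerance is met, and the sweep budget
      # scales inversely with the support size
      max_sweeps <- min(8000L, max(200L, ceiling(2e5 / length(S))))
      for (sweep_it in seq_len(max_sweeps)) {
        delta <- 0
        for (j in seq_along(S)) {
          dj <- DS[, j]
          nj <- col_norm2[S[j]]
          if (nj < 1e-14) next
          a <- sum(dj * r) + nj * cS[j]
          new_c <- sign(a) * max(abs(a) - lam_i, 0) / nj
          if (new_c != cS[j]) {
            r <- r + dj * (cS[j] - new_c)
            delta <- max(delta, abs(new_c - cS[j]))
            cS[j] <- new_c
          }
        }
        if (delta < 1e-14) break
        if (sweep_it %% 25 == 0) {
          gS <- crossprod(DS, r)[, 1]
          vS <- pmax(abs(gS) - lam_i, 0)
          aS <- cS != 0
          vS[aS] <- abs(gS[aS] - lam_i * sign(cS[aS]))
          if (max(vS) <= 0.5 * tol * lam_i) break
        }
      }
      ci <- rep(0, L)
      ci[S] <- cS
      # full KKT for this cell: stop when within tolerance
      g <- DtX[, i] - crossprod(D, D %*% ci)[, 1]
      v <- pmax(abs(g) - lam_i, 0)
      act_i <- ci != 0
      v[act_i] <- abs(g[act_i] - lam_i * sign(ci[act_i]))
      if (fb > 0) v[fb] <- 0
      if (max(v) <= tol * lam_i) break
    }
    obj <- function(cc) {
      0.5 * sum((X[, i] - D %*% cc)^2) + lam_i * sum(abs(cc))
    }
    if (obj(ci) <= obj(C[, i]) + 1e-12) C[, i] <- ci
  }
  if (length(need) > 0) viol <- kkt_violation(C)
  # absolute floor keeps the flag meaningful when lambda is near zero
  converged <- viol <= 10 * tol * pmax(lambda, 1e-12) + 1e-9
  if (!all(converged)) {
    warn(sprintf("sparse coding: %d/%d cells flagged non-converged",
                 sum(!converged), N))
  }
  structure(list(C = C, landmarks = landmarks, lambda = lambda,
                 alpha = alpha, converged = converged, iterations = iters,
                 cell_id = features$cell_id),
            class = "mihc_codes")
}

# symmetric non-negative affinity with zero diagonal from codes
codes_to_affinity <- function(codes) {
  C <- abs(codes$C)
  L <- nrow(C); N <- ncol(C)
  if (L == N && identical(codes$landmarks, seq_len(N))) {
    # full self-expressive case: W = |C| + |C|^T
    W <- C + t(C)
  } else {
    # landmark-mediated: cells are similar when they share landmark support
    Cn <- C
    nrm <- sqrt(colSums(Cn^2))
    nz <- nrm > 0
    Cn[, nz] <- sweep(Cn[, nz, drop = FALSE], 2, nrm[nz], "/")
    W <- crossprod(Cn)
  }
  diag(W) <- 0
  W[W < 0] <- 0
  (W + t(W)) / 2
}

spectral_embedding <- function(W, k) {
  d <- rowSums(W)
  d[d <= 0] <- 1e-12
  s <- 1 / sqrt(d)
  L_sym <- diag(nrow(W)) - (s * W) * rep(s, each = nrow(W))
  # smallest-eigenvalue eigenvectors of the normalized Laplacian
  eig <- eigen(L_sym, symmetric = TRUE)
  n <- nrow(W)
  U <- eig$vectors[, n:(n - k + 1), drop = FALSE]
  # row-normalize (Ng-Jordan-Weiss)
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm < 1e-12] <- 1
  U / nrm
}

#' Spectral clustering of the coded affinity graph
#'
#' Builds the symmetric affinity from the sparse codes (`|C| + |C|^T` when
#' all cells are landmarks; otherwise cosine similarity of landmark-support
#' profiles), embeds with the k smallest eigenvectors of the normalized
#' Laplacian, and partitions the row-normalized embedding by k-means with a
#' fixed seed.
#'
#' @param codes A `mihc_codes` from [sparse_code()].
#' @param k Number of groups.
#' @param seed Seed for the k-means initialization.
#' @param nstart k-means restarts.
#' @return Integer vector of group labels in `1..k` (one per cell).
#' @export
cluster_from_codes <- function(codes, k, seed = 1, nstart = 10) {
  N <- ncol(codes$C)
  if (k < 1) abort("k must be at least 1")
  if (k > N) abort("k exceeds the number of cells")
  if (k == 1) return(rep(1L, N))
  W <- codes_to_affinity(codes)
  U <- spectral_embedding(W, k)
  with_seed(seed, {
    km <- suppressWarnings(kmeans(U, centers = k, nstart = nstart,
                                  iter.max = 100))
    as.integer(km$cluster)
  })
}

#' Choose the number of groups by the elbow rule
#'
#' Computes a dispersion curve — the within-cluster sum of squares of
#' k-means in the spectral embedding (eigenvectors of the normalized
#' Laplacian, each weighted by `(1 - eigenvalue)^2` so uninformative
#' high-frequency directions are damped) — over `k_range`, and returns the
#' elbow: the k with the largest discrete second difference (maximum
#' curvature) of the normalized curve. The elbow only counts when the
#' dispersion drop into it dominates the drop just after it by at least
#' `min_strength` (a smooth, elbow-free decay never does); otherwise the
#' smallest k in the range is returned. The full curve is attached for
#' inspection.
#'
#' @param codes A `mihc_codes`.
#' @param k_range Candidate k values (sorted, within 1..N).
#' @param seed Seed for the embedded k-means runs.
#' @param min_strength Required ratio of the dispersion drop entering the
#'   elbow to the drop following it.
#' @return The chosen k, with the dispersion curve attached as attribute
#'   `"curve"` (tibble `k`, `wss`).
#' @export
choose_k <- function(codes, k_range = 1:8, seed = 1, min_strength = 3) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) abort("k_range must be non-empty")
  N <- ncol(codes$C)
  if (any(k_range < 1 | k_range > N)) abort("k_range outside 1..N")
  if (length(k_range) == 1) {
    out <- k_range
    attr(out, "curve") <- tibble(k = k_range, wss = NA_real_)
    return(out)
  }
  W <- codes_to_affinity(codes)
  d <- rowSums(W)
  d[d <= 0] <- 1e-12
  s <- 1 / sqrt(d)
  L_sym <- diag(nrow(W)) - (s * W) * rep(s, each = nrow(W))
  eig <- eigen(L_sym, symmetric = TRUE)
  kmax <- min(max(k_range), N - 1)
  lam <- rev(eig$values)[seq_len(kmax)]
  U <- eig$vectors[, ncol(eig$vectors):(ncol(eig$vectors) - kmax + 1),
                   drop = FALSE]
  U <- sweep(U, 2, pmax(1 - lam, 0)^2, "*")
  wss <- vapply(k_range, function(k) {
    if (k == 1) {
      sum(sweep(U, 2, colMeans(U))^2)
    } else if (k >= nrow(U)) {
      0
    } else {
      with_seed(seed + k, {
        suppressWarnings(kmeans(U, centers = k, nstart = 10,
                                iter.max = 100)$tot.withinss)
      })
    }
  }, numeric(1))
  curve <- tibble(k = k_range, wss = wss)
  k_star <- k_range[1]
  if (length(k_range) >= 3) {
    wn <- wss / max(wss[1], 1e-12)
    curv <- wn[1:(length(wn) - 2)] - 2 * wn[2:(length(wn) - 1)] +
      wn[3:length(wn)]
    cand <- which.max(curv) + 1
    drop_in <- wn[cand - 1] - wn[cand]
    drop_out <- max(wn[cand] - wn[cand + 1], 1e-12)
    if (drop_in >= min_strength * drop_out) k_star <- k_range[cand]
  }
  out <- k_star
  attr(out, "curve") <- curve
  out
}

#' Mean marker profile of each group
#'
#' @param labels Group labels (one per cell in `cells`).
#' @param cells Cell table with marker columns.
#' @param markers Marker columns to profile.
#' @return Tibble: `group`, `n_cells`, one column per marker (arithmetic
#'   mean over members), ordered by group id. Empty groups are dropped with
#'   a warning.
#' @export
cluster_profiles <- function(labels, cells, markers = mihc_panel()) {
  if (length(labels) != nrow(cells)) {
    abort("labels and cell table have different lengths")
  }
  groups <- sort(unique(labels))
  all_groups <- if (is.numeric(labels)) seq_len(max(labels)) else groups
  empty <- setdiff(all_groups, groups)
  if (length(empty) > 0) {
    warn(paste0("empty group(s) excluded from profiles: ",
                paste(empty, collapse = ", ")))
  }
  prof <- lapply(groups, function(g) {
    sub <- cells[labels == g, markers, drop = FALSE]
    row <- tibble(group = g, n_cells = nrow(sub))
    for (m in markers) row[[m]] <- mean(sub[[m]])
    row
  })
  bind_rows(prof)
}

#' Automated phenotyping by landmark sparse subspace clustering
#'
#' End-to-end convenience wrapper: CD45 immune filter, feature matrix,
#' landmark selection, sparse coding, spectral clustering and group
#' profiling.
#'
#' @param cells Cell table with all panel markers.
#' @param k Number of groups (default 20); `NULL` selects k by [choose_k()]
#'   over `k_range`.
#' @param cd45_cutoff CD45 immune cut-off (`NA` disables the filter).
#' @param n_landmarks Landmark count (capped at the cell count).
#' @param alpha Sparsity level of the coder.
#' @param normalization Feature normalization mode.
#' @param unit_norm Code cells on the unit sphere (see [sparse_code()]);
#'   default `TRUE` for intensity data.
#' @param markers Panel markers used as features.
#' @param seed Master seed (landmarks, coder, k-means).
#' @param k_range Candidate range when `k = NULL`.
#' @return A `mihc_ssc` object: `cells` (the clustered subset with a
#'   `group` column), `labels`, `codes`, `profiles`, `k`, `landmarks`,
#'   `parameters`.
#' @export
ssc_phenotype <- function(cells, k = 20, cd45_cutoff = 0.07,
                          n_landmarks = 2000, alpha = 0.05,
                          normalization = "none", unit_norm = TRUE,
                          markers = mihc_panel(),
                          seed = 1, k_range = 2:25) {
  sub <- if (is.na(cd45_cutoff)) cells else filter_immune(cells, cd45_cutoff)
  if (nrow(sub) < 2) abort("fewer than 2 cells after the immune filter")
  feats <- build_feature_matrix(sub, markers, normalization)
  lm_idx <- select_landmarks(feats, min(n_landmarks, ncol(feats$X)),
                             seed = seed)
  codes <- sparse_code(feats, lm_idx, alpha = alpha,
                       unit_norm = unit_norm)
  if (is.null(k)) {
    k <- as.integer(choose_k(codes, k_range, seed = seed))
  }
  labels <- cluster_from_codes(codes, k, seed = seed)
  out_cells <- sub
  out_cells$group <- labels
  structure(
    list(cells = out_cells, labels = labels, codes = codes,
         profiles = cluster_profiles(labels, sub, markers), k = k,
         landmarks = lm_idx,
         parameters = list(cd45_cutoff = cd45_cutoff, alpha = alpha,
                           n_landmarks = length(lm_idx),
                           normalization = normalization,
                           unit_norm = unit_norm, seed = seed)),
    class = "mihc_ssc"
  )
}

#' @export
print.mihc_ssc <- function(x, ...) {
  cat("<mihc_ssc> ", ncol(x$codes$C), " cells in ", x$k, " groups (",
      length(x$landmarks), " landmarks, alpha=", x$parameters$alpha,
      ")\n", sep = "")
  invisible(x)
}
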