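# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by enumeration / O(n^2) scans, separate from the package
# implementations they check.

# exact two-sided Mann-Whitney p by enumerating all rank assignments
# (tie-free data only)
mwu_enum_p <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  pooled <- c(g1, g2)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(idx1) {
    r <- rank(pooled)
    sum(r[idx1]) - n1 * (n1 + 1) / 2
  }
  obs_u <- u_of(seq_len(n1))
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(obs_u - mu))
}

# Kruskal-Wallis H from first principles (tie-corrected)
kruskal_enum_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(splits, function(ri) length(ri) * mean(ri)^2, numeric(1))) -
    3 * (n + 1)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / tie_corr
}

# rule-list gating evaluated one cell at a time with explicit loops
gate_brute_force <- function(sign_vec, rules) {
  for (r in rules) {
    ok <- TRUE
    for (m in names(r$require)) {
      want_pos <- r$require[[m]] == "+"
      if (sign_vec[[m]] != want_pos) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(r$label)
  }
  NA_character_
}

# O(n^2) nearest-distance oracle
nearest_dist_oracle <- function(cells, reference, target,
                               label_col = "phenotype") {
  lab <- cells[[label_col]]
  ref_i <- which(lab == reference)
  tgt_i <- which(lab == target)
  vapply(ref_i, function(i) {
    best <- Inf
    for (j in tgt_i) {
      if (j == i) next
      d <- sqrt((cells$x_um[i] - cells$x_um[j])^2 +
                  (cells$y_um[i] - cells$y_um[j])^2)
      if (d < best) best <- d
    }
    best
  }, numeric(1))
}

# brute-force knn by full sort per point (ties by index)
knn_oracle <- function(x, y, k) {
  n <- length(x)
  t(vapply(seq_len(n), function(i) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    order(d, seq_len(n))[seq_len(min(k, n - 1))]
  }, integer(min(k, n - 1))))
}

# lasso solution by support/sign enumeration: minimize
# 1/2 ||x - D c||^2 + lambda ||c||_1 for small dictionaries.
# Enumerates supports up to `max_support`, solves the stationarity system per
# sign pattern, and keeps solutions satisfying all KKT conditions.
lasso_enum <- function(D, x, lambda, max_support = 3, forbid = integer(0)) {
  L <- ncol(D)
  best <- rep(0, L)
  best_obj <- 0.5 * sum(x^2)
  check_kkt <- function(c_full) {
    r <- x - D %*% c_full
    g <- crossprod(D, r)
    ok <- TRUE
    for (j in seq_len(L)) {
      if (j %in% forbid) next
      if (c_full[j] != 0) {
        if (abs(g[j] - lambda * sign(c_full[j])) > 1e-8) ok <- FALSE
      } else if (abs(g[j]) > lambda + 1e-8) {
        ok <- FALSE
      }
    }
    ok
  }
  allowed <- setdiff(seq_len(L), forbid)
  if (check_kkt(best)) return(best)
  for (sz in seq_len(min(max_support, length(allowed)))) {
    for (S in asplit(combn(allowed, sz), 2)) {
      DS <- D[, S, drop = FALSE]
      G <- crossprod(DS)
      if (abs(det(G)) < 1e-12) next
      signs_grid <- expand.grid(rep(list(c(-1, 1)), sz))
      for (si in seq_len(nrow(signs_grid))) {
        s <- as.numeric(signs_grid[si, ])
        cS <- solve(G, crossprod(DS, x) - lambda * s)
        if (any(sign(cS) != s)) next
        c_full <- rep(0, L)
        c_full[S] <- cS
        if (check_kkt(c_full)) {
          obj <- 0.5 * sum((x - D %*% c_full)^2) + lambda * sum(abs(c_full))
          if (obj < best_obj - 1e-12) {
            best <- c_full
            best_obj <- obj
          }
        }
      }
    }
  }
  best
}
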