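# Landmark sparse subspace clustering: immune filter, feature matrix,
# landmarks, the l1 coder (against enumeration and glmnet oracles),
# spectral partitioning, model selection, profiles.

test_that("the CD45 immune filter is strictly greater-than", {
  cells <- tibble::tibble(cell_id = 1:3, roi_id = "r",
                          CD45 = c(0.06, 0.07, 0.08))
  kept <- filter_immune(cells)
  expect_equal(kept$CD45, 0.08)
  all_pos <- tibble::tibble(cell_id = 1:4, roi_id = "r",
                            CD45 = c(0.2, 0.5, 0.9, 0.01))
  expect_equal(nrow(filter_immune(all_pos, cd45_cutoff = 0)), 4)
  expect_error(filter_immune(tibble::tibble(cell_id = 1, roi_id = "r")),
               "CD45")
})

test_that("the immune filter matches a column-scan oracle on a fixture", {
  arcs <- fixture_archetypes()
  cells <- synth_cell_table(
    arcs, c("CD8 T cells" = 200, "Epithelial cells" = 300),
    noise_seed = 13)
  kept <- filter_immune(cells, 0.07)
  n_oracle <- 0
  for (i in seq_len(nrow(cells))) {
    if (cells$CD45[i] > 0.07) n_oracle <- n_oracle + 1
  }
  expect_equal(nrow(kept), n_oracle)
})

test_that("feature matrices honour the normalization contract", {
  arcs <- fixture_archetypes()
  cells <- synth_cell_table(arcs, c("CD8 T cells" = 50, "B cells" = 50),
                            noise_seed = 3)
  raw <- build_feature_matrix(cells, normalization = "none")
  expect_equal(dim(raw$X), c(10, 100))
  expect_equal(unname(raw$X["CD45", ]), cells$CD45)
  mx <- build_feature_matrix(cells, normalization = "max")
  expect_equal(unname(apply(mx$X, 1, max)), rep(1, 10))
  zs <- build_feature_matrix(cells, normalization = "zscore")
  expect_lt(max(abs(rowMeans(zs$X))), 1e-9)
  expect_lt(max(abs(apply(zs$X, 1, sd) - 1)), 1e-9)
  flat <- cells
  flat$CD45 <- 0.5
  expect_error(build_feature_matrix(flat, normalization = "zscore"),
               "variance")
})

test_that("landmark selection is deterministic and covers blobs", {
  arcs <- fixture_archetypes()
  cells <- synth_cell_table(
    arcs, c("CD8 T cells" = 100, "B cells" = 100,
            "CD163+ myelomonocytic cells" = 100), noise_seed = 5)
  feats <- build_feature_matrix(cells)
  all_l <- select_landmarks(feats, nrow(cells))
  expect_equal(all_l, seq_len(nrow(cells)))
  l1 <- select_landmarks(feats, 30, seed = 9)
  l2 <- select_landmarks(feats, 30, seed = 9)
  expect_identical(l1, l2)
  # k-means landmarks hit every archetype blob
  picked <- cells$true_label[l1]
  expect_setequal(unique(picked), unique(cells$true_label))
  expect_error(select_landmarks(feats, nrow(cells) + 1), "between")
})

test_that("the l1 coder matches the support/sign enumeration oracle", {
  fx <- fixture_two_subspaces(per = 5, m = 6)
  feats <- build_feature_matrix(fx$cells, markers = fx$markers)
  lms <- seq_len(10)
  codes <- sparse_code(feats, lms, alpha = 0.1)
  D <- feats$X
  for (i in c(1, 3, 6, 9)) {
    oracle <- lasso_enum(D, feats$X[, i], codes$lambda[i],
                         max_support = 3, forbid = i)
    expect_equal(unname(codes$C[, i]), oracle, tolerance = 1e-4)
  }
})

test_that("the l1 coder agrees with glmnet on random instances", {
  skip_if_not_installed("glmnet")
  set.seed(31)
  m <- 8; L <- 20
  D <- matrix(rnorm(m * L), m)
  xs <- matrix(rnorm(m * 4), m)
  df <- as.data.frame(t(cbind(D, xs)))
  names(df) <- paste0("M", 1:m)
  df$cell_id <- seq_len(L + 4); df$roi_id <- "r"
  feats <- build_feature_matrix(tibble::as_tibble(df),
                                markers = paste0("M", 1:m))
  codes <- sparse_code(feats, seq_len(L), alpha = 0.2, tol = 1e-6)
  for (i in (L + 1):(L + 4)) {
    lam <- codes$lambda[i]
    g <- glmnet::glmnet(D, feats$X[, i], lambda = lam / m,
                        intercept = FALSE, standardize = FALSE,
                        thresh = 1e-14)
    expect_equal(unname(codes$C[, i]),
                 as.numeric(g$beta), tolerance = 1e-3)
  }
})

test_that("a landmark never codes against itself and copies recover e_j", {
  # unit-norm landmarks in general position; a cell equal to landmark j
  # with a small lambda must code as (almost) the j-th unit vector
  set.seed(17)
  m <- 6; L <- 8
  D <- matrix(rnorm(m * L), m)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  df <- as.data.frame(t(cbind(D, D[, 3])))
  names(df) <- paste0("M", 1:m)
  df$cell_id <- seq_len(L + 1); df$roi_id <- "r"
  feats <- build_feature_matrix(tibble::as_tibble(df),
                                markers = paste0("M", 1:m))
  codes <- sparse_code(feats, seq_len(L), alpha = 1e-4, tol = 1e-7)
  expect_equal(unname(diag(codes$C[, seq_len(L)])), rep(0, L))
  c_copy <- codes$C[, L + 1]
  expect_equal(unname(c_copy[3]), 1, tolerance = 1e-2)
  expect_lt(max(abs(c_copy[-3])), 1e-2)
})

test_that("codes are subspace-preserving on orthogonal subspaces", {
  fx <- fixture_two_subspaces(per = 10, m = 6)
  feats <- build_feature_matrix(fx$cells, markers = fx$markers)
  codes <- sparse_code(feats, seq_len(20), alpha = 0.05)
  for (i in seq_len(20)) {
    supp <- which(abs(codes$C[, i]) > 1e-8)
    expect_true(all(fx$truth[supp] == fx$truth[i]), info = paste("cell", i))
    # cross-check the support against the enumeration oracle
    oracle <- lasso_enum(feats$X[, seq_len(20)], feats$X[, i],
                         codes$lambda[i], max_support = 2, forbid = i)
    expect_setequal(supp, which(abs(oracle) > 1e-8))
  }
})

test_that("affinities are symmetric, non-negative, zero-diagonal", {
  fx <- fixture_three_subspaces(n = 120, seed = 19)
  feats <- build_feature_matrix(fx$cells)
  for (lms in list(seq_len(120), select_landmarks(feats, 40, seed = 2))) {
    codes <- sparse_code(feats, lms, alpha = 0.05)
    W <- mihcflow:::codes_to_affinity(codes)
    expect_equal(W, t(W))
    expect_true(all(W >= 0))
    expect_equal(unname(diag(W)), rep(0, ncol(W)))
  }
})

test_that("block-diagonal affinities split into their blocks", {
  fx <- fixture_two_subspaces(per = 10, m = 6)
  feats <- build_feature_matrix(fx$cells, markers = fx$markers)
  codes <- sparse_code(feats, seq_len(20), alpha = 0.05)
  labels <- cluster_from_codes(codes, 2, seed = 5)
  expect_equal(adjusted_rand(labels, fx$truth), 1)
})

test_that("planted three-subspace structure is recovered", {
  fx <- fixture_three_subspaces(n = 600, noise = 0.05, seed = 11)
  feats <- build_feature_matrix(fx$cells)
  lms <- select_landmarks(feats, 150, seed = 3)
  codes <- sparse_code(feats, lms, alpha = 0.05)
  labels <- cluster_from_codes(codes, 3, seed = 4)
  expect_gte(adjusted_rand(labels, fx$truth), 0.9)
})

test_that("cell order does not change the partition", {
  fx <- fixture_three_subspaces(n = 150, seed = 23)
  perm <- mihcflow:::with_seed(5, sample(150))
  run <- function(cells) {
    feats <- build_feature_matrix(cells)
    codes <- sparse_code(feats, seq_len(nrow(cells)), alpha = 0.05)
    cluster_from_codes(codes, 3, seed = 7)
  }
  l1 <- run(fx$cells)
  l2 <- run(fx$cells[perm, ])
  expect_equal(adjusted_rand(l1[perm], l2), 1)
})

test_that("the elbow rule finds planted k and declines null structure", {
  arcs <- fixture_archetypes()
  blobs <- synth_cell_table(
    arcs, c("CD8 T cells" = 100, "B cells" = 100,
            "CD163+ myelomonocytic cells" = 100), noise_seed = 5)
  fb <- build_feature_matrix(blobs)
  cb <- sparse_code(fb, select_landmarks(fb, 60, seed = 1), alpha = 0.05)
  expect_equal(as.integer(choose_k(cb, 1:8, seed = 1)), 3)
  null_cells <- synth_cell_table(arcs, c("Other Th cells" = 300),
                                 noise_seed = 6)
  fn <- build_feature_matrix(null_cells)
  cn <- sparse_code(fn, select_landmarks(fn, 60, seed = 1), alpha = 0.05)
  expect_equal(as.integer(choose_k(cn, 1:6, seed = 1)), 1)
  expect_equal(as.integer(choose_k(cn, 4)), 4)
  expect_error(choose_k(cn, integer(0)), "non-empty")
})

test_that("cluster profiles reduce to means and order deterministically", {
  arcs <- fixture_archetypes()
  cells <- synth_cell_table(arcs, c("CD8 T cells" = 40), noise_seed = 2)
  single <- cluster_profiles(rep(1L, 40), cells)
  expect_equal(single$CD45, mean(cells$CD45))
  expect_equal(single$n_cells, 40)
  dup <- cells[c(1, 1), ]
  prof <- cluster_profiles(c(1L, 1L), dup)
  expect_equal(prof$CD3, dup$CD3[1])
  expect_warning(cluster_profiles(c(1L, 3L), cells[1:2, ]), "empty")
})

test_that("recovered group profiles mirror their archetypes", {
  arcs <- fixture_archetypes()
  cells <- synth_cell_table(
    arcs, c("CD8 T cells" = 150, "B cells" = 150,
            "T regulatory cells" = 150,
            "CD163+ myelomonocytic cells" = 150), noise_seed = 8)
  fit <- ssc_phenotype(cells, k = 4, cd45_cutoff = NA,
                       n_landmarks = 120, seed = 3)
  prof <- fit$profiles
  # map each group to its dominant truth label, then check +/- ordering
  for (g in prof$group) {
    members <- cells$true_label[fit$labels == g]
    arch <- arcs[[names(which.max(table(members)))]]
    pos <- names(arch$marker_signs)[arch$marker_signs == "+"]
    neg <- setdiff(mihc_panel(), pos)
    row <- prof[prof$group == g, ]
    expect_gt(min(unlist(row[pos])), max(unlist(row[neg])))
  }
})

test_that("the wrapper is seed-deterministic end to end", {
  arcs <- fixture_archetypes()
  cells <- synth_cell_table(
    arcs, c("CD8 T cells" = 120, "B cells" = 120,
            "Epithelial cells" = 120), noise_seed = 4)
  f1 <- ssc_phenotype(cells, k = 2, seed = 6, n_landmarks = 80)
  f2 <- ssc_phenotype(cells, k = 2, seed = 6, n_landmarks = 80)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$codes$C, f2$codes$C)
  expect_equal(nrow(tidy(f1)), sum(cells$CD45 > 0.07))
  expect_equal(glance(f1)$k, 2)
})

test_that("adjusted_rand matches the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(12)
  for (i in 1:5) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand(1:5, c(2, 3, 4, 5, 6)), 1)
})
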