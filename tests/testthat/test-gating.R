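# Hierarchical gating engine, spatial gate, density/proportion summaries.

sign_cells <- function(sign_list, thr = 0.1) {
  # build a one-row cell table from named +/- signs (0.5 = positive,
  # 0.01 = negative at the default thresholds)
  row <- tibble::tibble(cell_id = 1L, roi_id = "r", x_um = 0, y_um = 0,
                        area_um2 = 25)
  for (m in mihc_panel()) {
    row[[m]] <- if (isTRUE(sign_list[[m]] == "+")) 0.5 else 0.01
  }
  row
}

test_that("canonical marker combinations map to their phenotypes", {
  tree <- default_gating_tree()
  treg <- sign_cells(list(CD45 = "+", CD3 = "+", CD8 = "-", FOXP3 = "+"))
  expect_equal(apply_gating_tree(treg, tree)$phenotype,
               "T regulatory cells")
  m163 <- sign_cells(list(CD45 = "+", CD3 = "-", CD20 = "-", CD1C = "-",
                          CD68 = "+", CSF1R = "+", CD163 = "+"))
  expect_equal(apply_gating_tree(m163, tree)$phenotype,
               "CD163+ myelomonocytic cells")
  neg <- sign_cells(list())
  expect_equal(apply_gating_tree(neg, tree)$phenotype, "Non-immune cells")
  # CD45 below threshold wins regardless of the other markers
  odd <- sign_cells(list(CD3 = "+", CD8 = "+", FOXP3 = "+", CD68 = "+"))
  expect_equal(apply_gating_tree(odd, tree)$phenotype, "Non-immune cells")
})

test_that("all 1024 sign vectors agree with the brute-force evaluator", {
  tree <- default_gating_tree()
  panel <- mihc_panel()
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(panel)))
  names(grid) <- panel
  cells <- tibble::tibble(cell_id = seq_len(nrow(grid)), roi_id = "r",
                          x_um = 0, y_um = 0, area_um2 = 25)
  for (m in panel) cells[[m]] <- ifelse(grid[[m]], 0.5, 0.01)
  fast <- apply_gating_tree(cells, tree)$phenotype
  slow <- vapply(seq_len(nrow(grid)), function(i) {
    gate_brute_force(as.list(grid[i, ]), tree$rules)
  }, character(1))
  expect_identical(fast, slow)
  # partition: exactly one label per cell, counts conserve the total
  expect_false(anyNA(fast))
  expect_equal(sum(table(fast)), nrow(grid))
})

test_that("raising a threshold never grows a +-requiring phenotype", {
  arcs <- fixture_archetypes()
  cells <- synth_cell_table(arcs, c("CD8 T cells" = 150,
                                    "T regulatory cells" = 150,
                                    "Epithelial cells" = 100),
                            noise_seed = 4)
  tree <- default_gating_tree()
  n_treg <- function(thr) {
    tr <- tree
    tr$thresholds[["FOXP3"]] <- thr
    sum(apply_gating_tree(cells, tr)$phenotype == "T regulatory cells")
  }
  counts <- vapply(c(0.05, 0.1, 0.2, 0.4), n_treg, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("unknown rule markers are rejected", {
  expect_error(
    gating_tree(list(list(label = "x", require = list(NOPE = "+")),
                     list(label = "rest", require = list())),
                thresholds = c(CD45 = 0.07)),
    "threshold")
  expect_error(
    gating_tree(list(list(label = "x", require = list(CD45 = "+"))),
                thresholds = c(CD45 = 0.07)),
    "catch-all")
})

test_that("biaxial pair counts come from explicit enumeration", {
  expect_equal(biaxial_pair_count(10), 45)
  expect_equal(biaxial_pair_count(2), 1)
  # independent enumeration for 5 markers
  pairs <- 0
  for (i in 1:5) for (j in 1:5) if (i < j) pairs <- pairs + 1
  expect_equal(biaxial_pair_count(5), pairs)
  expect_error(biaxial_pair_count(1), "at least 2")
})

test_that("the spatial gate keeps the epithelium and its margin", {
  region <- region_rect(0, 0, 100, 100)
  cells <- tibble::tibble(
    cell_id = 1:4, roi_id = "r",
    x_um = c(50, 250, 350, 120), y_um = c(50, 50, 50, 120),
    area_um2 = 25)
  # distances to the region: 0 (inside), 150, 250, ~28
  kept <- spatial_gate(cells, region, margin_um = 200)
  expect_setequal(kept$cell_id, c(1, 2, 4))
  kept0 <- spatial_gate(cells, region, margin_um = 0)
  expect_equal(kept0$cell_id, 1)
  # monotone in the margin
  k50 <- spatial_gate(cells, region, margin_um = 50)$cell_id
  k200 <- spatial_gate(cells, region, margin_um = 200)$cell_id
  expect_true(all(k50 %in% k200))
})

test_that("polygon and mask regions agree with the rectangle gate", {
  rect <- region_rect(10, 10, 60, 40)
  poly <- region_polygon(cbind(c(10, 60, 60, 10), c(10, 10, 40, 40)))
  m <- matrix(0, 100, 100)
  m[11:40, 11:60] <- 1 # rows = y, cols = x at 1 um resolution
  msk <- region_mask(m)
  cells <- tibble::tibble(cell_id = 1:5, roi_id = "r",
                          x_um = c(30, 70, 90, 30, 5),
                          y_um = c(20, 20, 90, 80, 25), area_um2 = 25)
  for (margin in c(0, 15)) {
    ids <- lapply(list(rect, poly, msk), function(rg) {
      spatial_gate(cells, rg, margin_um = margin)$cell_id
    })
    expect_equal(ids[[1]], ids[[2]])
    expect_equal(ids[[1]], ids[[3]])
  }
})

test_that("densities and proportions follow the planted counts", {
  tree <- default_gating_tree()
  cells <- tibble::tibble(
    cell_id = 1:100, roi_id = "r", x_um = 0, y_um = 0, area_um2 = 25,
    phenotype = c(rep("CD163+ myelomonocytic cells", 30),
                  rep("CD163- myelomonocytic cells", 30),
                  rep("CD8 T cells", 40)))
  s <- summarize_density_proportion(cells, roi_area_mm2 = 0.5, tree)
  row <- s[s$population == "CD8 T cells", ]
  expect_equal(row$count, 40)
  expect_equal(row$density, 80) # 40 cells / 0.5 mm^2
  prop <- s[s$population == "CD163+ myelomonocytic cells", ]
  expect_equal(prop$proportion, 0.5) # 30 of 60 myelomonocytic
  pan <- s[s$population == "Pan immune cells", ]
  expect_equal(pan$count, 100)
  expect_equal(pan$proportion, 1) # all cells immune here
  expect_error(summarize_density_proportion(cells, -1, tree), "positive")
})

test_that("zero denominators are flagged undefined, not zero", {
  tree <- default_gating_tree()
  cells <- tibble::tibble(cell_id = 1:5, roi_id = "r", x_um = 0, y_um = 0,
                          area_um2 = 25,
                          phenotype = rep("Non-immune cells", 5))
  s <- summarize_density_proportion(cells, 1, tree)
  row <- s[s$population == "CD163+ myelomonocytic cells", ]
  expect_false(row$proportion_defined)
  expect_true(is.na(row$proportion))
})

test_that("gated fixtures reproduce generator ground truth end to end", {
  arcs <- fixture_archetypes()
  counts <- c("CD8 T cells" = 60, "T regulatory cells" = 50,
              "B cells" = 40, "CD163+ myelomonocytic cells" = 30,
              "Epithelial cells" = 70)
  cells <- synth_cell_table(arcs, counts, noise_seed = 11)
  gated <- apply_gating_tree(cells)
  tab <- table(gated$true_label, gated$phenotype)
  # each archetype lands on its own phenotype (epithelial -> non-immune)
  expect_equal(unname(tab["CD8 T cells", "CD8 T cells"]), 60)
  expect_equal(unname(tab["T regulatory cells", "T regulatory cells"]), 50)
  expect_equal(unname(tab["Epithelial cells", "Non-immune cells"]), 70)
  s <- summarize_density_proportion(gated, 1)
  expect_equal(s$count[s$population == "B cells"], 40)
})
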