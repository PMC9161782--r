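# Synthetic single-cell tables and tissue layouts with full ground truth.
# These emulate the per-cell data model of a sequential mIHC experiment
# (cell id, ROI, centroid, nucleus area, 10 marker mean intensities) plus a
# true phenotype label per cell, so every downstream stage can be tested
# against a known answer.

#' Simulate a single-cell marker-intensity table
#'
#' Draws `counts[label]` cells per archetype. A marker's intensity is
#' `mean_high` (positive sign) or `mean_low` (negative sign) times a lognormal
#' factor `exp(N(0, dispersion))`, clipped to `[0, 1]`. Nucleus areas are
#' lognormal around 28 um^2. Coordinates are left `NA`; use
#' [synth_tissue_layout()] to place cells.
#'
#' @param archetypes List of [archetype()] objects with unique labels.
#' @param counts Named integer vector/list: cells per archetype label.
#' @param noise_seed Integer seed; a fixed seed reproduces the table exactly.
#' @param roi_id ROI identifier stored on every row.
#' @return A tibble with columns `cell_id`, `roi_id`, `x_um`, `y_um`,
#'   `area_um2`, one column per panel marker, and `true_label`.
#' @export
#' @examples
#' arcs <- default_archetypes()
#' cells <- synth_cell_table(arcs, c("CD8 T cells" = 5, "B cells" = 5),
#'                           noise_seed = 1)
#' dim(cells)
synth_cell_table <- function(archetypes, counts, noise_seed = 1,
                             roi_id = "ROI-1") {
  labels <- vapply(archetypes, function(a) a$label, character(1))
  if (anyDuplicated(labels)) abort("archetype labels must be unique")
  counts <- unlist(counts)
  if (length(counts) > 0 && any(counts < 0)) abort("negative cell count")
  unknown <- setdiff(names(counts), labels)
  if (length(unknown) > 0) {
    abort(paste0("counts refer to unknown archetype(s): ",
                 paste(unknown, collapse = ", ")))
  }
  panel <- if (length(archetypes) > 0) archetypes[[1]]$panel else mihc_panel()

  empty <- tibble(
    cell_id = integer(0), roi_id = character(0),
    x_um = numeric(0), y_um = numeric(0), area_um2 = numeric(0)
  )
  for (m in panel) empty[[m]] <- numeric(0)
  empty$true_label <- character(0)
  counts <- counts[counts > 0]
  if (length(counts) == 0) return(empty)

  with_seed(noise_seed, {
    rows <- lapply(names(counts), function(lab) {
      a <- archetypes[[match(lab, labels)]]
      n <- as.integer(counts[[lab]])
      mu <- ifelse(a$marker_signs == "+", a$mean_high, a$mean_low)
      intens <- vapply(seq_along(panel), function(j) {
        pmin(1, pmax(0, mu[j] * rlnorm(n, meanlog = 0, sdlog = a$dispersion)))
      }, numeric(n))
      intens <- matrix(intens, nrow = n,
                       dimnames = list(NULL, panel))
      out <- tibble(
        cell_id = NA_integer_, roi_id = roi_id,
        x_um = NA_real_, y_um = NA_real_,
        area_um2 = rlnorm(n, meanlog = log(28), sdlog = 0.2)
      )
      out <- dplyr::bind_cols(out, as_tibble(intens))
      out$true_label <- lab
      out
    })
    out <- bind_rows(rows)
    out$cell_id <- seq_len(nrow(out))
    out
  })
}

#' Assign spatial coordinates to simulated cells
#'
#' Places the cells of a table inside a rectangular ROI according to a layout:
#' \describe{
#'   \item{`random`}{uniform over the ROI (complete spatial randomness).}
#'   \item{`clustered`}{per-label Gaussian clumps around random centres.}
#'   \item{`two_block`}{the first truth label in the left half, all others in
#'     the right half — a maximally segregated arrangement.}
#'   \item{`epithelium_margin`}{labels in `epithelium_labels` inside the
#'     epithelial region (left `epithelium_frac` of the ROI), the rest
#'     outside it.}
#' }
#'
#' @param table A cell table from [synth_cell_table()].
#' @param layout One of `"random"`, `"clustered"`, `"two_block"`,
#'   `"epithelium_margin"`.
#' @param roi_size `c(width_um, height_um)` of the ROI, both positive.
#' @param seed Integer seed for placement.
#' @param stage Disease-stage label attached to the scene.
#' @param cluster_sd Gaussian clump scale (um) for the clustered layout.
#' @param n_clumps_per_label Clumps per label for the clustered layout.
#' @param epithelium_frac Fraction of ROI width occupied by the epithelial
#'   region (a left-anchored rectangle).
#' @param epithelium_labels Truth labels placed inside the epithelium for the
#'   `epithelium_margin` layout; default the first label.
#' @param min_spacing Minimum centre-to-centre distance (um) enforced by
#'   rejection sampling in the `random` layout; useful when the scene will be
#'   rendered and nuclei should not overlap. 0 disables.
#' @return A `mihc_scene`: list with `roi_id`, `stage`, `cells` (tibble with
#'   filled `x_um`, `y_um`), `layout`, `roi_size`, and `epithelium` (a
#'   rectangle region, see [region_rect()]).
#' @export
synth_tissue_layout <- function(table, layout = c("random", "clustered",
                                                  "two_block",
                                                  "epithelium_margin"),
                                roi_size = c(500, 500), seed = 1,
                                stage = "NSQ", cluster_sd = 25,
                                n_clumps_per_label = 1,
                                epithelium_frac = 0.4,
                                epithelium_labels = NULL,
                                min_spacing = 0) {
  layout <- match.arg(layout)
  if (length(roi_size) != 2 || any(roi_size <= 0)) {
    abort("roi_size must be two positive lengths (um)")
  }
  w <- roi_size[1]; h <- roi_size[2]
  n <- nrow(table)
  labs <- table$true_label
  epi <- region_rect(0, 0, epithelium_frac * w, h)

  cells <- with_seed(seed, {
    x <- numeric(n); y <- numeric(n)
    if (layout == "random") {
      if (min_spacing > 0) {
        placed <- 0
        while (placed < n) {
          cand_x <- runif(1, 0, w); cand_y <- runif(1, 0, h)
          tries <- 0
          repeat {
            if (placed == 0 ||
                min((x[seq_len(placed)] - cand_x)^2 +
                    (y[seq_len(placed)] - cand_y)^2) >= min_spacing^2 ||
                tries >= 200) break
            cand_x <- runif(1, 0, w); cand_y <- runif(1, 0, h)
            tries <- tries + 1
          }
          placed <- placed + 1
          x[placed] <- cand_x; y[placed] <- cand_y
        }
      } else {
        x <- runif(n, 0, w); y <- runif(n, 0, h)
      }
    } else if (layout == "clustered") {
      for (lab in unique(labs)) {
        idx <- which(labs == lab)
        cx <- runif(n_clumps_per_label, 0.15 * w, 0.85 * w)
        cy <- runif(n_clumps_per_label, 0.15 * h, 0.85 * h)
        pick <- sample.int(n_clumps_per_label, length(idx), replace = TRUE)
        x[idx] <- cx[pick] + rnorm(length(idx), 0, cluster_sd)
        y[idx] <- cy[pick] + rnorm(length(idx), 0, cluster_sd)
      }
      x <- pmin(pmax(x, 0), w); y <- pmin(pmax(y, 0), h)
    } else if (layout == "two_block") {
      first <- labs == labs[1]
      x[first] <- runif(sum(first), 0, w / 2 * 0.95)
      x[!first] <- runif(sum(!first), w / 2 * 1.05, w)
      y <- runif(n, 0, h)
    } else { # epithelium_margin
      inside <- if (is.null(epithelium_labels)) labs == labs[1] else
        labs %in% epithelium_labels
      x[inside] <- runif(sum(inside), 0, epithelium_frac * w)
      x[!inside] <- runif(sum(!inside), epithelium_frac * w, w)
      y <- runif(n, 0, h)
    }
    out <- table
    out$x_um <- x; out$y_um <- y
    out
  })

  structure(
    list(roi_id = table$roi_id[1] %||% "ROI-1", stage = stage, cells = cells,
         layout = layout, roi_size = roi_size, epithelium = epi),
    class = "mihc_scene"
  )
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' @export
print.mihc_scene <- function(x, ...) {
  cat("<mihc_scene> ", x$roi_id, " (", x$stage, "): ", nrow(x$cells),
      " cells, ", x$layout, " layout, ",
      x$roi_size[1], "x", x$roi_size[2], " um\n", sep = "")
  invisible(x)
}

#' Simulate a staged multi-ROI cohort
#'
#' Builds one scene per requested ROI with stage-dependent phenotype mixing
#' that emulates the progression signal of a Barrett's-to-adenocarcinoma
#' cohort: regulatory T cells and the CD163+ myelomonocytic subset rise with
#' stage while CD8 T-cell share falls, on top of a stage-increasing total
#' immune density.
#'
#' @param n_roi_per_stage Named vector: ROIs per stage (defaults mirror a
#'   40-ROI cohort split 6/9/12/13 across NSQ/NDBE/Dys/EAC).
#' @param cells_per_roi Approximate cells per ROI.
#' @param seed Integer seed.
#' @param layout Layout passed to [synth_tissue_layout()].
#' @param roi_size ROI size in um.
#' @param archetypes Archetype list; defaults to [default_archetypes()].
#' @return List of `mihc_scene` objects; `roi_stage(scenes)` gives the
#'   roi-to-stage map.
#' @export
synth_cohort <- function(n_roi_per_stage = c(NSQ = 6, NDBE = 9, Dys = 12,
                                             EAC = 13),
                         cells_per_roi = 400, seed = 1,
                         layout = "clustered", roi_size = c(500, 500),
                         archetypes = default_archetypes()) {
  # stage-level mixing weights (relative); Treg and CD163+ rise, CD8 falls
  base <- c(
    "CD8 T cells" = 5, "Proliferating CD8 T cells" = 1,
    "T regulatory cells" = 1, "Other Th cells" = 4, "B cells" = 3,
    "CD163+ myelomonocytic cells" = 1, "CD163- myelomonocytic cells" = 4,
    "Monocytes macrophages fibrocytes" = 2,
    "CD1C+ myeloid dendritic cells" = 1, "Epithelial cells" = 20
  )
  shift <- list(
    NSQ  = c("T regulatory cells" = 1.0, "CD163+ myelomonocytic cells" = 1.0,
             "CD8 T cells" = 1.0, "Epithelial cells" = 1.3),
    NDBE = c("T regulatory cells" = 2.5, "CD163+ myelomonocytic cells" = 1.5,
             "CD8 T cells" = 0.9, "Epithelial cells" = 1.0),
    Dys  = c("T regulatory cells" = 2.5, "CD163+ myelomonocytic cells" = 4.0,
             "CD8 T cells" = 0.7, "Epithelial cells" = 0.8),
    EAC  = c("T regulatory cells" = 4.5, "CD163+ myelomonocytic cells" = 4.0,
             "CD8 T cells" = 0.5, "Epithelial cells" = 0.7)
  )
  scenes <- list()
  i <- 0
  for (stg in names(n_roi_per_stage)) {
    wts <- base
    adj <- shift[[stg]]
    wts[names(adj)] <- wts[names(adj)] * adj
    probs <- wts / sum(wts)
    for (r in seq_len(n_roi_per_stage[[stg]])) {
      i <- i + 1
      roi_seed <- seed * 1000L + i
      counts <- with_seed(roi_seed, {
        tabulate(sample.int(length(probs), cells_per_roi, replace = TRUE,
                            prob = probs), length(probs))
      })
      names(counts) <- names(probs)
      tab <- synth_cell_table(archetypes, counts, noise_seed = roi_seed + 1,
                              roi_id = sprintf("%s-%02d", stg, r))
      scenes[[i]] <- synth_tissue_layout(tab, layout, roi_size,
                                         seed = roi_seed + 2, stage = stg)
    }
  }
  scenes
}

#' Stage map of a scene list
#'
#' @param scenes List of `mihc_scene` objects.
#' @return Tibble with columns `roi_id`, `stage`.
#' @export
roi_stage <- function(scenes) {
  tibble(
    roi_id = vapply(scenes, function(s) s$roi_id, character(1)),
    stage = vapply(scenes, function(s) s$stage, character(1))
  )
}

#' Pool the cell tables of several scenes
#'
#' @param scenes List of `mihc_scene` objects.
#' @return One tibble with globally unique `cell_id`.
#' @export
scene_cells <- function(scenes) {
  out <- bind_rows(lapply(scenes, function(s) s$cells))
  out$cell_id <- seq_len(nrow(out))
  out
}
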