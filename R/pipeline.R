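# End-to-end pipeline driver: simulate -> render -> register -> segment ->
# quantify -> gate -> cluster -> spatial -> report, writing tidy CSVs at
# each boundary. Deterministic given the seed.

#' Run the full mIHC pipeline on synthetic tissue
#'
#' Simulates a staged cohort, renders the per-round brightfield images with
#' per-round misalignments, co-registers and quantifies them, gates the
#' resulting cell tables, clusters the immune cells by sparse subspace
#' clustering, computes neighbourhood enrichment per ROI, compares stages,
#' and writes the report bundle. Every stage is seeded from `seed`, so a
#' repeated run writes byte-identical CSVs.
#'
#' @param out_dir Output directory.
#' @param seed Master integer seed.
#' @param n_roi_per_stage Named vector: ROIs per stage.
#' @param cells_per_roi Cells per simulated ROI.
#' @param roi_size_um ROI edge lengths (um).
#' @param pixel_size_um Pixel size of the rendered images.
#' @param max_shift_px,max_angle_deg,max_log_scale Per-round misalignment
#'   ranges for the simulated acquisition.
#' @param k Number of SSC groups.
#' @param knn Neighbour count of the spatial graph.
#' @param n_perm Permutations of the enrichment test.
#' @param write_images Also write the round TIFFs (slower, larger).
#' @return Invisibly, a list with the main intermediate objects and the
#'   paths written.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         n_roi_per_stage = c(NSQ = 1, NDBE = 1, Dys = 1,
                                             EAC = 1),
                         cells_per_roi = 60, roi_size_um = c(60, 60),
                         pixel_size_um = 0.22,
                         max_shift_px = 8, max_angle_deg = 2,
                         max_log_scale = 0.01,
                         k = 6, knn = 10, n_perm = 200,
                         write_images = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- mihc_panel()
  arcs <- default_archetypes()

  scenes <- synth_cohort(n_roi_per_stage = n_roi_per_stage,
                         cells_per_roi = cells_per_roi, seed = seed,
                         layout = "random", roi_size = roi_size_um,
                         archetypes = arcs)
  # re-place with spacing so rendered nuclei stay separable
  scenes <- lapply(seq_along(scenes), function(i) {
    s <- scenes[[i]]
    synth_tissue_layout(s$cells, "random", s$roi_size,
                        seed = seed * 7919L + i, stage = s$stage,
                        min_spacing = 7)
  })
  stages_map <- roi_stage(scenes)
  roi_area_mm2 <- prod(roi_size_um) / 1e6

  cell_tabs <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    tfs <- with_seed(seed * 104729L + i, {
      c(list(similarity_transform()),
        lapply(seq_along(panel), function(j) {
          similarity_transform(
            exp(runif(1, -max_log_scale, max_log_scale)),
            runif(1, -max_angle_deg, max_angle_deg) * pi / 180,
            runif(1, -max_shift_px, max_shift_px),
            runif(1, -max_shift_px, max_shift_px))
        }))
    })
    rendered <- render_round_images(sc, panel, pixel_size_um,
                                    round_transforms = tfs,
                                    seed = seed * 31L + i)
    if (write_images) {
      write_round_images(rendered$rounds,
                         file.path(out_dir, "images", sc$roi_id))
    }
    stack <- register_stack(rendered$rounds, reference_round = 0,
                            seed = seed)
    mask <- segment_nuclei(stack$nuclear, pixel_size_um)
    cell_tabs[[i]] <- quantify_cells(mask, stack)
  }
  cells <- bind_rows(cell_tabs)
  cells$cell_id <- seq_len(nrow(cells))
  write_cell_table(cells, file.path(out_dir, "cells.csv"))

  tree <- default_gating_tree()
  gated <- apply_gating_tree(cells, tree)
  write_cell_table(gated, file.path(out_dir, "cells_gated.csv"))

  roi_info <- stages_map
  roi_info$area_mm2 <- roi_area_mm2
  summaries <- summarize_cohort(gated, roi_info, tree)

  fit <- ssc_phenotype(gated, k = k, seed = seed,
                       n_landmarks = min(500, nrow(gated)))
  readr::write_csv(tidy(fit), file.path(out_dir, "ssc_groups.csv"),
                   progress = FALSE)

  clustered <- fit$cells
  clustered$ssc_group <- paste0("G", clustered$group)
  enr <- list()
  for (i in seq_len(nrow(stages_map))) {
    sub <- clustered[clustered$roi_id == stages_map$roi_id[i], ,
                     drop = FALSE]
    if (nrow(sub) < knn + 1) next
    g <- spatial_graph(sub, k = knn)
    enr[[length(enr) + 1]] <- neighborhood_enrichment(
      g, sub$ssc_group, n_perm = n_perm, seed = seed + i)
  }
  enr_all <- bind_rows(enr)
  enr_stage <- if (nrow(enr_all) > 0) {
    aggregate_enrichment(enr_all, stages_map)
  } else NULL

  comparisons <- compare_stages(summaries)
  files <- render_report(summaries, comparisons, enr_stage, fit$profiles,
                         out_dir = file.path(out_dir, "report"),
                         figures = FALSE)
  if (nrow(enr_all) > 0) {
    readr::write_csv(enr_all, file.path(out_dir, "enrichment_roi.csv"),
                     progress = FALSE)
  }
  invisible(list(cells = cells, gated = gated, summaries = summaries,
                 fit = fit, enrichment = enr_all, stage_map = stages_map,
                 files = c(file.path(out_dir, "cells.csv"),
                           file.path(out_dir, "cells_gated.csv"),
                           file.path(out_dir, "ssc_groups.csv"),
                           files)))
}
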