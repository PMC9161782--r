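# Config-driven hierarchical gating: per-marker positivity thresholds turn
# intensities into sign vectors, an ordered rule list maps sign combinations
# to phenotype labels (first full match wins), and aggregate populations are
# unions of leaf phenotypes. This replaces interactive biaxial-plot gating
# with a deterministic engine.

#' Build a gating tree
#'
#' @param rules List of rules, each `list(label =, require = named list of
#'   "+"/"-" marker signs)`, evaluated in order; a rule with an empty
#'   `require` matches everything, and the final rule must be such a
#'   catch-all so every cell receives exactly one label.
#' @param thresholds Named numeric vector of per-marker positivity
#'   thresholds on the unit intensity scale (strict `>` is positive).
#' @param populations Optional list of aggregate populations:
#'   `list(name =, members = leaf labels, denominator = population name)`.
#' @return An object of class `mihc_gating_tree`.
#' @export
gating_tree <- function(rules, thresholds, populations = list()) {
  if (length(rules) == 0) abort("at least one rule required")
  thresholds <- unlist(thresholds)
  rule_markers <- unique(unlist(lapply(rules, function(r) names(r$require))))
  missing_thr <- setdiff(rule_markers, names(thresholds))
  if (length(missing_thr) > 0) {
    abort(paste0("no threshold for marker(s): ",
                 paste(missing_thr, collapse = ", ")))
  }
  last <- rules[[length(rules)]]
  if (length(last$require) != 0) {
    abort("the final rule must be a catch-all (empty `require`)")
  }
  for (r in rules) {
    if (is.null(r$label)) abort("every rule needs a label")
    bad <- setdiff(unlist(r$require), c("+", "-"))
    if (length(bad) > 0) abort("rule signs must be \"+\" or \"-\"")
  }
  structure(list(rules = rules, thresholds = thresholds,
                 populations = populations),
            class = "mihc_gating_tree")
}

#' Load a gating tree from YAML
#'
#' @param path YAML file with `thresholds`, ordered `rules` and optional
#'   `populations`; `default_gating_tree()` loads the configuration shipped
#'   with the package (a 10-marker immune panel tree).
#' @return A `mihc_gating_tree`.
#' @export
read_gating_tree <- function(path) {
  cfg <- yaml::read_yaml(path)
  rules <- lapply(cfg$rules, function(r) {
    list(label = r$label, require = as.list(unlist(r$require)))
  })
  gating_tree(rules, cfg$thresholds, cfg$populations %||% list())
}

#' @rdname read_gating_tree
#' @export
default_gating_tree <- function() {
  read_gating_tree(system.file("extdata", "gates.yaml",
                               package = "mihcflow", mustWork = TRUE))
}

#' @export
print.mihc_gating_tree <- function(x, ...) {
  cat("<mihc_gating_tree> ", length(x$rules), " rules, ",
      length(x$thresholds), " marker thresholds, ",
      length(x$populations), " aggregate populations\n", sep = "")
  for (r in x$rules) {
    sig <- if (length(r$require) == 0) "(catch-all)" else
      paste0(names(r$require), unlist(r$require), collapse = "")
    cat("  ", sig, " -> ", r$label, "\n", sep = "")
  }
  invisible(x)
}

#' Assign a phenotype to every cell by hierarchical gating
#'
#' Marker signs are `intensity > threshold`; rules are evaluated in the tree
#' order and the first rule whose sign conjunction is satisfied labels the
#' cell. The catch-all final rule guarantees a full partition.
#'
#' @param cells Cell table with one column per marker used by the tree.
#' @param tree A [gating_tree()] (default: the shipped configuration).
#' @return `cells` with a `phenotype` character column appended.
#' @export
#' @examples
#' cells <- synth_cell_table(default_archetypes(),
#'                           c("CD8 T cells" = 10), noise_seed = 1)
#' table(apply_gating_tree(cells)$phenotype)
apply_gating_tree <- function(cells, tree = default_gating_tree()) {
  markers <- unique(unlist(lapply(tree$rules,
                                  function(r) names(r$require))))
  missing <- setdiff(markers, names(cells))
  if (length(missing) > 0) {
    abort(paste0("cell table lacks marker column(s) used by the tree: ",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(cells)
  signs <- matrix(FALSE, n, length(markers),
                  dimnames = list(NULL, markers))
  for (m in markers) {
    signs[, m] <- cells[[m]] > tree$thresholds[[m]]
  }
  label <- rep(NA_character_, n)
  unassigned <- rep(TRUE, n)
  for (r in tree$rules) {
    if (!any(unassigned)) break
    match_r <- unassigned
    for (m in names(r$require)) {
      want <- r$require[[m]] == "+"
      match_r <- match_r & (signs[, m] == want)
    }
    label[match_r] <- r$label
    unassigned <- unassigned & !match_r
  }
  out <- cells
  out$phenotype <- label
  out
}

#' Number of biaxial plots needed for a marker panel
#'
#' Manual image cytometry inspects every unordered marker pair on a biaxial
#' plot; this counts those pairs by explicit enumeration.
#'
#' @param panel_size Number of markers (>= 2).
#' @return Integer pair count (e.g. 45 for a 10-marker panel).
#' @export
#' @examples
#' biaxial_pair_count(10)
biaxial_pair_count <- function(panel_size) {
  if (panel_size < 2) abort("panel_size must be at least 2")
  nrow(t(combn(seq_len(as.integer(panel_size)), 2)))
}

#' Spatial gate: epithelium plus stromal margin
#'
#' Keeps cells whose centroid lies inside the epithelial region or within
#' `margin_um` (Euclidean distance) of its boundary — the "epithelium +
#' adjacent stromal margin" gate used to focus on tissue-infiltrating immune
#' cells. Distance is computed on a rasterized region at `resolution_um`.
#'
#' @param cells Cell table with `x_um`, `y_um`.
#' @param region A [region_rect()], [region_polygon()] or [region_mask()] in
#'   the same um frame as the cells.
#' @param margin_um Stromal margin width (default 200 um).
#' @param resolution_um Rasterization resolution for the distance transform.
#' @return The filtered cell table (rows preserved in order).
#' @export
spatial_gate <- function(cells, region, margin_um = 200,
                         resolution_um = 1) {
  check_cell_table(cells, coords = TRUE)
  if (margin_um < 0) abort("margin_um must be non-negative")
  if (nrow(cells) == 0) return(cells)
  if (margin_um == 0) {
    keep <- region_contains(region, cells$x_um, cells$y_um)
  } else {
    d <- region_distance(region, cells$x_um, cells$y_um,
                         resolution_um = resolution_um)
    keep <- d <= margin_um
  }
  cells[keep, , drop = FALSE]
}

#' Density and proportion summaries per ROI and population
#'
#' Counts leaf phenotypes and the configured aggregate populations, converts
#' counts to densities (cells per mm^2 of ROI area) and computes each
#' population's proportion within its configured denominator population
#' (`NA` and flagged when the denominator count is zero).
#'
#' @param cells Gated cell table (needs `phenotype`; one ROI).
#' @param roi_area_mm2 ROI area in mm^2 (> 0).
#' @param tree The gating tree whose `populations` define aggregates and
#'   denominators.
#' @param stage Optional disease-stage label attached to every row.
#' @return Tibble: `roi_id`, `stage`, `population`, `count`, `density`
#'   (cells/mm^2), `denominator`, `proportion`, `proportion_defined`.
#' @export
summarize_density_proportion <- function(cells, roi_area_mm2,
                                         tree = default_gating_tree(),
                                         stage = NA_character_) {
  if (roi_area_mm2 <= 0) abort("roi_area_mm2 must be positive")
  if (!"phenotype" %in% names(cells)) {
    abort("cells must be gated first (no `phenotype` column)")
  }
  roi <- if (nrow(cells) > 0) cells$roi_id[1] else NA_character_
  leaf_counts <- table(cells$phenotype)
  count_of <- function(members) {
    sum(leaf_counts[intersect(members, names(leaf_counts))])
  }
  leaf_labels <- vapply(tree$rules, function(r) r$label, character(1))
  pops <- list()
  for (lab in unique(leaf_labels)) {
    pops[[lab]] <- list(name = lab, members = lab, denominator = NA)
  }
  for (p in tree$populations) {
    pops[[p$name]] <- list(name = p$name, members = unlist(p$members),
                           denominator = p$denominator %||% NA)
  }
  counts <- vapply(pops, function(p) count_of(p$members), numeric(1))
  total <- nrow(cells)
  denom_count <- function(dn) {
    if (is.na(dn)) return(NA_real_)
    if (identical(dn, "Total cells")) return(total)
    if (!dn %in% names(pops)) return(NA_real_)
    count_of(pops[[dn]]$members)
  }
  dns <- vapply(pops, function(p) as.character(p$denominator), character(1))
  dcounts <- vapply(dns, denom_count, numeric(1))
  tibble(
    roi_id = roi, stage = stage,
    population = names(pops),
    count = as.numeric(counts),
    density = as.numeric(counts) / roi_area_mm2,
    denominator = unname(dns),
    proportion = as.numeric(ifelse(!is.na(dcounts) & dcounts > 0,
                                   counts / dcounts, NA_real_)),
    proportion_defined = unname(!is.na(dcounts) & dcounts > 0)
  )
}

#' Summarize a whole cohort of gated scenes
#'
#' @param cells Gated cell table covering several ROIs.
#' @param roi_info Tibble with `roi_id`, `stage`, `area_mm2`.
#' @inheritParams summarize_density_proportion
#' @return Row-bound per-ROI summaries (see
#'   [summarize_density_proportion()]).
#' @export
summarize_cohort <- function(cells, roi_info,
                             tree = default_gating_tree()) {
  stopifnot(all(c("roi_id", "stage", "area_mm2") %in% names(roi_info)))
  bind_rows(lapply(seq_len(nrow(roi_info)), function(i) {
    sub <- cells[cells$roi_id == roi_info$roi_id[i], , drop = FALSE]
    summarize_density_proportion(sub, roi_info$area_mm2[i], tree,
                                 stage = roi_info$stage[i])
  }))
}
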