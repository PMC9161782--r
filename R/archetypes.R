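#' Define a phenotype archetype
#'
#' An archetype fixes, for one simulated cell phenotype, which panel markers
#' are positive and the intensity distribution cells of that phenotype draw
#' from. Positive markers are sampled around `mean_high`, negative markers
#' around `mean_low`, both with multiplicative lognormal noise of scale
#' `dispersion` and clipped to the unit intensity scale.
#'
#' @param label Phenotype name (unique within a set of archetypes).
#' @param positive Character vector of positive markers; all other panel
#'   markers are negative.
#' @param mean_high Mean intensity of positive markers, in `[0, 1]`.
#' @param mean_low Background mean of negative markers, in `[0, 1]`;
#'   must be below `mean_high`.
#' @param dispersion Lognormal sdlog of the multiplicative intensity noise.
#' @param panel Marker panel the signs refer to.
#' @return An object of class `mihc_archetype`.
#' @export
#' @examples
#' archetype("T regulatory cells", c("CD45", "CD3", "FOXP3"))
archetype <- function(label, positive,
                      mean_high = 0.45, mean_low = 0.02,
                      dispersion = 0.35, panel = mihc_panel()) {
  stopifnot(is.character(label), length(label) == 1)
  unknown <- setdiff(positive, panel)
  if (length(unknown) > 0) {
    abort(paste0("archetype '", label, "' uses marker(s) not in the panel: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!(mean_high > mean_low && mean_low >= 0)) {
    abort("need mean_high > mean_low >= 0")
  }
  signs <- ifelse(panel %in% positive, "+", "-")
  names(signs) <- panel
  structure(
    list(label = label, marker_signs = signs, mean_high = mean_high,
         mean_low = mean_low, dispersion = dispersion, panel = panel),
    class = "mihc_archetype"
  )
}

#' @export
print.mihc_archetype <- function(x, ...) {
  pos <- names(x$marker_signs)[x$marker_signs == "+"]
  cat("<mihc_archetype> ", x$label, ": ",
      if (length(pos)) paste0(pos, "+", collapse = "") else "(all negative)",
      "  high=", x$mean_high, " low=", x$mean_low,
      " disp=", x$dispersion, "\n", sep = "")
  invisible(x)
}

#' Default archetype set mirroring the hierarchical gating phenotypes
#'
#' One archetype per leaf phenotype of the default gating tree (regulatory
#' T cells, CD8 T cells, B cells, the CD163+/- myelomonocytic subsets, the
#' CD1C+ dendritic subset, ...) plus a marker-negative epithelial archetype,
#' so simulated tissue exercises the full gating tree and the clustering
#' concordance checks.
#'
#' @inheritParams archetype
#' @return Named list of `mihc_archetype` objects.
#' @export
default_archetypes <- function(mean_high = 0.45, mean_low = 0.02,
                               dispersion = 0.35, panel = mihc_panel()) {
  mk <- function(label, positive) {
    archetype(label, positive, mean_high, mean_low, dispersion, panel)
  }
  sets <- list(
    "CD8 T cells"                    = c("CD45", "CD3", "CD8"),
    "Proliferating CD8 T cells"      = c("CD45", "CD3", "CD8", "KI67"),
    "T regulatory cells"             = c("CD45", "CD3", "FOXP3"),
    "Other Th cells"                 = c("CD45", "CD3"),
    "B cells"                        = c("CD45", "CD20"),
    "CD163+ myelomonocytic cells"    = c("CD45", "CD68", "CSF1R", "CD163"),
    "CD163- myelomonocytic cells"    = c("CD45", "CD68", "CSF1R"),
    "Monocytes macrophages fibrocytes" = c("CD45", "CD68"),
    "CD1C+ myeloid dendritic cells"  = c("CD45", "CD1C"),
    "Epithelial cells"               = character(0)
  )
  out <- lapply(names(sets), function(nm) mk(nm, sets[[nm]]))
  names(out) <- names(sets)
  out
}
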