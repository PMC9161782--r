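# Chromogen quantification: optical-density stain separation of AEC and
# hematoxylin from brightfield RGB, watershed nuclear segmentation on the
# hematoxylin channel, and per-cell marker quantification.

#' Deconvolve AEC and hematoxylin from a brightfield RGB raster
#'
#' Converts RGB to optical density `OD = -log((rgb + eps) / background)` and
#' projects each pixel onto the two-stain basis by least squares. Negative
#' projections are clipped to zero and the result is rescaled to `[0, 1]` by
#' a fixed reference optical density `od_ref`.
#'
#' @param rgb `H x W x 3` array in `[0, background]`.
#' @param stains Basis from [stain_vectors()].
#' @param od_ref Optical density mapped to intensity 1; values above are
#'   clipped. Fixed, so intensities are comparable across ROIs.
#' @param eps Log-guard added to the RGB values.
#' @return List with matrices `aec` and `hematoxylin` in `[0, 1]`.
#' @export
#' @examples
#' px <- array(1, c(1, 1, 3)) # pure white
#' deconvolve_stains(px)$aec
deconvolve_stains <- function(rgb, stains = stain_vectors(), od_ref = 2,
                              eps = 1e-6) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  if (stains$background <= 0) abort("background level must be positive")
  V <- cbind(stains$aec, stains$hematoxylin)
  G <- crossprod(V)
  if (abs(det(G)) < 1e-10) abort("singular stain basis")
  proj <- solve(G, t(V)) # 2 x 3 least-squares projector
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  od <- -log((pmax(rgb, 0) + eps) / stains$background)
  flat <- matrix(od, H * W, 3)
  conc <- flat %*% t(proj)
  conc[conc < 0] <- 0
  conc <- pmin(conc / od_ref, 1)
  list(aec = matrix(conc[, 1], H, W),
       hematoxylin = matrix(conc[, 2], H, W))
}

#' Segment nuclei by watershed on the hematoxylin channel
#'
#' Thresholds the nuclear raster (Otsu by default), splits touching nuclei by
#' watershed on the distance transform, and drops components smaller than
#' `min_area_um2`. Labels are renumbered to consecutive positive integers in
#' deterministic (raster scan of component minima) order.
#'
#' @param nuclear Non-negative matrix (hematoxylin intensity).
#' @param pixel_size_um Physical pixel size.
#' @param min_area_um2 Minimum nucleus area kept.
#' @param threshold Foreground threshold; `NULL` uses Otsu's method.
#' @param tolerance,ext Watershed parameters (see [EBImage::watershed()]).
#' @return Integer label matrix (`0` = background) of class `mihc_mask`.
#' @export
segment_nuclei <- function(nuclear, pixel_size_um = 0.22, min_area_um2 = 8,
                           threshold = NULL, tolerance = 1, ext = 1) {
  if (any(nuclear < 0)) abort("nuclear raster must be non-negative")
  if (all(nuclear == 0)) {
    return(structure(matrix(0L, nrow(nuclear), ncol(nuclear)),
                     class = "mihc_mask"))
  }
  if (is.null(threshold)) {
    rng <- range(nuclear)
    if (diff(rng) < 1e-12) {
      return(structure(matrix(0L, nrow(nuclear), ncol(nuclear)),
                       class = "mihc_mask"))
    }
    threshold <- EBImage::otsu(EBImage::Image((nuclear - rng[1]) /
                                                diff(rng))) *
      diff(rng) + rng[1]
  }
  fg <- nuclear > threshold
  if (!any(fg)) {
    return(structure(matrix(0L, nrow(nuclear), ncol(nuclear)),
                     class = "mihc_mask"))
  }
  dm <- EBImage::distmap(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  labels <- EBImage::watershed(dm, tolerance = tolerance, ext = ext)
  labels <- matrix(as.integer(labels), nrow(fg), ncol(fg))

  # area filter in um^2
  min_px <- max(1L, floor(min_area_um2 / pixel_size_um^2))
  cnt <- tabulate(labels[labels > 0])
  drop <- which(cnt < min_px)
  if (length(drop) > 0) labels[labels %in% drop] <- 0L

  # deterministic relabelling: order components by first (column-major) pixel
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (length(ids) > 0) {
    first_px <- vapply(ids, function(i) which(labels == i)[1], numeric(1))
    remap <- integer(max(ids))
    remap[ids[order(first_px)]] <- seq_along(ids)
    pos <- labels > 0
    labels[pos] <- remap[labels[pos]]
  }
  structure(labels, class = "mihc_mask")
}

#' Quantify single cells over a registered stack
#'
#' Per segmented nucleus: centroid (unweighted pixel mean, converted to um),
#' area (pixel count times the pixel area), and the arithmetic mean of each
#' deconvolved marker raster over the nucleus pixels. An optional dilation
#' radius grows the measurement support beyond the nucleus for membrane
#' markers (default 0 - nucleus pixels only).
#'
#' @param mask Label matrix from [segment_nuclei()] (or ground truth).
#' @param stack A `mihc_stack`, or a named list of marker matrices.
#' @param pixel_size_um Physical pixel size.
#' @param roi_id ROI identifier for the output rows (defaults to the
#'   stack's).
#' @param dilate_um Measurement-support dilation radius in um (0 = nucleus).
#' @return Cell table tibble: `cell_id`, `roi_id`, `x_um`, `y_um`,
#'   `area_um2`, one column per marker.
#' @export
quantify_cells <- function(mask, stack, pixel_size_um = 0.22, roi_id = NULL,
                           dilate_um = 0) {
  if (inherits(stack, "mihc_stack")) {
    rasters <- stack$marker_rasters
    roi_id <- roi_id %||% stack$roi_id
    pixel_size_um <- stack$pixel_size_um
  } else {
    rasters <- stack
    roi_id <- roi_id %||% "ROI-1"
  }
  mask_m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  for (m in names(rasters)) {
    if (!all(dim(rasters[[m]]) == dim(mask_m))) {
      abort(paste0("marker raster '", m, "' shape differs from the mask"))
    }
  }
  ids <- setdiff(sort(unique(as.integer(mask_m))), 0L)
  markers <- names(rasters)
  if (length(ids) == 0) {
    out <- tibble(cell_id = integer(0), roi_id = character(0),
                  x_um = numeric(0), y_um = numeric(0), area_um2 = numeric(0))
    for (m in markers) out[[m]] <- numeric(0)
    return(out)
  }

  meas_mask <- mask_m
  if (dilate_um > 0) {
    r_px <- max(1L, round(dilate_um / pixel_size_um))
    # grow labels into background by nearest-label propagation via distmap
    # of the background, approximated with EBImage's Voronoi propagation
    meas_mask <- matrix(as.integer(
      EBImage::propagate(matrix(0, nrow(mask_m), ncol(mask_m)),
                         seeds = mask_m, lambda = 1e4)), nrow(mask_m))
    dist_bg <- EBImage::distmap(matrix(as.numeric(mask_m == 0),
                                       nrow(mask_m)))
    meas_mask[dist_bg > r_px] <- 0L
  }

  pos <- which(mask_m > 0)
  lab <- mask_m[pos]
  rows0 <- (pos - 1) %% nrow(mask_m) # y, 0-based
  cols0 <- (pos - 1) %/% nrow(mask_m) # x, 0-based
  g <- as.integer(factor(lab, levels = ids)) # 1..K in `ids` order
  npx <- tabulate(g, length(ids))
  x_um <- as.numeric(rowsum(cols0, g)) / npx * pixel_size_um
  y_um <- as.numeric(rowsum(rows0, g)) / npx * pixel_size_um

  out <- tibble(
    cell_id = ids, roi_id = roi_id,
    x_um = x_um, y_um = y_um,
    area_um2 = npx * pixel_size_um^2
  )
  mpos <- which(meas_mask > 0)
  mg <- as.integer(factor(meas_mask[mpos], levels = ids))
  keep <- !is.na(mg) # dilation cannot remove labels, but guard anyway
  mpos <- mpos[keep]; mg <- mg[keep]
  mnpx <- tabulate(mg, length(ids))
  for (m in markers) {
    out[[m]] <- as.numeric(rowsum(rasters[[m]][mpos], mg)) / mnpx
  }
  out
}
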