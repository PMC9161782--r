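# Brightfield renderer: turns a synthetic scene into per-round RGB rasters
# via a Beer-Lambert forward model. Each round carries the hematoxylin
# nuclear counterstain (shared structure that registration keys on) plus the
# AEC chromogen of that round's marker over marker-positive cells.

# Ruifrok-style unit optical-density vectors for hematoxylin and AEC.
.HEMA_OD <- c(0.650, 0.704, 0.286)
.AEC_OD <- c(0.2743, 0.6796, 0.6803)

#' Default AEC / hematoxylin stain basis
#'
#' Unit optical-density RGB vectors for the AEC chromogen and the hematoxylin
#' counterstain, plus the reference white level. Used both by the forward
#' renderer and by [deconvolve_stains()].
#'
#' @param aec_rgb,hematoxylin_rgb Length-3 non-negative OD vectors
#'   (normalized internally).
#' @param background Reference white level of the brightfield camera.
#' @return An object of class `mihc_stains`.
#' @export
stain_vectors <- function(aec_rgb = .AEC_OD, hematoxylin_rgb = .HEMA_OD,
                          background = 1) {
  norm <- function(v) {
    v <- as.numeric(v)
    stopifnot(length(v) == 3, all(v >= 0), sum(v^2) > 0)
    v / sqrt(sum(v^2))
  }
  a <- norm(aec_rgb); h <- norm(hematoxylin_rgb)
  if (abs(sum(a * h)) > 1 - 1e-8) abort("stain vectors are collinear")
  structure(list(aec = a, hematoxylin = h, background = background),
            class = "mihc_stains")
}

# additive concentration of an ellipse footprint onto a matrix (in place)
paint_ellipse <- function(mat, cx, cy, a, b, theta, value) {
  H <- nrow(mat); W <- ncol(mat)
  r <- max(a, b)
  x_rng <- max(1, floor(cx - r) + 1):min(W, ceiling(cx + r) + 1)
  y_rng <- max(1, floor(cy - r) + 1):min(H, ceiling(cy + r) + 1)
  if (length(x_rng) == 0 || length(y_rng) == 0) return(mat)
  xs <- x_rng - 1 - cx
  ys <- y_rng - 1 - cy
  cs <- cos(theta); sn <- sin(theta)
  # rotated ellipse inclusion test on the local grid
  u <- outer(ys, xs, function(y, x) (x * cs + y * sn))
  v <- outer(ys, xs, function(y, x) (-x * sn + y * cs))
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- mat[y_rng, x_rng, drop = FALSE]
  sub[inside] <- sub[inside] + value
  mat[y_rng, x_rng] <- sub
  mat
}

label_ellipse <- function(mat, cx, cy, a, b, theta, id) {
  H <- nrow(mat); W <- ncol(mat)
  r <- max(a, b)
  x_rng <- max(1, floor(cx - r) + 1):min(W, ceiling(cx + r) + 1)
  y_rng <- max(1, floor(cy - r) + 1):min(H, ceiling(cy + r) + 1)
  if (length(x_rng) == 0 || length(y_rng) == 0) return(mat)
  xs <- x_rng - 1 - cx
  ys <- y_rng - 1 - cy
  cs <- cos(theta); sn <- sin(theta)
  u <- outer(ys, xs, function(y, x) (x * cs + y * sn))
  v <- outer(ys, xs, function(y, x) (-x * sn + y * cs))
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- mat[y_rng, x_rng, drop = FALSE]
  claim <- inside & sub == 0 # first-come: cells never share a pixel
  sub[claim] <- id
  mat[y_rng, x_rng] <- sub
  mat
}

#' Render the per-round brightfield images of a scene
#'
#' Produces one RGB raster per staining round: round 0 is the hematoxylin
#' nuclear round; rounds 1..length(panel) add the AEC chromogen of one marker
#' over that marker's positive cells (chromogen amplitude proportional to the
#' cell's tabulated intensity). Images follow a Beer-Lambert model
#' `rgb = background * exp(-(c_hema * v_hema + c_aec * v_aec))` plus additive
#' Gaussian pixel noise, and each round is distorted by its similarity
#' transform. The ground-truth nucleus label mask lives in the undistorted
#' reference frame.
#'
#' @param scene A `mihc_scene` with placed cells.
#' @param panel Marker panel (one AEC round per marker).
#' @param pixel_size_um Physical pixel size; 0.22 um at 20x brightfield.
#' @param round_transforms List of `mihc_transform`, one per round
#'   (length `length(panel) + 1`), or `NULL` for all-identity.
#' @param seed Integer seed (nucleus shapes, texture, pixel noise).
#' @param noise_sd SD of the additive Gaussian pixel noise.
#' @param od_ref Optical density corresponding to unit marker intensity;
#'   must match the `od_ref` used at deconvolution for a calibrated
#'   round trip.
#' @param stains Stain basis from [stain_vectors()].
#' @param texture_amp OD amplitude of the smooth background tissue texture
#'   (shared across rounds; gives the feature matcher structure to lock on).
#' @return List with `rounds` (list of `mihc_round`: `roi_id`, `round_index`,
#'   `marker`, `rgb`, `pixel_size_um`), `mask` (integer label matrix, label =
#'   `cell_id`), and `scene`.
#' @export
render_round_images <- function(scene, panel = mihc_panel(),
                                pixel_size_um = 0.22,
                                round_transforms = NULL, seed = 1,
                                noise_sd = 0.008, od_ref = 2,
                                stains = stain_vectors(),
                                texture_amp = 0.18) {
  n_round <- length(panel) + 1
  if (is.null(round_transforms)) {
    round_transforms <- rep(list(similarity_transform()), n_round)
  }
  if (length(round_transforms) != n_round) {
    abort(sprintf("need %d transforms (one per round), got %d",
                  n_round, length(round_transforms)))
  }
  cells <- scene$cells
  check_cell_table(cells, coords = TRUE)
  W <- ceiling(scene$roi_size[1] / pixel_size_um)
  H <- ceiling(scene$roi_size[2] / pixel_size_um)

  geom <- with_seed(seed, {
    n <- nrow(cells)
    r_um <- sqrt(cells$area_um2 / pi)
    ecc <- exp(rnorm(n, 0, 0.12))
    list(
      cx = cells$x_um / pixel_size_um,
      cy = cells$y_um / pixel_size_um,
      a = r_um * ecc / pixel_size_um,
      b = r_um / ecc / pixel_size_um,
      theta = runif(n, 0, pi),
      hema_gain = exp(rnorm(n, 0, 0.2)),
      tex_seed = sample.int(.Machine$integer.max %/% 2, 1),
      noise_seeds = sample.int(.Machine$integer.max %/% 2, n_round)
    )
  })

  # shared structural maps in the reference frame
  hema <- matrix(0, H, W)
  mask <- matrix(0L, H, W)
  for (i in seq_len(nrow(cells))) {
    hema <- paint_ellipse(hema, geom$cx[i], geom$cy[i], geom$a[i], geom$b[i],
                          geom$theta[i], 0.6 * od_ref * geom$hema_gain[i])
    mask <- label_ellipse(mask, geom$cx[i], geom$cy[i], geom$a[i], geom$b[i],
                          geom$theta[i], as.integer(cells$cell_id[i]))
  }
  # smooth background texture (weak hematoxylin-channel tissue signal)
  tex <- with_seed(geom$tex_seed, {
    coarse <- matrix(runif(ceiling(H / 24) * ceiling(W / 24)),
                     ceiling(H / 24), ceiling(W / 24))
    up <- EBImage::resize(coarse, w = H, h = W)
    EBImage::gblur(up, sigma = 3) * texture_amp
  })
  hema_total <- hema + tex

  make_round <- function(idx, marker) {
    aec <- matrix(0, H, W)
    if (!is.na(marker)) {
      pos <- which(cells[[marker]] * od_ref > 0.02)
      for (i in pos) {
        dil <- 1.5 / pixel_size_um # ~1.5 um chromogen halo beyond the nucleus
        aec <- paint_ellipse(aec, geom$cx[i], geom$cy[i],
                             geom$a[i] + dil, geom$b[i] + dil,
                             geom$theta[i], cells[[marker]][i] * od_ref)
      }
    }
    tf <- round_transforms[[idx + 1]]
    ident <- tf$scale == 1 && tf$angle == 0 && all(tf$translation == 0)
    h_r <- hema_total; a_r <- aec
    if (!ident) {
      # moving image samples the reference at tf(p): warp with the inverse
      h_r <- warp_image(hema_total, tf_invert(tf))
      a_r <- warp_image(aec, tf_invert(tf))
    }
    rgb <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      rgb[, , ch] <- stains$background *
        exp(-(h_r * stains$hematoxylin[ch] + a_r * stains$aec[ch]))
    }
    rgb <- with_seed(geom$noise_seeds[idx + 1], {
      pmin(pmax(rgb + array(rnorm(length(rgb), 0, noise_sd), dim(rgb)), 0), 1)
    })
    structure(list(roi_id = scene$roi_id, round_index = idx, marker = marker,
                   rgb = rgb, pixel_size_um = pixel_size_um),
              class = "mihc_round")
  }

  rounds <- c(list(make_round(0, NA_character_)),
              lapply(seq_along(panel), function(j) make_round(j, panel[j])))
  list(rounds = rounds, mask = mask, scene = scene)
}

#' @export
print.mihc_round <- function(x, ...) {
  cat("<mihc_round> ", x$roi_id, " round ", x$round_index,
      if (!is.na(x$marker)) paste0(" (", x$marker, ")") else " (nuclear)",
      ": ", dim(x$rgb)[1], "x", dim(x$rgb)[2], " px @ ",
      x$pixel_size_um, " um/px\n", sep = "")
  invisible(x)
}

#' Write / read round images as TIFF
#'
#' @param rounds List of `mihc_round` objects.
#' @param dir Output directory (created if needed).
#' @param pixel_size_um Pixel size used when reading back.
#' @return `write_round_images()` the directory; `read_round_images()` a list
#'   of `mihc_round`.
#' @export
write_round_images <- function(rounds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in rounds) {
    nm <- sprintf("round_%02d%s.tif", r$round_index,
                  if (is.na(r$marker)) "_nuclear" else paste0("_", r$marker))
    tiff::writeTIFF(r$rgb, file.path(dir, nm))
  }
  invisible(dir)
}

#' @rdname write_round_images
#' @export
read_round_images <- function(dir, pixel_size_um = 0.22) {
  files <- sort(list.files(dir, pattern = "^round_\\d+.*\\.tif$",
                           full.names = TRUE))
  lapply(files, function(f) {
    base <- sub("\\.tif$", "", basename(f))
    parts <- strsplit(base, "_")[[1]]
    idx <- as.integer(parts[2])
    marker <- if (identical(parts[3], "nuclear")) NA_character_ else parts[3]
    structure(list(roi_id = basename(dirname(f)), round_index = idx,
                   marker = marker, rgb = tiff::readTIFF(f),
                   pixel_size_um = pixel_size_um),
              class = "mihc_round")
  })
}
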