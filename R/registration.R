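# Multi-round co-registration by feature matching: Harris corners on the
# tissue intensity gradients, normalized-patch descriptors, mutual
# nearest-neighbour matching with a ratio test, and a RANSAC-wrapped
# closed-form (Umeyama) similarity fit. The transform family is similarity
# (scale + rotation + translation); serial chromogenic rounds of one ROI do
# not deform the section, they only shift/rotate/rescale the field of view.

rgb_to_tissue_gray <- function(rgb) {
  # brightfield: tissue is dark on a white background; work on 1 - mean(rgb)
  if (length(dim(rgb)) == 3) 1 - (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  else 1 - rgb
}

sobel_gradients <- function(g) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 8
  list(x = EBImage::filter2(g, kx), y = EBImage::filter2(g, t(kx)))
}

#' Detect corner features in a round image
#'
#' Harris corner detection on the tissue intensity (1 - mean RGB): Sobel
#' gradients, Gaussian-windowed structure tensor, response
#' `det - kappa * trace^2`, greedy non-maximum suppression, and quadratic
#' sub-pixel refinement of the response peak.
#'
#' @param img An `mihc_round`, RGB array, or gray matrix.
#' @param n_features Maximum number of corners returned (strongest first).
#' @param sigma Structure-tensor integration scale (px).
#' @param kappa Harris sensitivity constant.
#' @param min_distance Suppression radius between corners (px).
#' @param response_floor Minimum corner response relative to the strongest;
#'   also guards against featureless images.
#' @return Tibble with 0-based `x`, `y` and `response`.
#' @export
detect_features <- function(img, n_features = 600, sigma = 2, kappa = 0.05,
                            min_distance = 7, response_floor = 1e-4) {
  g <- if (inherits(img, "mihc_round")) rgb_to_tissue_gray(img$rgb)
       else rgb_to_tissue_gray(img)
  g <- EBImage::gblur(g, sigma = 1)
  gr <- sobel_gradients(g)
  sxx <- EBImage::gblur(gr$x * gr$x, sigma = sigma)
  syy <- EBImage::gblur(gr$y * gr$y, sigma = sigma)
  sxy <- EBImage::gblur(gr$x * gr$y, sigma = sigma)
  resp <- (sxx * syy - sxy^2) - kappa * (sxx + syy)^2

  H <- nrow(resp); W <- ncol(resp)
  b <- 8 # keep clear of the border for descriptors
  inner <- resp[(b + 1):(H - b), (b + 1):(W - b)]
  # local maxima on the 3x3 neighbourhood
  is_max <- inner >= 0
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    shifted <- resp[(b + 1 + dy):(H - b + dy), (b + 1 + dx):(W - b + dx)]
    is_max <- is_max & inner >= shifted
  }
  cand <- which(is_max & inner > max(inner) * response_floor,
                arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble(x = numeric(0), y = numeric(0), response = numeric(0)))
  }
  vals <- inner[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  vals <- vals[ord]

  # greedy non-max suppression on a coarse occupancy grid
  cell <- max(1, min_distance)
  gy <- cand[, 1] %/% cell; gx <- cand[, 2] %/% cell
  taken <- new.env(hash = TRUE)
  keep <- integer(0)
  kx_ <- numeric(0); ky_ <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    yy <- cand[i, 1]; xx <- cand[i, 2]
    close <- FALSE
    for (ddy in -1:1) for (ddx in -1:1) {
      key <- paste0(gy[i] + ddy, "_", gx[i] + ddx)
      pts <- taken[[key]]
      if (!is.null(pts) &&
          any((pts[, 1] - yy)^2 + (pts[, 2] - xx)^2 < min_distance^2)) {
        close <- TRUE
      }
    }
    if (close) next
    key <- paste0(gy[i], "_", gx[i])
    taken[[key]] <- rbind(taken[[key]], c(yy, xx))
    keep <- c(keep, i)
    if (length(keep) >= n_features) break
  }
  cand <- cand[keep, , drop = FALSE]
  vals <- vals[keep]

  # sub-pixel quadratic refinement in the full response map
  row_f <- cand[, 1] + b; col_f <- cand[, 2] + b
  refine <- function(rm, r0, c0, axis) {
    if (axis == "x") {
      vm <- rm[cbind(r0, c0 - 1)]; v0 <- rm[cbind(r0, c0)]
      vp <- rm[cbind(r0, c0 + 1)]
    } else {
      vm <- rm[cbind(r0 - 1, c0)]; v0 <- rm[cbind(r0, c0)]
      vp <- rm[cbind(r0 + 1, c0)]
    }
    den <- vm - 2 * v0 + vp
    off <- ifelse(abs(den) > 1e-12, 0.5 * (vm - vp) / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  tibble(
    x = (col_f - 1) + refine(resp, row_f, col_f, "x"),
    y = (row_f - 1) + refine(resp, row_f, col_f, "y"),
    response = vals
  )
}

extract_descriptors <- function(gray, pts, patch = 11) {
  half <- patch %/% 2
  H <- nrow(gray); W <- ncol(gray)
  xi <- round(pts$x) + 1; yi <- round(pts$y) + 1
  ok <- xi > half & xi <= W - half & yi > half & yi <= H - half
  idx <- which(ok)
  if (length(idx) == 0) {
    return(list(desc = matrix(0, 0, patch^2), keep = idx))
  }
  offs <- expand.grid(dy = -half:half, dx = -half:half)
  desc <- matrix(0, length(idx), nrow(offs))
  for (j in seq_len(nrow(offs))) {
    desc[, j] <- gray[cbind(yi[idx] + offs$dy[j], xi[idx] + offs$dx[j])]
  }
  mu <- rowMeans(desc)
  desc <- desc - mu
  nrm <- sqrt(rowSums(desc^2))
  good <- nrm > 1e-8
  desc[good, ] <- desc[good, ] / nrm[good]
  list(desc = desc, keep = idx)
}

#' Detect and match features between two rounds
#'
#' Extracts corner features and normalized patch descriptors in both images
#' and returns mutual nearest-neighbour matches passing Lowe's ratio test.
#'
#' @param fixed,moving `mihc_round` objects (or rasters) of the same ROI and
#'   pixel size.
#' @param n_features,patch,ratio Detector/matcher tuning: corners per image,
#'   descriptor patch side (px), and the distance ratio threshold.
#' @param min_matches Matches below this count raise an
#'   "insufficient features" error rather than silently returning an
#'   identity-like answer.
#' @return Tibble of correspondences: `x_fixed`, `y_fixed`, `x_moving`,
#'   `y_moving`, `score` (descriptor correlation).
#' @export
detect_and_match_features <- function(fixed, moving, n_features = 600,
                                      patch = 11, ratio = 0.9,
                                      min_matches = 10) {
  if (inherits(fixed, "mihc_round") && inherits(moving, "mihc_round") &&
      !isTRUE(all.equal(fixed$pixel_size_um, moving$pixel_size_um))) {
    abort("fixed and moving rounds have different pixel sizes")
  }
  gf <- if (inherits(fixed, "mihc_round")) rgb_to_tissue_gray(fixed$rgb)
        else rgb_to_tissue_gray(fixed)
  gm <- if (inherits(moving, "mihc_round")) rgb_to_tissue_gray(moving$rgb)
        else rgb_to_tissue_gray(moving)
  gf_s <- EBImage::gblur(gf, 1); gm_s <- EBImage::gblur(gm, 1)

  pf <- detect_features(fixed, n_features = n_features)
  pm <- detect_features(moving, n_features = n_features)
  insufficient <- function() {
    abort(paste0("insufficient features to match rounds (",
                 nrow(pf), " fixed / ", nrow(pm), " moving corners)"),
          class = "mihc_insufficient_features")
  }
  if (nrow(pf) < min_matches || nrow(pm) < min_matches) insufficient()

  df <- extract_descriptors(gf_s, pf, patch)
  dm <- extract_descriptors(gm_s, pm, patch)
  if (nrow(df$desc) < min_matches || nrow(dm$desc) < min_matches) {
    insufficient()
  }
  pf <- pf[df$keep, ]; pm <- pm[dm$keep, ]

  corr <- df$desc %*% t(dm$desc) # NCC since descriptors are unit-normalized
  d2 <- pmax(2 - 2 * corr, 0) # squared descriptor distance
  best_m <- max.col(-d2, ties.method = "first")
  # ratio test: best vs second-best distance
  n1 <- nrow(d2)
  best_d <- d2[cbind(seq_len(n1), best_m)]
  d2_tmp <- d2
  d2_tmp[cbind(seq_len(n1), best_m)] <- Inf
  second_d <- d2_tmp[cbind(seq_len(n1), max.col(-d2_tmp,
                                                ties.method = "first"))]
  pass <- sqrt(best_d) < ratio * sqrt(second_d)
  # mutual check
  best_f <- max.col(-t(d2), ties.method = "first")
  mutual <- best_f[best_m] == seq_len(n1)
  sel <- which(pass & mutual)
  if (length(sel) < min_matches) insufficient()
  tibble(
    x_fixed = pf$x[sel], y_fixed = pf$y[sel],
    x_moving = pm$x[best_m[sel]], y_moving = pm$y[best_m[sel]],
    score = corr[cbind(sel, best_m[sel])]
  )
}

# closed-form least-squares similarity fit (Umeyama): moving -> fixed
fit_similarity_ls <- function(xm, ym, xf, yf) {
  mu_m <- c(mean(xm), mean(ym)); mu_f <- c(mean(xf), mean(yf))
  A <- cbind(xm - mu_m[1], ym - mu_m[2])
  B <- cbind(xf - mu_f[1], yf - mu_f[2])
  S <- crossprod(B, A) / length(xm) # 2x2 covariance
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, d))
  R <- sv$u %*% D %*% t(sv$v)
  var_m <- mean(A[, 1]^2 + A[, 2]^2)
  if (var_m < 1e-12) return(NULL) # degenerate (coincident points)
  s <- sum(diag(D) * sv$d) / var_m
  t_vec <- mu_f - s * as.numeric(R %*% mu_m)
  angle <- atan2(R[2, 1], R[1, 1])
  similarity_transform(s, angle, t_vec[1], t_vec[2])
}

#' Estimate a similarity transform from point correspondences
#'
#' Closed-form least-squares similarity fit (Umeyama) inside a random-sample
#' consensus loop; the final transform is refit on all inliers. With
#' `ransac = FALSE` a plain least-squares fit over all points is returned.
#'
#' @param correspondences Tibble from [detect_and_match_features()] (columns
#'   `x_fixed`, `y_fixed`, `x_moving`, `y_moving`).
#' @param ransac Use robust consensus (default) or plain least squares.
#' @param inlier_px Residual threshold (px) for consensus membership.
#' @param n_iter RANSAC iterations.
#' @param seed Seed of the sampling loop (fixed for reproducibility).
#' @return A `mihc_transform` mapping moving coordinates into the fixed
#'   frame, with attributes `inliers` (logical vector) and `rms` (inlier
#'   residual RMS, px).
#' @export
estimate_similarity <- function(correspondences, ransac = TRUE,
                                inlier_px = 2, n_iter = 500, seed = 1) {
  cc <- correspondences
  n <- nrow(cc)
  if (n < 3) abort("need at least 3 correspondences")
  xm <- cc$x_moving; ym <- cc$y_moving
  xf <- cc$x_fixed; yf <- cc$y_fixed
  # collinearity / duplicate-point guard on the moving set
  if (abs(stats::cov(xm, ym))^2 >=
      (1 - 1e-9) * stats::var(xm) * stats::var(ym) ||
      (stats::var(xm) + stats::var(ym)) < 1e-12) {
    abort("degenerate correspondence geometry (collinear or coincident)")
  }

  residuals_of <- function(tf) {
    pred <- tf_apply(tf, cbind(xm, ym))
    sqrt((pred[, 1] - xf)^2 + (pred[, 2] - yf)^2)
  }

  if (!ransac) {
    tf <- fit_similarity_ls(xm, ym, xf, yf)
    if (is.null(tf)) abort("degenerate correspondence geometry")
    res <- residuals_of(tf)
    attr(tf, "inliers") <- rep(TRUE, n)
    attr(tf, "rms") <- sqrt(mean(res^2))
    return(tf)
  }

  best_inl <- NULL
  best_count <- -1
  with_seed(seed, {
    for (it in seq_len(n_iter)) {
      pick <- sample.int(n, 2)
      # a similarity is determined by 2 point pairs
      if ((xm[pick[1]] - xm[pick[2]])^2 +
          (ym[pick[1]] - ym[pick[2]])^2 < 1e-9) next
      tf <- fit_similarity_ls(xm[pick], ym[pick], xf[pick], yf[pick])
      if (is.null(tf)) next
      inl <- residuals_of(tf) <= inlier_px
      if (sum(inl) > best_count) {
        best_count <- sum(inl)
        best_inl <- inl
      }
    }
  })
  if (is.null(best_inl) || best_count < 3) {
    abort("robust consensus failed: fewer than 3 inliers")
  }
  # refit on the consensus set, then once more on its refined inliers
  for (pass in 1:2) {
    tf <- fit_similarity_ls(xm[best_inl], ym[best_inl],
                            xf[best_inl], yf[best_inl])
    if (is.null(tf)) abort("degenerate inlier geometry")
    best_inl <- residuals_of(tf) <= inlier_px
    if (sum(best_inl) < 3) abort("robust consensus collapsed under refit")
  }
  res <- residuals_of(tf)
  attr(tf, "inliers") <- best_inl
  attr(tf, "rms") <- sqrt(mean(res[best_inl]^2))
  tf
}

#' Register all rounds of one ROI into a common frame
#'
#' Matches every round against the reference round, estimates per-round
#' similarity transforms, warps all rounds into the reference frame
#' (bilinear), and crops to the common valid region. The nuclear raster is
#' the hematoxylin channel of the nuclear round; per-marker AEC rasters are
#' produced by stain deconvolution of each warped round.
#'
#' @param rounds List of `mihc_round` objects (same ROI and pixel size); the
#'   nuclear round is the one with `marker = NA`.
#' @param reference_round Index (0-based `round_index`) of the reference.
#' @param stains Stain basis for deconvolution.
#' @param od_ref Reference OD mapping to intensity 1 (see
#'   [deconvolve_stains()]).
#' @param seed Seed for the consensus loops.
#' @param ... Passed to [detect_and_match_features()].
#' @return A `mihc_stack`: `roi_id`, `nuclear` (matrix), `marker_rasters`
#'   (named list of matrices), `transforms` (per round), `crop_box`
#'   (`xmin,xmax,ymin,ymax`, 0-based reference px), `pixel_size_um`,
#'   `reference_round`.
#' @export
register_stack <- function(rounds, reference_round = 0,
                           stains = stain_vectors(), od_ref = 2,
                           seed = 1, ...) {
  idxs <- vapply(rounds, function(r) r$round_index, numeric(1))
  if (anyDuplicated(idxs)) abort("duplicate round indices")
  px <- vapply(rounds, function(r) r$pixel_size_um, numeric(1))
  if (length(unique(px)) != 1) abort("rounds have mismatched pixel sizes")
  rois <- unique(vapply(rounds, function(r) r$roi_id, character(1)))
  if (length(rois) != 1) abort("rounds belong to different ROIs")
  ref_pos <- match(reference_round, idxs)
  if (is.na(ref_pos)) abort("reference round not present")
  ref <- rounds[[ref_pos]]
  H <- dim(ref$rgb)[1]; W <- dim(ref$rgb)[2]

  transforms <- list()
  warped <- list()
  for (r in rounds) {
    key <- as.character(r$round_index)
    if (r$round_index == reference_round) {
      transforms[[key]] <- similarity_transform()
      warped[[key]] <- r$rgb
      next
    }
    cc <- tryCatch(
      detect_and_match_features(ref, r, ...),
      error = function(e) {
        abort(paste0("round ", r$round_index, " failed feature matching: ",
                     conditionMessage(e)))
      })
    tf <- estimate_similarity(cc, seed = seed)
    transforms[[key]] <- tf
    warped[[key]] <- warp_image(r$rgb, tf, output_dim = c(H, W),
                                fill = stains$background)
  }

  # crop to the intersection of all warped rounds' valid quadrilaterals
  xmin <- 0; xmax <- W - 1; ymin <- 0; ymax <- H - 1
  for (key in names(transforms)) {
    tf <- transforms[[key]]
    corners <- tf_apply(tf, cbind(c(0, W - 1, W - 1, 0),
                                  c(0, 0, H - 1, H - 1)))
    xs <- sort(corners[, 1]); ys <- sort(corners[, 2])
    # inner axis-aligned rectangle of the transformed image quad
    xmin <- max(xmin, xs[2]); xmax <- min(xmax, xs[3])
    ymin <- max(ymin, ys[2]); ymax <- min(ymax, ys[3])
  }
  xmin <- ceiling(xmin); ymin <- ceiling(ymin)
  xmax <- floor(xmax); ymax <- floor(ymax)
  if (xmax <= xmin || ymax <= ymin) abort("empty common region after warp")
  crop <- function(img) img[(ymin + 1):(ymax + 1), (xmin + 1):(xmax + 1), ,
                            drop = FALSE]

  nuclear <- NULL
  marker_rasters <- list()
  for (r in rounds) {
    key <- as.character(r$round_index)
    dec <- deconvolve_stains(crop(warped[[key]]), stains, od_ref = od_ref)
    if (is.na(r$marker)) {
      nuclear <- dec$hematoxylin
    } else {
      marker_rasters[[r$marker]] <- dec$aec
    }
  }
  if (is.null(nuclear)) {
    # no dedicated nuclear round: fall back to the reference round's
    # hematoxylin channel
    dec <- deconvolve_stains(crop(warped[[as.character(reference_round)]]),
                             stains, od_ref = od_ref)
    nuclear <- dec$hematoxylin
  }

  structure(
    list(roi_id = rois, nuclear = nuclear, marker_rasters = marker_rasters,
         transforms = transforms,
         crop_box = c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
         pixel_size_um = px[1], reference_round = reference_round),
    class = "mihc_stack"
  )
}

#' @export
print.mihc_stack <- function(x, ...) {
  cat("<mihc_stack> ", x$roi_id, ": ", nrow(x$nuclear), "x", ncol(x$nuclear),
      " px, ", length(x$marker_rasters), " marker rasters, reference round ",
      x$reference_round, "\n", sep = "")
  invisible(x)
}
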