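# Similarity transforms (scale + rotation + translation) in pixel
# coordinates: x = column, y = row, 0-based, origin top-left.
# A transform maps moving-image coordinates into the fixed (reference)
# frame: p_fixed = scale * R(angle) %*% p_moving + t.

#' Similarity transform
#'
#' @param scale Positive isotropic scale factor.
#' @param angle Rotation in radians.
#' @param dx,dy Translation in pixels.
#' @return An object of class `mihc_transform`.
#' @export
#' @examples
#' tf <- similarity_transform(1.02, 3 * pi / 180, 10, -5)
#' tf_apply(tf, cbind(0, 0))
similarity_transform <- function(scale = 1, angle = 0, dx = 0, dy = 0) {
  if (!(is.finite(scale) && scale > 0)) abort("scale must be positive")
  structure(list(scale = scale, angle = angle,
                 translation = c(dx = dx, dy = dy)),
            class = "mihc_transform")
}

#' @export
print.mihc_transform <- function(x, ...) {
  cat(sprintf(
    "<mihc_transform> scale=%.6g angle=%.4g deg shift=(%.3g, %.3g) px\n",
    x$scale, x$angle * 180 / pi, x$translation[1], x$translation[2]))
  invisible(x)
}

tf_matrix <- function(tf) {
  cs <- cos(tf$angle); sn <- sin(tf$angle)
  tf$scale * matrix(c(cs, sn, -sn, cs), 2, 2)
}

#' Apply, invert and compose similarity transforms
#'
#' `tf_apply()` maps an n x 2 matrix of `(x, y)` points into the fixed frame;
#' `tf_invert()` returns the inverse transform; `tf_compose(a, b)` returns the
#' transform equivalent to applying `b` first, then `a`.
#'
#' @param tf,a,b `mihc_transform` objects.
#' @param xy Two-column matrix of points.
#' @return `tf_apply()` a matrix of mapped points; the others a transform.
#' @export
tf_apply <- function(tf, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  sweep(xy %*% t(tf_matrix(tf)), 2, -tf$translation)
}

#' @rdname tf_apply
#' @export
tf_invert <- function(tf) {
  s <- 1 / tf$scale
  a <- -tf$angle
  t_new <- -s * matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2) %*%
    tf$translation
  similarity_transform(s, a, t_new[1], t_new[2])
}

#' @rdname tf_apply
#' @export
tf_compose <- function(a, b) {
  # (a o b)(p) = a(b(p))
  t_new <- tf_matrix(a) %*% b$translation + a$translation
  similarity_transform(a$scale * b$scale, a$angle + b$angle,
                       t_new[1], t_new[2])
}

#' Warp an image through a similarity transform
#'
#' Resamples a moving image into the fixed frame of `tf` (which maps moving
#' coordinates to fixed coordinates) by inverse mapping: output pixel `p`
#' takes the value of the moving image at `tf^-1(p)`.
#'
#' @param img Matrix (`[y, x]`) or `H x W x C` array.
#' @param tf `mihc_transform` mapping `img` coordinates into the output frame.
#' @param output_dim `c(H, W)` of the output; defaults to the input size.
#' @param filter `"bilinear"` for intensities, `"nearest"` for label masks.
#' @param fill Value for pixels mapping outside the source.
#' @return Warped matrix/array of size `output_dim`.
#' @export
warp_image <- function(img, tf, output_dim = NULL,
                       filter = c("bilinear", "nearest"), fill = 0) {
  filter <- match.arg(filter)
  multi <- length(dim(img)) == 3
  d <- if (multi) dim(img)[1:2] else dim(img)
  if (is.null(output_dim)) output_dim <- d
  H <- output_dim[1]; W <- output_dim[2]
  inv <- tf_invert(tf)
  # output pixel grid, 0-based (x = col, y = row)
  xo <- rep(seq_len(W) - 1, each = H)
  yo <- rep(seq_len(H) - 1, times = W)
  src <- tf_apply(inv, cbind(xo, yo))
  xs <- src[, 1]; ys <- src[, 2]

  sample_one <- function(ch) {
    out <- rep(fill, H * W)
    if (filter == "nearest") {
      xi <- round(xs); yi <- round(ys)
      ok <- xi >= 0 & xi <= d[2] - 1 & yi >= 0 & yi <= d[1] - 1
      out[ok] <- ch[cbind(yi[ok] + 1, xi[ok] + 1)]
    } else {
      x0 <- floor(xs); y0 <- floor(ys)
      ok <- x0 >= 0 & x0 <= d[2] - 2 & y0 >= 0 & y0 <= d[1] - 2
      fx <- xs[ok] - x0[ok]; fy <- ys[ok] - y0[ok]
      rr <- y0[ok] + 1; cc <- x0[ok] + 1
      v00 <- ch[cbind(rr, cc)]
      v01 <- ch[cbind(rr, cc + 1)]
      v10 <- ch[cbind(rr + 1, cc)]
      v11 <- ch[cbind(rr + 1, cc + 1)]
      out[ok] <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
        v10 * (1 - fx) * fy + v11 * fx * fy
    }
    matrix(out, H, W)
  }

  if (multi) {
    out <- array(fill, dim = c(H, W, dim(img)[3]))
    for (c_i in seq_len(dim(img)[3])) out[, , c_i] <- sample_one(img[, , c_i])
    out
  } else {
    sample_one(img)
  }
}

#' Serialize transforms to JSON
#'
#' Writes/reads the per-round transforms of a registered stack as JSON
#' records `(round, scale, angle_deg, dx, dy, reference_round)`.
#'
#' @param transforms Named list of `mihc_transform` (names = round index).
#' @param reference_round Integer reference round.
#' @param path Output file.
#' @return `write_transforms()` the path, invisibly; `read_transforms()` a
#'   list with `transforms` and `reference_round`.
#' @export
write_transforms <- function(transforms, reference_round, path) {
  recs <- lapply(names(transforms), function(nm) {
    tf <- transforms[[nm]]
    list(round = as.integer(nm), scale = tf$scale,
         angle_deg = tf$angle * 180 / pi,
         dx = unname(tf$translation[1]), dy = unname(tf$translation[2]),
         reference_round = as.integer(reference_round))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  tfs <- list()
  ref <- NA_integer_
  for (r in recs) {
    tfs[[as.character(r$round)]] <- similarity_transform(
      r$scale, r$angle_deg * pi / 180, r$dx, r$dy)
    ref <- as.integer(r$reference_round)
  }
  list(transforms = tfs, reference_round = ref)
}
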