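# Tissue regions (epithelium annotations) in micrometre coordinates.
# All distance computations go through a rasterized mask at a fixed
# resolution so rectangle, polygon and mask inputs behave identically.

#' Tissue regions
#'
#' A region describes an annotated tissue area (typically the epithelium) in
#' micrometre coordinates. Three constructors are provided: an axis-aligned
#' rectangle, a simple polygon (vertex matrix, implicitly closed), and a
#' binary mask with an origin and pixel resolution.
#'
#' @param xmin,ymin,xmax,ymax Rectangle bounds in um.
#' @param vertices Two-column matrix of polygon vertices (um).
#' @param mask Binary matrix (`[y, x]`, nonzero = inside).
#' @param origin `c(x, y)` um position of the mask's `[1, 1]` pixel.
#' @param resolution_um Edge length of one mask pixel.
#' @return An object of class `mihc_region`.
#' @export
#' @examples
#' r <- region_rect(0, 0, 100, 50)
region_rect <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  structure(list(type = "rect", xmin = xmin, ymin = ymin,
                 xmax = xmax, ymax = ymax),
            class = "mihc_region")
}

#' @rdname region_rect
#' @export
region_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  structure(list(type = "polygon", vertices = vertices),
            class = "mihc_region")
}

#' @rdname region_rect
#' @export
region_mask <- function(mask, origin = c(0, 0), resolution_um = 1) {
  mask <- (as.matrix(mask) != 0)
  if (!any(mask)) abort("region mask is empty")
  structure(list(type = "mask", mask = mask, origin = origin,
                 resolution_um = resolution_um),
            class = "mihc_region")
}

region_bounds <- function(region) {
  switch(region$type,
    rect = c(region$xmin, region$ymin, region$xmax, region$ymax),
    polygon = c(min(region$vertices[, 1]), min(region$vertices[, 2]),
                max(region$vertices[, 1]), max(region$vertices[, 2])),
    mask = c(region$origin[1], region$origin[2],
             region$origin[1] + ncol(region$mask) * region$resolution_um,
             region$origin[2] + nrow(region$mask) * region$resolution_um)
  )
}

# even-odd point-in-polygon, vectorized over query points
points_in_polygon <- function(x, y, vertices) {
  n <- nrow(vertices)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > y) != (vy[j] > y)) &
      (x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Test point containment in a region
#'
#' @param region A `mihc_region`.
#' @param x,y Point coordinates (um), recycled together.
#' @return Logical vector.
#' @export
region_contains <- function(region, x, y) {
  switch(region$type,
    rect = x >= region$xmin & x <= region$xmax &
           y >= region$ymin & y <= region$ymax,
    polygon = points_in_polygon(x, y, region$vertices),
    mask = {
      ix <- floor((x - region$origin[1]) / region$resolution_um) + 1
      iy <- floor((y - region$origin[2]) / region$resolution_um) + 1
      ok <- ix >= 1 & ix <= ncol(region$mask) & iy >= 1 &
        iy <= nrow(region$mask)
      out <- logical(length(ix))
      out[ok] <- region$mask[cbind(iy[ok], ix[ok])]
      out
    }
  )
}

# Rasterize region over a bounding window wide enough to cover query points,
# and return the Euclidean distance (um) from each query point to the region
# (0 inside). Distances via EBImage's distance transform on the complement.
region_distance <- function(region, x, y, resolution_um = 1) {
  b <- region_bounds(region)
  pad <- resolution_um
  x0 <- min(b[1], x) - pad; y0 <- min(b[2], y) - pad
  x1 <- max(b[3], x) + pad; y1 <- max(b[4], y) + pad
  nx <- ceiling((x1 - x0) / resolution_um) + 1
  ny <- ceiling((y1 - y0) / resolution_um) + 1
  # pixel centres
  cx <- x0 + (seq_len(nx) - 0.5) * resolution_um
  cy <- y0 + (seq_len(ny) - 0.5) * resolution_um
  grid <- expand.grid(y = cy, x = cx)
  m <- matrix(region_contains(region, grid$x, grid$y), nrow = ny, ncol = nx)
  if (!any(m)) abort("region rasterizes to an empty mask")
  # distmap: each nonzero pixel -> distance to nearest zero; complement gives
  # distance-to-region for outside pixels
  d <- EBImage::distmap(matrix(as.numeric(!m), ny, nx)) * resolution_um
  ix <- pmin(pmax(floor((x - x0) / resolution_um) + 1, 1), nx)
  iy <- pmin(pmax(floor((y - y0) / resolution_um) + 1, 1), ny)
  as.numeric(d[cbind(iy, ix)])
}
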