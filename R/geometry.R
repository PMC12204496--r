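#' Polygon geometry utilities
#'
#' Polygons throughout the package are numeric matrices with two columns
#' (`x`, `y`) holding vertices in order, in physical micrometers; the closing
#' edge is implicit (last vertex connects back to the first). The y axis
#' follows the raster convention (downwards); all geometry here is
#' orientation-agnostic.
#'
#' @param poly two-column numeric matrix of vertices (µm).
#' @return `poly_area()` the enclosed area (µm²); `poly_perimeter()` the
#'   boundary length (µm); `poly_centroid()` the area centroid `c(x, y)`.
#' @examples
#' sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' poly_area(sq)       # 100
#' poly_perimeter(sq)  # 40
#' @export
poly_area <- function(poly) {
  abs(poly_signed_area(poly))
}

poly_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(nrow(poly), seq_len(nrow(poly) - 1L))
  0.5 * sum(x[j] * y - x * y[j])
}

#' @rdname poly_area
#' @export
poly_perimeter <- function(poly) {
  d <- poly - poly[c(nrow(poly), seq_len(nrow(poly) - 1L)), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' @rdname poly_area
#' @export
poly_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(nrow(poly), seq_len(nrow(poly) - 1L))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Point-in-polygon test (closed boundary convention)
#'
#' Even-odd rule; points lying exactly on the boundary count as inside, which
#' keeps cell attribution deterministic.
#'
#' @param x,y point coordinates (µm), recycled to common length.
#' @param poly polygon vertex matrix.
#' @return logical vector.
#' @export
points_in_poly <- function(x, y, poly) {
  n <- max(length(x), length(y))
  cpp_points_in_poly(rep_len(as.numeric(x), n), rep_len(as.numeric(y), n),
                     as.numeric(poly[, 1]), as.numeric(poly[, 2]))
}

#' Distance from points to a polygon boundary
#'
#' @inheritParams points_in_poly
#' @param signed if `TRUE`, points inside the polygon get distance 0.
#' @return numeric vector of distances (µm).
#' @export
dist_to_poly <- function(x, y, poly, signed = FALSE) {
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n); y <- rep_len(as.numeric(y), n)
  d <- cpp_dist_to_poly(x, y, as.numeric(poly[, 1]), as.numeric(poly[, 2]))
  if (signed) d[points_in_poly(x, y, poly)] <- 0
  d
}

#' Area of the intersection of circles with a polygon
#'
#' Exact Green's-theorem decomposition (each polygon edge contributes a
#' triangle or a circular-sector term); used as the boundary weight of the
#' modified Ripley's K statistic.
#'
#' @param cx,cy,r circle centers and radii (µm), recycled.
#' @param poly polygon vertex matrix.
#' @return numeric vector of intersection areas (µm²).
#' @export
circle_poly_area <- function(cx, cy, r, poly) {
  cpp_circle_poly_area(as.numeric(cx), as.numeric(cy), as.numeric(r),
                       as.numeric(poly[, 1]), as.numeric(poly[, 2]))
}

#' Feret (caliper) diameters of a polygon
#'
#' Maximum Feret diameter is the largest vertex-pair distance of the convex
#' hull; minimum Feret diameter is the smallest hull width over all hull edge
#' directions (rotating calipers).
#'
#' @param poly polygon vertex matrix.
#' @return `c(min = , max = )` in µm.
#' @export
feret_diameters <- function(poly) {
  h <- poly[grDevices::chull(poly[, 1], poly[, 2]), , drop = FALSE]
  nh <- nrow(h)
  if (nh < 2) return(c(min = 0, max = 0))
  dmax <- max(stats::dist(h))
  wmin <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- h[j, ] - h[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    p <- h %*% nrm
    wmin <- min(wmin, max(p) - min(p))
  }
  c(min = as.numeric(wmin), max = as.numeric(dmax))
}

convex_hull_poly <- function(poly) {
  poly[grDevices::chull(poly[, 1], poly[, 2]), , drop = FALSE]
}

# side lengths (short, long) of the minimum-area bounding rectangle
# (rotating calipers over convex hull edge directions)
min_bounding_rect <- function(poly) {
  h <- poly[grDevices::chull(poly[, 1], poly[, 2]), , drop = FALSE]
  nh <- nrow(h)
  if (nh < 3) {
    d <- max(stats::dist(h))
    return(c(short = 0, long = as.numeric(d)))
  }
  best <- c(Inf, Inf)
  barea <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- h[j, ] - h[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- h %*% u
    pv <- h %*% v
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    if (du * dv < barea) {
      barea <- du * dv
      best <- sort(c(du, dv))
    }
  }
  c(short = best[1], long = best[2])
}

#' Construct a regular-polygon approximation of a circle
#'
#' @param cx,cy center (µm); @param r radius (µm); @param n vertex count.
#' @return polygon vertex matrix.
#' @export
circle_polygon <- function(cx, cy, r, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# deterministic local seeding that restores the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483647)
}
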