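#' Stain mask container
#'
#' A binary raster for one stain channel, co-registered to the tissue section.
#' Rows index y (downward), columns index x; the center of pixel `(r, c)` lies
#' at `origin + (c - 0.5, r - 0.5) * pixel_size_um`.
#'
#' @param mask logical matrix (`TRUE` = stained).
#' @param pixel_size_um physical pixel size, µm per pixel.
#' @param origin `c(x, y)` of the grid corner (µm), default `c(0, 0)`.
#' @param channel stain name.
#' @return a `stain_mask` object.
#' @export
stain_mask <- function(mask, pixel_size_um, origin = c(0, 0), channel = "stain") {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!is.logical(mask)) mask <- mask > 0
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  structure(list(mask = mask, pixel_size_um = pixel_size_um,
                 origin = as.numeric(origin), channel = channel),
            class = "stain_mask")
}

#' @export
print.stain_mask <- function(x, ...) {
  cat(sprintf("<stain_mask> %s: %d x %d px @ %g um/px, %.0f um^2 stained\n",
              x$channel, nrow(x$mask), ncol(x$mask), x$pixel_size_um,
              sum(x$mask) * x$pixel_size_um^2))
  invisible(x)
}

mask_pixel_centers <- function(mask, rows, cols) {
  list(x = mask$origin[1] + (cols - 0.5) * mask$pixel_size_um,
       y = mask$origin[2] + (rows - 0.5) * mask$pixel_size_um)
}

same_grid <- function(a, b) {
  identical(dim(a$mask), dim(b$mask)) &&
    isTRUE(all.equal(a$pixel_size_um, b$pixel_size_um)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

# Rasterize a polygon onto the grid of `mask`: logical matrix of pixels whose
# centers fall inside the polygon (closed boundary convention). Only the
# bounding-box window is tested.
rasterize_polygon <- function(poly, mask) {
  px <- mask$pixel_size_um
  nr <- nrow(mask$mask); nc <- ncol(mask$mask)
  out <- matrix(FALSE, nr, nc)
  c0 <- max(1L, floor((min(poly[, 1]) - mask$origin[1]) / px))
  c1 <- min(nc, ceiling((max(poly[, 1]) - mask$origin[1]) / px) + 1L)
  r0 <- max(1L, floor((min(poly[, 2]) - mask$origin[2]) / px))
  r1 <- min(nr, ceiling((max(poly[, 2]) - mask$origin[2]) / px) + 1L)
  if (c1 < c0 || r1 < r0) return(out)
  rows <- r0:r1; cols <- c0:c1
  gx <- mask$origin[1] + (cols - 0.5) * px
  gy <- mask$origin[2] + (rows - 0.5) * px
  gg <- expand.grid(y = gy, x = gx)
  ins <- points_in_poly(gg$x, gg$y, poly)
  out[rows, cols] <- matrix(ins, length(rows), length(cols))
  out
}

# linear indices (into the full mask matrix) of pixels inside the polygon
rasterize_polygon_idx <- function(poly, mask) {
  px <- mask$pixel_size_um
  nr <- nrow(mask$mask); nc <- ncol(mask$mask)
  c0 <- max(1L, floor((min(poly[, 1]) - mask$origin[1]) / px))
  c1 <- min(nc, ceiling((max(poly[, 1]) - mask$origin[1]) / px) + 1L)
  r0 <- max(1L, floor((min(poly[, 2]) - mask$origin[2]) / px))
  r1 <- min(nr, ceiling((max(poly[, 2]) - mask$origin[2]) / px) + 1L)
  if (c1 < c0 || r1 < r0) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  gx <- mask$origin[1] + (cols - 0.5) * px
  gy <- mask$origin[2] + (rows - 0.5) * px
  gg <- expand.grid(r = rows, c = cols)
  ins <- points_in_poly(rep(gx, each = length(rows)), rep(gy, length(cols)), poly)
  (gg$c[ins] - 1L) * nr + gg$r[ins]
}

# Index all labeled components once; returns per-label cropped binary
# windows plus their grid origin (avoids full-raster scans per component).
component_windows <- function(lab, keep, mask) {
  nr <- nrow(lab)
  pos <- which(lab > 0)
  labv <- lab[pos]
  rows <- (pos - 1L) %% nr + 1L
  cols <- (pos - 1L) %/% nr + 1L
  px <- mask$pixel_size_um
  lapply(keep, function(k) {
    sel <- labv == k
    r <- rows[sel]; cc <- cols[sel]
    r0 <- min(r); c0 <- min(cc)
    bin <- matrix(FALSE, max(r) - r0 + 1L, max(cc) - c0 + 1L)
    bin[cbind(r - r0 + 1L, cc - c0 + 1L)] <- TRUE
    list(bin = bin, n_pixels = sum(sel),
         grid = list(pixel_size_um = px,
                     origin = mask$origin + c((c0 - 1L) * px, (r0 - 1L) * px)))
  })
}

# Trace the outer contour of one labeled component as a polygon in physical
# coordinates (marching squares at the 0.5 level on a zero-padded window).
polygonize_component <- function(bin, mask) {
  px <- mask$pixel_size_um
  padded <- matrix(0, nrow(bin) + 2L, ncol(bin) + 2L)
  padded[2:(nrow(bin) + 1L), 2:(ncol(bin) + 1L)] <- bin * 1
  xs <- mask$origin[1] + (seq_len(ncol(padded)) - 1.5) * px
  ys <- mask$origin[2] + (seq_len(nrow(padded)) - 1.5) * px
  cl <- grDevices::contourLines(x = xs, y = ys, z = t(padded), levels = 0.5)
  if (!length(cl)) return(NULL)
  areas <- vapply(cl, function(ct) poly_area(cbind(ct$x, ct$y)), numeric(1))
  ct <- cl[[which.max(areas)]]
  poly <- cbind(ct$x, ct$y)
  if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  poly
}

#' Segment stained regions from a binary mask
#'
#' Connected components (8-connected) of the stained pixels with an area of at
#' least `min_region_area_um2` (default 50 µm², the minimum stained-region
#' size used at islet detection), polygonized into physical µm coordinates.
#'
#' @param mask a [stain_mask()].
#' @param min_region_area_um2 minimum region area (µm²).
#' @return list of regions, each `list(polygon, area_um2, n_pixels)`; area is
#'   the pixel-count area.
#' @export
segment_stained_regions <- function(mask, min_region_area_um2 = 50) {
  if (!inherits(mask, "stain_mask")) stop("mask must be a stain_mask (pixel size required)")
  lab <- cpp_label_components(mask$mask, eight = TRUE)
  n <- max(lab)
  if (n == 0) return(list())
  px2 <- mask$pixel_size_um^2
  counts <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(counts * px2 >= min_region_area_um2)
  wins <- component_windows(lab, keep, mask)
  lapply(wins, function(w)
    list(polygon = polygonize_component(w$bin, w$grid),
         area_um2 = w$n_pixels * px2,
         n_pixels = w$n_pixels))
}

fill_holes <- function(bin) {
  bg <- cpp_label_components(!bin, eight = FALSE)
  if (max(bg) == 0) return(bin)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  bin | (bg > 0 & !(bg %in% border_labels))
}

#' Shape descriptors of a polygon
#'
#' Circularity \eqn{4\pi A/P^2}, solidity \eqn{A/A_{hull}}, and aspect ratio
#' (short/long side of the minimum-area bounding rectangle, so a square and a
#' circle both score 1 and a 2:1 rectangle scores 0.5), all clamped to (0, 1]
#' against numerical noise.
#'
#' @param poly polygon vertex matrix (µm).
#' @return named numeric: `area_um2`, `perimeter_um`, `circularity`,
#'   `solidity`, `aspect_ratio`.
#' @export
shape_descriptors <- function(poly) {
  a <- poly_area(poly)
  if (!is.finite(a) || a <= 0) stop("degenerate polygon: zero area")
  p <- poly_perimeter(poly)
  hull <- convex_hull_poly(poly)
  br <- min_bounding_rect(poly)
  c(area_um2 = a,
    perimeter_um = p,
    circularity = min(1, 4 * pi * a / p^2),
    solidity = min(1, a / poly_area(hull)),
    aspect_ratio = min(1, unname(br["short"] / br["long"])))
}

#' Equivalent circular diameter and spherical volume of an islet area
#'
#' Under the circularity/sphericity assumption, `diameter = 2 sqrt(area/pi)`
#' and `volume = (pi/6) diameter^3`; the 1,000 µm² minimum islet corresponds
#' to a ~36 µm diameter.
#'
#' @param area_um2 islet section area(s), µm².
#' @return data.frame with `diameter_um` and `volume_um3`.
#' @export
equivalent_diameter_volume <- function(area_um2) {
  if (any(area_um2 < 0, na.rm = TRUE)) stop("negative area")
  d <- 2 * sqrt(area_um2 / pi)
  data.frame(diameter_um = d, volume_um3 = pi / 6 * d^3)
}

#' Build islet objects from the six islet-defining stain masks
#'
#' Islets are the 8-connected components of the union of the six hormone
#' channels (CHGA, ProINS, INS, GCG, SST, PPY), with holes filled to create
#' contiguous objects, components below `min_islet_area_um2` removed, and
#' objects within `border_margin_um` of the tissue boundary removed.
#'
#' @param channel_masks named list of six [stain_mask()]s on one pixel grid.
#' @param tissue a [tissue_section()].
#' @param min_islet_area_um2 minimum islet area (µm², default 1,000).
#' @param border_margin_um tissue-border exclusion margin (µm, default 10).
#' @return islet `data.frame`: `id`, `area_um2`, `perimeter_um`,
#'   `centroid_x_um`, `centroid_y_um`, `circularity`, `solidity`,
#'   `aspect_ratio`, `equivalent_diameter_um`, `polygon_wkt`.
#' @export
build_islets <- function(channel_masks, tissue,
                         min_islet_area_um2 = 1000, border_margin_um = 10) {
  stopifnot(length(channel_masks) >= 1)
  ref <- channel_masks[[1]]
  for (m in channel_masks)
    if (!same_grid(ref, m)) stop("stain masks are not on the same pixel grid")
  un <- Reduce(`|`, lapply(channel_masks, function(m) m$mask))
  un <- fill_holes(un)
  lab <- cpp_label_components(un, eight = TRUE)
  nlab <- max(lab)
  px2 <- ref$pixel_size_um^2
  rows <- list()
  if (nlab > 0) {
    counts <- tabulate(lab[lab > 0], nbins = nlab)
    keep <- which(counts * px2 >= min_islet_area_um2)
    wins <- component_windows(lab, keep, ref)
    for (wi in seq_along(keep)) {
      k <- keep[wi]
      poly <- polygonize_component(wins[[wi]]$bin, wins[[wi]]$grid)
      if (is.null(poly) || nrow(poly) < 3) next
      cen <- poly_centroid(poly)
      if (!points_in_poly(cen[1], cen[2], tissue$boundary)) next
      # closed-form distance between the islet polygon and the boundary line
      dmin <- min(dist_to_poly(poly[, 1], poly[, 2], tissue$boundary),
                  dist_to_poly(tissue$boundary[, 1], tissue$boundary[, 2], poly))
      if (dmin < border_margin_um) next
      sd <- shape_descriptors(poly)
      rows[[length(rows) + 1L]] <- data.frame(
        area_um2 = counts[k] * px2,
        perimeter_um = unname(sd["perimeter_um"]),
        centroid_x_um = cen[1], centroid_y_um = cen[2],
        circularity = unname(sd["circularity"]),
        solidity = unname(sd["solidity"]),
        aspect_ratio = unname(sd["aspect_ratio"]),
        equivalent_diameter_um = 2 * sqrt(counts[k] * px2 / pi),
        polygon_wkt = polygon_to_wkt(poly),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(id = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), centroid_x_um = numeric(),
                      centroid_y_um = numeric(), circularity = numeric(),
                      solidity = numeric(), aspect_ratio = numeric(),
                      equivalent_diameter_um = numeric(),
                      polygon_wkt = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Islet cell density
#'
#' Number of nuclei whose coordinates fall inside the islet polygon, divided
#' by the islet area in mm². Points on the boundary count as inside.
#'
#' @param poly islet polygon (µm) or WKT string.
#' @param nuclei data.frame with `x_um`, `y_um`.
#' @return cells per mm².
#' @export
islet_cell_density <- function(poly, nuclei) {
  if (is.character(poly)) poly <- wkt_to_polygon(poly)
  if (nrow(nuclei) == 0) return(0)
  n <- sum(points_in_poly(nuclei$x_um, nuclei$y_um, poly))
  n / (poly_area(poly) / 1e6)
}
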