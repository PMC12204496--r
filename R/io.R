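#' Serialize / parse polygons as WKT
#'
#' Islet tables carry their polygons in a `polygon_wkt` column so that a plain
#' CSV round-trips the full geometry vertex-exactly.
#'
#' @param poly polygon vertex matrix (µm).
#' @return `polygon_to_wkt()` a `POLYGON ((...))` string; `wkt_to_polygon()`
#'   the vertex matrix.
#' @export
polygon_to_wkt <- function(poly) {
  v <- rbind(poly, poly[1, , drop = FALSE])  # WKT rings are closed
  sprintf("POLYGON ((%s))",
          paste(sprintf("%.17g %.17g", v[, 1], v[, 2]), collapse = ", "))
}

#' @rdname polygon_to_wkt
#' @param wkt a WKT `POLYGON` string.
#' @export
wkt_to_polygon <- function(wkt) {
  m <- regmatches(wkt, regexec("^\\s*POLYGON\\s*\\(\\((.*)\\)\\)\\s*$", wkt))[[1]]
  if (length(m) < 2) stop("malformed WKT polygon: ", substr(wkt, 1, 60))
  toks <- strsplit(trimws(strsplit(m[2], ",")[[1]]), "\\s+")
  xy <- suppressWarnings(
    t(vapply(toks, function(t) as.numeric(t[1:2]), numeric(2))))
  if (anyNA(xy)) stop("malformed WKT polygon coordinates")
  if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  unname(xy)
}

#' Tissue section container
#'
#' @param boundary polygon vertex matrix (µm) delimiting the parenchyma.
#' @param region `"PT"` (tail) or `"PH"` (head).
#' @param donor_id donor identifier.
#' @param stage disease stage: `"Ctrl"`, `"AAb"`, `"T1DS"` or `"T1DL"`.
#' @param pancreas_region_weight_g regional pancreas weight (g) or `NA`.
#' @return a `tissue_section` object; `parenchymal_area_mm2` is derived from
#'   the boundary polygon.
#' @export
tissue_section <- function(boundary, region = "PT", donor_id = "donor",
                           stage = "Ctrl", pancreas_region_weight_g = NA_real_) {
  stopifnot(is.matrix(boundary), ncol(boundary) == 2, nrow(boundary) >= 3)
  region <- match.arg(region, c("PT", "PH"))
  stage <- match.arg(stage, c("Ctrl", "AAb", "T1DS", "T1DL"))
  structure(list(
    boundary = boundary,
    parenchymal_area_mm2 = poly_area(boundary) / 1e6,
    region = region, donor_id = donor_id, stage = stage,
    pancreas_region_weight_g = pancreas_region_weight_g
  ), class = "tissue_section")
}

#' @export
print.tissue_section <- function(x, ...) {
  cat(sprintf("<tissue_section> donor %s [%s, %s], %.2f mm^2 parenchyma, %d vertices\n",
              x$donor_id, x$region, x$stage, x$parenchymal_area_mm2,
              nrow(x$boundary)))
  invisible(x)
}

#' Read / write a tissue boundary as GeoJSON
#'
#' Coordinates are micrometers in the section frame (y axis downward); section
#' metadata travels in the feature `properties`.
#'
#' @param tissue a [tissue_section()].
#' @param path file path.
#' @export
write_tissue_geojson <- function(tissue, path) {
  ring <- rbind(tissue$boundary, tissue$boundary[1, , drop = FALSE])
  gj <- list(
    type = "Feature",
    properties = list(
      unit = "micrometer", region = tissue$region, donor_id = tissue$donor_id,
      stage = tissue$stage,
      pancreas_region_weight_g = tissue$pancreas_region_weight_g,
      parenchymal_area_mm2 = tissue$parenchymal_area_mm2
    ),
    geometry = list(
      type = "Polygon",
      coordinates = list(lapply(seq_len(nrow(ring)),
                                function(i) as.numeric(ring[i, ])))
    )
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_tissue_geojson
#' @export
read_tissue_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (identical(gj$type, "FeatureCollection")) gj <- gj$features[[1]]
  geom <- gj$geometry
  if (!identical(geom$type, "Polygon")) stop("expected a GeoJSON Polygon")
  ring <- geom$coordinates[[1]]
  xy <- t(vapply(ring, function(p) as.numeric(unlist(p)[1:2]), numeric(2)))
  if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  pr <- gj$properties
  w <- pr$pancreas_region_weight_g
  tissue_section(unname(xy),
                 region = pr$region %||% "PT",
                 donor_id = pr$donor_id %||% "donor",
                 stage = pr$stage %||% "Ctrl",
                 pancreas_region_weight_g = if (is.null(w)) NA_real_ else as.numeric(w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write the islet table
#'
#' Plain UTF-8 comma CSV with a mandatory header; the `polygon_wkt` column
#' round-trips geometry vertex-exactly and unknown columns are preserved.
#'
#' @param islets islet `data.frame`.
#' @param path file path.
#' @export
write_islet_table <- function(islets, path) {
  utils::write.csv(islets, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_islet_table
#' @export
read_islet_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("polygon_wkt" %in% names(df)) {
    bad <- which(!grepl("^\\s*POLYGON", df$polygon_wkt))
    if (length(bad))
      stop("malformed WKT in rows: ", paste(utils::head(bad, 10), collapse = ", "))
  }
  df
}

#' Read / write stain masks as portable graymap text + JSON sidecar
#'
#' The binary mask is stored as an ASCII PGM (P2) image; the sidecar records
#' the channel name, pixel size (µm/px) and grid origin so that masks remain
#' co-registered.
#'
#' @param mask a [stain_mask()].
#' @param path output path (`.pgm`); the sidecar is `path + ".json"`.
#' @export
write_stain_mask <- function(mask, path) {
  m <- mask$mask
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "1"), con)
  apply_rows <- apply(m * 1L, 1L, paste, collapse = " ")
  writeLines(apply_rows, con)
  jsonlite::write_json(list(channel = mask$channel,
                            pixel_size_um = mask$pixel_size_um,
                            origin = as.numeric(mask$origin)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stain_mask
#' @export
read_stain_mask <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  m <- matrix(vals > 0, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"))
  stain_mask(m, pixel_size_um = as.numeric(side$pixel_size_um),
             origin = as.numeric(unlist(side$origin)),
             channel = side$channel %||% "unknown")
}

#' Read / write a cell point table
#'
#' CSV with columns `x_um`, `y_um`, `class` (`"CD45"` or `"nucleus"`).
#'
#' @param cells cell `data.frame`; @param path file path.
#' @export
write_cells <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "class")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cells table missing column(s): ", paste(miss, collapse = ", "))
  df
}
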