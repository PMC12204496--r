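#' Default radii grid for the modified Ripley's K
#'
#' 25 log-spaced radii between 400 and 10,000 µm (configurable; the upper end
#' may be extended to 20,000 µm to match wider axes).
#' @param from,to radius range (µm); @param n number of radii.
#' @return numeric vector of radii (µm).
#' @export
ripley_radii <- function(from = 400, to = 10000, n = 25) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Boundary-weighted modified Ripley's K
#'
#' Circles of increasing radius are placed at each islet; the number of other
#' islets inside each circle is divided by the fraction of the circle area
#' lying inside the tissue polygon (the boundary weight), averaged across
#' islets, and normalized by the count expected under complete spatial
#' randomness (slide-average density times the circle area). K = 1 indicates
#' a random distribution; K = 2 a doubled local density.
#'
#' @param centroids two-column matrix or data.frame of islet centroids (µm).
#' @param tissue a [tissue_section()].
#' @param radii ascending radii grid (µm), default [ripley_radii()].
#' @param min_weight islets with a boundary weight below this at a radius are
#'   skipped there (variance guard; default 0.01).
#' @param pooled if `TRUE`, the per-radius statistic is the pooled ratio
#'   (sum of counts over sum of weighted expectations) instead of the average
#'   of per-islet adjusted counts (sensitivity-analysis ordering).
#' @return `ripley_curve` data.frame: `radius_um`, `k`, `mean_adjusted_count`,
#'   `n_islets_used`; attributes `slide_density_per_um2` and `auc`
#'   (trapezoidal area under K over the radii grid).
#' @export
ripley_modified <- function(centroids, tissue, radii = ripley_radii(),
                            min_weight = 0.01, pooled = FALSE) {
  xy <- as.matrix(centroids)[, 1:2, drop = FALSE]
  if (any(radii <= 0)) stop("radii must be positive")
  ins <- points_in_poly(xy[, 1], xy[, 2], tissue$boundary)
  if (any(!ins)) {
    warning(sum(!ins), " centroid(s) outside the tissue polygon rejected")
    xy <- xy[ins, , drop = FALSE]
  }
  n <- nrow(xy)
  if (n < 2) stop("need at least 2 centroids inside the tissue")
  area <- tissue$parenchymal_area_mm2 * 1e6
  rho <- n / area
  counts <- cpp_count_within(xy[, 1], xy[, 2], radii)
  k <- mac <- used <- numeric(length(radii))
  for (j in seq_along(radii)) {
    r <- radii[j]
    w <- circle_poly_area(xy[, 1], xy[, 2], r, tissue$boundary) / (pi * r^2)
    keep <- w >= min_weight
    used[j] <- sum(keep)
    expected <- rho * pi * r^2
    if (!any(keep)) { k[j] <- NA; mac[j] <- NA; next }
    if (pooled) {
      k[j] <- sum(counts[keep, j]) / sum(w[keep] * expected)
      mac[j] <- mean(counts[keep, j] / w[keep])
    } else {
      adj <- counts[keep, j] / w[keep]
      mac[j] <- mean(adj)
      k[j] <- mac[j] / expected
    }
  }
  out <- data.frame(radius_um = radii, k = k, mean_adjusted_count = mac,
                    n_islets_used = used)
  ok <- !is.na(k)
  attr(out, "slide_density_per_um2") <- rho
  attr(out, "auc") <- if (sum(ok) >= 2)
    sum(diff(radii[ok]) * (utils::head(k[ok], -1) + utils::tail(k[ok], -1)) / 2)
  else NA_real_
  class(out) <- c("ripley_curve", "data.frame")
  out
}

#' Fractal dimension of an islet distribution
#'
#' Slope of the ordinary least-squares best-fit line of log10 mean
#' boundary-adjusted islet count against log10 search radius, excluding radii
#' <= 600 µm. Complete spatial randomness gives a slope near 2.
#'
#' @param curve a [ripley_modified()] result (or data.frame with `radius_um`
#'   and `mean_adjusted_count`).
#' @param exclude_radius_um radii at or below this are excluded (default 600).
#' @return list: `slope`, `intercept`, `n_points`.
#' @export
fractal_dimension <- function(curve, exclude_radius_um = 600) {
  keep <- curve$radius_um > exclude_radius_um &
    is.finite(curve$mean_adjusted_count) & curve$mean_adjusted_count > 0
  if (sum(keep) < 3) stop("need at least 3 retained radii with nonzero counts")
  fit <- stats::lm(log10(curve$mean_adjusted_count[keep]) ~
                     log10(curve$radius_um[keep]))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_points = sum(keep))
}

#' Radius-pruned Delaunay neighborhood metrics
#'
#' Global Delaunay triangulation of the islet centroids; edges longer than
#' `max_radius_um` (default 4,000 µm) are pruned. Each islet reports the mean
#' length of its retained incident edges and the mean area of incident
#' triangles whose three edges are all retained. An islet left without
#' retained neighbors receives the fallback assignment: distance 4 mm and
#' area pi x 16 mm² (`is_fallback = TRUE`).
#'
#' @param centroids two-column matrix/data.frame of centroids (µm).
#' @param max_radius_um maximum neighbor search radius (µm).
#' @return `data.frame`: `islet_id`, `mean_distance_um`, `mean_area_um2`,
#'   `n_neighbors`, `is_fallback`.
#' @export
delaunay_metrics <- function(centroids, max_radius_um = 4000) {
  xy <- as.matrix(centroids)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (n < 1) stop("need at least 1 centroid")
  fallback_d <- max_radius_um
  fallback_a <- pi * max_radius_um^2         # 4 mm radius -> pi x 16 mm^2
  out <- data.frame(islet_id = seq_len(n),
                    mean_distance_um = rep(fallback_d, n),
                    mean_area_um2 = rep(fallback_a, n),
                    n_neighbors = 0L,
                    is_fallback = rep(TRUE, n))
  if (n < 3) return(out)
  tri <- cpp_delaunay(xy[, 1], xy[, 2])
  if (nrow(tri) == 0) return(out)
  edge_len <- function(a, b) sqrt(rowSums((xy[a, , drop = FALSE] -
                                             xy[b, , drop = FALSE])^2))
  # unique undirected edges
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  e <- unique(e)
  len <- edge_len(e[, 1], e[, 2])
  keep <- len <= max_radius_um
  e <- e[keep, , drop = FALSE]; len <- len[keep]
  if (nrow(e)) {
    sums <- counts <- numeric(n)
    for (col in 1:2) {
      t1 <- tapply(len, e[, col], sum)
      sums[as.integer(names(t1))] <- sums[as.integer(names(t1))] + t1
      t2 <- table(e[, col])
      counts[as.integer(names(t2))] <- counts[as.integer(names(t2))] + t2
    }
    has <- counts > 0
    out$mean_distance_um[has] <- sums[has] / counts[has]
    out$n_neighbors <- as.integer(counts)
    out$is_fallback <- !has
  }
  # triangles with all three edges retained contribute areas
  l1 <- edge_len(tri[, 1], tri[, 2])
  l2 <- edge_len(tri[, 2], tri[, 3])
  l3 <- edge_len(tri[, 3], tri[, 1])
  tok <- l1 <= max_radius_um & l2 <= max_radius_um & l3 <= max_radius_um
  if (any(tok)) {
    tt <- tri[tok, , drop = FALSE]
    ar <- abs((xy[tt[, 2], 1] - xy[tt[, 1], 1]) * (xy[tt[, 3], 2] - xy[tt[, 1], 2]) -
                (xy[tt[, 3], 1] - xy[tt[, 1], 1]) * (xy[tt[, 2], 2] - xy[tt[, 1], 2])) / 2
    asum <- acnt <- numeric(n)
    for (col in 1:3) {
      t1 <- tapply(ar, tt[, col], sum)
      asum[as.integer(names(t1))] <- asum[as.integer(names(t1))] + t1
      t2 <- table(tt[, col])
      acnt[as.integer(names(t2))] <- acnt[as.integer(names(t2))] + t2
    }
    hasA <- acnt > 0
    out$mean_area_um2[hasA & !out$is_fallback] <-
      (asum / pmax(acnt, 1))[hasA & !out$is_fallback]
  }
  out
}

#' Cluster-scoped Delaunay metrics and isolated-islet fractions
#'
#' Delaunay triangulation run separately for the islets of each phenotype
#' cluster with an 8 mm search radius. An islet is isolated when fewer than
#' two islets of the same cluster lie within 8 mm (triangulation impossible
#' for it). Summaries apply the reporting suppression rule (<3 islets or
#' <2 donors).
#'
#' @param centroids two-column matrix/data.frame (µm).
#' @param clusters cluster label per islet.
#' @param donors optional donor id per islet (enables the <2-donor rule).
#' @param max_radius_mm search radius (mm, default 8).
#' @return list: `islets` (`cluster`, `is_isolated`, `mean_distance_um`,
#'   `mean_area_um2` for non-isolated), `summary` per cluster
#'   (`isolated_fraction`, `mean_area_nonisolated_um2`, `suppressed`,
#'   `suppressed_reason`).
#' @export
cluster_delaunay <- function(centroids, clusters, donors = NULL,
                             max_radius_mm = 8) {
  xy <- as.matrix(centroids)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  stopifnot(length(clusters) == n)
  rmax <- max_radius_mm * 1000
  res <- data.frame(islet_id = seq_len(n), cluster = as.character(clusters),
                    is_isolated = TRUE,
                    mean_distance_um = NA_real_, mean_area_um2 = NA_real_,
                    stringsAsFactors = FALSE)
  for (cl in unique(res$cluster)) {
    idx <- which(res$cluster == cl)
    if (length(idx) < 2) next
    sub <- xy[idx, , drop = FALSE]
    d <- as.matrix(stats::dist(sub))
    neigh <- rowSums(d <= rmax) - 1L
    iso <- neigh < 2
    res$is_isolated[idx] <- iso
    if (sum(!iso) >= 3) {
      dm <- delaunay_metrics(sub, max_radius_um = rmax)
      res$mean_distance_um[idx][!dm$is_fallback] <-
        dm$mean_distance_um[!dm$is_fallback]
      res$mean_area_um2[idx][!dm$is_fallback] <- dm$mean_area_um2[!dm$is_fallback]
    }
  }
  cls <- sort(unique(res$cluster))
  summ <- do.call(rbind, lapply(cls, function(cl) {
    idx <- which(res$cluster == cl)
    n_d <- if (is.null(donors)) NA_integer_ else length(unique(donors[idx]))
    reason <- character(0)
    if (length(idx) < 3) reason <- c(reason, "<3 islets")
    if (!is.null(donors) && n_d < 2) reason <- c(reason, "<2 donors")
    data.frame(cluster = cl, n_islets = length(idx), n_donors = n_d,
               isolated_fraction = mean(res$is_isolated[idx]),
               mean_area_nonisolated_um2 =
                 if (any(!res$is_isolated[idx]))
                   mean(res$mean_area_um2[idx], na.rm = TRUE) else NA_real_,
               suppressed = length(reason) > 0,
               suppressed_reason = paste(reason, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  summ$isolated_fraction[summ$suppressed] <- NA_real_
  summ$mean_area_nonisolated_um2[summ$suppressed] <- NA_real_
  list(islets = res, summary = summ)
}

#' Back-projection map of islets onto the tissue outline
#'
#' Renders islets as circles at their centroids (radius proportional to the
#' equivalent diameter, uniformly enlarged), colored by phenotype cluster or
#' by binned CD45+ burden (bins 0, 1-4, 5-9, 10-14, 15+), over the tissue
#' outline — the data behind cluster-location and insulitis-context maps.
#'
#' @param islets islet table (needs centroids and `equivalent_diameter_um`;
#'   `cluster` or `cd45_total` depending on `color_by`).
#' @param tissue a [tissue_section()].
#' @param color_by `"cluster"` or `"cd45_bins"`.
#' @param enlargement global radius scale factor (default 3).
#' @return list (GeoJSON-style FeatureCollection) with the outline and one
#'   point feature per islet carrying `radius_um` and `color`.
#' @export
back_project <- function(islets, tissue, color_by = c("cluster", "cd45_bins"),
                         enlargement = 3) {
  color_by <- match.arg(color_by)
  cluster_pal <- c("I" = "#1f77b4", "II" = "#2ca02c", "III" = "#9467bd",
                   "IV" = "#ff7f0e", "V-A" = "#d62728", "V-BC" = "#8c564b",
                   "null" = "#bbbbbb", "unassigned" = "#555555")
  cd45_pal <- c("0" = "#f0f0f0", "1-4" = "#fdd0a2", "5-9" = "#fd8d3c",
                "10-14" = "#d94801", "15+" = "#7f2704")
  ring <- rbind(tissue$boundary, tissue$boundary[1, , drop = FALSE])
  outline <- list(type = "Feature",
                  properties = list(kind = "tissue_outline"),
                  geometry = list(type = "Polygon",
                                  coordinates = list(lapply(seq_len(nrow(ring)),
                                                            function(i) as.numeric(ring[i, ])))))
  feats <- list(outline)
  if (nrow(islets) > 0) {
    if (color_by == "cluster") {
      key <- as.character(islets$cluster)
      key[!key %in% names(cluster_pal)] <- "unassigned"
      cols <- cluster_pal[key]
      labs <- key
    } else {
      b <- cut(islets$cd45_total, c(-Inf, 0, 4, 9, 14, Inf),
               labels = names(cd45_pal))
      labs <- as.character(b)
      cols <- cd45_pal[labs]
    }
    for (i in seq_len(nrow(islets))) {
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(kind = "islet", islet_id = islets$id[i],
                          radius_um = islets$equivalent_diameter_um[i] / 2 * enlargement,
                          value = labs[i], color = unname(cols[i])),
        geometry = list(type = "Point",
                        coordinates = c(islets$centroid_x_um[i],
                                        islets$centroid_y_um[i])))
    }
  }
  list(type = "FeatureCollection", features = feats)
}
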