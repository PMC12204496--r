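#' Non-overlapping peri-islet regions
#'
#' Expands each islet boundary by `margin_um` (default 20 µm) and partitions
#' contested territory between neighboring islets at the equidistant line
#' (watershed on a fine raster; exactly equidistant pixels go to the lower
#' islet id). Peri regions exclude all islet interiors and are clipped to the
#' tissue polygon.
#'
#' @param islets islet table with `polygon_wkt`.
#' @param tissue a [tissue_section()].
#' @param margin_um expansion distance (µm).
#' @param pixel_size_um raster resolution for the watershed (µm, default 2).
#' @return `data.frame`: `islet_id`, `peri_area_um2`, `peri_polygon_wkt`
#'   (largest ring of the region; the area comes from the raster).
#' @export
expand_peri_regions <- function(islets, tissue, margin_um = 20,
                                pixel_size_um = 2) {
  if (margin_um <= 0) stop("margin_um must be positive")
  n <- nrow(islets)
  out <- data.frame(islet_id = islets$id,
                    peri_area_um2 = numeric(n),
                    peri_polygon_wkt = character(n),
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  polys <- lapply(islets$polygon_wkt, wkt_to_polygon)
  cx <- islets$centroid_x_um; cy <- islets$centroid_y_um
  rmax <- vapply(seq_len(n), function(i)
    sqrt(max((polys[[i]][, 1] - cx[i])^2 + (polys[[i]][, 2] - cy[i])^2)),
    numeric(1))
  px <- pixel_size_um
  for (i in seq_len(n)) {
    poly <- polys[[i]]
    bb <- apply(poly, 2, range)
    g <- stain_mask(matrix(FALSE,
                           nrow = ceiling((bb[2, 2] - bb[1, 2] + 2 * margin_um + 4 * px) / px),
                           ncol = ceiling((bb[2, 1] - bb[1, 1] + 2 * margin_um + 4 * px) / px)),
                    px, origin = c(bb[1, 1] - margin_um - 2 * px,
                                   bb[1, 2] - margin_um - 2 * px))
    rows <- seq_len(nrow(g$mask)); cols <- seq_len(ncol(g$mask))
    gg <- expand.grid(r = rows, c = cols)
    cen <- mask_pixel_centers(g, gg$r, gg$c)
    d_own <- dist_to_poly(cen$x, cen$y, poly)
    ok <- !points_in_poly(cen$x, cen$y, poly) & d_own <= margin_um & d_own > 0
    # clip to tissue
    ok[ok] <- points_in_poly(cen$x[ok], cen$y[ok], tissue$boundary)
    nb <- setdiff(which(sqrt((cx - cx[i])^2 + (cy - cy[i])^2) <
                          rmax + rmax[i] + 2 * margin_um + 1), i)
    for (j in nb) {
      if (!any(ok)) break
      sub <- which(ok)
      dj <- dist_to_poly(cen$x[sub], cen$y[sub], polys[[j]], signed = TRUE)
      drop <- dj < d_own[sub] | (dj == d_own[sub] & islets$id[j] < islets$id[i])
      ok[sub[drop]] <- FALSE
    }
    out$peri_area_um2[i] <- sum(ok) * px^2
    bin <- matrix(FALSE, nrow(g$mask), ncol(g$mask))
    bin[cbind(gg$r[ok], gg$c[ok])] <- TRUE
    pg <- polygonize_component(bin, g)
    out$peri_polygon_wkt[i] <- if (is.null(pg)) "" else polygon_to_wkt(pg)
  }
  out
}

#' Attribute cells to islet compartments
#'
#' Point-in-polygon attribution: a cell inside an islet polygon is intra-islet
#' (boundary counts as inside); a cell within `margin_um` of exactly the
#' nearest islet (and inside no islet) is peri-islet of that islet; farther
#' cells are unattributed. Each cell counts for at most one compartment.
#' Nuclei counts include CD45+ cells (they are nucleated cells).
#'
#' @param islets islet table with `polygon_wkt`.
#' @param cells data.frame with `x_um`, `y_um`, `class` in
#'   `c("CD45", "nucleus")`.
#' @param margin_um peri-islet band width (µm, default 20).
#' @return list: `records` (per-islet `IsletImmuneRecord` data.frame with
#'   `cd45_intra`, `cd45_peri`, `cd45_total`, `nuclei_intra`, `nuclei_peri`,
#'   `freq_intra`, `freq_peri`, `freq_flag_intra`, `freq_flag_peri`),
#'   `n_unattributed`, `n_rejected` (cells with unknown class).
#' @export
attribute_cells <- function(islets, cells, margin_um = 20) {
  n <- nrow(islets)
  rec <- data.frame(islet_id = islets$id,
                    cd45_intra = 0L, cd45_peri = 0L,
                    nuclei_intra = 0L, nuclei_peri = 0L)
  known <- cells$class %in% c("CD45", "nucleus")
  n_rejected <- sum(!known)
  cells <- cells[known, , drop = FALSE]
  n_unattributed <- 0L
  if (n > 0 && nrow(cells) > 0) {
    polys <- lapply(islets$polygon_wkt, wkt_to_polygon)
    cx <- islets$centroid_x_um; cy <- islets$centroid_y_um
    rmax <- vapply(seq_len(n), function(i)
      sqrt(max((polys[[i]][, 1] - cx[i])^2 + (polys[[i]][, 2] - cy[i])^2)),
      numeric(1))
    m <- nrow(cells)
    best_d <- rep(Inf, m)   # distance to nearest islet boundary (outside)
    owner <- rep(NA_integer_, m)
    compartment <- rep("none", m)
    for (i in seq_len(n)) {
      cand <- which(compartment != "intra" &
                      abs(cells$x_um - cx[i]) <= rmax[i] + margin_um &
                      abs(cells$y_um - cy[i]) <= rmax[i] + margin_um)
      if (!length(cand)) next
      ins <- points_in_poly(cells$x_um[cand], cells$y_um[cand], polys[[i]])
      if (any(ins)) {
        compartment[cand[ins]] <- "intra"
        owner[cand[ins]] <- i
      }
      rest <- cand[!ins]
      if (length(rest)) {
        d <- dist_to_poly(cells$x_um[rest], cells$y_um[rest], polys[[i]])
        upd <- d <= margin_um & d < best_d[rest]
        best_d[rest[upd]] <- d[upd]
        sel <- rest[upd]
        compartment[sel] <- "peri"
        owner[sel] <- i
      }
    }
    n_unattributed <- sum(compartment == "none")
    cd45 <- cells$class == "CD45"
    for (comp in c("intra", "peri")) {
      sel <- compartment == comp
      if (!any(sel)) next
      tb_all <- tabulate(owner[sel], nbins = n)
      tb_cd <- tabulate(owner[sel & cd45], nbins = n)
      rec[[paste0("nuclei_", comp)]] <- tb_all
      rec[[paste0("cd45_", comp)]] <- tb_cd
    }
  } else {
    n_unattributed <- nrow(cells)
  }
  rec$cd45_total <- rec$cd45_intra + rec$cd45_peri
  safe_freq <- function(a, b) ifelse(b == 0, 0, a / b)
  rec$freq_intra <- safe_freq(rec$cd45_intra, rec$nuclei_intra)
  rec$freq_peri <- safe_freq(rec$cd45_peri, rec$nuclei_peri)
  rec$freq_flag_intra <- rec$nuclei_intra == 0
  rec$freq_flag_peri <- rec$nuclei_peri == 0
  list(records = rec, n_unattributed = n_unattributed, n_rejected = n_rejected)
}

#' Automated consensus insulitis diagnosis
#'
#' An islet is insulitic when its total associated CD45+ count (intra- plus
#' peri-islet) reaches `islet_threshold` (default 15); a donor is diagnosed
#' positive when at least `donor_threshold` (default 3) insulitic islets occur
#' across that donor's analyzed sections (tail and head pooled).
#'
#' @param records per-islet immune records (needs `cd45_total`; a `donor_id`
#'   column groups islets by donor, single donor assumed when absent).
#' @param islet_threshold CD45+ count threshold per islet.
#' @param donor_threshold insulitic islet count threshold per donor.
#' @return list: `records` with an `insulitic` flag appended, and `donors`
#'   (per-donor `n_insulitic`, `diagnosis`).
#' @export
call_insulitis <- function(records, islet_threshold = 15, donor_threshold = 3) {
  records$insulitic <- records$cd45_total >= islet_threshold
  donor <- if ("donor_id" %in% names(records)) records$donor_id
           else rep("donor", nrow(records))
  agg <- stats::aggregate(list(n_insulitic = records$insulitic),
                          by = list(donor_id = donor), FUN = sum)
  agg$diagnosis <- agg$n_insulitic >= donor_threshold
  if (nrow(records) == 0)
    agg <- data.frame(donor_id = character(), n_insulitic = integer(),
                      diagnosis = logical())
  list(records = records, donors = agg)
}

#' Immune burden summaries
#'
#' Fraction of islets with at least one associated CD45+ cell, CD45+ density
#' per mm² of combined islet plus peri-islet area, per-cluster mean intra-
#' and peri-islet CD45+ frequencies, and the peri:intra frequency ratio
#' (flagged undefined when the intra frequency is zero).
#'
#' @param records per-islet immune records (needs `cd45_total`, `freq_intra`,
#'   `freq_peri`; optional `cluster` for the per-cluster table, optional
#'   `peri_area_um2`).
#' @param islets matching islet table (for `area_um2`).
#' @return list of summaries (`prevalence_ge1`, `cd45_density_per_mm2`,
#'   `ratio_peri_intra`, `ratio_undefined`, `per_cluster`).
#' @export
burden_metrics <- function(records, islets) {
  if (nrow(records) == 0)
    return(list(prevalence_ge1 = numeric(0), cd45_density_per_mm2 = numeric(0),
                ratio_peri_intra = numeric(0), ratio_undefined = logical(0),
                per_cluster = data.frame()))
  prev <- mean(records$cd45_total >= 1)
  area_mm2 <- sum(islets$area_um2) / 1e6 +
    if ("peri_area_um2" %in% names(records)) sum(records$peri_area_um2) / 1e6 else 0
  dens <- if (area_mm2 > 0) sum(records$cd45_total) / area_mm2 else NA_real_
  mfi <- mean(records$freq_intra); mfp <- mean(records$freq_peri)
  per_cluster <- NULL
  if ("cluster" %in% names(records)) {
    per_cluster <- stats::aggregate(
      list(mean_freq_intra = records$freq_intra,
           mean_freq_peri = records$freq_peri),
      by = list(cluster = records$cluster), FUN = mean)
  }
  list(prevalence_ge1 = prev,
       cd45_density_per_mm2 = dens,
       mean_freq_intra = mfi, mean_freq_peri = mfp,
       ratio_peri_intra = if (mfi == 0) NA_real_ else mfp / mfi,
       ratio_undefined = mfi == 0,
       per_cluster = per_cluster)
}
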