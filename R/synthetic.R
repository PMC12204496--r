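#' Channel and cluster vocabularies
#'
#' `hormone_channels()` returns the eight hormone stains quantified per islet;
#' `all_channels()` additionally includes the nested high-proinsulin channel;
#' `defining_channels()` the six stains whose union defines islet objects;
#' `cluster_levels()` the major islet phenotype clusters.
#' @return character vector.
#' @export
hormone_channels <- function() {
  c("CHGA", "ProINS_total", "INS", "IAPP", "ProGCG", "GCG", "SST", "PPY")
}

#' @rdname hormone_channels
#' @export
all_channels <- function() c(hormone_channels(), "ProINS_hi")

#' @rdname hormone_channels
#' @export
defining_channels <- function() {
  c("CHGA", "ProINS_total", "INS", "GCG", "SST", "PPY")
}

#' @rdname hormone_channels
#' @export
cluster_levels <- function() c("I", "II", "III", "IV", "V-A", "V-BC")

#' Load a stage template preset
#'
#' Stage templates parameterize the synthetic cohort generator. The shipped
#' presets transcribe the study's printed group summaries (insulin-deficient
#' islet fractions, GCG-deficient fractions, PPY subsets, CD45 prevalence,
#' insulitis rates, size distributions) into generative parameters; fields not
#' printed by the study are one-time realistic choices (see the methods
#' vignette).
#'
#' @param stage `"Ctrl"`, `"AAb"`, `"T1DS"` or `"T1DL"`.
#' @param region `"PT"` or `"PH"`.
#' @param path optional path to a template JSON file (editable presets).
#' @return a validated `stage_template` list.
#' @export
load_stage_template <- function(stage, region, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "templates", "stage_templates.json",
                        package = "isletmap", mustWork = TRUE)
  all <- jsonlite::read_json(path, simplifyVector = TRUE)
  key <- paste(stage, region, sep = "_")
  if (!key %in% names(all)) stop("no template for ", key)
  tpl <- all[[key]]
  tpl$stage <- stage
  tpl$region <- region
  validate_stage_template(tpl)
}

#' @rdname load_stage_template
#' @export
list_stage_templates <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "templates", "stage_templates.json",
                        package = "isletmap", mustWork = TRUE)
  names(jsonlite::read_json(path))
}

#' Validate a stage template
#'
#' Checks every fraction lies in \[0, 1\], the cluster mixture sums to 1, the
#' insulin-deficient fraction is consistent with the mixture of beta-negative
#' clusters, the marginal GCG-deficient fraction is attainable given clusters
#' with forced GCG status, and the size-distribution truncation bound equals
#' the pipeline's minimum islet area.
#'
#' @param tpl a template list (see [load_stage_template()]).
#' @return the template, invisibly classed `stage_template`.
#' @export
validate_stage_template <- function(tpl) {
  cl <- cluster_levels()
  mix <- unlist(tpl$cluster_mix)[cl]
  if (anyNA(mix) || any(mix < 0) || abs(sum(mix) - 1) > 1e-6)
    stop("cluster_mix must cover clusters ", paste(cl, collapse = ", "),
         " and sum to 1")
  fr <- c(tpl$frac_IDI, tpl$frac_GCG_deficient, tpl$frac_PPY_dominant)
  if (any(fr < 0 | fr > 1)) stop("subset fractions must lie in [0, 1]")
  idi <- sum(mix[c("IV", "V-A", "V-BC")])
  if (abs(idi - tpl$frac_IDI) > 1e-6)
    stop("frac_IDI inconsistent with cluster_mix (IV + V-A + V-BC = ",
         signif(idi, 4), ")")
  if (abs(mix[["IV"]] - tpl$frac_PPY_dominant) > 1e-6)
    stop("frac_PPY_dominant must equal the cluster IV mixture weight")
  forced <- sum(mix[c("III", "IV")])   # alpha-cell-free clusters
  free <- sum(mix[c("I", "II")])
  pfree <- gcg_def_free_prob(tpl)
  if (is.na(pfree) || pfree < -1e-9 || pfree > 1 + 1e-9)
    stop("frac_GCG_deficient (", tpl$frac_GCG_deficient,
         ") unattainable: forced deficient mass ", signif(forced, 4),
         ", free mass ", signif(free, 4))
  if (!isTRUE(all.equal(as.numeric(tpl$min_islet_area_um2), 1000)))
    stop("size distribution truncation bound must equal the 1,000 um^2 ",
         "minimum islet area")
  pany <- unlist(tpl$cd45_model$p_any)[cl]
  if (anyNA(pany) || any(pany < 0 | pany > 1))
    stop("cd45_model$p_any must give per-cluster probabilities in [0, 1]")
  pins <- tpl$cd45_model$p_insulitic
  host <- sum(mix[c("II", "V-A")])
  if (pins < 0 || pins > 1 || (pins > 0 && pins > host + 1e-9))
    stop("p_insulitic exceeds the mass of insulitis-hosting clusters II/V-A")
  hr <- tpl$hormone_rules
  for (k in cl) {
    v <- unlist(hr[[k]])[hormone_channels()]
    if (anyNA(v) || any(v < 0 | v > 1))
      stop("hormone_rules for cluster ", k, " must cover all 8 channels in [0, 1]")
  }
  if (!tpl$spatial_mode %in% c("uniform", "thinned_patches"))
    stop("spatial_mode must be 'uniform' or 'thinned_patches'")
  class(tpl) <- c("stage_template", "list")
  invisible(tpl)
}

# conditional GCG-deficiency probability inside the free clusters (I, II);
# clusters III/IV are alpha-cell-free (always deficient), V is GCG-high (never)
gcg_def_free_prob <- function(tpl) {
  mix <- unlist(tpl$cluster_mix)[cluster_levels()]
  forced <- sum(mix[c("III", "IV")])
  free <- sum(mix[c("I", "II")])
  if (free <= 0) {
    if (abs(tpl$frac_GCG_deficient - forced) < 1e-6) return(0)
    return(NA_real_)
  }
  (tpl$frac_GCG_deficient - forced) / free
}

#' Implied marginal probability that an islet has >= 1 associated CD45+ cell
#'
#' Marginalizes the per-cluster CD45 presence probabilities over the cluster
#' mixture (insulitic islets always carry CD45).
#' @param tpl a stage template.
#' @return probability in \[0, 1\].
#' @export
implied_cd45_prevalence <- function(tpl) {
  cl <- cluster_levels()
  mix <- unlist(tpl$cluster_mix)[cl]
  pany <- unlist(tpl$cd45_model$p_any)[cl]
  sum(mix * pany)
}

#' Generate a tissue section polygon
#'
#' A star-shaped parenchymal boundary inside a `width_mm` by `height_mm`
#' bounding box. With `irregularity = 0` the boundary is the exact rectangle;
#' positive irregularity pulls the boundary inward by a smooth random radial
#' field (at 0.3 the area stays above half the bounding box).
#'
#' @param seed integer seed (full determinism).
#' @param width_mm,height_mm bounding box (mm), positive.
#' @param irregularity in \[0, 1\].
#' @param region,donor_id,stage,pancreas_region_weight_g section metadata.
#' @return a [tissue_section()] with coordinates in µm.
#' @export
generate_tissue <- function(seed, width_mm, height_mm, irregularity = 0.3,
                            region = "PT", donor_id = "synthetic", stage = "Ctrl",
                            pancreas_region_weight_g = NA_real_) {
  if (!is.finite(width_mm) || !is.finite(height_mm) ||
      width_mm <= 0 || height_mm <= 0)
    stop("tissue dimensions must be positive")
  if (irregularity < 0 || irregularity > 1) stop("irregularity must be in [0, 1]")
  w <- width_mm * 1000; h <- height_mm * 1000
  if (irregularity == 0) {
    poly <- cbind(c(0, w, w, 0), c(0, 0, h, h))
  } else {
    poly <- with_seed(seed, {
      n <- 64L; nctl <- 16L
      ctl <- stats::runif(nctl) * 0.85
      th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
      # periodic linear interpolation of the control field
      pos <- th / (2 * pi) * nctl
      i0 <- floor(pos); frac <- pos - i0
      u <- ctl[(i0 %% nctl) + 1L] * (1 - frac) + ctl[((i0 + 1) %% nctl) + 1L] * frac
      cx <- w / 2; cy <- h / 2
      rx <- (w / 2) / pmax(abs(cos(th)), 1e-12)
      ry <- (h / 2) / pmax(abs(sin(th)), 1e-12)
      R <- pmin(rx, ry) * (1 - irregularity * u)
      cbind(cx + R * cos(th), cy + R * sin(th))
    })
  }
  tissue_section(poly, region = region, donor_id = donor_id, stage = stage,
                 pancreas_region_weight_g = pancreas_region_weight_g)
}

# noisy star-convex islet polygon centered at origin with exact target area;
# returns list(poly, rmax)
make_islet_shape <- function(area_um2, roughness = 0.18, elong_sd = 0.18,
                             n_vertices = 20L) {
  r0 <- sqrt(area_um2 / pi)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  z <- stats::rnorm(n_vertices)
  z <- (z + c(z[-1], z[1]) + c(z[n_vertices], z[-n_vertices])) / 3  # smooth
  rho <- r0 * pmax(0.3, 1 + roughness * z)
  s <- exp(stats::rnorm(1, 0, elong_sd))
  phi <- stats::runif(1, 0, pi)
  x <- rho * cos(th) * s
  y <- rho * sin(th) / s
  xr <- x * cos(phi) - y * sin(phi)
  yr <- x * sin(phi) + y * cos(phi)
  poly <- cbind(xr, yr)
  poly <- poly * sqrt(area_um2 / poly_area(poly))  # exact area
  list(poly = poly, rmax = sqrt(max(rowSums(poly^2))))
}

draw_truncated_lognormal <- function(n, meanlog, sdlog, min_area) {
  lo <- stats::plnorm(min_area, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, lo, 1), meanlog, sdlog)
}

#' Generate an islet table with ground truth for one tissue section
#'
#' Islet counts follow a Poisson law at the template density; sizes follow the
#' template's truncated log-normal (per-cluster size multipliers shift the
#' log-mean); islets are star-convex noisy polygons placed without overlap
#' (minimum 10 µm gap) strictly inside the tissue; phenotype cluster, hormone
#' fractions, CD45 counts and nuclei counts are drawn per the template and
#' recorded as ground truth columns (`true_*`).
#'
#' @param template a validated stage template.
#' @param tissue a [tissue_section()] with at least 1 mm² parenchyma.
#' @param seed integer seed.
#' @param max_retries placement attempts per islet before a placement error.
#' @return `data.frame` with geometry, metadata and ground-truth columns.
#' @export
generate_islets <- function(template, tissue, seed, max_retries = 200L) {
  tpl <- validate_stage_template(template)
  if (tissue$parenchymal_area_mm2 < 1) stop("tissue area must be >= 1 mm^2")
  with_seed(seed, {
    thin <- tpl$spatial_mode == "thinned_patches"
    keep_frac <- 1
    patches <- NULL
    if (thin) {
      th <- tpl$thinning
      keep_frac <- 1 - th$area_fraction * th$p_remove
      bb <- apply(tissue$boundary, 2, range)
      area_t <- tissue$parenchymal_area_mm2 * 1e6
      npatch <- max(1L, round(th$area_fraction * area_t / (pi * th$patch_radius_um^2)))
      px <- stats::runif(npatch, bb[1, 1], bb[2, 1])
      py <- stats::runif(npatch, bb[1, 2], bb[2, 2])
      patches <- cbind(px, py)
    }
    lambda <- tpl$islet_density_per_mm2 * tissue$parenchymal_area_mm2 / keep_frac
    n <- stats::rpois(1, lambda)
    if (n == 0) return(empty_islet_table())
    cl <- cluster_levels()
    mix <- unlist(tpl$cluster_mix)[cl]
    clusters <- sample(cl, n, replace = TRUE, prob = mix)
    mult <- unlist(tpl$size_multipliers)[cl]
    areas <- vapply(seq_len(n), function(i)
      draw_truncated_lognormal(1, tpl$size_lognormal$meanlog + log(mult[[clusters[i]]]),
                               tpl$size_lognormal$sdlog, tpl$min_islet_area_um2),
      numeric(1))
    shapes <- lapply(areas, make_islet_shape)
    rmax <- vapply(shapes, `[[`, numeric(1), "rmax")
    bb <- apply(tissue$boundary, 2, range)
    placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
    keep <- logical(n)
    cx <- numeric(n); cy <- numeric(n)
    gap <- 10
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        x <- stats::runif(1, bb[1, 1], bb[2, 1])
        y <- stats::runif(1, bb[1, 2], bb[2, 2])
        if (!points_in_poly(x, y, tissue$boundary)) next
        if (dist_to_poly(x, y, tissue$boundary) <= rmax[i] + 1) next
        if (length(placed_x)) {
          d <- sqrt((placed_x - x)^2 + (placed_y - y)^2)
          if (any(d < placed_r + rmax[i] + gap)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) stop("islet placement failed after ", max_retries,
                    " retries; density too high for tissue")
      # patch thinning removes (not relocates) islets inside thinned patches
      if (thin && nrow(patches) &&
          any((patches[, 1] - x)^2 + (patches[, 2] - y)^2 <
              tpl$thinning$patch_radius_um^2) &&
          stats::runif(1) < tpl$thinning$p_remove) {
        next
      }
      keep[i] <- TRUE
      cx[i] <- x; cy[i] <- y
      placed_x <- c(placed_x, x); placed_y <- c(placed_y, y)
      placed_r <- c(placed_r, rmax[i])
    }
    idx <- which(keep)
    if (!length(idx)) return(empty_islet_table())
    n2 <- length(idx)
    clusters <- clusters[idx]; areas <- areas[idx]
    shapes <- shapes[idx]; cx <- cx[idx]; cy <- cy[idx]
    # subset flags
    pfree <- gcg_def_free_prob(tpl)
    gcg_def <- clusters %in% c("III", "IV") |
      (clusters %in% c("I", "II") & stats::runif(n2) < pfree)
    sst_pos <- stats::runif(n2) < (tpl$p_SST_positive %||% 0.65)
    # hormone fractions
    prof <- t(vapply(seq_len(n2), function(i)
      draw_hormone_profile(clusters[i], gcg_def[i], sst_pos[i], tpl$hormone_rules),
      numeric(length(all_channels()))))
    colnames(prof) <- paste0("true_frac_", all_channels())
    # CD45 counts
    cdm <- tpl$cd45_model
    host <- clusters %in% c("II", "V-A")
    p_host <- sum(unlist(tpl$cluster_mix)[c("II", "V-A")])
    p_ins_cond <- if (p_host > 0) cdm$p_insulitic / p_host else 0
    insulitic <- host & stats::runif(n2) < p_ins_cond
    pany <- unlist(cdm$p_any)[clusters]
    any_cd45 <- insulitic | stats::runif(n2) < pany
    total <- integer(n2)
    total[insulitic] <- 15L + as.integer(stats::rnbinom(
      sum(insulitic), mu = cdm$insulitic_mu, size = cdm$insulitic_size))
    nonins <- any_cd45 & !insulitic
    # cap at 14 so p_insulitic is exactly the >= 15 crossing probability
    total[nonins] <- 1L + pmin(as.integer(stats::rnbinom(
      sum(nonins), mu = cdm$nb_mu, size = cdm$nb_size)), 13L)
    peri <- as.integer(stats::rbinom(n2, total, cdm$peri_share))
    intra <- total - peri
    nuclei <- pmax(1L, as.integer(round(
      areas / 1e6 * tpl$cell_density_per_mm2 * exp(stats::rnorm(n2, 0, 0.2)))))
    polys <- vapply(seq_len(n2), function(i) {
      p <- shapes[[i]]$poly
      polygon_to_wkt(cbind(p[, 1] + cx[i], p[, 2] + cy[i]))
    }, character(1))
    data.frame(
      id = seq_len(n2),
      donor_id = tissue$donor_id, region = tissue$region, stage = tissue$stage,
      centroid_x_um = cx, centroid_y_um = cy,
      area_um2 = areas,
      polygon_wkt = polys,
      true_cluster = clusters,
      true_gcg_deficient = gcg_def,
      true_sst_positive = sst_pos,
      prof,
      true_cd45_intra = intra, true_cd45_peri = peri,
      true_cd45_total = total,
      true_insulitic = insulitic,
      true_nuclei = nuclei,
      stringsAsFactors = FALSE)
  })
}

empty_islet_table <- function() {
  df <- data.frame(id = integer(), donor_id = character(), region = character(),
                   stage = character(), centroid_x_um = numeric(),
                   centroid_y_um = numeric(), area_um2 = numeric(),
                   polygon_wkt = character(), true_cluster = character(),
                   true_gcg_deficient = logical(), true_sst_positive = logical(),
                   stringsAsFactors = FALSE)
  for (ch in all_channels()) df[[paste0("true_frac_", ch)]] <- numeric(0)
  df$true_cd45_intra <- integer(0); df$true_cd45_peri <- integer(0)
  df$true_cd45_total <- integer(0); df$true_insulitic <- logical(0)
  df$true_nuclei <- integer(0)
  df
}

# draw one islet's per-channel area fractions, honoring the subset-defining
# constraints around the 1% threshold
draw_hormone_profile <- function(cluster, gcg_def, sst_pos, rules) {
  mu <- unlist(rules[[cluster]])[hormone_channels()]
  v <- pmin(0.97, pmax(0, mu * exp(stats::rnorm(length(mu), 0, 0.4))))
  names(v) <- hormone_channels()
  idi <- cluster %in% c("IV", "V-A", "V-BC")
  if (idi) {
    v["ProINS_total"] <- stats::runif(1, 0, 0.008)
    v["INS"] <- stats::runif(1, 0, 0.006)
    v["IAPP"] <- stats::runif(1, 0, 0.006)
  } else {
    v["ProINS_total"] <- max(v[["ProINS_total"]], 0.02)
    v["INS"] <- max(v[["INS"]], 0.015)
  }
  if (cluster %in% c("V-A", "V-BC")) {
    v["GCG"] <- max(v[["GCG"]], 0.02)
    v["ProGCG"] <- max(v[["ProGCG"]], 0.02)
  } else if (gcg_def) {
    v["GCG"] <- stats::runif(1, 0, 0.008)
    v["ProGCG"] <- stats::runif(1, 0, 0.008)
  } else {
    v["GCG"] <- max(v[["GCG"]], 0.02)
    v["ProGCG"] <- max(v[["ProGCG"]], 0.02)
  }
  if (cluster == "IV") v["PPY"] <- max(v[["PPY"]], 0.3)
  else if (cluster == "III") v["PPY"] <- max(v[["PPY"]], 0.05)
  else v["PPY"] <- stats::runif(1, 0, 0.008)
  v["SST"] <- if (sst_pos) max(v[["SST"]], 0.015) else stats::runif(1, 0, 0.008)
  # CHGA tops up the six defining channels so their union can tile the islet
  def_others <- sum(v[c("ProINS_total", "INS", "GCG", "SST", "PPY")])
  v["CHGA"] <- min(1, max(v[["CHGA"]], 1.05 - def_others))
  hi <- v[["ProINS_total"]] * stats::runif(1, 0.3, 0.7)
  c(v, ProINS_hi = hi)[all_channels()]
}

#' Render per-channel binary stain masks from an islet table
#'
#' Rasterizes each islet polygon and partitions its pixels into angular
#' sectors so that (a) the union of the six defining channels tiles the whole
#' islet and (b) each channel's pixel count matches the islet's ground-truth
#' fraction (to rounding). The high-proinsulin channel is nested inside total
#' proinsulin.
#'
#' @param islets islet table from [generate_islets()] (needs `polygon_wkt` and
#'   `true_frac_*` columns).
#' @param pixel_size_um pixel size, must be <= 5 µm so the smallest islet
#'   spans at least two pixels across.
#' @param channels channels to render (default all nine).
#' @param bbox optional `c(xmin, ymin, xmax, ymax)` grid extent (µm); default
#'   the islet bounding box padded by 5 pixels.
#' @return named list of [stain_mask()]s on a common grid.
#' @export
render_stain_masks <- function(islets, pixel_size_um, channels = all_channels(),
                               bbox = NULL) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0 || pixel_size_um > 5)
    stop("pixel_size_um must be in (0, 5] so the smallest islet spans >= 2 px")
  if (is.null(bbox)) {
    if (nrow(islets) == 0) bbox <- c(0, 0, 10 * pixel_size_um, 10 * pixel_size_um)
    else {
      polys <- lapply(islets$polygon_wkt, wkt_to_polygon)
      xs <- range(unlist(lapply(polys, function(p) p[, 1])))
      ys <- range(unlist(lapply(polys, function(p) p[, 2])))
      pad <- 5 * pixel_size_um
      bbox <- c(xs[1] - pad, ys[1] - pad, xs[2] + pad, ys[2] + pad)
    }
  }
  origin <- c(bbox[1], bbox[2])
  nc <- max(1L, ceiling((bbox[3] - bbox[1]) / pixel_size_um))
  nr <- max(1L, ceiling((bbox[4] - bbox[2]) / pixel_size_um))
  masks <- lapply(channels, function(ch)
    stain_mask(matrix(FALSE, nr, nc), pixel_size_um, origin, ch))
  names(masks) <- channels
  if (nrow(islets) == 0) return(masks)
  ref <- masks[[1]]
  nr <- nrow(ref$mask)
  defs <- defining_channels()
  for (i in seq_len(nrow(islets))) {
    poly <- wkt_to_polygon(islets$polygon_wkt[i])
    idx <- rasterize_polygon_idx(poly, ref)
    pix <- cbind((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
    npix <- nrow(pix)
    if (npix == 0) next
    cen <- poly_centroid(poly)
    gx <- origin[1] + (pix[, 2] - 0.5) * pixel_size_um
    gy <- origin[2] + (pix[, 1] - 0.5) * pixel_size_um
    ang <- atan2(gy - cen[2], gx - cen[1])
    # deterministic per-islet rotation of the sector layout
    ord <- order((ang + (islets$id[i] * 2.39996)) %% (2 * pi))
    pix <- pix[ord, , drop = FALSE]
    fr <- vapply(all_channels(),
                 function(ch) islets[[paste0("true_frac_", ch)]][i], numeric(1))
    fdef <- fr[defs]
    shares <- fdef / sum(fdef)
    bounds <- round(cumsum(c(0, shares)) * npix)
    centers <- floor((bounds[-1] + bounds[-length(bounds)]) / 2)
    names(centers) <- defs
    take <- function(center, k) {
      if (k <= 0) return(integer(0))
      ((center - floor(k / 2) + seq_len(k) - 1) %% npix) + 1L
    }
    sel <- list()
    for (ci in seq_along(defs)) {
      ch <- defs[ci]
      k <- round(fr[[ch]] * npix)
      # always cover the channel's own sector, then grow symmetrically
      wedge_len <- bounds[ci + 1] - bounds[ci]
      k <- max(k, 0L)
      if (k >= wedge_len && wedge_len > 0) {
        idxs <- take(centers[[ch]], k)
      } else {
        idxs <- if (wedge_len > 0) ((bounds[ci] + seq_len(min(k, wedge_len)) - 1) %% npix) + 1L
                else take(centers[[ch]], k)
      }
      sel[[ch]] <- idxs
    }
    sel[["IAPP"]] <- take(centers[["INS"]], round(fr[["IAPP"]] * npix))
    sel[["ProGCG"]] <- take(centers[["GCG"]], round(fr[["ProGCG"]] * npix))
    # nested high-proinsulin: innermost share of the total-proinsulin pixels
    kp <- length(sel[["ProINS_total"]])
    khi <- min(kp, round(fr[["ProINS_hi"]] * npix))
    sel[["ProINS_hi"]] <- if (khi > 0) sel[["ProINS_total"]][
      order(abs(seq_len(kp) - (kp + 1) / 2))[seq_len(khi)]] else integer(0)
    for (ch in channels) {
      idxs <- sel[[ch]]
      if (length(idxs))
        masks[[ch]]$mask[pix[idxs, , drop = FALSE]] <- TRUE
    }
  }
  masks
}

#' Generate nuclei and CD45+ cell points for an islet table
#'
#' Places each islet's ground-truth nuclei and intra-islet CD45+ cells
#' uniformly inside its polygon, peri-islet CD45+ cells and nuclei in the
#' islet's share of the 20 µm expansion band (watershed-consistent: a peri
#' point is nearer to its own islet than to any other), and records nothing
#' outside these regions.
#'
#' @param islets islet table from [generate_islets()].
#' @param template the stage template (peri nuclei density reuses
#'   `cell_density_per_mm2`).
#' @param seed integer seed.
#' @param margin_um peri-islet band width (µm, default 20).
#' @return `data.frame` with `x_um`, `y_um`, `class` (`"CD45"`/`"nucleus"`).
#' @export
generate_cells <- function(islets, template, seed, margin_um = 20) {
  tpl <- validate_stage_template(template)
  if (nrow(islets) == 0)
    return(data.frame(x_um = numeric(), y_um = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  with_seed(seed, {
    polys <- lapply(islets$polygon_wkt, wkt_to_polygon)
    cx <- islets$centroid_x_um; cy <- islets$centroid_y_um
    rmax <- vapply(seq_along(polys), function(i)
      sqrt(max((polys[[i]][, 1] - cx[i])^2 + (polys[[i]][, 2] - cy[i])^2)),
      numeric(1))
    out <- vector("list", nrow(islets))
    for (i in seq_len(nrow(islets))) {
      poly <- polys[[i]]
      nin <- islets$true_nuclei[i]
      cin <- islets$true_cd45_intra[i]
      pts_in <- sample_in_polygon(nin + cin, poly)
      nb <- which(sqrt((cx - cx[i])^2 + (cy - cy[i])^2) <
                    rmax + rmax[i] + 2 * margin_um + 1)
      nb <- setdiff(nb, i)
      ann_area <- peri_annulus_area(poly, margin_um)  # rough, for nuclei count
      nper <- stats::rpois(1, ann_area / 1e6 * tpl$cell_density_per_mm2)
      cper <- islets$true_cd45_peri[i]
      pts_out <- sample_in_annulus(nper + cper, i, polys, nb, margin_um)
      xy <- rbind(pts_in, pts_out)
      cls <- c(rep("nucleus", nin), rep("CD45", cin),
               rep("nucleus", nrow(pts_out) - cper), rep("CD45", cper))
      out[[i]] <- data.frame(x_um = xy[, 1], y_um = xy[, 2], class = cls,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

sample_in_polygon <- function(n, poly, max_iter = 200L) {
  if (n <= 0) return(matrix(numeric(0), 0, 2))
  bb <- apply(poly, 2, range)
  got <- matrix(numeric(0), 0, 2)
  for (it in seq_len(max_iter)) {
    m <- max(16L, 2L * (n - nrow(got)))
    x <- stats::runif(m, bb[1, 1], bb[2, 1])
    y <- stats::runif(m, bb[1, 2], bb[2, 2])
    ok <- points_in_poly(x, y, poly) & dist_to_poly(x, y, poly) > 0.5
    got <- rbind(got, cbind(x[ok], y[ok]))
    if (nrow(got) >= n) return(got[seq_len(n), , drop = FALSE])
  }
  got  # pathological polygon: return what we have
}

peri_annulus_area <- function(poly, margin_um) {
  poly_perimeter(poly) * margin_um  # first-order band area estimate
}

sample_in_annulus <- function(n, i, polys, nb, margin_um, max_iter = 400L) {
  if (n <= 0) return(matrix(numeric(0), 0, 2))
  poly <- polys[[i]]
  bb <- apply(poly, 2, range)
  bb[1, ] <- bb[1, ] - margin_um; bb[2, ] <- bb[2, ] + margin_um
  got <- matrix(numeric(0), 0, 2)
  for (it in seq_len(max_iter)) {
    m <- max(16L, 4L * (n - nrow(got)))
    x <- stats::runif(m, bb[1, 1], bb[2, 1])
    y <- stats::runif(m, bb[1, 2], bb[2, 2])
    d <- dist_to_poly(x, y, poly)
    ok <- !points_in_poly(x, y, poly) & d > 0.5 & d <= margin_um - 0.5
    if (length(nb)) {
      for (j in nb) {
        if (!any(ok)) break
        dj <- dist_to_poly(x, y, polys[[j]], signed = TRUE)
        ok <- ok & dj > d  # watershed: stay nearer to own islet
      }
    }
    got <- rbind(got, cbind(x[ok], y[ok]))
    if (nrow(got) >= n) return(got[seq_len(n), , drop = FALSE])
  }
  got
}
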