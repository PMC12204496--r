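#' Per-islet hormone staining area fractions
#'
#' For each of the nine channels, the stained pixel area inside the islet
#' polygon divided by the islet pixel area; `endocrine_union` is the area of
#' the union of the eight hormone stains over the islet area.
#'
#' @param islets islet table with a `polygon_wkt` column.
#' @param channel_masks named list of [stain_mask()]s on one grid; must
#'   contain all of [all_channels()] (a missing channel is an error, never a
#'   silent zero).
#' @return `data.frame`: `islet_id`, one `frac_<channel>` column per channel,
#'   and `frac_endocrine_union`.
#' @export
hormone_profiles <- function(islets, channel_masks) {
  need <- all_channels()
  miss <- setdiff(need, names(channel_masks))
  if (length(miss))
    stop("missing channel mask(s): ", paste(miss, collapse = ", "))
  ref <- channel_masks[[need[1]]]
  for (ch in need)
    if (!same_grid(ref, channel_masks[[ch]]))
      stop("channel masks are not co-registered on one pixel grid")
  out <- vector("list", nrow(islets))
  for (i in seq_len(nrow(islets))) {
    poly <- wkt_to_polygon(islets$polygon_wkt[i])
    idx <- rasterize_polygon_idx(poly, ref)
    n <- length(idx)
    fr <- vapply(need, function(ch) {
      if (n == 0) return(0)
      sum(channel_masks[[ch]]$mask[idx]) / n
    }, numeric(1))
    un <- if (n == 0) 0 else {
      u <- rep(FALSE, n)
      for (ch in hormone_channels()) u <- u | channel_masks[[ch]]$mask[idx]
      sum(u) / n
    }
    row <- as.data.frame(as.list(fr))
    names(row) <- paste0("frac_", need)
    row$frac_endocrine_union <- un
    row$islet_id <- islets$id[i]
    out[[i]] <- row
  }
  if (!length(out)) {
    df <- data.frame(islet_id = integer())
    for (ch in need) df[[paste0("frac_", ch)]] <- numeric(0)
    df$frac_endocrine_union <- numeric(0)
    return(df)
  }
  df <- do.call(rbind, out)
  df[, c("islet_id", setdiff(names(df), "islet_id"))]
}

#' Pairwise overlap of hormone stains within an islet
#'
#' Jaccard index \eqn{J(A,B) = |A \cap B| / |A \cup B|} (0 by convention when
#' the union is empty) and directional double-positive fraction
#' \eqn{|A \cap B| / |A|} for every ordered pair of the eight hormone stains
#' (56 pairs), on stained pixels inside the islet polygon.
#'
#' @param islet one islet row (with `polygon_wkt`).
#' @param channel_masks named list of co-registered [stain_mask()]s.
#' @return `data.frame`: `channel_a`, `channel_b`, `jaccard`,
#'   `double_positive_frac`.
#' @export
jaccard_pairs <- function(islet, channel_masks) {
  chs <- hormone_channels()
  miss <- setdiff(chs, names(channel_masks))
  if (length(miss)) stop("missing channel mask(s): ", paste(miss, collapse = ", "))
  poly <- wkt_to_polygon(islet$polygon_wkt)
  ref <- channel_masks[[chs[1]]]
  idx <- rasterize_polygon_idx(poly, ref)
  inmask <- lapply(chs, function(ch) channel_masks[[ch]]$mask[idx])
  names(inmask) <- chs
  rows <- list()
  for (a in chs) for (b in chs) {
    if (a == b) next
    inter <- sum(inmask[[a]] & inmask[[b]])
    un <- sum(inmask[[a]] | inmask[[b]])
    na <- sum(inmask[[a]])
    rows[[length(rows) + 1L]] <- data.frame(
      channel_a = a, channel_b = b,
      jaccard = if (un == 0) 0 else inter / un,
      double_positive_frac = if (na == 0) 0 else inter / na,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Classify islet subsets at the 1% staining threshold
#'
#' Deficiency is strict (`< threshold`), positivity inclusive
#' (`>= threshold`): insulin-deficient islets (IDIs) have <1% total
#' proinsulin content, GCG-deficient islets <1% glucagon content; PPY/SST
#' positivity at >=1%.
#'
#' @param profiles output of [hormone_profiles()] (or any data.frame with
#'   `frac_ProINS_total`, `frac_GCG`, `frac_PPY`, `frac_SST`).
#' @param threshold area-fraction threshold (default 0.01).
#' @return `data.frame`: `islet_id`, `is_IDI`, `is_GCG_deficient`,
#'   `is_PPY_positive`, `is_SST_positive`.
#' @export
classify_subsets <- function(profiles, threshold = 0.01) {
  need <- c("frac_ProINS_total", "frac_GCG", "frac_PPY", "frac_SST")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) stop("profile missing column(s): ", paste(miss, collapse = ", "))
  data.frame(
    islet_id = profiles$islet_id %||% seq_len(nrow(profiles)),
    is_IDI = profiles$frac_ProINS_total < threshold,
    is_GCG_deficient = profiles$frac_GCG < threshold,
    is_PPY_positive = profiles$frac_PPY >= threshold,
    is_SST_positive = profiles$frac_SST >= threshold)
}

#' Per-section summaries of islet and hormone content
#'
#' Cumulative stained channel areas (sum over islets of islet area times
#' channel fraction), islet density per mm² parenchyma, relative islet area
#' as a percentage of parenchyma, and the INS:GCG cumulative area ratio
#' (flagged undefined when the GCG area is zero).
#'
#' @param islets islet table (needs `area_um2`).
#' @param profiles matching [hormone_profiles()] table.
#' @param tissue a [tissue_section()] with positive parenchymal area.
#' @return one-row `data.frame` of summaries plus `cum_area_<channel>_um2`
#'   columns.
#' @export
section_summaries <- function(islets, profiles, tissue) {
  if (tissue$parenchymal_area_mm2 <= 0) stop("parenchymal area must be positive")
  amm2 <- tissue$parenchymal_area_mm2
  n <- nrow(islets)
  base <- data.frame(
    donor_id = tissue$donor_id, region = tissue$region, stage = tissue$stage,
    n_islets = n,
    islet_density_per_mm2 = n / amm2,
    relative_islet_area_pct = sum(islets$area_um2) / (amm2 * 1e6) * 100,
    stringsAsFactors = FALSE)
  cums <- numeric(length(all_channels()))
  names(cums) <- all_channels()
  if (n > 0) {
    ord <- match(islets$id, profiles$islet_id)
    for (ch in all_channels())
      cums[ch] <- sum(islets$area_um2 * profiles[[paste0("frac_", ch)]][ord])
  }
  ins <- cums[["INS"]]; gcg <- cums[["GCG"]]
  base$ins_gcg_ratio <- if (n == 0 || gcg == 0) NA_real_ else ins / gcg
  base$ins_gcg_undefined <- n == 0 || gcg == 0
  cum_df <- as.data.frame(as.list(cums))
  names(cum_df) <- paste0("cum_area_", all_channels(), "_um2")
  cbind(base, cum_df)
}

#' Endocrine mass estimate from a relative staining area
#'
#' `mass_mg = relative_fraction * region_weight_g * 1000`; a missing weight
#' yields the `NA` missing-data sentinel, never zero.
#'
#' @param relative_fraction staining area as a fraction of parenchyma, \[0,1\].
#' @param region_weight_g regional pancreas weight (g), possibly `NA`.
#' @return mass in mg (NA when the weight is missing).
#' @export
estimate_mass <- function(relative_fraction, region_weight_g) {
  if (any(relative_fraction < 0 | relative_fraction > 1, na.rm = TRUE))
    stop("relative_fraction must lie in [0, 1]")
  ifelse(is.na(region_weight_g), NA_real_,
         relative_fraction * region_weight_g * 1000)
}

#' Size-binned islet property profiles with exponential fits
#'
#' Islet sizes are stratified into `n_bins` equal-width bins of log2(area)
#' spanning the observed range; per-bin property means are fitted with
#' \eqn{y = a e^{b x}} (x = log2 area) by least squares on the bin means.
#'
#' @param islets islet table (needs `area_um2`).
#' @param properties data.frame of per-islet properties aligned with
#'   `islets` rows (numeric columns).
#' @param n_bins number of log2-size bins (default 14).
#' @return list with `bins` (per-bin, per-property means and counts) and
#'   `fits` (per-property `a`, `b`, `r_squared`, or `NA` when fewer than two
#'   non-empty bins).
#' @export
size_binned_profile <- function(islets, properties, n_bins = 14) {
  stopifnot(nrow(islets) == nrow(properties))
  x <- log2(islets$area_um2)
  br <- seq(min(x), max(x), length.out = n_bins + 1L)
  br[length(br)] <- br[length(br)] + 1e-9
  bin <- findInterval(x, br, rightmost.closed = TRUE)
  bin[bin > n_bins] <- n_bins
  mids <- (br[-1] + br[-length(br)]) / 2
  counts <- tabulate(bin, nbins = n_bins)
  bins <- data.frame(bin = seq_len(n_bins), log2_area_mid = mids,
                     n_islets = counts,
                     total_area_um2 = vapply(seq_len(n_bins), function(b)
                       sum(islets$area_um2[bin == b]), numeric(1)))
  fits <- list()
  for (p in names(properties)) {
    m <- vapply(seq_len(n_bins), function(b) {
      v <- properties[[p]][bin == b]
      if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    }, numeric(1))
    bins[[paste0("mean_", p)]] <- m
    ok <- !is.na(m) & counts > 0
    if (sum(ok) < 2) {
      warning("fewer than 2 non-empty bins for '", p, "': fit skipped")
      fits[[p]] <- list(a = NA_real_, b = NA_real_, r_squared = NA_real_)
      next
    }
    fits[[p]] <- fit_exponential(mids[ok], m[ok])
  }
  list(bins = bins, fits = fits)
}

# least-squares fit of y = a exp(b x); log-linear start, Gauss-Newton refine
fit_exponential <- function(x, y) {
  pos <- y > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(y[pos]) ~ x[pos])
    a0 <- exp(stats::coef(lf)[[1]]); b0 <- stats::coef(lf)[[2]]
  } else {
    a0 <- max(mean(y), 1e-6); b0 <- 0
  }
  fit <- tryCatch(
    stats::nls(y ~ a * exp(b * x), start = list(a = a0, b = b0),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pred <- a0 * exp(b0 * x)
    a <- a0; b <- b0
  } else {
    a <- stats::coef(fit)[["a"]]; b <- stats::coef(fit)[["b"]]
    pred <- stats::predict(fit)
  }
  ssr <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  list(a = a, b = b, r_squared = if (sst > 0) 1 - ssr / sst else 1)
}
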