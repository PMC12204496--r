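# Shared fixtures: templates and fast islet-table annotation.

with_seed <- isletmap:::with_seed

# A deliberately well-separated six-cluster template: every cluster differs
# from its neighbors on several feature axes (hormone composition and CD45
# burden), as required for the cluster-recovery checks.
separated_template <- function(density = 15) {
  tpl <- load_stage_template("Ctrl", "PT")
  tpl$cluster_mix <- list("I" = 0.2, "II" = 0.2, "III" = 0.15, "IV" = 0.15,
                          "V-A" = 0.15, "V-BC" = 0.15)
  tpl$frac_IDI <- 0.45
  tpl$frac_PPY_dominant <- 0.15
  tpl$frac_GCG_deficient <- 0.30   # forced clusters only, none in I/II
  tpl$p_SST_positive <- 1
  tpl$islet_density_per_mm2 <- density
  tpl$cd45_model$p_any <- list("I" = 0, "II" = 1, "III" = 0, "IV" = 0,
                               "V-A" = 1, "V-BC" = 0)
  tpl$cd45_model$nb_mu <- 12
  tpl$cd45_model$nb_size <- 50
  tpl$hormone_rules <- list(
    "I"    = list(CHGA = 0.85, ProINS_total = 0.50, INS = 0.40, IAPP = 0.35,
                  ProGCG = 0.25, GCG = 0.20, SST = 0.08, PPY = 0.004),
    "II"   = list(CHGA = 0.85, ProINS_total = 0.15, INS = 0.12, IAPP = 0.05,
                  ProGCG = 0.25, GCG = 0.20, SST = 0.08, PPY = 0.004),
    "III"  = list(CHGA = 0.60, ProINS_total = 0.35, INS = 0.30, IAPP = 0.25,
                  ProGCG = 0.004, GCG = 0.003, SST = 0.08, PPY = 0.30),
    "IV"   = list(CHGA = 0.20, ProINS_total = 0.003, INS = 0.002, IAPP = 0.002,
                  ProGCG = 0.003, GCG = 0.003, SST = 0.08, PPY = 0.80),
    "V-A"  = list(CHGA = 0.80, ProINS_total = 0.003, INS = 0.002, IAPP = 0.002,
                  ProGCG = 0.15, GCG = 0.35, SST = 0.30, PPY = 0.004),
    "V-BC" = list(CHGA = 0.80, ProINS_total = 0.002, INS = 0.002, IAPP = 0.002,
                  ProGCG = 0.55, GCG = 0.40, SST = 0.05, PPY = 0.004))
  validate_stage_template(tpl)
}

# A clean size-distribution template: unit size multipliers and negligible
# truncation mass, so the closed-form log-normal median exp(mu) applies.
clean_size_template <- function() {
  tpl <- load_stage_template("Ctrl", "PT")
  tpl$size_lognormal <- list(meanlog = 9, sdlog = 0.5)
  tpl$size_multipliers <- as.list(stats::setNames(rep(1, 6), cluster_levels()))
  tpl$islet_density_per_mm2 <- 10
  validate_stage_template(tpl)
}

# Annotate a generated islet table with the measured-column names the
# downstream stages expect, directly from ground truth (bypasses rendering
# for tests that exercise later stages only).
annotate_from_truth <- function(isl) {
  for (ch in all_channels())
    isl[[paste0("frac_", ch)]] <- isl[[paste0("true_frac_", ch)]]
  isl$frac_endocrine_union <- pmin(1, isl$true_frac_CHGA + 0.05)
  if (nrow(isl) >= 3) {
    dm <- delaunay_metrics(isl[, c("centroid_x_um", "centroid_y_um")])
    isl$mean_delaunay_area_um2 <- dm$mean_area_um2
  } else {
    isl$mean_delaunay_area_um2 <- pi * 8000^2
  }
  isl$cd45_total <- isl$true_cd45_total
  isl$circularity <- vapply(isl$polygon_wkt, function(w)
    shape_descriptors(wkt_to_polygon(w))[["circularity"]], numeric(1))
  isl
}

binom_se <- function(p, n) sqrt(p * (1 - p) / n)

square_mask <- function(nr, nc, px = 1, channel = "stain") {
  stain_mask(matrix(FALSE, nr, nc), px, channel = channel)
}
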