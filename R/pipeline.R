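#' Pipeline configuration
#'
#' All numeric defaults equal the published analysis settings: minimum islet
#' area 1,000 µm², tissue border margin 10 µm, peri-islet band 20 µm, subset
#' threshold 1%, insulitis thresholds 15 CD45 / 3 islets, Delaunay search
#' radii 4,000 µm (slide) and 8 mm (cluster scope), UMAP 50 / 0.1 / 1000,
#' DBSCAN (0.5, 50) and (0.2, 20), Ripley radii 400-10,000 µm. Units are µm
#' throughout; `seed` is the master seed for every stochastic stage.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_islet_area_um2 = 1000,
    border_margin_um = 10,
    peri_margin_um = 20,
    subset_threshold = 0.01,
    insulitis_islet_threshold = 15,
    insulitis_donor_threshold = 3,
    delaunay_max_radius_um = 4000,
    cluster_delaunay_max_radius_mm = 8,
    umap_n_neighbors = 50,
    umap_min_dist = 0.1,
    umap_n_epochs = 1000,
    dbscan_eps1 = 0.5, dbscan_minpts1 = 50,
    dbscan_eps2 = 0.2, dbscan_minpts2 = 20,
    ripley_from_um = 400, ripley_to_um = 10000, ripley_n = 25,
    pixel_size_um = 2,
    peri_raster_um = 2,
    compute_peri_areas = TRUE,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Synthesize a multi-donor cohort of sections
#'
#' For each donor and region, generates a tissue polygon, an islet table with
#' ground truth, rendered stain masks and cell points from the shipped stage
#' templates. Donor-level variability jitters the cluster mixture on the
#' logit scale (`donor_jitter_sd`).
#'
#' @param donors_per_group named integer vector, e.g.
#'   `c(Ctrl = 2, AAb = 2, T1DS = 2, T1DL = 2)`.
#' @param seed master seed.
#' @param regions regions per donor (default both `"PT"` and `"PH"`).
#' @param width_mm,height_mm,irregularity tissue geometry.
#' @param pixel_size_um mask rendering resolution.
#' @param density_scale multiplies template islet densities (scaled-down test
#'   cohorts).
#' @return list of sections, each `list(tissue, islets, masks, cells)`.
#' @export
synthesize_cohort <- function(donors_per_group = c(Ctrl = 2, AAb = 2,
                                                   T1DS = 2, T1DL = 2),
                              seed = 1, regions = c("PT", "PH"),
                              width_mm = 4, height_mm = 4, irregularity = 0.2,
                              pixel_size_um = 2, density_scale = 1) {
  sections <- list()
  di <- 0L
  for (stage in names(donors_per_group)) {
    for (d in seq_len(donors_per_group[[stage]])) {
      di <- di + 1L
      donor_id <- sprintf("%s_%02d", stage, d)
      for (region in regions) {
        tpl <- load_stage_template(stage, region)
        s_sec <- child_seed(seed, di * 100 + match(region, c("PT", "PH")))
        tpl2 <- jitter_template(tpl, child_seed(s_sec, 1))
        tissue <- generate_tissue(child_seed(s_sec, 2), width_mm, height_mm,
                                  irregularity, region = region,
                                  donor_id = donor_id, stage = stage,
                                  pancreas_region_weight_g = 30)
        tpl2$islet_density_per_mm2 <- tpl2$islet_density_per_mm2 * density_scale
        islets <- generate_islets(tpl2, tissue, child_seed(s_sec, 3))
        masks <- render_stain_masks(islets, pixel_size_um,
                                    bbox = c(0, 0, width_mm * 1000, height_mm * 1000))
        cells <- generate_cells(islets, tpl2, child_seed(s_sec, 4))
        sections[[paste(donor_id, region, sep = "_")]] <-
          list(tissue = tissue, islets = islets, masks = masks, cells = cells)
      }
    }
  }
  sections
}

# donor-level logit jitter of the cluster mixture (renormalized); the
# subset-fraction fields are re-derived so the template stays consistent
jitter_template <- function(tpl, seed) {
  sd <- tpl$donor_jitter_sd %||% 0
  if (sd <= 0) return(tpl)
  pfree0 <- max(0, min(1, gcg_def_free_prob(tpl)))
  with_seed(seed, {
    mix <- unlist(tpl$cluster_mix)[cluster_levels()]
    lg <- log(pmax(mix, 1e-6)) + stats::rnorm(length(mix), 0, sd)
    mix2 <- exp(lg) / sum(exp(lg))
    tpl$cluster_mix <- as.list(mix2)
    tpl$frac_IDI <- unname(sum(mix2[c("IV", "V-A", "V-BC")]))
    tpl$frac_PPY_dominant <- unname(mix2[["IV"]])
    # keep the free-cluster conditional deficiency probability fixed
    forced <- sum(mix2[c("III", "IV")])
    free <- sum(mix2[c("I", "II")])
    tpl$frac_GCG_deficient <- unname(min(1, forced + free * pfree0))
    validate_stage_template(tpl)
  })
}

#' Run the full analysis pipeline on a cohort of sections
#'
#' Stage order: segmentation, hormone quantification, subset classification,
#' immune attribution, slide Delaunay and Ripley statistics, pooled UMAP +
#' two-round DBSCAN clustering with semantic label mapping (plus the
#' rule-based key), cluster-scoped Delaunay, insulitis diagnosis, and the
#' cohort report. Identical inputs and seed give identical outputs.
#'
#' @param sections list of sections (`list(tissue, masks, cells)`, e.g. from
#'   [synthesize_cohort()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list: `islets` (pooled annotated table), `sections` (per-section
#'   summaries incl. Ripley AUC and fractal dimension), `donors` (insulitis
#'   diagnoses), `clusters` (magnitude tables), `cluster_spatial`,
#'   `manifest`.
#' @export
run_pipeline <- function(sections, config = pipeline_config(), out_dir = NULL) {
  stopifnot(length(sections) >= 1)
  counters <- list()
  pooled <- list()
  section_rows <- list()
  for (nm in names(sections)) {
    sec <- sections[[nm]]
    if (is.null(sec$tissue) || is.null(sec$masks) || is.null(sec$cells))
      stop("section '", nm, "' must provide tissue, masks and cells")
    defs <- sec$masks[defining_channels()]
    if (any(vapply(defs, is.null, logical(1))))
      stop("section '", nm, "' missing defining channel mask(s)")
    islets <- build_islets(defs, sec$tissue,
                           min_islet_area_um2 = config$min_islet_area_um2,
                           border_margin_um = config$border_margin_um)
    counters[[nm]] <- c(n_islets = nrow(islets))
    if (nrow(islets) == 0) next
    islets$donor_id <- sec$tissue$donor_id
    islets$region <- sec$tissue$region
    islets$stage <- sec$tissue$stage
    prof <- hormone_profiles(islets, sec$masks)
    islets <- cbind(islets, prof[match(islets$id, prof$islet_id),
                                 setdiff(names(prof), "islet_id")])
    subs <- classify_subsets(prof, threshold = config$subset_threshold)
    islets <- cbind(islets, subs[match(islets$id, subs$islet_id),
                                 setdiff(names(subs), "islet_id")])
    att <- attribute_cells(islets, sec$cells, margin_um = config$peri_margin_um)
    rec <- att$records
    if (config$compute_peri_areas) {
      peri <- expand_peri_regions(islets, sec$tissue,
                                  margin_um = config$peri_margin_um,
                                  pixel_size_um = config$peri_raster_um)
      rec$peri_area_um2 <- peri$peri_area_um2[match(rec$islet_id, peri$islet_id)]
    }
    islets <- cbind(islets, rec[match(islets$id, rec$islet_id),
                                setdiff(names(rec), "islet_id")])
    dm <- delaunay_metrics(islets[, c("centroid_x_um", "centroid_y_um")],
                           max_radius_um = config$delaunay_max_radius_um)
    islets$mean_delaunay_distance_um <- dm$mean_distance_um
    islets$mean_delaunay_area_um2 <- dm$mean_area_um2
    islets$delaunay_fallback <- dm$is_fallback
    radii <- ripley_radii(config$ripley_from_um, config$ripley_to_um,
                          config$ripley_n)
    rip_auc <- NA_real_; fdim <- NA_real_
    if (nrow(islets) >= 2) {
      curve <- ripley_modified(islets[, c("centroid_x_um", "centroid_y_um")],
                               sec$tissue, radii)
      rip_auc <- attr(curve, "auc")
      fdim <- tryCatch(fractal_dimension(curve)$slope, error = function(e) NA_real_)
    }
    ss <- section_summaries(islets, prof, sec$tissue)
    ss$ripley_auc <- rip_auc
    ss$fractal_dimension <- fdim
    ss$frac_IDI <- mean(islets$is_IDI)
    ss$frac_GCG_deficient <- mean(islets$is_GCG_deficient)
    ss$frac_PPY_positive <- mean(islets$is_PPY_positive)
    ss$prevalence_cd45_ge1 <- mean(islets$cd45_total >= 1)
    ss$islet_mass_mg <- estimate_mass(
      ss$relative_islet_area_pct / 100,
      sec$tissue$pancreas_region_weight_g)
    ss$section <- nm
    section_rows[[nm]] <- ss
    islets$section <- nm
    pooled[[nm]] <- islets
  }
  if (!length(pooled)) stop("no islets recovered from any section")
  islets <- do.call(rbind, pooled)
  rownames(islets) <- NULL
  # pooled clustering
  feats <- assemble_features(islets)
  if (nrow(feats) >= config$umap_n_neighbors + 1) {
    emb <- embed_umap(feats, n_neighbors = config$umap_n_neighbors,
                      min_dist = config$umap_min_dist,
                      n_epochs = config$umap_n_epochs, seed = config$seed)
    asg <- cluster_two_round(emb, config$dbscan_eps1, config$dbscan_minpts1,
                             config$dbscan_eps2, config$dbscan_minpts2)
    mapped <- map_cluster_labels(asg, islets, threshold = config$subset_threshold)
    islets$umap_1 <- emb[, 1]; islets$umap_2 <- emb[, 2]
    islets$dbscan_major <- asg$major
    islets$subcluster <- asg$subcluster
    islets$cluster <- mapped$labels
    map_report <- mapped$report
  } else {
    warning("too few islets for UMAP (need ", config$umap_n_neighbors + 1,
            "); cluster labels fall back to the rule-based key")
    islets$cluster <- rule_based_key(islets, islets$cd45_total,
                                     threshold = config$subset_threshold)
    map_report <- NULL
  }
  islets$cluster_key <- rule_based_key(islets, islets$cd45_total,
                                       threshold = config$subset_threshold)
  # insulitis across each donor's sections
  ins <- call_insulitis(islets,
                        islet_threshold = config$insulitis_islet_threshold,
                        donor_threshold = config$insulitis_donor_threshold)
  islets$insulitic <- ins$records$insulitic
  # cluster-scoped Delaunay per section
  cl_spatial <- lapply(names(pooled), function(nm) {
    sub <- islets[islets$section == nm, , drop = FALSE]
    cd <- cluster_delaunay(sub[, c("centroid_x_um", "centroid_y_um")],
                           sub$cluster, donors = sub$donor_id,
                           max_radius_mm = config$cluster_delaunay_max_radius_mm)
    cd$summary$section <- nm
    cd$summary
  })
  cl_spatial <- do.call(rbind, cl_spatial)
  clusters <- cluster_summaries(islets)
  sections_df <- do.call(rbind, section_rows)
  rownames(sections_df) <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("isletmap")),
    config = unclass(config),
    n_sections = length(sections),
    n_islets = nrow(islets),
    per_section_counts = counters)
  res <- list(islets = islets, sections = sections_df, donors = ins$donors,
              clusters = clusters, cluster_spatial = cl_spatial,
              map_report = map_report, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_islet_table(islets, file.path(out_dir, "islets.csv"))
    utils::write.csv(sections_df, file.path(out_dir, "sections.csv"),
                     row.names = FALSE)
    utils::write.csv(ins$donors, file.path(out_dir, "insulitis.csv"),
                     row.names = FALSE)
    utils::write.csv(clusters$cells, file.path(out_dir, "cluster_cells.csv"),
                     row.names = FALSE)
    utils::write.csv(cl_spatial, file.path(out_dir, "cluster_spatial.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
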