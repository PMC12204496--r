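test_that("generate_tissue honors its contract", {
  t0 <- generate_tissue(1, 20, 20, 0)
  expect_equal(t0$parenchymal_area_mm2, 400)
  expect_equal(nrow(t0$boundary), 4)
  # determinism
  a <- generate_tissue(1, 20, 20, 0.3)
  b <- generate_tissue(1, 20, 20, 0.3)
  expect_identical(a$boundary, b$boundary)
  # area bounds at irregularity 0.3 (shoelace oracle inside poly_area)
  for (s in 2:6) {
    tt <- generate_tissue(s, 20, 20, 0.3)
    expect_gte(tt$parenchymal_area_mm2, 0.5 * 400)
    expect_lte(tt$parenchymal_area_mm2, 400)
  }
  expect_error(generate_tissue(1, -1, 20), "positive")
  expect_error(generate_tissue(1, 20, 0), "positive")
  expect_error(generate_tissue(1, 20, 20, 2), "irregularity")
})

test_that("generate_islets: determinism, counts, constraints", {
  tpl <- load_stage_template("Ctrl", "PT")
  tis <- generate_tissue(3, 5, 5, 0.1)
  a <- generate_islets(tpl, tis, 7)
  b <- generate_islets(tpl, tis, 7)
  expect_identical(a, b)
  expect_true(all(a$area_um2 >= 1000))
  # all geometry strictly inside the tissue
  for (i in seq_len(nrow(a))) {
    poly <- wkt_to_polygon(a$polygon_wkt[i])
    expect_true(all(points_in_poly(poly[, 1], poly[, 2], tis$boundary)))
  }
  expect_true(all(points_in_poly(a$centroid_x_um, a$centroid_y_um,
                                 tis$boundary)))
  # pairwise disjoint with a gap (conservative circle check on sampled pairs)
  if (nrow(a) >= 2) {
    d <- as.matrix(dist(a[, c("centroid_x_um", "centroid_y_um")]))
    diag(d) <- Inf
    expect_gt(min(d), 2 * sqrt(min(a$area_um2) / pi))
  }
  # density 0 -> empty table
  tpl0 <- tpl; tpl0$islet_density_per_mm2 <- 0
  expect_equal(nrow(generate_islets(tpl0, tis, 1)), 0)
  # overfull packing -> placement error
  tplx <- tpl; tplx$islet_density_per_mm2 <- 500
  expect_error(generate_islets(tplx, generate_tissue(1, 1.2, 1.2, 0), 1,
                               max_retries = 20L), "placement")
})

test_that("generate_islets recovers configured fractions (3 SE) and counts", {
  tpl <- load_stage_template("Ctrl", "PT")
  tpl$islet_density_per_mm2 <- 10
  tis <- generate_tissue(4, 12, 12, 0)
  isl <- generate_islets(tpl, tis, 11)
  n <- nrow(isl)
  expect_gte(n, 1000)
  # Poisson count (4 SD guard band)
  lam <- 10 * tis$parenchymal_area_mm2
  expect_lt(abs(n - lam), 4 * sqrt(lam))
  # configured subset fractions via the ground truth labels
  expect_lt(abs(mean(isl$true_frac_ProINS_total < 0.01) - tpl$frac_IDI),
            3 * binom_se(tpl$frac_IDI, n))
  expect_lt(abs(mean(isl$true_frac_GCG < 0.01) - tpl$frac_GCG_deficient),
            3 * binom_se(tpl$frac_GCG_deficient, n))
  expect_lt(abs(mean(isl$true_cluster == "IV") - tpl$frac_PPY_dominant),
            3 * binom_se(tpl$frac_PPY_dominant, n))
  prev <- implied_cd45_prevalence(tpl)
  expect_lt(abs(mean(isl$true_cd45_total >= 1) - prev), 3 * binom_se(prev, n))
})

test_that("size distribution median matches the log-normal closed form", {
  tpl <- clean_size_template()
  tis <- generate_tissue(5, 15, 15, 0)
  isl <- generate_islets(tpl, tis, 13)
  expect_gte(nrow(isl), 2000)
  expect_lt(abs(median(isl$area_um2) / exp(9) - 1), 0.05)
})

test_that("render_stain_masks meets its area and separation contracts", {
  # single circular islet of 10,000 um^2 at 1 um/px
  r <- sqrt(1e4 / pi)
  circ <- circle_polygon(200, 200, r, 96)
  circ <- circ * sqrt(1e4 / poly_area(circ))  # exact area
  isl <- data.frame(id = 1L, centroid_x_um = 200, centroid_y_um = 200,
                    polygon_wkt = polygon_to_wkt(circ))
  for (ch in all_channels()) isl[[paste0("true_frac_", ch)]] <- 0
  isl$true_frac_CHGA <- 1
  isl$true_frac_GCG <- 0.5
  m <- render_stain_masks(isl, 1)
  npx <- sum(m$CHGA$mask)
  expect_gte(npx, 9000); expect_lte(npx, 11000)
  expect_equal(sum(m$INS$mask), 0)             # zero fraction -> empty channel
  expect_lt(abs(sum(m$GCG$mask) / npx - 0.5), 0.1)
  expect_error(render_stain_masks(isl, 6), "pixel")
  # two islets 5 um apart with 2 um pixels do not merge
  sq1 <- cbind(c(100, 160, 160, 100), c(100, 100, 160, 160))
  sq2 <- sq1; sq2[, 1] <- sq2[, 1] + 65   # 5 um gap
  isl2 <- do.call(rbind, list(isl, isl))
  isl2$id <- 1:2
  isl2$polygon_wkt <- c(polygon_to_wkt(sq1), polygon_to_wkt(sq2))
  isl2$centroid_x_um <- c(130, 195); isl2$centroid_y_um <- 130
  m2 <- render_stain_masks(isl2, 2)
  lab <- isletmap:::cpp_label_components(m2$CHGA$mask, TRUE)
  expect_equal(max(lab), 2)
})

test_that("rendered channel fractions track ground truth within 10%", {
  tpl <- load_stage_template("Ctrl", "PH")
  tis <- generate_tissue(2, 3, 3, 0)
  isl <- generate_islets(tpl, tis, 31)
  m <- render_stain_masks(isl, 2, bbox = c(0, 0, 3000, 3000))
  prof <- hormone_profiles(isl, m)
  for (ch in all_channels()) {
    tr <- isl[[paste0("true_frac_", ch)]]
    got <- prof[[paste0("frac_", ch)]][match(isl$id, prof$islet_id)]
    expect_lt(max(abs(got - tr)), 0.1)
  }
  # the six defining channels tile each islet
  expect_true(all(prof$frac_endocrine_union > 0.99))
  expect_true(all(prof$frac_ProINS_hi <= prof$frac_ProINS_total + 1e-9))
})

test_that("generate_cells: determinism, CD45 controls, ground-truth match", {
  tpl <- separated_template(density = 4)
  tis <- generate_tissue(6, 3, 3, 0)
  isl <- generate_islets(tpl, tis, 17)
  a <- generate_cells(isl, tpl, 23)
  b <- generate_cells(isl, tpl, 23)
  expect_identical(a, b)
  att <- attribute_cells(isl, a)
  expect_identical(att$records$cd45_intra, isl$true_cd45_intra)
  expect_identical(att$records$cd45_peri, isl$true_cd45_peri)
  # p_any = 0 everywhere -> no CD45 points at all
  tpl0 <- tpl
  tpl0$cd45_model$p_any <- as.list(stats::setNames(rep(0, 6), cluster_levels()))
  tpl0$cd45_model$p_insulitic <- 0
  isl0 <- generate_islets(tpl0, tis, 17)
  c0 <- generate_cells(isl0, tpl0, 23)
  expect_equal(sum(c0$class == "CD45"), 0)
})

test_that("template validation rejects inconsistent parameterizations", {
  tpl <- load_stage_template("Ctrl", "PT")
  bad <- tpl; bad$frac_IDI <- 0.5
  expect_error(validate_stage_template(bad), "frac_IDI")
  bad <- tpl; bad$cluster_mix[["I"]] <- 0.9
  expect_error(validate_stage_template(bad), "sum to 1")
  bad <- tpl; bad$min_islet_area_um2 <- 500
  expect_error(validate_stage_template(bad), "1,000")
  bad <- tpl; bad$frac_GCG_deficient <- 0.999
  expect_error(validate_stage_template(bad), "unattainable")
  expect_true(all(paste(rep(c("Ctrl", "AAb", "T1DS", "T1DL"), each = 2),
                        c("PT", "PH"), sep = "_") %in% list_stage_templates()))
})
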