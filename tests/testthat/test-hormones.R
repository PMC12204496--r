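# a 40x40 px islet at 1 um/px with hand-built channel masks
make_scene <- function(fill = list()) {
  poly <- cbind(c(10, 50, 50, 10), c(10, 10, 50, 50))
  isl <- data.frame(id = 1L, area_um2 = 1600,
                    centroid_x_um = 30, centroid_y_um = 30,
                    polygon_wkt = polygon_to_wkt(poly))
  masks <- lapply(all_channels(), function(ch) square_mask(60, 60))
  names(masks) <- all_channels()
  for (ch in names(fill)) masks[[ch]]$mask <- fill[[ch]]
  list(islets = isl, masks = masks)
}

full <- matrix(FALSE, 60, 60); full[11:50, 11:50] <- TRUE
left <- matrix(FALSE, 60, 60); left[11:50, 11:30] <- TRUE
right <- matrix(FALSE, 60, 60); right[11:50, 31:50] <- TRUE

test_that("hormone fractions: full, empty, disjoint halves, missing channel", {
  sc <- make_scene(list(CHGA = full, INS = left, GCG = right))
  p <- hormone_profiles(sc$islets, sc$masks)
  expect_equal(p$frac_CHGA, 1)
  expect_equal(p$frac_SST, 0)
  expect_equal(p$frac_INS, 0.5)
  expect_equal(p$frac_GCG, 0.5)
  expect_equal(p$frac_endocrine_union, 1)  # CHGA alone covers the islet
  expect_error(hormone_profiles(sc$islets, sc$masks[-2]), "missing channel")
})

test_that("Jaccard pairs: identities, nesting, 56 ordered pairs", {
  nested <- matrix(FALSE, 60, 60); nested[11:50, 11:30] <- TRUE  # 800 px
  half_nested <- matrix(FALSE, 60, 60); half_nested[11:30, 11:30] <- TRUE # 400
  sc <- make_scene(list(CHGA = full, INS = full, GCG = nested,
                        SST = half_nested))
  jp <- jaccard_pairs(sc$islets, sc$masks)
  expect_equal(nrow(jp), 56)
  g <- function(a, b) jp[jp$channel_a == a & jp$channel_b == b, ]
  expect_equal(g("CHGA", "INS")$jaccard, 1)          # identical masks
  expect_equal(g("CHGA", "PPY")$jaccard, 0)          # empty partner -> 0
  expect_equal(g("GCG", "SST")$jaccard, 0.5)         # nested halves
  expect_equal(g("GCG", "SST")$double_positive_frac, 0.5)
  expect_equal(g("SST", "GCG")$double_positive_frac, 1)
  # symmetry of the Jaccard index across ordered pairs
  m <- merge(jp, jp, by.x = c("channel_a", "channel_b"),
             by.y = c("channel_b", "channel_a"))
  expect_equal(m$jaccard.x, m$jaccard.y)
})

test_that("subset classification at the 1% threshold (strict/inclusive)", {
  prof <- data.frame(islet_id = 1:4,
                     frac_ProINS_total = c(0.009, 0.01, 0.5, 0),
                     frac_GCG = c(0.02, 0.02, 0, 0.009),
                     frac_PPY = c(0, 0.01, 0.5, 0),
                     frac_SST = c(0.01, 0.0099, 0, 0.2))
  s <- classify_subsets(prof)
  expect_equal(s$is_IDI, c(TRUE, FALSE, FALSE, TRUE))   # strict <
  expect_equal(s$is_GCG_deficient, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(s$is_PPY_positive, c(FALSE, TRUE, TRUE, FALSE))  # inclusive >=
  expect_equal(s$is_SST_positive, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("section summaries compute densities, areas and ratios", {
  tis <- tissue_section(cbind(c(0, 1e4, 1e4, 0), c(0, 0, 1e4, 1e4)))  # 100 mm2
  isl <- data.frame(id = 1:2, area_um2 = c(1e4, 1e4))
  prof <- data.frame(islet_id = 1:2)
  for (ch in all_channels()) prof[[paste0("frac_", ch)]] <- 0
  prof$frac_INS <- c(0.2, 0.2); prof$frac_GCG <- c(0.1, 0.1)
  ss <- section_summaries(isl, prof, tis)
  expect_equal(ss$islet_density_per_mm2, 0.02)
  expect_equal(ss$relative_islet_area_pct, 0.02)
  expect_equal(ss$ins_gcg_ratio, 2)
  expect_false(ss$ins_gcg_undefined)
  # no islets -> zero density, undefined ratio
  s0 <- section_summaries(isl[0, ], prof[0, ], tis)
  expect_equal(s0$islet_density_per_mm2, 0)
  expect_true(s0$ins_gcg_undefined)
  expect_error(section_summaries(isl, prof,
                                 structure(list(parenchymal_area_mm2 = 0),
                                           class = "tissue_section")),
               "positive")
})

test_that("mass estimation is linear and respects the missing sentinel", {
  expect_equal(estimate_mass(0.01, 10), 100)
  expect_equal(estimate_mass(0, 10), 0)
  expect_equal(estimate_mass(0.002, 25), 50)
  expect_true(is.na(estimate_mass(0.01, NA)))
  for (alpha in c(0.5, 2, 10))
    expect_equal(estimate_mass(alpha * 0.01, 30),
                 alpha * estimate_mass(0.01, 30))
  expect_error(estimate_mass(1.5, 10), "\\[0, 1\\]")
})

test_that("size-binned profiles: conservation and exponential recovery", {
  set.seed(42)
  n <- 600
  isl <- data.frame(area_um2 = exp(runif(n, log(1000), log(1e5))))
  x <- log2(isl$area_um2)
  props <- data.frame(flat = rep(3, n),
                      expo = 2 * exp(0.3 * x) * exp(rnorm(n, 0, 0.001)))
  res <- size_binned_profile(isl, props, n_bins = 14)
  expect_equal(sum(res$bins$n_islets), n)
  expect_equal(sum(res$bins$total_area_um2), sum(isl$area_um2))
  expect_lt(abs(res$fits$flat$b), 1e-6)
  expect_equal(res$fits$expo$a, 2, tolerance = 0.02)
  expect_equal(res$fits$expo$b, 0.3, tolerance = 0.02)
  expect_gt(res$fits$expo$r_squared, 0.999)
  # all islets in one bin -> fit skipped with a warning, mean still returned
  one <- data.frame(area_um2 = rep(2000, 5))
  expect_warning(r1 <- size_binned_profile(one, data.frame(p = 1:5), 14),
                 "skipped")
  expect_true(is.na(r1$fits$p$b))
  expect_equal(sum(r1$bins$n_islets), 5)
})

test_that("end-to-end subset recovery stays within 3 binomial SE", {
  tpl <- load_stage_template("Ctrl", "PT")
  tpl$islet_density_per_mm2 <- 10
  tis <- generate_tissue(4, 12, 12, 0)
  isl <- generate_islets(tpl, tis, 11)
  n <- nrow(isl)
  expect_gte(n, 1000)
  prof <- data.frame(islet_id = isl$id,
                     frac_ProINS_total = isl$true_frac_ProINS_total,
                     frac_GCG = isl$true_frac_GCG,
                     frac_PPY = isl$true_frac_PPY,
                     frac_SST = isl$true_frac_SST)
  s <- classify_subsets(prof)
  expect_lt(abs(mean(s$is_IDI) - tpl$frac_IDI),
            3 * binom_se(tpl$frac_IDI, n))
  expect_lt(abs(mean(s$is_GCG_deficient) - tpl$frac_GCG_deficient),
            3 * binom_se(tpl$frac_GCG_deficient, n))
  expect_lt(abs(mean(s$is_IDI & s$is_PPY_positive) - tpl$frac_PPY_dominant),
            3 * binom_se(tpl$frac_PPY_dominant, n))
})
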