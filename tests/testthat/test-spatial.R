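test_that("modified Ripley's K: basic contracts", {
  tis <- generate_tissue(1, 20, 20, 0)
  # a single pair at distance d: K = 0 for r < d
  pair <- cbind(c(9000, 11000), c(10000, 10000))
  cv <- ripley_modified(pair, tis, radii = c(500, 1000, 1500))
  expect_equal(cv$k, c(0, 0, 0))
  cv2 <- ripley_modified(pair, tis, radii = c(2500))
  expect_gt(cv2$k, 0)
  # centroids outside the tissue are rejected with a warning
  out <- rbind(pair, c(-5000, -5000), c(15000, 9000))
  expect_warning(cv3 <- ripley_modified(out, tis, radii = c(2500)),
                 "outside")
  expect_error(ripley_modified(pair[1, , drop = FALSE], tis), "at least 2")
  expect_error(ripley_modified(pair, tis, radii = c(-1, 100)), "positive")
  # pooled ordering variant runs and stays close to per-islet ordering for CSR
  xy <- with_seed(2, cbind(runif(800, 0, 20000), runif(800, 0, 20000)))
  r <- seq(400, 2000, length.out = 5)
  k_a <- ripley_modified(xy, tis, r)$k
  k_b <- ripley_modified(xy, tis, r, pooled = TRUE)$k
  expect_lt(max(abs(k_a - k_b)), 0.1)
})

test_that("K is invariant under rigid motion of the whole scene", {
  xy <- with_seed(3, cbind(runif(300, 0, 5000), runif(300, 0, 5000)))
  tis <- generate_tissue(1, 5, 5, 0)
  r <- c(400, 800, 1200)
  k0 <- ripley_modified(xy, tis, r)$k
  # translate everything by (3000, -1000)
  tis2 <- tissue_section(sweep(tis$boundary, 2, c(3000, -1000), "+"))
  xy2 <- sweep(xy, 2, c(3000, -1000), "+")
  expect_equal(ripley_modified(xy2, tis2, r)$k, k0, tolerance = 1e-12)
})

test_that("fractal dimension: exact and analytic scaling oracles", {
  # counts exactly proportional to r^2 -> slope 2 (machine precision)
  r <- ripley_radii(400, 10000, 15)
  curve <- data.frame(radius_um = r, mean_adjusted_count = 3 * r^2)
  expect_equal(fractal_dimension(curve)$slope, 2, tolerance = 1e-9)
  # radii at or below 600 um are excluded from the fit
  curve2 <- curve
  curve2$mean_adjusted_count[curve2$radius_um <= 600] <- 1e6
  expect_equal(fractal_dimension(curve2)$slope, 2, tolerance = 1e-9)
  # 1-D pattern: points on a line, small radii -> slope ~ 1
  tisL <- generate_tissue(1, 30, 30, 0)
  xyL <- cbind(seq(1000, 29000, by = 25), 15000)
  cvL <- ripley_modified(xyL, tisL, ripley_radii(650, 4000, 10))
  expect_equal(fractal_dimension(cvL)$slope, 1, tolerance = 0.05)
  expect_error(fractal_dimension(curve[1:2, ]), "3 retained")
})

test_that("Delaunay metrics agree with a frozen scipy.spatial oracle", {
  pts <- matrix(c(
    999.02, 103.416, 761.242, 247.869, 567.524, 413.661, 587.301, 713.195,
    430.06, 559.675, 406.786, 541.897,
    464.953, 266.255, 136.899, 50.926, 49.627, 276.451, 589.633, 394.801,
    647.749, 803.9, 950.603, 362.172), ncol = 2)
  dm <- delaunay_metrics(pts, max_radius_um = Inf)
  expect_equal(sum(dm$n_neighbors) / 2, 27)  # scipy: 27 unique edges
  expect_equal(dm$mean_distance_um,
               c(490.089409, 455.127732, 298.598158, 286.286477, 279.951538,
                 278.062909, 255.555314, 240.748154, 309.150721, 296.440317,
                 507.526892, 249.213951),
               tolerance = 1e-6)
})

test_that("Delaunay lattice and fallback closed forms", {
  # hexagonal (triangular) lattice, spacing 500 um
  g <- expand.grid(i = 0:10, j = 0:10)
  hx <- cbind(g$i * 500 + (g$j %% 2) * 250, g$j * 500 * sqrt(3) / 2)
  dm <- delaunay_metrics(hx, 4000)
  interior <- which(hx[, 1] > 700 & hx[, 1] < 4300 &
                      hx[, 2] > 700 & hx[, 2] < 3600)
  expect_equal(dm$mean_distance_um[interior], rep(500, length(interior)))
  expect_equal(dm$mean_area_um2[interior],
               rep(sqrt(3) / 4 * 500^2, length(interior)))
  # equilateral triangle, side 1,000 um
  tri <- cbind(c(0, 1000, 500), c(0, 0, 500 * sqrt(3)))
  dt <- delaunay_metrics(tri)
  expect_equal(dt$mean_distance_um, rep(1000, 3))
  expect_equal(dt$mean_area_um2, rep(sqrt(3) / 4 * 1e6, 3))
  # neighborless islet gets the 4 mm / pi x 16 mm^2 fallback
  pts <- rbind(c(0, 0), c(500, 0), c(250, 400), c(6000, 6000))
  df <- delaunay_metrics(pts, 4000)
  expect_true(df$is_fallback[4])
  expect_equal(df$mean_distance_um[4], 4000)
  expect_equal(df$mean_area_um2[4], pi * 16 * 1e6)
  expect_false(any(df$is_fallback[1:3]))
  # pruning at infinity reproduces the unpruned triangulation
  d_inf <- delaunay_metrics(pts, Inf)
  expect_false(any(d_inf$is_fallback))
  # collinear points: all fallback
  dc <- delaunay_metrics(cbind(1:5 * 100, 0), 4000)
  expect_true(all(dc$is_fallback))
})

test_that("cluster-scoped Delaunay: isolation rule and scope", {
  # every islet with >= 2 same-cluster neighbors within 8 mm -> none isolated
  xy <- with_seed(4, cbind(runif(30, 0, 4000), runif(30, 0, 4000)))
  cd <- cluster_delaunay(xy, rep("I", 30))
  expect_equal(cd$summary$isolated_fraction[1], 0)
  # 3 islets pairwise 10 mm apart -> all isolated
  far <- cbind(c(0, 10000, 5000), c(0, 0, 10000 * sqrt(3) / 2))
  cf <- cluster_delaunay(far, rep("I", 3))
  expect_equal(cf$islets$is_isolated, rep(TRUE, 3))
  expect_equal(cf$summary$isolated_fraction[1], 1)
  # interleaved clusters: per-cluster triangulations ignore the other cluster
  inter <- cbind(c(0, 1000, 2000, 500, 1500, 2500), rep(0, 6))
  lab <- rep(c("A", "B"), 3)
  ci <- cluster_delaunay(inter, lab, max_radius_mm = 8)
  # cluster A members are 0,2000 apart etc. -> neighbors only within A
  dA <- ci$islets$mean_distance_um[ci$islets$cluster == "A"]
  expect_true(all(is.na(dA) | dA >= 1000))
  # increasing the radius never increases the isolated fraction
  spread <- with_seed(5, cbind(runif(40, 0, 30000), runif(40, 0, 30000)))
  fr <- vapply(c(2, 4, 8, 16), function(r)
    cluster_delaunay(spread, rep("I", 40), max_radius_mm = r)$summary$isolated_fraction[1],
    numeric(1))
  expect_true(all(diff(fr) <= 0))
  # tiny cluster -> summary suppressed
  cs <- cluster_delaunay(far[1:2, ], rep("I", 2), donors = c("a", "b"))
  expect_true(cs$summary$suppressed[1])
})

test_that("back projection document and CD45 binning", {
  tis <- generate_tissue(1, 2, 2, 0)
  empty <- back_project(data.frame(id = integer(), centroid_x_um = numeric(),
                                   centroid_y_um = numeric(),
                                   equivalent_diameter_um = numeric(),
                                   cluster = character()), tis)
  expect_length(empty$features, 1)  # outline only
  isl <- data.frame(id = 1:3, centroid_x_um = c(500, 900, 1300),
                    centroid_y_um = 800,
                    equivalent_diameter_um = c(40, 80, 60),
                    cd45_total = c(0, 17, 7), cluster = c("I", "II", "null"))
  doc <- back_project(isl, tis, "cd45_bins")
  vals <- vapply(doc$features[-1], function(f) f$properties$value, character(1))
  expect_equal(vals, c("0", "15+", "5-9"))
  radii <- vapply(doc$features[-1], function(f) f$properties$radius_um, numeric(1))
  expect_equal(radii[2] / radii[1], 2)  # relative sizes preserved
  doc2 <- back_project(isl, tis, "cluster")
  cols <- vapply(doc2$features[-1], function(f) f$properties$color, character(1))
  expect_equal(length(unique(cols)), 3)
})
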