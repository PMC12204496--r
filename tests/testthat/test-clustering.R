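feature_table <- function(n, area = 5000, cd45 = 0, circ = 0.8,
                          fracs = 0.1) {
  isl <- data.frame(area_um2 = rep(area, n))
  for (ch in hormone_channels()) isl[[paste0("frac_", ch)]] <- fracs
  isl$frac_endocrine_union <- pmin(1, fracs * 3)
  isl$mean_delaunay_area_um2 <- 1e6
  isl$cd45_total <- cd45
  isl$circularity <- circ
  isl
}

test_that("assemble_features transforms and z-scores as documented", {
  # column [e-1, e^2-1] -> ln(x+1) = [1, 2]; population SD of [1, 2] is 0.5,
  # so the z-scores are [-1, +1]
  isl <- feature_table(2)
  isl$area_um2 <- c(exp(1) - 1, exp(2) - 1)
  for (ch in hormone_channels()) isl[[paste0("frac_", ch)]] <- 0
  expect_warning(f <- assemble_features(isl), "degenerate")
  expect_equal(unname(f[, "islet_area"]), c(-1, 1), tolerance = 1e-12)
  # zero hormone area -> ln(1) = 0 before scaling
  raw <- log(isl$frac_INS * isl$area_um2 + 1)
  expect_equal(raw, c(0, 0))
  # constant columns become zeros with a degenerate-variance warning
  expect_true(all(f[, "cd45_total"] == 0))
  expect_error(assemble_features(isl[, -1]), "missing column")
})

test_that("embed_umap is deterministic and separates feature blobs", {
  set.seed(7)
  X <- rbind(matrix(rnorm(500 * 5, 0), ncol = 5),
             matrix(rnorm(500 * 5, 8), ncol = 5))
  e1 <- embed_umap(X, n_neighbors = 15, n_epochs = 200, seed = 3)
  e2 <- embed_umap(X, n_neighbors = 15, n_epochs = 200, seed = 3)
  expect_identical(e1, e2)
  g1 <- e1[1:500, ]; g2 <- e1[501:1000, ]
  between <- sqrt(sum((colMeans(g1) - colMeans(g2))^2))
  within95 <- stats::quantile(sqrt(rowSums(sweep(g1, 2, colMeans(g1))^2)), 0.95)
  expect_gt(between, within95)
  # duplicate rows are tolerated
  Xd <- X[c(1:50, 1:50), ]
  expect_silent(embed_umap(Xd, n_neighbors = 10, n_epochs = 50, seed = 1))
  # too few points -> error pointing at the rule-based key
  expect_error(embed_umap(X[1:10, ], n_neighbors = 50), "rule_based_key")
})

test_that("two-round DBSCAN on constructed coordinates", {
  set.seed(1)
  blob <- function(cx, cy, n = 60) cbind(rnorm(n, cx, 0.05), rnorm(n, cy, 0.05))
  one <- blob(0, 0, 80)
  a1 <- cluster_two_round(one)
  expect_equal(length(setdiff(unique(a1$major), 0L)), 1)
  six <- do.call(rbind, lapply(1:6, function(i) blob(5 * i, 0)))
  a6 <- cluster_two_round(six)
  expect_equal(length(setdiff(unique(a6$major), 0L)), 6)
  expect_equal(sum(a6$major == 0), 0)
  scattered <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  a0 <- cluster_two_round(scattered)
  expect_true(all(a0$major == 0L))
  # subclusters nest into majors by majority overlap
  expect_true(all(a6$subcluster[a6$major > 0] ==
                    "" | grepl("^\\d+\\.", a6$subcluster[a6$major > 0])))
})

test_that("semantic label mapping follows the phenotype decision list", {
  n <- 60
  mk <- function(major, proins, ppy, gcg, cd45) {
    isl <- feature_table(n)
    isl$frac_ProINS_total <- proins; isl$frac_PPY <- ppy
    isl$frac_GCG <- gcg; isl$cd45_total <- cd45
    list(asg = data.frame(major = rep(major, n), subcluster = ""), isl = isl)
  }
  a <- mk(1, 0.4, 0, 0.2, 5)          # beta+, CD45+ -> II
  m <- map_cluster_labels(a$asg, a$isl)
  expect_equal(unique(m$labels), "II")
  b <- mk(1, 0.004, 0.6, 0.003, 0)    # beta-, PPY-dominant -> IV
  expect_equal(unique(map_cluster_labels(b$asg, b$isl)$labels), "IV")
  cc <- mk(1, 0.004, 0.002, 0.003, 0) # hormone-depleted -> unassigned report
  mc <- map_cluster_labels(cc$asg, cc$isl)
  expect_equal(unique(mc$labels), "unassigned")
  expect_equal(mc$report$label, "unassigned")
  # noise points stay "null"
  d <- mk(0, 0.4, 0, 0.2, 0)
  expect_equal(unique(map_cluster_labels(d$asg, d$isl)$labels), "null")
})

test_that("rule-based key matches its published truth table and is pure", {
  prof <- data.frame(frac_INS = c(0.02, 0.005, 0.005, 0.02, 0.005, 0.005),
                     frac_GCG = c(0.02, 0.003, 0.02, 0.02, 0.02, 0.003),
                     frac_PPY = c(0.001, 0.05, 0.001, 0.05, 0.001, 0.001))
  cd <- c(0, 0, 1, 0, 0, 0)
  expect_equal(rule_based_key(prof, cd),
               c("I", "IV", "V-A", "III", "V-BC", "V-BC"))
  expect_identical(rule_based_key(prof, cd), rule_based_key(prof, cd))
  # missing PPY column treated as zero
  expect_equal(rule_based_key(prof[1, c("frac_INS", "frac_GCG")], 0), "I")
})

test_that("cluster label recovery on a well-separated synthetic cohort", {
  tpl <- separated_template(density = 8)
  tis <- generate_tissue(1, 9, 9, 0)
  isl <- annotate_from_truth(generate_islets(tpl, tis, 11))
  key <- rule_based_key(isl, isl$cd45_total)
  expect_gte(adjusted_rand_index(key, isl$true_cluster), 0.9)
})

test_that("cluster summaries: normalization, suppression, order invariance", {
  isl <- data.frame(
    donor_id = rep(c("d1", "d2"), each = 50),
    region = "PT", stage = "Ctrl",
    cluster = c(rep("I", 30), rep("II", 15), rep("III", 5),
                rep("I", 40), rep("V-A", 2), rep("II", 8)))
  cs <- cluster_summaries(isl)
  for (d in c("d1", "d2")) {
    sub <- cs$cells[cs$cells$donor_id == d, ]
    expect_equal(sum(sub$fraction), 1, tolerance = 1e-9)
  }
  # 2-islet cluster suppressed at the cell level
  expect_true(cs$cells$suppressed[cs$cells$donor_id == "d2" &
                                    cs$cells$cluster == "V-A"])
  # cluster with >= 3 islets but only one donor -> group suppressed
  g <- cs$groups[cs$groups$cluster == "III", ]
  expect_true(g$suppressed)
  expect_equal(g$suppressed_reason, "<2 donors")
  gI <- cs$groups[cs$groups$cluster == "I", ]
  expect_false(gI$suppressed)
  # invariance to islet ordering
  cs2 <- cluster_summaries(isl[sample(nrow(isl)), ])
  o1 <- cs$cells[order(cs$cells$donor_id, cs$cells$cluster), ]
  o2 <- cs2$cells[order(cs2$cells$donor_id, cs2$cells$cluster), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("adjusted Rand index identities", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(9, 9, 7, 7, 5, 5)), 1)  # relabeled
  b <- c(1, 2, 1, 2, 1, 2)
  expect_lt(adjusted_rand_index(a, b), 0.1)
})
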