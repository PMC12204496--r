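#' Assemble the single-islet feature matrix
#'
#' Twelve features per islet: log-transformed raw staining areas (µm²) of the
#' eight hormone stains, the endocrine union area, the islet area and the
#' mean Delaunay area, plus the associated CD45+ count and circularity
#' untransformed. Areas get a +1 µm² pseudocount inside the natural log
#' (zero hormone areas are common in insulin-deficient islets); every column
#' is z-scored over the pooled islet set with the population SD.
#'
#' @param islets islet table with `area_um2`, `frac_<channel>` for the eight
#'   hormone channels, `frac_endocrine_union`, `mean_delaunay_area_um2`,
#'   `cd45_total`, `circularity`.
#' @return numeric matrix (one row per islet) with attributes `center` and
#'   `scale`.
#' @export
assemble_features <- function(islets) {
  need <- c("area_um2", paste0("frac_", hormone_channels()),
            "frac_endocrine_union", "mean_delaunay_area_um2",
            "cd45_total", "circularity")
  miss <- setdiff(need, names(islets))
  if (length(miss))
    stop("islet table missing column(s): ", paste(miss, collapse = ", "))
  raw <- cbind(
    sapply(hormone_channels(), function(ch)
      log(islets[[paste0("frac_", ch)]] * islets$area_um2 + 1)),
    endocrine_union = log(islets$frac_endocrine_union * islets$area_um2 + 1),
    islet_area = log(islets$area_um2 + 1),
    delaunay_area = log(islets$mean_delaunay_area_um2 + 1),
    cd45_total = islets$cd45_total,
    circularity = islets$circularity)
  n <- nrow(raw)
  ctr <- colMeans(raw)
  sdp <- sqrt(colMeans(sweep(raw, 2, ctr)^2))  # population SD
  degen <- sdp < 1e-12
  if (any(degen))
    warning("degenerate (constant) feature column(s): ",
            paste(colnames(raw)[degen], collapse = ", "))
  sdp[degen] <- 1
  z <- sweep(sweep(raw, 2, ctr), 2, sdp, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- sdp
  z
}

# curve parameters (a, b) of the low-dimensional similarity
# 1/(1 + a d^(2b)) matched to the min_dist kernel
find_ab_params <- function(min_dist = 0.1, spread = 1) {
  x <- seq(0, spread * 3, length.out = 300)[-1]
  y <- ifelse(x < min_dist, 1, exp(-(x - min_dist) / spread))
  fit <- stats::nls(y ~ 1 / (1 + a * x^(2 * b)),
                    start = list(a = 1.5, b = 0.9),
                    control = stats::nls.control(maxiter = 200, warnOnly = TRUE))
  as.list(stats::coef(fit))
}

# smoothed-kNN calibration: per-point bandwidth sigma such that the summed
# exponential weights equal log2(k); rho is the distance to the nearest
# neighbor (local connectivity 1)
smooth_knn <- function(dists, n_iter = 64, tol = 1e-5) {
  k <- ncol(dists)
  target <- log2(k)
  n <- nrow(dists)
  rho <- dists[, 1]
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    d <- pmax(dists[i, ] - rho[i], 0)
    if (all(d == 0)) { sigma[i] <- 1; next }
    lo <- 0; hi <- Inf; mid <- 1
    for (it in seq_len(n_iter)) {
      val <- sum(exp(-d / mid))
      if (abs(val - target) < tol) break
      if (val > target) { hi <- mid; mid <- (lo + hi) / 2 }
      else { lo <- mid; mid <- if (is.finite(hi)) (lo + hi) / 2 else mid * 2 }
    }
    sigma[i] <- mid
  }
  list(rho = rho, sigma = sigma)
}

#' 2-D UMAP embedding of the islet feature matrix
#'
#' Compact in-package implementation of the reference algorithm: exact kNN,
#' smoothed-kNN fuzzy simplicial set with union symmetrization, PCA
#' initialization, and stochastic gradient optimization with negative
#' sampling (single-threaded, fully deterministic for a given seed).
#' Defaults follow the pipeline settings: `n_neighbors = 50`,
#' `min_dist = 0.1`, `n_epochs = 1000`.
#'
#' @param features numeric matrix from [assemble_features()].
#' @param n_neighbors,min_dist,n_epochs UMAP parameters.
#' @param seed integer seed.
#' @return n x 2 embedding matrix.
#' @export
embed_umap <- function(features, n_neighbors = 50, min_dist = 0.1,
                       n_epochs = 1000, seed = 1) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < n_neighbors + 1)
    stop("need at least n_neighbors + 1 = ", n_neighbors + 1,
         " islets for UMAP; use rule_based_key() for small sets")
  kn <- cpp_knn(X, as.integer(n_neighbors))
  cal <- smooth_knn(kn$dist)
  w <- exp(-pmax(kn$dist - cal$rho, 0) / cal$sigma)
  ii <- rep(seq_len(n), n_neighbors)
  jj <- as.vector(kn$idx)
  ww <- as.vector(w)
  # fuzzy set union: W + W' - W o W'
  key <- paste(ii, jj)
  tkey <- paste(jj, ii)
  m <- match(tkey, key)
  wt <- ifelse(is.na(m), 0, ww[m])
  wu <- ww + wt - ww * wt
  # unique undirected support, then both directions (as in the reference
  # implementation: each directed copy is sampled with the shared weight)
  keep <- ii < jj | is.na(m)
  ei <- ii[keep]; ej <- jj[keep]; ew <- wu[keep]
  dup <- duplicated(paste(pmin(ei, ej), pmax(ei, ej)))
  ei <- ei[!dup]; ej <- ej[!dup]; ew <- ew[!dup]
  ei2 <- c(ei, ej); ej2 <- c(ej, ei); ew2 <- c(ew, ew)
  ei <- ei2; ej <- ej2; ew <- ew2
  wmax <- max(ew)
  drop <- ew < wmax / n_epochs
  ei <- ei[!drop]; ej <- ej[!drop]; ew <- ew[!drop]
  eps <- wmax / ew  # epochs per sample
  ab <- find_ab_params(min_dist)
  init <- component_pca_init(X, ei, ej)
  emb <- cpp_umap_optimize(as.integer(ei), as.integer(ej), eps, init,
                           ab$a, ab$b, 1.0, as.integer(n_epochs), 1.0, 5L,
                           as.integer(seed))
  colnames(emb) <- c("umap_1", "umap_2")
  emb
}

# Initialization of the embedding: connected components of the kNN-union
# graph are laid out on a coarse grid (they share no attractive edges, so a
# tangled start cannot be repaired by the optimizer); within each component,
# PCA coordinates scaled to a compact patch. Deterministic.
component_pca_init <- function(X, ei, ej) {
  n <- nrow(X)
  comp <- graph_components(n, ei, ej)
  k <- max(comp)
  init <- matrix(0, n, 2)
  ng <- ceiling(sqrt(k))
  # components ordered by size, largest first
  sizes <- tabulate(comp, nbins = k)
  ord <- order(-sizes)
  for (ci in seq_len(k)) {
    cid <- ord[ci]
    idx <- which(comp == cid)
    sub <- X[idx, , drop = FALSE]
    loc <- if (length(idx) >= 3) {
      pc <- stats::prcomp(sub, center = TRUE, rank. = 2)
      sc <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
      if (ncol(sc) < 2) sc <- cbind(sc, 0)
      mx <- max(abs(sc))
      if (mx > 0) sc / mx * 2 else sc
    } else matrix(0, length(idx), 2)
    off <- c(((ci - 1) %% ng) * 15, ((ci - 1) %/% ng) * 15)
    init[idx, ] <- sweep(loc, 2, off, "+")
  }
  init
}

graph_components <- function(n, ei, ej) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(ei)) {
    a <- find(ei[e]); b <- find(ej[e])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Two-round DBSCAN clustering of the embedding
#'
#' Round 1 (high epsilon 0.5, minimum 50 points) defines the major clusters;
#' round 2 (low epsilon 0.2, minimum 20 points) defines subclusters, nested
#' into the major clusters by majority overlap. Noise points are `"null"`.
#'
#' @param embedding n x 2 matrix from [embed_umap()].
#' @param eps1,minpts1 round-1 DBSCAN parameters.
#' @param eps2,minpts2 round-2 DBSCAN parameters.
#' @return `data.frame`: `major` (integer id, 0 = null), `subcluster`
#'   (string, `""` for unclustered).
#' @export
cluster_two_round <- function(embedding, eps1 = 0.5, minpts1 = 50,
                              eps2 = 0.2, minpts2 = 20) {
  emb <- as.matrix(embedding)
  major <- cpp_dbscan(emb, eps1, as.integer(minpts1))
  sub <- cpp_dbscan(emb, eps2, as.integer(minpts2))
  subl <- rep("", nrow(emb))
  for (s in setdiff(unique(sub), 0L)) {
    idx <- sub == s
    host <- major[idx]
    host <- host[host > 0]
    maj <- if (length(host)) as.integer(names(which.max(table(host)))) else 0L
    subl[idx] <- paste0(maj, ".", s)
  }
  data.frame(major = major, subcluster = subl, stringsAsFactors = FALSE)
}

#' Map DBSCAN cluster ids onto the islet phenotype vocabulary
#'
#' Labels are assigned semantically from per-cluster medians (DBSCAN indices
#' are not stable across runs): beta-positive clusters split into III
#' (PPY-positive, uncinate context), II (CD45-associated) and I (neither);
#' beta-negative clusters into IV (PPY-dominant) and V (glucagon-high), with
#' V split into V-A (CD45-associated) and V-BC (not). A cluster matching no
#' rule is reported `"unassigned"`, never silently merged.
#'
#' @param assignments result of [cluster_two_round()].
#' @param islets matching islet table with `frac_ProINS_total`, `frac_PPY`,
#'   `frac_GCG` and `cd45_total` columns.
#' @param threshold positivity threshold on median fractions (default 0.01).
#' @return list: `labels` (character per islet: vocabulary label, `"null"`,
#'   or `"unassigned"`), `report` (per DBSCAN id: medians and mapped label).
#' @export
map_cluster_labels <- function(assignments, islets, threshold = 0.01) {
  need <- c("frac_ProINS_total", "frac_PPY", "frac_GCG", "cd45_total")
  miss <- setdiff(need, names(islets))
  if (length(miss)) stop("islet table missing column(s): ", paste(miss, collapse = ", "))
  major <- assignments$major
  labels <- rep("null", length(major))
  ids <- setdiff(sort(unique(major)), 0L)
  report <- list()
  for (id in ids) {
    idx <- major == id
    beta <- stats::median(islets$frac_ProINS_total[idx])
    ppy <- stats::median(islets$frac_PPY[idx])
    gcg <- stats::median(islets$frac_GCG[idx])
    cd45 <- mean(islets$cd45_total[idx] >= 1)
    lab <- if (beta >= threshold) {
      if (ppy >= threshold) "III"
      else if (cd45 >= 0.5) "II"
      else "I"
    } else {
      if (ppy >= threshold) "IV"
      else if (gcg >= threshold) { if (cd45 >= 0.5) "V-A" else "V-BC" }
      else "unassigned"
    }
    labels[idx] <- lab
    report[[length(report) + 1L]] <- data.frame(
      dbscan_id = id, n = sum(idx), median_proins = beta, median_ppy = ppy,
      median_gcg = gcg, frac_cd45_ge1 = cd45, label = lab,
      stringsAsFactors = FALSE)
  }
  list(labels = labels,
       report = if (length(report)) do.call(rbind, report) else
         data.frame(dbscan_id = integer(), n = integer(),
                    median_proins = numeric(), median_ppy = numeric(),
                    median_gcg = numeric(), frac_cd45_ge1 = numeric(),
                    label = character()))
}

#' Rule-based islet phenotype key
#'
#' A deterministic decision list over the 1% positivity threshold and CD45
#' association, approximating the embedding-based clustering from the three
#' standard stains (INS, GCG, CD45) plus optional PPY. Truth table:
#' \preformatted{
#' INS >= 1% (insulin-containing):
#'   PPY >= 1%            -> III
#'   else CD45 >= 1       -> II
#'   else                 -> I
#' INS < 1% (insulin-deficient):
#'   PPY >= 1%            -> IV
#'   else GCG >= 1%:
#'     CD45 >= 1          -> V-A
#'     else               -> V-BC
#'   else                 -> V-BC (hormone-depleted terminal islet)
#' }
#'
#' @param profiles data.frame with `frac_INS`, `frac_GCG`, `frac_PPY`
#'   (optional; treated as 0 when absent).
#' @param cd45_total CD45+ counts per islet.
#' @param threshold positivity threshold (default 0.01).
#' @return character vector of major cluster labels.
#' @export
rule_based_key <- function(profiles, cd45_total, threshold = 0.01) {
  need <- c("frac_INS", "frac_GCG")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) stop("profiles missing column(s): ", paste(miss, collapse = ", "))
  ppy <- rep_len(if ("frac_PPY" %in% names(profiles)) profiles$frac_PPY else 0,
                 nrow(profiles))
  ici <- profiles$frac_INS >= threshold
  cd <- rep_len(cd45_total >= 1, nrow(profiles))
  gcg <- profiles$frac_GCG >= threshold
  ifelse(ici,
         ifelse(ppy >= threshold, "III", ifelse(cd, "II", "I")),
         ifelse(ppy >= threshold, "IV", ifelse(gcg & cd, "V-A", "V-BC")))
}

#' Relative cluster magnitudes per donor and region
#'
#' Cluster fractions per donor-region over all islets (labeled plus null,
#' summing to 1); group-level means apply the reporting suppression rule:
#' a donor-region cell with fewer than 3 islets in a cluster, or a
#' stage-region cluster represented by fewer than 2 donors, is suppressed and
#' flagged with a machine-readable reason.
#'
#' @param islets islet table with `donor_id`, `region`, `stage` and a
#'   `cluster` label column.
#' @return list: `cells` (donor-region-cluster fractions with per-cell
#'   suppression) and `groups` (stage-region-cluster donor means with donor
#'   counts and suppression).
#' @export
cluster_summaries <- function(islets) {
  need <- c("donor_id", "region", "stage", "cluster")
  miss <- setdiff(need, names(islets))
  if (length(miss)) stop("islet table missing column(s): ", paste(miss, collapse = ", "))
  key <- interaction(islets$donor_id, islets$region, drop = TRUE)
  cells <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- islets[key == k, , drop = FALSE]
    tb <- table(sub$cluster)
    data.frame(donor_id = sub$donor_id[1], region = sub$region[1],
               stage = sub$stage[1], cluster = names(tb),
               n_islets = as.integer(tb),
               fraction = as.numeric(tb) / nrow(sub),
               suppressed = as.integer(tb) < 3,
               suppressed_reason = ifelse(as.integer(tb) < 3, "<3 islets", ""),
               stringsAsFactors = FALSE)
  }))
  rownames(cells) <- NULL
  ok <- cells[!cells$suppressed, , drop = FALSE]
  groups <- do.call(rbind, lapply(
    split(ok, list(ok$stage, ok$region, ok$cluster), drop = TRUE),
    function(g) data.frame(stage = g$stage[1], region = g$region[1],
                           cluster = g$cluster[1],
                           n_donors = length(unique(g$donor_id)),
                           mean_fraction = mean(g$fraction),
                           stringsAsFactors = FALSE)))
  if (!is.null(groups)) {
    rownames(groups) <- NULL
    groups$suppressed <- groups$n_donors < 2
    groups$suppressed_reason <- ifelse(groups$suppressed, "<2 donors", "")
    groups$mean_fraction[groups$suppressed] <- NA_real_
  }
  list(cells = cells, groups = groups)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors of equal length.
#' @return adjusted-for-chance agreement in \[-1, 1\] (1 = identical
#'   partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tb <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tb))
  sum_a <- sum(comb2(rowSums(tb)))
  sum_b <- sum(comb2(colSums(tb)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
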