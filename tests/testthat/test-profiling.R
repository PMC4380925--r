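toy_cells <- function() {
  # 3 wells x 2 features, hand-checkable
  data.frame(well_id = c("w1", "w1", "w2", "w2", "w3", "w3"),
             line_id = c("A", "A", "A", "A", "B", "B"),
             medium = "base", treatment = "untreated",
             cell_area = c(10, 14, 20, 24, 30, 34),
             nuc_area = c(1, 3, 2, 4, 3, 5),
             stringsAsFactors = FALSE)
}

test_that("Z-scored columns have mean 0 and population SD 1", {
  wp <- well_profiles(toy_cells(), features = c("cell_area", "nuc_area"))
  expect_equal(unname(colMeans(wp$z)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(wp$z, 2, morphloc:::pop_sd)), c(1, 1),
               tolerance = 1e-9)
})

test_that("well means and Z values match hand arithmetic", {
  wp <- well_profiles(toy_cells(), features = c("cell_area", "nuc_area"))
  # well means: 12, 22, 32; grand mean 22; population SD sqrt(200/3)
  expect_equal(wp$profiles$cell_area, c(12, 22, 32))
  sd_pop <- sqrt(mean((c(12, 22, 32) - 22)^2))
  expect_equal(unname(wp$z[, "cell_area"]),
               (c(12, 22, 32) - 22) / sd_pop, tolerance = 1e-12)
  expect_equal(wp$profiles$n_cells, c(2L, 2L, 2L))
})

test_that("a well of identical cells profiles to the cell value", {
  cells <- data.frame(well_id = c("w1", "w1", "w2"), line_id = "A",
                      medium = "base", treatment = "untreated",
                      cell_area = c(7, 7, 9))
  wp <- well_profiles(cells, features = "cell_area")
  expect_equal(wp$profiles$cell_area, c(7, 9))
})

test_that("zero-variance features are excluded with a warning", {
  cells <- toy_cells()
  cells$flat <- 5
  expect_warning(wp <- well_profiles(cells,
                                     features = c("cell_area", "flat")),
                 "zero-variance")
  expect_false("flat" %in% colnames(wp$z))
})

test_that("PCA scores match a brute-force eigendecomposition oracle", {
  set.seed(10)
  z <- scale(matrix(rnorm(12), 4, 3), center = TRUE, scale = FALSE)
  pc <- pca_scores(z, k = 3L)
  # oracle: eigen of the covariance matrix, scores = projections
  ev <- eigen(crossprod(z) / (nrow(z) - 1), symmetric = TRUE)
  expect_equal(pc$var_fraction, ev$values[1:3] / sum(ev$values),
               tolerance = 1e-10)
  for (k in 1:3)  # loadings defined up to sign
    expect_equal(abs(unname(pc$loadings[, k])), abs(ev$vectors[, k]),
                 tolerance = 1e-8)
  proj <- z %*% ev$vectors
  for (k in 1:3)
    expect_equal(abs(unname(pc$scores[, k])), abs(unname(proj[, k])),
                 tolerance = 1e-8)
})

test_that("a rank-1 matrix loads 100% of variance on PC1", {
  u <- c(1, 2, 3, 4); v <- c(1, -1, 2)
  z <- u %*% t(v)
  expect_warning(pc <- pca_scores(z, k = 3L), "truncat")
  expect_equal(pc$var_fraction[1], 1, tolerance = 1e-12)
})

test_that("variance fractions are monotone non-increasing and sum <= 1", {
  set.seed(11)
  pc <- pca_scores(matrix(rnorm(80), 10, 8), k = 5L)
  expect_true(all(diff(pc$var_fraction) <= 1e-12))
  expect_lte(sum(pc$var_fraction), 1 + 1e-12)
})

test_that("full-component PCA reconstructs Z to machine precision", {
  set.seed(12)
  z <- scale(matrix(rnorm(60), 10, 6), scale = FALSE)
  pc <- pca_scores(z, k = 6L)
  zhat <- pc$scores %*% t(pc$loadings)
  expect_lt(norm(z - zhat, "F"), 1e-8)
})

test_that("duplicated rows merge first at height 0", {
  set.seed(13)
  m <- matrix(rnorm(40), 5, 8)
  m <- rbind(m, m[1, ] )
  rownames(m) <- paste0("L", 1:6)
  cl <- cluster_lines(m)
  expect_equal(min(cl$hclust$height), 0, tolerance = 1e-12)
  first <- cl$hclust$merge[which.min(cl$hclust$height), ]
  expect_setequal(rownames(m)[-first], c("L1", "L6"))
})

test_that("well-separated planted groups are recovered by a 2-cluster cut", {
  set.seed(14)
  g1 <- matrix(rnorm(4 * 6, 0, 1), 4, 6) +
    matrix(rep(c(5, -5, 5, -5, 5, -5), each = 4), 4, 6)
  g2 <- matrix(rnorm(4 * 6, 0, 1), 4, 6) +
    matrix(rep(c(-5, 5, -5, 5, -5, 5), each = 4), 4, 6)
  m <- rbind(g1, g2)
  rownames(m) <- paste0("L", 1:8)
  cl <- cluster_lines(m, k = 2L)
  expect_length(unique(cl$clusters[1:4]), 1L)
  expect_length(unique(cl$clusters[5:8]), 1L)
  expect_true(cl$clusters[1] != cl$clusters[5])
})

test_that("the correlation distance matrix is symmetric with zero diagonal", {
  set.seed(15)
  m <- matrix(rnorm(30), 5, 6)
  rownames(m) <- paste0("L", 1:5)
  d <- as.matrix(cluster_lines(m)$dist)
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_equal(unname(diag(d)), rep(0, 5), tolerance = 1e-12)
})

test_that("dendrogram topology is invariant to row order", {
  set.seed(16)
  m <- matrix(rnorm(48), 6, 8)
  rownames(m) <- paste0("L", 1:6)
  cl1 <- cluster_lines(m, k = 3L)
  perm <- c(4, 1, 6, 2, 5, 3)
  cl2 <- cluster_lines(m[perm, ], k = 3L)
  # same partition up to label permutation
  p1 <- cl1$clusters[paste0("L", 1:6)]
  p2 <- cl2$clusters[paste0("L", 1:6)]
  expect_equal(length(unique(paste(p1, p2))), length(unique(p1)))
  expect_equal(sort(cl1$hclust$height), sort(cl2$hclust$height),
               tolerance = 1e-12)
})

test_that("constant rows are excluded from clustering with a warning", {
  m <- rbind(matrix(rnorm(15), 3, 5), rep(1, 5))
  rownames(m) <- c("a", "b", "c", "flat")
  expect_warning(cl <- cluster_lines(m), "constant")
  expect_false("flat" %in% cl$hclust$labels)
})

# -- feature selection -----------------------------------------------------

sim_selection_cells <- function(shift_feature = "ruffliness", shift = 1,
                                n = 1000L, lines = 4L, seed = 20L) {
  set.seed(seed)
  out <- NULL
  feats <- c("cell_area", "nuc_area", "ruffliness", "neighbor_fraction")
  for (li in seq_len(lines)) {
    tfr <- rnorm(n)
    d <- data.frame(line_id = paste0("L", li), treatment = "untreated",
                    log10_tf_ratio = tfr)
    for (f in feats) d[[f]] <- rnorm(n)
    # plant a mean shift in one feature for high-ratio cells
    hi <- tfr >= quantile(tfr, 0.75)
    d[[shift_feature]][hi] <- d[[shift_feature]][hi] + shift
    out <- rbind(out, d)
  }
  out
}

test_that("a planted 1-SD group shift ranks that feature first", {
  cells <- sim_selection_cells()
  sel <- select_discriminative_features(
    cells, features = c("cell_area", "nuc_area", "ruffliness",
                        "neighbor_fraction"), k = 2L)
  expect_equal(sel$selected[1], "ruffliness")
  expect_equal(unname(sel$votes[1]), 4)
})

test_that("features identical across groups gather zero votes", {
  cells <- sim_selection_cells(shift = 0)
  cells$constant <- 1
  sel <- select_discriminative_features(
    cells, features = c("cell_area", "constant"), k = 2L)
  expect_equal(unname(sel$votes["constant"]), 0)
})

test_that("k beyond the catalog returns all candidates, ordered", {
  cells <- sim_selection_cells()
  sel <- select_discriminative_features(
    cells, features = c("cell_area", "nuc_area", "ruffliness"), k = 100L)
  expect_length(sel$selected, 3L)
  expect_true(!is.unsorted(rev(sel$votes)))
})

test_that("selection is invariant to line renaming; small groups skipped", {
  cells <- sim_selection_cells(n = 400L)
  ren <- cells
  ren$line_id <- paste0("zz_", ren$line_id)
  s1 <- suppressWarnings(select_discriminative_features(cells, features = c(
    "cell_area", "ruffliness"), k = 2L))
  s2 <- suppressWarnings(select_discriminative_features(ren, features = c(
    "cell_area", "ruffliness"), k = 2L))
  expect_equal(s1$selected, s2$selected)
  tiny <- cells[cells$line_id %in% c("L1", "L2") &
                  seq_len(nrow(cells)) %% 40 == 0, ]
  w <- capture_warnings(select_discriminative_features(
    rbind(cells[cells$line_id == "L3", ], tiny),
    features = c("cell_area", "ruffliness"), k = 2L))
  expect_true(any(grepl("skipped", w)))
})
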