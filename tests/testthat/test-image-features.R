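# -- segmentation ----------------------------------------------------------

test_that("recovered cell masks overlap the true masks (Jaccard > 0.9)", {
  sc <- simulate_scene(scene_spec(
    image_size = 384L,
    colony_plan = data.frame(x = c(110, 270), y = c(110, 260),
                             n = c(4, 5), spacing = 0.95),
    tf_ratio_target = 1.8, seed = 3L))
  reg <- segment_regions(sc$nucleus, sc$body)
  expect_equal(length(reg$cell_ids), nrow(sc$truth))
  true_cell <- sc$labels$cell
  for (id in reg$cell_ids) {
    seg <- reg$cell == id
    tl <- true_cell[seg]
    tid <- as.integer(names(which.max(table(tl[tl > 0]))))
    tru <- true_cell == tid
    jac <- sum(seg & tru) / sum(seg | tru)
    expect_gt(jac, 0.9)
  }
})

test_that("the perinuclear ring of a circular cell is a w_r-wide annulus", {
  lb <- disk_labels(r_cell = 50, r_nuc = 20)
  reg <- region_labels(lb$nucleus, lb$cell, ring_width = 4L)
  ring_px <- sum(reg$ring == 1L)
  expect_equal(ring_px, pi * (24^2 - 20^2), tolerance = 0.05)
})

test_that("blank images yield an empty result without error", {
  z <- matrix(0, 64, 64)
  reg <- segment_regions(z, z)
  expect_length(reg$cell_ids, 0L)
  expect_error(segment_regions(matrix(0, 10, 10), matrix(0, 12, 12)),
               "dimensions")
})

# -- shape features --------------------------------------------------------

test_that("a digitized disk has roundness near 1 and zero centers distance", {
  lb <- disk_labels(r_cell = 40, r_nuc = 15)
  reg <- region_labels(lb$nucleus, lb$cell, pixel_size = 1)
  sf <- shape_features(reg)
  expect_gte(sf$cell_roundness, 0.95)
  expect_equal(sf$centers_distance, 0, tolerance = 0.51)
  expect_equal(sf$cell_area, pi * 40^2, tolerance = 0.03)
  expect_equal(sf$cell_length_width, 1, tolerance = 0.05)
})

test_that("area_nuc_cyto follows the cytoplasm = cell - nucleus convention", {
  lb <- disk_labels(r_cell = 40, r_nuc = 15)
  reg <- region_labels(lb$nucleus, lb$cell, pixel_size = 1)
  sf <- shape_features(reg)
  a_cell <- sum(lb$cell); a_nuc <- sum(lb$nucleus)
  expect_equal(sf$area_nuc_cyto, a_nuc / (a_cell - a_nuc), tolerance = 1e-9)
  # reference arithmetic: 2000 px^2 cell, 300 px^2 nucleus
  expect_equal(300 / (2000 - 300), 0.1765, tolerance = 5e-4)
})

test_that("an offset nucleus yields the planted centers distance", {
  lb <- disk_labels(r_cell = 40, r_nuc = 12, nuc_offset = c(10, 0))
  reg <- region_labels(lb$nucleus, lb$cell, pixel_size = 2)
  sf <- shape_features(reg)
  expect_equal(sf$centers_distance, 20, tolerance = 0.1)
})

test_that("cells without a nucleus are dropped with a warning", {
  lb <- disk_labels(r_cell = 30, r_nuc = 10)
  nuc0 <- lb$nucleus; nuc0[] <- 0L
  expect_warning(reg <- region_labels(nuc0, lb$cell), "without a nucleus")
  expect_length(reg$cell_ids, 0L)
})

# -- context features ------------------------------------------------------

test_that("two abutting squares have NF = 0.25 within one boundary pixel", {
  lb <- square_pair_labels(s = 40L)
  reg <- region_labels(lb$nucleus, lb$cell)
  cf <- context_features(reg)
  s <- 40L
  n_boundary <- 4L * s - 4L
  for (k in 1:2) {
    contact_px <- cf$neighbor_fraction[k] * n_boundary
    expect_lte(abs(contact_px - s), 1.5)
  }
  expect_equal(cf$colony_size, c(2, 2))
  expect_equal(cf$n_neighbors, c(1L, 1L))
})

test_that("NF is in [0,1] and colonies partition the adjacency graph", {
  sc <- simulate_scene(scene_spec(
    image_size = 400L,
    colony_plan = data.frame(x = c(110, 280), y = c(110, 280),
                             n = c(3, 4), spacing = 0.9),
    seed = 6L))
  reg <- region_labels(sc$labels$nucleus, sc$labels$cell)
  cf <- context_features(reg)
  expect_true(all(cf$neighbor_fraction >= 0 & cf$neighbor_fraction <= 1))
  expect_setequal(unique(cf$colony_size), c(3, 4))
})

# -- intensity features ----------------------------------------------------

test_that("uniform membrane intensity gives zero ruffliness; ratios are exact", {
  lb <- disk_labels(r_cell = 40, r_nuc = 15)
  reg <- region_labels(lb$nucleus, lb$cell)
  body <- matrix(500, lb$n, lb$n)
  tf <- matrix(100, lb$n, lb$n)
  tf[lb$nucleus == 1L] <- 200
  inf <- intensity_features(reg, list(body = body, tf = tf))
  expect_equal(inf$ruffliness, 0)
  expect_equal(inf$tf_ratio, 2.0, tolerance = 1e-9)
  expect_equal(inf$log10_tf_ratio, log10(2), tolerance = 1e-9)
  # equal nuclear and ring means give ratio 1, log 0
  inf2 <- intensity_features(reg, list(body = body, tf = matrix(100, lb$n, lb$n)))
  expect_equal(inf2$tf_ratio, 1.0)
  expect_equal(inf2$log10_tf_ratio, 0)
})

test_that("a zero ring mean flags the record and excludes it downstream", {
  lb <- disk_labels(r_cell = 40, r_nuc = 15)
  reg <- region_labels(lb$nucleus, lb$cell)
  tf <- matrix(0, lb$n, lb$n)
  tf[lb$nucleus == 1L] <- 100
  inf <- intensity_features(reg, list(body = matrix(1, lb$n, lb$n), tf = tf))
  expect_false(inf$ratio_valid)
  expect_warning(
    tab <- morphloc:::measure_cells(reg, list(body = matrix(1, lb$n, lb$n),
                                              tf = tf)),
    "invalid ring")
  expect_equal(nrow(tab), 0L)
})

# -- full extraction -------------------------------------------------------

test_that("extracted tables carry all 77 catalog features, finite", {
  sc <- simulate_scene(scene_spec(image_size = 256L, n_cells = 4L,
                                  seed = 12L))
  tab <- extract_feature_table(sc$nucleus, sc$body, sc$tf,
                               metadata = list(line_id = "demo"))
  expect_true(all(feature_catalog()$feature %in% names(tab)))
  expect_true(all(cell_metadata_columns() %in% names(tab)))
  expect_true(all(vapply(tab[, feature_catalog()$feature],
                         function(v) all(is.finite(v)), logical(1))))
  expect_true(all(canonical17_features() %in% names(tab)))
  expect_equal(unique(tab$line_id), "demo")
})

# -- invariants ------------------------------------------------------------

test_that("doubling pixel size doubles lengths and quadruples areas;
           dimensionless features are invariant", {
  lb <- disk_labels(r_cell = 40, r_nuc = 15, nuc_offset = c(6, 0))
  body <- matrix(500, lb$n, lb$n); body[lb$cell == 1L] <- 800
  tf <- matrix(100, lb$n, lb$n); tf[lb$nucleus == 1L] <- 180
  r1 <- region_labels(lb$nucleus, lb$cell, pixel_size = 0.65)
  r2 <- region_labels(lb$nucleus, lb$cell, pixel_size = 1.30)
  s1 <- shape_features(r1); s2 <- shape_features(r2)
  expect_equal(s2$cell_area, 4 * s1$cell_area)
  expect_equal(s2$cell_perimeter, 2 * s1$cell_perimeter)
  expect_equal(s2$centers_distance, 2 * s1$centers_distance)
  expect_equal(s2$cell_roundness, s1$cell_roundness)
  expect_equal(s2$area_nuc_cyto, s1$area_nuc_cyto)
  i1 <- intensity_features(r1, list(body = body, tf = tf))
  i5 <- intensity_features(r1, list(body = 5 * body, tf = 5 * tf))
  expect_equal(i5$tf_ratio, i1$tf_ratio)
  expect_equal(i5$ruffliness, i1$ruffliness)
  c1 <- context_features(r1); c2 <- context_features(r2)
  expect_equal(c2$neighbor_fraction, c1$neighbor_fraction)
})

test_that("adding a contacting neighbor never decreases NF", {
  lb <- square_pair_labels(s = 30L)
  solo_cell <- lb$cell; solo_cell[solo_cell == 2L] <- 0L
  solo_nuc <- lb$nucleus; solo_nuc[solo_nuc == 2L] <- 0L
  nf_solo <- context_features(
    region_labels(solo_nuc, solo_cell))$neighbor_fraction[1]
  nf_pair <- context_features(
    region_labels(lb$nucleus, lb$cell))$neighbor_fraction[1]
  expect_gte(nf_pair, nf_solo)
})

test_that("extractor output matches generator ground truth within tolerance", {
  worst_area <- worst_nf <- worst_tf <- 0
  n_checked <- 0L
  for (sd_ in c(3L, 11L)) {
    sc <- simulate_scene(scene_spec(
      image_size = 384L,
      colony_plan = data.frame(x = c(110, 270), y = c(110, 260),
                               n = c(4, 5), spacing = 0.95),
      tf_ratio_target = 1.8, tf_ratio_sd_log10 = 0.05, seed = sd_))
    tab <- extract_feature_table(sc$nucleus, sc$body, sc$tf)
    reg <- attr(tab, "regions")
    true_cell <- sc$labels$cell
    pairs <- vapply(tab$cell_id, function(id) {
      tl <- true_cell[reg$cell == id]
      as.integer(names(which.max(table(tl[tl > 0]))))
    }, integer(1))
    tt <- sc$truth[match(pairs, sc$truth$cell_id), ]
    worst_area <- max(worst_area,
                      abs(tab$cell_area - tt$cell_area) / tt$cell_area)
    worst_nf <- max(worst_nf,
                    abs(tab$neighbor_fraction - tt$neighbor_fraction))
    worst_tf <- max(worst_tf, abs(tab$tf_ratio - tt$tf_ratio) / tt$tf_ratio)
    n_checked <- n_checked + nrow(tab)
  }
  expect_gte(n_checked, 15L)
  expect_lte(worst_area, 0.02)
  expect_lte(worst_nf, 0.05)
  expect_lte(worst_tf, 0.05)
})
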