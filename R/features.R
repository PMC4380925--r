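#' Geometric shape features per cell
#'
#' Computes the geometry block of the feature catalog from a
#' \code{\link{region_labels}} object: areas (um^2), chain-code-corrected
#' perimeters (um), isoperimetric roundness \eqn{4\pi A/P^2}, fitted-ellipse
#' length/width and eccentricity, bounding-box extent, convex-hull solidity,
#' equivalent diameter, the nuclear/cytoplasmic area ratio
#' (cytoplasm = cell - nucleus), protrusion measures from boundary
#' excursions beyond a smoothed outline, and the nucleus-to-cell-centroid
#' polarity distances.
#'
#' Cells without a nucleus are dropped by \code{\link{region_labels}}
#' upstream, with a warning.
#'
#' @param regions A \code{RegionLabels} object.
#' @param protrusion_sigma Gaussian smoothing bandwidth for the reference
#'   outline, pixels of arc length.
#' @param protrusion_excess Fractional radial excess above the smoothed
#'   outline that counts as a protrusion.
#' @return data.frame keyed by \code{cell_id} with the geometry, protrusion
#'   and polarity feature columns.
#' @export
shape_features <- function(regions, protrusion_sigma = 10,
                           protrusion_excess = 0.15) {
  stopifnot(inherits(regions, "RegionLabels"))
  ids <- regions$cell_ids
  px <- regions$pixel_size
  if (length(ids) == 0L) return(empty_feature_frame(shape_feature_names()))
  ccont <- label_contours(regions$cell)
  ncont <- label_contours(regions$nucleus)
  rows <- lapply(ids, function(id) {
    cg <- region_geometry(regions$cell, ccont[[as.character(id)]], id, px)
    ng <- region_geometry(regions$nucleus, ncont[[as.character(id)]], id, px)
    pr <- protrusion_metrics(ccont[[as.character(id)]], px,
                             protrusion_sigma, protrusion_excess)
    cyto_area <- cg$area - ng$area
    data.frame(
      cell_id = id,
      cell_area = cg$area, cell_perimeter = cg$perimeter,
      cell_roundness = cg$roundness, cell_length = cg$length,
      cell_width = cg$width, cell_length_width = cg$length / cg$width,
      cell_eccentricity = cg$eccentricity, cell_extent = cg$extent,
      cell_solidity = cg$solidity, cell_equiv_diameter = cg$equiv_diameter,
      nuc_area = ng$area, nuc_perimeter = ng$perimeter,
      nuc_roundness = ng$roundness, nuc_length = ng$length,
      nuc_width = ng$width, nuc_length_width = ng$length / ng$width,
      nuc_eccentricity = ng$eccentricity, nuc_extent = ng$extent,
      nuc_solidity = ng$solidity, nuc_equiv_diameter = ng$equiv_diameter,
      area_nuc_cyto = if (cyto_area > 0) ng$area / cyto_area else NA_real_,
      area_nuc_cell = ng$area / cg$area,
      protrusion_count = pr$count, protrusion_extent = pr$extent,
      protrusion_mean_length = pr$mean_length,
      protrusion_arc_fraction = pr$arc_fraction,
      boundary_radial_cv = pr$radial_cv,
      centers_distance = sqrt(sum((cg$centroid - ng$centroid)^2)) * px,
      centers_distance_rel =
        sqrt(sum((cg$centroid - ng$centroid)^2)) * px /
          (cg$equiv_diameter / 2),
      nuc_clearance = nucleus_clearance(ncont[[as.character(id)]],
                                        ccont[[as.character(id)]], px),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

shape_feature_names <- function() {
  cat77 <- feature_catalog()
  c(cat77$feature[cat77$category %in% c("geometry", "protrusion", "polarity")])
}

empty_feature_frame <- function(feature_names) {
  df <- as.data.frame(matrix(numeric(0), nrow = 0,
                             ncol = length(feature_names) + 1L))
  names(df) <- c("cell_id", feature_names)
  df
}

# ordered 8-connected contours for every label, 1-based coordinates,
# named by label id
label_contours <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  out <- stats::setNames(vector("list", length(ids)), as.character(ids))
  if (length(ids) == 0L) return(out)
  oc <- EBImage::ocontour(EBImage::Image(lab))
  for (id in ids) {
    m <- oc[[id]]
    if (is.null(m) || nrow(m) == 0L) {
      # fall back to unordered boundary pixels (degenerate tiny object)
      idx <- which(lab == id, arr.ind = TRUE)
      m <- idx - 1L
    }
    out[[as.character(id)]] <- m + 1  # ocontour is 0-based
  }
  out
}

# chain-code perimeter with the classical corner-corrected step weights;
# calibrated so digitized disks give isoperimetric roundness ~ 1
chain_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 3L) return(max(n, 1) * 1.0)
  d <- contour - contour[c(2:n, 1L), ]
  diag_step <- abs(d[, 1]) == 1 & abs(d[, 2]) == 1
  axial <- sum(!diag_step)
  diags <- sum(diag_step)
  0.948 * axial + 1.340 * diags
}

# area, perimeter, centroid, second-moment ellipse, extent, solidity for
# one label; lengths in micrometres, areas in square micrometres
region_geometry <- function(lab, contour, id, px) {
  idx <- which(lab == id, arr.ind = TRUE)
  npix <- nrow(idx)
  area <- npix * px^2
  per <- chain_perimeter(contour) * px
  centroid <- colMeans(idx)
  if (npix >= 3L) {
    cv <- stats::cov(idx) * (npix - 1) / npix
    ev <- eigen(cv, symmetric = TRUE)$values
    ev <- pmax(ev, 1 / 12)  # single-pixel variance floor
    len <- 4 * sqrt(ev[1]) * px
    wid <- 4 * sqrt(ev[2]) * px
    ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
  } else {
    len <- wid <- sqrt(area); ecc <- 0
  }
  bbox_area <- prod(apply(idx, 2, function(v) diff(range(v)) + 1)) * px^2
  hull_area <- contour_hull_area(contour) * px^2
  list(area = area, perimeter = per,
       roundness = min(1, 4 * pi * area / per^2),
       length = len, width = wid, eccentricity = ecc,
       extent = area / bbox_area,
       solidity = min(1, area / max(hull_area, area)),
       equiv_diameter = 2 * sqrt(area / pi),
       centroid = centroid)
}

# convex hull area from contour points (shoelace), with a half-pixel
# boundary correction so a hull of n pixels is not underestimated
contour_hull_area <- function(contour) {
  if (nrow(contour) < 3L) return(nrow(contour))
  h <- grDevices::chull(contour[, 1], contour[, 2])
  pts <- contour[h, , drop = FALSE]
  n <- nrow(pts)
  if (n < 3L) return(nrow(contour))
  x <- pts[, 1]; y <- pts[, 2]
  a <- abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  # boundary pixels contribute ~half a pixel each outside the lattice hull
  a + chain_perimeter(pts) / 2 + 1
}

# protrusions: contiguous boundary arcs whose radial distance from the
# centroid exceeds the circularly Gaussian-smoothed radial profile by more
# than `excess`
protrusion_metrics <- function(contour, px, sigma, excess) {
  n <- nrow(contour)
  if (n < 8L)
    return(list(count = 0, extent = 0, mean_length = 0, arc_fraction = 0,
                radial_cv = 0))
  ctr <- colMeans(contour)
  r <- sqrt((contour[, 1] - ctr[1])^2 + (contour[, 2] - ctr[2])^2)
  rs <- smooth_circular(r, sigma)
  rs <- pmax(rs, 1e-9)
  rel <- r / rs - 1
  flag <- rel > excess
  runs <- circular_runs(flag)
  # step lengths along the contour for arc measurement
  d <- contour[c(2:n, 1L), ] - contour
  step <- sqrt(d[, 1]^2 + d[, 2]^2)
  arc_len <- vapply(runs, function(ix) sum(step[ix]), numeric(1))
  total <- sum(step)
  list(count = length(runs),
       extent = max(rel, 0),
       mean_length = if (length(runs)) mean(arc_len) * px else 0,
       arc_fraction = if (length(runs)) sum(arc_len) / total else 0,
       radial_cv = stats::sd(r) / mean(r))
}

# minimum distance (um) from the nucleus boundary to the cell boundary
nucleus_clearance <- function(nuc_contour, cell_contour, px) {
  if (is.null(nuc_contour) || is.null(cell_contour) ||
      nrow(nuc_contour) == 0L || nrow(cell_contour) == 0L)
    return(NA_real_)
  # thin both to at most 200 points to bound the cross-distance cost
  thin <- function(m, k = 200L)
    m[unique(round(seq(1, nrow(m), length.out = min(k, nrow(m))))), ,
      drop = FALSE]
  a <- thin(nuc_contour); b <- thin(cell_contour)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2)) * px
}

#' Cell-context features: contact, colonies, edge flags
#'
#' Neighbor fraction (NF) is the proportion of a cell's boundary pixels
#' whose 8-neighborhood touches a different cell label. Colonies are
#' connected components of the cell-adjacency graph; cells with NF below
#' \code{edge_nf_threshold} or touching the image border are flagged as
#' colony-edge cells.
#'
#' @param regions A \code{RegionLabels} object.
#' @param edge_nf_threshold NF below which a cell counts as a colony-edge
#'   cell.
#' @return data.frame keyed by \code{cell_id} with columns
#'   \code{neighbor_fraction}, \code{n_neighbors}, \code{colony_id},
#'   \code{colony_size}, \code{colony_area}, \code{is_edge_cell},
#'   \code{is_border_cell}, \code{nn_centroid_dist}.
#' @export
context_features <- function(regions, edge_nf_threshold = 0.5) {
  stopifnot(inherits(regions, "RegionLabels"))
  ids <- regions$cell_ids
  if (length(ids) == 0L)
    return(data.frame(cell_id = integer(0), neighbor_fraction = numeric(0),
                      n_neighbors = numeric(0), colony_id = numeric(0),
                      colony_size = numeric(0), colony_area = numeric(0),
                      is_edge_cell = numeric(0), is_border_cell = numeric(0),
                      nn_centroid_dist = numeric(0)))
  lab <- regions$cell
  px <- regions$pixel_size
  nx <- nrow(lab); ny <- ncol(lab)
  conts <- label_contours(lab)
  shifts <- expand.grid(dx = -1:1, dy = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0), ]

  nf <- numeric(length(ids))
  nbrs <- vector("list", length(ids))
  areas <- numeric(length(ids))
  cents <- matrix(0, length(ids), 2)
  for (k in seq_along(ids)) {
    id <- ids[k]
    bp <- conts[[as.character(id)]]
    idx <- which(lab == id, arr.ind = TRUE)
    areas[k] <- nrow(idx) * px^2
    cents[k, ] <- colMeans(idx)
    contact <- logical(nrow(bp))
    touching <- integer(0)
    for (s in seq_len(nrow(shifts))) {
      qx <- bp[, 1] + shifts$dx[s]; qy <- bp[, 2] + shifts$dy[s]
      ok <- qx >= 1 & qx <= nx & qy >= 1 & qy <= ny
      v <- rep(0L, nrow(bp))
      v[ok] <- lab[cbind(qx[ok], qy[ok])]
      hit <- v > 0L & v != id
      contact <- contact | hit
      touching <- union(touching, v[hit])
    }
    nf[k] <- mean(contact)
    nbrs[[k]] <- touching
  }

  # colony structure from the adjacency graph
  edges <- do.call(rbind, lapply(seq_along(ids), function(k) {
    if (length(nbrs[[k]]) == 0L) return(NULL)
    cbind(ids[k], nbrs[[k]])
  }))
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- as.character(ids)
  if (!is.null(edges)) {
    em <- unique(t(apply(edges, 1, sort)))
    g <- igraph::add_edges(g, t(matrix(match(em, ids), ncol = 2)))
  }
  comp <- igraph::components(g)
  colony_id <- comp$membership
  colony_size <- comp$csize[colony_id]
  colony_area <- as.numeric(tapply(areas, colony_id, sum))[colony_id]

  border <- as.numeric(ids %in% regions$border_cells)
  if (length(ids) > 1L) {
    dd <- as.matrix(stats::dist(cents)) * px
    diag(dd) <- Inf
    nnd <- apply(dd, 1, min)
  } else {
    nnd <- sqrt(nx^2 + ny^2) * px  # finite sentinel: image diagonal
  }

  data.frame(cell_id = ids, neighbor_fraction = nf,
             n_neighbors = vapply(nbrs, length, integer(1)),
             colony_id = as.numeric(colony_id),
             colony_size = as.numeric(colony_size),
             colony_area = colony_area,
             is_edge_cell = as.numeric(nf < edge_nf_threshold | border > 0),
             is_border_cell = border,
             nn_centroid_dist = as.numeric(nnd),
             stringsAsFactors = FALSE)
}

#' Intensity features, ruffliness, and the nuclear/perinuclear TF ratio
#'
#' Per-region (nucleus, cytoplasm, membrane band, perinuclear ring, whole
#' cell) mean, SD and integrated intensity for the cell-body and TF
#' channels; ruffliness = coefficient of variation of the body-channel
#' intensity over the membrane band; \code{tf_ratio} = mean TF intensity
#' over the nucleus / mean TF intensity over the perinuclear ring, the
#' screen's NF-kB activation proxy.
#'
#' @param regions A \code{RegionLabels} object.
#' @param channels Named list with numeric matrices \code{body} and
#'   \code{tf}, aligned with the label images.
#' @return data.frame keyed by \code{cell_id} with the intensity feature
#'   columns plus \code{ratio_valid} (FALSE when the ring mean is zero or
#'   the ring is empty; such records are excluded downstream).
#' @export
intensity_features <- function(regions, channels) {
  stopifnot(inherits(regions, "RegionLabels"))
  if (is.null(channels$body) || is.null(channels$tf))
    stop("channels must contain 'body' and 'tf' matrices")
  body <- as.matrix(channels$body); tf <- as.matrix(channels$tf)
  if (!all(dim(body) == dim(regions$cell)) ||
      !all(dim(tf) == dim(regions$cell)))
    stop("channel images not aligned with label images")
  ids <- regions$cell_ids
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    cellpix <- regions$cell == id
    nucpix <- regions$nucleus == id
    cytopix <- cellpix & !nucpix
    mempix <- regions$membrane == id
    ringpix <- regions$ring == id
    reg <- list(nuc = nucpix, cyto = cytopix, mem = mempix,
                ring = ringpix, cell = cellpix)
    vals <- list()
    for (rn in names(reg)) {
      for (chn in c("body", "tf")) {
        v <- (if (chn == "body") body else tf)[reg[[rn]]]
        m <- if (length(v)) mean(v) else 0
        s <- if (length(v) > 1L) stats::sd(v) else 0
        vals[[sprintf("%s_%s_mean", rn, chn)]] <- m
        vals[[sprintf("%s_%s_sd", rn, chn)]] <- s
        vals[[sprintf("%s_%s_total", rn, chn)]] <- sum(v)
      }
    }
    ring_tf_mean <- vals$ring_tf_mean
    ratio_valid <- sum(ringpix) > 0L && ring_tf_mean > 0
    tf_ratio <- if (ratio_valid) vals$nuc_tf_mean / ring_tf_mean else NA_real_
    safe_div <- function(a, b) if (b > 0) a / b else 0
    row <- data.frame(
      cell_id = id,
      as.data.frame(vals),
      ruffliness = if (sum(mempix) > 1L && vals$mem_body_mean > 0)
        vals$mem_body_sd / vals$mem_body_mean else 0,
      ring_body_cv = if (sum(ringpix) > 1L && vals$ring_body_mean > 0)
        vals$ring_body_sd / vals$ring_body_mean else 0,
      cell_body_cv = safe_div(vals$cell_body_sd, vals$cell_body_mean),
      tf_ratio = tf_ratio,
      log10_tf_ratio = if (ratio_valid && tf_ratio > 0) log10(tf_ratio)
        else NA_real_,
      tf_nuc_cell_ratio = safe_div(vals$nuc_tf_mean, vals$cell_tf_mean),
      tf_nuc_fraction = safe_div(vals$nuc_tf_total, vals$cell_tf_total),
      body_nuc_cyto_ratio = safe_div(vals$nuc_body_mean,
                                     vals$cyto_body_mean),
      mem_cell_ratio_body = safe_div(vals$mem_body_mean,
                                     vals$cell_body_mean),
      ring_cell_ratio_tf = safe_div(vals$ring_tf_mean, vals$cell_tf_mean),
      ratio_valid = ratio_valid,
      stringsAsFactors = FALSE)
    out[[k]] <- row
  }
  if (length(out) == 0L) {
    nm <- feature_catalog()
    nm <- nm$feature[nm$category == "intensity"]
    df <- empty_feature_frame(nm)
    df$ratio_valid <- logical(0)
    return(df)
  }
  do.call(rbind, out)
}

#' Extract the full 77-feature table from one scene
#'
#' Segments (or accepts true labels for) a scene and assembles one row per
#' retained cell with exactly the 77 catalog features plus metadata
#' columns. Cells without a nucleus or with an invalid perinuclear ring
#' (zero TF reference signal) are excluded.
#'
#' @param nucleus_img,body_img,tf_img Channel matrices; \code{tf_img}
#'   carries the transcription-factor stain.
#' @param pixel_size Micrometres per pixel.
#' @param metadata Named list of metadata values recycled over cells
#'   (e.g. \code{list(line_id = "MCF7", well_id = "A01", medium = "base",
#'   treatment = "untreated", field_id = 1)}).
#' @param true_labels Optional ground-truth label list, see
#'   \code{\link{segment_regions}}.
#' @param ... Passed to \code{\link{segment_regions}}.
#' @return data.frame with \code{cell_metadata_columns()} followed by the
#'   77 catalog features, all finite; attribute \code{"regions"} holds the
#'   \code{RegionLabels} used.
#' @export
extract_feature_table <- function(nucleus_img, body_img, tf_img,
                                  pixel_size = 0.65, metadata = list(),
                                  true_labels = NULL, ...) {
  regions <- segment_regions(nucleus_img, body_img, pixel_size = pixel_size,
                             true_labels = true_labels, ...)
  tab <- measure_cells(regions, channels = list(body = body_img, tf = tf_img))
  md <- utils::modifyList(
    list(field_id = 1L, well_id = "W01", line_id = "synthetic",
         medium = "base", treatment = "untreated"), metadata)
  n <- nrow(tab)
  meta_df <- data.frame(cell_id = tab$cell_id,
                        field_id = rep(md$field_id, length.out = max(n, 0)),
                        well_id = rep(md$well_id, length.out = max(n, 0)),
                        line_id = rep(md$line_id, length.out = max(n, 0)),
                        medium = rep(md$medium, length.out = max(n, 0)),
                        treatment = rep(md$treatment, length.out = max(n, 0)),
                        stringsAsFactors = FALSE)
  out <- cbind(meta_df, tab[, setdiff(names(tab), "cell_id"), drop = FALSE])
  missing_feats <- setdiff(feature_catalog()$feature, names(out))
  if (length(missing_feats) > 0L)
    stop("catalog features unmapped: ", paste(missing_feats, collapse = ", "))
  out <- out[, c(cell_metadata_columns(), feature_catalog()$feature)]
  attr(out, "regions") <- regions
  out
}

# shared measurement core: geometry + context + intensity on given regions,
# restricted to ring-valid cells, all catalog columns finite
measure_cells <- function(regions, channels) {
  sf <- shape_features(regions)
  cf <- context_features(regions)
  inf <- intensity_features(regions, channels)
  tab <- merge(merge(sf, cf, by = "cell_id"), inf, by = "cell_id")
  drop <- !tab$ratio_valid | !is.finite(tab$tf_ratio) |
    !stats::complete.cases(tab[, feature_catalog()$feature])
  if (any(drop)) {
    warning(sprintf("excluding %d cell(s) with invalid ring or non-finite features",
                    sum(drop)))
    tab <- tab[!drop, , drop = FALSE]
  }
  tab
}
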