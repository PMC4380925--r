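#' Specify a synthetic two-channel microscopy scene
#'
#' Describes a scene of cells rendered as radially perturbed ellipses with
#' optional protrusion lobes, organised in colonies. Contacting cells abut
#' (shared boundaries, no body overlap); nuclei are offset ellipses strictly
#' inside their cell. The TF channel is painted so that the mean nuclear /
#' mean perinuclear intensity of each cell equals its (optionally noisy)
#' planted ratio target.
#'
#' @param image_size Image edge length, pixels (square scene).
#' @param pixel_size Micrometres per pixel.
#' @param colony_plan data.frame with columns \code{x}, \code{y} (colony
#'   center, pixels), \code{n} (cells) and optionally \code{spacing}
#'   (center spacing as a multiple of the cell diameter; < 1 gives
#'   contact). When NULL, \code{n_cells} isolated cells are scattered.
#' @param n_cells Number of scattered cells when no colony plan is given.
#' @param body_radius Mean cell-body radius, micrometres.
#' @param body_radius_cv Cell-to-cell CV of the body radius.
#' @param eccentricity Ellipse eccentricity of the cell body in [0, 1).
#' @param protrusion_count,protrusion_length Number of protrusion lobes per
#'   cell and their length as a fraction of the local radius.
#' @param ruffle_amplitude SD of the smooth radial boundary perturbation
#'   (fraction of radius); also modulates membrane-band staining so that
#'   rendered ruffliness tracks it.
#' @param nuc_radius_frac,nuc_offset_frac Nucleus radius and centroid
#'   offset as fractions of the body radius; their sum must stay below
#'   0.9 so the nucleus fits at the stated offset.
#' @param tf_baseline Cytoplasmic TF intensity (arbitrary units).
#' @param tf_ratio_target Planted nuclear/perinuclear TF ratio (> 0).
#' @param tf_ratio_sd_log10 Per-cell SD of the planted log10 ratio.
#' @param pixel_noise_sd Additive Gaussian pixel noise SD on all channels.
#' @param seed Integer seed; same spec + seed gives identical pixels.
#' @return Object of class \code{SceneSpec}.
#' @export
scene_spec <- function(image_size = 512L, pixel_size = 0.65,
                       colony_plan = NULL, n_cells = 10L,
                       body_radius = 20, body_radius_cv = 0.1,
                       eccentricity = 0.6, protrusion_count = 0L,
                       protrusion_length = 0.35, ruffle_amplitude = 0.03,
                       nuc_radius_frac = 0.45, nuc_offset_frac = 0.15,
                       tf_baseline = 1000, tf_ratio_target = 1.5,
                       tf_ratio_sd_log10 = 0, pixel_noise_sd = 0,
                       seed = 1L) {
  if (is.null(colony_plan)) {
    if (n_cells < 0L) stop("n_cells must be >= 0")
  } else {
    stopifnot(is.data.frame(colony_plan),
              all(c("x", "y", "n") %in% names(colony_plan)))
    if (is.null(colony_plan$spacing)) colony_plan$spacing <- 0.95
    n_cells <- sum(colony_plan$n)
  }
  if (body_radius <= 0) stop("body_radius must be > 0")
  if (eccentricity < 0 || eccentricity >= 1)
    stop("eccentricity must be in [0, 1)")
  if (nuc_radius_frac <= 0) stop("nucleus radius must be > 0")
  if (nuc_radius_frac + nuc_offset_frac >= 0.9)
    stop("nucleus does not fit inside the cell body at the stated offset")
  if (tf_ratio_target <= 0) stop("tf_ratio_target must be > 0")
  structure(list(image_size = as.integer(image_size),
                 pixel_size = pixel_size, colony_plan = colony_plan,
                 n_cells = as.integer(n_cells), body_radius = body_radius,
                 body_radius_cv = body_radius_cv,
                 eccentricity = eccentricity,
                 protrusion_count = as.integer(protrusion_count),
                 protrusion_length = protrusion_length,
                 ruffle_amplitude = ruffle_amplitude,
                 nuc_radius_frac = nuc_radius_frac,
                 nuc_offset_frac = nuc_offset_frac,
                 tf_baseline = tf_baseline,
                 tf_ratio_target = tf_ratio_target,
                 tf_ratio_sd_log10 = tf_ratio_sd_log10,
                 pixel_noise_sd = pixel_noise_sd,
                 seed = as.integer(seed)),
            class = "SceneSpec")
}

#' Render a synthetic scene with ground truth
#'
#' Draws the scene described by a \code{\link{scene_spec}}: nucleus-stain,
#' cell-body and TF intensity channels, the true nucleus/cell label
#' images, and a ground-truth cell table. The truth table contains the
#' full catalog measured on the true label images (the generative
#' geometry, measured exactly), plus the planted per-cell TF ratio in
#' \code{true_tf_ratio}. Overlapping body claims are resolved by nearest
#' normalized radius, so contacting cells share boundaries but never
#' overlap; nucleus pixels always belong to their own cell.
#'
#' @param spec A \code{SceneSpec}.
#' @return List with matrices \code{nucleus}, \code{body}, \code{tf},
#'   label list \code{labels} (\code{$nucleus}, \code{$cell}), the
#'   \code{truth} data.frame, and the echoed \code{spec}.
#' @export
simulate_scene <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  with_seed(spec$seed, render_scene(spec))
}

render_scene <- function(spec) {
  n <- spec$image_size
  px <- spec$pixel_size
  r_px <- spec$body_radius / px

  centers <- place_cells(spec, r_px)
  ncell <- nrow(centers)

  cell_lab <- matrix(0L, n, n)
  nuc_lab <- matrix(0L, n, n)
  claim <- matrix(Inf, n, n)
  ruffle_field <- matrix(0, n, n)  # per-pixel ruffle modulation near membrane

  ntheta <- 720L
  theta <- seq(0, 2 * pi, length.out = ntheta + 1L)[-(ntheta + 1L)]
  cell_params <- vector("list", ncell)

  for (i in seq_len(ncell)) {
    ri <- r_px * max(0.3, 1 + stats::rnorm(1, 0, spec$body_radius_cv))
    e <- spec$eccentricity
    a <- ri * (1 - e^2)^(-1 / 4)
    b <- ri * (1 - e^2)^(1 / 4)
    phi <- stats::runif(1, 0, 2 * pi)
    # smooth ruffle harmonics, normalized to the requested SD
    ruff <- rep(0, ntheta)
    if (spec$ruffle_amplitude > 0) {
      for (k in 3:8)
        ruff <- ruff + stats::rnorm(1) * cos(k * theta + stats::runif(1, 0, 2 * pi))
      ruff <- ruff / max(pop_sd(ruff), 1e-9) * spec$ruffle_amplitude
    }
    bump <- rep(0, ntheta)
    if (spec$protrusion_count > 0L) {
      for (p in seq_len(spec$protrusion_count)) {
        th0 <- stats::runif(1, 0, 2 * pi)
        dth <- pmin(abs(theta - th0), 2 * pi - abs(theta - th0))
        bump <- bump + spec$protrusion_length * exp(-0.5 * (dth / 0.22)^2)
      }
    }
    thr <- theta - phi
    r_ell <- a * b / sqrt((b * cos(thr))^2 + (a * sin(thr))^2)
    r_theta <- pmax(r_ell * (1 + ruff + bump), 2)
    cell_params[[i]] <- list(center = centers[i, 1:2], r_theta = r_theta,
                             ruff = ruff, a = a, b = b, phi = phi, ri = ri)

    # rasterize with normalized-radius claims
    rmax <- max(r_theta)
    xr <- max(1L, floor(centers[i, 1] - rmax - 1)):
      min(n, ceiling(centers[i, 1] + rmax + 1))
    yr <- max(1L, floor(centers[i, 2] - rmax - 1)):
      min(n, ceiling(centers[i, 2] + rmax + 1))
    dx <- outer(xr - centers[i, 1], rep(1, length(yr)))
    dy <- outer(rep(1, length(xr)), yr - centers[i, 2])
    rho <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx) %% (2 * pi)
    aidx <- pmin(ntheta, floor(ang / (2 * pi) * ntheta) + 1L)
    cl <- rho / r_theta[aidx]
    sel <- cl <= 1 & cl < claim[xr, yr]
    sub_lab <- cell_lab[xr, yr]; sub_claim <- claim[xr, yr]
    sub_ruf <- ruffle_field[xr, yr]
    sub_lab[sel] <- i
    sub_claim[sel] <- cl[sel]
    # membrane-zone staining modulation follows the ruffle pattern
    memsel <- sel & cl > 0.8
    sub_ruf[memsel] <- ruff[aidx[memsel]] / max(spec$ruffle_amplitude, 1e-9)
    cell_lab[xr, yr] <- sub_lab
    claim[xr, yr] <- sub_claim
    ruffle_field[xr, yr] <- sub_ruf
  }

  # nuclei: offset ellipse, forced onto own cell; cross-cell nucleus
  # overlap is a packing failure
  for (i in seq_len(ncell)) {
    p <- cell_params[[i]]
    rn <- spec$nuc_radius_frac * p$ri
    off_dir <- stats::runif(1, 0, 2 * pi)
    ncx <- p$center[1] + spec$nuc_offset_frac * p$ri * cos(off_dir)
    ncy <- p$center[2] + spec$nuc_offset_frac * p$ri * sin(off_dir)
    an <- rn * 1.1; bn <- rn / 1.1
    phin <- stats::runif(1, 0, 2 * pi)
    xr <- max(1L, floor(ncx - an - 1)):min(n, ceiling(ncx + an + 1))
    yr <- max(1L, floor(ncy - an - 1)):min(n, ceiling(ncy + an + 1))
    dx <- outer(xr - ncx, rep(1, length(yr)))
    dy <- outer(rep(1, length(xr)), yr - ncy)
    u <- dx * cos(phin) + dy * sin(phin)
    v <- -dx * sin(phin) + dy * cos(phin)
    inside <- (u / an)^2 + (v / bn)^2 <= 1
    sub_n <- nuc_lab[xr, yr]
    if (any(sub_n[inside] > 0L))
      stop(sprintf("placement error: nucleus overlap involving cell %d", i))
    sub_n[inside] <- i
    nuc_lab[xr, yr] <- sub_n
    sub_c <- cell_lab[xr, yr]
    sub_c[inside] <- i   # nucleus pixels always belong to their own cell
    cell_lab[xr, yr] <- sub_c
  }

  # channels
  nucleus_img <- matrix(80, n, n)
  nucleus_img[nuc_lab > 0L] <- 3000
  body_img <- matrix(60, n, n)
  body_img[cell_lab > 0L] <- 1200 * (1 + 0.15 * ruffle_field[cell_lab > 0L])
  body_img[nuc_lab > 0L] <- 1000
  # cell-cell junctions are optically resolvable in a real body stain:
  # render a subtle intensity dip along shared boundaries
  seam <- cell_lab > 0L &
    (rbind(cell_lab[-1, ], 0L) != cell_lab & rbind(cell_lab[-1, ], 0L) > 0L |
     rbind(0L, cell_lab[-n, ]) != cell_lab & rbind(0L, cell_lab[-n, ]) > 0L |
     cbind(cell_lab[, -1], 0L) != cell_lab & cbind(cell_lab[, -1], 0L) > 0L |
     cbind(0L, cell_lab[, -n]) != cell_lab & cbind(0L, cell_lab[, -n]) > 0L)
  body_img[seam] <- body_img[seam] * 0.72

  ratios <- spec$tf_ratio_target *
    10^(stats::rnorm(ncell, 0, spec$tf_ratio_sd_log10))
  tf_img <- matrix(40, n, n)
  tf_img[cell_lab > 0L] <- spec$tf_baseline
  nz <- which(nuc_lab > 0L)
  tf_img[nz] <- spec$tf_baseline * ratios[nuc_lab[nz]]

  if (spec$pixel_noise_sd > 0) {
    nucleus_img <- pmax(nucleus_img +
                          stats::rnorm(n * n, 0, spec$pixel_noise_sd), 0)
    body_img <- pmax(body_img + stats::rnorm(n * n, 0, spec$pixel_noise_sd), 0)
    tf_img <- pmax(tf_img + stats::rnorm(n * n, 0, spec$pixel_noise_sd), 0)
  }

  labels <- list(nucleus = nuc_lab, cell = cell_lab)
  regions <- region_labels(nuc_lab, cell_lab, pixel_size = px)
  truth <- suppressWarnings(
    measure_cells(regions, channels = list(body = body_img, tf = tf_img)))
  truth$true_tf_ratio <- ratios[truth$cell_id]
  truth$colony <- centers[truth$cell_id, 3]

  list(nucleus = nucleus_img, body = body_img, tf = tf_img,
       labels = labels, truth = truth, spec = spec)
}

# colony layout: hexagonal shells around each colony center; scattered
# placement with rejection sampling otherwise
place_cells <- function(spec, r_px) {
  n <- spec$image_size
  out <- NULL
  if (!is.null(spec$colony_plan)) {
    for (ci in seq_len(nrow(spec$colony_plan))) {
      cp <- spec$colony_plan[ci, ]
      d <- cp$spacing * 2 * r_px
      pos <- hex_layout(cp$n, cp$x, cp$y, d)
      margin <- 1.6 * r_px
      if (any(pos[, 1] < margin | pos[, 1] > n - margin |
              pos[, 2] < margin | pos[, 2] > n - margin))
        stop(sprintf("placement error: colony %d does not fit in the image", ci))
      out <- rbind(out, cbind(pos, ci))
    }
  } else if (spec$n_cells > 0L) {
    margin <- 1.8 * r_px
    if (2 * margin >= n)
      stop("placement error: colony 1 cells larger than the image")
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0L
    while (nrow(pts) < spec$n_cells) {
      cand <- c(stats::runif(1, margin, n - margin),
                stats::runif(1, margin, n - margin))
      ok <- nrow(pts) == 0L ||
        all(sqrt(rowSums(sweep(pts, 2, cand)^2)) > 2.6 * r_px)
      if (ok) pts <- rbind(pts, cand)
      tries <- tries + 1L
      if (tries > 20000L)
        stop("placement error: colony 1 cannot be packed without overlap")
    }
    out <- cbind(pts, seq_len(spec$n_cells))
  } else {
    out <- matrix(numeric(0), 0, 3)
  }
  colnames(out) <- c("x", "y", "colony")
  out
}

# positions on a hexagonal lattice spiral: center, then rings of 6, 12, ...
hex_layout <- function(k, cx, cy, d) {
  pos <- matrix(c(cx, cy), 1, 2)
  ring <- 1L
  while (nrow(pos) < k) {
    for (j in seq_len(6L * ring)) {
      ang <- 2 * pi * (j - 1) / (6L * ring) + (ring %% 2) * pi / 6
      pos <- rbind(pos, c(cx + ring * d * cos(ang), cy + ring * d * sin(ang)))
      if (nrow(pos) >= k) break
    }
    ring <- ring + 1L
  }
  pos[seq_len(k), , drop = FALSE]
}

#' Write a rendered scene to disk
#'
#' Channels and label images as 16-bit TIFF, ground truth as CSV, and all
#' generator parameters echoed to a JSON sidecar.
#'
#' @param scene Result of \code{\link{simulate_scene}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- character(0)
  sc <- 1 / 65535
  for (ch in c("nucleus", "body", "tf")) {
    p <- file.path(dir, paste0(ch, ".tif"))
    EBImage::writeImage(EBImage::Image(pmin(scene[[ch]] * sc, 1)), p,
                        type = "tiff", bits.per.sample = 16L)
    f <- c(f, p)
  }
  for (lb in c("nucleus", "cell")) {
    p <- file.path(dir, paste0("labels_", lb, ".tif"))
    EBImage::writeImage(EBImage::Image(scene$labels[[lb]] * sc), p,
                        type = "tiff", bits.per.sample = 16L)
    f <- c(f, p)
  }
  tp <- file.path(dir, "truth.csv")
  utils::write.csv(scene$truth, tp, row.names = FALSE)
  sp <- file.path(dir, "scene_spec.json")
  jsonlite::write_json(unclass(scene$spec)[
    !vapply(unclass(scene$spec), is.data.frame, logical(1))],
    sp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(f, tp, sp))
}
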