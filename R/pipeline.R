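#' Validate a run configuration
#'
#' A run configuration is a named list (or a YAML file path) with a
#' \code{stages} vector (subset of \code{scene}, \code{features},
#' \code{profile}, \code{networks}, \code{regression}, \code{dynamics}),
#' per-stage seeds, an output directory, and optional threshold overrides
#' (confidence 0.6, alpha 0.01, folds 10, level 0.95, dt 5 by default).
#' Unknown keys and missing input files fail validation before any stage
#' runs.
#'
#' @param config Named list or path to a YAML file.
#' @return The normalized configuration (class \code{RunConfig}).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    stages = c("scene", "features", "profile", "networks", "regression",
               "dynamics"),
    out_dir = tempfile("morphloc_run_"),
    seed = 1L,
    seeds = list(),
    inputs = list(),
    n_cells_table = 400L,
    n_lines = 3L,
    n_traces = 12L,
    bootstrap = 30L,
    thresholds = list(confidence = 0.6, confidence_high = 0.9,
                      alpha = 0.01, folds = 10L, level = 0.95, dt = 5))
  known <- names(defaults)
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  bad_stage <- setdiff(cfg$stages, defaults$stages)
  if (length(bad_stage) > 0L)
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  for (p in unlist(cfg$inputs))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  # every stochastic stage gets a seed derived from the master seed
  for (st in cfg$stages)
    if (is.null(cfg$seeds[[st]]))
      cfg$seeds[[st]] <- (cfg$seed * 131L + match(st, defaults$stages)) %%
        .Machine$integer.max
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the screen pipeline end to end
#'
#' Executes the requested stages in dependency order on bundled synthetic
#' inputs (or user tables supplied via \code{config$inputs$cells} /
#' \code{$foldchanges} / \code{$traces}): scene simulation, feature
#' extraction, well profiling + PCA + clustering + feature selection,
#' per-line dependency networks and their frequency summary, the
#' shape-response regression with cross-validation, and wavelet dynamics.
#' All outputs (CSV/JSON/GraphML/Newick) land under \code{out_dir}
#' together with a manifest recording seeds, parameters and file hashes;
#' rerunning with the same configuration reproduces every output
#' byte-identically.
#'
#' @param config A \code{\link{run_config}} (or list / YAML path).
#' @return Invisibly, a list of stage results plus \code{manifest}.
#' @export
run_screen <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  written <- character(0)
  log_path <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  cat("", file = log_path)
  logline("morphloc run; master seed %d", cfg$seed)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s (partial outputs kept in %s)",
                   name, conditionMessage(e), cfg$out_dir), call. = FALSE))
  }

  if ("scene" %in% cfg$stages) {
    res$scene <- step("scene", {
      spec <- scene_spec(
        image_size = 384L,
        colony_plan = data.frame(x = c(110, 270), y = c(110, 260),
                                 n = c(4, 5), spacing = 0.95),
        tf_ratio_target = 1.6, tf_ratio_sd_log10 = 0.08,
        seed = cfg$seeds$scene)
      sc <- simulate_scene(spec)
      written <<- c(written, write_scene(sc, file.path(cfg$out_dir, "scene")))
      logline("scene: %d cells rendered", nrow(sc$truth))
      sc
    })
  }

  if ("features" %in% cfg$stages) {
    res$features <- step("features", {
      if (!is.null(cfg$inputs$cells)) {
        cells <- utils::read.csv(cfg$inputs$cells, stringsAsFactors = FALSE)
      } else {
        sc <- res$scene
        if (is.null(sc)) {
          spec <- scene_spec(image_size = 384L,
                             colony_plan = data.frame(
                               x = c(110, 270), y = c(110, 260),
                               n = c(4, 5), spacing = 0.95),
                             tf_ratio_target = 1.6, tf_ratio_sd_log10 = 0.08,
                             seed = cfg$seeds$features)
          sc <- simulate_scene(spec)
        }
        cells <- extract_feature_table(sc$nucleus, sc$body, sc$tf,
                                       pixel_size = sc$spec$pixel_size)
      }
      p <- file.path(cfg$out_dir, "cells.csv")
      utils::write.csv(cells, p, row.names = FALSE)
      written <<- c(written, p)
      logline("features: %d cells x %d catalog features", nrow(cells), 77L)
      cells
    })
  }

  # multi-line synthetic single-cell table for profiling/networks
  sim_lines <- function(seed) {
    feats <- canonical17_features()
    tabs <- lapply(seq_len(cfg$n_lines), function(li) {
      planted <- planted_dependency(
        feats,
        edges = data.frame(
          from = c("cell_area", "ruffliness", "neighbor_fraction"),
          to = "tf_ratio",
          coef = c(-0.4, 0.5, -0.3) * (1 + 0.1 * li)),
        noise_sd = c(tf_ratio = 0.15),
        treatment_shift = c(untreated = 0, tnf_1h = 0.3))
      simulate_feature_table(planted, n_cells = cfg$n_cells_table,
                             conditions = c("untreated", "tnf_1h"),
                             seed = seed + li,
                             line_id = sprintf("line%02d", li))$table
    })
    do.call(rbind, tabs)
  }

  if ("profile" %in% cfg$stages) {
    res$profile <- step("profile", {
      cells <- sim_lines(cfg$seeds$profile)
      wp <- well_profiles(cells)
      pca <- pca_scores(wp$z, k = min(8L, nrow(wp$z) - 1L))
      sc_lines <- rowsum(pca$scores, wp$profiles$line_id) /
        as.vector(table(wp$profiles$line_id))
      cl <- cluster_lines(sc_lines, k = min(2L, nrow(sc_lines)))
      sel <- select_discriminative_features(cells, k = 17L,
                                            alpha = cfg$thresholds$alpha)
      p1 <- file.path(cfg$out_dir, "well_profiles.csv")
      utils::write.csv(wp$profiles, p1, row.names = FALSE)
      p2 <- file.path(cfg$out_dir, "dendrogram.nwk")
      ape::write.tree(ape::as.phylo(cl$hclust), file = p2)
      p3 <- file.path(cfg$out_dir, "selected_features.json")
      jsonlite::write_json(list(selected = sel$selected,
                                votes = as.list(sel$votes)),
                           p3, auto_unbox = TRUE, digits = NA)
      written <<- c(written, p1, p2, p3)
      logline("profile: %d wells, %d PCs, %d features selected",
              nrow(wp$profiles), ncol(pca$scores), length(sel$selected))
      list(cells = cells, profiles = wp, pca = pca, clustering = cl,
           selection = sel)
    })
  }

  if ("networks" %in% cfg$stages) {
    res$networks <- step("networks", {
      cells <- if (!is.null(res$profile)) res$profile$cells
               else sim_lines(cfg$seeds$networks)
      nodecols <- c("cell_area", "ruffliness", "neighbor_fraction",
                    "area_nuc_cyto", "nuc_area")
      nodecols <- intersect(c(nodecols, "log10_tf_ratio"), names(cells))
      nets <- list()
      for (li in unique(cells$line_id)) for (tr in unique(cells$treatment)) {
        d <- cells[cells$line_id == li & cells$treatment == tr, nodecols]
        names(d)[names(d) == "log10_tf_ratio"] <- "tf_ratio"
        disc <- discretize_features(d)
        nw <- learn_network(disc, B = cfg$bootstrap,
                            seed = cfg$seeds$networks + nchar(li) +
                              match(tr, unique(cells$treatment)),
                            conf_threshold = cfg$thresholds$confidence,
                            metadata = list(line_id = li, treatment = tr))
        pth <- file.path(cfg$out_dir,
                         sprintf("network_%s_%s.graphml", li, tr))
        write_network_graphml(nw, pth)
        written <<- c(written, pth)
        nets[[length(nets) + 1L]] <- nw
      }
      summ <- dependency_summary(nets, threshold = cfg$thresholds$confidence)
      p <- file.path(cfg$out_dir, "dependency_frequency.csv")
      utils::write.csv(summ, p, row.names = FALSE)
      written <<- c(written, p)
      logline("networks: %d models, confidence threshold %g",
              length(nets), cfg$thresholds$confidence)
      list(networks = nets, summary = summ)
    })
  }

  if ("regression" %in% cfg$stages) {
    res$regression <- step("regression", {
      fc <- if (!is.null(cfg$inputs$foldchanges))
        utils::read.csv(cfg$inputs$foldchanges, stringsAsFactors = FALSE)
      else simulate_fold_change_panel(
        default_panel_coefficients(), n_conditions = 176L,
        noise_sd = panel_noise_for_r2(default_panel_coefficients(), 0.37),
        seed = cfg$seeds$regression)
      cvres <- crossvalidate_and_flag_outliers(
        fc, folds = cfg$thresholds$folds, seed = cfg$seeds$regression,
        level = cfg$thresholds$level)
      rep_ <- list(coefficients = as.list(cvres$model$coefficients),
                   r_squared = cvres$model$r_squared,
                   error_variance = cvres$model$error_variance,
                   p_value = cvres$model$p_value,
                   cv_mae_mean = cvres$cv_mae_mean,
                   cv_mae_sd = cvres$cv_mae_sd,
                   outliers = cvres$outliers)
      p <- file.path(cfg$out_dir, "regression_report.json")
      jsonlite::write_json(rep_, p, auto_unbox = TRUE, digits = NA)
      p2 <- file.path(cfg$out_dir, "regression_residuals.csv")
      utils::write.csv(
        data.frame(condition_id = fc$condition_id,
                   residual = stats::residuals(cvres$model$fit)),
        p2, row.names = FALSE)
      written <<- c(written, p, p2)
      logline("regression: R^2 = %.3f, %d outliers",
              cvres$model$r_squared, cvres$n_outliers)
      cvres
    })
  }

  if ("dynamics" %in% cfg$stages) {
    res$dynamics <- step("dynamics", {
      traces <- if (!is.null(cfg$inputs$traces))
        frame_to_traces(utils::read.csv(cfg$inputs$traces,
                                        stringsAsFactors = FALSE))
      else {
        conds <- list(control = 115, y27 = 120, noc = 60)
        unlist(lapply(names(conds), function(cn)
          lapply(seq_len(cfg$n_traces), function(i)
            simulate_trace(oscillation_params(
              period = conds[[cn]], noise_sd = 0.02,
              dt = cfg$thresholds$dt, duration = 355,
              seed = cfg$seeds$dynamics + i * 7L +
                match(cn, names(conds)) * 1000L),
              cell_id = i, condition = cn))), recursive = FALSE)
      }
      peaks <- do.call(rbind, lapply(traces, function(tr) {
        pk <- first_peak_metrics(tr)
        data.frame(cell_id = tr$cell_id, condition = tr$condition,
                   amplitude = pk$amplitude, time = pk$time,
                   flag = pk$flag, stringsAsFactors = FALSE)
      }))
      hist_ <- suppressWarnings(
        period_frequency_comparison(traces, t = 180))
      p1 <- file.path(cfg$out_dir, "first_peaks.csv")
      utils::write.csv(peaks, p1, row.names = FALSE)
      p2 <- file.path(cfg$out_dir, "period_frequencies.csv")
      utils::write.csv(hist_, p2, row.names = FALSE)
      written <<- c(written, p1, p2)
      logline("dynamics: %d traces, %d period-histogram rows",
              length(traces), nrow(hist_))
      list(traces = traces, peaks = peaks, histogram = hist_)
    })
  }

  manifest <- list(
    package = "morphloc",
    version = as.character(utils::packageVersion("morphloc")),
    stages = cfg$stages,
    seed = cfg$seed,
    seeds = cfg$seeds,
    thresholds = cfg$thresholds,
    files = lapply(stats::setNames(written, basename(written)),
                   function(p) unname(tools::md5sum(p))))
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

#' Map an external table onto the canonical schema
#'
#' Renames columns of a user-supplied CSV-style table onto the canonical
#' cell-table or fold-change schema; unmapped columns are preserved under
#' an \code{ext.} namespace. Missing required canonical columns after
#' mapping raise a schema error naming them.
#'
#' @param df data.frame to convert.
#' @param column_map Named character vector: canonical name ->  source
#'   column name. Identity entries may be omitted when the source column
#'   already has the canonical name.
#' @param kind \code{"cells"} (requires metadata + tf_ratio) or
#'   \code{"fold_change"} (requires condition_id, d_nf, d_ruffliness,
#'   d_anucacyto, d_tfratio).
#' @return data.frame in canonical column order.
#' @export
convert_external_table <- function(df, column_map = character(0),
                                   kind = c("cells", "fold_change")) {
  kind <- match.arg(kind)
  required <- if (kind == "fold_change")
    c("condition_id", "d_nf", "d_ruffliness", "d_anucacyto", "d_tfratio")
  else c(cell_metadata_columns(), "tf_ratio")
  out <- df
  for (canon in names(column_map)) {
    src <- column_map[[canon]]
    if (!(src %in% names(out)))
      stop(sprintf("mapped source column '%s' not found", src))
    if (canon != src) {
      names(out)[names(out) == src] <- canon
      message(sprintf("column '%s' renamed to '%s'", src, canon))
    }
  }
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols) > 0L)
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  canonical <- if (kind == "cells")
    unique(c(required, feature_catalog()$feature)) else required
  extra <- setdiff(names(out), canonical)
  names(out)[match(extra, names(out))] <-
    ifelse(startsWith(extra, "ext."), extra, paste0("ext.", extra))
  lead <- intersect(canonical, names(out))
  out[, c(lead, setdiff(names(out), lead)), drop = FALSE]
}
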