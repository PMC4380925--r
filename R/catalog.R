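#' The 77-entry single-cell feature catalog
#'
#' Returns the canonical ordered catalog of the 77 shape, context and
#' intensity features measured for every segmented cell, together with a
#' category tag per feature and a flag marking the canonical 17-feature
#' subset used by the dependency-network stage.
#'
#' Categories follow the screen's grouping: cell and nuclear geometry,
#' protrusion, polarity (nucleus/cell centroid displacement), context
#' (cell-cell contact and colony structure) and intensity (per-region
#' statistics of the cell-body and TF channels, membrane ruffliness, and
#' the nuclear/perinuclear TF ratio).
#'
#' @return A data.frame with columns \code{feature} (character, unique),
#'   \code{category} (one of geometry, protrusion, polarity, context,
#'   intensity) and \code{canonical17} (logical).
#' @export
#' @examples
#' cat77 <- feature_catalog()
#' nrow(cat77)              # 77
#' sum(cat77$canonical17)   # 17
feature_catalog <- function() {
  geom_cell <- c("cell_area", "cell_perimeter", "cell_roundness",
                 "cell_length", "cell_width", "cell_length_width",
                 "cell_eccentricity", "cell_extent", "cell_solidity",
                 "cell_equiv_diameter")
  geom_nuc <- c("nuc_area", "nuc_perimeter", "nuc_roundness",
                "nuc_length", "nuc_width", "nuc_length_width",
                "nuc_eccentricity", "nuc_extent", "nuc_solidity",
                "nuc_equiv_diameter")
  geom_ratio <- c("area_nuc_cyto", "area_nuc_cell")
  protrusion <- c("protrusion_count", "protrusion_extent",
                  "protrusion_mean_length", "protrusion_arc_fraction",
                  "boundary_radial_cv")
  polarity <- c("centers_distance", "centers_distance_rel", "nuc_clearance")
  context <- c("neighbor_fraction", "n_neighbors", "colony_size",
               "colony_area", "is_edge_cell", "is_border_cell",
               "nn_centroid_dist")
  regions <- c("nuc", "cyto", "mem", "ring", "cell")
  channels <- c("body", "tf")
  stats_ <- c("mean", "sd", "total")
  grid <- expand.grid(stat = stats_, region = regions, channel = channels,
                      stringsAsFactors = FALSE)
  intensity_basic <- sprintf("%s_%s_%s", grid$region, grid$channel, grid$stat)
  intensity_extra <- c("ruffliness", "ring_body_cv", "cell_body_cv",
                       "tf_ratio", "log10_tf_ratio", "tf_nuc_cell_ratio",
                       "tf_nuc_fraction", "body_nuc_cyto_ratio",
                       "mem_cell_ratio_body", "ring_cell_ratio_tf")
  feature <- c(geom_cell, geom_nuc, geom_ratio, protrusion, polarity,
               context, intensity_basic, intensity_extra)
  category <- c(rep("geometry", length(c(geom_cell, geom_nuc, geom_ratio))),
                rep("protrusion", length(protrusion)),
                rep("polarity", length(polarity)),
                rep("context", length(context)),
                rep("intensity", length(intensity_basic) +
                      length(intensity_extra)))
  stopifnot(length(feature) == 77L, !anyDuplicated(feature))
  data.frame(feature = feature, category = category,
             canonical17 = feature %in% canonical17_features(),
             stringsAsFactors = FALSE)
}

#' The canonical 17-feature subset
#'
#' The 17 features most frequently significantly different between cells
#' with high and low NF-kB ratios across cell lines; these plus the TF
#' log-ratio are the node vocabulary of the dependency networks.
#'
#' @return Character vector of length 17, a subset of
#'   \code{feature_catalog()$feature}.
#' @export
canonical17_features <- function() {
  c("cell_area", "nuc_area", "cell_roundness", "nuc_roundness",
    "cell_length_width", "cell_eccentricity", "nuc_eccentricity",
    "cell_perimeter", "area_nuc_cyto", "protrusion_count",
    "protrusion_extent", "ruffliness", "centers_distance",
    "centers_distance_rel", "neighbor_fraction", "n_neighbors",
    "colony_size")
}

#' Metadata column names attached to every cell record
#' @return Character vector of metadata column names.
#' @keywords internal
cell_metadata_columns <- function() {
  c("cell_id", "field_id", "well_id", "line_id", "medium", "treatment")
}
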