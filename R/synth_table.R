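#' Specify a planted morphology -> TF-ratio dependency structure
#'
#' Defines the generative model behind synthetic single-cell feature
#' tables: a mixture of morphological states (multi-modal shape
#' distributions), an acyclic set of linear structural equations among
#' features and the TF log-ratio, per-node Gaussian noise, and an additive
#' per-condition shift on the TF log-ratio (e.g. a TNF-alpha response).
#'
#' @param features Character vector of feature node names (the TF node
#'   \code{tf_ratio} is implicit and must not appear here).
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{coef}; \code{to} may be \code{"tf_ratio"}. Must be acyclic.
#' @param noise_sd Named numeric vector of structural noise SDs per node
#'   (defaults to 0.1 for unnamed nodes); all > 0 unless a node is meant
#'   to be deterministic (0 allowed).
#' @param state_mixture List of components, each
#'   \code{list(weight=, mean=named vector, sd=named vector)} over the
#'   feature nodes; weights must sum to 1. Default: a single standard
#'   component.
#' @param treatment_shift Named numeric vector: additive shift on the TF
#'   log-ratio per condition name; conditions absent from it shift by 0.
#' @return Object of class \code{PlantedDependency}.
#' @export
planted_dependency <- function(features,
                               edges = NULL,
                               noise_sd = NULL,
                               state_mixture = NULL,
                               treatment_shift = c(untreated = 0)) {
  stopifnot(is.character(features), length(features) >= 1L)
  if ("tf_ratio" %in% features) stop("tf_ratio is implicit; do not list it")
  nodes <- c(features, "tf_ratio")
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        coef = numeric(0), stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "coef") %in% names(edges)))
  if (nrow(edges) > 0L) {
    if (!all(edges$from %in% features))
      stop("edge sources must be feature nodes")
    if (!all(edges$to %in% nodes))
      stop("edge targets must be feature nodes or tf_ratio")
    g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                       vertices = nodes)
    if (!igraph::is_dag(g)) {
      cyc <- tryCatch(
        names(igraph::feedback_arc_set(g)), error = function(e) NULL)
      stop("planted dag contains a cycle",
           if (!is.null(cyc)) paste0(" (arcs: ",
                                     paste(cyc, collapse = ", "), ")"))
    }
  }
  sd_full <- stats::setNames(rep(0.1, length(nodes)), nodes)
  if (!is.null(noise_sd)) {
    if (any(noise_sd < 0)) stop("noise SDs must be >= 0")
    sd_full[names(noise_sd)] <- noise_sd
  }
  if (is.null(state_mixture))
    state_mixture <- list(list(
      weight = 1,
      mean = stats::setNames(rep(0, length(features)), features),
      sd = stats::setNames(rep(1, length(features)), features)))
  w <- vapply(state_mixture, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("mixture weights must sum to 1")
  for (cmp in state_mixture)
    if (any(cmp$sd <= 0)) stop("mixture SDs must be > 0")
  structure(list(features = features, nodes = nodes, edges = edges,
                 noise_sd = sd_full, state_mixture = state_mixture,
                 treatment_shift = treatment_shift),
            class = "PlantedDependency")
}

#' Simulate a single-cell feature table from a planted dependency
#'
#' Draws each cell's morphological state from the mixture, evaluates the
#' structural equations in topological order (node value = mixture draw +
#' sum of coef x parent + noise), and produces the TF log-ratio from its
#' planted parents plus noise plus the condition's treatment shift.
#' Columns \code{tf_ratio} (= 10^log-ratio) and \code{log10_tf_ratio} are
#' both present.
#'
#' @param planted A \code{\link{planted_dependency}} object.
#' @param n_cells Cells per condition (>= 1).
#' @param conditions Character vector of condition (treatment) names.
#' @param seed Integer seed.
#' @param line_id Line label stored in the metadata columns.
#' @return List with \code{table} (data.frame, \code{n_cells} x
#'   \code{length(conditions)} rows) and \code{network} (the true edge
#'   data.frame).
#' @export
simulate_feature_table <- function(planted, n_cells, conditions = "untreated",
                                   seed = 1L, line_id = "synthetic") {
  stopifnot(inherits(planted, "PlantedDependency"), n_cells >= 1L)
  with_seed(seed, {
    feats <- planted$features
    out <- vector("list", length(conditions))
    for (ci in seq_along(conditions)) {
      cond <- conditions[ci]
      shift <- planted$treatment_shift[cond]
      if (is.na(shift)) shift <- 0
      w <- vapply(planted$state_mixture, `[[`, numeric(1), "weight")
      state <- sample.int(length(w), n_cells, replace = TRUE, prob = w)
      base <- matrix(0, n_cells, length(feats),
                     dimnames = list(NULL, feats))
      for (k in seq_along(planted$state_mixture)) {
        cmp <- planted$state_mixture[[k]]
        sel <- state == k
        if (!any(sel)) next
        mu <- stats::setNames(rep(0, length(feats)), feats)
        sdv <- stats::setNames(rep(1, length(feats)), feats)
        mu[names(cmp$mean)] <- cmp$mean
        sdv[names(cmp$sd)] <- cmp$sd
        for (f in feats)
          base[sel, f] <- stats::rnorm(sum(sel), mu[f], sdv[f])
      }
      vals <- matrix(0, n_cells, length(planted$nodes),
                     dimnames = list(NULL, planted$nodes))
      g <- igraph::graph_from_data_frame(
        planted$edges[, c("from", "to")], vertices = planted$nodes)
      topo <- names(igraph::topo_sort(g))
      for (nd in topo) {
        contrib <- rep(0, n_cells)
        e <- planted$edges[planted$edges$to == nd, , drop = FALSE]
        if (nrow(e) > 0L)
          for (j in seq_len(nrow(e)))
            contrib <- contrib + e$coef[j] * vals[, e$from[j]]
        noise <- if (planted$noise_sd[nd] > 0)
          stats::rnorm(n_cells, 0, planted$noise_sd[nd]) else 0
        if (nd == "tf_ratio") {
          vals[, nd] <- contrib + noise + shift
        } else {
          vals[, nd] <- base[, nd] + contrib + noise
        }
      }
      df <- as.data.frame(vals[, feats, drop = FALSE])
      df$log10_tf_ratio <- vals[, "tf_ratio"]
      df$tf_ratio <- 10^df$log10_tf_ratio
      df <- cbind(data.frame(
        cell_id = (ci - 1L) * n_cells + seq_len(n_cells),
        field_id = 1L,
        well_id = sprintf("%s_%s", line_id, cond),
        line_id = line_id, medium = "base", treatment = cond,
        stringsAsFactors = FALSE), df)
      out[[ci]] <- df
    }
    list(table = do.call(rbind, out), network = planted$edges)
  })
}
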