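#' Aggregate single cells to well profiles and Z-score the feature matrix
#'
#' Computes per-well feature means over retained cells and standardizes
#' each feature column as (value - mean)/SD with the population
#' (divisor-n) SD. Zero-variance features are excluded from the Z matrix
#' with a warning.
#'
#' @param cells Cell table with metadata columns (\code{well_id},
#'   \code{line_id}, \code{medium}, \code{treatment}) and numeric feature
#'   columns.
#' @param features Which feature columns to profile; defaults to every
#'   catalog feature present in the table.
#' @return List with \code{profiles} (data.frame: metadata, n_cells, and
#'   per-feature well means) and \code{z} (numeric matrix of Z-scored well
#'   means, rownames = well ids).
#' @export
well_profiles <- function(cells, features = NULL) {
  if (is.null(features))
    features <- intersect(feature_catalog()$feature, names(cells))
  stopifnot(length(features) >= 1L, "well_id" %in% names(cells))
  sp <- split(cells, cells$well_id)
  profs <- do.call(rbind, lapply(sp, function(d) {
    cbind(data.frame(well_id = d$well_id[1],
                     line_id = if ("line_id" %in% names(d)) d$line_id[1] else NA,
                     medium = if ("medium" %in% names(d)) d$medium[1] else NA,
                     treatment = if ("treatment" %in% names(d))
                       d$treatment[1] else NA,
                     n_cells = nrow(d), stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(d[, features, drop = FALSE]))))
  }))
  rownames(profs) <- NULL
  m <- as.matrix(profs[, features, drop = FALSE])
  rownames(m) <- profs$well_id
  sds <- apply(m, 2, pop_sd)
  keep <- is.finite(sds) & sds > 0
  if (any(!keep))
    warning("zero-variance feature(s) excluded from Z matrix: ",
            paste(features[!keep], collapse = ", "))
  z <- scale(m[, keep, drop = FALSE],
             center = colMeans(m[, keep, drop = FALSE]),
             scale = sds[keep])
  attr(z, "scaled:center") <- colMeans(m[, keep, drop = FALSE])
  attr(z, "scaled:scale") <- sds[keep]
  list(profiles = profs, z = z)
}

#' Principal component scores of a Z-scored profile matrix
#'
#' Eigen-decomposition of the covariance of the (already standardized)
#' matrix; scores are the projections on the leading \code{k} loading
#' vectors, mirroring the screen's morphospace built from the first eight
#' PCs of well-average features.
#'
#' @param z Numeric matrix (wells x features), typically the \code{z} slot
#'   of \code{\link{well_profiles}}.
#' @param k Number of components to keep (truncated to the matrix rank,
#'   with a warning).
#' @return List with \code{scores} (rows x k), \code{loadings}
#'   (features x k, orthonormal), \code{var_fraction} (length k,
#'   non-increasing) and \code{sdev} (all singular values / sqrt(n-1)).
#' @export
pca_scores <- function(z, k = 8L) {
  z <- as.matrix(z)
  if (nrow(z) < 2L) stop("need at least 2 rows for PCA")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (k > rank) {
    warning(sprintf("k = %d exceeds rank %d; truncated", k, rank))
    k <- rank
  }
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       var_fraction = vf[seq_len(k)],
       sdev = pc$sdev)
}

#' Hierarchical clustering of cell lines in morphospace
#'
#' Distance = 1 - Pearson correlation of the mean-centered score vectors
#' (centered correlation); centroid linkage; merge order is deterministic
#' with index tie-breaking (hclust). Constant rows, whose correlation is
#' undefined, are excluded with a warning.
#'
#' @param scores Numeric matrix (lines x components), rownames = line ids.
#' @param k Number of flat clusters to cut (NULL for none).
#' @param h Cut height alternative to \code{k}.
#' @return List with \code{hclust} (the dendrogram), \code{dist} (the
#'   distance matrix) and \code{clusters} (named integer vector or NULL).
#' @export
cluster_lines <- function(scores, k = NULL, h = NULL) {
  m <- as.matrix(scores)
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  rs <- apply(m, 1, stats::sd)
  bad <- !is.finite(rs) | rs == 0
  if (any(bad)) {
    warning("constant row(s) excluded (correlation undefined): ",
            paste(rownames(m)[bad], collapse = ", "))
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("fewer than 2 usable rows after exclusions")
  d <- stats::as.dist(1 - stats::cor(t(m)))
  hc <- stats::hclust(d, method = "centroid")
  clusters <- NULL
  if (!is.null(k) || !is.null(h))
    clusters <- stats::cutree(hc, k = k, h = h)
  list(hclust = hc, dist = d, clusters = clusters)
}

#' Select features discriminating high- from low-NF-kB cells
#'
#' Within each line/condition group, cells are split into high and low TF
#' log-ratio groups (upper vs lower quartile); each feature is compared
#' between groups with a Welch t-test, and the group "votes" for the
#' feature when P < alpha. Features are ranked by vote count (ties broken
#' by mean absolute t statistic, then name) and the top \code{k} are
#' returned — the screen's "most frequently significantly different"
#' criterion.
#'
#' @param cells Cell table with \code{line_id}, \code{treatment},
#'   \code{log10_tf_ratio} and feature columns.
#' @param features Candidate features; defaults to catalog features
#'   present.
#' @param k Number of features to return (all, ordered, if k exceeds the
#'   candidate count).
#' @param alpha Vote significance level.
#' @param min_group Minimum cells per quartile group; smaller groups are
#'   skipped with a warning.
#' @return List with \code{selected} (character, length <= k),
#'   \code{votes} (named integer vector over all candidates) and
#'   \code{pvalues} (feature x group matrix).
#' @export
select_discriminative_features <- function(cells, features = NULL, k = 17L,
                                           alpha = 0.01, min_group = 10L) {
  if (is.null(features))
    features <- setdiff(intersect(feature_catalog()$feature, names(cells)),
                        c("tf_ratio", "log10_tf_ratio"))
  stopifnot("log10_tf_ratio" %in% names(cells),
            all(c("line_id", "treatment") %in% names(cells)))
  if (length(unique(cells$line_id)) < 2L)
    stop("need at least 2 cell lines")
  groups <- split(cells, interaction(cells$line_id, cells$treatment,
                                     drop = TRUE))
  pmat <- matrix(NA_real_, length(features), length(groups),
                 dimnames = list(features, names(groups)))
  tmat <- matrix(NA_real_, length(features), length(groups),
                 dimnames = list(features, names(groups)))
  for (gi in seq_along(groups)) {
    d <- groups[[gi]]
    qs <- stats::quantile(d$log10_tf_ratio, c(0.25, 0.75), na.rm = TRUE)
    hi <- d[d$log10_tf_ratio >= qs[2], , drop = FALSE]
    lo <- d[d$log10_tf_ratio <= qs[1], , drop = FALSE]
    if (nrow(hi) < min_group || nrow(lo) < min_group) {
      warning(sprintf("group %s skipped (quartile groups < %d cells)",
                      names(groups)[gi], min_group))
      next
    }
    for (f in features) {
      x <- hi[[f]]; y <- lo[[f]]
      if (pop_sd(x) == 0 && pop_sd(y) == 0) next  # identical: no vote
      tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
      if (!is.null(tt)) {
        pmat[f, gi] <- tt$p.value
        tmat[f, gi] <- tt$statistic
      }
    }
  }
  votes <- rowSums(pmat < alpha, na.rm = TRUE)
  mean_abs_t <- rowMeans(abs(tmat), na.rm = TRUE)
  mean_abs_t[is.nan(mean_abs_t)] <- 0
  ord <- order(-votes, -mean_abs_t, features)
  ranked <- features[ord]
  list(selected = ranked[seq_len(min(k, length(ranked)))],
       votes = votes[ord], pvalues = pmat)
}
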