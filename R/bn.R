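#' Quantile-discretize a numeric cell table
#'
#' Bins each numeric column into \code{levels} states at its empirical
#' quantiles, the usual preprocessing for discrete Bayesian-network
#' structure learning on single-cell features. Bin edges are recorded so
#' the binning is reproducible and rank-invariant (any strictly monotone
#' transform of a column yields identical states). Constant columns
#' collapse to a single state and are flagged with a warning.
#'
#' @param x data.frame or matrix of numeric columns.
#' @param levels Number of states per variable (default 3).
#' @return List with \code{states} (integer matrix, entries in
#'   1..levels), \code{edges} (list of numeric bin-edge vectors) and
#'   \code{n_states} (integer vector per column).
#' @export
discretize_features <- function(x, levels = 3L) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("columns must be numeric")
  if (nrow(m) < levels) stop("need at least `levels` rows")
  p <- ncol(m)
  states <- matrix(1L, nrow(m), p, dimnames = dimnames(m))
  edges <- vector("list", p)
  names(edges) <- colnames(m)
  n_states <- stats::setNames(integer(p), colnames(m))
  for (j in seq_len(p)) {
    v <- m[, j]
    qs <- stats::quantile(v, probs = seq(0, 1, length.out = levels + 1L),
                          names = FALSE, type = 7)
    qs <- unique(qs)
    if (length(qs) < 2L) {
      warning(sprintf("constant column '%s': single state",
                      colnames(m)[j]))
      edges[[j]] <- qs
      n_states[j] <- 1L
      next
    }
    b <- findInterval(v, qs, rightmost.closed = TRUE, all.inside = TRUE)
    states[, j] <- as.integer(b)
    edges[[j]] <- qs
    n_states[j] <- length(qs) - 1L
  }
  list(states = states, edges = edges, n_states = n_states)
}

# ---- BDeu scoring -------------------------------------------------------

# log BDeu family score of `child` given `parents` (column indices);
# states: integer matrix (1-based), r: states per column, ess: equivalent
# sample size
bdeu_family_score <- function(states, r, child, parents, ess = 1) {
  n <- nrow(states)
  ri <- r[child]
  if (length(parents) == 0L) {
    njk <- tabulate(states[, child], ri)
    a <- ess / ri
    return(sum(lgamma(a + njk) - lgamma(a)) +
             lgamma(ess) - lgamma(ess + n))
  }
  q <- prod(r[parents])
  cfg <- rep(1L, n)
  stride <- 1L
  for (p_ in parents) {
    cfg <- cfg + (states[, p_] - 1L) * stride
    stride <- stride * r[p_]
  }
  cell <- (cfg - 1L) * ri + states[, child]
  njk <- tabulate(cell, q * ri)
  nj <- tabulate(cfg, q)
  ajk <- ess / (q * ri)
  aj <- ess / q
  obs <- njk > 0L
  obsj <- nj > 0L
  sum(lgamma(ajk + njk[obs]) - lgamma(ajk)) +
    sum(lgamma(aj) - lgamma(aj + nj[obsj]))
}

# total score of a DAG given as adjacency matrix (adj[i,j]=1 : i -> j)
bdeu_score <- function(states, r, adj, ess = 1) {
  sum(vapply(seq_len(ncol(states)), function(j)
    bdeu_family_score(states, r, j, which(adj[, j] > 0L), ess),
    numeric(1)))
}

# would adding edge i -> j create a cycle? (is i reachable from j?)
creates_cycle <- function(adj, i, j) {
  p <- ncol(adj)
  seen <- logical(p)
  stack <- j
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v == i) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(adj[v, ] > 0L))
  }
  FALSE
}

# greedy hill climbing over add/delete/reverse moves with cached family
# scores; returns the adjacency matrix of a local score optimum
hill_climb <- function(states, r, ess = 1, max_parents = 3L,
                       init_adj = NULL, forbidden_from = integer(0)) {
  p <- ncol(states)
  adj <- if (is.null(init_adj)) matrix(0L, p, p) else init_adj
  fam <- vapply(seq_len(p), function(j)
    bdeu_family_score(states, r, j, which(adj[, j] > 0L), ess), numeric(1))
  repeat {
    best <- list(delta = 1e-9, move = NULL)
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j) next
      if (adj[i, j] == 0L && adj[j, i] == 0L) {
        # add i -> j
        if (i %in% forbidden_from) next
        if (sum(adj[, j]) >= max_parents) next
        if (creates_cycle(adj, i, j)) next
        new_j <- bdeu_family_score(states, r, j,
                                   c(which(adj[, j] > 0L), i), ess)
        delta <- new_j - fam[j]
        if (delta > best$delta)
          best <- list(delta = delta, move = c(1L, i, j), new = new_j)
      } else if (adj[i, j] == 1L) {
        # delete i -> j
        pa <- setdiff(which(adj[, j] > 0L), i)
        new_j <- bdeu_family_score(states, r, j, pa, ess)
        delta <- new_j - fam[j]
        if (delta > best$delta)
          best <- list(delta = delta, move = c(2L, i, j), new = new_j)
        # reverse i -> j  (becomes j -> i)
        if (!(j %in% forbidden_from) && sum(adj[, i]) < max_parents) {
          adj[i, j] <- 0L
          ok <- !creates_cycle(adj, j, i)
          adj[i, j] <- 1L
          if (ok) {
            new_i <- bdeu_family_score(states, r, i,
                                       c(which(adj[, i] > 0L), j), ess)
            delta2 <- (new_j - fam[j]) + (new_i - fam[i])
            if (delta2 > best$delta)
              best <- list(delta = delta2, move = c(3L, i, j),
                           new = new_j, new2 = new_i)
          }
        }
      }
    }
    if (is.null(best$move)) break
    op <- best$move[1]; i <- best$move[2]; j <- best$move[3]
    if (op == 1L) {
      adj[i, j] <- 1L; fam[j] <- best$new
    } else if (op == 2L) {
      adj[i, j] <- 0L; fam[j] <- best$new
    } else {
      adj[i, j] <- 0L; adj[j, i] <- 1L
      fam[j] <- best$new; fam[i] <- best$new2
    }
  }
  attr(adj, "score") <- sum(fam)
  adj
}

# random DAG for restarts: random topological order, sparse edges
random_dag <- function(p, max_parents) {
  ord <- sample.int(p)
  adj <- matrix(0L, p, p)
  for (k in 2:p) {
    npa <- sample.int(min(max_parents, k - 1L), 1L) - 1L
    if (npa > 0L) {
      pa <- sample(ord[seq_len(k - 1L)], npa)
      adj[pa, ord[k]] <- 1L
    }
  }
  adj
}

#' Learn a dependency network with bootstrap edge confidence
#'
#' Per bootstrap resample (cells drawn with replacement), a DAG is learned
#' by greedy hill climbing with random restarts maximizing the
#' Bayesian-Dirichlet (BDeu) score. Edge confidence is the fraction of
#' resamples containing the adjacency in either orientation; an edge is
#' reported oriented when at least \code{orient_threshold} of its
#' supporting resamples agree on the direction (otherwise the dependency
#' direction "cannot be determined" and the edge is undirected). Edges
#' with confidence above \code{conf_threshold} are flagged as confident —
#' the display cutoff used for reporting dependencies.
#'
#' @param disc Output of \code{\link{discretize_features}} (or an integer
#'   state matrix).
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param ess BDeu equivalent sample size.
#' @param restarts Random restarts per resample (first start is the empty
#'   graph).
#' @param max_parents Per-node parent limit.
#' @param orient_threshold Direction-consistency cutoff in (0.5, 1].
#' @param conf_threshold Confidence flag cutoff.
#' @param tf_sink If TRUE, forbid edges out of \code{tf_ratio} (treat the
#'   TF node as a sink) — a sensitivity-analysis option.
#' @param metadata Named list stored on the network (line_id, treatment,
#'   ...).
#' @return Object of class \code{DependencyNetwork}: list with
#'   \code{nodes}, \code{edges} (data.frame: from, to, oriented,
#'   confidence, confident), and \code{metadata} (includes n_cells, B,
#'   seed, score name).
#' @export
learn_network <- function(disc, B = 100L, seed = 1L, ess = 1,
                          restarts = 5L, max_parents = 3L,
                          orient_threshold = 0.7, conf_threshold = 0.6,
                          tf_sink = FALSE, metadata = list()) {
  states <- if (is.list(disc)) disc$states else disc
  if (nrow(states) < 100L)
    stop("need at least 100 rows to learn a network (got ",
         nrow(states), ")")
  if (ncol(states) < 2L) stop("need at least 2 columns")
  r <- apply(states, 2, max)
  p <- ncol(states)
  nodes <- colnames(states)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(p))
  forbidden <- if (tf_sink) which(nodes == "tf_ratio") else integer(0)

  adj_count <- matrix(0, p, p)   # directed counts over resamples
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(states), replace = TRUE)
      sb <- states[idx, , drop = FALSE]
      best <- hill_climb(sb, r, ess, max_parents,
                         forbidden_from = forbidden)
      if (restarts > 1L) {
        for (rs in seq_len(restarts - 1L)) {
          cand <- hill_climb(sb, r, ess, max_parents,
                             init_adj = random_dag(p, max_parents),
                             forbidden_from = forbidden)
          if (attr(cand, "score") > attr(best, "score")) best <- cand
        }
      }
      adj_count <- adj_count + best
    }
  })

  edges <- NULL
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    supp <- adj_count[i, j] + adj_count[j, i]
    if (supp == 0) next
    conf <- supp / B
    fwd <- adj_count[i, j] / supp
    oriented <- max(fwd, 1 - fwd) >= orient_threshold
    a <- if (fwd >= 0.5) nodes[i] else nodes[j]
    b_ <- if (fwd >= 0.5) nodes[j] else nodes[i]
    edges <- rbind(edges, data.frame(
      from = a, to = b_, oriented = oriented, confidence = conf,
      confident = conf > conf_threshold, stringsAsFactors = FALSE))
  }
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        oriented = logical(0), confidence = numeric(0),
                        confident = logical(0), stringsAsFactors = FALSE)
  edges <- edges[order(-edges$confidence, edges$from, edges$to), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  # oriented consensus edges must stay acyclic: demote orientation of any
  # edge (in decreasing confidence) that would close a cycle
  adj <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    if (!edges$oriented[k]) next
    i <- match(edges$from[k], nodes); j <- match(edges$to[k], nodes)
    if (creates_cycle(adj, i, j)) edges$oriented[k] <- FALSE
    else adj[i, j] <- 1L
  }
  md <- utils::modifyList(
    list(line_id = NA_character_, treatment = NA_character_,
         n_cells = nrow(states), B = as.integer(B),
         seed = as.integer(seed), score = sprintf("bdeu(ess=%g)", ess),
         restarts = as.integer(restarts),
         max_parents = as.integer(max_parents)),
    metadata)
  structure(list(nodes = nodes, edges = edges, metadata = md),
            class = "DependencyNetwork")
}

#' @export
print.DependencyNetwork <- function(x, ...) {
  cat(sprintf("DependencyNetwork: %d nodes, %d edges (%d confident)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$confident)))
  invisible(x)
}

#' Frequency of dependencies on a target node across networks
#'
#' Counts, per feature and per treatment stratum, the number of networks
#' in which an edge between the feature and the target has confidence
#' above the threshold (in either orientation) — the cross-line
#' dependency-frequency summary.
#'
#' @param networks List of \code{DependencyNetwork}.
#' @param target Target node name.
#' @param threshold Confidence threshold for counting a dependency.
#' @return data.frame feature x stratum of counts; networks lacking the
#'   target node are skipped with a warning.
#' @export
dependency_summary <- function(networks, target = "tf_ratio",
                               threshold = 0.6) {
  feats <- sort(unique(unlist(lapply(networks, function(nw)
    setdiff(nw$nodes, target)))))
  strata <- unique(vapply(networks, function(nw)
    as.character(nw$metadata$treatment), character(1)))
  if (length(strata) == 0L) strata <- NA_character_
  counts <- matrix(0L, length(feats), length(strata),
                   dimnames = list(feats, strata))
  for (nw in networks) {
    if (!(target %in% nw$nodes)) {
      warning(sprintf("network (%s) lacks target '%s'; skipped",
                      nw$metadata$line_id, target))
      next
    }
    st <- as.character(nw$metadata$treatment)
    e <- nw$edges
    hit <- (e$from == target | e$to == target) & e$confidence > threshold
    partner <- ifelse(e$from == target, e$to, e$from)[hit]
    for (f in unique(partner)) counts[f, st] <- counts[f, st] + 1L
  }
  out <- data.frame(feature = rownames(counts), counts, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out
}

#' Export a dependency network as GraphML
#'
#' Confidence and orientation become edge attributes; undirected edges are
#' encoded with \code{oriented = FALSE}.
#'
#' @param network A \code{DependencyNetwork}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    network$edges, directed = TRUE,
    vertices = data.frame(name = network$nodes))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
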