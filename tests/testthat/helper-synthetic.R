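# shared fixture builders and independent oracles, built in code at test time

# centered disk label image (optionally with a concentric/offset nucleus)
disk_labels <- function(r_cell, r_nuc = NULL, n = 2L * r_cell + 21L,
                        nuc_offset = c(0, 0)) {
  cx <- (n + 1) / 2
  cell <- matrix(0L, n, n)
  nuc <- matrix(0L, n, n)
  for (x in 1:n) {
    d2 <- (x - cx)^2 + ((1:n) - cx)^2
    cell[x, d2 <= r_cell^2] <- 1L
    if (!is.null(r_nuc)) {
      d2n <- (x - cx - nuc_offset[1])^2 + ((1:n) - cx - nuc_offset[2])^2
      nuc[x, d2n <= r_nuc^2] <- 1L
    }
  }
  list(cell = cell, nucleus = nuc, n = n)
}

# two abutting axis-aligned squares of side s sharing one full side
square_pair_labels <- function(s = 40L, pad = 10L) {
  nx <- 2L * s + 2L * pad
  ny <- s + 2L * pad
  cell <- matrix(0L, nx, ny)
  cell[pad + (1:s), pad + (1:s)] <- 1L
  cell[pad + s + (1:s), pad + (1:s)] <- 2L
  nuc <- matrix(0L, nx, ny)
  r <- max(3L, s %/% 5L)
  c1 <- c(pad + s / 2, pad + s / 2)
  c2 <- c(pad + 1.5 * s, pad + s / 2)
  for (x in 1:nx) {
    d1 <- (x - c1[1])^2 + ((1:ny) - c1[2])^2
    d2 <- (x - c2[1])^2 + ((1:ny) - c2[2])^2
    nuc[x, d1 <= r^2] <- 1L
    nuc[x, d2 <= r^2] <- 2L
  }
  list(cell = cell, nucleus = nuc)
}

# discrete 3-state noisy-channel chain X -> Y -> Z; `flip` is the
# probability a state is resampled uniformly at each step
discrete_chain <- function(n, flip = 0.25, seed = 1L) {
  set.seed(seed)
  resample <- function(x) {
    m <- stats::runif(n) < flip
    x[m] <- sample.int(3L, sum(m), replace = TRUE)
    x
  }
  X <- sample.int(3L, n, replace = TRUE)
  Y <- resample(X)
  Z <- resample(Y)
  cbind(X = X, Y = Y, Z = Z)
}

# ---- independent oracles -------------------------------------------------

# all 25 DAGs on 3 labelled nodes, as a list of adjacency matrices,
# enumerated by brute force over the 2^6 directed graphs
all_dags_3 <- function() {
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  out <- list()
  for (code in 0:(3^3 - 1)) {
    digits <- (code %/% 3^(0:2)) %% 3  # 0 none, 1 forward, 2 backward
    adj <- matrix(0L, 3, 3)
    for (k in 1:3) {
      if (digits[k] == 1L) adj[pairs[k, 1], pairs[k, 2]] <- 1L
      if (digits[k] == 2L) adj[pairs[k, 2], pairs[k, 1]] <- 1L
    }
    g <- igraph::graph_from_adjacency_matrix(adj)
    if (igraph::is_dag(g)) out[[length(out) + 1L]] <- adj
  }
  out
}

# independent BDeu scorer: plain-loop Dirichlet-multinomial marginal
# likelihood, written without reference to the package internals
oracle_bdeu <- function(states, adj, ess = 1) {
  p <- ncol(states)
  r <- apply(states, 2, max)
  total <- 0
  for (j in seq_len(p)) {
    parents <- which(adj[, j] == 1L)
    if (length(parents) == 0L) {
      configs <- factor(rep(1L, nrow(states)))
    } else {
      configs <- interaction(as.data.frame(states[, parents, drop = FALSE]),
                             drop = FALSE)
    }
    q <- if (length(parents) == 0L) 1 else prod(r[parents])
    aj <- ess / q
    ajk <- ess / (q * r[j])
    for (cf in levels(configs)) {
      sel <- configs == cf
      nj <- sum(sel)
      total <- total + lgamma(aj) - lgamma(aj + nj)
      for (s in seq_len(r[j])) {
        njk <- sum(states[sel, j] == s)
        total <- total + lgamma(ajk + njk) - lgamma(ajk)
      }
    }
  }
  unname(total)
}

# best adjacency (undirected skeleton) over all 3-node DAGs by exhaustive
# oracle scoring
oracle_best_skeleton <- function(states, ess = 1) {
  dags <- all_dags_3()
  scores <- vapply(dags, function(a) oracle_bdeu(states, a, ess), numeric(1))
  best <- dags[[which.max(scores)]]
  list(skeleton = (best + t(best)) > 0, score = max(scores))
}

# FFT periodogram dominant period (independent of the wavelet path)
periodogram_period <- function(values, dt) {
  x <- values - mean(values)
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  freqs <- (0:(n - 1)) / (n * dt)
  half <- 2:floor(n / 2)
  1 / freqs[half][which.max(sp[half])]
}
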