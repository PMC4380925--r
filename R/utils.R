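#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to a reproducible state, evaluates \code{expr}, and restores
#' the caller's RNG state afterwards, so generators are deterministic without
#' clobbering the session RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single non-missing number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# population standard deviation (divisor n), matching (value - mean)/SD
# Z-scaling with the full-sample SD
pop_sd <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# coefficient of variation; 0 for a constant region, NA for empty
cv_of <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

# circular (wrapped) Gaussian smoothing of a periodic signal via FFT
smooth_circular <- function(x, sigma) {
  n <- length(x)
  if (n < 3L || sigma <= 0) return(x)
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
  g <- exp(-0.5 * (2 * pi * k / n)^2 * sigma^2)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE)) / n
}

# runs of TRUE in a circular sequence; returns list of integer index vectors
circular_runs <- function(flag) {
  n <- length(flag)
  if (n == 0L || !any(flag)) return(list())
  if (all(flag)) return(list(seq_len(n)))
  # rotate so position 1 is FALSE, then use rle
  start <- which(!flag)[1L]
  rot <- c(seq(start, n), seq_len(start - 1L))
  f <- flag[rot]
  r <- rle(f)
  ends <- cumsum(r$lengths)
  begins <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list()
  for (i in seq_along(r$values)) {
    if (r$values[i]) out[[length(out) + 1L]] <- rot[begins[i]:ends[i]]
  }
  out
}
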