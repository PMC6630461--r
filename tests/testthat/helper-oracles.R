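# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's own algorithms: component counts come from union-find
# over an explicit edge sweep, shortest paths from Floyd-Warshall, modularity
# optima from exhaustive set-partition enumeration, and slopes from the
# closed-form OLS ratio.

# number of connected components of the graph with edges w <= lambda
uf_components <- function(w, lambda) {
  N <- nrow(w)
  parent <- seq_len(N)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    if (!is.na(w[i, j]) && w[i, j] <= lambda) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(N), find, integer(1))))
}

# single-linkage merge heights by sweeping every candidate threshold
sweep_merge_heights <- function(w) {
  cand <- sort(unique(w[upper.tri(w)]))
  heights <- numeric(0)
  prev <- nrow(w)
  for (l in cand) {
    b <- uf_components(w, l)
    if (b < prev) heights <- c(heights, rep(l, prev - b))
    prev <- b
  }
  heights
}

# all-pairs shortest path distances; NA = absent edge
floyd_warshall <- function(w) {
  d <- w
  d[is.na(d)] <- Inf
  diag(d) <- 0
  N <- nrow(d)
  for (k in seq_len(N)) for (i in seq_len(N)) for (j in seq_len(N))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# closed-form OLS slope magnitude
ols_slope_abs <- function(x, y) {
  abs(sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2))
}

# direct elementwise evaluation of the IPF definition
ipf_direct <- function(lam) {
  m <- length(lam)
  vals <- numeric(m)
  for (i in 0:(m - 2L))
    vals[i + 1L] <- (m - i) / (m * (m - 1)) * sum(lam[(i + 2L):m])
  vals[m] <- 0
  vals
}

# every set partition of n items as restricted-growth assignment vectors
all_partitions <- function(n) {
  out <- list()
  recurse <- function(assign, k) {
    if (length(assign) == n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible(NULL))
    }
    for (b in seq_len(k + 1L)) recurse(c(assign, b), max(k, b))
  }
  recurse(integer(0), 0L)
  out
}

# symmetric random complete distance network
random_network <- function(N, wmin = 0, wmax = 2) {
  w <- matrix(0, N, N)
  w[upper.tri(w)] <- runif(N * (N - 1) / 2, wmin, wmax)
  w <- w + t(w)
  weighted_network(w)
}

# small random SUV table
random_suv <- function(K, N, group = "g", baseline = 5) {
  suv_table(matrix(rnorm(K * N, mean = baseline), K, N), group = group)
}

# ipf_plot from raw coordinates (bypasses the pipeline for analytic cases)
make_ipf_plot <- function(lambda, ipf_vals) {
  structure(cbind(lambda = lambda, ipf = ipf_vals), class = "ipf_plot")
}

make_kernel_params <- function(p = 5L, sigma = 1, c_weight = 1) {
  structure(list(p = as.integer(p), sigma = sigma, c_weight = c_weight),
            class = "kernel_params")
}
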