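#' Graph filtration of a weighted distance network
#'
#' Sweeping a threshold lambda from 0 upward over a distance network yields a
#' nested family of binary graphs (edges with weight <= lambda), and the
#' zeroth persistent homology of this filtration records the heights at
#' which connected components merge.  For a distance matrix those merge
#' heights are exactly the single-linkage dendrogram heights, equivalently
#' the sorted edge weights of a minimum spanning tree, so the whole
#' threshold sweep is obtained in O(N^2 log N) without choosing any single
#' threshold.  The filtration sequence is
#' `lambda_0 = 0 <= lambda_1 <= ... <= lambda_{m-1}` with `m = N` for a
#' connected N-node network; tied merge heights are retained as repeated
#' values.
#'
#' @param network a complete [weighted_network] (the unfiltered correlation
#'   distance network; absent edges are not allowed here).
#' @return An object of class `filtration`: list with `lam` (the ordered
#'   critical values, `lam[1] = 0`) and `m` (their count).
#' @examples
#' net <- correlation_distance(
#'   simulate_cohort(cohort_spec(n_subjects = 30, n_roi = 8, seed = 1)))$network
#' graph_filtration(net)
#' @seealso [betti_curve()], [ipf()]
#' @export
graph_filtration <- function(network) {
  stopifnot(inherits(network, "weighted_network"))
  w <- network$weights
  N <- nrow(w)
  if (N < 2L) stop("filtration needs at least 2 nodes")
  if (anyNA(w[upper.tri(w)]))
    stop("filtration requires a complete distance network; ",
         "apply it before edge filtering")
  heights <- sort(stats::hclust(stats::as.dist(w), method = "single")$height)
  filtration(c(0, heights))
}

#' @rdname graph_filtration
#' @param lam numeric vector of critical values starting at 0,
#'   non-decreasing.
#' @export
filtration <- function(lam) {
  lam <- as.numeric(lam)
  if (length(lam) < 2L) stop("a filtration needs at least 2 values")
  if (lam[1L] != 0) stop("the filtration must start at lambda_0 = 0")
  if (is.unsorted(lam)) stop("filtration values must be non-decreasing")
  if (!all(is.finite(lam))) stop("filtration values must be finite")
  structure(list(lam = lam, m = length(lam)), class = "filtration")
}

#' @export
print.filtration <- function(x, ...) {
  cat(sprintf("filtration: m = %d critical values in [0, %.4g]\n",
              x$m, max(x$lam)))
  invisible(x)
}

#' Betti number plot (number of connected components over the filtration)
#'
#' The zeroth Betti number beta0(lambda) counts connected components of the
#' thresholded graph.  It starts at `m` isolated nodes, drops by one at
#' every merge height, and is right-continuous: on `[lambda_i,
#' lambda_{i+1})` it equals `m - i`, with tied heights collapsing several
#' drops into one.
#'
#' @param filt a [filtration].
#' @return Object of class `betti_curve`: a data frame with one row per
#'   distinct critical value (`lambda`, `beta0`).
#' @seealso [beta0_at()], [bnp_index()]
#' @export
betti_curve <- function(filt) {
  stopifnot(inherits(filt, "filtration"))
  lam <- filt$lam
  m <- filt$m
  ulam <- unique(lam)
  # components remaining once all merges at height <= lambda have happened
  beta0 <- vapply(ulam, function(l) m - sum(lam[-1L] <= l), numeric(1))
  structure(data.frame(lambda = ulam, beta0 = as.integer(beta0)),
            class = c("betti_curve", "data.frame"))
}

#' Evaluate a Betti curve at arbitrary thresholds
#'
#' @param curve a [betti_curve].
#' @param lambda numeric vector of thresholds.
#' @return Integer vector of component counts (right-continuous step
#'   function; below the first critical value every node is its own
#'   component).
#' @export
beta0_at <- function(curve, lambda) {
  stopifnot(inherits(curve, "betti_curve"))
  idx <- findInterval(lambda, curve$lambda)
  n0 <- curve$beta0[1L]  # component count at lambda_0 = 0
  ifelse(idx == 0L, n0, curve$beta0[pmax(idx, 1L)])
}

#' @export
plot.betti_curve <- function(x, ...) {
  graphics::plot(x$lambda, x$beta0, type = "s",
                 xlab = expression(lambda), ylab = expression(beta[0]),
                 main = "Betti number plot", ...)
  invisible(x)
}

#' Slope index of the Betti number plot
#'
#' The absolute value of the ordinary-least-squares slope of beta0 against
#' lambda over the curve's points (the step function sampled at its distinct
#' critical values), used as a univariate network index: larger values mean
#' faster component merging per unit of distance.
#'
#' @param curve a [betti_curve].
#' @return Scalar index.
#' @export
bnp_index <- function(curve) {
  stopifnot(inherits(curve, "betti_curve"))
  abs_ols_slope(curve$lambda, curve$beta0)
}

abs_ols_slope <- function(x, y) {
  if (length(unique(x)) < 2L)
    stop("slope undefined: all lambda values identical")
  xc <- x - mean(x)
  abs(sum(xc * y) / sum(xc^2))
}

#' Integrated persistent feature (IPF) of a filtration
#'
#' The IPF augments the Betti number plot with the cost of the aggregation
#' still to come.  At the i-th critical value (0-based) of a filtration
#' `lambda_0 = 0 <= ... <= lambda_{m-1}` it is
#' \deqn{IPF_{\lambda_i} = \frac{m-i}{m(m-1)} \sum_{k=i+1}^{m-1} \lambda_k}
#' for `i <= m - 2`, and 0 at the last value: the remaining component count
#' times the remaining merge cost, normalized by `m(m-1)`.  The resulting
#' plot is non-negative, non-increasing and ends at exactly 0.
#'
#' @param filt a [filtration].
#' @return Object of class `ipf_plot`: an `m x 2` matrix with columns
#'   `lambda` and `ipf`.
#' @examples
#' ipf(filtration(c(0, 0.2, 0.5, 0.9)))
#' @seealso [sip()], [kbi()]
#' @export
ipf <- function(filt) {
  stopifnot(inherits(filt, "filtration"))
  lam <- filt$lam
  m <- filt$m
  # tail sums: sum_{k > i} lambda_k, computed right-to-left
  tail_sum <- rev(cumsum(rev(lam)))  # tail_sum[i+1] = sum_{k >= i} lam_k
  i <- seq_len(m) - 1L               # 0-based index
  vals <- numeric(m)
  keep <- i <= m - 2L
  vals[keep] <- (m - i[keep]) / (m * (m - 1)) *
    (tail_sum[i[keep] + 1L] - lam[i[keep] + 1L])
  vals[m] <- 0
  structure(cbind(lambda = lam, ipf = vals), class = "ipf_plot")
}

#' @export
print.ipf_plot <- function(x, ...) {
  cat(sprintf("ipf_plot: %d points, IPF from %.4g down to %.4g\n",
              nrow(x), x[1L, "ipf"], x[nrow(x), "ipf"]))
  invisible(x)
}

#' @export
plot.ipf_plot <- function(x, ...) {
  graphics::plot(x[, "lambda"], x[, "ipf"], type = "b", pch = 16, cex = 0.5,
                 xlab = expression(lambda), ylab = "IPF",
                 main = "Integrated persistent feature", ...)
  invisible(x)
}

#' Slope of the IPF plot (SIP)
#'
#' The absolute OLS slope of the IPF values against their filtration values,
#' a univariate index of how fast the network integrates: strongly coupled
#' networks aggregate their components quickly and show a steeper IPF
#' descent.
#'
#' @param plot an [ipf_plot][ipf].
#' @return Scalar index.
#' @export
sip <- function(plot) {
  stopifnot(inherits(plot, "ipf_plot"))
  abs_ols_slope(plot[, "lambda"], plot[, "ipf"])
}

#' Kernel parameters for the kernel-based IPF index
#'
#' Data-driven bandwidth and weighting constants shared by a set of IPF
#' plots (all plots entering an analysis, template included):
#' `sigma` is the median over plots of the within-plot median Euclidean
#' distance between point pairs; `c_weight` is
#' `(median over plots of the within-plot median positive lambda)^(-p)`,
#' so that `C * lambda^p` is about 1 at a typical filtration value and the
#' arctan persistence weights are neither saturated nor vanishing there.
#' The zero entry `lambda_0 = 0` is excluded from the lambda medians.
#'
#' @param plots list of [ipf_plot][ipf] objects.
#' @param p positive integer exponent of the persistence weight, default 5.
#' @return Object of class `kernel_params`: list with `p`, `sigma`,
#'   `c_weight`.
#' @export
kernel_params <- function(plots, p = 5L) {
  if (inherits(plots, "ipf_plot")) plots <- list(plots)
  if (!length(plots) || !all(vapply(plots, inherits, logical(1), "ipf_plot")))
    stop("`plots` must be a non-empty list of ipf_plot objects")
  if (p < 1) stop("`p` must be a positive integer")
  med_pair <- vapply(plots, function(P) {
    if (nrow(P) < 2L) stop("each plot needs at least 2 points")
    stats::median(stats::dist(unclass(P)))
  }, numeric(1))
  sigma <- stats::median(med_pair)
  if (sigma == 0) stop("sigma = 0: all points coincide within every plot")
  med_lam <- vapply(plots, function(P) {
    pos <- P[, "lambda"][P[, "lambda"] > 0]
    if (!length(pos)) stop("a plot has no positive lambda values")
    stats::median(pos)
  }, numeric(1))
  structure(list(p = as.integer(p), sigma = sigma,
                 c_weight = stats::median(med_lam)^(-p)),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("kernel_params: p = %d, sigma = %.6g, C = %.6g\n",
              x$p, x$sigma, x$c_weight))
  invisible(x)
}

#' Kernel-based IPF index (KBI)
#'
#' Measures the similarity of an IPF plot `X` to a template plot `T`
#' (typically derived from the control group's average network) through a
#' persistence-weighted Gaussian kernel:
#' \deqn{KBI(X) = \frac{1}{N}\sum_{i=1}^{N}
#'   \arctan(C (\lambda^X_i)^p)\,\arctan(C (\lambda^T_i)^p)\,
#'   e^{-\|x_i - t_i\|^2 / (2\sigma^2)}}
#' Points are matched by index after sorting both plots by lambda (always
#' valid here because both plots derive from the same atlas and hence have
#' equal point counts).  The arctan factors up-weight essential (large-
#' lambda) persistence and suppress noise; the Gaussian factor decays with
#' the distance between matched points.  The result lies in
#' `[0, (pi/2)^2]`, and the `lambda_0 = 0` point contributes 0
#' automatically.
#'
#' @param X,T [ipf_plot][ipf] objects with equal point counts.
#' @param params a [kernel_params] object.
#' @return Scalar index; larger means more similar to the template (up to
#'   the persistence weighting).
#' @export
kbi <- function(X, T, params) {
  stopifnot(inherits(X, "ipf_plot"), inherits(T, "ipf_plot"),
            inherits(params, "kernel_params"))
  if (nrow(X) != nrow(T))
    stop("X and T have different point counts (", nrow(X), " vs ", nrow(T), ")")
  if (!all(is.finite(X)) || !all(is.finite(T)))
    stop("non-finite values in IPF plots")
  Xs <- unclass(X)[order(X[, "lambda"], X[, "ipf"]), , drop = FALSE]
  Ts <- unclass(T)[order(T[, "lambda"], T[, "ipf"]), , drop = FALSE]
  wX <- atan(params$c_weight * Xs[, "lambda"]^params$p)
  wT <- atan(params$c_weight * Ts[, "lambda"]^params$p)
  d2 <- rowSums((Xs - Ts)^2)
  mean(wX * wT * exp(-d2 / (2 * params$sigma^2)))
}

#' IPF template from a control group
#'
#' Convenience composition: the IPF plot of the average metabolic network of
#' the control (NC) subjects, i.e.
#' `ipf(graph_filtration(correlation_distance(nc_suv, method)$network))`.
#' Used as the fixed template `T` of the [kbi()] index.
#'
#' @param nc_suv the control group's [suv_table].
#' @param method correlation method passed to [correlation_distance()].
#' @return An [ipf_plot][ipf].
#' @export
template_from_controls <- function(nc_suv, method = "pearson") {
  ipf(graph_filtration(correlation_distance(nc_suv, method)$network))
}
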