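#' Weighted correlation-distance networks
#'
#' A `weighted_network` is a symmetric `N x N` matrix of unitless edge
#' distances between ROIs with a zero diagonal.  Edges removed by
#' significance filtering are stored as `NA` (absent), not as zero weight.
#'
#' @param weights symmetric numeric matrix, zero diagonal; `NA` marks an
#'   absent edge.
#' @param roi_labels ROI labels, defaulting to the matrix dimnames.
#' @param meta list of provenance fields (distance method, source group,
#'   subject count, whether the network was filtered).
#' @return An object of class `weighted_network`.
#' @export
weighted_network <- function(weights, roi_labels = NULL, meta = list()) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix")
  N <- nrow(weights)
  if (ncol(weights) != N) stop("`weights` must be square")
  if (N < 2L) stop("a network needs at least 2 nodes")
  if (is.null(roi_labels)) roi_labels <- rownames(weights)
  if (is.null(roi_labels)) roi_labels <- paste0("roi", seq_len(N))
  roi_labels <- as.character(roi_labels)
  if (length(roi_labels) != N || anyDuplicated(roi_labels))
    stop("`roi_labels` must be ", N, " unique labels")
  asym <- abs(weights - t(weights))
  na_mismatch <- is.na(weights) != is.na(t(weights))
  if (any(asym > 1e-8, na.rm = TRUE) || any(na_mismatch)) {
    ij <- which((!is.na(asym) & asym > 1e-8) | na_mismatch,
                arr.ind = TRUE)[1L, ]
    stop(sprintf("asymmetric weights at (%s, %s)",
                 roi_labels[ij[1L]], roi_labels[ij[2L]]))
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (any(weights < 0, na.rm = TRUE)) {
    ij <- which(weights < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative weight at (%s, %s)",
                 roi_labels[ij[1L]], roi_labels[ij[2L]]))
  }
  dimnames(weights) <- list(roi_labels, roi_labels)
  structure(list(weights = weights, roi_labels = roi_labels, meta = meta),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  N <- nrow(x$weights)
  present <- sum(!is.na(x$weights[upper.tri(x$weights)]))
  cat(sprintf("weighted_network: %d ROIs, %d/%d edges present\n",
              N, present, N * (N - 1L) / 2L))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  if (present > 0L)
    cat(sprintf("  weight range [%.4g, %.4g]\n",
                min(x$weights[upper.tri(x$weights)], na.rm = TRUE),
                max(x$weights[upper.tri(x$weights)], na.rm = TRUE)))
  invisible(x)
}

#' Group-wise correlation-distance network from an SUV table
#'
#' Builds the weighted metabolic network of one group: the edge weight
#' between ROIs i and j is the correlation distance
#' `w_ij = 1 - r_ij`, where `r_ij` is the chosen correlation of mean SUV
#' across the group's subjects, so weights live in `[0, 2]` (0 for perfectly
#' coupled regions, 2 for perfectly anti-coupled ones).  Two-sided p-values
#' for the test of zero correlation accompany the network: the t transform
#' with `K - 2` degrees of freedom for Pearson and Spearman, the normal
#' approximation for Kendall's tau.
#'
#' @param suv an [suv_table] with `K >= 3` subjects.
#' @param method `"pearson"` (default), `"spearman"` or `"kendall"`.
#' @return A list with components `network` (a [weighted_network]) and
#'   `pvals` (an `edge_pvalues` object holding the symmetric p-value matrix
#'   and the number of unique ROI pairs `m_tests`).
#' @examples
#' x <- simulate_cohort(cohort_spec(n_subjects = 30, n_roi = 10, seed = 1))
#' net <- correlation_distance(x)$network
#' net
#' @seealso [bonferroni_filter()], [graph_filtration()]
#' @export
correlation_distance <- function(suv,
                                 method = c("pearson", "spearman", "kendall")) {
  stopifnot(inherits(suv, "suv_table"))
  method <- match.arg(method)
  K <- nrow(suv$values)
  if (K < 3L) stop("correlation distance needs at least 3 subjects (got ", K, ")")
  sds <- apply(suv$values, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance ROI: ",
         paste(suv$roi_labels[sds == 0], collapse = ", "))
  r <- stats::cor(suv$values, method = method)
  w <- 1 - r
  # guard against numerical noise just outside [0, 2]
  out <- w < 0 | w > 2
  if (any(out & (w < -1e-12 | w > 2 + 1e-12)))
    stop("correlation distance outside [0, 2] beyond tolerance")
  w[out] <- pmin(pmax(w[out], 0), 2)
  diag(w) <- 0
  p <- cor_pvalues(r, K, method)
  net <- weighted_network(w, roi_labels = suv$roi_labels,
                          meta = list(method = method, group = suv$group,
                                      n_subjects = K, filtered = FALSE))
  list(network = net,
       pvals = edge_pvalues(p, roi_labels = suv$roi_labels))
}

# two-sided p-values for a correlation matrix
cor_pvalues <- function(r, K, method) {
  if (method == "kendall") {
    # normal approximation for tau under independence
    z <- 3 * r * sqrt(K * (K - 1)) / sqrt(2 * (2 * K + 5))
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    rr <- pmin(pmax(r, -1), 1)
    tstat <- rr * sqrt((K - 2) / pmax(1 - rr^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = K - 2)
    p[abs(rr) == 1] <- 0
  }
  diag(p) <- 1
  p
}

#' @rdname correlation_distance
#' @param pvals symmetric matrix of two-sided edge p-values.
#' @param roi_labels ROI labels for the p-value matrix.
#' @export
edge_pvalues <- function(pvals, roi_labels = NULL) {
  if (!is.matrix(pvals) || any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("`pvals` must be a matrix of values in [0, 1]")
  N <- nrow(pvals)
  if (is.null(roi_labels)) roi_labels <- rownames(pvals)
  if (is.null(roi_labels)) roi_labels <- paste0("roi", seq_len(N))
  dimnames(pvals) <- list(roi_labels, roi_labels)
  structure(list(pvals = pvals, roi_labels = as.character(roi_labels),
                 m_tests = N * (N - 1L) / 2L),
            class = "edge_pvalues")
}

#' Bonferroni edge filter
#'
#' Retains only edges whose correlation p-value passes the Bonferroni
#' threshold `p < alpha / m`, where `m = N(N-1)/2` is the number of unique
#' ROI pairs (strict inequality; an edge exactly at the threshold is
#' removed).  Removed edges become absent (`NA`), retained weights are
#' unchanged.  The filter is applied before graph-theory indices
#' ([cpl()], [network_diameter()], [modularity_index()]); the persistence
#' indices use the unfiltered network, since the filtration itself sweeps
#' all thresholds.
#'
#' @param network a [weighted_network].
#' @param pvals matching [edge_pvalues].
#' @param alpha family-wise significance level in `(0, 1]`, default 0.05.
#' @return The filtered [weighted_network].
#' @export
bonferroni_filter <- function(network, pvals, alpha = 0.05) {
  stopifnot(inherits(network, "weighted_network"),
            inherits(pvals, "edge_pvalues"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]")
  if (!identical(dim(network$weights), dim(pvals$pvals)))
    stop("network and p-value shapes differ")
  w <- network$weights
  drop <- pvals$pvals >= alpha / pvals$m_tests
  diag(drop) <- FALSE
  w[drop] <- NA_real_
  meta <- network$meta
  meta$filtered <- TRUE
  meta$alpha <- alpha
  weighted_network(w, roi_labels = network$roi_labels, meta = meta)
}

#' Read and write weighted networks
#'
#' Square-matrix serialization: a delimited text file whose header and first
#' column carry matching ROI labels, with `NA` for absent edges.
#' `read_network()` also accepts a three-column edge list
#' (`from`, `to`, `weight`); node pairs never mentioned become absent edges.
#'
#' @param path file path.
#' @param sep field separator, default `","`.
#' @param x a [weighted_network].
#' @return `read_network()` returns a [weighted_network];
#'   `write_network()` returns `path` invisibly.
#' @export
read_network <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 3L && names(df)[1L] != "roi") {
    labs <- sort(unique(c(as.character(df[[1L]]), as.character(df[[2L]]))))
    w <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(labs, labs))
    diag(w) <- 0
    for (k in seq_len(nrow(df))) {
      i <- as.character(df[k, 1L]); j <- as.character(df[k, 2L])
      w[i, j] <- w[j, i] <- as.numeric(df[k, 3L])
    }
    return(weighted_network(w, roi_labels = labs))
  }
  labs <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "double"
  if (!identical(labs, colnames(m)))
    stop("row and column ROI labels differ")
  weighted_network(m, roi_labels = labs)
}

#' @rdname read_network
#' @export
write_network <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "weighted_network"))
  num <- matrix(ifelse(is.na(x$weights), "NA", sprintf("%.17g", x$weights)),
                nrow(x$weights))
  out <- cbind(roi = x$roi_labels, num)
  colnames(out) <- c("roi", x$roi_labels)
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
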