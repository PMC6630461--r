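#' Index pipelines for group-wise inference
#'
#' Builds a function mapping one group's [suv_table] to a scalar network
#' index, wiring together network construction, optional Bonferroni edge
#' filtering (for the graph-theory indices) and the chosen index.  Such
#' pipelines are the `index_fn` arguments of [permutation_test()] and
#' [resample_networks()].
#'
#' For `measure = "kbi"` a fixed `template` (an [ipf_plot][ipf]) and fixed
#' [kernel_params] are required; both are held constant across permutations
#' and resamples so that the index of a pseudo-group never peeks at the true
#' group labels.
#'
#' @param measure one of `"sip"`, `"bnp"`, `"kbi"`, `"cpl"`, `"nd"`,
#'   `"mod"`.
#' @param method correlation method for network construction.
#' @param template [ipf_plot][ipf] template, required for `"kbi"`.
#' @param params [kernel_params], required for `"kbi"`.
#' @param alpha Bonferroni level for edge filtering before the graph-theory
#'   indices (`"cpl"`, `"nd"`, `"mod"`); the persistence indices use the
#'   unfiltered network.
#' @param seed seed forwarded to [modularity_index()].
#' @return A function of one argument (an [suv_table]) returning a scalar.
#' @examples
#' fn <- network_index_fn("sip")
#' fn(simulate_cohort(cohort_spec(n_subjects = 30, n_roi = 10, seed = 1)))
#' @export
network_index_fn <- function(measure = c("sip", "bnp", "kbi",
                                         "cpl", "nd", "mod"),
                             method = "pearson", template = NULL,
                             params = NULL, alpha = 0.05, seed = 1L) {
  measure <- match.arg(measure)
  if (measure == "kbi") {
    if (is.null(template))
      stop("measure 'kbi' needs a `template` IPF plot")
    if (is.null(params))
      stop("measure 'kbi' needs fixed `params` (see kernel_params())")
  }
  force(method); force(alpha); force(seed)
  function(suv) {
    built <- correlation_distance(suv, method)
    switch(measure,
      sip = sip(ipf(graph_filtration(built$network))),
      bnp = bnp_index(betti_curve(graph_filtration(built$network))),
      kbi = kbi(ipf(graph_filtration(built$network)), template, params),
      cpl = cpl(bonferroni_filter(built$network, built$pvals, alpha)),
      nd = network_diameter(bonferroni_filter(built$network, built$pvals,
                                              alpha)),
      mod = modularity_index(bonferroni_filter(built$network, built$pvals,
                                               alpha), seed = seed)$mod)
  }
}

#' Group-wise permutation test for a univariate network index
#'
#' Because each group contributes a single group-wise network, no parametric
#' null distribution is available for a network index; the null is built
#' empirically.  The observed statistic is the absolute index difference
#' between the two groups' networks.  Each permutation randomly reassigns
#' the pooled subjects to two pseudo-groups of the original sizes, rebuilds
#' both group-wise networks, and records the absolute index difference.
#' The p-value is the fraction of permuted differences at least as large as
#' the observed one (ties count; two-sided by construction since the
#' statistic is absolute).
#'
#' @param groupA,groupB [suv_table] objects with identical ROI label sets
#'   and at least 3 subjects each.
#' @param index_fn function from [suv_table] to scalar, e.g. from
#'   [network_index_fn()].
#' @param n_perm number of permutations, default 10000.
#' @param seed integer seed for reproducibility.
#' @param smooth if `TRUE`, use the add-one estimator
#'   `(count + 1) / (n_perm + 1)` so the p-value can never be exactly 0.
#' @return Object of class `perm_test`: list with `observed_diff`,
#'   `permuted_diffs`, `p_value`, `n_perm`, `seed`.
#' @examples
#' g <- simulate_three_groups(cohort_spec(n_subjects = 12, n_roi = 8,
#'                                        seed = 4), scales = c(0.3, 0.6, 0.9))
#' permutation_test(g$low, g$high, network_index_fn("sip"),
#'                  n_perm = 200, seed = 1)
#' @export
permutation_test <- function(groupA, groupB, index_fn, n_perm = 10000L,
                             seed = NULL, smooth = FALSE) {
  stopifnot(inherits(groupA, "suv_table"), inherits(groupB, "suv_table"),
            is.function(index_fn))
  if (!setequal(groupA$roi_labels, groupB$roi_labels))
    stop("the two groups cover different ROI sets")
  if (nrow(groupA$values) < 3L || nrow(groupB$values) < 3L)
    stop("each group needs at least 3 subjects")
  # align B's columns to A's ROI order
  groupB <- suv_table(groupB$values[, groupA$roi_labels, drop = FALSE],
                      subject_ids = groupB$subject_ids,
                      roi_labels = groupA$roi_labels, group = groupB$group)
  observed <- abs(index_fn(groupA) - index_fn(groupB))
  pooled <- rbind(groupA$values, groupB$values)
  rownames(pooled) <- paste0("p", seq_len(nrow(pooled)))
  kA <- nrow(groupA$values)
  kT <- nrow(pooled)
  if (!is.null(seed)) set.seed(seed)
  permuted <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(kT, kA)
    pa <- suv_table(pooled[idx, , drop = FALSE], group = "permA")
    pb <- suv_table(pooled[-idx, , drop = FALSE], group = "permB")
    abs(index_fn(pa) - index_fn(pb))
  }, numeric(1))
  count <- sum(permuted >= observed)
  p <- if (smooth) (count + 1) / (n_perm + 1) else count / n_perm
  structure(list(observed_diff = observed, permuted_diffs = permuted,
                 p_value = p, n_perm = as.integer(n_perm), seed = seed,
                 smooth = smooth),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test: observed |diff| = %.6g\n", x$observed_diff))
  cat(sprintf("  p = %.4g  (%d permutations%s)\n", x$p_value, x$n_perm,
              if (x$smooth) ", add-one smoothed" else ""))
  invisible(x)
}

#' @export
plot.perm_test <- function(x, ...) {
  graphics::hist(x$permuted_diffs, breaks = 40,
                 xlab = "permuted |index difference|",
                 main = "Permutation null distribution", ...)
  graphics::abline(v = x$observed_diff, col = "red3", lwd = 2)
  invisible(x)
}
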