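#' Specification of a synthetic cohort
#'
#' Describes a group of subjects whose regional mean uptake values are drawn
#' from a multivariate normal with block-structured correlation: `within_r`
#' inside each block of ROIs, `between_r` across blocks, both multiplied by
#' a per-group `coupling_scale` that models the group's overall metabolic
#' coupling (integration) strength.  Values are shifted by `baseline` and
#' truncated below at 0 to emulate non-negative uptake.
#'
#' The defaults emulate an FDG-PET-like cohort: 90 ROIs organised as 45
#' blocks of two (homologous left-right region pairs, the strongest
#' inter-regional couplings in brain data), moderate within-pair correlation
#' (0.40), weak global inter-regional correlation (0.10), baseline uptake 5
#' with unit residual spread, and 280 subjects (a typical control-group
#' size).  Block sizes are made as equal as possible when `n_roi` is not
#' divisible by `n_blocks`.
#'
#' @param n_subjects subjects per group.
#' @param n_roi number of ROIs.
#' @param n_blocks number of correlation blocks (modules); defaults to
#'   `floor(n_roi / 2)`, i.e. blocks of two.
#' @param within_r target inter-ROI correlation inside a block, in (-1, 1).
#' @param between_r target correlation across blocks, in (-1, 1).
#' @param baseline mean SUV level added to every value.
#' @param noise_sd residual spread (> 0).
#' @param coupling_scale per-group multiplier on both correlations;
#'   `|within_r * coupling_scale|` must stay below 1.
#' @param seed integer seed (optional).
#' @return Object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [simulate_three_groups()]
#' @export
cohort_spec <- function(n_subjects = 280L, n_roi = 90L, n_blocks = NULL,
                        within_r = 0.40, between_r = 0.10, baseline = 5,
                        noise_sd = 1, coupling_scale = 1, seed = NULL) {
  if (n_roi < 3L) stop("`n_roi` must be at least 3")
  # default: blocks of two, emulating homologous region pairs
  if (is.null(n_blocks)) n_blocks <- max(1L, n_roi %/% 2L)
  if (n_subjects < 2L) stop("`n_subjects` must be at least 2")
  if (n_blocks < 1L || n_blocks > n_roi)
    stop("`n_blocks` must lie in [1, n_roi]")
  if (abs(within_r) >= 1 || abs(between_r) >= 1)
    stop("correlations must lie in (-1, 1)")
  if (abs(within_r * coupling_scale) >= 1)
    stop("|within_r * coupling_scale| must stay below 1")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_roi = as.integer(n_roi), n_blocks = as.integer(n_blocks),
                 within_r = within_r, between_r = between_r,
                 baseline = baseline, noise_sd = noise_sd,
                 coupling_scale = coupling_scale, seed = seed),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("cohort_spec: %d subjects x %d ROIs, %d blocks, ",
                     "r_within %.2f, r_between %.2f, coupling %.2f\n"),
              x$n_subjects, x$n_roi, x$n_blocks, x$within_r, x$between_r,
              x$coupling_scale))
  invisible(x)
}

# block id per ROI, sizes as equal as possible
block_assignment <- function(n_roi, n_blocks) {
  sizes <- diff(round(seq(0, n_roi, length.out = n_blocks + 1)))
  rep(seq_len(n_blocks), sizes)
}

# target correlation matrix of a spec (coupling scale applied)
cohort_sigma <- function(spec) {
  blk <- block_assignment(spec$n_roi, spec$n_blocks)
  rw <- spec$within_r * spec$coupling_scale
  rb <- spec$between_r * spec$coupling_scale
  sigma <- outer(blk, blk, function(a, b) ifelse(a == b, rw, rb))
  diag(sigma) <- 1
  sigma
}

#' Simulate a synthetic cohort
#'
#' Draws an [suv_table] from the multivariate normal model described by a
#' [cohort_spec]: block-structured correlation scaled by the group's
#' coupling strength, shifted by the baseline and truncated below at zero.
#' Deterministic under the spec's `seed`.
#'
#' @param spec a [cohort_spec].
#' @param group group label for the resulting table.
#' @return An [suv_table] of dimension `n_subjects x n_roi`.
#' @examples
#' simulate_cohort(cohort_spec(n_subjects = 20, n_roi = 10, seed = 1))
#' @export
simulate_cohort <- function(spec, group = "synthetic") {
  stopifnot(inherits(spec, "cohort_spec"))
  sigma <- cohort_sigma(spec)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf(paste0("target correlation is not positive definite ",
                        "(within_r = %g, between_r = %g, coupling_scale = %g, ",
                        "n_blocks = %d)"),
                 spec$within_r, spec$between_r, spec$coupling_scale,
                 spec$n_blocks))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  z <- matrix(stats::rnorm(spec$n_subjects * spec$n_roi),
              spec$n_subjects) %*% ch
  vals <- pmax(spec$baseline + spec$noise_sd * z, 0)
  suv_table(vals,
            subject_ids = sprintf("s%03d", seq_len(spec$n_subjects)),
            roi_labels = sprintf("roi%03d", seq_len(spec$n_roi)),
            group = group)
}

#' Simulate three groups differing only in coupling strength
#'
#' Generates three cohorts identical in every respect except
#' `coupling_scale`, emulating a progression of network integration
#' strength (e.g. patients < prodromal < controls).  Seeds are derived from
#' the base spec's seed (base, base+1, base+2) so the three groups are
#' independent but jointly reproducible.
#'
#' @param base a [cohort_spec]; its `coupling_scale` is ignored.
#' @param scales increasing numeric vector of three coupling scales.
#' @param groups labels for the three cohorts.
#' @return Named list of three [suv_table]s (`low`, `mid`, `high` by
#'   default).
#' @export
simulate_three_groups <- function(base, scales = c(0.3, 0.6, 0.9),
                                  groups = c("low", "mid", "high")) {
  stopifnot(inherits(base, "cohort_spec"), length(scales) == 3L,
            length(groups) == 3L)
  if (is.unsorted(scales, strictly = TRUE))
    stop("`scales` must be strictly increasing")
  out <- lapply(seq_along(scales), function(i) {
    sp <- cohort_spec(n_subjects = base$n_subjects, n_roi = base$n_roi,
                      n_blocks = base$n_blocks, within_r = base$within_r,
                      between_r = base$between_r, baseline = base$baseline,
                      noise_sd = base$noise_sd, coupling_scale = scales[i],
                      seed = if (is.null(base$seed)) NULL else
                        base$seed + i - 1L)
    simulate_cohort(sp, group = groups[i])
  })
  stats::setNames(out, groups)
}
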