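test_that("correlation distance hits its analytic endpoints", {
  set.seed(21)
  base <- rnorm(6, 5)
  vals <- cbind(r1 = base, r2 = base, r3 = -base + 12, r4 = rnorm(6, 5))
  net <- correlation_distance(suv_table(vals))$network
  expect_equal(net$weights["r1", "r2"], 0)        # identical columns, r = 1
  expect_equal(net$weights["r1", "r3"], 2)        # mirrored column, r = -1
  expect_true(all(diag(net$weights) == 0))
})

test_that("pearson distances match the explicit covariance-sum oracle", {
  set.seed(22)
  x <- random_suv(5, 3)
  w <- correlation_distance(x)$network$weights
  v <- x$values
  for (i in 1:2) for (j in (i + 1):3) {
    xi <- v[, i]; xj <- v[, j]
    covij <- sum((xi - mean(xi)) * (xj - mean(xj))) / (5 - 1)
    sdi <- sqrt(sum((xi - mean(xi))^2) / 4)
    sdj <- sqrt(sum((xj - mean(xj))^2) / 4)
    expect_equal(w[i, j], 1 - covij / (sdi * sdj), tolerance = 1e-12)
  }
})

test_that("edge p-values agree with cor.test", {
  set.seed(23)
  x <- random_suv(12, 4)
  for (method in c("pearson", "spearman")) {
    p <- correlation_distance(x, method)$pvals$pvals
    ref <- stats::cor.test(x$values[, 1], x$values[, 2], method = method,
                           exact = FALSE)$p.value
    expect_equal(p[1, 2], ref, tolerance = 1e-10)
  }
  # kendall uses the standard normal approximation for tau
  p <- correlation_distance(x, "kendall")$pvals$pvals
  tau <- stats::cor(x$values[, 1], x$values[, 2], method = "kendall")
  K <- 12
  z <- 3 * tau * sqrt(K * (K - 1)) / sqrt(2 * (2 * K + 5))
  expect_equal(p[1, 2], 2 * pnorm(-abs(z)), tolerance = 1e-12)
})

test_that("degenerate SUV tables are rejected with a named culprit", {
  v <- matrix(rnorm(12, 5), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  v[, 2] <- 3
  expect_error(correlation_distance(suv_table(v)), "zero-variance ROI: b")
  expect_error(correlation_distance(random_suv(2, 3)), "at least 3 subjects")
})

test_that("distances are invariant to subject order and equivariant to ROI order", {
  set.seed(24)
  x <- random_suv(10, 5)
  w1 <- correlation_distance(x)$network$weights
  perm_rows <- sample(10)
  x2 <- suv_table(x$values[perm_rows, ], group = x$group)
  expect_equal(correlation_distance(x2)$network$weights, w1, tolerance = 1e-12)
  perm_cols <- sample(5)
  x3 <- suv_table(x$values[, perm_cols], group = x$group)
  expect_equal(correlation_distance(x3)$network$weights,
               w1[perm_cols, perm_cols], tolerance = 1e-12)
})

test_that("rank-based distances ignore monotone transforms", {
  set.seed(25)
  x <- random_suv(9, 4)
  y <- suv_table(exp(x$values / 2), group = x$group)
  for (method in c("spearman", "kendall")) {
    expect_equal(correlation_distance(x, method)$network$weights,
                 correlation_distance(y, method)$network$weights,
                 tolerance = 1e-12)
  }
})

test_that("bonferroni filter removes exactly the non-significant edges", {
  set.seed(26)
  net <- random_network(4)
  m <- 6L

  # all p-values 1: nothing survives
  p1 <- edge_pvalues(matrix(1, 4, 4), net$roi_labels)
  f1 <- bonferroni_filter(net, p1)
  expect_true(all(is.na(f1$weights[upper.tri(f1$weights)])))

  # boundary: p exactly alpha/m is removed (strict inequality)
  pm <- matrix(1, 4, 4)
  pm[1, 2] <- pm[2, 1] <- 0.05 / m
  f2 <- bonferroni_filter(net, edge_pvalues(pm, net$roi_labels))
  expect_true(is.na(f2$weights[1, 2]))
  pm[1, 2] <- pm[2, 1] <- 0.05 / m - 1e-9
  f3 <- bonferroni_filter(net, edge_pvalues(pm, net$roi_labels))
  expect_identical(f3$weights[1, 2], net$weights[1, 2])

  expect_error(bonferroni_filter(net, p1, alpha = 0), "alpha")
  expect_error(bonferroni_filter(net, p1, alpha = 1.2), "alpha")
})

test_that("an engineered strong pair is the only survivor, per the t-tail oracle", {
  set.seed(27)
  K <- 10
  shared <- rnorm(K)
  vals <- cbind(r1 = 5 + shared, r2 = 5 + shared + rnorm(K, sd = 1e-3),
                r3 = rnorm(K, 5), r4 = rnorm(K, 5))
  built <- correlation_distance(suv_table(vals))
  filt <- bonferroni_filter(built$network, built$pvals, alpha = 0.05)
  present <- which(!is.na(filt$weights) & upper.tri(filt$weights),
                   arr.ind = TRUE)
  expect_equal(nrow(present), 1L)
  expect_equal(unname(present[1, ]), c(1L, 2L))
  # recompute the surviving pair's p-value independently
  r <- cor(vals[, 1], vals[, 2])
  pt_oracle <- 2 * pt(-abs(r * sqrt((K - 2) / (1 - r^2))), df = K - 2)
  expect_equal(built$pvals$pvals[1, 2], pt_oracle, tolerance = 1e-12)
  expect_lt(pt_oracle, 0.05 / 6)
})

test_that("filtering never adds edges nor alters retained weights", {
  set.seed(28)
  x <- random_suv(15, 8)
  built <- correlation_distance(x)
  f <- bonferroni_filter(built$network, built$pvals)
  kept <- !is.na(f$weights)
  expect_identical(f$weights[kept], built$network$weights[kept])
  expect_true(all(is.na(f$weights) | kept))
})
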