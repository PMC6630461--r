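test_that("graph filtration equals single-linkage merge heights", {
  # two nodes joined by one weight
  w <- matrix(c(0, 0.7, 0.7, 0), 2, 2)
  f <- graph_filtration(weighted_network(w))
  expect_equal(f$lam, c(0, 0.7))
  expect_equal(f$m, 2L)

  # distinct weights: merge heights equal the exhaustive threshold sweep
  set.seed(31)
  for (rep in 1:20) {
    net <- random_network(sample(4:12, 1))
    f <- graph_filtration(net)
    expect_equal(f$lam[-1L], sweep_merge_heights(net$weights),
                 tolerance = 1e-12)
  }

  # complete graph with all equal weights: N - 1 tied heights
  w <- matrix(0.4, 5, 5); diag(w) <- 0
  f <- graph_filtration(weighted_network(w))
  expect_equal(f$lam, c(0, rep(0.4, 4)))

  expect_error(graph_filtration(unclass(weighted_network(matrix(0, 2, 2)))),
               "weighted_network")
})

test_that("filtration objects enforce their invariants", {
  expect_error(filtration(c(0.1, 0.5)), "lambda_0 = 0")
  expect_error(filtration(c(0, 0.5, 0.3)), "non-decreasing")
  expect_error(filtration(0), "at least 2")
  f <- filtration(c(0, 0.2, 0.2, 0.8))
  expect_equal(f$m, 4L)
})

test_that("the Betti curve counts components exactly", {
  set.seed(32)
  for (rep in 1:10) {
    N <- sample(3:10, 1)
    net <- random_network(N)
    f <- graph_filtration(net)
    curve <- betti_curve(f)
    # at 0 every node is isolated; beyond the last height one component
    expect_equal(beta0_at(curve, 0), N)
    expect_equal(beta0_at(curve, max(f$lam) + 1), 1L)
    # at midpoints between critical values, compare to union-find
    mids <- (head(unique(f$lam), -1) + tail(unique(f$lam), -1)) / 2
    for (l in c(mids, unique(f$lam)))
      expect_equal(beta0_at(curve, l), uf_components(net$weights, l))
  }
})

test_that("ties collapse into a single Betti drop", {
  w <- matrix(0.4, 4, 4); diag(w) <- 0
  curve <- betti_curve(graph_filtration(weighted_network(w)))
  expect_equal(curve$lambda, c(0, 0.4))
  expect_equal(curve$beta0, c(4L, 1L))
})

test_that("bnp_index is the absolute OLS slope of the Betti plot", {
  # constant curve: slope 0
  flat <- structure(data.frame(lambda = c(0, 1, 2), beta0 = c(3L, 3L, 3L)),
                    class = c("betti_curve", "data.frame"))
  expect_equal(bnp_index(flat), 0)
  # exact line beta0 = 90 - 300 lambda
  lam <- seq(0, 0.25, by = 0.05)
  line <- structure(data.frame(lambda = lam, beta0 = 90 - 300 * lam),
                    class = c("betti_curve", "data.frame"))
  expect_equal(bnp_index(line), 300, tolerance = 1e-10)
  # random curve against the closed-form oracle
  set.seed(33)
  curve <- betti_curve(graph_filtration(random_network(9)))
  expect_equal(bnp_index(curve), ols_slope_abs(curve$lambda, curve$beta0),
               tolerance = 1e-12)
})

test_that("IPF reproduces its defining formula", {
  # worked example
  plt <- ipf(filtration(c(0, 0.2, 0.5, 0.9)))
  expect_equal(unname(plt[, "ipf"]),
               c(4 / 12 * 1.6, 3 / 12 * 1.4, 2 / 12 * 0.9, 0),
               tolerance = 1e-12)
  # last value is exactly zero, values non-increasing and non-negative
  set.seed(34)
  for (rep in 1:25) {
    m <- sample(3:30, 1)
    lam <- c(0, sort(runif(m - 1, 0, 2)))
    v <- ipf(filtration(lam))[, "ipf"]
    expect_identical(v[m], 0)
    expect_true(all(diff(v) <= 1e-15))
    expect_true(all(v >= 0))
    expect_equal(v, ipf_direct(lam), tolerance = 1e-12)
  }
  # scaling all lambda by s scales every IPF value by s
  lam <- c(0, 0.1, 0.4, 0.5, 1.1)
  expect_equal(ipf(filtration(3 * lam))[, "ipf"],
               3 * ipf(filtration(lam))[, "ipf"], tolerance = 1e-12)
})

test_that("SIP is the absolute slope of the IPF plot", {
  plt <- ipf(filtration(c(0, 0.2, 0.5, 0.9)))
  expect_equal(sip(plt), 0.5833333333, tolerance = 1e-9)
  expect_equal(sip(plt), ols_slope_abs(plt[, "lambda"], plt[, "ipf"]),
               tolerance = 1e-12)
  # flat plot has zero slope; doubling IPF values doubles the slope
  expect_equal(sip(make_ipf_plot(c(0, 1, 2), c(1, 1, 1))), 0)
  doubled <- make_ipf_plot(plt[, "lambda"], 2 * plt[, "ipf"])
  expect_equal(sip(doubled), 2 * sip(plt), tolerance = 1e-12)
  expect_error(sip(make_ipf_plot(c(1, 1), c(0, 1))), "identical")
})

test_that("kernel parameters match brute-force median enumeration", {
  p1 <- make_ipf_plot(c(0, 0.2, 0.6), c(0.5, 0.3, 0))
  p2 <- make_ipf_plot(c(0, 0.4, 1.0), c(0.9, 0.4, 0))
  kp <- kernel_params(list(p1, p2))
  expect_identical(kp$p, 5L)
  med_pair <- function(P) {
    d <- c()
    for (i in 1:(nrow(P) - 1)) for (j in (i + 1):nrow(P))
      d <- c(d, sqrt(sum((P[i, ] - P[j, ])^2)))
    sort(d)[ceiling(length(d) / 2)]  # odd count here
  }
  expect_equal(kp$sigma, median(c(med_pair(p1), med_pair(p2))),
               tolerance = 1e-12)
  # positive-lambda medians: (0.2+0.6)/2 = 0.4 and (0.4+1.0)/2 = 0.7
  expect_equal(kp$c_weight, median(c(0.4, 0.7))^(-5), tolerance = 1e-12)

  # scale equivariance: coordinates times s
  s <- 2.5
  kp_s <- kernel_params(list(make_ipf_plot(s * p1[, 1], s * p1[, 2]),
                             make_ipf_plot(s * p2[, 1], s * p2[, 2])))
  expect_equal(kp_s$sigma, s * kp$sigma, tolerance = 1e-12)
  expect_equal(kp_s$c_weight, s^(-5) * kp$c_weight, tolerance = 1e-12)

  expect_error(kernel_params(list(make_ipf_plot(c(0, 0), c(1, 1)))), "sigma")
})

test_that("KBI matches hand evaluation and its analytic properties", {
  # unit self-match: single point, lambda = 1, C = 1 -> arctan(1)^2
  one <- make_ipf_plot(1, 0.3)
  params <- make_kernel_params(sigma = 0.7, c_weight = 1)
  expect_equal(kbi(one, one, params), pi^2 / 16, tolerance = 1e-12)

  # all lambda^X = 0 annihilates every term
  X0 <- make_ipf_plot(c(0, 0), c(0.4, 0.1))
  T0 <- make_ipf_plot(c(0, 0.8), c(0.4, 0))
  expect_equal(kbi(X0, T0, params), 0)

  # two-point hand evaluation, sigma = 0.5, C = 1
  X <- make_ipf_plot(c(0.3, 0.9), c(0.5, 0))
  T <- make_ipf_plot(c(0.4, 0.8), c(0.45, 0.05))
  hand <- mean(c(
    atan(0.3^5) * atan(0.4^5) * exp(-((0.3 - 0.4)^2 + (0.5 - 0.45)^2) / 0.5),
    atan(0.9^5) * atan(0.8^5) * exp(-((0.9 - 0.8)^2 + (0.05)^2) / 0.5)))
  expect_equal(kbi(X, T, make_kernel_params(sigma = 0.5, c_weight = 1)),
               hand, tolerance = 1e-12)

  # symmetry and non-negativity
  set.seed(35)
  for (rep in 1:10) {
    A <- ipf(filtration(c(0, sort(runif(7, 0, 2)))))
    B <- ipf(filtration(c(0, sort(runif(7, 0, 2)))))
    kp <- kernel_params(list(A, B))
    expect_equal(kbi(A, B, kp), kbi(B, A, kp), tolerance = 1e-12)
    expect_gte(kbi(A, B, kp), 0)
    expect_lte(kbi(A, B, kp), (pi / 2)^2)
  }

  expect_error(kbi(one, X, params), "point counts")
})

test_that("the pipeline indices ignore node labels", {
  set.seed(36)
  x <- random_suv(20, 8)
  net <- correlation_distance(x)$network
  perm <- sample(8)
  net_p <- weighted_network(net$weights[perm, perm])
  f <- graph_filtration(net); fp <- graph_filtration(net_p)
  expect_equal(f$lam, fp$lam, tolerance = 1e-12)
  expect_equal(bnp_index(betti_curve(f)), bnp_index(betti_curve(fp)))
  expect_equal(sip(ipf(f)), sip(ipf(fp)), tolerance = 1e-12)
})

test_that("the control template is the composed three-step pipeline", {
  set.seed(37)
  nc <- random_suv(15, 7, group = "NC")
  tpl <- template_from_controls(nc)
  direct <- ipf(graph_filtration(correlation_distance(nc, "pearson")$network))
  expect_equal(unclass(tpl), unclass(direct), tolerance = 0)
  expect_identical(unname(tpl[nrow(tpl), "ipf"]), 0)

  # with shared lambda, the Gaussian factor makes T its own best match
  kp <- kernel_params(list(tpl))
  self <- kbi(tpl, tpl, kp)
  for (rep in 1:20) {
    pert <- make_ipf_plot(tpl[, "lambda"],
                          pmax(tpl[, "ipf"] + rnorm(nrow(tpl), sd = 0.05), 0))
    expect_lte(kbi(pert, tpl, kp), self + 1e-12)
  }
})
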