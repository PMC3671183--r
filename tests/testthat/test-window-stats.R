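grid_curve <- function(f, n = 100L, probe = "p") {
  x <- seq(0, 1, length.out = n)
  list(x_grid = x, mean = f(x), probe = probe)
}

test_that("windowed trapezoid integrals handle exact cases and bad windows", {
  const1 <- grid_curve(function(x) rep(1, length(x)))
  w <- marker_window(0.63, 0.93)
  expect_equal(area_integral(const1, w)$value, 0.30)

  lin <- grid_curve(identity)
  expect_equal(area_integral(lin, marker_window(1e-12, 1))$value, 0.5,
               tolerance = 1e-9)

  expect_error(marker_window(0.95, 0.63), "x1 < x2")
  part <- list(x_grid = seq(0.2, 1, length.out = 50), mean = rep(1, 50))
  expect_error(area_integral(part, marker_window(0.1, 0.5)), "span")
})

test_that("windowed integrals are additive and monotone", {
  set.seed(7)
  y <- cumsum(rnorm(100))
  y <- (y - min(y)) / diff(range(y))
  cur <- list(x_grid = seq(0, 1, length.out = 100), mean = y)
  for (m in c(0.41, 0.6377, 0.8)) {
    whole <- area_integral(cur, marker_window(0.3, 0.9))$value
    left <- area_integral(cur, marker_window(0.3, m))$value
    right <- area_integral(cur, marker_window(m, 0.9))$value
    expect_equal(left + right, whole, tolerance = 1e-12)
  }
  lower <- list(x_grid = cur$x_grid, mean = y * 0.7)
  expect_lte(area_integral(lower, marker_window(0.2, 0.77))$value,
             area_integral(cur, marker_window(0.2, 0.77))$value)
})

test_that("trapezoid integrals match a dense Riemann oracle on smooth curves", {
  set.seed(11)
  for (i in 1:5) {
    knots <- sort(c(0, runif(6), 1))
    sf <- splinefun(knots, runif(8, 0.1, 1), method = "natural")
    cur <- grid_curve(function(x) pmax(sf(x), 0.01))
    x1 <- runif(1, 0, 0.5); x2 <- runif(1, x1 + 0.1, 1)
    w <- marker_window(x1, x2)
    got <- area_integral(cur, w)$value
    # midpoint Riemann sum over the piecewise-linear curve, 1e6 intervals
    xs <- seq(x1, x2, length.out = 1e6 + 1)
    mids <- (xs[-1] + xs[-length(xs)]) / 2
    oracle <- sum(approx(cur$x_grid, cur$mean, mids)$y) * (x2 - x1) / 1e6
    expect_lt(abs(got - oracle), 1e-4)
    if (requireNamespace("pracma", quietly = TRUE)) {
      # third route: pracma's trapezoid on a fine restriction
      fine <- seq(x1, x2, length.out = 2e5)
      expect_equal(got, pracma::trapz(fine, approx(cur$x_grid, cur$mean,
                                                   fine)$y),
                   tolerance = 1e-6)
    }
  }
})

test_that("half-max window derivation finds analytic crossings", {
  pulse <- grid_curve(function(x) ifelse(x >= 0.6 & x <= 0.9, 1, 0))
  w <- derive_window(structure(pulse, class = "averaged_profile"))
  step <- 1 / 99
  expect_lt(abs(w$x1 - 0.6), step + 1e-12)
  expect_lt(abs(w$x2 - 0.9), step + 1e-12)
  expect_equal(w$source, "half_max_of_marker")

  # triangular peak at 0.78 with half-max width 0.3
  tri <- grid_curve(function(x) pmax(0, 1 - abs(x - 0.78) / 0.3))
  wt <- derive_window(structure(tri, class = "averaged_profile"))
  expect_lt(abs(wt$x1 - (0.78 - 0.15)), step)
  expect_lt(abs(wt$x2 - (0.78 + 0.15)), step)

  const <- grid_curve(function(x) rep(0.4, length(x)))
  expect_error(derive_window(structure(const, class = "averaged_profile")),
               "no half-max crossing")
  bimodal <- grid_curve(function(x)
    pmax(0, 1 - abs(x - 0.2) / 0.05, 1 - abs(x - 0.8) / 0.05))
  expect_error(derive_window(structure(bimodal, class = "averaged_profile")),
               "disjoint")
})

test_that("KS statistic matches trivial cases and brute-force enumeration", {
  w <- marker_window(0, 1)
  mk <- function(v) structure(list(x_grid = seq(0, 1, length.out = length(v)),
                                   mean = v, n_scans = length(v), probe = "p"),
                              class = "averaged_profile")
  same <- mk(c(0.2, 0.5, 0.9, 0.4))
  r <- ks_compare(same, same, w)
  expect_equal(r$D, 0)
  expect_equal(r$p_value, 1)

  lo <- mk(c(0.1, 0.2, 0.3)); hi <- mk(c(0.7, 0.8, 0.9))
  expect_equal(ks_compare(lo, hi, w)$D, 1)

  # brute-force ECDF enumeration oracle, small samples with ties
  set.seed(3)
  for (i in 1:100) {
    n1 <- sample(2:10, 1); n2 <- sample(2:10, 1)
    a <- round(runif(n1), sample(1:2, 1))
    b <- round(runif(n2), sample(1:2, 1))
    r <- ks_compare(mk(a), mk(b), w)
    expect_identical(r$D, brute_ks_D(a, b))
    expect_equal(r$n1, n1)
  }
})

test_that("KS p-value agrees with the asymptotic two-sample reference", {
  set.seed(21)
  a <- runif(40); b <- runif(45, 0.1, 1.1)
  mk <- function(v) structure(list(x_grid = seq(0, 1, length.out = length(v)),
                                   mean = v, n_scans = length(v)),
                              class = "averaged_profile")
  r <- ks_compare(mk(a), mk(b), marker_window(0, 1))
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(r$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-7)
})

test_that("KS D is invariant under strictly monotone transforms", {
  set.seed(9)
  mk <- function(v) structure(list(x_grid = seq(0, 1, length.out = length(v)),
                                   mean = v, n_scans = length(v)),
                              class = "averaged_profile")
  w <- marker_window(0, 1)
  for (i in 1:20) {
    a <- runif(12); b <- runif(15)
    base <- ks_compare(mk(a), mk(b), w)$D
    expect_equal(ks_compare(mk(exp(a)), mk(exp(b)), w)$D, base)
    expect_equal(ks_compare(mk(a^3), mk(b^3), w)$D, base)
  }
})

test_that("density_cdf mode compares normalized cumulative integrals", {
  f <- function(x) ifelse(x > 0.5, 1, 0.2)
  c1 <- grid_curve(f)
  r <- ks_compare(structure(c1, class = "averaged_profile"),
                  structure(c1, class = "averaged_profile"),
                  marker_window(0.1, 0.9), mode = "density_cdf")
  expect_equal(r$D, 0)
  expect_false(r$p_value_defined)

  zero <- grid_curve(function(x) ifelse(x < 0.45, 1, 0))
  expect_error(
    ks_compare(structure(zero, class = "averaged_profile"),
               structure(c1, class = "averaged_profile"),
               marker_window(0.5, 0.9), mode = "density_cdf"),
    "all-zero")
})

test_that("scan-count effective n is used when requested", {
  mk <- function(v, ns) structure(
    list(x_grid = seq(0, 1, length.out = length(v)), mean = v, n_scans = ns),
    class = "averaged_profile")
  set.seed(5)
  a <- mk(runif(30), 12L); b <- mk(runif(30) + 0.2, 12L)
  r_scan <- ks_compare(a, b, marker_window(0, 1), n_for_p = "scans")
  r_val <- ks_compare(a, b, marker_window(0, 1), n_for_p = "values")
  expect_equal(r_scan$D, r_val$D)
  expect_equal(r_scan$n1, 12L)
  expect_equal(r_val$n1, 30L)
  expect_gt(r_scan$p_value, r_val$p_value)
  expect_equal(r_scan$n_meaning, "contributing scans")
})

test_that("windowed integral tables report pairwise ratios", {
  c1 <- structure(grid_curve(function(x) rep(1, length(x)), probe = "A"),
                  class = "averaged_profile")
  c2 <- structure(grid_curve(function(x) rep(0.5, length(x)), probe = "B"),
                  class = "averaged_profile")
  out <- compare_windowed_integrals(list(A = c1, B = c2),
                                    marker_window(0.63, 0.93))
  expect_equal(out$integrals$value, c(0.30, 0.15))
  expect_equal(out$ratios$ratio[out$ratios$probe_a == "A"], 2.0)
  out_self <- compare_windowed_integrals(list(A = c1, A2 = c1))
  expect_equal(unique(out_self$ratios$ratio), 1.0)
  expect_error(compare_windowed_integrals(list(A = c1)), "two probes")
})
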