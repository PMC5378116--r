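test_that("segregating-sites PMF matches the quadrature oracle across regimes", {
  set.seed(11)
  for (reg in c("bidirectional", "uni_M1_zero", "uni_M2_zero", "none")) {
    for (k in 1:10) {
      p <- draw_params(reg)
      theta <- runif(1, 0.5, 4)
      st <- sample(1:3, 1)
      for (s in c(0L, 3L, 17L, 120L)) {
        pm <- seg_sites_pmf(s, st, theta, p)
        orc <- quad_pmf(s, st, theta, p)
        if (orc > 1e-250)
          expect_lt(abs(pm - orc) / orc, 1e-7)
      }
    }
  }
})

test_that("PMF is a proper distribution and nonnegative", {
  p <- sim_params()
  for (st in 1:3) {
    # truncation at mean + 12 sd of the compound distribution, extended
    # while visible mass remains at the cut
    m <- seg_sites_mean(st, 2, p)
    et2 <- 2 * integrate_pw(function(t) t * coal_time_survival(t, st, p),
                            density_breaks(p))
    vs <- m + 4 * (et2 - coal_time_mean(st, p)^2)  # theta*ET + theta^2*VarT
    smax <- ceiling(m + 12 * sqrt(vs))
    while (seg_sites_pmf(smax, st, 2, p) > 1e-14) smax <- ceiling(smax * 1.5)
    pr <- seg_sites_pmf(0:smax, st, 2, p)
    expect_true(all(pr >= 0))
    expect_lt(abs(sum(pr) - 1), 1e-9)
  }
  # randomized nonnegativity grid
  set.seed(5)
  for (k in 1:20) {
    p <- draw_params(sample(c("bidirectional", "uni_M1_zero", "uni_M2_zero"), 1))
    pr <- seg_sites_pmf(0:80, sample(1:3, 1), runif(1, 0.2, 5), p)
    expect_true(all(pr >= 0))
  }
})

test_that("log PMF is stable for very large counts and consistent with the PMF", {
  p <- sim_params()
  lp <- seg_sites_logpmf(c(5L, 5000L, 10000L), 3, 50, p)
  expect_true(all(is.finite(lp)))
  expect_equal(exp(seg_sites_logpmf(5, 1, 2, p)), seg_sites_pmf(5, 1, 2, p),
               tolerance = 1e-12)
  # monotone tail decay beyond the mode
  tail_lp <- seg_sites_logpmf(200:260, 3, 2, p)
  expect_true(all(diff(tail_lp) < 0))
})

test_that("truncated Poisson sums via the Poisson CDF agree with high-precision sums", {
  # e^-x sum_{l<=s} x^l/l! computed in log space, against Kahan-style
  # compensated summation in extended range via Rmpfr-free brute force at
  # moderate x and via the Poisson CDF's own complement identity at large x
  xs <- c(0.5, 3, 40, 400, 4000, 10000)
  ss <- c(0L, 2L, 35L, 420L, 3900L, 10000L)
  for (i in seq_along(xs)) {
    x <- xs[i]; s <- ss[i]
    direct <- ppois(s, x)
    if (x <= 400) {
      l <- 0:s
      brute <- sum(exp(-x + l * log(x) - lgamma(l + 1)))
      expect_equal(direct, brute, tolerance = 1e-10)
    }
    # complement identity P[X<=s] + P[X>s] = 1 at full precision
    expect_equal(direct + ppois(s, x, lower.tail = FALSE), 1, tolerance = 1e-12)
  }
})

test_that("the compiled kernel agrees with the pure-R reference implementation", {
  set.seed(61)
  for (k in 1:30) {
    reg <- sample(c("bidirectional", "uni_M1_zero", "uni_M2_zero", "none"), 1)
    p <- draw_params(reg)
    sp <- migration_spectrum(p)
    st <- sample(1:3, 1)
    s <- sample(c(0:50, 120L, 1000L, 5000L), 12)
    th <- runif(12, 0.2, 5)
    cxx <- iimfit:::segsites_logpmf_kernel(s, th, st, p, sp)
    ref <- iimfit:::segsites_logpmf_kernel_r(s, th, st, p, sp)
    both_inf <- !is.finite(cxx) & !is.finite(ref)
    rel <- abs(cxx - ref) / pmax(abs(ref), 1)
    rel[both_inf] <- 0
    expect_lt(max(rel), 1e-5)
  }
})

test_that("theta limits behave correctly", {
  p <- sim_params()
  for (st in 1:3)
    expect_gt(seg_sites_pmf(0, st, 1e-12, p), 1 - 1e-9)
  expect_equal(seg_sites_mean(3, 0, p), 0)
  # mean identity: sum s * pmf = theta * E[T]
  m <- sum((0:600) * seg_sites_pmf(0:600, 3, 2, p))
  expect_equal(m, seg_sites_mean(3, 2, p), tolerance = 1e-6)
  # state 3, no gene flow: mean = theta * (tau0 + a)
  p0 <- coal_params(a = 0.75, tau1 = 1, tau0 = 2)
  expect_equal(seg_sites_mean(3, 2, p0), 2 * 2.75)
})

test_that("simulated counts agree with the PMF (chi-square goodness of fit)", {
  set.seed(97)
  for (reg in c("bidirectional", "uni_M1_zero", "uni_M2_zero", "none")) {
    p <- draw_params(reg)
    theta <- 2
    st <- sample(1:3, 1)
    n <- 3e4
    tt <- simulate_coal_time(n, st, p)
    s <- rpois(n, theta * tt)
    smax <- max(s)
    pr <- seg_sites_pmf(0:smax, st, theta, p)
    obs <- tabulate(s + 1L, nbins = smax + 1L)
    keep <- n * pr >= 5
    chi <- sum((obs[keep] - n * pr[keep])^2 / (n * pr[keep]))
    pval <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
    expect_gt(pval, 0.001)
  }
})
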