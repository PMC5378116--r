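test_that("simulated coalescence times follow the analytic law", {
  set.seed(123)
  for (reg in c("bidirectional", "uni_M1_zero", "none")) {
    p <- draw_params(reg)
    for (st in c(1, 3)) {
      x <- simulate_coal_time(2e4, st, p)
      ks <- suppressWarnings(
        ks.test(x, function(q) 1 - coal_time_survival(q, st, p)))
      expect_gt(ks$p.value, 0.001)
      se <- sd(x) / sqrt(length(x))
      expect_lt(abs(mean(x) - coal_time_mean(st, p)), 3.5 * se)
    }
  }
  # no gene flow, state 3: exactly tau0 + Exp(a)
  p0 <- coal_params(a = 0.75, tau1 = 0.5, tau0 = 2)
  x <- simulate_coal_time(5e3, 3, p0)
  expect_true(all(x > p0$tau0))
  # isolation dominates when tau1 is large
  p1 <- coal_params(c1 = 1.3, tau1 = 25, tau0 = 26, M1 = 1, M2 = 1)
  x1 <- simulate_coal_time(2e4, 1, p1)
  expect_lt(abs(mean(x1) - 1.3), 0.05)
})

test_that("data sets are deterministic given the seed and have the right design", {
  phi <- sim_phi()
  d1 <- simulate_iim_data(4000, phi = phi, seed = 5)
  d2 <- simulate_iim_data(4000, phi = phi, seed = 5)
  expect_identical(d1, d2)
  d3 <- simulate_iim_data(4000, phi = phi, seed = 6)
  expect_false(identical(d1$s, d3$s))
  # state composition 1/4, 1/4, 1/2
  expect_equal(as.integer(table(d1$state)), c(1000L, 1000L, 2000L))
  # Gamma(15,15) relative rates: mean 1, sd 1/sqrt(15)
  expect_lt(abs(mean(d1$rel_rate) - 1), 0.02)
  expect_lt(abs(sd(d1$rel_rate) - 1 / sqrt(15)), 0.03)
})

test_that("segregating-site counts have the compound-Poisson moments", {
  phi <- sim_phi()
  p <- phi_to_coal(phi)
  d <- simulate_iim_data(6e4, phi = phi, seed = 8)
  s3 <- d$s[d$state == 3]
  m_theory <- 2 * coal_time_mean(3, p)  # E[s] = theta E[T] since E[r] = 1
  se <- sd(s3) / sqrt(length(s3))
  expect_lt(abs(mean(s3) - m_theory), 3.5 * se)
  # unit fixed rates reproduce the homogeneous-rate model exactly
  dh <- simulate_iim_data(1000, phi = phi, rel_rates = rep(1, 1000), seed = 3)
  expect_true(all(dh$rel_rate == 1))
})

test_that("the multi-epoch simulator reduces to the IIM law for a 3-stage history", {
  p <- sim_params()
  ep <- data.frame(duration = c(p$tau1, p$tau0 - p$tau1),
                   size1 = c(p$c1, 1), size2 = c(p$c2, p$b),
                   M1 = c(0, p$M1), M2 = c(0, p$M2))
  set.seed(77)
  for (st in c(1, 3)) {
    x <- iimfit:::ctmc_absorb(2e4, st, 0,
                              lapply(seq_len(2), function(i)
                                list(t_end = cumsum(ep$duration)[i],
                                     size1 = ep$size1[i], size2 = ep$size2[i],
                                     M1 = ep$M1[i], M2 = ep$M2[i])),
                              p$a)
    ks <- suppressWarnings(
      ks.test(x, function(q) 1 - coal_time_survival(q, st, p)))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("secondary-contact histories allow pre-ancestral state-3 coalescence", {
  # migration only in a middle epoch: state-3 pairs can coalesce before the
  # ancestral stage, unlike under pure isolation
  ep <- data.frame(duration = c(0.5, 1.5, 0.5),
                   size1 = c(1, 1, 1), size2 = c(1, 1, 1),
                   M1 = c(0, 1.5, 0), M2 = c(0, 1.5, 0))
  d <- simulate_multiepoch_data(4000, ep, anc_size = 1, theta = 2, seed = 21)
  expect_s3_class(d, "loci_table")
  set.seed(22)
  x <- iimfit:::ctmc_absorb(5e3, 3, 0,
                            lapply(1:3, function(i)
                              list(t_end = cumsum(ep$duration)[i],
                                   size1 = 1, size2 = 1,
                                   M1 = ep$M1[i], M2 = ep$M2[i])), 1)
  expect_gt(mean(x < 2.5), 0.2)   # substantial mass before the ancestral stage
  expect_equal(mean(x < 0.5), 0)  # none during the first isolation epoch
})

test_that("per-epoch state occupancy matches a matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  # one migration epoch; compare absorption by its end against expm
  p <- coal_params(b = 1.6, tau1 = 0, tau0 = 1.2, M1 = 0.8, M2 = 0.3)
  set.seed(31)
  x <- simulate_coal_time(3e4, 1, p)
  frac <- mean(x <= p$tau0)
  oracle <- expm_mig_cdf(p, 1, p$tau0)
  se <- sqrt(oracle * (1 - oracle) / 3e4)
  expect_lt(abs(frac - oracle), 3.5 * se)
})
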