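test_that("coalescence-time density integrates to one and matches the oracle CDF", {
  set.seed(23)
  for (reg in c("bidirectional", "uni_M1_zero", "uni_M2_zero", "none")) {
    p <- draw_params(reg)
    for (st in 1:3) {
      I <- integrate_pw(function(t) coal_time_density(t, st, p),
                        density_breaks(p))
      expect_lt(abs(I - 1), 1e-8)
    }
  }
  # density equals the numerical derivative of 1 - survival at interior points
  p <- sim_params()
  for (st in 1:3) for (t0 in c(0.5, 1.5, 3.0)) {
    h <- 1e-6
    num <- (coal_time_survival(t0 - h, st, p) - coal_time_survival(t0 + h, st, p)) / (2 * h)
    expect_equal(coal_time_density(t0, st, p), num, tolerance = 1e-6)
  }
})

test_that("assembled CDF is continuous at the stage boundaries", {
  set.seed(31)
  for (reg in c("bidirectional", "uni_M1_zero", "none")) {
    p <- draw_params(reg)
    eps <- 1e-9
    for (st in 1:3) for (tb in c(p$tau1, p$tau0)) {
      lo <- coal_time_survival(max(tb - eps, 0), st, p)
      hi <- coal_time_survival(tb + eps, st, p)
      expect_lt(abs(hi - lo), 1e-7)
    }
  }
})

test_that("survival starts at 1, decreases, and the mean has its closed forms", {
  p <- sim_params()
  for (st in 1:3) {
    expect_equal(coal_time_survival(0, st, p), 1)
    sv <- coal_time_survival(seq(0, 10, by = 0.1), st, p)
    expect_true(all(diff(sv) <= 1e-12))
  }
  # no gene flow, state 3: survival 1 until tau0, then Exp(1/a)
  p0 <- coal_params(a = 0.75, tau1 = 1, tau0 = 2)
  expect_equal(coal_time_mean(3, p0), p0$tau0 + p0$a)
  # mean agrees with quadrature of the survival for the full model
  for (st in 1:3) {
    m_quad <- integrate_pw(function(t) coal_time_survival(t, st, p),
                           density_breaks(p))
    expect_equal(coal_time_mean(st, p), m_quad, tolerance = 1e-8)
  }
})

test_that("empty migration or isolation stages are exact limits", {
  # tau1 = tau0: pure isolation then ancestral
  p <- coal_params(a = 0.75, c1 = 1.2, tau1 = 2, tau0 = 2)
  expect_equal(coal_time_density(2.5, 3, p), (1 / 0.75) * exp(-0.5 / 0.75))
  expect_equal(coal_time_density(1, 3, p), 0)
  expect_equal(coal_time_density(1, 1, p), (1 / 1.2) * exp(-1 / 1.2))
  # tau1 = 0: no isolation stage
  p2 <- coal_params(b = 1.3, tau1 = 0, tau0 = 1.5, M1 = 0.4, M2 = 0.9)
  sp <- migration_spectrum(p2)
  expect_equal(coal_time_density(0.5, 1, p2),
               sum(sp$A[1, ] * sp$lam * exp(-sp$lam * 0.5)))
  I <- integrate(function(t) coal_time_density(t, 2, p2), 0, Inf,
                 rel.tol = 1e-10)$value
  expect_lt(abs(I - 1), 1e-8)
})

test_that("domain errors are raised for negative times and bad states", {
  p <- sim_params()
  expect_error(coal_time_density(-0.1, 1, p), "nonnegative")
  expect_error(coal_time_survival(c(1, -2), 2, p), "nonnegative")
  expect_error(coal_time_mean(4, p), "state")
})
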