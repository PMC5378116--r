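test_that("Wald intervals are symmetric and shrink with information", {
  phi0 <- phi_vector(theta_a = 2, theta = 3, theta_b = 2, V = 6)
  d_small <- simulate_iim_data(1500, phi = phi0, seed = 4)
  d_big <- simulate_iim_data(12000, phi = phi0, seed = 4)
  f_small <- fit_iim(d_small, "ISO", n_starts = 2, seed = 1, hessian = TRUE)
  f_big <- fit_iim(d_big, "ISO", n_starts = 2, seed = 1, hessian = TRUE)
  ci_s <- wald_ci(f_small); ci_b <- wald_ci(f_big)
  expect_equal(ci_s$upper - ci_s$estimate, ci_s$estimate - ci_s$lower)
  # eight-fold data: standard errors shrink roughly like 1/sqrt(n)
  expect_true(all(ci_b$se < ci_s$se))
  expect_error(wald_ci(fit_iim(d_small, "ISO", n_starts = 1, seed = 1)),
               "Hessian")
})

test_that("profile intervals contain the MLE and approach Wald on large data", {
  phi0 <- phi_vector(theta_a = 2, theta = 3, theta_b = 2, V = 6)
  d <- simulate_iim_data(12000, phi = phi0, seed = 4)
  f <- fit_iim(d, "ISO", n_starts = 2, seed = 1, hessian = TRUE)
  wd <- wald_ci(f)
  pr <- profile_ci(d, f, "theta")
  expect_gt(f$free[["theta"]], pr$lower)
  expect_lt(f$free[["theta"]], pr$upper)
  wrow <- wd[wd$parameter == "theta", ]
  expect_lt(abs(pr$lower - wrow$lower) / abs(wrow$estimate), 0.02)
  expect_lt(abs(pr$upper - wrow$upper) / abs(wrow$estimate), 0.02)
})

test_that("mutation-rate calibration follows the molecular clock reading", {
  expect_equal(calibrate_mu(46.2, 1e7, 0.1), 2.31e-7)
  # doubling the divergence time halves the rate
  expect_equal(calibrate_mu(10, 2e7, 0.1), calibrate_mu(10, 1e7, 0.1) / 2)
  expect_equal(calibrate_mu(3, 1e7, 0.1), 3 * 5e-9)
  expect_error(calibrate_mu(0, 1e7, 0.1), "positive")
})

test_that("conversion to demographic units applies the printed estimator forms", {
  phi <- phi_vector(theta_a = 3.273, theta = 3.357, theta_b = 1.929,
                    theta_c1 = 6.623, theta_c2 = 2.647,
                    T1 = 6.930, V = 9.778, M1 = 0, M2 = 0.223)
  mu <- 2.31e-7; g <- 0.1
  cv <- convert_estimates(phi, g = g, mu_hat = mu)
  # t0 = (g / 2mu)(T1 + V): about 3.62 million years at these values
  expect_equal(cv$t0, (0.1 / (2 * mu)) * (6.930 + 9.778))
  expect_equal(cv$t0 / 1e6, 3.617, tolerance = 1e-3)
  expect_equal(cv$t1, (0.1 / (2 * mu)) * 6.930)
  expect_equal(cv$Na, 3.273 / (4 * mu))
  # s1 = M2 b / 2 with b = theta_b / theta
  b_hat <- 1.929 / 3.357
  expect_equal(cv$s1, 0.223 * b_hat / 2)
  expect_equal(cv$s1, 0.064, tolerance = 0.01)
  expect_equal(cv$q1, mu * 0.223 * b_hat / 3.357)
  # no gene flow means no migrants
  phi0 <- phi; phi0[["M2"]] <- 0
  cv0 <- convert_estimates(phi0, g = g, mu_hat = mu)
  expect_equal(cv0$q1, 0); expect_equal(cv0$s1, 0)
  # times scale linearly with the generation length
  cv2 <- convert_estimates(phi, g = 0.2, mu_hat = mu)
  expect_equal(cv2$t0, 2 * cv$t0)
})

test_that("delta-method intervals on the converted scale are coherent", {
  # unidirectional gene-flow model with an interior M2 estimate
  uni <- iim_model("custom",
                   free = c("theta_a", "theta", "theta_b", "V", "M2"),
                   fixed = c(T1 = 0, M1 = 0),
                   tied = c(theta_c1 = "theta", theta_c2 = "theta_b"))
  phi0 <- phi_vector(theta_a = 2, theta = 3, theta_b = 2, V = 5, M2 = 0.8)
  d <- simulate_iim_data(4000, phi = phi0, seed = 9)
  f <- fit_iim(d, uni, n_starts = 2, seed = 1, hessian = TRUE)
  mu <- 2e-7
  ci <- delta_method_ci(f, d, g = 0.1, mu_hat = mu)
  expect_setequal(ci$quantity, c("Na", "N", "Nb", "t0", "q1"))
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  # point estimates agree with convert_estimates
  cv <- convert_estimates(f, g = 0.1, mu_hat = mu)
  expect_equal(ci$estimate[ci$quantity == "t0"], cv$t0, tolerance = 1e-8)
  expect_equal(ci$estimate[ci$quantity == "Na"], cv$Na, tolerance = 1e-8)
  expect_equal(ci$estimate[ci$quantity == "q1"], cv$q1, tolerance = 1e-8)
  # interval widths scale linearly with g for the time quantities
  ci2 <- delta_method_ci(f, d, g = 0.2, mu_hat = mu)
  w1 <- ci$upper[ci$quantity == "t0"] - ci$lower[ci$quantity == "t0"]
  w2 <- ci2$upper[ci2$quantity == "t0"] - ci2$lower[ci2$quantity == "t0"]
  expect_equal(w2, 2 * w1, tolerance = 1e-6)
})
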