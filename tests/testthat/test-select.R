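test_that("the LRT computes D, df and conservativeness flags correctly", {
  phi0 <- phi_vector(theta_a = 2, theta = 3, theta_b = 2, V = 6)
  d <- simulate_iim_data(2000, phi = phi0, seed = 12)
  f0 <- fit_iim(d, "ISO", n_starts = 2, seed = 1)
  init <- iimfit:::expand_phi(f0$free, f0$model)[iim_model("IM1")$free]
  f1 <- fit_iim(d, "IM1", n_starts = 2, seed = 1, init = init)
  t01 <- lrt(f0, f1)
  expect_gte(t01$D, 0)
  expect_equal(t01$df, 2L)
  expect_true(t01$boundary)   # M1 = M2 = 0 is a boundary null
  expect_equal(t01$p_naive, pchisq(t01$D, 2, lower.tail = FALSE))
  # identical fits give D = 0, p = 1
  t00 <- lrt(f0, structure(list(logL = f0$logL, model = iim_model("IM1")),
                           class = "iim_fit"))
  expect_equal(t00$D, 0); expect_equal(t00$p_naive, 1)
  # non-nested comparisons are refused
  expect_error(lrt(f1, f0), "not nested")
})

test_that("gene flow and its cessation are detected on informative data", {
  # strong unidirectional gene flow ending well in the past
  phi1 <- phi_vector(theta_a = 2, theta = 3, theta_b = 2.5,
                     T1 = 3, V = 4, M1 = 0, M2 = 1.2)
  d <- simulate_iim_data(6000, phi = phi1, seed = 77)
  sel <- forward_selection(d, c("ISO", "IM1", "IIM1"), alpha = 0.05,
                           n_starts = 2, seed = 2)
  expect_true(all(sel$tests$rejected[sel$tests$H0 == "ISO"]))
  # the selected model frees T1 (an IIM-class history)
  expect_true("T1" %in% sel$selected$free)
  # and the backward step never removes parameters the data support
  expect_gt(sel$fit$free[["M2"]], 0.2)
})

test_that("forward selection stops at ISO on isolation data and handles a single model", {
  phi0 <- phi_vector(theta_a = 2, theta = 3, theta_b = 2, V = 6)
  d <- simulate_iim_data(4000, phi = phi0, seed = 13)
  sel <- forward_selection(d, c("ISO", "IM1"), alpha = 0.01,
                           n_starts = 2, seed = 3)
  expect_equal(sel$selected$name, "ISO")
  sel1 <- forward_selection(d, "ISO", n_starts = 1, seed = 3)
  expect_equal(sel1$selected$name, "ISO")
  expect_null(sel1$tests)
})

test_that("the boundary null study shows the naive chi-square test is conservative", {
  # small-scale version of the boundary simulation: data generated under the
  # ISO null, ISO vs IM1 tested with the chi-square(2) 5% cutoff
  phi0 <- phi_vector(theta_a = 2, theta = 3, theta_b = 2, V = 6)
  st <- boundary_null_study("ISO", "IM1", phi0, n_datasets = 6,
                            n_loci = 1500, seed = 100, n_starts = 1)
  expect_equal(st$n_failed, 0)
  expect_equal(st$df, 2L)
  expect_true(all(st$D >= 0))
  # with 6 replicates a conservative 5% test should essentially never reject
  expect_lte(st$rejection_rate, 1 / 6 + 1e-9)
  expect_equal(length(st$empirical_quantiles), length(st$chisq_quantiles))
})
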