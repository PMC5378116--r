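test_that("with independent loci the sandwich collapses to the Fisher covariance", {
  phi0 <- phi_vector(theta_a = 2, theta = 3, theta_b = 2, V = 6)
  d <- simulate_iim_data(3e4, phi = phi0, seed = 19)
  d$block <- d$locus_id              # every locus its own block
  f <- fit_iim(d, "ISO", n_starts = 2, seed = 1, hessian = TRUE)
  g <- godambe_info(f, d)
  expect_equal(g$n_blocks, nrow(d))
  # robust and Fisher standard errors agree within 15% on large clean data
  expect_true(all(abs(g$se_robust / g$se_fisher - 1) < 0.15))
  ev <- eigen(g$V, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))           # score covariance positive definite
  expect_equal(g$Ginv, t(g$Ginv))
})

test_that("duplicated loci inflate robust standard errors by about sqrt(2)", {
  phi0 <- phi_vector(theta_a = 2, theta = 3, theta_b = 2, V = 6)
  d <- simulate_iim_data(8000, phi = phi0, seed = 23)
  d2 <- rbind(d, transform(d, locus_id = paste0(locus_id, "_copy")))
  d2$block <- rep(d$locus_id, 2)     # each pair of identical loci is a block
  d2 <- as_loci_table(d2)
  f <- fit_iim(d2, "ISO", n_starts = 2, seed = 1, hessian = TRUE)
  g <- godambe_info(f, d2)
  ratio <- g$se_robust / g$se_fisher
  expect_true(all(abs(ratio - sqrt(2)) < 0.12))
})

test_that("robust LRT weights are near one for independent loci, and the p-value tracks the naive one", {
  # both migration rates interior so the alternative optimum is away from
  # the boundary (finite-difference information is well defined there)
  phi1 <- phi_vector(theta_a = 2, theta = 3, theta_b = 2.5, V = 5,
                     M1 = 0.6, M2 = 0.8)
  d <- simulate_iim_data(8000, phi = phi1, seed = 29)
  d$block <- d$locus_id
  f0 <- fit_iim(d, "ISO", n_starts = 2, seed = 1)
  init <- iimfit:::expand_phi(f0$free, f0$model)[iim_model("IM1")$free]
  f1 <- fit_iim(d, "IM1", n_starts = 2, seed = 1, init = init,
                hessian = TRUE)
  g <- godambe_info(f1, d)
  rt <- robust_lrt(f0, f1, g)
  expect_true(all(abs(rt$weights - 1) < 0.3))
  expect_gt(rt$p_robust, 0)
  # both p-values detect the strong gene-flow signal decisively
  expect_lt(rt$p_naive, 1e-6)
  expect_lt(rt$p_robust, 1e-4)
  # duplicating the data (pairs as blocks) weakens the evidence: the robust
  # p-value exceeds the naive one computed on the duplicated data
  d2 <- rbind(d, transform(d, locus_id = paste0(locus_id, "_copy")))
  d2$block <- rep(d$locus_id, 2)
  d2 <- as_loci_table(d2)
  f0d <- fit_iim(d2, "ISO", n_starts = 2, seed = 1)
  init <- iimfit:::expand_phi(f0d$free, f0d$model)[iim_model("IM1")$free]
  f1d <- fit_iim(d2, "IM1", n_starts = 2, seed = 1, init = init,
                 hessian = TRUE)
  gd <- godambe_info(f1d, d2)
  rtd <- robust_lrt(f0d, f1d, gd)
  expect_gt(rtd$p_robust, rtd$p_naive)
  expect_gt(mean(rtd$weights), 1.5)  # duplication doubles the weights
})

test_that("block bookkeeping is validated", {
  phi0 <- phi_vector(theta_a = 2, theta = 3, theta_b = 2, V = 6)
  d <- simulate_iim_data(500, phi = phi0, seed = 1)
  f <- fit_iim(d, "ISO", n_starts = 1, seed = 1, hessian = TRUE)
  expect_error(godambe_info(f, d), "block")
  d$block <- "all_one"
  expect_error(godambe_info(f, d), "2 blocks")
  d$block <- rep(c("a", "b"), length.out = nrow(d))
  expect_error(godambe_info(f, d), "rank|fewer")
})
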