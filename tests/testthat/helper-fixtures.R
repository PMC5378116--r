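# shared fixtures: parameter sets spanning the four migration regimes and
# a matrix-exponential oracle for migration-stage absorption probabilities

sim_params <- function() {
  # generating values of the simulation-study design
  coal_params(a = 0.75, b = 1.25, c1 = 1.5, c2 = 2,
              tau1 = 1, tau0 = 2, M1 = 0.5, M2 = 0.75)
}

sim_phi <- function() coal_to_phi(sim_params(), theta = 2)

# random parameter draw in a given migration regime
draw_params <- function(regime = c("bidirectional", "uni_M1_zero",
                                   "uni_M2_zero", "none")) {
  regime <- match.arg(regime)
  M1 <- if (regime %in% c("bidirectional", "uni_M2_zero")) runif(1, 0.05, 2.5) else 0
  M2 <- if (regime %in% c("bidirectional", "uni_M1_zero")) runif(1, 0.05, 2.5) else 0
  tau1 <- runif(1, 0, 1.5)
  coal_params(a = runif(1, 0.3, 2), b = runif(1, 0.4, 2.5),
              c1 = runif(1, 0.4, 2.5), c2 = runif(1, 0.4, 2.5),
              tau1 = tau1, tau0 = tau1 + runif(1, 0.1, 2),
              M1 = M1, M2 = M2)
}

# absorption CDF of the migration-stage chain from sampling state i, by
# matrix exponential of the generator (independent of the eigen route)
expm_mig_cdf <- function(params, state, t) {
  Q <- mig_generator(params)
  row <- c(1, 3, 2)[state]  # sampling state -> internal row
  vapply(t, function(u) as.matrix(Matrix::expm(Q * u))[row, 4], numeric(1))
}

# piecewise adaptive quadrature with explicit breakpoints (the integrands
# have kinks at the stage boundaries, which defeats a single 0-Inf call)
integrate_pw <- function(f, breaks, rel.tol = 1e-11) {
  breaks <- unique(sort(breaks))
  total <- 0
  for (k in seq_len(length(breaks) - 1)) {
    total <- total + stats::integrate(f, breaks[k], breaks[k + 1],
                                      rel.tol = rel.tol,
                                      subdivisions = 1000L,
                                      stop.on.error = FALSE)$value
  }
  total
}

density_breaks <- function(params, upper = NULL) {
  if (is.null(upper)) upper <- params$tau0 + 60 * params$a
  c(0, params$tau1, params$tau0, params$tau0 + 5 * params$a, upper)
}

# quadrature oracle for the segregating-sites PMF, integrating the Poisson
# kernel against the coalescence-time density piecewise (the integrand is a
# narrow spike for large s, so integrate each stage separately)
quad_pmf <- function(s, state, theta, params) {
  logf <- function(t) dpois(s, theta * t, log = TRUE) +
    log(pmax(coal_time_density(t, state, params), 1e-320))
  tau1 <- params$tau1; tau0 <- params$tau0
  mode_t <- max((s + 1) / theta, tau0 + 1)
  sdw <- sqrt(s + 1) / theta
  hi <- mode_t + 30 * sdw + 30 * params$a
  breaks <- c(0, tau1, tau0, max(mode_t - 10 * sdw, 0), mode_t,
              mode_t + 10 * sdw, hi)
  # rescale by the peak log-integrand so the quadrature works near unit scale
  grid <- seq(1e-9, hi, length.out = 2000)
  mx <- max(logf(grid))
  exp(mx) * integrate_pw(function(t) exp(logf(t) - mx), breaks)
}
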