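#' Wald confidence intervals from the observed information
#'
#' Intervals of the form estimate \eqn{\pm z_{(1+level)/2}} times the square
#' root of the diagonal of the inverted negative Hessian of the
#' log-likelihood at the optimum. Reliable when the estimate is interior to
#' the parameter space and the sample is large; a warning is issued when any
#' boundary-constrained parameter sits within tolerance of its bound.
#'
#' @param fit an [fit_iim()] result with a Hessian (refit with
#'   \code{hessian = TRUE} if absent).
#' @param level confidence level (default 0.95).
#' @param boundary_tol closeness to the zero bound that triggers a warning.
#' @return Data frame with columns \code{estimate}, \code{se}, \code{lower},
#'   \code{upper}, one row per free parameter.
#' @export
wald_ci <- function(fit, level = 0.95, boundary_tol = 1e-4) {
  if (is.null(fit$hessian))
    stop("fit carries no Hessian; rerun fit_iim() with hessian = TRUE")
  est <- fit$free
  bounded <- !(names(est) %in% PHI_LOGSCALE)
  if (any(bounded & est < boundary_tol))
    warning("estimate(s) ",
            paste(names(est)[bounded & est < boundary_tol], collapse = ", "),
            " lie on or near the boundary; Wald intervals are unreliable ",
            "there (consider profile_ci)")
  info <- -fit$hessian
  cov <- tryCatch(solve(info), error = function(e)
    stop("singular Hessian; use profile_ci() instead"))
  se <- sqrt(pmax(diag(cov), 0))
  z <- stats::qnorm((1 + level) / 2)
  data.frame(parameter = names(est), estimate = unname(est), se = se,
             lower = unname(est - z * se), upper = unname(est + z * se),
             row.names = NULL)
}

#' Profile-likelihood confidence interval for one parameter
#'
#' Finds the two points where the profile log-likelihood (all other free
#' parameters re-optimised) has dropped by half the \eqn{\chi^2_1} quantile
#' (1.9207 at 95\%) below the maximum, by monotone bisection on each side of
#' the estimate. More expensive than Wald intervals but accurate for skewed
#' likelihoods and near boundaries.
#'
#' @param data the loci table the model was fitted to.
#' @param fit the [fit_iim()] result.
#' @param param name of the free parameter to profile.
#' @param level confidence level.
#' @param max_expand bracketing steps before an endpoint is declared
#'   one-sided.
#' @param tol bisection tolerance on the parameter scale, relative to the
#'   estimate's magnitude.
#' @return Data frame with \code{lower}, \code{upper} and logical flags
#'   \code{lower_open}, \code{upper_open} set when the search hit its bounds
#'   (one-sided interval).
#' @export
profile_ci <- function(data, fit, param, level = 0.95, max_expand = 40,
                       tol = 1e-3) {
  data <- as_loci_table(data)
  model <- fit$model
  if (!param %in% model$free) stop("'", param, "' is not free in this model")
  drop_target <- stats::qchisq(level, df = 1) / 2
  target <- fit$logL - drop_target
  others <- setdiff(model$free, param)

  prof <- function(value) {
    if (length(others) == 0L) {
      fr <- stats::setNames(value, param)
      return(make_loglik_fn(data, model)(fr))
    }
    sub <- iim_model("custom",
                     free = others,
                     fixed = c(stats::setNames(value, param), model$fixed),
                     tied = model$tied)
    f <- fit_iim(data, sub, n_starts = 1, seed = fit$seed,
                 init = fit$free[others], control = list(subsample = Inf))
    f$logL
  }

  est <- fit$free[[param]]
  positive <- param %in% PHI_LOGSCALE
  lo_bound <- if (positive) 1e-10 else 0
  scale <- max(abs(est), 0.05)

  search_side <- function(dir) {  # dir = -1 lower, +1 upper
    step <- 0.25 * scale
    x_in <- est
    x_out <- NA
    open <- FALSE
    for (k in seq_len(max_expand)) {
      cand <- est + dir * step
      if (dir < 0 && cand <= lo_bound) {
        cand <- lo_bound
        if (prof(cand) >= target) { open <- TRUE; x_out <- cand; break }
        x_out <- cand; break
      }
      if (prof(cand) < target) { x_out <- cand; break }
      x_in <- cand
      step <- step * 1.8
      if (k == max_expand) { open <- TRUE; x_out <- cand }
    }
    if (open) return(list(x = x_out, open = TRUE))
    # bisection between x_in (inside) and x_out (outside)
    for (k in 1:60) {
      mid <- (x_in + x_out) / 2
      if (abs(x_out - x_in) < tol * scale) break
      if (prof(mid) >= target) x_in <- mid else x_out <- mid
    }
    list(x = (x_in + x_out) / 2, open = FALSE)
  }

  lo <- search_side(-1)
  hi <- search_side(+1)
  data.frame(parameter = param, estimate = est,
             lower = lo$x, upper = hi$x,
             lower_open = lo$open, upper_open = hi$open, row.names = NULL)
}

#' Calibrate the average mutation rate from outgroup divergence
#'
#' Reads a molecular-clock calibration: if the ingroup-outgroup split is
#' \code{divergence_time_years} ago and a generation lasts \code{g} years,
#' two sequences are separated by \eqn{2\,t/g} generations and the expected
#' pairwise difference count is \eqn{2 t \mu / g}, so \eqn{\hat\mu =
#' \bar{k} g / (2 t)} per locus per generation.
#'
#' @param mean_outgroup_divergence average pairwise differences between
#'   ingroup and outgroup sequences (over loci).
#' @param divergence_time_years calibration time in years.
#' @param g generation time in years.
#' @return \eqn{\hat\mu}, the mutation rate per locus per generation.
#' @examples
#' calibrate_mu(46.2, 1e7, 0.1)  # 2.31e-7
#' @export
calibrate_mu <- function(mean_outgroup_divergence, divergence_time_years, g) {
  if (mean_outgroup_divergence <= 0 || divergence_time_years <= 0 || g <= 0)
    stop("all calibration inputs must be positive")
  mean_outgroup_divergence * g / (2 * divergence_time_years)
}

#' Convert mutation-scaled estimates to demographic units
#'
#' Applies the standard conversions: effective sizes \eqn{\hat N_x =
#' \hat\theta_x / (4\hat\mu)} (diploid individuals), times \eqn{\hat t_0 =
#' (g/2\hat\mu)(\hat T_1 + \hat V)} and \eqn{\hat t_1 = (g/2\hat\mu)\hat
#' T_1} (years), the forward migrant fraction \eqn{\hat q_1 = \hat\mu \hat
#' M_2 \hat b / \hat\theta} and the migrant count per generation \eqn{\hat
#' s_1 = \hat M_2 \hat b / 2}, with \eqn{\hat b = \hat\theta_b/\hat\theta}.
#'
#' @param fit an [fit_iim()] result (or a full phi vector).
#' @param g generation time in years.
#' @param mu_hat mutation rate per locus per generation (see
#'   [calibrate_mu()]).
#' @return Named list of converted point estimates: \code{Na, N, Nb, Nc1,
#'   Nc2} (diploid individuals), \code{t0, t1} (years), \code{q1} (fraction
#'   per generation), \code{s1} (sequences per generation).
#' @export
convert_estimates <- function(fit, g, mu_hat) {
  if (g <= 0 || mu_hat <= 0) stop("g and mu_hat must be positive")
  phi <- if (inherits(fit, "iim_fit")) fit$phi_hat else fit
  validate_phi(phi)
  b_hat <- phi[["theta_b"]] / phi[["theta"]]
  list(Na  = phi[["theta_a"]]  / (4 * mu_hat),
       N   = phi[["theta"]]    / (4 * mu_hat),
       Nb  = phi[["theta_b"]]  / (4 * mu_hat),
       Nc1 = phi[["theta_c1"]] / (4 * mu_hat),
       Nc2 = phi[["theta_c2"]] / (4 * mu_hat),
       t0  = (g / (2 * mu_hat)) * (phi[["T1"]] + phi[["V"]]),
       t1  = (g / (2 * mu_hat)) * phi[["T1"]],
       q1  = mu_hat * phi[["M2"]] * b_hat / phi[["theta"]],
       s1  = phi[["M2"]] * b_hat / 2)
}

# conversion parameterisation: the model's free parameters with V replaced
# by T0 = T1 + V and M2 by MB = M2 * theta_b / theta^2 (= M2 b / theta, the
# forward migrant fraction divided by mu). Each converted quantity is then a
# constant times one coordinate, so the covariance transforms diagonally.
phi_to_conv <- function(phi, model) {
  cv <- phi[model$free]
  names(cv) <- model$free
  if ("V" %in% model$free) {
    cv[["V"]] <- phi[["T1"]] + phi[["V"]]
    names(cv)[names(cv) == "V"] <- "T0"
  }
  if ("M2" %in% model$free) {
    cv[["M2"]] <- phi[["M2"]] * phi[["theta_b"]] / phi[["theta"]]^2
    names(cv)[names(cv) == "M2"] <- "MB"
  }
  cv
}

conv_to_free <- function(cv, model) {
  free <- cv
  names(free) <- model$free
  if ("V" %in% model$free) {
    T1 <- if ("T1" %in% model$free) free[["T1"]] else
      if ("T1" %in% names(model$fixed)) model$fixed[["T1"]] else 0
    free[["V"]] <- cv[[which(model$free == "V")]] - T1
  }
  if ("M2" %in% model$free) {
    free[["M2"]] <- cv[[which(model$free == "M2")]] *
      free[["theta"]]^2 / free[["theta_b"]]
  }
  free
}

#' Delta-method intervals for converted estimates
#'
#' Re-expresses the fitted model in a conversion parameterisation — the
#' model's free parameters with \eqn{V} replaced by \eqn{T_0 = T_1 + V}
#' and \eqn{M_2} by \eqn{M_2 b/\theta} (divided by \eqn{\mu} this is the
#' forward migrant fraction) — recomputes the observed-information Hessian
#' directly in that parameterisation (no hand chain rule), and returns
#' Gaussian intervals on the converted scale using the diagonal linear map
#' to demographic units (covariance \eqn{W \Sigma W^T}).
#'
#' @inheritParams convert_estimates
#' @param data the loci table the model was fitted to.
#' @param level confidence level.
#' @return Data frame of converted estimates with Wald bounds, one row per
#'   free parameter's converted quantity (subset of \code{Na, N, Nb, Nc1,
#'   Nc2, t1, t0, q1}).
#' @export
delta_method_ci <- function(fit, data, g, mu_hat, level = 0.95) {
  if (!inherits(fit, "iim_fit")) stop("fit must be an iim_fit")
  if (fit$phi_hat[["M1"]] != 0)
    stop("the conversion parameterisation assumes unidirectional gene flow (M1 = 0)")
  data <- as_loci_table(data)
  model <- fit$model
  cv_hat <- phi_to_conv(fit$phi_hat, model)
  loglik_cv <- function(cv) {
    free <- tryCatch(conv_to_free(cv, model), error = function(e) NULL)
    if (is.null(free) || any(!is.finite(free))) return(-Inf)
    phi <- tryCatch({
      ph <- expand_phi(free, model); validate_phi(ph); ph
    }, error = function(e) NULL)
    if (is.null(phi)) return(-Inf)
    tryCatch(iim_loglik(data, phi), error = function(e) -Inf)
  }
  nonneg <- !(model$free %in% PHI_LOGSCALE)
  H <- fd_hessian(loglik_cv, cv_hat, nonneg = nonneg)
  Sigma <- tryCatch(solve(-H), error = function(e)
    stop("singular Hessian in the conversion parameterisation"))
  w_all <- c(theta_a = 1 / (4 * mu_hat), theta = 1 / (4 * mu_hat),
             theta_b = 1 / (4 * mu_hat), theta_c1 = 1 / (4 * mu_hat),
             theta_c2 = 1 / (4 * mu_hat), T1 = g / (2 * mu_hat),
             T0 = g / (2 * mu_hat), MB = mu_hat)
  name_map <- c(theta_a = "Na", theta = "N", theta_b = "Nb",
                theta_c1 = "Nc1", theta_c2 = "Nc2", T1 = "t1",
                T0 = "t0", MB = "q1")
  w <- w_all[names(cv_hat)]
  est_c <- w * cv_hat
  se_c <- w * sqrt(pmax(diag(Sigma), 0))
  z <- stats::qnorm((1 + level) / 2)
  data.frame(quantity = unname(name_map[names(cv_hat)]),
             estimate = unname(est_c),
             lower = unname(est_c - z * se_c),
             upper = unname(est_c + z * se_c), row.names = NULL)
}
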