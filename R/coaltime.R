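#' Distribution of the pairwise coalescence time under the IIM model
#'
#' Density, survival function and mean of the coalescence time \eqn{T^{(i)}}
#' of two lineages sampled in state \eqn{i} (1: both in deme 1; 2: both in
#' deme 2; 3: one in each deme). The law is assembled piecewise from the
#' three stages of the model:
#' \itemize{
#'   \item isolation, \eqn{[0, \tau_1]}: exponential with rate \eqn{1/c_i}
#'     for states 1 and 2; no coalescence from state 3;
#'   \item migration, \eqn{(\tau_1, \tau_0]}: the surviving mass times the
#'     signed exponential mixture of [migration_spectrum()], re-based at
#'     \eqn{\tau_1};
#'   \item ancestral, \eqn{(\tau_0, \infty)}: the surviving mass times an
#'     exponential with rate \eqn{1/a}, re-based at \eqn{\tau_0}.
#' }
#' Empty stages (\eqn{\tau_1 = 0} or \eqn{\tau_1 = \tau_0}) are exact limits:
#' the corresponding piece simply carries no probability mass.
#'
#' @param t time(s), in units of \eqn{2N} generations; nonnegative.
#' @param state sampling state, 1, 2 or 3.
#' @param params a [coal_params()] object.
#' @param spectrum optionally, a precomputed [migration_spectrum()] for
#'   \code{params} (cached by likelihood code; recomputed when \code{NULL}).
#' @return `coal_time_density` and `coal_time_survival` return numeric
#'   vectors the length of `t`; `coal_time_mean` a scalar (infinite when
#'   absorption is not certain, e.g. state 3 with no gene flow and no
#'   ancestral stage would never arise since \code{tau0} is finite).
#' @examples
#' p <- coal_params(a = 0.75, b = 1.25, c1 = 1.5, c2 = 2,
#'                  tau1 = 1, tau0 = 2, M1 = 0.5, M2 = 0.75)
#' coal_time_density(c(0.5, 1.5, 3), state = 3, params = p)
#' coal_time_mean(3, p)
#' @export
coal_time_density <- function(t, state, params, spectrum = NULL) {
  check_state(state)
  validate_coal_params(params)
  if (any(t < 0)) stop("t must be nonnegative")
  if (is.null(spectrum)) spectrum <- migration_spectrum(params)
  tau1 <- params$tau1; tau0 <- params$tau0
  siso_tau1 <- iso_survival(tau1, state, params)
  smig_delta <- 1 - spectrum_cdf(spectrum, state, tau0 - tau1)

  out <- numeric(length(t))
  iso <- t <= tau1
  mig <- t > tau1 & t <= tau0
  anc <- t > tau0
  if (any(iso)) {
    out[iso] <- if (state == 3) 0 else {
      ci <- if (state == 1) params$c1 else params$c2
      (1 / ci) * exp(-t[iso] / ci)
    }
  }
  if (any(mig))
    out[mig] <- siso_tau1 * spectrum_pdf(spectrum, state, t[mig] - tau1)
  if (any(anc))
    out[anc] <- siso_tau1 * smig_delta * (1 / params$a) *
      exp(-(t[anc] - tau0) / params$a)
  out
}

#' @rdname coal_time_density
#' @export
coal_time_survival <- function(t, state, params, spectrum = NULL) {
  check_state(state)
  validate_coal_params(params)
  if (any(t < 0)) stop("t must be nonnegative")
  if (is.null(spectrum)) spectrum <- migration_spectrum(params)
  tau1 <- params$tau1; tau0 <- params$tau0
  siso_tau1 <- iso_survival(tau1, state, params)
  smig_delta <- 1 - spectrum_cdf(spectrum, state, tau0 - tau1)

  out <- numeric(length(t))
  iso <- t <= tau1
  mig <- t > tau1 & t <= tau0
  anc <- t > tau0
  if (any(iso)) out[iso] <- iso_survival(t[iso], state, params)
  if (any(mig))
    out[mig] <- siso_tau1 *
      (1 - spectrum_cdf(spectrum, state, t[mig] - tau1))
  if (any(anc))
    out[anc] <- siso_tau1 * smig_delta * exp(-(t[anc] - tau0) / params$a)
  pmin(pmax(out, 0), 1)
}

#' @rdname coal_time_density
#' @export
coal_time_mean <- function(state, params, spectrum = NULL) {
  check_state(state)
  validate_coal_params(params)
  if (is.null(spectrum)) spectrum <- migration_spectrum(params)
  tau1 <- params$tau1; tau0 <- params$tau0
  delta <- tau0 - tau1
  siso_tau1 <- iso_survival(tau1, state, params)
  Ai <- spectrum$A[state, ]; lam <- spectrum$lam
  smig_delta <- 1 - sum(Ai * (1 - exp(-lam * delta)))

  m_iso <- if (state == 3) tau1 else {
    ci <- if (state == 1) params$c1 else params$c2
    ci * (1 - exp(-tau1 / ci))
  }
  # integral of the migration-stage survival over (0, delta]
  m_mig <- siso_tau1 *
    ((1 - sum(Ai)) * delta + sum(Ai * (1 - exp(-lam * delta)) / lam))
  m_anc <- siso_tau1 * smig_delta * params$a
  m_iso + m_mig + m_anc
}

iso_survival <- function(t, state, params) {
  if (state == 3) rep(1, length(t))
  else exp(-t / if (state == 1) params$c1 else params$c2)
}

check_state <- function(state) {
  if (!(length(state) == 1L && state %in% c(1, 2, 3)))
    stop("state must be 1, 2 or 3")
  invisible(state)
}
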