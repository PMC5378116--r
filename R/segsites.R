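#' Distribution of the number of segregating sites for a pair of sequences
#'
#' Under the infinite-sites model, the number of segregating sites \eqn{S}
#' between two sequences is Poisson with mean \eqn{\theta T} given their
#' coalescence time \eqn{T}. Integrating \eqn{T} out against the piecewise
#' exponential-mixture law of the IIM coalescent gives a closed-form PMF:
#' an isolation piece (geometric-like, states 1 and 2 only), a migration
#' piece (one signed term per exponential component), and an ancestral piece.
#'
#' All truncated Poisson sums \eqn{e^{-x}\sum_{l\le s} x^l/l!} are evaluated
#' as regularised incomplete-gamma (Poisson CDF) calls and every factor of
#' the form \eqn{x^s/(1+x)^{s+1}} is kept in log-space, so the PMF is stable
#' for counts of several thousand where the naive printed form overflows.
#'
#' @param s nonnegative integer count(s) of segregating sites.
#' @param state sampling state, 1, 2 or 3.
#' @param theta scaled mutation rate of the locus (\eqn{\theta_j = r_j
#'   \theta}); strictly positive.
#' @param params a [coal_params()] object.
#' @param spectrum optional precomputed [migration_spectrum()].
#' @return Numeric vector the length of \code{s}: probabilities for
#'   `seg_sites_pmf`, log-probabilities for `seg_sites_logpmf`, and for
#'   `seg_sites_mean` the scalar \eqn{\theta E[T^{(i)}]}.
#' @examples
#' p <- coal_params(a = 0.75, b = 1.25, c1 = 1.5, c2 = 2,
#'                  tau1 = 1, tau0 = 2, M1 = 0.5, M2 = 0.75)
#' seg_sites_pmf(0:5, state = 3, theta = 2, params = p)
#' @export
seg_sites_pmf <- function(s, state, theta, params, spectrum = NULL) {
  exp(seg_sites_logpmf(s, state, theta, params, spectrum))
}

#' @rdname seg_sites_pmf
#' @export
seg_sites_logpmf <- function(s, state, theta, params, spectrum = NULL) {
  check_state(state)
  validate_coal_params(params)
  if (any(s < 0) || any(s != floor(s))) stop("s must be nonnegative integer(s)")
  if (!is.numeric(theta) || any(theta <= 0)) stop("theta must be > 0")
  if (is.null(spectrum)) spectrum <- migration_spectrum(params)
  segsites_logpmf_kernel(s, rep_len(theta, length(s)), state, params, spectrum)
}

#' @rdname seg_sites_pmf
#' @export
seg_sites_mean <- function(state, theta, params, spectrum = NULL) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0)
    stop("theta must be a nonnegative scalar")
  theta * coal_time_mean(state, params, spectrum)
}

# log(exp(la) - exp(lb)) for la >= lb, elementwise; -Inf when equal
log_diff_exp <- function(la, lb) {
  d <- lb - la
  out <- la + log1p(-exp(d))
  out[d >= 0] <- -Inf
  out[la == -Inf] <- -Inf
  out
}

# Vectorised log-PMF kernel: s and theta are equal-length vectors, state is
# scalar. This is the per-locus workhorse behind the multilocus likelihood;
# the inner loop runs in C++ (src/segsites_kernel.cpp).
segsites_logpmf_kernel <- function(s, theta, state, params, spectrum) {
  tau1 <- params$tau1; tau0 <- params$tau0; a <- params$a
  Ai <- spectrum$A[state, ]; lam <- spectrum$lam
  ci <- if (state == 1) params$c1 else if (state == 2) params$c2 else Inf
  log_siso <- if (state == 3) 0 else -tau1 / ci
  smig_delta <- 1 - sum(Ai * (1 - exp(-lam * (tau0 - tau1))))
  .segsites_logpmf_cpp(as.integer(s), as.numeric(theta),
                       as.numeric(Ai), as.numeric(lam),
                       ci, a, tau1, tau0, smig_delta, log_siso)
}

# Pure-R reference implementation of the same kernel, retained as an
# independent check on the compiled path (see the test suite).
segsites_logpmf_kernel_r <- function(s, theta, state, params, spectrum) {
  tau1 <- params$tau1; tau0 <- params$tau0; a <- params$a
  delta <- tau0 - tau1
  Ai <- spectrum$A[state, ]; lam <- spectrum$lam
  ci <- if (state == 1) params$c1 else if (state == 2) params$c2 else Inf
  log_siso <- if (state == 3) 0 else -tau1 / ci
  smig_delta <- 1 - sum(Ai * (1 - exp(-lam * delta)))

  n <- length(s)
  # collect signed log-magnitude terms: up to 1 (iso) + 3 (mig) + 1 (anc)
  logs <- matrix(-Inf, n, 5L)
  sgns <- matrix(1, n, 5L)

  # isolation piece: geom(s; ci*theta) * P[Pois((1/ci+theta)tau1) > s]
  if (state != 3 && tau1 > 0) {
    x <- ci * theta
    logs[, 1L] <- s * log(x / (1 + x)) - log1p(x) +
      stats::ppois(s, (1 / ci + theta) * tau1, lower.tail = FALSE, log.p = TRUE)
  }
  # migration piece, one signed term per exponential component
  if (delta > 0) {
    for (j in 1:3) {
      if (Ai[j] == 0) next
      beta <- lam[j] + theta
      lo1 <- if (tau1 > 0) stats::ppois(s, beta * tau1, log.p = TRUE) else 0
      lo0 <- stats::ppois(s, beta * tau0, log.p = TRUE)
      ld <- log_diff_exp(lo1, lo0)
      logs[, 1L + j] <- log(abs(Ai[j])) + log_siso + log(lam[j]) - log(beta) +
        s * log(theta / beta) + lam[j] * tau1 + ld
      sgns[, 1L + j] <- sign(Ai[j])
    }
  }
  # ancestral piece
  if (smig_delta > 0) {
    x <- a * theta
    logs[, 5L] <- log_siso + log(smig_delta) + tau0 / a +
      s * log(x / (1 + x)) - log1p(x) +
      stats::ppois(s, (1 / a + theta) * tau0, log.p = TRUE)
  }

  # signed log-sum-exp with a clamp for tiny negative rounding residuals
  m <- logs[, 1L]
  for (k in 2:5) m <- pmax(m, logs[, k])
  r <- rowSums(sgns * exp(logs - m))
  gross <- rowSums(exp(logs - m))
  neg <- r < 0
  if (any(neg)) {
    bad <- r < -1e-12 * pmax(gross, 1)
    if (any(bad & is.finite(m)))
      stop("catastrophic cancellation in segregating-sites PMF (most negative ",
           "relative residual ", format(min(r[bad] / pmax(gross[bad], 1))), ")")
    r[neg] <- 0
  }
  out <- m + log(r)
  out[m == -Inf] <- -Inf
  # guard against precision loss at extreme rate combinations (huge decay
  # rates cancelling in log space): probabilities cannot exceed 1
  pos <- out > 0
  if (any(pos)) {
    if (any(out[pos] > 1e-6))
      stop("precision loss in segregating-sites PMF (log-probability ",
           format(max(out[pos])), " > 0); parameters are too extreme")
    out[pos] <- 0
  }
  out
}
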