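#' Mixture-of-exponentials spectrum of the migration-stage absorption time
#'
#' The density of the time to coalescence of two lineages during the
#' migration stage, started from sampling state \eqn{i}, is a signed mixture
#' of exponentials
#' \deqn{f^{(i)}_{mig}(t) = \sum_{j=1}^{3} A_{ij} \lambda_j e^{-\lambda_j t},}
#' and its distribution function is \eqn{F^{(i)}_{mig}(t) = \sum_j A_{ij}
#' (1 - e^{-\lambda_j t})}. This function returns the decay rates
#' \eqn{\lambda_j} and the coefficient matrix \eqn{A} (rows indexed by
#' sampling state 1, 2, 3).
#'
#' Four regimes are distinguished by the signs of the migration rates:
#' \describe{
#'   \item{bidirectional (\eqn{M_1>0, M_2>0})}{\eqn{\lambda_j} are the
#'     absolute values of the three strictly negative eigenvalues of the
#'     migration-stage generator, and \eqn{A_{ij} = -V^{-1}_{ij} V_{j4}}
#'     where the rows of \eqn{V} are the left eigenvectors.}
#'   \item{unidirectional (\eqn{M_1=0, M_2>0} or \eqn{M_1>0, M_2=0})}{fully
#'     explicit coefficients obtained from the moment-generating-function
#'     system by partial fractions.}
#'   \item{no gene flow}{states 1 and 2 are simple exponentials with rates 1
#'     and \eqn{1/b}; state 3 cannot coalesce during this stage (its row of
#'     \eqn{A} is zero).}
#' }
#' For each state from which absorption is certain the rows of \eqn{A} sum to
#' 1; a zero row indicates that coalescence during the migration stage is
#' impossible from that state.
#'
#' Eigenvalues are sorted decreasingly; near-degenerate spectra (which form a
#' measure-zero set in parameter space) are resolved by a tiny multiplicative
#' perturbation of \eqn{M_1, M_2, b}, with a warning.
#'
#' @param params a [coal_params()] object.
#' @return A list of class \code{"iim_spectrum"}: \code{regime} (one of
#'   \code{"bidirectional"}, \code{"uni_M1_zero"}, \code{"uni_M2_zero"},
#'   \code{"none"}), \code{lam} (length-3 positive decay rates), \code{A}
#'   (3x3 coefficient matrix, rows = sampling states 1, 2, 3).
#' @examples
#' migration_spectrum(coal_params(b = 1.25, tau1 = 0.5, tau0 = 2,
#'                                M1 = 0.5, M2 = 0.75))
#' @export
migration_spectrum <- function(params) {
  validate_coal_params(params)
  M1 <- params$M1; M2 <- params$M2; b <- params$b
  if (M1 > 0 && M2 > 0) {
    spectrum_bidirectional(params)
  } else if (M1 == 0 && M2 > 0) {
    spectrum_uni_M1_zero(M2, b)
  } else if (M1 > 0 && M2 == 0) {
    spectrum_uni_M2_zero(M1, b)
  } else {
    spectrum_none(b)
  }
}

# closed forms for M1 = 0, M2 > 0 (partial fractions of the MGF system)
spectrum_uni_M1_zero <- function(M2, b) {
  if (degenerate_lambdas(c(1, M2 / 2, 1 / b + M2))) {
    warning("near-degenerate spectrum; perturbing M2 and b")
    M2 <- M2 * (1 + 1e-9); b <- b * (1 + 1e-9)
  }
  lam <- c(1, M2 / 2, 1 / b + M2)
  A <- matrix(0, 3, 3)
  A[1, ] <- c(1, 0, 0)
  A[2, 1] <- b * M2^2 / ((M2 - 2) * (1 - b + b * M2))
  A[2, 2] <- 4 * b * M2 / ((2 - M2) * (2 + b * M2))
  A[2, 3] <- (1 / b) / (1 / b + M2) +
    b^2 * M2^2 / ((2 + b * M2) * (1 - b + b * M2) * (1 / b + M2))
  A[3, ] <- c(M2 / (M2 - 2), 2 / (2 - M2), 0)
  new_spectrum("uni_M1_zero", lam, A)
}

# mirror case M1 > 0, M2 = 0, derived by the same MGF / partial-fraction route
spectrum_uni_M2_zero <- function(M1, b) {
  if (degenerate_lambdas(c(1 + M1, M1 / 2, 1 / b))) {
    warning("near-degenerate spectrum; perturbing M1 and b")
    M1 <- M1 * (1 + 1e-9); b <- b * (1 + 1e-9)
  }
  lam <- c(1 + M1, M1 / 2, 1 / b)
  A <- matrix(0, 3, 3)
  A[1, 1] <- 1 / (1 + M1) +
    M1^2 / ((1 + M1) * (2 + M1) * (b + b * M1 - 1))
  A[1, 2] <- 4 * M1 / ((2 + M1) * (2 - b * M1))
  A[1, 3] <- b^2 * M1^2 / ((b + b * M1 - 1) * (b * M1 - 2))
  A[2, ] <- c(0, 0, 1)
  A[3, ] <- c(0, 2 / (2 - b * M1), b * M1 / (b * M1 - 2))
  new_spectrum("uni_M2_zero", lam, A)
}

spectrum_none <- function(b) {
  # state 3 cannot coalesce before tau0: zero coefficient row; the third
  # decay rate is arbitrary (its coefficient is 0 in every row)
  lam <- c(1, 1 / b, 1 / b + 1)
  A <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 0))
  new_spectrum("none", lam, A)
}

spectrum_bidirectional <- function(params, depth = 0L) {
  Q <- mig_generator(params)
  ed <- eigen(t(Q))            # columns are left eigenvectors of Q
  vals <- ed$values
  if (max(abs(Im(vals))) > 1e-9 * max(abs(vals), 1))
    stop("migration-stage generator has eigenvalues with non-negligible ",
         "imaginary part; cannot form the exponential mixture")
  vals <- Re(vals)
  neg <- order(vals)[1:3]      # the three strictly negative eigenvalues
  lam <- -vals[neg]
  if (degenerate_lambdas(lam)) {
    if (depth >= 3L) stop("degenerate migration-stage spectrum persists after perturbation")
    warning("near-degenerate spectrum; perturbing M1, M2 and b")
    p2 <- params
    p2$M1 <- p2$M1 * (1 + 1e-9); p2$M2 <- p2$M2 * (1 - 1e-9)
    p2$b <- p2$b * (1 + 1e-9)
    return(spectrum_bidirectional(p2, depth + 1L))
  }
  V <- t(ed$vectors)           # rows are left eigenvectors
  if (max(abs(Im(V))) > 1e-9 * max(abs(Re(V))))
    stop("complex eigenvectors beyond tolerance in migration-stage spectrum")
  V <- Re(V)
  Vinv <- solve(V)
  # sort the negative-eigenvalue components so lam[1] >= lam[2] >= lam[3]
  ordj <- neg[order(lam, decreasing = TRUE)]
  lam <- sort(lam, decreasing = TRUE)
  # A[i, j] = -Vinv[i, j] * V[j, 4] over internal states i in (1, 3, 2)
  Aint <- -Vinv[1:3, ordj, drop = FALSE] *
    matrix(V[ordj, 4], 3, 3, byrow = TRUE)
  A <- Aint[c(1, 3, 2), , drop = FALSE]  # re-index rows to sampling states 1,2,3
  new_spectrum("bidirectional", lam, A)
}

degenerate_lambdas <- function(lam) {
  d <- abs(outer(lam, lam, "-"))
  min(d[upper.tri(d)]) < 1e-8 * max(lam)
}

new_spectrum <- function(regime, lam, A) {
  dimnames(A) <- list(state = c("1", "2", "3"), component = 1:3)
  structure(list(regime = regime, lam = as.numeric(lam), A = A),
            class = "iim_spectrum")
}

#' @export
print.iim_spectrum <- function(x, ...) {
  cat(sprintf("Migration-stage absorption spectrum (%s regime)\n", x$regime))
  cat("  decay rates:", paste(sprintf("%.6g", x$lam), collapse = ", "), "\n")
  cat("  coefficients A (rows = sampling states 1, 2, 3):\n")
  print(round(x$A, 6))
  invisible(x)
}

# migration-stage CDF and density from a spectrum, vectorised in t
spectrum_cdf <- function(spec, state, t) {
  Ai <- spec$A[state, ]
  out <- numeric(length(t))
  for (j in 1:3) out <- out + Ai[j] * (1 - exp(-spec$lam[j] * t))
  out
}

spectrum_pdf <- function(spec, state, t) {
  Ai <- spec$A[state, ]
  out <- numeric(length(t))
  for (j in 1:3) out <- out + Ai[j] * spec$lam[j] * exp(-spec$lam[j] * t)
  out
}
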