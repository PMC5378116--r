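#' Coalescent-scale parameters of the IIM model
#'
#' Bundles the eight parameters of the two-deme isolation-with-initial-migration
#' (IIM) coalescent, with time measured in units of \eqn{2N} generations where
#' \eqn{N} is the size of subpopulation 1 during the migration stage.
#'
#' Looking backward in time, the two sampled lineages first experience an
#' isolation stage (from the present back to \code{tau1}), then a migration
#' stage (\code{tau1} to \code{tau0}) during which lineages move between demes,
#' and finally the ancestral panmictic population (beyond \code{tau0}).
#'
#' @param a relative size of the ancestral population (\eqn{2N_{anc}/2N}).
#' @param b relative size of subpopulation 2 during the migration stage.
#' @param c1,c2 relative sizes of subpopulations 1 and 2 during the isolation
#'   stage.
#' @param tau1 time (units of \eqn{2N} generations) at which gene flow ceased.
#' @param tau0 time of the ancestral split; must satisfy
#'   \code{0 <= tau1 <= tau0}.
#' @param M1,M2 scaled backward migration rates \eqn{M_i = 4N m_i}; a single
#'   lineage currently in deme \eqn{i} migrates at rate \eqn{M_i/2}.
#'
#' @return An object of class \code{"coal_params"} (a validated list).
#' @examples
#' coal_params(a = 0.75, b = 1.25, c1 = 1.5, c2 = 2,
#'             tau1 = 1, tau0 = 2, M1 = 0.5, M2 = 0.75)
#' @export
coal_params <- function(a = 1, b = 1, c1 = 1, c2 = 1,
                        tau1 = 0, tau0 = 0, M1 = 0, M2 = 0) {
  p <- list(a = a, b = b, c1 = c1, c2 = c2,
            tau1 = tau1, tau0 = tau0, M1 = M1, M2 = M2)
  validate_coal_params(p)
  structure(p, class = "coal_params")
}

validate_coal_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in c("a", "b", "c1", "c2", "tau1", "tau0", "M1", "M2"))
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite numeric scalar")
  if (p$a <= 0 || p$b <= 0 || p$c1 <= 0 || p$c2 <= 0)
    stop("population sizes a, b, c1, c2 must be strictly positive")
  if (p$tau1 < 0 || p$tau0 < p$tau1)
    stop("times must satisfy 0 <= tau1 <= tau0")
  if (p$M1 < 0 || p$M2 < 0)
    stop("migration rates M1, M2 must be nonnegative")
  invisible(p)
}

#' @export
print.coal_params <- function(x, ...) {
  cat("IIM coalescent parameters (time unit: 2N generations)\n")
  cat(sprintf("  sizes     a = %.4g  b = %.4g  c1 = %.4g  c2 = %.4g\n",
              x$a, x$b, x$c1, x$c2))
  cat(sprintf("  times     tau1 = %.4g  tau0 = %.4g\n", x$tau1, x$tau0))
  cat(sprintf("  migration M1 = %.4g  M2 = %.4g\n", x$M1, x$M2))
  invisible(x)
}

# names of the 9 entries of the mutation-scaled parameter vector phi
PHI_NAMES <- c("theta_a", "theta", "theta_b", "theta_c1", "theta_c2",
               "T1", "V", "M1", "M2")

#' Mutation-scaled parameter vector
#'
#' The likelihood is maximised in an identifiable, mutation-scaled
#' parameterisation: \code{theta_a} \eqn{= \theta a}, \code{theta_b}
#' \eqn{= \theta b}, \code{theta_c1} \eqn{= \theta c_1}, \code{theta_c2}
#' \eqn{= \theta c_2}, \code{T1} \eqn{= \theta\tau_1},
#' \code{V} \eqn{= \theta(\tau_0-\tau_1)}, plus \code{theta}, \code{M1},
#' \code{M2}.
#'
#' @param theta_a,theta,theta_b,theta_c1,theta_c2 mutation-scaled sizes (> 0).
#' @param T1,V mutation-scaled epoch lengths (>= 0).
#' @param M1,M2 scaled migration rates (>= 0).
#' @return Named numeric vector of class \code{"phi_vector"} with the nine
#'   entries in canonical order.
#' @seealso [phi_to_coal()], [coal_to_phi()]
#' @export
phi_vector <- function(theta_a, theta, theta_b,
                       theta_c1 = theta, theta_c2 = theta_b,
                       T1 = 0, V = 0, M1 = 0, M2 = 0) {
  phi <- c(theta_a = theta_a, theta = theta, theta_b = theta_b,
           theta_c1 = theta_c1, theta_c2 = theta_c2,
           T1 = T1, V = V, M1 = M1, M2 = M2)
  validate_phi(phi)
  structure(phi, class = c("phi_vector", "numeric"))
}

validate_phi <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 9L)
    stop("phi must be a numeric vector of length 9")
  if (is.null(names(phi)) || !all(names(phi) == PHI_NAMES))
    stop("phi must be named ", paste(PHI_NAMES, collapse = ", "))
  if (any(!is.finite(phi))) stop("phi entries must be finite")
  if (any(phi[1:5] <= 0)) stop("mutation-scaled sizes must be > 0")
  if (any(phi[6:9] < 0)) stop("T1, V, M1, M2 must be >= 0")
  invisible(phi)
}

#' Convert a phi vector to coalescent-scale parameters
#'
#' @param phi a [phi_vector()] (or named numeric vector in the same order).
#' @return For `phi_to_coal`, a [coal_params()] object; the average scaled
#'   mutation rate `theta` is carried in attribute `"theta"`.
#' @export
phi_to_coal <- function(phi) {
  th <- phi[["theta"]]
  p <- coal_params(a  = phi[["theta_a"]] / th,
                   b  = phi[["theta_b"]] / th,
                   c1 = phi[["theta_c1"]] / th,
                   c2 = phi[["theta_c2"]] / th,
                   tau1 = phi[["T1"]] / th,
                   tau0 = (phi[["T1"]] + phi[["V"]]) / th,
                   M1 = phi[["M1"]], M2 = phi[["M2"]])
  attr(p, "theta") <- th
  p
}

#' @rdname phi_to_coal
#' @param params a [coal_params()] object.
#' @param theta average scaled mutation rate over loci.
#' @return For `coal_to_phi`, a [phi_vector()].
#' @export
coal_to_phi <- function(params, theta) {
  phi_vector(theta_a = theta * params$a, theta = theta,
             theta_b = theta * params$b,
             theta_c1 = theta * params$c1, theta_c2 = theta * params$c2,
             T1 = theta * params$tau1,
             V = theta * (params$tau0 - params$tau1),
             M1 = params$M1, M2 = params$M2)
}

#' Nested model family
#'
#' Defines which entries of the phi vector are free and which are fixed (and,
#' for the simpler models, tied). The family mirrors the forward-selection
#' ladder used for two-deme divergence scenarios:
#' \describe{
#'   \item{ISO}{divergence in complete isolation: free \code{theta_a, theta,
#'     theta_b, V}; \code{T1 = M1 = M2 = 0}; isolation-stage sizes tied to the
#'     migration-stage sizes (\code{theta_c1 = theta}, \code{theta_c2 =
#'     theta_b}).}
#'   \item{IM1}{divergence with gene flow until the present: ISO plus free
#'     \code{M1, M2}.}
#'   \item{IIM1}{gene flow until time \code{T1} ago: IM1 plus free \code{T1}.}
#'   \item{IIM2}{IIM1 plus free isolation-stage sizes \code{theta_c1,
#'     theta_c2} (the full model).}
#'   \item{IIM3}{IIM2 with \code{M1} fixed at 0 (unidirectional gene flow).}
#' }
#'
#' @param name one of \code{"ISO"}, \code{"IM1"}, \code{"IIM1"},
#'   \code{"IIM2"}, \code{"IIM3"}, or \code{"custom"}.
#' @param free for \code{name = "custom"}: character vector of free phi
#'   entries.
#' @param fixed for \code{name = "custom"}: named numeric vector of fixed phi
#'   values (unnamed entries default to 0 for \code{T1, V, M1, M2}).
#' @param tied for \code{name = "custom"}: named character vector mapping a
#'   phi entry to the entry whose value it copies.
#' @return An object of class \code{"iim_model"} with elements \code{name},
#'   \code{free}, \code{fixed}, \code{tied}, \code{df} (number of free
#'   parameters).
#' @examples
#' iim_model("IIM3")
#' @export
iim_model <- function(name = c("IIM2", "ISO", "IM1", "IIM1", "IIM3", "custom"),
                      free = NULL, fixed = NULL, tied = NULL) {
  name <- match.arg(name)
  tie_cs <- c(theta_c1 = "theta", theta_c2 = "theta_b")
  spec <- switch(name,
    ISO  = list(free = c("theta_a", "theta", "theta_b", "V"),
                fixed = c(T1 = 0, M1 = 0, M2 = 0), tied = tie_cs),
    IM1  = list(free = c("theta_a", "theta", "theta_b", "V", "M1", "M2"),
                fixed = c(T1 = 0), tied = tie_cs),
    IIM1 = list(free = c("theta_a", "theta", "theta_b", "V", "T1", "M1", "M2"),
                fixed = NULL, tied = tie_cs),
    IIM2 = list(free = setdiff(PHI_NAMES, character()),
                fixed = NULL, tied = NULL),
    IIM3 = list(free = setdiff(PHI_NAMES, "M1"),
                fixed = c(M1 = 0), tied = NULL),
    custom = list(free = free, fixed = fixed, tied = tied))
  if (name == "custom") {
    if (is.null(spec$free)) stop("custom model needs a 'free' set")
  }
  spec$free <- intersect(PHI_NAMES, spec$free)  # canonical order
  bad <- setdiff(names(spec$fixed), PHI_NAMES)
  if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  overlap <- intersect(spec$free, c(names(spec$fixed), names(spec$tied)))
  if (length(overlap))
    stop("parameter(s) both free and fixed/tied: ", paste(overlap, collapse = ", "))
  covered <- c(spec$free, names(spec$fixed), names(spec$tied))
  miss <- setdiff(PHI_NAMES, covered)
  if (length(miss))
    stop("model leaves parameter(s) unspecified: ", paste(miss, collapse = ", "))
  structure(list(name = name, free = spec$free, fixed = spec$fixed,
                 tied = spec$tied, df = length(spec$free)),
            class = "iim_model")
}

#' @export
print.iim_model <- function(x, ...) {
  cat(sprintf("IIM model family member '%s' (%d free parameters)\n", x$name, x$df))
  cat("  free :", paste(x$free, collapse = ", "), "\n")
  if (length(x$fixed))
    cat("  fixed:", paste(sprintf("%s = %g", names(x$fixed), x$fixed),
                          collapse = ", "), "\n")
  if (length(x$tied))
    cat("  tied :", paste(sprintf("%s = %s", names(x$tied), x$tied),
                          collapse = ", "), "\n")
  invisible(x)
}

# Expand a free-parameter vector into a full 9-entry phi vector under a model
# mask. `free` is a named numeric vector over model$free.
expand_phi <- function(free, model) {
  phi <- stats::setNames(numeric(9L), PHI_NAMES)
  phi[model$free] <- free[model$free]
  if (length(model$fixed)) phi[names(model$fixed)] <- model$fixed
  if (length(model$tied))  phi[names(model$tied)]  <- phi[model$tied]
  structure(phi, class = c("phi_vector", "numeric"))
}

# Is model0 nested in model1 (free set strictly contained, compatible masks)?
is_nested <- function(model0, model1) {
  all(model0$free %in% model1$free) && model0$df < model1$df
}
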