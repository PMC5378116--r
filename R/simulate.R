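#' Simulate pairwise coalescence times under the IIM model
#'
#' Exact draws from the piecewise law of the pairwise coalescence time: an
#' exponential during the isolation stage (truncated at \eqn{\tau_1}), a
#' continuous-time Markov chain (Gillespie) trajectory through the migration
#' stage on \eqn{(\tau_1, \tau_0]}, and a shifted exponential in the
#' ancestral population. No eigen-decomposition is involved, so these draws
#' are an independent check on the analytic densities.
#'
#' @param n number of replicate draws.
#' @param state sampling state, 1, 2 or 3.
#' @param params a [coal_params()] object.
#' @return Numeric vector of \code{n} coalescence times (units of \eqn{2N}
#'   generations).
#' @examples
#' p <- coal_params(a = 0.75, b = 1.25, c1 = 1.5, c2 = 2,
#'                  tau1 = 1, tau0 = 2, M1 = 0.5, M2 = 0.75)
#' set.seed(1); mean(simulate_coal_time(1e4, 3, p))
#' @export
simulate_coal_time <- function(n, state, params) {
  check_state(state)
  validate_coal_params(params)
  epochs <- iim_epochs(params)
  out <- rep(NA_real_, n)
  # isolation stage: states 1 and 2 coalesce as Kingman pairs, state 3 waits
  if (state != 3 && params$tau1 > 0) {
    ci <- if (state == 1) params$c1 else params$c2
    e <- stats::rexp(n, rate = 1 / ci)
    done <- e <= params$tau1
    out[done] <- e[done]
  }
  alive <- which(is.na(out))
  if (length(alive)) {
    res <- ctmc_absorb(length(alive), state, params$tau1, epochs$mig, params$a)
    out[alive] <- res
  }
  out
}

# migration-stage epoch description shared with the multi-epoch simulator
iim_epochs <- function(params) {
  list(mig = list(t_end = params$tau0, size1 = 1, size2 = params$b,
                  M1 = params$M1, M2 = params$M2))
}

# Vectorised Gillespie walk through one piecewise-constant epoch list, then
# the ancestral stage. states coded 1, 2, 3; returns absorption times.
# `epochs` is a list of (t_end, size1, size2, M1, M2) with increasing t_end.
ctmc_absorb <- function(n, state, t_start, epochs, anc_size) {
  if (!is.list(epochs[[1]])) epochs <- list(epochs)
  t <- rep(t_start, n)
  st <- rep(state, n)
  coal_t <- rep(NA_real_, n)
  for (ep in epochs) {
    rate_coal <- c(1 / ep$size1, 1 / ep$size2, 0)
    rate_move <- c(ep$M1, ep$M2, (ep$M1 + ep$M2) / 2)  # indexed by state code
    active <- which(is.na(coal_t) & t < ep$t_end)
    while (length(active)) {
      s_a <- st[active]
      tot <- rate_coal[s_a] + rate_move[s_a]
      dt <- ifelse(tot > 0, stats::rexp(length(active), rate = pmax(tot, 1e-300)), Inf)
      tnew <- t[active] + dt
      stay <- tnew < ep$t_end
      idx <- active[stay]
      if (length(idx)) {
        s_i <- st[idx]
        tot_i <- rate_coal[s_i] + rate_move[s_i]
        u <- stats::runif(length(idx)) * tot_i
        coal <- u < rate_coal[s_i]
        t[idx] <- tnew[stay]
        coal_t[idx[coal]] <- t[idx[coal]]
        move <- idx[!coal]
        if (length(move)) {
          s_m <- st[move]
          ns <- integer(length(move))
          ns[s_m == 1] <- 3L
          ns[s_m == 2] <- 3L
          if (any(s_m == 3)) {
            # from state 3: to 1 at rate M2/2, to 2 at rate M1/2
            p1 <- ep$M2 / (ep$M1 + ep$M2)
            ns[s_m == 3] <- ifelse(stats::runif(sum(s_m == 3)) < p1, 1L, 2L)
          }
          st[move] <- ns
        }
      }
      t[active[!stay]] <- ep$t_end
      active <- idx[is.na(coal_t[idx])]
    }
  }
  alive <- which(is.na(coal_t))
  coal_t[alive] <- t[alive] + stats::rexp(length(alive), rate = 1 / anc_size)
  coal_t
}

#' Simulate a multilocus data set under the IIM model
#'
#' Reproduces the simulation protocol used to study estimator behaviour:
#' each locus contributes one pair of sequences; sampling states are
#' allocated in fixed proportions (default 1/4 state 1, 1/4 state 2, 1/2
#' state 3); per-locus relative mutation rates are drawn from a
#' Gamma(15, 15) distribution (mean 1) unless a fixed vector is supplied;
#' the coalescence time is drawn exactly from the IIM law; and the
#' segregating-site count is Poisson with mean \eqn{r_j \theta T}.
#'
#' @param n_loci number of loci.
#' @param phi a [phi_vector()] of generating values (alternatively supply
#'   \code{params} and \code{theta}).
#' @param params,theta coalescent-scale generating values (ignored when
#'   \code{phi} given).
#' @param state_proportions length-3 nonnegative weights for states 1, 2, 3;
#'   locus counts are the rounded proportions, so a data set of \code{n_loci}
#'   always has the same composition.
#' @param rate_gamma shape and rate of the Gamma distribution of relative
#'   mutation rates.
#' @param rel_rates optional fixed vector of relative rates (length
#'   \code{n_loci}), reused across data sets to mirror the fixed-rate-vector
#'   batch design.
#' @param seed integer seed; the data set is a deterministic function of the
#'   arguments.
#' @return A [as_loci_table()] data frame with a \code{true_T} attribute-free
#'   column omitted (only observable quantities are returned).
#' @examples
#' d <- simulate_iim_data(1000, phi = phi_vector(theta_a = 1.5, theta = 2,
#'   theta_b = 2.5, T1 = 2, V = 2, M1 = 0.5, M2 = 0.75), seed = 7)
#' table(d$state)
#' @export
simulate_iim_data <- function(n_loci, phi = NULL, params = NULL, theta = NULL,
                              state_proportions = c(0.25, 0.25, 0.5),
                              rate_gamma = c(15, 15), rel_rates = NULL,
                              seed = 1) {
  if (is.null(phi)) {
    if (is.null(params) || is.null(theta))
      stop("supply either phi or (params, theta)")
    phi <- coal_to_phi(params, theta)
  }
  validate_phi(phi)
  params <- phi_to_coal(phi)
  theta <- phi[["theta"]]
  if (length(state_proportions) != 3L || any(state_proportions < 0) ||
      sum(state_proportions) <= 0)
    stop("state_proportions must be 3 nonnegative weights")
  pr <- state_proportions / sum(state_proportions)
  n_state <- round(n_loci * pr)
  n_state[3] <- n_loci - n_state[1] - n_state[2]

  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (is.null(rel_rates)) {
    rel_rates <- stats::rgamma(n_loci, shape = rate_gamma[1], rate = rate_gamma[2])
  } else if (length(rel_rates) != n_loci) {
    stop("rel_rates must have length n_loci")
  }
  states <- rep(1:3, times = n_state)
  Tcoal <- numeric(n_loci)
  for (st in 1:3) {
    idx <- which(states == st)
    if (length(idx)) Tcoal[idx] <- simulate_coal_time(length(idx), st, params)
  }
  s <- stats::rpois(n_loci, lambda = rel_rates * theta * Tcoal)
  as_loci_table(data.frame(locus_id = sprintf("L%06d", seq_len(n_loci)),
                           state = states, s = s, rel_rate = rel_rates,
                           order_index = seq_len(n_loci)))
}

#' Simulate under a general piecewise-constant two-deme history
#'
#' A generalisation of the IIM simulator to an arbitrary sequence of
#' two-deme epochs with constant sizes and migration rates, ending in a
#' panmictic ancestral population. Useful for studying how IIM fits respond
#' to histories that violate the three-stage assumption (gradual size change,
#' secondary contact). The IIM model itself is the two-epoch special case,
#' which serves as a regression check.
#'
#' @param n_loci number of loci.
#' @param epochs data frame (or list of lists) with columns
#'   \code{duration}, \code{size1}, \code{size2}, \code{M1}, \code{M2};
#'   epochs run from the present backwards.
#' @param anc_size relative size of the final ancestral population.
#' @param theta average scaled mutation rate.
#' @inheritParams simulate_iim_data
#' @return A loci table as in [simulate_iim_data()].
#' @examples
#' # secondary-contact history: isolation, then gene flow, then isolation
#' ep <- data.frame(duration = c(0.5, 1, 0.5),
#'                  size1 = c(1.5, 1, 1), size2 = c(2, 1.25, 1.25),
#'                  M1 = c(0, 0.5, 0), M2 = c(0, 0.75, 0))
#' d <- simulate_multiepoch_data(500, ep, anc_size = 0.75, theta = 2, seed = 3)
#' @export
simulate_multiepoch_data <- function(n_loci, epochs, anc_size, theta,
                                     state_proportions = c(0.25, 0.25, 0.5),
                                     rate_gamma = c(15, 15), rel_rates = NULL,
                                     seed = 1) {
  epochs <- as.data.frame(epochs)
  need <- c("duration", "size1", "size2", "M1", "M2")
  if (!all(need %in% names(epochs)))
    stop("epochs needs columns ", paste(need, collapse = ", "))
  if (any(epochs$duration <= 0) || any(epochs$size1 <= 0) | any(epochs$size2 <= 0))
    stop("epoch durations and sizes must be positive")
  if (anc_size <= 0 || theta <= 0) stop("anc_size and theta must be positive")
  pr <- state_proportions / sum(state_proportions)
  n_state <- round(n_loci * pr)
  n_state[3] <- n_loci - n_state[1] - n_state[2]

  set.seed(as.integer(seed) %% .Machine$integer.max)
  if (is.null(rel_rates))
    rel_rates <- stats::rgamma(n_loci, shape = rate_gamma[1], rate = rate_gamma[2])
  t_end <- cumsum(epochs$duration)
  ep_list <- lapply(seq_len(nrow(epochs)), function(i)
    list(t_end = t_end[i], size1 = epochs$size1[i], size2 = epochs$size2[i],
         M1 = epochs$M1[i], M2 = epochs$M2[i]))
  states <- rep(1:3, times = n_state)
  Tcoal <- numeric(n_loci)
  for (st in 1:3) {
    idx <- which(states == st)
    if (length(idx))
      Tcoal[idx] <- ctmc_absorb(length(idx), st, 0, ep_list, anc_size)
  }
  s <- stats::rpois(n_loci, lambda = rel_rates * theta * Tcoal)
  as_loci_table(data.frame(locus_id = sprintf("L%06d", seq_len(n_loci)),
                           state = states, s = s, rel_rate = rel_rates,
                           order_index = seq_len(n_loci)))
}
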