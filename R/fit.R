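# Internal fast likelihood closure: pre-splits the data by state so repeated
# evaluations during optimisation avoid per-call validation overhead.
make_loglik_fn <- function(data, model) {
  by_state <- lapply(1:3, function(st) {
    idx <- data$state == st
    list(s = data$s[idx], r = data$rel_rate[idx])
  })
  force(model)
  function(free) {
    phi <- expand_phi(free, model)
    if (any(phi[1:5] <= 0) || any(phi[6:9] < 0)) return(-Inf)
    params <- tryCatch(phi_to_coal(phi), error = function(e) NULL)
    if (is.null(params)) return(-Inf)
    spectrum <- tryCatch(suppressWarnings(migration_spectrum(params)),
                         error = function(e) NULL)
    if (is.null(spectrum)) return(-Inf)
    theta <- phi[["theta"]]
    total <- 0
    for (st in 1:3) {
      d <- by_state[[st]]
      if (!length(d$s)) next
      ll <- tryCatch(
        segsites_logpmf_kernel(d$s, d$r * theta, st, params, spectrum),
        error = function(e) NULL)
      if (is.null(ll)) return(-Inf)
      total <- total + sum(ll)
    }
    if (!is.finite(total)) -Inf else total
  }
}

# free-parameter transforms: log for the mutation-scaled sizes, identity with
# a lower bound of zero for epoch lengths and migration rates
PHI_LOGSCALE <- c("theta_a", "theta", "theta_b", "theta_c1", "theta_c2")

to_working <- function(free) {
  w <- free
  lg <- names(free) %in% PHI_LOGSCALE
  w[lg] <- log(free[lg])
  w
}
from_working <- function(w) {
  free <- w
  lg <- names(w) %in% PHI_LOGSCALE
  free[lg] <- exp(w[lg])
  free[!lg] <- pmax(free[!lg], 0)
  free
}

# method-of-moments style starting centre: match per-state means of s / r_j
mom_start <- function(data, model) {
  m <- vapply(1:3, function(st) {
    idx <- data$state == st
    if (!any(idx)) return(NA_real_)
    mean(data$s[idx] / data$rel_rate[idx])
  }, numeric(1))
  m[!is.finite(m)] <- NA_real_
  m3 <- if (is.na(m[3])) max(m, 2, na.rm = TRUE) else m[3]
  m1 <- if (is.na(m[1])) 0.6 * m3 else m[1]
  m2 <- if (is.na(m[2])) 0.6 * m3 else m[2]
  th_a <- max(0.5 * m3, 0.05)
  gap <- max(m3 - th_a, 0.1)
  centre <- c(theta_a = th_a, theta = max(m1, 0.05), theta_b = max(m2, 0.05),
              theta_c1 = max(m1, 0.05), theta_c2 = max(m2, 0.05),
              T1 = if ("T1" %in% model$free) 0.3 * gap else 0,
              V = 0.7 * gap, M1 = 0.25, M2 = 0.25)
  centre[model$free]
}

#' Maximum-likelihood fit of an IIM-family model
#'
#' Maximises the multilocus log-likelihood over the free parameters of a
#' model mask, in the mutation-scaled parameterisation. Each start is a
#' two-stage local search: a Nelder-Mead simplex polish followed by bounded
#' quasi-Newton (\code{L-BFGS-B}), with the mutation-scaled sizes optimised
#' on the log scale and the epoch lengths and migration rates bounded below
#' by zero (so boundary hypotheses such as \eqn{M_1 = 0} are exactly
#' attainable). Starts are placed around a method-of-moments centre with
#' Latin-hypercube jitter; the whole procedure is deterministic given
#' \code{(data, model, n_starts, seed)}.
#'
#' @param data a loci table ([as_loci_table()]).
#' @param model an [iim_model()] (or model name string).
#' @param n_starts number of local optimisations.
#' @param seed integer seed for start placement.
#' @param init optional named vector of free-parameter values used as the
#'   centre of the first start (e.g. a nested fit's estimates for warm
#'   starts).
#' @param hessian compute the observed-information Hessian (central finite
#'   differences) at the optimum.
#' @param control list; \code{nm_maxit} and \code{lbfgs_maxit} cap the two
#'   optimiser stages, \code{reltol} is the simplex relative tolerance,
#'   \code{subsample} is the locus count above which the multistart search
#'   runs on a stratified random subsample before a full-data quasi-Newton
#'   polish (set to \code{Inf} to disable).
#' @return An object of class \code{"iim_fit"}: \code{phi_hat} (full phi
#'   vector), \code{free} (free-parameter estimates), \code{logL},
#'   \code{hessian} (or \code{NULL}), \code{model}, \code{converged},
#'   \code{n_starts}, \code{seed}, and a per-start summary table
#'   \code{starts}.
#' @examples
#' \donttest{
#' sim <- simulate_iim_data(n_loci = 2000, phi = phi_vector(
#'   theta_a = 1.5, theta = 2, theta_b = 2.5, theta_c1 = 3, theta_c2 = 4,
#'   T1 = 2, V = 2, M1 = 0.5, M2 = 0.75), seed = 1)
#' fit <- fit_iim(sim, "ISO", n_starts = 2, seed = 1)
#' fit$logL
#' }
#' @export
fit_iim <- function(data, model = "IIM2", n_starts = 10, seed = 1,
                    init = NULL, hessian = FALSE, control = list()) {
  data <- as_loci_table(data)
  if (!nrow(data)) stop("empty data set")
  if (is.character(model)) model <- iim_model(model)
  ctl <- utils::modifyList(list(nm_maxit = 500, lbfgs_maxit = 200,
                                reltol = 1e-8, subsample = 12000,
                                rounds = 2L, polish_cycles = 3L), control)
  states_present <- sort(unique(data$state))
  if (length(states_present) < 3L)
    warning("observations cover only sampling state(s) ",
            paste(states_present, collapse = ", "),
            "; joint identifiability of all parameters is reduced")

  loglik <- make_loglik_fn(data, model)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  # multistart search runs on a stratified subsample for large data sets;
  # the best candidates are then polished on the full data
  search_data <- data
  if (nrow(data) > ctl$subsample) {
    idx <- unlist(lapply(1:3, function(st) {
      rows <- which(data$state == st)
      n_take <- ceiling(length(rows) * ctl$subsample / nrow(data))
      if (length(rows)) sample(rows, min(n_take, length(rows))) else integer(0)
    }))
    search_data <- data[sort(idx), , drop = FALSE]
  }
  loglik_search <- make_loglik_fn(search_data, model)
  negobj <- function(w) {
    v <- loglik_search(from_working(w))
    if (!is.finite(v)) 1e10 else -v
  }
  fd <- make_fd_pair(negobj)
  k <- model$df
  centre <- mom_start(data, model)
  if (!is.null(init)) {
    if (!all(model$free %in% names(init)))
      stop("init must name all free parameters of the model")
    centre <- init[model$free]
    centre[PHI_LOGSCALE[PHI_LOGSCALE %in% model$free]] <-
      pmax(centre[PHI_LOGSCALE[PHI_LOGSCALE %in% model$free]], 1e-4)
  }
  starts <- matrix(rep(centre, each = n_starts), n_starts, k,
                   dimnames = list(NULL, model$free))
  if (n_starts > 1) {
    u <- lhs::randomLHS(n_starts - 1L, k)
    for (j in seq_len(k)) {
      nm <- model$free[j]
      if (nm %in% PHI_LOGSCALE) {
        starts[-1L, j] <- centre[j] * exp((u[, j] - 0.5) * 2 * log(3))
      } else if (nm %in% c("T1", "V")) {
        starts[-1L, j] <- pmax(centre[j], 0.05) * exp((u[, j] - 0.5) * 2 * log(3))
      } else {  # migration rates: spread over [0, 1.5]
        starts[-1L, j] <- u[, j] * 1.5
      }
    }
  }

  # working-scale box: sizes within e^-12 .. e^15, epoch lengths and
  # migration rates within [0, 30] (generous for mutation-scaled data)
  lower <- ifelse(model$free %in% PHI_LOGSCALE, -12, 0)
  upper <- ifelse(model$free %in% PHI_LOGSCALE, 15, 30)
  runs <- vector("list", n_starts)
  for (r in seq_len(n_starts)) {
    w0 <- to_working(stats::setNames(starts[r, ], model$free))
    nm <- stats::optim(w0, negobj, method = "Nelder-Mead",
                       control = list(maxit = ctl$nm_maxit, reltol = ctl$reltol))
    bf <- tryCatch(
      stats::optim(nm$par, fd$fn, gr = fd$gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = ctl$lbfgs_maxit, factr = 1e7)),
      error = function(e) nm)
    cand <- list(nm, bf)
    if (ctl$rounds >= 2L) {
      # a second simplex-polish round catches quasi-Newton stalls on ridges
      nm2 <- stats::optim(bf$par, negobj, method = "Nelder-Mead",
                          control = list(maxit = ctl$nm_maxit, reltol = ctl$reltol))
      bf2 <- tryCatch(
        stats::optim(nm2$par, fd$fn, gr = fd$gr, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = ctl$lbfgs_maxit, factr = 1e7)),
        error = function(e) nm2)
      cand <- c(cand, list(nm2, bf2))
    }
    best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "value"))]]
    runs[[r]] <- list(par = best$par, value = best$value,
                      converged = is.finite(best$value) && best$value < 1e10)
  }
  vals <- vapply(runs, `[[`, numeric(1), "value")
  if (all(!vapply(runs, `[[`, logical(1), "converged")))
    stop("all optimisation starts failed; check the data and model mask")
  bestrun <- runs[[which.min(vals)]]

  if (nrow(search_data) < nrow(data)) {
    # rank the start optima by the full-data likelihood, not the subsample
    # one: distinct basins can order differently under subsampling noise
    full_vals <- vapply(runs, function(r) {
      if (!is.finite(r$value) || r$value >= 1e10) return(Inf)
      v <- loglik(from_working(stats::setNames(r$par, model$free)))
      if (is.finite(v)) -v else Inf
    }, numeric(1))
    if (any(is.finite(full_vals)))
      bestrun <- runs[[which.min(full_vals)]]
  }

  if (nrow(search_data) < nrow(data)) {
    # full-data polish from the best subsample optimum: cycles of bounded
    # quasi-Newton (central-difference gradients, which are robust to the
    # objective's rounding noise on flat ridges) and short simplex rounds,
    # until the cycle stops improving
    negfull <- function(w) {
      v <- loglik(from_working(w))
      if (!is.finite(v)) 1e10 else -v
    }
    fdf <- make_fd_pair(negfull, h_rel = 1e-4, central = TRUE)
    cur <- list(par = bestrun$par, value = negfull(bestrun$par))
    for (cycle in seq_len(ctl$polish_cycles)) {
      prev <- cur$value
      bf <- tryCatch(
        stats::optim(cur$par, fdf$fn, gr = fdf$gr, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = ctl$lbfgs_maxit, factr = 1e7)),
        error = function(e) cur)
      if (bf$value < cur$value) cur <- list(par = bf$par, value = bf$value)
      nmflush <- stats::optim(cur$par, negfull, method = "Nelder-Mead",
                              control = list(maxit = 200, reltol = ctl$reltol))
      if (nmflush$value < cur$value)
        cur <- list(par = nmflush$par, value = nmflush$value)
      if (prev - cur$value < 0.05) break
    }
    if (is.finite(cur$value) && cur$value < 1e10)
      bestrun <- list(par = cur$par, value = cur$value, converged = TRUE)
  }
  free_hat <- from_working(stats::setNames(bestrun$par, model$free))
  phi_hat <- expand_phi(free_hat, model)
  logL <- loglik(free_hat)

  H <- NULL
  if (hessian) H <- fd_hessian(loglik, free_hat)

  structure(list(phi_hat = phi_hat, free = free_hat, logL = logL,
                 hessian = H, model = model, converged = TRUE,
                 n_starts = n_starts, seed = seed,
                 starts = data.frame(start = seq_len(n_starts),
                                     negLogL = vals),
                 n_loci = nrow(data)),
            class = "iim_fit")
}

# objective plus forward-difference gradient sharing a one-deep cache:
# L-BFGS-B requests the gradient at the point it just evaluated, so the
# base value is reused rather than recomputed
# The step must clear the objective's rounding noise (magnitude ~ |logL| *
# 1e-12): too small a step makes quasi-Newton stall on nearly flat ridges.
make_fd_pair <- function(negfn, h_rel = 2e-5, central = FALSE) {
  last_w <- NULL; last_v <- NULL
  fn <- function(w) {
    v <- negfn(w)
    last_w <<- w; last_v <<- v
    v
  }
  gr <- function(w) {
    h <- h_rel * (1 + abs(w))
    g <- numeric(length(w))
    if (central) {
      for (i in seq_along(w)) {
        wp <- w; wp[i] <- w[i] + h[i]
        wm <- w; wm[i] <- w[i] - h[i]
        g[i] <- (negfn(wp) - negfn(wm)) / (2 * h[i])
      }
    } else {
      f0 <- if (!is.null(last_w) && identical(w, last_w)) last_v else fn(w)
      for (i in seq_along(w)) {
        wi <- w; wi[i] <- w[i] + h[i]
        g[i] <- (negfn(wi) - f0) / h[i]
      }
    }
    g
  }
  list(fn = fn, gr = gr)
}

# central finite-difference Hessian of fn (a log-likelihood over named free
# parameters), step h_k = base * (1 + |x_k|). Parameters pinned at the zero
# boundary use a one-sided (forward) stencil so the result stays finite;
# curvature in those directions is then an interior approximation only.
fd_hessian <- function(fn, x, base = 1e-4, nonneg = NULL) {
  k <- length(x)
  h <- base * (1 + abs(x))
  if (is.null(nonneg)) nonneg <- !(names(x) %in% PHI_LOGSCALE)
  f0 <- fn(x)
  # per-coordinate offsets: central (-h, +h) or forward (0, +2h) at a bound
  lo <- -h; hi <- h
  for (i in seq_len(k)) {
    if (nonneg[i] && x[i] - h[i] < 0) {
      if (x[i] < 1e-10) { lo[i] <- 0; hi[i] <- 2 * h[i] }
      else { h[i] <- x[i] / 2; lo[i] <- -h[i]; hi[i] <- h[i] }
    }
  }
  H <- matrix(NA_real_, k, k, dimnames = list(names(x), names(x)))
  at <- function(di, dj = NULL, j = NULL, i) {
    y <- x; y[i] <- x[i] + di
    if (!is.null(j)) y[j] <- x[j] + dj
    fn(y)
  }
  for (i in seq_len(k)) {
    fp <- at(hi[i], i = i); fm <- at(lo[i], i = i)
    # for the one-sided stencil (lo = 0) this is the forward second difference
    step2 <- (hi[i] - lo[i]) / 2
    H[i, i] <- if (lo[i] == 0) {
      fmid <- at(hi[i] / 2, i = i)
      (f0 - 2 * fmid + fp) / (hi[i] / 2)^2
    } else (fp + fm - 2 * f0) / step2^2
    for (j in seq_len(i - 1L)) {
      fpp <- at(hi[i], hi[j], j, i); fpm <- at(hi[i], lo[j], j, i)
      fmp <- at(lo[i], hi[j], j, i); fmm <- at(lo[i], lo[j], j, i)
      H[i, j] <- H[j, i] <- (fpp - fpm - fmp + fmm) /
        ((hi[i] - lo[i]) * (hi[j] - lo[j]))
    }
  }
  (H + t(H)) / 2
}

#' @export
print.iim_fit <- function(x, ...) {
  cat(sprintf("IIM-family maximum-likelihood fit: model %s, %d loci\n",
              x$model$name, x$n_loci))
  cat(sprintf("  logL = %.4f  (%d starts, seed %s)\n", x$logL, x$n_starts,
              format(x$seed)))
  est <- x$free
  cat("  estimates:\n")
  for (nm in names(est)) cat(sprintf("    %-9s %.4f\n", nm, est[nm]))
  invisible(x)
}

#' @export
logLik.iim_fit <- function(object, ...) {
  structure(object$logL, df = object$model$df, class = "logLik")
}
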