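#' Likelihood-ratio test between nested IIM-family fits
#'
#' Computes \eqn{D = 2(\log L_1 - \log L_0)} and the naive \eqn{\chi^2}
#' p-value with degrees of freedom equal to the difference in free-parameter
#' counts. When any of the additional parameters of the alternative is fixed
#' at the zero boundary under the null (gene-flow rates, epoch lengths), the
#' true null distribution is a mixture of \eqn{\chi^2} laws with smaller
#' degrees of freedom, and the naive p-value is conservative; such tests are
#' flagged by \code{boundary}.
#'
#' @param fit0 null-model fit (nested).
#' @param fit1 alternative-model fit.
#' @param tol tolerance for a slightly negative statistic caused by
#'   optimiser error; anything below \code{-tol} is an error (refit with
#'   more starts).
#' @return An object of class \code{"iim_lrt"}: \code{D}, \code{df},
#'   \code{p_naive}, \code{p_robust} (NA unless computed by
#'   [robust_lrt()]), \code{boundary}.
#' @export
lrt <- function(fit0, fit1, tol = 1e-6) {
  if (!inherits(fit0, "iim_fit") || !inherits(fit1, "iim_fit"))
    stop("fit0 and fit1 must be iim_fit objects")
  if (!is_nested(fit0$model, fit1$model))
    stop("'", fit0$model$name, "' is not nested in '", fit1$model$name, "'")
  D <- 2 * (fit1$logL - fit0$logL)
  if (D < -tol)
    stop("alternative fit has lower likelihood than the null (D = ",
         format(D), "); refit with more starts")
  D <- max(D, 0)
  extra <- setdiff(fit1$model$free, fit0$model$free)
  df <- fit1$model$df - fit0$model$df
  fixed0 <- fit0$model$fixed
  boundary <- any(extra %in% c("T1", "V", "M1", "M2") &
                    vapply(extra, function(nm)
                      isTRUE(fixed0[[nm]] == 0) ||
                        (nm %in% names(fit0$model$tied)), logical(1)))
  structure(list(D = D, df = df,
                 p_naive = stats::pchisq(D, df, lower.tail = FALSE),
                 p_robust = NA_real_, boundary = boundary,
                 models = c(fit0$model$name, fit1$model$name)),
            class = "iim_lrt")
}

#' @export
print.iim_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: %s (H0) vs %s (H1)\n",
              x$models[1], x$models[2]))
  cat(sprintf("  D = %.4f  df = %d  naive p = %.4g\n", x$D, x$df, x$p_naive))
  if (!is.na(x$p_robust))
    cat(sprintf("  robust (scaled-shifted chi-square) p = %.4g\n", x$p_robust))
  if (x$boundary)
    cat("  note: null fixes parameter(s) on the boundary; the naive chi-square",
        "p-value is expected to be conservative\n")
  invisible(x)
}

#' Null distribution of the LRT statistic at a boundary
#'
#' Replicates the simulate-fit-fit pipeline used to check that the naive
#' \eqn{\chi^2} test is conservative when the null model lies on the
#' boundary of the alternative's parameter space: data sets are generated
#' under the null, both models are fitted (the alternative warm-started from
#' the null optimum so the statistic cannot go negative), and the empirical
#' distribution of \eqn{D} is compared with the nominal \eqn{\chi^2}.
#'
#' @param model0,model1 nested [iim_model()]s (or names).
#' @param generating_phi full phi vector of null generating values.
#' @param n_datasets number of replicate data sets.
#' @param n_loci loci per data set.
#' @param seed master seed (replicate r uses seed + r for its data).
#' @param level nominal significance level for the rejection-rate summary.
#' @param n_starts multistart count per fit.
#' @param control optimiser controls passed to [fit_iim()].
#' @param ... further arguments passed to [simulate_iim_data()].
#' @return List: \code{D} (vector of statistics, failures dropped),
#'   \code{n_failed}, \code{rejection_rate} at \code{level},
#'   \code{chisq_quantiles} (theoretical quantiles matching the empirical
#'   ones for a Q-Q display), \code{df}.
#' @export
boundary_null_study <- function(model0, model1, generating_phi,
                                n_datasets = 20, n_loci = 8000, seed = 1,
                                level = 0.05, n_starts = 2,
                                control = list(), ...) {
  if (is.character(model0)) model0 <- iim_model(model0)
  if (is.character(model1)) model1 <- iim_model(model1)
  if (!is_nested(model0, model1)) stop("model0 must be nested in model1")
  Ds <- rep(NA_real_, n_datasets)
  for (r in seq_len(n_datasets)) {
    d <- simulate_iim_data(n_loci, phi = generating_phi,
                           seed = seed + r, ...)
    res <- tryCatch({
      f0 <- fit_iim(d, model0, n_starts = n_starts, seed = seed + r,
                    control = control)
      init1 <- expand_phi(f0$free, model0)[model1$free]
      f1 <- fit_iim(d, model1, n_starts = n_starts, seed = seed + r,
                    init = init1, control = control)
      lrt(f0, f1)$D
    }, error = function(e) NA_real_)
    Ds[r] <- res
  }
  ok <- Ds[!is.na(Ds)]
  df <- model1$df - model0$df
  crit <- stats::qchisq(1 - level, df)
  pp <- (seq_along(ok) - 0.5) / length(ok)
  list(D = ok, n_failed = sum(is.na(Ds)),
       rejection_rate = mean(ok > crit), level = level, df = df,
       empirical_quantiles = sort(ok),
       chisq_quantiles = stats::qchisq(pp, df))
}

# Compare nested fits; if the alternative's likelihood fell below the
# null's by more than the tolerance (optimiser noise when the true
# difference is zero), refit the alternative warm-started from the null
# and clamp residual noise.
lrt_refit <- function(f0, f1, data, n_starts, seed) {
  out <- tryCatch(list(test = lrt(f0, f1), fit1 = f1), error = function(e) NULL)
  if (!is.null(out)) return(out)
  init <- expand_phi(f0$free, f0$model)[f1$model$free]
  lg <- PHI_LOGSCALE[PHI_LOGSCALE %in% names(init)]
  init[lg] <- pmax(init[lg], 1e-4)
  f1b <- fit_iim(data, f1$model, n_starts = n_starts, seed = seed,
                 init = init)
  if (f1b$logL < f0$logL) f1b$logL <- f0$logL  # identical up to noise
  list(test = lrt(f0, f1b), fit1 = f1b)
}

#' Forward model selection with a backward boundary check
#'
#' Walks a nested model sequence forward, keeping the alternative whenever
#' the likelihood-ratio test rejects at \code{alpha}; afterwards, any free
#' boundary parameter estimated at (numerically) zero is removed if doing so
#' leaves the log-likelihood unchanged, which yields the parsimonious final
#' model (e.g. the unidirectional variant when \eqn{\hat M_1 = 0}).
#'
#' @param data a loci table.
#' @param model_sequence character vector of nested model names, simplest
#'   first (default the standard ladder ISO, IM1, IIM1, IIM2).
#' @param alpha significance level for each forward test.
#' @param n_starts,seed fitting controls (alternatives are warm-started from
#'   the incumbent).
#' @param zero_tol estimates below this are treated as on the boundary in
#'   the backward step.
#' @return List with \code{selected} (an [iim_model()]), \code{fit} (its
#'   fit), \code{tests} (data frame of the comparisons performed) and
#'   \code{fits} (all fitted models by name).
#' @export
forward_selection <- function(data, model_sequence = c("ISO", "IM1", "IIM1", "IIM2"),
                              alpha = 0.05, n_starts = 3, seed = 1,
                              zero_tol = 1e-4) {
  data <- as_loci_table(data)
  if (!length(model_sequence)) stop("empty model sequence")
  fits <- list()
  cur_name <- model_sequence[1]
  cur <- fit_iim(data, cur_name, n_starts = n_starts, seed = seed)
  fits[[cur_name]] <- cur
  tests <- NULL
  for (nm in model_sequence[-1]) {
    alt_model <- iim_model(nm)
    init <- expand_phi(cur$free, cur$model)[alt_model$free]
    init[PHI_LOGSCALE[PHI_LOGSCALE %in% names(init)]] <-
      pmax(init[PHI_LOGSCALE[PHI_LOGSCALE %in% names(init)]], 1e-4)
    alt <- fit_iim(data, alt_model, n_starts = n_starts, seed = seed,
                   init = init)
    res <- lrt_refit(cur, alt, data, n_starts, seed)
    alt <- res$fit1; tst <- res$test
    fits[[nm]] <- alt
    tests <- rbind(tests, data.frame(H0 = cur$model$name, H1 = nm,
                                     D = tst$D, df = tst$df,
                                     p = tst$p_naive,
                                     boundary = tst$boundary,
                                     rejected = tst$p_naive < alpha))
    if (tst$p_naive >= alpha) break
    cur <- alt
  }
  # backward step: drop boundary-valued free parameters that cost no likelihood
  repeat {
    on_bound <- names(cur$free)[!(names(cur$free) %in% PHI_LOGSCALE) &
                                  cur$free < zero_tol]
    if (!length(on_bound)) break
    nm_drop <- on_bound[1]
    red_model <- iim_model("custom",
                           free = setdiff(cur$model$free, nm_drop),
                           fixed = c(stats::setNames(0, nm_drop),
                                     cur$model$fixed),
                           tied = cur$model$tied)
    red_name <- if (cur$model$name == "IIM2" && nm_drop == "M1") "IIM3"
                else paste0(cur$model$name, "-", nm_drop)
    if (red_name == "IIM3") red_model <- iim_model("IIM3")
    red <- fit_iim(data, red_model, n_starts = n_starts, seed = seed,
                   init = cur$free[red_model$free])
    tst <- lrt_refit(red, cur, data, n_starts, seed)$test
    tests <- rbind(tests, data.frame(H0 = red_name, H1 = cur$model$name,
                                     D = tst$D, df = tst$df, p = tst$p_naive,
                                     boundary = tst$boundary,
                                     rejected = tst$p_naive < alpha))
    if (tst$p_naive < alpha) break
    red$model$name <- red_name
    fits[[red_name]] <- red
    cur <- red
  }
  list(selected = cur$model, fit = cur, tests = tests, fits = fits)
}
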