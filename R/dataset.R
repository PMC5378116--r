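#' Per-locus observation table
#'
#' The unit of data is one pair of haploid sequences per locus, summarised by
#' its sampling configuration and the number of segregating sites. A loci
#' table is a plain data frame with columns:
#' \describe{
#'   \item{locus_id}{unique character identifier;}
#'   \item{state}{sampling configuration, 1 (both sequences from population
#'     1), 2 (both from population 2) or 3 (one from each);}
#'   \item{s}{nonnegative integer count of segregating sites;}
#'   \item{rel_rate}{relative mutation rate \eqn{r_j} of the locus (treated
#'     as a known constant; defaults to 1);}
#'   \item{block}{optional cluster label for linkage-aware (Godambe)
#'     analyses;}
#'   \item{order_index}{optional genome-order index, required by
#'     [block_reduce()].}
#' }
#'
#' @param df a data frame with at least \code{locus_id}, \code{state},
#'   \code{s}; \code{rel_rate} defaults to 1 with a notice.
#' @return The validated data frame with class \code{"loci_table"} prepended.
#' @export
as_loci_table <- function(df) {
  if (!is.data.frame(df)) stop("expected a data frame of loci")
  need <- c("locus_id", "state", "s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"rel_rate" %in% names(df)) {
    message("no 'rel_rate' column: assuming homogeneous mutation rates (r_j = 1)")
    df$rel_rate <- 1
  }
  df$locus_id <- as.character(df$locus_id)
  bad <- which(!df$state %in% c(1L, 2L, 3L))
  if (length(bad))
    stop("invalid sampling state at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!(is.finite(df$s) & df$s >= 0 & df$s == floor(df$s)))
  if (length(bad))
    stop("segregating-site counts must be nonnegative integers; bad row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!(is.finite(df$rel_rate) & df$rel_rate > 0))
  if (length(bad))
    stop("relative rates must be > 0; bad row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (anyDuplicated(df$locus_id))
    stop("locus_id values must be unique")
  class(df) <- unique(c("loci_table", class(df)))
  df
}

#' Multilocus composite log-likelihood
#'
#' The log-likelihood of a loci table under a phi vector: the sum over loci
#' of the log segregating-sites PMF with locus mutation rate \eqn{\theta_j =
#' r_j \theta}. Loci are treated as independent; under linkage this is a
#' composite (independence) log-likelihood and should be paired with
#' [godambe_info()] for uncertainty statements.
#'
#' The migration-stage spectrum depends only on the parameters, not on the
#' locus, and is computed once per call; per-locus work is a handful of
#' Poisson-CDF evaluations, which keeps full-genome likelihood scans fast.
#'
#' @param data a [as_loci_table()] data frame.
#' @param phi a [phi_vector()].
#' @param by_locus if \code{TRUE}, return the vector of per-locus
#'   log-likelihood contributions (in the row order of \code{data}).
#' @return The scalar log-likelihood, or a vector if \code{by_locus}.
#' @export
iim_loglik <- function(data, phi, by_locus = FALSE) {
  data <- as_loci_table(data)
  validate_phi(phi)
  params <- phi_to_coal(phi)
  theta <- attr(params, "theta")
  spectrum <- migration_spectrum(params)
  ll <- numeric(nrow(data))
  for (st in 1:3) {
    idx <- which(data$state == st)
    if (!length(idx)) next
    ll[idx] <- segsites_logpmf_kernel(data$s[idx], data$rel_rate[idx] * theta,
                                      st, params, spectrum)
  }
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll))[1]
    stop("non-finite log-likelihood contribution at locus '",
         data$locus_id[bad], "' (state ", data$state[bad],
         ", s = ", data$s[bad], ")")
  }
  if (by_locus) ll else sum(ll)
}
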