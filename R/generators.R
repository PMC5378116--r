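#' Generator matrices of the IIM coalescent
#'
#' Rate matrices (per unit of \eqn{2N} generations) of the three
#' continuous-time Markov chains that describe the genealogy of two lineages
#' during the migration, isolation and ancestral stages of the IIM model.
#'
#' The migration-stage chain lives on the sampling states 1 (both lineages in
#' deme 1), 3 (one in each deme), 2 (both in deme 2) and the absorbing
#' coalesced state. Internally the state order is \code{(1, 3, 2, coalesced)}:
#' state 3 occupies the second row and column, which keeps the matrix as
#' symmetric as possible. From state 1 a lineage pair coalesces at rate 1 and
#' a single migration (rate \eqn{M_1/2} per lineage) moves the chain to state
#' 3; from state 3 the chain moves to state 1 at rate \eqn{M_2/2} or to state
#' 2 at rate \eqn{M_1/2}; from state 2 coalescence occurs at rate \eqn{1/b}
#' and migration at rate \eqn{M_2}.
#'
#' @param params a [coal_params()] object.
#' @return A square rate matrix with zero row sums; attribute
#'   \code{"state_order"} records the state labels in row/column order.
#' @examples
#' p <- coal_params(b = 1.25, tau1 = 1, tau0 = 2, M1 = 0.5, M2 = 0.75)
#' mig_generator(p)
#' @export
mig_generator <- function(params) {
  validate_coal_params(params)
  M1 <- params$M1; M2 <- params$M2; b <- params$b
  Q <- matrix(0, 4, 4)
  # state order (1, 3, 2, coalesced)
  Q[1, ] <- c(-(1 + M1), M1, 0, 1)
  Q[2, ] <- c(M2 / 2, -(M1 + M2) / 2, M1 / 2, 0)
  Q[3, ] <- c(0, M2, -(M2 + 1 / b), 1 / b)
  structure(Q, state_order = c("1", "3", "2", "coalesced"))
}

#' @rdname mig_generator
#' @param state sampling state, 1 or 2 (state 3 cannot coalesce during the
#'   isolation stage; its density assembly handles that case directly).
#' @export
iso_generator <- function(params, state) {
  validate_coal_params(params)
  if (!state %in% c(1, 2))
    stop("isolation-stage generator is defined for sampling states 1 and 2 only")
  rate <- 1 / if (state == 1) params$c1 else params$c2
  structure(matrix(c(-rate, rate, 0, 0), 2, 2, byrow = TRUE),
            state_order = c(as.character(state), "coalesced"))
}

#' @rdname mig_generator
#' @export
anc_generator <- function(params) {
  validate_coal_params(params)
  rate <- 1 / params$a
  structure(matrix(c(-rate, rate, 0, 0), 2, 2, byrow = TRUE),
            state_order = c("0", "coalesced"))
}
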