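#' Budget-apportioning gamma sequences
#'
#' Every online procedure apportions its error budget over future hypotheses
#' via a sequence of non-negative weights \eqn{\gamma_1, \ldots, \gamma_N}
#' summing to 1, where \eqn{N} is the pre-specified horizon (the assumed
#' upper bound \code{Nbound} on the number of experimental arms). The
#' default is uniform, \eqn{\gamma_i = 1/N}, which spreads the budget evenly
#' and makes Bonferroni at level \eqn{\alpha/N} the no-discovery floor of
#' LOND. A polynomially decaying alternative (\eqn{\gamma_i \propto
#' i^{-a}}, normalised over the horizon) front-loads the budget onto early
#' hypotheses.
#'
#' @param horizon positive integer; length of the sequence (the budget is
#'   exhausted after \code{horizon} hypotheses).
#' @param type \code{"uniform"} or \code{"power"} (polynomial decay).
#' @param exponent decay exponent \eqn{a > 0} for \code{type = "power"};
#'   default 1.6.
#' @return numeric vector of length \code{horizon}, non-negative, summing
#'   to 1, with attribute \code{"type"}.
#' @examples
#' gamma_sequence(20)                    # uniform 1/20
#' gamma_sequence(20, "power")           # decaying, sums to 1
#' @export
gamma_sequence <- function(horizon, type = c("uniform", "power"),
                           exponent = 1.6) {
  type <- match.arg(type)
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1 ||
      horizon != round(horizon)) {
    stop("'horizon' must be a positive integer")
  }
  horizon <- as.integer(horizon)
  g <- switch(type,
    uniform = rep(1 / horizon, horizon),
    power   = {
      w <- seq_len(horizon)^(-exponent)
      w / sum(w)
    }
  )
  attr(g, "type") <- type
  g
}

# gamma_j for possibly out-of-range indices: 0 for j <= 0 or j > horizon.
# Online level formulas index gamma at lags like i - tau_j that can be
# non-positive before any discovery is relevant.
gamma_at <- function(gamma, idx) {
  out <- numeric(length(idx))
  ok <- idx >= 1L & idx <= length(gamma)
  out[ok] <- gamma[idx[ok]]
  out
}

# Round half away from zero at 'digits' decimal places (presentation rule
# for reported testing levels: 0.00125 prints as 0.0013, unlike round()).
round_half_up <- function(x, digits = 4L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
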