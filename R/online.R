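#' Fully online testing procedures
#'
#' Each procedure walks the stream once, assigning hypothesis \eqn{H_i} a
#' testing level \eqn{\alpha_i} that depends only on the past, and rejects
#' when \eqn{p_i \le \alpha_i}. All share a pre-specified level
#' \eqn{\alpha} and (except uncorrected testing) a horizon-\code{Nbound}
#' weight sequence \eqn{\gamma} (see \code{\link{gamma_sequence}});
#' streams longer than the horizon are an error.
#'
#' \describe{
#'   \item{\code{run_uncorrected}}{\eqn{\alpha_i = \alpha}: no multiplicity
#'     adjustment (comparator).}
#'   \item{\code{run_bonferroni}}{\eqn{\alpha_i = \alpha/N} with
#'     \eqn{N = } \code{Nbound}, the pre-trial bound on the number of
#'     arms — not the realised number.}
#'   \item{\code{run_lond}}{levels based on number of discoveries:
#'     \eqn{\alpha_i = \alpha\gamma_i (D(i-1) + 1)} where \eqn{D(i-1)}
#'     counts rejections so far. Controls the FDR under independence and
#'     positive dependence, and always rejects at least as much as
#'     Bonferroni under the same uniform \eqn{\gamma}.}
#'   \item{\code{run_lord}}{the LORD++ alpha-investing rule
#'     \eqn{\alpha_i = \gamma_i W_0 + (\alpha - W_0)\gamma_{i-\tau_1} +
#'     \alpha \sum_{j \ge 2} \gamma_{i-\tau_j}}, where \eqn{\tau_j} is the
#'     time of the \eqn{j}-th discovery and \eqn{W_0 \in (0, \alpha]} the
#'     initial wealth. Discoveries, especially recent ones, replenish the
#'     budget.}
#'   \item{\code{run_saffron}}{adaptive alpha-investing that reserves the
#'     budget for candidate hypotheses (\eqn{p \le \lambda}):
#'     \eqn{\alpha_i = \min\{\lambda,\; W_0\gamma_{i - C_{0+}} +
#'     ((1-\lambda)\alpha - W_0)\gamma_{i - \tau_1 - C_{1+}} +
#'     (1-\lambda)\alpha\sum_{j\ge2}\gamma_{i - \tau_j - C_{j+}}\}}, with
#'     \eqn{C_{j+}} the number of candidates after the \eqn{j}-th
#'     discovery and before \eqn{i}.}
#'   \item{\code{run_addis}}{SAFFRON with discarding: hypotheses with
#'     \eqn{p > \tau} are discarded and consume no wealth; the remaining
#'     (selected) substream is tested with the SAFFRON update run at the
#'     hypothesis's position in that substream, candidacy at \eqn{\lambda}
#'     and per-discovery budget \eqn{(\tau - \lambda)\alpha}. With
#'     \eqn{\tau = 1} this reproduces SAFFRON decision-for-decision.}
#'   \item{\code{run_addis_spending}}{FWER-controlling alpha-spending with
#'     discarding and candidacy: \eqn{\alpha_i = \alpha(\tau - \lambda)
#'     \gamma_{g(i)}} where \eqn{g(i) = 1 + \#\{j < i : \lambda < p_j \le
#'     \tau\}}; only non-candidate, non-discarded hypotheses advance the
#'     spending index. With \eqn{\tau = 1, \lambda = 0} this is plain
#'     alpha-spending \eqn{\alpha_i = \alpha\gamma_i}.}
#' }
#'
#' @param stream a \code{\link{pvalue_stream}} (or bare numeric vector of
#'   p-values in testing order).
#' @param alpha overall error level (FWER or FDR depending on procedure).
#' @param Nbound horizon: assumed upper bound on the number of hypotheses.
#' @param gamma weight sequence over the horizon; default uniform
#'   \code{1/Nbound}.
#' @param W0 initial wealth (LORD: \code{alpha/2}; SAFFRON:
#'   \code{(1-lambda)*alpha/2}; ADDIS: \code{(tau-lambda)*alpha/2}).
#' @param lambda candidacy threshold in (0,1) (SAFFRON) or
#'   \code{[0, tau)} (ADDIS family).
#' @param tau discarding threshold in \code{(lambda, 1]}.
#' @return a decision record (see \code{\link{make_decisions}}): data
#'   frame with columns \code{i}, \code{id}, \code{batch}, \code{p},
#'   \code{alphai}, \code{rejected}, and attribute \code{"alpha_next"} —
#'   the level the procedure would assign to the next hypothesis.
#' @examples
#' s <- stampede_pvalues()
#' run_lond(s, alpha = 0.025, Nbound = 20)
#' @name online_procedures
NULL

check_horizon <- function(m, gamma) {
  if (m > length(gamma)) {
    stop("stream has ", m, " hypotheses but the gamma horizon is only ",
         length(gamma), "; Nbound must be chosen at least as large as the ",
         "number of hypotheses tested")
  }
}

#' @rdname online_procedures
#' @export
run_uncorrected <- function(stream, alpha) {
  stream <- as_pstream(stream)
  make_decisions(stream, rep(alpha, nrow(stream)), alpha_next = alpha)
}

#' @rdname online_procedures
#' @export
run_bonferroni <- function(stream, alpha, Nbound) {
  stream <- as_pstream(stream)
  check_horizon(nrow(stream), numeric(Nbound))
  lev <- alpha / Nbound
  make_decisions(stream, rep(lev, nrow(stream)), alpha_next = lev)
}

#' @rdname online_procedures
#' @export
run_lond <- function(stream, alpha, Nbound,
                     gamma = gamma_sequence(Nbound)) {
  stream <- as_pstream(stream)
  m <- nrow(stream)
  check_horizon(m, gamma)
  alphai <- numeric(m)
  D <- 0L
  rejected <- logical(m)
  for (i in seq_len(m)) {
    alphai[i] <- alpha * gamma[i] * (D + 1L)
    rejected[i] <- stream$p[i] <= alphai[i]
    if (rejected[i]) D <- D + 1L
  }
  nxt <- if (m + 1 <= length(gamma)) alpha * gamma[m + 1] * (D + 1L) else NA_real_
  make_decisions(stream, alphai, alpha_next = nxt, rejected = rejected)
}

# LORD++ level at position i given discovery times tau (all < i)
lord_level <- function(i, tau, alpha, gamma, W0) {
  val <- gamma_at(gamma, i) * W0
  if (length(tau) >= 1) {
    val <- val + (alpha - W0) * gamma_at(gamma, i - tau[1])
  }
  if (length(tau) >= 2) {
    val <- val + alpha * sum(gamma_at(gamma, i - tau[-1]))
  }
  val
}

#' @rdname online_procedures
#' @export
run_lord <- function(stream, alpha, Nbound,
                     gamma = gamma_sequence(Nbound), W0 = alpha / 2) {
  stream <- as_pstream(stream)
  if (W0 <= 0 || W0 > alpha) stop("W0 must satisfy 0 < W0 <= alpha")
  m <- nrow(stream)
  check_horizon(m, gamma)
  alphai <- numeric(m)
  rejected <- logical(m)
  tau <- integer(0)
  for (i in seq_len(m)) {
    alphai[i] <- lord_level(i, tau, alpha, gamma, W0)
    rejected[i] <- stream$p[i] <= alphai[i]
    if (rejected[i]) tau <- c(tau, i)
  }
  make_decisions(stream, alphai,
                 alpha_next = lord_level(m + 1L, tau, alpha, gamma, W0),
                 rejected = rejected)
}

# SAFFRON-type level at (sub)stream position i, given candidate history
# cand[1..i-1] and discovery positions tau (< i). 'budget' is the
# per-discovery earning ((1-lambda)*alpha for SAFFRON, (tau-lambda)*alpha
# for ADDIS); the level is capped at lambda so rejections are candidates.
adaptive_level <- function(i, cand, tau, alpha, gamma, W0, lambda, budget) {
  past <- seq_len(i - 1L)
  c0 <- sum(cand[past])
  val <- W0 * gamma_at(gamma, i - c0)
  if (length(tau) >= 1) {
    cj <- vapply(tau, function(tj) {
      if (tj + 1L > i - 1L) 0L else sum(cand[seq.int(tj + 1L, i - 1L)])
    }, integer(1))
    val <- val + (budget - W0) * gamma_at(gamma, i - tau[1] - cj[1])
    if (length(tau) >= 2) {
      val <- val + budget * sum(gamma_at(gamma, i - tau[-1] - cj[-1]))
    }
  }
  min(lambda, val)
}

#' @rdname online_procedures
#' @export
run_saffron <- function(stream, alpha, Nbound,
                        gamma = gamma_sequence(Nbound), lambda = 0.5,
                        W0 = (1 - lambda) * alpha / 2) {
  stream <- as_pstream(stream)
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie strictly in (0, 1)")
  if (W0 <= 0 || W0 > (1 - lambda) * alpha) {
    stop("W0 must satisfy 0 < W0 <= (1 - lambda) * alpha")
  }
  m <- nrow(stream)
  check_horizon(m, gamma)
  budget <- (1 - lambda) * alpha
  alphai <- numeric(m)
  rejected <- logical(m)
  cand <- logical(m)
  tau <- integer(0)
  for (i in seq_len(m)) {
    alphai[i] <- adaptive_level(i, cand, tau, alpha, gamma, W0, lambda,
                                budget)
    rejected[i] <- stream$p[i] <= alphai[i]
    cand[i] <- stream$p[i] <= lambda
    if (rejected[i]) tau <- c(tau, i)
  }
  nxt <- adaptive_level(m + 1L, cand, tau, alpha, gamma, W0, lambda, budget)
  make_decisions(stream, alphai, alpha_next = nxt, rejected = rejected)
}

#' @rdname online_procedures
#' @export
run_addis <- function(stream, alpha, Nbound,
                      gamma = gamma_sequence(Nbound), lambda = 0.25,
                      tau = 0.5, W0 = (tau - lambda) * alpha / 2) {
  stream <- as_pstream(stream)
  if (lambda < 0 || lambda >= tau || tau > 1) {
    stop("thresholds must satisfy 0 <= lambda < tau <= 1")
  }
  if (W0 <= 0 || W0 > (tau - lambda) * alpha) {
    stop("W0 must satisfy 0 < W0 <= (tau - lambda) * alpha")
  }
  m <- nrow(stream)
  check_horizon(m, gamma)
  budget <- (tau - lambda) * alpha
  alphai <- numeric(m)
  rejected <- logical(m)
  # state over the selected (p <= tau) substream only
  cand <- logical(0)
  disc <- integer(0)   # discovery positions within the substream
  for (i in seq_len(m)) {
    pos <- length(cand) + 1L
    alphai[i] <- adaptive_level(pos, cand, disc, alpha, gamma, W0, lambda,
                                budget)
    p_i <- stream$p[i]
    rejected[i] <- p_i <= alphai[i]
    if (p_i <= tau) {          # selected: advances the substream state
      cand <- c(cand, p_i <= lambda)
      if (rejected[i]) disc <- c(disc, pos)
    }                          # discarded: consumes no wealth
  }
  nxt <- adaptive_level(length(cand) + 1L, cand, disc, alpha, gamma, W0,
                        lambda, budget)
  make_decisions(stream, alphai, alpha_next = nxt, rejected = rejected)
}

#' @rdname online_procedures
#' @export
run_addis_spending <- function(stream, alpha, Nbound,
                               gamma = gamma_sequence(Nbound),
                               lambda = 0.25, tau = 0.5) {
  stream <- as_pstream(stream)
  if (lambda < 0 || lambda >= tau || tau > 1) {
    stop("thresholds must satisfy 0 <= lambda < tau <= 1")
  }
  m <- nrow(stream)
  check_horizon(m, gamma)
  # spending index advances on non-candidate, non-discarded p-values
  spent_before <- c(0L, cumsum(stream$p > lambda & stream$p <= tau))
  alphai <- alpha * (tau - lambda) * gamma_at(gamma, 1L + spent_before[seq_len(m)])
  nxt_idx <- 1L + spent_before[m + 1L]
  nxt <- if (nxt_idx <= length(gamma)) {
    alpha * (tau - lambda) * gamma[nxt_idx]
  } else 0
  make_decisions(stream, alphai, alpha_next = nxt)
}
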