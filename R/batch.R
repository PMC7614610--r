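#' Online batched testing procedures
#'
#' When several arms report together, hypotheses arrive in batches and an
#' offline procedure is run within each batch at a batch level
#' \eqn{\alpha_t} chosen online, so that error control holds across
#' batches. Batch membership is taken from the stream's \code{batch}
#' column (shared entry times); within-batch order is irrelevant to the
#' decisions.
#'
#' Level updates (batch \eqn{t} of size \eqn{n_t}, \eqn{R_{1:t-1}} total
#' rejections in earlier batches, \eqn{\gamma} a weight sequence over the
#' batch horizon):
#' \describe{
#'   \item{\code{run_batch_bh}}{BH within each batch at
#'     \eqn{\alpha_t = \alpha\gamma_t (n_t + R_{1:t-1})/n_t}: each batch
#'     receives a \eqn{\gamma}-share of the budget, scaled up by earlier
#'     discoveries. A single batch with \eqn{\gamma_1 = 1} is exactly
#'     offline BH at \eqn{\alpha}.}
#'   \item{\code{run_batch_prds}}{BH within each batch at
#'     \eqn{\alpha_t = \alpha\gamma_t} (pure cross-batch spending). This
#'     is the variant that remains valid when p-values within a batch are
#'     positively dependent (PRDS) — as induced here by shared concurrent
#'     controls — and independent across batches, since
#'     \eqn{E[V_t/\max(R_t,1)] \le \alpha_t} for BH under PRDS and the
#'     levels sum to at most \eqn{\alpha}.}
#'   \item{\code{run_batch_stbh}}{Storey-BH within each batch
#'     (\code{lambda_storey} tuning), same discovery-earning level update
#'     as \code{run_batch_bh}; a single batch with \eqn{\gamma_1 = 1} is
#'     exactly offline Storey-BH at \eqn{\alpha}.}
#'   \item{\code{run_repeated_bh}, \code{run_repeated_holm}}{naive
#'     comparators: BH (resp. Holm) at full level \eqn{\alpha} within
#'     every batch, with no cross-batch accounting. These do not control
#'     the FDR (FWER) across batches; with batches of size 1 repeated
#'     Holm is exactly uncorrected testing.}
#' }
#'
#' The default batch horizon extrapolates the observed batch sizes to the
#' hypothesis bound: \code{ceiling(Nbound * B / m)} batches for \code{B}
#' observed batches of \code{m} hypotheses in total (equal to
#' \code{Nbound/b} for constant batch size \code{b}), with uniform
#' \eqn{\gamma} unless supplied.
#'
#' @param stream a \code{\link{pvalue_stream}} with a \code{batch} column
#'   (or bare numeric vector: one batch per hypothesis).
#' @param alpha overall FDR (FWER for Holm) level.
#' @param Nbound assumed bound on the total number of hypotheses, used
#'   for the default horizon; defaults to the stream length.
#' @param gamma optional weight sequence over the batch horizon
#'   (non-negative, summing to 1).
#' @param lambda_storey Storey threshold for \code{run_batch_stbh}.
#' @return a decision record (see \code{\link{make_decisions}});
#'   \code{alphai} holds the batch level applied to each hypothesis, and
#'   attribute \code{"alpha_next"} the level a next batch of size 1 would
#'   receive.
#' @examples
#' s <- stampede_pvalues()
#' run_batch_prds(s, alpha = 0.025, Nbound = 20)
#' @name batch_procedures
NULL

batch_gamma <- function(stream, Nbound, gamma) {
  B <- max(stream$batch)
  if (!is.null(gamma)) {
    if (B > length(gamma)) stop("more batches than the gamma horizon")
    return(gamma)
  }
  horizon <- max(B, ceiling(Nbound * B / nrow(stream)))
  gamma_sequence(horizon)
}

run_batched <- function(stream, alpha, Nbound, gamma, inner, earn) {
  stream <- as_pstream(stream)
  if (nrow(stream) == 0) stop("empty stream")
  if (is.null(Nbound)) Nbound <- nrow(stream)
  gamma <- batch_gamma(stream, Nbound, gamma)
  B <- max(stream$batch)
  alphai <- numeric(nrow(stream))
  rejected <- logical(nrow(stream))
  R_prev <- 0L
  for (t in seq_len(B)) {
    idx <- which(stream$batch == t)
    n_t <- length(idx)
    lev <- alpha * gamma[t] * if (earn) (n_t + R_prev) / n_t else 1
    lev <- min(1, lev)
    rej <- inner(stream$p[idx], lev)
    alphai[idx] <- lev
    rejected[idx] <- rej
    R_prev <- R_prev + sum(rej)
  }
  nxt <- if (B + 1 <= length(gamma)) {
    min(1, alpha * gamma[B + 1] * if (earn) (1 + R_prev) else 1)
  } else 0
  make_decisions(stream, alphai, alpha_next = nxt, rejected = rejected)
}

#' @rdname batch_procedures
#' @export
run_batch_bh <- function(stream, alpha, Nbound = NULL, gamma = NULL) {
  run_batched(stream, alpha, Nbound, gamma, inner = bh, earn = TRUE)
}

#' @rdname batch_procedures
#' @export
run_batch_prds <- function(stream, alpha, Nbound = NULL, gamma = NULL) {
  run_batched(stream, alpha, Nbound, gamma, inner = bh, earn = FALSE)
}

#' @rdname batch_procedures
#' @export
run_batch_stbh <- function(stream, alpha, Nbound = NULL, gamma = NULL,
                           lambda_storey = 0.5) {
  run_batched(stream, alpha, Nbound, gamma,
              inner = function(p, q) storey_bh(p, q, lambda_storey),
              earn = TRUE)
}

run_per_batch <- function(stream, alpha, inner) {
  stream <- as_pstream(stream)
  rejected <- logical(nrow(stream))
  for (t in unique(stream$batch)) {
    idx <- which(stream$batch == t)
    rejected[idx] <- inner(stream$p[idx], alpha)
  }
  make_decisions(stream, rep(alpha, nrow(stream)), alpha_next = alpha,
                 rejected = rejected)
}

#' @rdname batch_procedures
#' @export
run_repeated_bh <- function(stream, alpha) run_per_batch(stream, alpha, bh)

#' @rdname batch_procedures
#' @export
run_repeated_holm <- function(stream, alpha) run_per_batch(stream, alpha, holm)
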