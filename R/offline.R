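#' Offline multiple-testing comparators
#'
#' Classical procedures that require all p-values at once, used as
#' comparators and as the within-batch engines of the online batched
#' procedures.
#'
#' \describe{
#'   \item{\code{bh}}{Benjamini-Hochberg step-up at FDR level \code{q}:
#'     reject the \eqn{k} smallest p-values where \eqn{k} is the largest
#'     index with \eqn{p_{(k)} \le kq/M}.}
#'   \item{\code{storey_bh}}{adaptive BH: estimates the null proportion as
#'     \eqn{\hat\pi_0 = (1 + \#\{p > \lambda\}) / (M(1 - \lambda))},
#'     capped at 1, then runs BH at level \eqn{q/\hat\pi_0}.}
#'   \item{\code{holm}}{Holm step-down at FWER level \code{alpha}.}
#' }
#' BH and Holm rejection sets are computed via
#' \code{\link[stats]{p.adjust}}.
#'
#' @param pvalues numeric vector of p-values (any order).
#' @param q FDR level (BH, Storey-BH).
#' @param alpha FWER level (Holm).
#' @param lambda_storey null-proportion tuning threshold in (0,1),
#'   default 0.5.
#' @return logical vector: \code{TRUE} where the hypothesis is rejected.
#' @examples
#' bh(stampede_pvalues()$p, q = 0.025)
#' @export
bh <- function(pvalues, q) {
  stopifnot(is.numeric(pvalues), all(is.finite(pvalues)))
  if (length(pvalues) == 0) return(logical(0))
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' @rdname bh
#' @export
storey_bh <- function(pvalues, q, lambda_storey = 0.5) {
  stopifnot(is.numeric(pvalues), all(is.finite(pvalues)))
  if (lambda_storey <= 0 || lambda_storey >= 1) {
    stop("lambda_storey must lie strictly in (0, 1)")
  }
  M <- length(pvalues)
  if (M == 0) return(logical(0))
  pi0 <- min(1, (1 + sum(pvalues > lambda_storey)) / (M * (1 - lambda_storey)))
  bh(pvalues, q / pi0)
}

#' @rdname bh
#' @export
holm <- function(pvalues, alpha) {
  stopifnot(is.numeric(pvalues), all(is.finite(pvalues)))
  if (length(pvalues) == 0) return(logical(0))
  stats::p.adjust(pvalues, method = "holm") <= alpha
}
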