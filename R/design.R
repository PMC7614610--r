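#' Platform-trial design
#'
#' Structural parameters of one simulated platform trial: \code{K}
#' experimental arms, each enrolling \code{n} patients over a duration of
#' \code{r} time units (so \code{n/r} patients per arm per unit time, which
#' must be an integer), compared against a common control arm that accrues
#' at the same constant rate for the whole trial. Arms enter according to
#' one of four patterns; each arm is tested once, when its \code{n}-th
#' outcome is observed, against the controls enrolled while it was active
#' (its concurrent controls).
#'
#' Entry patterns (arm \eqn{i}, \eqn{i = 1, \ldots, K}):
#' \itemize{
#'   \item \code{"all-at-once"}: \eqn{t_i = 0} (offline testing);
#'   \item \code{"batch"}: batches of size \code{b}, \eqn{t_i = r(j-1)} for
#'     arms in batch \eqn{j};
#'   \item \code{"staggered"}: \eqn{t_i = r(i-1)/s};
#'   \item \code{"one-by-one"}: \eqn{t_i = r(i-1)} (fully online,
#'     non-overlapping windows).
#' }
#'
#' @param K number of experimental arms (integer >= 1).
#' @param n per-arm sample size (default 50).
#' @param r arm duration in time units (default 10); \code{n/r} must be an
#'   integer.
#' @param sigma known outcome standard deviation (default 1).
#' @param mu0 control mean (default 0).
#' @param alpha nominal one-sided error level (default 0.025).
#' @param Nbound assumed upper bound on the total number of arms
#'   (default \code{K}; must be >= \code{K}).
#' @param entry entry-pattern name (see Details).
#' @param b batch size for \code{entry = "batch"}; \code{K} must be
#'   divisible by \code{b}.
#' @param s stagger divisor (> 0) for \code{entry = "staggered"}.
#' @return an object of class \code{"trial_design"}: a list with the above
#'   fields plus \code{accrual = n/r} and the entry-time vector \code{t}.
#' @examples
#' trial_design(K = 20, entry = "one-by-one")
#' trial_design(K = 10, entry = "batch", b = 5)
#' @export
trial_design <- function(K, n = 50, r = 10, sigma = 1, mu0 = 0,
                         alpha = 0.025, Nbound = K,
                         entry = c("one-by-one", "all-at-once", "batch",
                                   "staggered"),
                         b = 5, s = 2) {
  entry <- match.arg(entry)
  stopifnot(K >= 1, K == round(K), n >= 1, r > 0, sigma > 0,
            alpha > 0, alpha < 1)
  if (n %% r != 0) {
    stop("'n' must be divisible by 'r' so that the accrual rate n/r is an integer")
  }
  if (Nbound < K) stop("'Nbound' must be at least K")
  t <- make_entry_times(entry, K = K, r = r, b = b, s = s)
  structure(
    list(K = as.integer(K), n = as.integer(n), r = r, sigma = sigma,
         mu0 = mu0, alpha = alpha, Nbound = as.integer(Nbound),
         entry = entry, b = b, s = s, accrual = as.integer(n / r), t = t),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Platform-trial design:", x$K, "arms vs shared control\n")
  cat("  n =", x$n, " r =", x$r, " accrual =", x$accrual,
      "/unit time  sigma =", x$sigma, "\n")
  cat("  entry:", x$entry,
      if (x$entry == "batch") paste0("(b = ", x$b, ")"),
      if (x$entry == "staggered") paste0("(s = ", x$s, ")"), "\n")
  cat("  alpha =", x$alpha, " Nbound =", x$Nbound, "\n")
  invisible(x)
}

#' Arm entry times for a given entry pattern
#'
#' @param pattern one of \code{"all-at-once"}, \code{"batch"},
#'   \code{"staggered"}, \code{"one-by-one"}.
#' @param K number of arms.
#' @param r arm duration.
#' @param b batch size (batch pattern only).
#' @param s stagger divisor (staggered pattern only).
#' @return non-decreasing numeric vector of \code{K} entry times, starting
#'   at 0.
#' @examples
#' make_entry_times("one-by-one", K = 3, r = 10)   # 0 10 20
#' make_entry_times("staggered", K = 3, r = 10, s = 2)  # 0 5 10
#' @export
make_entry_times <- function(pattern, K, r, b = 5, s = 2) {
  stopifnot(K >= 1, r > 0)
  i <- seq_len(K)
  t <- switch(pattern,
    "all-at-once" = rep(0, K),
    "one-by-one"  = r * (i - 1),
    "batch" = {
      if (K %% b != 0) stop("K must be divisible by the batch size b")
      r * (ceiling(i / b) - 1)
    },
    "staggered" = {
      if (s <= 0) stop("stagger divisor s must be positive")
      r * (i - 1) / s
    },
    stop("unknown entry pattern: ", pattern)
  )
  stopifnot(!is.unsorted(t))
  t
}

#' Treatment-mean scenarios
#'
#' Builds the vector of true treatment means \eqn{\mu_1, \ldots, \mu_K}
#' for one of three scenarios, and flags the non-null arms
#' (\eqn{\mu_i - \mu_0 > 0}):
#' \itemize{
#'   \item \code{"global-null"}: all \eqn{\mu_i = 0};
#'   \item \code{"fixed"}: \code{m} effective treatments with mean
#'     \code{effect} (default 0.5), placed at the start (\code{"early"}),
#'     the end (\code{"late"}), or at random positions (\code{"random"});
#'   \item \code{"staircase"}: \eqn{\mu_i = (i - \lceil K/2\rceil)/K}
#'     (\code{"increasing"}), its reverse
#'     \eqn{(\lceil K/2\rceil - i + 1)/K} (\code{"decreasing"}), or a
#'     random permutation of the increasing values (\code{"random"}).
#'     Arms with negative means are conservative nulls.
#' }
#'
#' @param name scenario name.
#' @param K number of arms.
#' @param m number of effective treatments (fixed scenario; \code{1 <= m <= K}).
#' @param ordering placement of effects: \code{"early"}, \code{"late"} or
#'   \code{"random"} for fixed; \code{"increasing"}, \code{"decreasing"} or
#'   \code{"random"} for staircase.
#' @param effect effective-treatment mean for the fixed scenario
#'   (default 0.5).
#' @param mu0 control mean used to flag non-nulls (default 0).
#' @return list with \code{mu} (length \code{K}) and logical
#'   \code{nonnull}.
#' @examples
#' make_treatment_means("fixed", K = 5, m = 2, ordering = "early")
#' make_treatment_means("staircase", K = 5, ordering = "increasing")
#' @export
make_treatment_means <- function(name = c("global-null", "fixed", "staircase"),
                                 K, m = 1, ordering = "early",
                                 effect = 0.5, mu0 = 0) {
  name <- match.arg(name)
  stopifnot(K >= 1)
  mu <- switch(name,
    "global-null" = rep(0, K),
    "fixed" = {
      if (m < 1 || m > K) stop("'m' must satisfy 1 <= m <= K")
      idx <- switch(ordering,
        early  = seq_len(m),
        late   = seq.int(K - m + 1L, K),
        random = sample.int(K, m),
        stop("unknown ordering for fixed scenario: ", ordering)
      )
      mu <- rep(0, K)
      mu[idx] <- effect
      mu
    },
    "staircase" = {
      base <- (seq_len(K) - ceiling(K / 2)) / K
      switch(ordering,
        increasing = base,
        decreasing = (ceiling(K / 2) - seq_len(K) + 1) / K,
        random     = sample(base),
        stop("unknown ordering for staircase scenario: ", ordering)
      )
    }
  )
  list(mu = mu, nonnull = mu - mu0 > 0)
}

#' Concurrent-control counts and index sets
#'
#' Control patients arrive at a constant rate of \code{accrual} per unit
#' time for the whole trial, patient \eqn{j} at time \eqn{(j-1)/}
#' \code{accrual}. Arm \eqn{i}'s concurrent controls are those arriving in
#' the half-open window \eqn{[t_i, t_i + r)}; with constant accrual every
#' arm active for its full duration has \eqn{N_0(i) = } \code{accrual}
#' \eqn{\times r} concurrent controls. Overlapping arm windows share
#' control patients (the source of positive dependence between test
#' statistics); abutting one-by-one windows share none.
#'
#' @param t vector of arm entry times (non-decreasing).
#' @param r arm duration.
#' @param accrual control patients per unit time (integer).
#' @return list with integer vector \code{N0} and list \code{sets} of
#'   control patient indices per arm.
#' @examples
#' concurrent_control_sets(c(0, 10, 20), r = 10, accrual = 5)
#' @export
concurrent_control_sets <- function(t, r, accrual) {
  stopifnot(length(t) >= 1, !is.unsorted(t), r > 0, accrual >= 1)
  total <- (max(t) + r) * accrual
  arrive <- (seq_len(total) - 1) / accrual   # arrival time of control j
  sets <- lapply(t, function(ti) which(arrive >= ti & arrive < ti + r))
  list(N0 = vapply(sets, length, integer(1)), sets = sets)
}
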