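#' Simulate platform-trial test statistics
#'
#' Draws patient-level outcomes \eqn{X_{ij} \sim N(\mu_i, \sigma^2)} for
#' the \code{n} patients on each experimental arm and for every control
#' patient (rate \code{n/r} per unit time over the whole trial), then forms
#' for each arm \eqn{i} the treatment mean \eqn{\bar X_i}, the concurrent
#' control mean \eqn{\bar X_{0(i)}} over the \eqn{N_0(i)} controls enrolled
#' while the arm was active, the test statistic
#' \deqn{Z_i = \frac{\bar X_i - \bar X_{0(i)}}
#'                  {\sigma\sqrt{1/N_0(i) + 1/n}},}
#' and the one-sided p-value \eqn{p_i = P(N(0,1) > Z_i)} (upper tail).
#' Under \eqn{\theta_i = \mu_i - \mu_0 = 0} each \eqn{Z_i} is standard
#' normal; arms whose windows overlap share controls and hence have
#' positively correlated statistics (correlation \eqn{n/(n + N_0)} = 0.5
#' when all arms run concurrently with \eqn{N_0 = n}).
#'
#' \code{simulate_replicates} is the vectorised engine returning matrices
#' over many replicates; \code{simulate_replicate} wraps one replicate as a
#' tidy per-arm data frame in entry-time order (ties broken by arm index),
#' with batch labels derived from shared entry times.
#'
#' @param design a \code{\link{trial_design}}.
#' @param mu vector of \code{K} true treatment means (e.g. from
#'   \code{\link{make_treatment_means}}); defaults to the global null.
#' @param nreps number of independent replicates.
#' @return \code{simulate_replicates}: list with \code{K x nreps} matrices
#'   \code{z} and \code{p}, plus \code{N0}, \code{batch} and
#'   \code{nonnull} vectors. \code{simulate_replicate}: data frame with
#'   one row per arm (columns \code{arm}, \code{t_entry}, \code{t_exit},
#'   \code{batch}, \code{xbar}, \code{xbar0}, \code{N0}, \code{z},
#'   \code{p}, \code{nonnull}).
#' @examples
#' d <- trial_design(K = 3, entry = "one-by-one")
#' simulate_replicate(d, mu = c(0.5, 0, 0))
#' @export
simulate_replicates <- function(design, mu = rep(design$mu0, design$K),
                                nreps = 1L) {
  stopifnot(inherits(design, "trial_design"), length(mu) == design$K,
            nreps >= 1)
  K <- design$K; n <- design$n; sigma <- design$sigma
  cc <- concurrent_control_sets(design$t, design$r, design$accrual)
  N0 <- cc$N0
  nctrl <- (max(design$t) + design$r) * design$accrual

  # controls: nctrl x nreps; concurrent means by window slice
  ctrl <- matrix(stats::rnorm(nctrl * nreps, design$mu0, sigma),
                 nrow = nctrl, ncol = nreps)
  xbar0 <- matrix(0, K, nreps)
  for (i in seq_len(K)) {
    idx <- cc$sets[[i]]
    xbar0[i, ] <- .colSums(ctrl[idx, , drop = FALSE], length(idx), nreps) /
      length(idx)
  }

  # treatments: per-arm means of n draws, arms stacked
  trt <- matrix(stats::rnorm(K * n * nreps, mean = rep(mu, each = n),
                             sd = sigma),
                nrow = K * n, ncol = nreps)
  xbar <- rowsum(trt, group = rep(seq_len(K), each = n)) / n

  se <- sigma * sqrt(1 / N0 + 1 / n)
  z <- (xbar - xbar0) / se
  p <- stats::pnorm(z, lower.tail = FALSE)

  list(z = z, p = p, xbar = xbar, xbar0 = xbar0, N0 = N0,
       batch = match(design$t, unique(design$t)),
       nonnull = mu - design$mu0 > 0)
}

#' @rdname simulate_replicates
#' @export
simulate_replicate <- function(design, mu = rep(design$mu0, design$K)) {
  sim <- simulate_replicates(design, mu, nreps = 1L)
  ord <- order(design$t, seq_len(design$K))  # entry order, index tie-break
  data.frame(
    arm = ord,
    t_entry = design$t[ord],
    t_exit = design$t[ord] + design$r,
    batch = sim$batch[ord],
    xbar = sim$xbar[ord, 1],
    xbar0 = sim$xbar0[ord, 1],
    N0 = sim$N0[ord],
    z = sim$z[ord, 1],
    p = sim$p[ord, 1],
    nonnull = sim$nonnull[ord]
  )
}

#' Deterministic per-replicate child seeds
#'
#' One master seed yields a reproducible vector of child seeds so any
#' single replicate can be re-simulated in isolation.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length \code{n}, each below \code{2^31}.
#' @export
derive_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max, n)
}

#' Export simulated replicates as a tidy table
#'
#' Runs \code{nreps} independent replicates of a design/scenario and
#' returns (optionally writes) one row per replicate and arm.
#'
#' @param design a \code{\link{trial_design}}.
#' @param scenario list of arguments to \code{\link{make_treatment_means}}
#'   (\code{name}, and for fixed/staircase scenarios \code{m},
#'   \code{ordering}, \code{effect}). Random orderings are redrawn each
#'   replicate.
#' @param nreps number of replicates.
#' @param seed master seed.
#' @param file optional path to write a CSV.
#' @return data frame with columns \code{replicate}, \code{arm},
#'   \code{t_entry}, \code{batch}, \code{N0}, \code{z}, \code{p},
#'   \code{nonnull}.
#' @export
simulate_to_table <- function(design, scenario = list(name = "global-null"),
                              nreps = 10, seed = 1, file = NULL) {
  seeds <- derive_seeds(seed, nreps)
  out <- vector("list", nreps)
  for (k in seq_len(nreps)) {
    set.seed(seeds[k])
    means <- do.call(make_treatment_means,
                     c(scenario, list(K = design$K, mu0 = design$mu0)))
    rep_k <- simulate_replicate(design, means$mu)
    out[[k]] <- cbind(replicate = k,
                      rep_k[c("arm", "t_entry", "batch", "N0", "z", "p",
                              "nonnull")])
  }
  res <- do.call(rbind, out)
  if (!is.null(file)) utils::write.csv(res, file, row.names = FALSE)
  res
}
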