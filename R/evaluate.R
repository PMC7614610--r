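#' Confusion counts for one replicate
#'
#' @param decisions a decision record (any \code{run_*} procedure) or a
#'   logical rejection vector.
#' @param nonnull logical vector flagging truly non-null hypotheses,
#'   aligned with the decisions.
#' @return one-row data frame with \code{V} (false rejections), \code{R}
#'   (total rejections), \code{S} (true rejections) and \code{m1} (number
#'   of non-nulls); \code{V + S = R}.
#' @examples
#' d <- run_lond(stampede_pvalues(), 0.025, Nbound = 20)
#' confusion_counts(d, nonnull = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
#' @export
confusion_counts <- function(decisions, nonnull) {
  rej <- if (is.data.frame(decisions)) decisions$rejected else decisions
  if (length(rej) != length(nonnull)) {
    stop("decisions and nonnull flags have different lengths")
  }
  data.frame(V = sum(rej & !nonnull), R = sum(rej),
             S = sum(rej & nonnull), m1 = sum(nonnull))
}

#' Monte-Carlo error-rate and power estimates
#'
#' Aggregates per-replicate confusion counts into the four performance
#' measures: FWER \eqn{= P(V \ge 1)}, FDR \eqn{= E[V/\max(R,1)]},
#' disjunctive power \eqn{= P(S \ge 1)} and sensitivity
#' \eqn{= E[S/m_1]}. The power metrics are computed over replicates with
#' at least one non-null hypothesis; if there are none they are reported
#' as \code{NA}. Standard errors are the usual
#' \eqn{\sqrt{\hat v / n_{\mathrm{reps}}}} of the per-replicate indicator
#' or ratio.
#'
#' @param outcomes data frame of per-replicate counts (rows as returned
#'   by \code{\link{confusion_counts}}).
#' @return data frame with columns \code{metric}, \code{estimate},
#'   \code{se}, \code{nreps}.
#' @export
summarize_outcomes <- function(outcomes) {
  stopifnot(nrow(outcomes) >= 1)
  mc <- function(x) {
    n <- length(x)
    data.frame(estimate = mean(x),
               se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
               nreps = n)
  }
  fwer <- mc(as.numeric(outcomes$V >= 1))
  fdr <- mc(outcomes$V / pmax(outcomes$R, 1))
  pow <- outcomes[outcomes$m1 >= 1, , drop = FALSE]
  disj <- if (nrow(pow) > 0) mc(as.numeric(pow$S >= 1)) else {
    data.frame(estimate = NA_real_, se = NA_real_, nreps = 0L)
  }
  sens <- if (nrow(pow) > 0) mc(pow$S / pow$m1) else {
    data.frame(estimate = NA_real_, se = NA_real_, nreps = 0L)
  }
  cbind(metric = c("FWER", "FDR", "disjunctive-power", "sensitivity"),
        rbind(fwer, fdr, disj, sens))
}

#' Named set of testing procedures for a simulation cell
#'
#' Builds closures over a common \code{(alpha, Nbound, gamma)}
#' configuration so that all procedures can be applied to the same
#' simulated p-value streams. Hyperparameters follow the package
#' defaults (LORD \code{W0 = alpha/2}; SAFFRON \code{lambda = 0.5},
#' \code{W0 = (1-lambda)alpha/2}; ADDIS and ADDIS-spending
#' \code{lambda = 0.25}, \code{tau = 0.5}; Storey \code{lambda = 0.5})
#' unless overridden via \code{...}.
#'
#' @param alpha overall error level.
#' @param Nbound hypothesis-count bound (gamma horizon).
#' @param which character vector of procedure names; any of
#'   \code{"uncorrected"}, \code{"bonferroni"}, \code{"lond"},
#'   \code{"lord"}, \code{"saffron"}, \code{"addis"},
#'   \code{"addis-spending"}, \code{"bh"}, \code{"storey-bh"},
#'   \code{"holm"}, \code{"batch-bh"}, \code{"batch-prds"},
#'   \code{"batch-stbh"}, \code{"repeated-bh"}, \code{"repeated-holm"}.
#' @param gamma weight sequence over the \code{Nbound} horizon (fully
#'   online procedures); default uniform.
#' @param ... hyperparameter overrides: \code{W0_lord}, \code{lambda_saffron},
#'   \code{lambda_addis}, \code{tau_addis}, \code{lambda_storey}.
#' @return named list of functions \code{f(stream)} returning decision
#'   records.
#' @export
procedure_set <- function(alpha, Nbound,
                          which = c("uncorrected", "bonferroni", "lond",
                                    "lord"),
                          gamma = gamma_sequence(Nbound), ...) {
  hp <- list(...)
  W0_lord <- hp$W0_lord %||% (alpha / 2)
  l_saf <- hp$lambda_saffron %||% 0.5
  l_add <- hp$lambda_addis %||% 0.25
  t_add <- hp$tau_addis %||% 0.5
  l_sty <- hp$lambda_storey %||% 0.5
  offline_wrap <- function(f) {
    function(stream) {
      stream <- as_pstream(stream)
      make_decisions(stream, rep(alpha, nrow(stream)),
                     rejected = f(stream$p))
    }
  }
  all <- list(
    "uncorrected" = function(stream) run_uncorrected(stream, alpha),
    "bonferroni" = function(stream) run_bonferroni(stream, alpha, Nbound),
    "lond" = function(stream) run_lond(stream, alpha, Nbound, gamma),
    "lord" = function(stream) run_lord(stream, alpha, Nbound, gamma,
                                       W0 = W0_lord),
    "saffron" = function(stream) run_saffron(stream, alpha, Nbound, gamma,
                                             lambda = l_saf),
    "addis" = function(stream) run_addis(stream, alpha, Nbound, gamma,
                                         lambda = l_add, tau = t_add),
    "addis-spending" = function(stream)
      run_addis_spending(stream, alpha, Nbound, gamma,
                         lambda = l_add, tau = t_add),
    "bh" = offline_wrap(function(p) bh(p, alpha)),
    "storey-bh" = offline_wrap(function(p) storey_bh(p, alpha, l_sty)),
    "holm" = offline_wrap(function(p) holm(p, alpha)),
    "batch-bh" = function(stream) run_batch_bh(stream, alpha, Nbound),
    "batch-prds" = function(stream) run_batch_prds(stream, alpha, Nbound),
    "batch-stbh" = function(stream) run_batch_stbh(stream, alpha, Nbound,
                                                   lambda_storey = l_sty),
    "repeated-bh" = function(stream) run_repeated_bh(stream, alpha),
    "repeated-holm" = function(stream) run_repeated_holm(stream, alpha)
  )
  unknown <- setdiff(which, names(all))
  if (length(unknown)) stop("unknown procedure(s): ",
                            paste(unknown, collapse = ", "))
  all[which]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replicated evaluation of procedures on one simulation cell
#'
#' Simulates \code{nreps} platform trials from one design/scenario cell
#' and applies every procedure to the same simulated p-value streams
#' (common random numbers, so procedure contrasts are paired), returning
#' Monte-Carlo estimates of all four metrics per procedure.
#'
#' Hypotheses enter the stream in entry-time order (arm index breaking
#' ties) with batch labels from shared entry times. Scenarios with a
#' random ordering redraw the ordering each replicate.
#'
#' @param design a \code{\link{trial_design}}.
#' @param scenario list of \code{\link{make_treatment_means}} arguments
#'   (\code{name}, \code{m}, \code{ordering}, \code{effect}).
#' @param procedures named list from \code{\link{procedure_set}}.
#' @param nreps number of simulated trials.
#' @param seed integer seed for this cell.
#' @param crn if \code{FALSE}, re-simulates fresh streams for every
#'   procedure instead of sharing them.
#' @return data frame: \code{procedure}, \code{metric}, \code{estimate},
#'   \code{se}, \code{nreps}.
#' @export
evaluate_scenario <- function(design, scenario, procedures, nreps = 10000,
                              seed = 1, crn = TRUE) {
  stopifnot(length(procedures) >= 1, !is.null(names(procedures)))
  ord <- order(design$t, seq_len(design$K))
  run_one_set <- function(seed_offset) {
    set.seed(seed + seed_offset)
    random_order <- !is.null(scenario$ordering) &&
      identical(scenario$ordering, "random")
    if (!random_order) {
      means <- do.call(make_treatment_means,
                       c(scenario, list(K = design$K, mu0 = design$mu0)))
      sim <- simulate_replicates(design, means$mu, nreps)
      pmat <- sim$p[ord, , drop = FALSE]
      nonnull <- matrix(means$nonnull[ord], design$K, nreps)
    } else {
      pmat <- matrix(NA_real_, design$K, nreps)
      nonnull <- matrix(NA, design$K, nreps)
      for (k in seq_len(nreps)) {
        means <- do.call(make_treatment_means,
                         c(scenario, list(K = design$K, mu0 = design$mu0)))
        sim <- simulate_replicates(design, means$mu, 1L)
        pmat[, k] <- sim$p[ord, 1]
        nonnull[, k] <- means$nonnull[ord]
      }
    }
    list(p = pmat, nonnull = nonnull,
         batch = match(design$t[ord], unique(design$t[ord])))
  }
  streams <- run_one_set(0L)
  out <- vector("list", length(procedures))
  for (j in seq_along(procedures)) {
    if (!crn && j > 1) streams <- run_one_set(j - 1L)
    counts <- matrix(0L, nreps, 4L)
    for (k in seq_len(nreps)) {
      stream <- pvalue_stream(streams$p[, k], batch = streams$batch)
      dec <- procedures[[j]](stream)
      nn <- streams$nonnull[, k]
      counts[k, ] <- c(sum(dec$rejected & !nn), sum(dec$rejected),
                       sum(dec$rejected & nn), sum(nn))
    }
    outc <- data.frame(V = counts[, 1], R = counts[, 2], S = counts[, 3],
                       m1 = counts[, 4])
    out[[j]] <- cbind(procedure = names(procedures)[j],
                      summarize_outcomes(outc))
  }
  do.call(rbind, out)
}

#' Run a grid of simulation cells
#'
#' Evaluates a set of procedures over a grid of scenario cells
#' (combinations of \code{K}, \code{Nbound} multiplier, entry pattern and
#' mean scenario), each with its own deterministically derived seed, and
#' returns one tidy table. The same master seed always reproduces the
#' same table.
#'
#' @param cells data frame with one row per cell; columns \code{K},
#'   \code{Nbound} (absolute), \code{entry}, \code{scenario} (name),
#'   and optionally \code{m}, \code{ordering}, \code{b}, \code{s}.
#' @param which character vector of procedure names (see
#'   \code{\link{procedure_set}}).
#' @param alpha nominal level (default 0.025).
#' @param nreps replicates per cell.
#' @param seed master seed.
#' @param n per-arm sample size; \code{r} arm duration.
#' @param r arm duration.
#' @param ... passed to \code{\link{procedure_set}}.
#' @return tidy data frame: cell columns + \code{procedure},
#'   \code{metric}, \code{estimate}, \code{se}, \code{nreps}.
#' @export
run_grid <- function(cells, which = c("uncorrected", "bonferroni", "lond"),
                     alpha = 0.025, nreps = 1000, seed = 1,
                     n = 50, r = 10, ...) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1,
            all(c("K", "Nbound", "entry", "scenario") %in% names(cells)))
  seeds <- derive_seeds(seed, nrow(cells))
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    design <- trial_design(K = cell$K, n = n, r = r, alpha = alpha,
                           Nbound = cell$Nbound, entry = cell$entry,
                           b = cell$b %||% 5, s = cell$s %||% 2)
    scenario <- list(name = cell$scenario)
    if (!is.null(cells$m) && !is.na(cell$m)) scenario$m <- cell$m
    if (!is.null(cells$ordering) && !is.na(cell$ordering)) {
      scenario$ordering <- cell$ordering
    }
    procs <- procedure_set(alpha, cell$Nbound, which = which, ...)
    res <- evaluate_scenario(design, scenario, procs, nreps = nreps,
                             seed = seeds[ci])
    out[[ci]] <- cbind(cell, res, row.names = NULL)
  }
  do.call(rbind, out)
}
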