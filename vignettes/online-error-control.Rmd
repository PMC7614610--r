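---
title: "Online error rate control for platform trials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online error rate control for platform trials: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onlinetrial)
```

## The problem

A platform trial evaluates a growing collection of experimental
treatments against one shared control arm under a single master
protocol. Hypotheses are therefore tested *over time*: when arm $i$
reports, a decision must be made without knowing how many arms will
eventually join, or what their p-values will be. Testing every arm at
the conventional one-sided $\alpha = 0.025$ inflates the familywise
error rate (FWER) badly — under a global null with $K$ independent
comparisons the chance of at least one false claim is $1 - (1 -
\alpha)^K$, about 40% at $K = 20$. The classical fix, Bonferroni at
$\alpha/N_{\mathrm{bound}}$ for a pre-specified bound
$N_{\mathrm{bound}}$ on the number of arms, is valid but can be very
conservative.

Online multiple-testing procedures sit between these extremes: each
hypothesis $H_i$ receives a testing level $\alpha_i$ computed from past
decisions only, and the sequence of levels is engineered so that the
FWER or the false discovery rate (FDR) is controlled at every point of
the stream. This package implements the platform-trial simulation model
needed to study these procedures, the procedures themselves, a
replicated evaluation engine, and a deterministic re-analysis of the
seven reported STAMPEDE prostate-cancer comparisons.

## The trial model

One simulated trial has $K$ experimental arms. Arm $i$ enters at time
$t_i$, enrols $n$ patients over $r$ time units (so $n/r$ patients per
unit time, an integer), and is tested once, when its last outcome is
observed. Outcomes are normal with known variance: $X_{ij} \sim
N(\mu_i, \sigma^2)$ for patients on arm $i$, and $N(\mu_0, \sigma^2)$
on the control, which accrues at the same constant rate $n/r$ for the
whole trial. The effect of interest is $\theta_i = \mu_i - \mu_0$, with
$H_{0i}: \theta_i \le 0$ tested one-sidedly.

Arm $i$ is compared only against its *concurrent* controls — the
$N_{0(i)}$ control patients enrolled during $[t_i, t_i + r)$:
$$Z_i = \frac{\bar X_i - \bar X_{0(i)}}
  {\sigma\sqrt{1/N_{0(i)} + 1/n}}
  \sim N\!\left(\frac{\theta_i}{\sigma\sqrt{1/N_{0(i)} + 1/n}},\, 1\right),
  \qquad p_i = 1 - \Phi(Z_i).$$
With constant accrual every full-duration arm has $N_{0(i)} = n$, so an
effect of $\theta = 0.5$ at $\sigma = 1$, $n = 50$ gives $E[Z_i] =
0.5 / \sqrt{2/50} = 2.5$.

Two modelling choices matter for the dependence structure:

* **Half-open concurrency windows.** $[t_i, t_i + r)$ means arms that
  enter one-by-one ($t_i = r(i-1)$) have *abutting, disjoint* control
  sets, so their $Z_i$ are exactly independent — the setting in which
  the online FDR procedures carry their formal guarantees. Arms with
  overlapping windows share controls and have positively correlated
  statistics, $\mathrm{corr}(Z_i, Z_j) = n/(n + N_0) = 0.5$ when all
  arms run simultaneously with $N_0 = n$. Both limits are verified
  empirically in the test suite.
* **Unit-time accrual blocks.** Patient arrival order within a block is
  irrelevant because only window membership enters the statistics; the
  four entry patterns (all-at-once, batches of $b$, staggered
  $t_i = r(i-1)/s$, one-by-one) all produce integer window boundaries.

The generator emulates an idealised trial. Compared with real platform
trials it has no interim analyses or early stopping, no survival or
binary endpoints, equal per-arm sample sizes, a known $\sigma$, and
accrual that never pauses. A passing simulation study therefore speaks
to the *multiplicity* behaviour of the procedures under this clean
normal model, not to their interaction with adaptive features of real
trials.

## Fully online procedures

All procedures share the level $\alpha$ and a non-negative sequence
$\gamma_1, \ldots, \gamma_{N_\mathrm{bound}}$ summing to one that
apportions the budget over the horizon; exceeding the horizon is an
error rather than a silent renormalisation. The uniform sequence
$\gamma_i = 1/N_{\mathrm{bound}}$ is the default throughout: it makes
LOND's no-discovery floor exactly Bonferroni's $\alpha/N_\mathrm{bound}$
(so the dominance of LOND over Bonferroni is transparent) and it
reproduces the published STAMPEDE next-arm levels for both procedures
to the printed digit. A polynomially decaying alternative
(`gamma_sequence(h, "power")`, $\gamma_i \propto i^{-1.6}$) is provided
for users who expect early hypotheses to matter more; the adaptive
procedures' published STAMPEDE levels evidently used a decaying
sequence, so their rows are reproduced here qualitatively, not
digit-for-digit (see the case-study section below).

With $D(i-1)$ the number of discoveries before $i$ and $\tau_j$ the
time of the $j$-th discovery:

* **LOND** (FDR; valid under independence and positive dependence):
  $\alpha_i = \alpha \gamma_i \,(D(i-1) + 1)$. The $+1$ convention is
  required for the procedure to start at all and matches its published
  behaviour on the STAMPEDE stream.
* **LORD++** (FDR): $\alpha_i = \gamma_i W_0 + (\alpha - W_0)
  \gamma_{i - \tau_1} + \alpha \sum_{j \ge 2} \gamma_{i - \tau_j}$,
  with initial wealth $W_0 \in (0, \alpha]$, default $\alpha/2$.
* **SAFFRON** (FDR): adaptive investing over *candidates*
  ($p \le \lambda$), capped at $\lambda$, with per-discovery budget
  $(1-\lambda)\alpha$ and candidate-discounted $\gamma$ lags (the
  $C_{j+}$ counts). Defaults $\lambda = 0.5$,
  $W_0 = (1-\lambda)\alpha/2$.
* **ADDIS** (FDR): SAFFRON plus *discarding* of hypotheses with
  $p > \tau$, which consume no wealth. Implemented by running the
  SAFFRON update at the hypothesis's position in the non-discarded
  substream with budget $(\tau - \lambda)\alpha$ — an equivalent way of
  writing the selected-count bookkeeping that makes the $\tau = 1$
  reduction to SAFFRON hold decision-for-decision by construction.
  Defaults $\lambda = 0.25$, $\tau = 0.5$.
* **ADDIS-spending** (FWER, strong sense): alpha-spending with
  discarding and candidacy, $\alpha_i = \alpha(\tau - \lambda)
  \gamma_{g(i)}$ where $g(i)$ counts past p-values in
  $(\lambda, \tau]$ plus one. At $\tau = 1, \lambda = 0$ this is plain
  alpha-spending $\alpha \gamma_i$.

Rejection always uses the weak inequality $p_i \le \alpha_i$. Because
exact hyperparameter choices genuinely change the adaptive procedures'
decisions, every default above is surfaced as an argument and recorded
in the decision records the procedures return.

## Batched procedures

When several arms report together, an offline procedure is run within
each batch at a batch-level $\alpha_t$ chosen online. The level updates
used here are deliberately the simplest ones satisfying the defining
contracts of the three published batch procedures:

* **BatchBH** and **BatchStBH**: $\alpha_t = \alpha \gamma_t
  (n_t + R_{1:t-1})/n_t$ — each batch gets a $\gamma$-share of the
  budget, scaled up by earlier discoveries; BH (resp. Storey-BH) runs
  inside the batch. A single batch with $\gamma_1 = 1$ is exactly the
  offline procedure at $\alpha$.
* **BatchPRDS**: $\alpha_t = \alpha \gamma_t$, pure cross-batch
  spending. Within-batch positive dependence (PRDS) — exactly what
  shared concurrent controls induce — is handled by the inner BH bound
  $E[V_t/\max(R_t, 1)] \le \alpha_t$, and the levels sum to at most
  $\alpha$, so FDR control needs no within-batch independence.

The batch-level $\gamma$ horizon extrapolates the observed batch sizes
to the hypothesis bound, $\lceil N_\mathrm{bound} \cdot B / m \rceil$
batches ($= N_\mathrm{bound}/b$ for constant batch size $b$). The naive
comparators `run_repeated_bh()` / `run_repeated_holm()` apply BH/Holm
at full level $\alpha$ in every batch; with batches of size one
repeated Holm *is* uncorrected testing, and the simulation suite
demonstrates its failure to control the FDR across batches.

## Evaluation

`evaluate_scenario()` simulates replicated trials and applies every
procedure to the *same* p-value streams (common random numbers), so
procedure contrasts are paired; a flag disables this. Four measures are
estimated with Monte-Carlo standard errors: FWER $= P(V \ge 1)$, FDR
$= E[V/\max(R,1)]$, disjunctive power $= P(S \ge 1)$ and sensitivity
$= E[S/m_1]$, the latter two over replicates with at least one non-null
arm. Scenarios with random effect placement redraw the placement every
replicate, i.e. the estimates average over the ordering.

Mean scenarios: global null; fixed means ($m$ effective treatments at
$\mu = 0.5$, placed early, late or at random); and a staircase
$\mu_i = (i - \lceil K/2 \rceil)/K$ in increasing, decreasing
(reversed and shifted by $1/K$) or randomly permuted order, whose
negative-mean arms act as conservative nulls — the regime discarding
(ADDIS) is designed for.

Reproducibility: one master seed deterministically derives per-cell and
per-replicate child seeds (`derive_seeds()`), so any grid cell or
single replicate can be regenerated in isolation and the same
configuration always yields an identical results table.

## Numerical and reporting conventions

* Levels are compared to p-values exactly as computed; rounding to the
  4 decimal places in which levels are conventionally printed happens
  only at the presentation layer, and rounds half away from zero
  ($0.00125 \to 0.0013$).
* Degenerate inputs are defined: $K = 1$ designs, empty streams, and
  batches in which everything is discarded all return well-formed
  results; mis-specified inputs ($m > K$, $\lambda \ge \tau$, streams
  longer than the horizon, batch sizes not dividing $K$) are errors.
* Entry-time ties are broken by arm index; batch membership is derived
  from shared entry times.

## Problem sizes

The packaged acceptance run uses 10,000 replicates per simulated
scenario (Monte-Carlo SE on a 40% rate: about 0.5 percentage points;
on a 2.5% FDR: about 0.15). The `analysis/` drivers default to 2,000
replicates per cell, which resolves every qualitative ordering they
report while keeping a full grid run to minutes on one core. Property
tests in the suite use 1,000 random streams per contract.

## The STAMPEDE case study

`stampede_pvalues()` packages the seven reported comparisons (arms B-H
against standard of care) in reporting order with their four reporting
batches; `reproduce_case_study()` applies any procedure set at
$\alpha \in \{0.025, 0.05, 0.1\}$ and also reports $\alpha_8$, the
level the next arm would face. With $N_\mathrm{bound} = 20$ and uniform
$\gamma$, Bonferroni and LOND reproduce the published rejection sets
and all published $\alpha_8$ values exactly; uncorrected testing and
offline BH likewise. The adaptive and batch procedures reproduce the
published *qualitative* picture (only G survives strict control at
$\alpha = 0.025$; adaptive procedures recover C and E as $\alpha$
grows) but not the published levels, which depend on unpublished
hyperparameter choices; these rows are treated as calibration
references, and the package records its own defaults with every run.

```{r case-study}
reproduce_case_study(which = c("uncorrected", "bonferroni", "lond", "bh"))
```

## Known limitations

* Each hypothesis is tested exactly once: no interim looks, futility
  stops or group-sequential extensions, and no accommodation of more
  arms than $N_\mathrm{bound}$.
* The batch level updates are the contract-faithful simple forms
  described above, not the sharpest published variants; their error
  control is verified by simulation in the test suite rather than
  inherited from a proof.
* FDR-controlling procedures do not control the FWER; the simulation
  grid quantifies (rather than bounds) that inflation.
* The generator's normal-known-variance outcomes make p-values exact;
  with estimated variances or non-normal endpoints the levels would be
  approximate in finite samples.
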