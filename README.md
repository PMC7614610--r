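# onlinetrial

Simulation framework for **online error rate control in platform
trials** — trials that evaluate a growing number of experimental
treatments against one shared control arm, with arms entering over
time.

## The problem

When arm *i* of a platform trial reports, its hypothesis
H<sub>0i</sub>: θ<sub>i</sub> ≤ 0 (θ<sub>i</sub> = μ<sub>i</sub> −
μ<sub>0</sub>) must be tested *now*, without knowing how many arms will
follow. Testing every arm at one-sided α = 0.025 inflates the
familywise error rate to 1 − (1 − α)<sup>K</sup> ≈ 40% by K = 20
independent comparisons; Bonferroni at α/N<sub>bound</sub> (with
N<sub>bound</sub> a pre-trial bound on the number of arms) controls it
but wastes power. Online multiple-testing procedures assign each
hypothesis a level α<sub>i</sub> computed from past decisions only,
controlling the FWER or FDR at every point of the stream:

- **LOND**: α<sub>i</sub> = α γ<sub>i</sub> (D(i−1) + 1), where D(i−1)
  counts discoveries so far — FDR control, valid under the positive
  dependence induced by shared controls, and never rejects less than
  Bonferroni;
- **LORD++**: α<sub>i</sub> = γ<sub>i</sub>W<sub>0</sub> +
  (α − W<sub>0</sub>)γ<sub>i−τ1</sub> + α Σ<sub>j≥2</sub>
  γ<sub>i−τj</sub> — alpha-investing, discoveries replenish the budget;
- **SAFFRON** / **ADDIS**: adaptive investing that concentrates the
  budget on candidate p-values (≤ λ) and, for ADDIS, discards p-values
  above τ without spending;
- **ADDIS-spending**: the FWER-controlling spending analogue;
- **BatchBH / BatchPRDS / BatchStBH**: BH-type procedures run within
  reporting batches at online-chosen batch levels;
- offline comparators: BH, Storey-BH, Holm, Bonferroni, uncorrected.

Here γ<sub>1..N<sub>bound</sub></sub> are non-negative weights summing
to 1 (uniform 1/N<sub>bound</sub> by default).

The package provides the trial generator (staggered entry, concurrent
shared controls, Z<sub>i</sub> = (X̄<sub>i</sub> − X̄<sub>0(i)</sub>) /
(σ√(1/N<sub>0(i)</sub> + 1/n)), one-sided p-values), all procedures
above, a replicated evaluation engine for FWER / FDR / disjunctive
power / sensitivity, and a deterministic re-analysis of the seven
reported STAMPEDE prostate-cancer comparisons. It is aimed at trial
statisticians weighing multiplicity strategies for platform protocols
and at methodologists studying online testing at clinical-trial scale
(tens, not thousands, of hypotheses).

## Worked example

LOND on the seven published STAMPEDE p-values, with N<sub>bound</sub> =
20 assumed arms and uniform γ:

```r
library(onlinetrial)
run_lond(stampede_pvalues(), alpha = 0.025, Nbound = 20)
#> Online testing decisions (1 rejection of 7)
#>   i id batch     p  alphai rejected
#> 1 1  B     1 0.450 0.00125    FALSE
#> 2 2  C     1 0.006 0.00125    FALSE
#> 3 3  E     1 0.022 0.00125    FALSE
#> 4 4  D     2 0.847 0.00125    FALSE
#> 5 5  F     2 0.130 0.00125    FALSE
#> 6 6  G     3 0.001 0.00125     TRUE
#> 7 7  H     4 0.266 0.00250    FALSE
#> next testing level: 0.0025
```

Every arm starts at the Bonferroni floor α γ<sub>i</sub> = 0.025/20 =
0.00125; only arm G (abiraterone, p = 0.001) clears it. That discovery
doubles the level for arm H and for the *next* arm to enter the trial
(α<sub>8</sub> = 0.0025) — twice what Bonferroni will ever allow, while
still controlling the FDR. `reproduce_case_study()` tabulates all
procedures at α ∈ {0.025, 0.05, 0.1}.

Simulating the other side of the trade-off (global null, K = 20 arms
entering one-by-one):

```r
d <- trial_design(K = 20, entry = "one-by-one", Nbound = 20)
procs <- procedure_set(0.025, 20, which = c("uncorrected", "lond"))
res <- evaluate_scenario(d, list(name = "global-null"), procs,
                         nreps = 10000, seed = 1)
subset(res, metric == "FWER", c(procedure, estimate, se))
#>     procedure estimate          se
#> 1 uncorrected   0.3962 0.004891314
#> 5        lond   0.0246 0.001549104
```

Uncorrected testing makes at least one false claim in ~40% of trials;
LOND stays at the nominal 2.5%.

## Repository layout

- `R/` — the package: generator, procedures, evaluation engine, case
  study;
- `analysis/01_case_study.R` … `04_batched.R` — numbered drivers that
  re-run the study's analyses at desk scale and write tidy tables to
  `results/`;
- `vignettes/online-error-control.Rmd` — model, procedures,
  assumptions, design choices and limitations;
- `tests/testthat/` — unit, property and acceptance tests (hand-stepped
  oracles for every level update; Monte-Carlo error-control checks).

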