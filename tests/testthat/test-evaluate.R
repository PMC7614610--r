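test_that("confusion counts are exact", {
  nn <- c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)  # C, E, G non-null
  d <- run_lond(stampede_pvalues(), 0.025, Nbound = 20)  # rejects G only
  cc <- confusion_counts(d, nn)
  expect_equal(unlist(cc), c(V = 0, R = 1, S = 1, m1 = 3))

  expect_equal(unlist(confusion_counts(rep(FALSE, 4), rep(FALSE, 4))),
               c(V = 0, R = 0, S = 0, m1 = 0))
  expect_equal(unlist(confusion_counts(rep(TRUE, 5), rep(FALSE, 5))),
               c(V = 5, R = 5, S = 0, m1 = 0))
  expect_error(confusion_counts(rep(TRUE, 3), rep(FALSE, 4)), "lengths")
})

test_that("metric estimates aggregate replicate outcomes as defined", {
  out <- data.frame(V = c(1, 0), R = c(1, 2), S = c(0, 2), m1 = c(2, 2))
  m <- summarize_outcomes(out)
  est <- setNames(m$estimate, m$metric)
  expect_equal(est[["FWER"]], 0.5)
  expect_equal(est[["FDR"]], 0.5)
  expect_equal(est[["disjunctive-power"]], 0.5)
  expect_equal(est[["sensitivity"]], 0.5)

  clean <- summarize_outcomes(data.frame(V = 0, R = 0, S = 0, m1 = 1))
  expect_equal(clean$estimate[clean$metric == "FWER"], 0)
  expect_equal(clean$estimate[clean$metric == "FDR"], 0)

  # no non-null hypotheses anywhere: power metrics are undefined
  gn <- summarize_outcomes(data.frame(V = 1, R = 1, S = 0, m1 = 0))
  expect_true(is.na(gn$estimate[gn$metric == "sensitivity"]))
  expect_equal(gn$estimate[gn$metric == "FDR"], 1)
})

test_that("uncorrected global-null FWER matches the closed form", {
  d <- trial_design(K = 5, entry = "one-by-one", Nbound = 5)
  procs <- procedure_set(0.025, 5, which = c("uncorrected", "bonferroni"))
  res <- evaluate_scenario(d, list(name = "global-null"), procs,
                           nreps = 4000, seed = 801)
  unc <- res[res$procedure == "uncorrected" & res$metric == "FWER", ]
  expect_lt(abs(unc$estimate - (1 - 0.975^5)), 3 * unc$se)
  # any procedure with uniformly smaller levels has smaller FWER (paired)
  bon <- res[res$procedure == "bonferroni" & res$metric == "FWER", ]
  expect_lte(bon$estimate, unc$estimate)
  expect_lt(abs(bon$estimate - (1 - (1 - 0.025 / 5)^5)), 3 * bon$se)
})

test_that("LOND sensitivity dominates Bonferroni replicate by replicate", {
  d <- trial_design(K = 10, entry = "one-by-one", Nbound = 10)
  procs <- procedure_set(0.025, 10, which = c("bonferroni", "lond"))
  res <- evaluate_scenario(d, list(name = "fixed", m = 3, ordering = "early"),
                           procs, nreps = 1500, seed = 802)
  sens <- res[res$metric == "sensitivity", ]
  expect_gte(sens$estimate[sens$procedure == "lond"],
             sens$estimate[sens$procedure == "bonferroni"])
})

test_that("raising Nbound weakly lowers Bonferroni and LOND error and power", {
  # identical seeds pair the streams, so monotonicity in the levels is exact
  res <- list()
  for (Nb in c(5, 10, 25)) {
    d <- trial_design(K = 5, entry = "one-by-one", Nbound = Nb)
    procs <- procedure_set(0.025, Nb, which = c("bonferroni", "lond"))
    res[[as.character(Nb)]] <-
      evaluate_scenario(d, list(name = "fixed", m = 3, ordering = "early"),
                        procs, nreps = 800, seed = 803)
  }
  for (proc in c("bonferroni", "lond")) {
    for (metric in c("FWER", "sensitivity")) {
      vals <- vapply(res, function(r) {
        r$estimate[r$procedure == proc & r$metric == metric]
      }, numeric(1))
      expect_true(all(diff(vals) <= 1e-12))
    }
  }
})

test_that("grid runs are deterministic given the master seed", {
  cells <- expand.grid(K = 5, Nbound = c(5, 10), entry = "one-by-one",
                       scenario = "global-null",
                       stringsAsFactors = FALSE)
  g1 <- run_grid(cells, which = c("uncorrected", "lond"), nreps = 100,
                 seed = 42)
  g2 <- run_grid(cells, which = c("uncorrected", "lond"), nreps = 100,
                 seed = 42)
  expect_identical(g1, g2)
  expect_true(all(g1$estimate >= 0 & g1$estimate <= 1, na.rm = TRUE))
  # FWER >= FDR cell by cell
  wide <- merge(g1[g1$metric == "FWER", ], g1[g1$metric == "FDR", ],
                by = c("K", "Nbound", "procedure"))
  expect_true(all(wide$estimate.x >= wide$estimate.y))
  expect_error(run_grid(data.frame(K = 7, Nbound = 7, entry = "batch",
                                   scenario = "global-null"),
                        nreps = 10),
               "divisible")
})
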