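stampede <- stampede_pvalues()

test_that("bonferroni tests every hypothesis at alpha/Nbound", {
  d <- run_bonferroni(stampede, alpha = 0.025, Nbound = 20)
  expect_equal(d$alphai, rep(0.00125, 7))
  expect_equal(rejected_ids(d), "G")
  d2 <- run_bonferroni(stampede, alpha = 0.1, Nbound = 20)
  expect_equal(rejected_ids(d2), "G")
  # Nbound = 1 reduces to a single uncorrected test
  one <- run_bonferroni(0.02, alpha = 0.025, Nbound = 1)
  expect_true(one$rejected)
  expect_error(run_bonferroni(stampede, 0.025, Nbound = 5), "horizon")
})

test_that("uncorrected testing applies alpha to everything", {
  d <- run_uncorrected(stampede, alpha = 0.025)
  expect_equal(sort(rejected_ids(d)), c("C", "E", "G"))
  expect_equal(attr(d, "alpha_next"), 0.025)
  expect_equal(nrow(run_uncorrected(numeric(0), 0.025)), 0)
  expect_false(any(run_uncorrected(rep(1, 4), 0.025)$rejected))
})

test_that("LOND levels scale with one plus the discovery count", {
  # hand-stepped: alpha*gamma = 0.00125 throughout
  d <- run_lond(c(0.0001, 0.0024, 1), alpha = 0.025, Nbound = 20)
  expect_equal(d$alphai, c(0.00125, 0.0025, 0.00375))
  expect_equal(d$rejected, c(TRUE, TRUE, FALSE))
  # no discoveries: Bonferroni-like floor alpha*gamma_i
  d0 <- run_lond(rep(0.9, 5), alpha = 0.025, Nbound = 20)
  expect_equal(d0$alphai, rep(0.00125, 5))
})

test_that("LORD++ invests wealth per its level formula", {
  g <- gamma_sequence(20)
  # before any discovery the level is gamma_i * W0
  d0 <- run_lord(rep(0.9, 4), alpha = 0.025, Nbound = 20)
  expect_equal(d0$alphai, g[1:4] * 0.0125)
  # total spend without discoveries never exceeds W0 <= alpha
  expect_lt(sum(run_lord(rep(1, 20), 0.025, 20)$alphai), 0.0125 + 1e-12)
  # a discovery at tau_1 = 1 contributes (alpha - W0) * gamma_(i-1)
  d1 <- run_lord(c(0.0001, 0.5), alpha = 0.025, Nbound = 20)
  expect_equal(d1$alphai[2], 0.05 * 0.0125 + 0.0125 * 0.05)  # = 0.00125
  expect_error(run_lord(0.5, 0.025, 20, W0 = 0.05), "W0")
})

test_that("SAFFRON matches a hand-stepped oracle of its update rule", {
  g <- gamma_sequence(20)
  d <- run_saffron(0.9, alpha = 0.025, Nbound = 20)
  expect_equal(d$alphai, min(0.5, (0.5 * 0.025 / 2) * g[1]))

  for (seed in 1:25) {
    set.seed(seed)
    p <- random_stream(15)
    d <- run_saffron(p, alpha = 0.05, Nbound = 20, lambda = 0.4)
    o <- saffron_oracle(p, alpha = 0.05, gamma = g, lambda = 0.4,
                        W0 = (1 - 0.4) * 0.05 / 2)
    expect_equal(d$alphai, o$alphai)
    expect_equal(d$rejected, o$rejected)
  }
  # a single-early-discovery stream against the oracle
  p <- c(0.001, 0.9, 0.9, 0.9)
  d <- run_saffron(p, alpha = 0.025, Nbound = 20, lambda = 0.5)
  o <- saffron_oracle(p, 0.025, g, 0.5, W0 = 0.5 * 0.025 / 2)
  expect_equal(d$alphai, o$alphai)
  expect_error(run_saffron(p, 0.025, 20, lambda = 1.2), "lambda")
})

test_that("ADDIS discards large p-values and otherwise walks the substream", {
  # second hypothesis discarded: third gets the level of substream position 2
  full <- run_addis(c(0.001, 0.6, 0.001), alpha = 0.025, Nbound = 20,
                    lambda = 0.25, tau = 0.5)
  sub <- run_addis(c(0.001, 0.001), alpha = 0.025, Nbound = 20,
                   lambda = 0.25, tau = 0.5)
  expect_equal(full$alphai[3], sub$alphai[2])
  expect_false(full$rejected[2])

  # all p = 1 with tau = 0.5: everything discarded, levels frozen at the start
  d1 <- run_addis(rep(1, 6), alpha = 0.025, Nbound = 20)
  expect_false(any(d1$rejected))
  expect_equal(d1$alphai, rep(d1$alphai[1], 6))
  expect_error(run_addis(0.5, 0.025, 20, lambda = 0.6, tau = 0.5),
               "lambda < tau")
})

test_that("ADDIS with tau = 1 reproduces SAFFRON decision-for-decision", {
  for (seed in 1:40) {
    set.seed(seed)
    p <- random_stream(sample(5:20, 1))
    a <- run_addis(p, alpha = 0.05, Nbound = 20, lambda = 0.25, tau = 1,
                   W0 = (1 - 0.25) * 0.05 / 2)
    s <- run_saffron(p, alpha = 0.05, Nbound = 20, lambda = 0.25,
                     W0 = (1 - 0.25) * 0.05 / 2)
    expect_equal(a$alphai, s$alphai)
    expect_identical(a$rejected, s$rejected)
  }
})

test_that("ADDIS-spending reduces to plain alpha-spending and to Bonferroni", {
  g <- gamma_sequence(20)
  for (seed in 1:20) {
    set.seed(seed)
    p <- random_stream(12)
    d <- run_addis_spending(p, alpha = 0.025, Nbound = 20, lambda = 0,
                            tau = 1)
    expect_equal(d$alphai, 0.025 * g[1:12])  # exactly alpha * gamma_i
    bon <- run_bonferroni(p, 0.025, 20)      # uniform gamma: same decisions
    expect_identical(d$rejected, bon$rejected)
  }
  # discarding freezes the spending index
  d2 <- run_addis_spending(c(0.9, 0.9, 0.01), 0.025, 20)
  expect_equal(d2$alphai, rep(0.025 * 0.25 * g[1], 3))
})

test_that("levels are valid and decisions follow the weak inequality", {
  procs <- procedure_set(0.05, 20,
                         which = c("uncorrected", "bonferroni", "lond",
                                   "lord", "saffron", "addis",
                                   "addis-spending"))
  for (seed in 1:15) {
    set.seed(seed)
    p <- random_stream(18)
    for (f in procs) {
      d <- f(p)
      expect_true(all(d$alphai >= 0 & d$alphai <= 1))
      expect_identical(d$rejected, d$p <= d$alphai)
      an <- attr(d, "alpha_next")
      expect_true(is.na(an) || (an >= 0 && an <= 1))
    }
  }
})

test_that("LOND rejects a superset of Bonferroni under shared uniform gamma", {
  set.seed(500)
  for (i in 1:200) {
    p <- random_stream(sample(3:20, 1))
    lond <- run_lond(p, alpha = 0.025, Nbound = 20)
    bon <- run_bonferroni(p, alpha = 0.025, Nbound = 20)
    expect_true(all(lond$rejected[bon$rejected]))
  }
})

test_that("stream order matters to online procedures", {
  p <- c(0.001, 0.0005, 0.02, 0.7, 0.04)
  a <- run_lond(p, 0.05, Nbound = 5)
  b <- run_lond(rev(p), 0.05, Nbound = 5)
  expect_false(identical(sort(a$p[a$rejected]), sort(b$p[b$rejected])))
})
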