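one_batch <- function(p) pvalue_stream(p, batch = rep(1, length(p)))

test_that("a single batch with full budget reduces to the offline procedure", {
  set.seed(700)
  for (i in 1:100) {
    p <- random_stream(sample(2:12, 1))
    s <- one_batch(p)
    expect_identical(run_batch_bh(s, 0.05, gamma = 1)$rejected, bh(p, 0.05))
    expect_identical(run_batch_prds(s, 0.05, gamma = 1)$rejected, bh(p, 0.05))
    expect_identical(run_batch_stbh(s, 0.05, gamma = 1)$rejected,
                     storey_bh(p, 0.05))
    expect_identical(run_repeated_bh(s, 0.05)$rejected, bh(p, 0.05))
    expect_identical(run_repeated_holm(s, 0.05)$rejected, holm(p, 0.05))
  }
})

test_that("batch levels follow the discovery-earning update", {
  g <- gamma_sequence(4)
  # batch 1 rejects nothing: batch 2 level is alpha * gamma_2
  s <- pvalue_stream(c(0.9, 0.8, 0.5, 0.01), batch = c(1, 1, 2, 2))
  d <- run_batch_bh(s, 0.1, gamma = g)
  expect_equal(unique(d$alphai[1:2]), 0.1 * g[1] * (2 + 0) / 2)
  expect_equal(unique(d$alphai[3:4]), 0.1 * g[2])

  # batch 1 rejects both: batch 2 level earns (n2 + R1)/n2
  s2 <- pvalue_stream(c(1e-5, 1e-5, 0.5, 0.01), batch = c(1, 1, 2, 2))
  d2 <- run_batch_bh(s2, 0.1, gamma = g)
  expect_equal(unique(d2$alphai[3:4]), 0.1 * g[2] * (2 + 2) / 2)

  # BatchPRDS spends alpha * gamma_t regardless of discoveries
  d3 <- run_batch_prds(s2, 0.1, gamma = g)
  expect_equal(d3$alphai, 0.1 * g[c(1, 1, 2, 2)])
})

test_that("within-batch order does not change batched decisions", {
  set.seed(701)
  for (i in 1:20) {
    p <- random_stream(9)
    s <- pvalue_stream(p, id = paste0("H", 1:9), batch = rep(1:3, each = 3))
    perm <- c(sample(1:3), sample(4:6), sample(7:9))
    s2 <- pvalue_stream(p[perm], id = paste0("H", perm),
                        batch = rep(1:3, each = 3))
    for (f in list(run_batch_bh, run_batch_prds, run_batch_stbh)) {
      expect_setequal(rejected_ids(f(s, 0.1, Nbound = 9)),
                      rejected_ids(f(s2, 0.1, Nbound = 9)))
    }
  }
})

test_that("repeated Holm on size-1 batches is uncorrected testing", {
  set.seed(702)
  for (i in 1:50) {
    p <- random_stream(8)
    s <- pvalue_stream(p, batch = 1:8)
    expect_identical(run_repeated_holm(s, 0.05)$rejected,
                     run_uncorrected(p, 0.05)$rejected)
  }
})

test_that("batched FDR is controlled on independent all-null batches, repeated BH is not", {
  set.seed(703)
  nreps <- 4000
  alpha <- 0.05
  batch <- rep(1:2, each = 10)
  fdp <- matrix(0, nreps, 3,
                dimnames = list(NULL, c("batch-bh", "batch-prds",
                                        "repeated-bh")))
  for (k in seq_len(nreps)) {
    s <- pvalue_stream(stats::runif(20), batch = batch)
    for (nm in colnames(fdp)) {
      f <- switch(nm, "batch-bh" = run_batch_bh, "batch-prds" = run_batch_prds,
                  "repeated-bh" = function(s, a, Nbound) run_repeated_bh(s, a))
      R <- sum(f(s, alpha, Nbound = 20)$rejected)
      fdp[k, nm] <- R / max(R, 1)  # all null: V = R
    }
  }
  se <- apply(fdp, 2, stats::sd) / sqrt(nreps)
  expect_lt(mean(fdp[, "batch-bh"]), alpha + 2 * se["batch-bh"])
  expect_lt(mean(fdp[, "batch-prds"]), alpha + 2 * se["batch-prds"])
  # the naive strategy exceeds the nominal level across batches
  expect_gt(mean(fdp[, "repeated-bh"]), alpha + 2 * se["repeated-bh"])
})
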