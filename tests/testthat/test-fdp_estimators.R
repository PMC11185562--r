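test_that("combined, lower-bound and sample estimates match closed forms", {
  expect_equal(as.numeric(combinedFdp(96, 4, r = 1)), 0.08)
  expect_equal(as.numeric(combinedFdp(96, 4, r = 5)), 0.048)
  expect_equal(as.numeric(combinedFdp(10, 0, r = 1)), 0)
  expect_error(combinedFdp(10, 1, r = 0), "positive")

  expect_equal(lowerBoundFdp(96, 4), 0.04)
  expect_equal(lowerBoundFdp(0, 5), 1)
  expect_equal(lowerBoundFdp(0, 0), 0)

  expect_equal(as.numeric(sampleFdp(96, 4, r = 1)), 4 / 96)
  expect_equal(as.numeric(sampleFdp(96, 4, r = 2)), 2 / 96)
  expect_equal(as.numeric(sampleFdp(50, 0, r = 1)), 0)
  expect_error(sampleFdp(0, 3, r = 1), "undefined")
  expect_equal(attr(sampleFdp(96, 4, r = 1), "note"), "not a valid bound")
})

test_that("combined = lower * (1 + 1/r) exactly, before capping", {
  set.seed(3)
  for (i in 1:50) {
    nT <- sample(0:500, 1); nE <- sample(0:200, 1)
    if (nT + nE == 0) nT <- 1
    r <- sample(c(0.5, 1, 2, 5, 8), 1)
    expect_equal(attr(combinedFdp(nT, nE, r), "raw"),
                 lowerBoundFdp(nT, nE) * (1 + 1 / r))
  }
})

test_that("paired counts match hand classification", {
  tab <- DiscoveryTable(
    id = c("T1", "T2", "T3", "E4"),
    label = c(rep("original", 3), "entrapment"),
    score = c(9, 8, 7.5, 7.2),
    pairKey = c(NA, NA, NA, "T4"))   # paired target absent -> -Inf
  cts <- pairedCounts(tab, s = 7)
  expect_equal(cts$n_entrap, 1)
  expect_equal(cts$n_e_ge_s_t_lt, 1)
  expect_equal(cts$n_e_gt_t_ge_s, 0)
  expect_equal(as.numeric(pairedFdp(cts, nTarget = 3)), 0.5)

  tab2 <- DiscoveryTable(
    id = c("T1", "T2", "E2"),
    label = c("original", "original", "entrapment"),
    score = c(9, 8, 8.5),
    pairKey = c(NA, NA, "T2"))
  cts2 <- pairedCounts(tab2, s = 7)
  expect_equal(cts2$n_entrap, 1)
  expect_equal(cts2$n_e_ge_s_t_lt, 0)
  expect_equal(cts2$n_e_gt_t_ge_s, 1)
  expect_equal(as.numeric(pairedFdp(cts2, nTarget = 2)), 1)  # capped
  expect_equal(attr(pairedFdp(cts2, nTarget = 2), "raw"), 3 / 3)

  cts3 <- pairedCounts(tab2, s = 100)
  expect_equal(unlist(cts3[c("n_entrap", "n_e_ge_s_t_lt",
                             "n_e_gt_t_ge_s")]),
               c(n_entrap = 0, n_e_ge_s_t_lt = 0, n_e_gt_t_ge_s = 0))
  expect_equal(as.numeric(pairedFdp(cts3, nTarget = 10)), 0)
})

test_that("paired counts agree with the brute-force classifier", {
  for (i in 1:30) {
    tab <- randomDiscoveryTable(nOrig = 60, nEntrap = 40, seed = i)
    rows <- as.data.frame(tab)
    for (s in quantile(rows$score, c(0.1, 0.5, 0.9))) {
      got <- pairedCounts(tab, s = s)
      want <- bruteForcePairedCounts(rows, s)
      expect_equal(got$n_entrap, want$n_entrap)
      expect_equal(got$n_e_ge_s_t_lt, want$n_e_ge_s_t_lt)
      expect_equal(got$n_e_gt_t_ge_s, want$n_e_gt_t_ge_s)
    }
  }
})

test_that("score ties between entrapment and target break by a seeded coin", {
  tab <- DiscoveryTable(id = c("T1", "E1"),
                        label = c("original", "entrapment"),
                        score = c(5, 5), pairKey = c(NA, "T1"))
  outcomes <- vapply(1:100, function(i)
    pairedCounts(tab, s = 4, seed = i)$n_e_gt_t_ge_s, numeric(1))
  expect_setequal(unique(outcomes), c(0, 1))
  expect_identical(pairedCounts(tab, s = 4, seed = 1),
                   pairedCounts(tab, s = 4, seed = 1))
})

test_that("the k-matched estimator reduces to the paired one at k = 1", {
  tab <- randomDiscoveryTable(seed = 9)
  cts <- pairedCounts(tab, s = 5)
  expect_equal(as.numeric(kMatchedFdp(cts, 40)),
               as.numeric(pairedFdp(cts, 40)))
})

test_that("the k-matched estimate dominates the lower bound", {
  for (i in 1:10) {
    tab <- randomDiscoveryTable(nOrig = 40, nEntrap = 40, seed = 100 + i)
    rows <- as.data.frame(tab)
    s <- quantile(rows$score, 0.3)
    cts <- pairedCounts(tab, s = s)
    cts$k <- 2L
    nT <- sum(rows$label == "original" & rows$score >= s)
    expect_gte(as.numeric(kMatchedFdp(cts, nT)),
               lowerBoundFdp(nT, cts$n_entrap))
  }
})

test_that("k-matched estimator stays an upper bound on null-only data", {
  ## all database peptides absent, k = r = 2: the mean estimate over
  ## replicates must not fall below the mean realized FDP
  cfg <- simConfig(nNative = 0, nAbsent = 300, r = 2, k = 2,
                   nReplicates = 500, seed = 17)
  est <- true <- numeric(cfg$nReplicates)
  set.seed(17)
  for (i in seq_len(cfg$nReplicates)) {
    search <- simulateSearch(cfg, seed = NULL)
    rows <- as.data.frame(search$table)
    disc <- rows[rows$qvalue <= 0.1, , drop = FALSE]
    true[i] <- if (nrow(disc)) mean(disc$known_false) else 0
    if (!nrow(disc)) { est[i] <- 0; next }
    cts <- pairedCounts(search$table, s = min(disc$score), k = 2)
    est[i] <- kMatchedFdp(cts, sum(disc$label == "original"))
  }
  d <- est - true
  expect_gte(mean(d), -2 * sd(d) / sqrt(length(d)))
})

test_that("fdpCurve is consistent with the scalar estimators", {
  tab <- randomDiscoveryTable(nOrig = 80, nEntrap = 50, seed = 12)
  rows <- as.data.frame(tab)
  curve <- fdpCurve(tab, thresholds = 0.5,
                    methods = c("lower", "combined", "sample", "paired"))
  disc <- rows[rows$qvalue <= 0.5, ]
  nT <- sum(disc$label == "original"); nE <- sum(disc$label == "entrapment")
  expect_equal(curve$n_target, nT)
  expect_equal(curve$lower, lowerBoundFdp(nT, nE))
  expect_equal(curve$combined, as.numeric(combinedFdp(nT, nE, 1)))
  expect_equal(curve$sample, as.numeric(sampleFdp(nT, nE, 1)))
  cts <- pairedCounts(tab, s = min(disc$score))
  expect_equal(curve$paired, as.numeric(pairedFdp(cts, nT)))
})

test_that("fdpCurve: empty discovery sets give zero estimates and counts
           grow monotonically", {
  tab <- DiscoveryTable(id = c("T1", "E1"),
                        label = c("original", "entrapment"),
                        score = c(2, 1), qvalue = c(0.9, 0.95),
                        pairKey = c(NA, "T1"))
  curve <- fdpCurve(tab, thresholds = c(0.05, 0.1, 0.5))
  expect_true(all(curve$lower == 0))
  expect_true(all(curve$paired == 0))

  tab2 <- randomDiscoveryTable(seed = 30)
  curve2 <- fdpCurve(tab2, thresholds = seq(0.05, 1, by = 0.05))
  expect_true(all(diff(curve2$n_target + curve2$n_entrap) >= 0))
  expect_error(fdpCurve(tab2, thresholds = c(0.5, 0.1)), "increasing")
})

test_that("lower bound never exceeds the paired estimate along a curve", {
  for (i in 1:10) {
    tab <- randomDiscoveryTable(nOrig = 60, nEntrap = 60, seed = 200 + i)
    curve <- fdpCurve(tab, thresholds = seq(0.1, 1, by = 0.1))
    keep <- curve$n_target + curve$n_entrap > 0
    expect_true(all(curve$lower[keep] <= curve$paired[keep] + 1e-12))
  }
})

test_that("fdpCurve is invariant to row order and id relabeling", {
  tab <- randomDiscoveryTable(seed = 44)
  rows <- as.data.frame(tab)
  perm <- sample(nrow(rows))
  tab2 <- DiscoveryTable(id = rows$id[perm], label = rows$label[perm],
                         score = rows$score[perm],
                         qvalue = rows$qvalue[perm],
                         pairKey = rows$pair_key[perm])
  ids <- unique(c(rows$id, rows$pair_key[!is.na(rows$pair_key)]))
  relab <- setNames(paste0("X", seq_along(ids)), ids)
  tab3 <- DiscoveryTable(id = unname(relab[rows$id]), label = rows$label,
                         score = rows$score, qvalue = rows$qvalue,
                         pairKey = ifelse(is.na(rows$pair_key), NA,
                                          unname(relab[rows$pair_key])))
  th <- seq(0.1, 1, by = 0.1)
  expect_equal(fdpCurve(tab, thresholds = th),
               fdpCurve(tab2, thresholds = th))
  expect_equal(fdpCurve(tab, thresholds = th),
               fdpCurve(tab3, thresholds = th))
})

test_that("coverage bands follow the standard-error reading", {
  d <- 0.01 * sqrt(99 / 100)
  x <- c(rep(0.05 - d, 50), rep(0.05 + d, 50))  # sample sd exactly 0.01
  band <- coverageBand(x)
  expect_equal(band$half_width, 0.00196, tolerance = 1e-10)
  expect_equal(band$n, 100)
  expect_equal(coverageBand(x, literal = TRUE)$half_width, 0.000196)
  expect_equal(coverageBand(rep(0.2, 10))$half_width, 0)
  expect_error(coverageBand(0.5), "at least 2")
})

test_that("inflation rate matches its definition", {
  expect_equal(inflationRate(1000, 950)$rate, 100 * 50 / 950)
  expect_equal(inflationRate(500, 500)$rate, 0)
  expect_lt(inflationRate(900, 1000)$rate, 0)
  expect_error(inflationRate(10, 0), "positive")
})

test_that("directFdp counts known-false discoveries", {
  tab <- DiscoveryTable(id = sprintf("P%03d", 1:100),
                        label = "original", score = 1:100,
                        knownFalse = c(rep(TRUE, 2), rep(FALSE, 98)))
  expect_equal(directFdp(tab), 0.02)
  tabAll <- DiscoveryTable(id = "a", label = "original", score = 1,
                           knownFalse = TRUE)
  expect_equal(directFdp(tabAll), 1)
  tabNone <- DiscoveryTable(id = "a", label = "original", score = 1,
                            knownFalse = FALSE)
  expect_equal(directFdp(tabNone), 0)
})
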