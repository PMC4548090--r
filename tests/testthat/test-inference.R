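test_that("empirical likelihood tracks density and flags unreachable values", {
  set.seed(1)
  v <- rnorm(2000)
  # ratio method: a value at the mode scores ~1, 3 sd out scores much less
  Lm <- empiricalLikelihood(v, mean(v), method = "ratio")
  Lt <- empiricalLikelihood(v, mean(v) + 3 * sd(v), method = "ratio")
  expect_gt(Lm$L, 0.9)
  expect_lt(Lt$L, Lm$L)
  # product method preserves the same ordering within one distribution
  expect_gt(empiricalLikelihood(v, mean(v))$L,
            empiricalLikelihood(v, mean(v) + 3 * sd(v))$L)
  # outside the simulated support (beyond one bandwidth): undefined
  out <- empiricalLikelihood(v, max(v) + 1)
  expect_false(out$defined)
  expect_true(is.na(out$L))
  # degenerate distribution
  expect_equal(empiricalLikelihood(rep(0.3, 60), 0.3)$L, 1)
  expect_false(empiricalLikelihood(rep(0.3, 60), 0.4)$defined)
})

test_that("one-tailed P follows the counting definitions", {
  v <- 1:999 / 1000
  expect_equal(oneTailedP(v, -1), 1 / 1000)        # below all simulated values
  expect_equal(oneTailedP(v, median(v)), 0.5)
  set.seed(2)
  u <- runif(1999)
  expect_lt(abs(oneTailedP(u, 0.9) - 0.10), 0.03)  # counting oracle
  # invariance under monotone rescaling
  expect_equal(oneTailedP(u, 0.9), oneTailedP(exp(u), exp(0.9)))
  expect_equal(oneTailedP(u, 0.2, convention = "below"),
               (sum(u <= 0.2) + 1) / 2000)
})

test_that("AIC weights follow their algebra and are shift-invariant", {
  t1 <- aicTable(c(a = log(0.5), b = log(0.5)))
  expect_equal(t1$dAIC, c(0, 0))
  expect_true(all(t1$equally_plausible))
  # likelihood ratio e^2 -> dAIC = 4, AICw = e^-2
  t2 <- aicTable(c(best = 1, second = 1 - 2))
  expect_equal(t2$dAIC, c(0, 4))
  expect_equal(t2$AICw, c(1, exp(-2)), tolerance = 1e-12)
  expect_equal(sum(t2$AICw_norm), 1)
  # adding a constant to all logL changes nothing downstream
  t3 <- aicTable(c(best = 11, second = 9))
  expect_equal(t3$dAIC, t2$dAIC)
  expect_equal(t3$AICw, t2$AICw)
  # undefined entries stay undefined; all-undefined errors
  t4 <- aicTable(c(a = 0, b = NA))
  expect_true(is.na(t4$dAIC[2]) && !t4$defined[2])
  expect_error(aicTable(c(a = NA_real_, b = NA_real_)), "undefined")
})

test_that("compareScenarios assembles the table and respects shapes", {
  spec <- buildScenario("stability", N0 = 60, nDemes = 2L, tEnd = 30L)
  samp <- SampleConfig(counts = c(5L, 5L))
  lc <- tinyLocus(mu = 3e-4, L = 200L)
  b1 <- runBatch(spec, lc, samp, nReps = 60, rngSeed = 5)
  # single scenario: trivially dAIC = 0 wherever defined
  obs <- list(cp = list(mean_h = median(batchStats(b1)$mean_h),
                        mean_pi = median(batchStats(b1)$mean_pi)))
  cmp <- compareScenarios(list(stability = b1), observed = obs)
  tab <- comparisonTable(cmp)
  expect_true(all(tab$dAIC[tab$defined] == 0))
  expect_equal(tab$P[tab$statistic == "mean_h" & tab$defined], 0.5,
               tolerance = 0.2)
  # a second scenario with a different locus label is a schema error
  b2 <- runBatch(spec, tinyLocus(mu = 3e-4, L = 200L), samp,
                 nReps = 60, rngSeed = 6)
  b2@stats$locus <- "other"
  expect_error(compareScenarios(list(a = b1, b = b2)), "mismatch")
})

test_that("bestScenario sums evidence and penalises impossibility", {
  mk <- function(df) new("ModelComparison", table = df, observed = list(),
                         meta = list())
  df <- data.frame(scenario = rep(c("a", "b"), 2),
                   locus = "cp", statistic = rep(c("mean_h", "mean_pi"), each = 2),
                   dAIC = c(0, 3, 1, 0), defined = TRUE)
  expect_equal(bestScenario(mk(df)), "a")   # total 1 vs 3
  df$defined[3] <- FALSE; df$dAIC[3] <- NA  # "a" cannot produce mean_pi
  expect_equal(bestScenario(mk(df)), "b")
})
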