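test_that("TSS filtering keeps exactly the skilled layers", {
  d <- makeSuitabilityStack(list(nCells = 20, nEnm = 2, nAogcm = 2,
                                 tss = c(rep(0.4, 3), rep(0.7, 9))),
                            rngSeed = 1)
  st <- d$stack
  expect_equal(ncol(stackValues(filterBySkill(st, -1))), 12)  # identity
  expect_message(f <- filterBySkill(st, 0.5), "3 layer")
  expect_equal(ncol(stackValues(f)), 9)
  allLow <- makeSuitabilityStack(list(nCells = 5, tss = 0.2), rngSeed = 1)$stack
  expect_error(filterBySkill(allLow, 0.5), "empty stack")
})

test_that("ensemble is the TSS-weighted mean, order- and scale-invariant", {
  cells <- data.frame(cell_id = c("c1", "c2"), x = 0, y = 0)
  layers <- data.frame(enm = c("E1", "E2"), aogcm = "G1",
                       period = "present", tss = c(0.9, 0.3))
  vals <- cbind(c(1, 0.2), c(0, 0.6))
  st <- SuitabilityStack(cells, vals, layers)
  em <- ensembleMap(st, "present")
  expect_equal(em$suitability[1], (0.9 * 1 + 0.3 * 0) / 1.2)  # 0.75
  # equal weights reduce to the arithmetic mean
  st2 <- SuitabilityStack(cells, vals, transform(layers, tss = 0.5))
  expect_equal(ensembleMap(st2, "present")$suitability, rowMeans(vals))
  # single layer: identity
  st1 <- SuitabilityStack(cells, vals[, 1, drop = FALSE], layers[1, ])
  expect_equal(ensembleMap(st1, "present")$suitability, vals[, 1])
  # uniform weight rescaling and layer order change nothing
  st3 <- SuitabilityStack(cells, vals[, 2:1], transform(layers[2:1, ],
                                                        tss = tss * 2 / 2))
  expect_equal(ensembleMap(st3, "present")$suitability, em$suitability)
  expect_error(ensembleMap(st, "LGM"), "no layers")
})

test_that("range size counts threshold exceedances", {
  v <- c(seq(0, 0.45, length.out = 13), seq(0.5, 1, length.out = 7))
  expect_equal(rangeSize(v, 0), 20)
  expect_equal(rangeSize(v, 1 + 1e-9), 0)
  expect_equal(rangeSize(v, 0.5), 7)
})

test_that("map classification follows the range-shift definition", {
  expect_equal(classifyMap(100, 200), "Expansion")
  expect_equal(classifyMap(150, 150), "Stability")
  expect_equal(classifyMap(200, 100, stabilityTol = 0), "Retraction")
  expect_warning(lab <- classifyMap(0, 0), "undefined")
  expect_true(is.na(lab))
  # antisymmetry: swapping the two periods swaps Expansion and Retraction
  set.seed(6)
  for (i in 1:25) {
    a <- sample(0:300, 1); b <- sample(0:300, 1)
    if (a == 0 && b == 0) next
    l1 <- classifyMap(a, b); l2 <- classifyMap(b, a)
    if (l1 == "Stability") expect_equal(l2, "Stability")
    if (l1 == "Expansion") expect_equal(l2, "Retraction")
    if (l1 == "Retraction") expect_equal(l2, "Expansion")
  }
})

test_that("scenario frequencies reproduce a designed 13 x 4 stack", {
  labs <- rep("Stability", 52)
  labs[1:34] <- "Expansion"
  d <- makeSuitabilityStack(list(nCells = 150, nEnm = 13, nAogcm = 4,
                                 cellSd = 0.12, shiftLabels = labs,
                                 shiftDelta = 0.2),
                            rngSeed = 3)
  sf <- scenarioFrequencies(d$stack, threshold = 0.5, stabilityTol = 0.05)
  expect_equal(unname(sf$percent["Expansion"]), round(100 * 34 / 52, 1))
  expect_equal(nrow(sf$records), 52)
  # all pairs identical across periods: 100% stability
  d2 <- makeSuitabilityStack(list(nCells = 40, nEnm = 2, nAogcm = 2,
                                  cellSd = 0.2), rngSeed = 4)
  sf2 <- scenarioFrequencies(d2$stack)
  expect_equal(unname(sf2$percent["Stability"]), 100)
})

test_that("refugium rule is a per-period conjunction with monotone nesting", {
  cells <- data.frame(cell_id = paste0("c", 1:3), x = 0, y = 0)
  mk <- function(v) cbind(cells, suitability = v)
  maps <- list(LGM = mk(c(0.6, 0.6, 1)), mid = mk(c(0.7, 0.7, 1)),
               present = mk(c(0.5, 0.49, 1)))
  expect_equal(refugium(maps, 0.5), c("c1", "c3"))  # 0.49 excluded, 0.5 kept
  expect_equal(refugium(maps, 0), c("c1", "c2", "c3"))
  # nesting across the published sensitivity thresholds on a random stack
  d <- makeSuitabilityStack(list(nCells = 200, cellSd = 0.25, sdInter = 0.05),
                            rngSeed = 5)
  cons <- lapply(setNames(unique(stackLayers(d$stack)$period),
                          unique(stackLayers(d$stack)$period)),
                 function(p) ensembleMap(d$stack, p))
  refs <- lapply(c(0.4, 0.5, 0.6, 0.7), function(th) refugium(cons, th))
  for (i in 2:4) expect_true(all(refs[[i]] %in% refs[[i - 1]]))
})

test_that("occurrence percentile ranks thresholds correctly", {
  cells <- data.frame(cell_id = paste0("c", 1:1000), x = 0, y = 0)
  set.seed(8)
  v <- runif(1000)
  map <- cbind(cells, suitability = v)
  occ <- cells$cell_id
  expect_lt(abs(occurrencePercentile(map, occ, 0.1) - 10), 3)
  expect_equal(occurrencePercentile(map, occ, min(v)), 0)
  hi <- cells$cell_id[v > 0.5]
  expect_equal(occurrencePercentile(map, hi, 0.3), 0)  # all above threshold
  expect_error(occurrencePercentile(map, character(), 0.5), "no occurrence")
  # inverse lookup is consistent
  th <- percentileToThreshold(map, occ, 10)
  expect_lte(occurrencePercentile(map, occ, th), 10)
})

test_that("variance partition matches an independent ANOVA fit", {
  d <- makeSuitabilityStack(list(nCells = 6, nEnm = 3, nAogcm = 2,
                                 sdTime = 0.05, sdEnm = 0.04, sdAogcm = 0.03,
                                 sdInter = 0.02), rngSeed = 9)
  st <- d$stack
  vp <- variancePartition(st)
  ly <- stackLayers(st)
  for (ci in 1:6) {
    y <- stackValues(st)[ci, ]
    fit <- aov(y ~ factor(ly$period) + factor(ly$period):factor(ly$enm) +
                 factor(ly$period):factor(ly$aogcm))
    ss <- summary(fit)[[1]][, "Sum Sq"]
    tot <- sum(ss)
    expect_equal(unname(unlist(vp$perCell[ci, 2:5])),
                 unname(ss / tot), tolerance = 1e-8)
  }
  # SS additivity per cell (the residual closes the decomposition exactly)
  expect_equal(rowSums(vp$perCell[, 2:5]), rep(1, 6), tolerance = 1e-10)
})

test_that("variance partition recovers designed variance ratios", {
  # target proportions 50/30/15/5 translated into component sds
  E <- 3; A <- 2; P <- 3
  target <- c(time = 0.5, enm_time = 0.3, aogcm_time = 0.15, residual = 0.05)
  sds <- sqrt(c(target["time"] / (E * A * (P - 1)),
                target["enm_time"] / (A * P * (E - 1)),
                target["aogcm_time"] / (E * P * (A - 1)),
                target["residual"] / (P * (E - 1) * (A - 1)))) * 0.2
  d <- makeSuitabilityStack(list(nCells = 500, nEnm = E, nAogcm = A,
                                 sdTime = sds[1], sdEnm = sds[2],
                                 sdAogcm = sds[3], sdInter = sds[4]),
                            rngSeed = 10)
  vp <- variancePartition(d$stack)
  expect_lt(max(abs(vp$summary - target)), 0.05)
  # pure time effects give proportion 1
  d1 <- makeSuitabilityStack(list(nCells = 30, sdTime = 0.1), rngSeed = 11)
  vp1 <- variancePartition(d1$stack)
  expect_equal(unname(vp1$summary["time"]), 1, tolerance = 1e-9)
  expect_equal(unname(vp1$summary["aogcm_time"]), 0, tolerance = 1e-9)
})
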