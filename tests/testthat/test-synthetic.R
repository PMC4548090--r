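test_that("designed haplotype datasets verify closed-loop against the truth", {
  ds <- makeHaplotypeDataset(list(length = 2100L,
                                  diffMatrix = matrix(c(0, 10, 10, 0), 2),
                                  popCounts = list(P1 = c(`1` = 11, `2` = 5))),
                             rngSeed = 2)
  expect_equal(ds$truth$perPop$h, (16 / 15) * (1 - (121 + 25) / 256),
               tolerance = 1e-12)
  # independent brute-force over the constructed sequences
  expect_equal(nucleotideDiversity(ds$alignment)$pi,
               bruteForcePi(as.character(ds$alignment@seqs)),
               tolerance = 1e-12)
  expect_equal(nucleotideDiversity(ds$alignment)$pi, ds$truth$perPop$pi,
               tolerance = 1e-12)
  # the realised differences are exactly the designed ones
  pd <- pairwiseDifferences(ds$alignment)
  expect_equal(max(pd$d), 10L)
  expect_true(all(pd$d %in% c(0L, 10L)))

  # monomorphic populations are exactly zero
  ds0 <- makeHaplotypeDataset(list(length = 100L,
                                   diffMatrix = matrix(0, 1, 1),
                                   popCounts = list(A = c(`1` = 5),
                                                    B = c(`1` = 7))),
                              rngSeed = 3)
  expect_identical(ds0$truth$perPop$h, c(0, 0))
  expect_identical(nucleotideDiversity(ds0$alignment)$pi, 0)

  # purity: same design + seed -> identical dataset
  ds2 <- makeHaplotypeDataset(list(length = 2100L,
                                   diffMatrix = matrix(c(0, 10, 10, 0), 2),
                                   popCounts = list(P1 = c(`1` = 11, `2` = 5))),
                              rngSeed = 2)
  expect_identical(as.character(ds$alignment@seqs),
                   as.character(ds2$alignment@seqs))

  # infeasible (non star-additive) difference matrices are rejected
  bad <- matrix(c(0, 4, 4, 4, 0, 20, 4, 20, 0), 3)
  expect_error(makeHaplotypeDataset(list(length = 100L, diffMatrix = bad,
                                         popCounts = list(A = c(1, 1, 1)))),
               "star-additive")
})

test_that("a full 21-population design matches the study dimensions", {
  counts <- defaultSampleCounts()
  pops <- sprintf("P%02d", seq_along(counts))
  popCounts <- lapply(seq_along(counts), function(i) {
    n <- counts[i]
    if (i %in% c(1, 6, 8)) setNames(c(n - 4, 4), c(1, i + 1))
    else setNames(n, 1)
  })
  names(popCounts) <- pops
  K <- 22
  D <- matrix(0, K, K)
  D[1, 2:K] <- D[2:K, 1] <- 3
  for (i in 2:(K - 1)) for (j in (i + 1):K) D[i, j] <- D[j, i] <- 6
  ds <- makeHaplotypeDataset(list(length = 2100L, diffMatrix = D,
                                  popCounts = popCounts), rngSeed = 4)
  expect_equal(length(ds$alignment@seqs), sum(counts))
  expect_equal(nrow(ds$truth$perPop), 21)
  expect_equal(sum(ds$truth$perPop$k > 1), 3)
})

test_that("pseudo-observed summaries are pure functions of the seed", {
  samp <- SampleConfig(counts = rep(4L, 3))
  lc <- tinyLocus(mu = 1e-4, L = 250L)
  a <- makePseudoObserved("expansion", N0 = 300, loci = lc, samples = samp,
                          rngSeed = 42, nDemes = 3L, tEnd = 80L)
  b <- makePseudoObserved("expansion", N0 = 300, loci = lc, samples = samp,
                          rngSeed = 42, nDemes = 3L, tEnd = 80L)
  expect_identical(a$observed, b$observed)
  expect_equal(a$truth, "expansion")
})

test_that("designed suitability stacks carry their truth", {
  # time-only variation
  d <- makeSuitabilityStack(list(nCells = 25, sdTime = 0.08), rngSeed = 6)
  expect_equal(unname(d$truth$propExpected["time"]), 1)
  vp <- variancePartition(d$stack)
  expect_equal(unname(vp$summary["time"]), 1, tolerance = 1e-9)
  # a designed refugium block is recovered exactly
  ref <- sprintf("c%04d", 1:12)
  d2 <- makeSuitabilityStack(list(nCells = 60, cellSd = 0.1,
                                  refugiumCells = ref), rngSeed = 7)
  cons <- lapply(setNames(unique(stackLayers(d2$stack)$period),
                          unique(stackLayers(d2$stack)$period)),
                 function(p) ensembleMap(d2$stack, p))
  expect_setequal(refugium(cons, 0.5), ref)
})
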