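test_that("haplotype collapsing matches identity, indel coding and designed counts", {
  # identity: 3 identical + 1 distinct -> k = 2
  a <- alnFrom(c("ACGTACGT", "ACGTACGT", "ACGTACGT", "ACGTACGA"))
  expect_equal(collapseHaplotypes(a)$k, 2L)

  # a 6-bp gap run vs its filled form: 2 haplotypes, 1 coded difference
  gap <- "ACG------TACGTACG"
  fil <- "ACGTTTTTTTACGTACG"
  a2 <- alnFrom(c(gap, fil))
  ht <- collapseHaplotypes(a2, codeIndels = TRUE, minIndelLen = 2L)
  expect_equal(ht$k, 2L)
  pd <- pairwiseDifferences(a2, codeIndels = TRUE, minIndelLen = 2L)
  expect_equal(pd$d[1, 2], 1L)          # the run is one evolutionary event
  expect_equal(pd$L[1, 2], 11L)         # gap columns fall under pairwise deletion

  # counts come back per population, 11/5 by construction
  ds <- makeHaplotypeDataset(list(length = 2100L,
                                  diffMatrix = matrix(c(0, 10, 10, 0), 2),
                                  popCounts = list(P1 = c(`1` = 11, `2` = 5))),
                             rngSeed = 7)
  ht2 <- collapseHaplotypes(ds$alignment, ds$popmap)
  expect_equal(ht2$k, 2L)
  expect_equal(sort(as.integer(ht2$counts)), c(5L, 11L))
  expect_equal(ht2$perPop$n, 16)

  # ragged input is rejected
  expect_error(HaplotypeAlignment(c("ACGT", "ACG")), "ragged")
})

test_that("Nei haplotype diversity matches hand-computed values exactly", {
  expect_identical(haplotypeDiversity(c(14)), 0)
  expect_equal(haplotypeDiversity(c(11, 5)),
               (16 / 15) * (1 - (121 + 25) / 256), tolerance = 1e-12)
  expect_equal(haplotypeDiversity(c(1, 1)), 1)
  expect_warning(h1 <- haplotypeDiversity(c(1)), "n < 2")
  expect_true(is.na(h1))
  expect_error(haplotypeDiversity(c(2, 2), n = 5), "sum to n")
})

test_that("nucleotide diversity and its SD follow the definitions", {
  base <- paste(rep("A", 100), collapse = "")
  three <- paste(c(rep("A", 97), "C", "C", "C"), collapse = "")
  a <- alnFrom(c(base, three))
  nd <- nucleotideDiversity(a)
  expect_equal(nd$pi, 0.03, tolerance = 1e-12)
  # hand-computed Nei total variance for n = 2, L = 100, pi = 0.03:
  # (3 * 0.03) / (3 * 1 * 100) + (2 * 9 / 18) * 0.03^2 = 3e-4 + 9e-4
  expect_equal(nd$sd, sqrt(1.2e-3), tolerance = 1e-12)

  same <- alnFrom(rep(base, 4))
  nd0 <- nucleotideDiversity(same)
  expect_identical(nd0$pi, 0)
  expect_identical(nd0$sd, 0)

  # brute-force oracle on a random 4-sequence fixture
  ra <- randomAln(4, 100, seed = 42)
  expect_equal(nucleotideDiversity(ra)$pi,
               bruteForcePi(as.character(ra@seqs)), tolerance = 1e-12)
})

test_that("h, pi and k are invariant under reordering and duplication", {
  ra <- randomAln(6, 80, seed = 5)
  seqs <- as.character(ra@seqs)
  perm <- alnFrom(unname(seqs[c(3, 1, 6, 2, 5, 4)]))
  expect_equal(nucleotideDiversity(alnFrom(unname(seqs)))$pi,
               nucleotideDiversity(perm)$pi, tolerance = 1e-12)
  k0 <- collapseHaplotypes(alnFrom(unname(seqs)))$k
  dup <- alnFrom(unname(c(seqs, seqs[2])))
  expect_lte(collapseHaplotypes(dup)$k, k0)
})

test_that("Ewens probabilities match the Stirling table and Fu's FS its closed form", {
  # |s(5, k)| = {24, 50, 35, 10, 1}; at theta = 1 the rising factorial is 120
  expect_equal(ewensProbabilities(5, 1), c(24, 50, 35, 10, 1) / 120,
               tolerance = 1e-12)
  for (n in c(2, 10, 30))
    for (th in c(0.1, 1, 10))
      expect_equal(sum(ewensProbabilities(n, th)), 1, tolerance = 1e-9)

  # n = 2 closed form: Pr(K=1) = 1/(1+theta), Pr(K=2) = theta/(1+theta)
  th <- 2.5
  expect_equal(ewensProbabilities(2, th), c(1, th) / (1 + th),
               tolerance = 1e-12)
  ff <- fuFs(2, 2, 1, nSim = 100, rngSeed = 1)
  expect_equal(ff$FS, 0, tolerance = 1e-9)   # S' = 0.5 -> ln(1) = 0
  expect_equal(ff$Sprime, 0.5, tolerance = 1e-12)
  expect_error(fuFs(2, 2, 0), "thetaHat")
  # k = 1: S' = 1, sentinel
  ff1 <- fuFs(1, 10, 0.5, nSim = 50, rngSeed = 1)
  expect_true(is.infinite(ff1$FS) && ff1$degenerate)
})

test_that("theta converts to Ne per ploidy and cross-checks the printed table", {
  mu <- 0.0294 / (2 * 40788.9)      # back-solved from the overall row
  expect_equal(thetaToNe(0.0294, mu, 1), 40788.9, tolerance = 1e-9)
  expect_identical(thetaToNe(0, mu, 1), 0)
  # a per-population theta under the same mu lands on its printed Ne
  expect_equal(thetaToNe(0.00117, mu, 1), 1629.7, tolerance = 5e-3)
  # diploid doubles the denominator
  expect_equal(thetaToNe(0.0294, mu, 2), 40788.9 / 2, tolerance = 1e-9)
  expect_error(thetaToNe(0.1, 0), "mu")
})

test_that("great-circle distances are right on analytic cases", {
  expect_equal(haversineKm(c(10, 20), c(10, 20)), 0)
  expect_equal(haversineKm(c(0, 0), c(0, 180)), pi * 6371, tolerance = 1e-6)
  expect_equal(haversineKm(c(0, 0), c(0, 1)), 2 * pi * 6371 / 360,
               tolerance = 1e-6)
  expect_error(haversineKm(c(100, 0), c(0, 0)), "out of range")
  pm <- PopulationMap(c(a = "P1", b = "P2"),
                      coords = data.frame(pop = c("P1", "P2"),
                                          lat = c(0, 0), lon = c(0, 1)))
  expect_equal(populationDistances(pm)["P1", "P2"], 111.1949, tolerance = 1e-4)
})
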