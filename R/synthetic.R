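#' Build a haplotype alignment with known truth
#'
#' Constructs template haplotypes realising a prescribed pairwise-difference
#' matrix exactly (no back-mutation: template i differs from template 1 at a
#' dedicated block of sites, so the matrix must be star-additive:
#' d[i, j] = d[1, i] + d[1, j] for i, j > 1), then assembles populations from
#' prescribed per-population template counts. The truth record carries
#' hand-computable Nei h and pi per population.
#'
#' @param design List with \code{length} (sites), \code{diffMatrix} (K x K
#'   symmetric, zero diagonal) and \code{popCounts} (named list; each element
#'   an integer vector of per-template counts, named by template index).
#' @param rngSeed Seed; template bases and difference sites are deterministic
#'   functions of it.
#' @return List with \code{alignment} (\linkS4class{HaplotypeAlignment}),
#'   \code{popmap} (\linkS4class{PopulationMap}) and \code{truth} (per-pop
#'   n, k, h, pi and the templates used).
#' @export
makeHaplotypeDataset <- function(design, rngSeed = 1L) {
  L <- design$length
  D <- as.matrix(design$diffMatrix)
  K <- nrow(D)
  if (any(D != t(D)) || any(diag(D) != 0))
    stop("design error: diffMatrix must be symmetric with zero diagonal")
  b <- if (K > 1) D[1, 2:K] else integer()
  if (K > 2) {
    for (i in 2:(K - 1)) for (j in (i + 1):K)
      if (D[i, j] != b[i - 1] + b[j - 1])
        stop("design error: diffMatrix is not star-additive ",
             "(d[i,j] must equal d[1,i] + d[1,j])")
  }
  if (sum(b) > L) stop("design error: differences exceed locus length")
  set.seed(rngSeed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  siteOrder <- sample.int(L)  # deterministic under the seed
  templates <- matrix(rep(ref, K), nrow = K, byrow = TRUE)
  off <- 0L
  for (i in seq_len(K - 1)) {
    if (b[i] == 0) next
    sites <- siteOrder[(off + 1):(off + b[i])]
    off <- off + b[i]
    for (s in sites) {
      alt <- sample(setdiff(bases, ref[s]), 1)
      templates[i + 1, s] <- alt
    }
  }
  tmplSeq <- apply(templates, 1, paste, collapse = "")

  seqs <- character(); pops <- character(); ids <- character()
  truthPop <- list()
  for (p in names(design$popCounts)) {
    counts <- design$popCounts[[p]]
    tid <- as.integer(names(counts))
    if (is.null(names(counts)) || anyNA(tid)) tid <- seq_along(counts)
    n <- sum(counts)
    sid <- sprintf("%s_%02d", p, seq_len(n))
    seqs <- c(seqs, rep(tmplSeq[tid], counts))
    ids <- c(ids, sid)
    pops <- c(pops, rep(p, n))
    # truth: Nei h and pi from the design itself
    h <- if (n >= 2) (n / (n - 1)) * (1 - sum((counts / n)^2)) else NA_real_
    totd <- 0
    if (length(tid) > 1) {
      for (a in seq_along(tid)[-length(tid)])
        for (bb in (a + 1):length(tid))
          totd <- totd + counts[a] * counts[bb] * D[tid[a], tid[bb]]
    }
    pi <- if (n >= 2) totd / choose(n, 2) / L else NA_real_
    truthPop[[p]] <- data.frame(pop = p, n = n, k = sum(counts > 0),
                                h = h, pi = pi)
  }
  names(seqs) <- ids
  aln <- HaplotypeAlignment(seqs, locusLabel = design$label %||% "synthetic",
                            ploidyFactor = design$ploidyFactor %||% 1L)
  popmap <- PopulationMap(setNames(pops, ids), coords = design$coords)
  list(alignment = aln, popmap = popmap,
       truth = list(perPop = do.call(rbind, truthPop),
                    templates = tmplSeq, diffMatrix = D, seed = rngSeed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a suitability stack with known structure
#'
#' Layers follow an additive model per cell:
#' baseline + cell effect + time effect + ENM(time) + AOGCM(time) +
#' interaction, each drawn independently per cell with the given standard
#' deviations, plus optional per-(ENM, AOGCM) range-shift offsets and an
#' optional designated refugium block; values are clamped to [0, 1]. The
#' truth record stores the expected variance-partition proportions and the
#' intended classification labels.
#'
#' @param design List; recognised fields (all optional): \code{nCells} (100),
#'   \code{nEnm} (3), \code{nAogcm} (2), \code{periods}
#'   (LGM, midHolocene, present), \code{baseline} (0.5), \code{cellSd} (0),
#'   \code{sdTime}, \code{sdEnm}, \code{sdAogcm}, \code{sdInter} (all 0),
#'   \code{shiftLabels} (character per (enm, aogcm) pair), \code{shiftDelta}
#'   (0.15), \code{refugiumCells} (cell ids forced suitable in all periods),
#'   \code{tss} (0.7, scalar or per layer), \code{nOccurrences} (0).
#' @param rngSeed Seed.
#' @return List with \code{stack} (\linkS4class{SuitabilityStack}) and
#'   \code{truth}.
#' @export
makeSuitabilityStack <- function(design = list(), rngSeed = 1L) {
  d <- design
  nC <- d$nCells %||% 100L
  E <- d$nEnm %||% 3L; A <- d$nAogcm %||% 2L
  periods <- d$periods %||% c("LGM", "midHolocene", "present")
  P <- length(periods)
  base <- d$baseline %||% 0.5
  set.seed(rngSeed)
  cells <- data.frame(cell_id = sprintf("c%04d", seq_len(nC)),
                      x = runif(nC, -60, -35), y = runif(nC, -25, 0))
  layers <- expand.grid(enm = paste0("ENM", seq_len(E)),
                        aogcm = paste0("GCM", seq_len(A)),
                        period = periods, stringsAsFactors = FALSE)
  layers$tss <- if (length(d$tss %||% 0.7) == 1) rep(d$tss %||% 0.7, nrow(layers))
                else d$tss
  sdT <- d$sdTime %||% 0; sdE <- d$sdEnm %||% 0
  sdA <- d$sdAogcm %||% 0; sdI <- d$sdInter %||% 0
  cellBase <- base + rnorm(nC, 0, d$cellSd %||% 0)
  vals <- matrix(0, nC, nrow(layers))
  Tef <- matrix(rnorm(nC * P, 0, sdT), nC, P)
  Eef <- array(rnorm(nC * E * P, 0, sdE), c(nC, E, P))
  Aef <- array(rnorm(nC * A * P, 0, sdA), c(nC, A, P))
  for (l in seq_len(nrow(layers))) {
    e <- match(layers$enm[l], unique(layers$enm))
    a <- match(layers$aogcm[l], unique(layers$aogcm))
    p <- match(layers$period[l], periods)
    v <- cellBase + Tef[, p] + Eef[, e, p] + Aef[, a, p] +
      rnorm(nC, 0, sdI)
    if (!is.null(d$shiftLabels)) {
      pairIdx <- (a - 1) * E + e
      lab <- d$shiftLabels[pairIdx]
      delta <- d$shiftDelta %||% 0.15
      sgn <- switch(lab, Expansion = 1, Retraction = -1, Stability = 0)
      if (layers$period[l] == "LGM") v <- v - sgn * delta
      if (layers$period[l] == "present") v <- v + sgn * delta
    }
    if (!is.null(d$refugiumCells)) {
      inRef <- cells$cell_id %in% d$refugiumCells
      v[inRef] <- pmax(v[inRef], 0.75)
      v[!inRef] <- pmin(v[!inRef], 0.35)
    }
    vals[, l] <- pmin(1, pmax(0, v))
  }
  occ <- character()
  nOcc <- d$nOccurrences %||% 0L
  if (nOcc > 0) occ <- sample(cells$cell_id, nOcc)
  # expected variance-partition proportions from the generating model
  comp <- c(time = E * A * (P - 1) * sdT^2,
            enm_time = A * P * (E - 1) * sdE^2,
            aogcm_time = E * P * (A - 1) * sdA^2,
            residual = P * (E - 1) * (A - 1) * sdI^2)
  truth <- list(propExpected = if (sum(comp) > 0) comp / sum(comp) else comp,
                shiftLabels = d$shiftLabels,
                refugiumCells = d$refugiumCells, seed = rngSeed)
  list(stack = SuitabilityStack(cells, vals, layers, occ), truth = truth)
}

#' Pseudo-observed summary from a known scenario
#'
#' Runs one coalescent replicate under the named scenario and packages its
#' cross-deme mean diversities as an observed summary, with the generating
#' scenario as truth. Used for scenario self-recovery experiments.
#'
#' @param scenario Scenario name.
#' @param N0 Present deme size.
#' @param loci List of \linkS4class{LocusModel}s.
#' @param samples A \linkS4class{SampleConfig}.
#' @param rngSeed Seed.
#' @param nDemes,tEnd Passed to \code{\link{buildScenario}}.
#' @return List with \code{observed} (as \code{\link{observedSummary}}) and
#'   \code{truth} (generating scenario).
#' @export
makePseudoObserved <- function(scenario, N0 = 10000, loci, samples,
                               rngSeed = 1L, nDemes = 21L, tEnd = 1750L) {
  spec <- buildScenario(scenario, N0 = N0, nDemes = nDemes, tEnd = tEnd)
  rep <- simulateReplicate(spec, loci, samples, rngSeed = rngSeed)
  obs <- lapply(split(rep$means, rep$means$locus), function(m)
    list(mean_h = m$mean_h, mean_pi = m$mean_pi))
  list(observed = obs, truth = scenario, seed = rngSeed)
}
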