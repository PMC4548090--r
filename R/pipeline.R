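#' Per-population diversity report (stats stage)
#'
#' Computes, for each locus, the per-population sample size, number of
#' haplotypes, Nei's haplotype diversity and nucleotide diversity (with SD),
#' plus a cross-population Mean row and a pooled Overall row (both are
#' reported because they answer different questions: the Mean row is the
#' population average the scenario comparison uses; the Overall row pools all
#' samples). Populations with fewer than \code{minDemography} samples are
#' flagged as too small for demographic parameters.
#'
#' @param alignments Named list of \linkS4class{HaplotypeAlignment} (one per
#'   locus).
#' @param popmap A \linkS4class{PopulationMap}.
#' @param outDir Optional output directory for TSV + JSON reports.
#' @param allowPartial Keep going when some samples are missing from the map
#'   (default FALSE: abort listing them).
#' @param minDemography Minimum n for demographic estimation (default 5).
#' @inheritParams collapseHaplotypes
#' @return Named list (per locus) of data.frames in the column order pop, N,
#'   k, h, pi, pi_sd, demography.
#' @export
runStats <- function(alignments, popmap, outDir = NULL, allowPartial = FALSE,
                     minDemography = 5L, codeIndels = TRUE, minIndelLen = 2L) {
  if (is(alignments, "HaplotypeAlignment"))
    alignments <- setNames(list(alignments), locusLabel(alignments))
  out <- list()
  for (lc in names(alignments)) {
    aln <- alignments[[lc]]
    miss <- setdiff(sampleIds(aln), names(popmap@assignment))
    if (length(miss) > 0) {
      if (!allowPartial)
        stop("samples missing from population map: ",
             paste(miss, collapse = ", "))
      warning("dropping samples missing from map: ",
              paste(miss, collapse = ", "))
      keep <- setdiff(sampleIds(aln), miss)
      aln <- HaplotypeAlignment(as.character(aln@seqs)[keep],
                                locusLabel(aln), ploidyFactor(aln))
    }
    ht <- collapseHaplotypes(aln, popmap, codeIndels, minIndelLen)
    rows <- list()
    for (p in ht$perPop$pop) {
      ids <- names(ht$haplotype)[popmap@assignment[names(ht$haplotype)] == p]
      n <- length(ids)
      counts <- as.integer(ht$popCounts[[p]])
      h <- if (n >= 2) haplotypeDiversity(counts) else NA_real_
      if (n >= 2) {
        nd <- nucleotideDiversity(aln, subset = ids, codeIndels = codeIndels,
                                  minIndelLen = minIndelLen)
        pv <- nd$pi; psd <- nd$sd
      } else pv <- psd <- NA_real_
      rows[[p]] <- data.frame(pop = p, N = n, k = length(counts), h = h,
                              pi = pv, pi_sd = psd,
                              demography = if (n < minDemography)
                                "not estimated (n too small)" else "ok")
    }
    tab <- do.call(rbind, rows)
    ok <- !is.na(tab$h)
    meanRow <- data.frame(pop = "Mean", N = NA, k = mean(tab$k),
                          h = mean(tab$h[ok]), pi = mean(tab$pi[ok]),
                          pi_sd = NA_real_, demography = "")
    ndAll <- nucleotideDiversity(aln, codeIndels = codeIndels,
                                 minIndelLen = minIndelLen)
    htAll <- collapseHaplotypes(aln, codeIndels = codeIndels,
                                minIndelLen = minIndelLen)
    overall <- data.frame(pop = "Overall", N = ht$n, k = htAll$k,
                          h = haplotypeDiversity(as.integer(htAll$counts)),
                          pi = ndAll$pi, pi_sd = ndAll$sd, demography = "")
    tab <- rbind(tab, meanRow, overall)
    rownames(tab) <- NULL
    out[[lc]] <- tab
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      .writeResult(tab, file.path(outDir, paste0("diversity_", lc, ".tsv")),
                   .runMeta(extra = list(locus = lc)))
    }
  }
  out
}

#' Scenario comparison report (compare stage)
#'
#' Simulates batches for every scenario at each initial deme size in the
#' config, compares them against the observed summary and writes the
#' comparison tables. Config fields (with defaults): \code{scenarios} (all
#' four), \code{N0} (10000), \code{nDemes} (21), \code{tEnd} (1750),
#' \code{loci} (organellar + nuclear defaults), \code{samples}
#' (\code{SampleConfig()}), \code{nReps} (2000), \code{observed}
#' (\code{observedSummary()}), \code{seed} (1).
#'
#' @param config List, see Details.
#' @param outDir Optional output directory.
#' @return Named list (per N0) of \linkS4class{ModelComparison}.
#' @export
runCompare <- function(config = list(), outDir = NULL) {
  cf <- config
  scen <- cf$scenarios %||% c("stability", "expansion", "retraction",
                              "multiple_refugia")
  N0s <- cf$N0 %||% 10000
  loci <- cf$loci %||% list(organellarLocus(), nuclearLocus())
  samples <- cf$samples %||% SampleConfig()
  nReps <- cf$nReps %||% 2000L
  observed <- cf$observed %||% observedSummary()
  seed <- cf$seed %||% 1L
  set.seed(seed)
  batchSeeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                  length(scen) * length(N0s)),
                       nrow = length(scen),
                       dimnames = list(scen, as.character(N0s)))
  out <- list()
  for (n0 in N0s) {
    batches <- list()
    for (s in scen) {
      spec <- buildScenario(s, N0 = n0, nDemes = cf$nDemes %||% 21L,
                            tEnd = cf$tEnd %||% 1750L)
      batches[[s]] <- runBatch(spec, loci, samples, nReps = nReps,
                               rngSeed = batchSeeds[s, as.character(n0)])
    }
    cmp <- compareScenarios(batches, observed = observed)
    out[[as.character(n0)]] <- cmp
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      .writeResult(cmp@table,
                   file.path(outDir, sprintf("comparison_N0_%s.tsv", n0)),
                   .runMeta(seed, list(N0 = n0, nReps = nReps,
                                       scenarios = scen)))
    }
  }
  out
}

#' ENM post-processing report (enm stage)
#'
#' TSS filtering, per-period ensembles, range-shift classification of the
#' (ENM, AOGCM) map pairs, refugium mapping, occurrence-percentile check and
#' hierarchical variance partition, from a stack or a manifest path. Config
#' fields: \code{tssMin} (0.5), \code{threshold} (0.5), \code{stabilityTol}
#' (0.05).
#'
#' @param stack A \linkS4class{SuitabilityStack} or a manifest CSV path.
#' @param config List of thresholds.
#' @param outDir Optional output directory.
#' @return List with \code{frequencies}, \code{refugium}, \code{variance},
#'   \code{consensus}, \code{occurrencePercentile}.
#' @export
runEnm <- function(stack, config = list(), outDir = NULL) {
  if (is.character(stack)) stack <- readSuitabilityStack(stack)
  tssMin <- config$tssMin %||% 0.5
  thr <- config$threshold %||% 0.5
  tol <- config$stabilityTol %||% 0.05
  periods <- unique(stack@layers$period)
  need <- c("LGM", "present")
  gap <- setdiff(need, periods)
  if (length(gap) > 0) stop("missing period(s): ", paste(gap, collapse = ", "))
  flt <- filterBySkill(stack, tssMin)
  vp <- variancePartition(flt)
  freq <- scenarioFrequencies(flt, threshold = thr, stabilityTol = tol)
  cons <- lapply(setNames(periods, periods),
                 function(p) ensembleMap(flt, p))
  ref <- refugium(cons, threshold = thr)
  occP <- if (length(flt@occurrences) > 0)
    occurrencePercentile(cons[["present"]], flt@occurrences, thr) else NA_real_
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeResult(freq$records, file.path(outDir, "classification.tsv"),
                 .runMeta(extra = list(threshold = thr, tssMin = tssMin)))
    .writeResult(vp$perCell, file.path(outDir, "variance_partition.tsv"),
                 .runMeta(extra = list(summary = as.list(vp$summary))))
    writeLines(ref, file.path(outDir, "refugium_cells.txt"))
    for (p in periods)
      write.table(cons[[p]], file.path(outDir, sprintf("consensus_%s.csv", p)),
                  sep = ",", row.names = FALSE, quote = FALSE)
  }
  list(frequencies = freq, refugium = ref, variance = vp, consensus = cons,
       occurrencePercentile = occP)
}
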