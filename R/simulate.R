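# per-deme haplotype and nucleotide diversity from a variant-site matrix
# (simulated sequences have no gaps, so all L sites are comparable)
.demeStats <- function(tips, L, deme) {
  demes <- sort(unique(deme))
  out <- data.frame(deme = demes, n = NA_real_, h = NA_real_, pi = NA_real_)
  for (i in seq_along(demes)) {
    idx <- which(deme == demes[i])
    nd <- length(idx)
    out$n[i] <- nd
    if (nd < 2) next
    sub <- tips[idx, , drop = FALSE]
    if (ncol(sub) == 0) {
      out$h[i] <- 0; out$pi[i] <- 0
      next
    }
    key <- do.call(paste, c(as.data.frame(sub), sep = ","))
    out$h[i] <- haplotypeDiversity(as.integer(table(key)))
    tot <- 0
    for (a in seq_len(nd - 1))
      for (b in (a + 1):nd)
        tot <- tot + sum(sub[a, ] != sub[b, ])
    out$pi[i] <- tot / choose(nd, 2) / L
  }
  out
}

#' Simulate one replicate: genealogies, sequences and diversity summaries
#'
#' Draws an independent genealogy per locus (loci are unlinked), evolves
#' sequences, and computes per-deme haplotype and nucleotide diversity plus
#' their cross-deme means (over demes with n >= 2) -- the summary statistics
#' the scenario comparison uses.
#'
#' @param spec A \linkS4class{ScenarioSpec}.
#' @param loci List of \linkS4class{LocusModel}s.
#' @param samples A \linkS4class{SampleConfig}.
#' @param rngSeed Optional seed; a fixed seed makes the replicate
#'   bit-reproducible.
#' @param returnAlignments Also keep the simulated alignments (default FALSE).
#' @return Object of class \code{SimReplicate}: list with \code{perDeme}
#'   (data.frame locus, deme, n, h, pi), \code{means} (data.frame locus,
#'   mean_h, mean_pi) and optional \code{alignments}.
#' @export
simulateReplicate <- function(spec, loci, samples, rngSeed = NULL,
                              returnAlignments = FALSE) {
  if (is(loci, "LocusModel")) loci <- list(loci)
  if (!is.null(rngSeed)) set.seed(rngSeed)
  perDeme <- list()
  means <- list()
  alns <- list()
  for (lc in loci) {
    gen <- backwardCoalescent(spec, samples, ploidyFactor = lc@ploidyFactor)
    mv <- .mutateVariants(gen, lc)
    st <- .demeStats(mv$tips, mv$L, gen$tipDeme)
    st$locus <- lc@label
    perDeme[[lc@label]] <- st
    ok <- !is.na(st$h)
    means[[lc@label]] <- data.frame(locus = lc@label,
                                    mean_h = mean(st$h[ok]),
                                    mean_pi = mean(st$pi[ok]))
    if (returnAlignments) {
      bases <- c("A", "C", "G", "T")
      rootChars <- bases[mv$rootSeq]
      seqs <- vapply(seq_len(nrow(mv$tips)), function(i) {
        s <- rootChars
        if (length(mv$sites) > 0) s[mv$sites] <- bases[mv$tips[i, ]]
        paste(s, collapse = "")
      }, character(1))
      names(seqs) <- paste0("t", seq_along(seqs), "_deme", gen$tipDeme)
      alns[[lc@label]] <- HaplotypeAlignment(seqs, lc@label, lc@ploidyFactor)
    }
  }
  structure(list(perDeme = do.call(rbind, perDeme),
                 means = do.call(rbind, means),
                 alignments = if (returnAlignments) alns else NULL,
                 scenario = spec@name, seed = rngSeed),
            class = "SimReplicate")
}

#' @export
print.SimReplicate <- function(x, ...) {
  cat(sprintf("SimReplicate under '%s':\n", x$scenario))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Run a batch of replicates under one scenario
#'
#' Replicates are keyed by (seed, replicate index): per-replicate sub-seeds
#' are drawn once from \code{rngSeed}, so any replicate can be reproduced in
#' isolation and replicates never share randomness. Aborted replicates (MRCA
#' cap hit) are logged and re-drawn from reserve sub-seeds.
#'
#' @inheritParams simulateReplicate
#' @param nReps Number of replicates (default 2000, the study convention; use
#'   fewer for desk-scale runs).
#' @param rngSeed Integer seed for the batch.
#' @return A \linkS4class{SimulationSummary}.
#' @export
runBatch <- function(spec, loci, samples, nReps = 2000L, rngSeed = 1L) {
  stopifnot(nReps >= 1)
  if (is(loci, "LocusModel")) loci <- list(loci)
  set.seed(rngSeed)
  subSeeds <- sample.int(.Machine$integer.max - 1L, nReps + 50L)
  rows <- vector("list", nReps)
  aborted <- 0L
  reserve <- nReps
  for (r in seq_len(nReps)) {
    seed <- subSeeds[r]
    repeat {
      res <- tryCatch(simulateReplicate(spec, loci, samples, rngSeed = seed),
                      error = function(e) e)
      if (!inherits(res, "error")) break
      aborted <- aborted + 1L
      reserve <- reserve + 1L
      if (reserve > length(subSeeds))
        stop("too many aborted replicates: ", conditionMessage(res))
      seed <- subSeeds[reserve]
    }
    m <- res$means
    m$rep <- r
    rows[[r]] <- m
  }
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  if (aborted > 0)
    message(aborted, " replicate(s) hit the generation cap and were re-drawn")
  new("SimulationSummary", stats = stats[, c("rep", "locus", "mean_h", "mean_pi")],
      scenario = spec, seed = as.integer(rngSeed),
      params = list(loci = loci, samples = samples, nReps = nReps,
                    aborted = aborted))
}
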