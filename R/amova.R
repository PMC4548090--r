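#' One-level AMOVA and Phi-ST with permutation test
#'
#' Analysis of molecular variance on the matrix of pairwise sequence
#' differences (Excoffier-style: the difference count plays the role of the
#' squared molecular distance). The among-population variance fraction is
#' reported as Phi-ST (the F_ST analogue for haplotype data), with a
#' non-parametric permutation test shuffling individuals among populations.
#'
#' Populations with fewer than 2 samples are excluded with a warning.
#'
#' @param aln A \linkS4class{HaplotypeAlignment} (or a precomputed symmetric
#'   matrix of pairwise differences with sample ids as dimnames).
#' @param popmap A \linkS4class{PopulationMap}.
#' @param nPerm Number of permutations (default 10000, the study convention).
#' @param rngSeed Optional seed for the permutation test.
#' @param pairwise Also compute the pairwise Phi-ST matrix (default TRUE).
#' @inheritParams collapseHaplotypes
#' @return Object of class \code{StructureResult}: list with
#'   \code{sigmaAmong}, \code{sigmaWithin}, \code{phiST}, \code{p},
#'   \code{pairwisePhi}, \code{ss} (sums of squared differences) and
#'   \code{df}.
#' @export
amovaFst <- function(aln, popmap, nPerm = 10000L, rngSeed = NULL,
                     pairwise = TRUE, codeIndels = TRUE, minIndelLen = 2L) {
  if (is(aln, "HaplotypeAlignment")) {
    d <- pairwiseDifferences(aln, codeIndels, minIndelLen)$d
  } else {
    d <- as.matrix(aln)
  }
  pops <- popmap@assignment[rownames(d)]
  if (anyNA(pops)) stop("samples missing from population map")
  sizes <- table(pops)
  drop <- names(sizes)[sizes < 2]
  if (length(drop) > 0) {
    warning("excluding populations with n < 2: ", paste(drop, collapse = ", "))
    keep <- !(pops %in% drop)
    d <- d[keep, keep]
    pops <- pops[keep]
  }
  if (length(unique(pops)) < 2) stop("need at least 2 populations with n >= 2")
  if (!is.null(rngSeed)) set.seed(rngSeed)

  obs <- .amovaComponents(d, pops)
  perm <- if (nPerm > 0) {
    vapply(seq_len(nPerm), function(b)
      .amovaComponents(d, sample(pops))$phiST, 0)
  } else numeric()
  p <- if (nPerm > 0) (sum(perm >= obs$phiST) + 1) / (nPerm + 1) else NA_real_

  pw <- NULL
  if (pairwise) {
    up <- sort(unique(pops))
    pw <- matrix(NA_real_, length(up), length(up), dimnames = list(up, up))
    diag(pw) <- 0
    for (i in seq_along(up)[-length(up)]) {
      for (j in (i + 1):length(up)) {
        sel <- pops %in% up[c(i, j)]
        pw[i, j] <- pw[j, i] <- .amovaComponents(d[sel, sel], pops[sel])$phiST
      }
    }
  }
  structure(c(obs, list(p = p, pairwisePhi = pw, nPerm = nPerm)),
            class = "StructureResult")
}

# variance components from a squared-distance matrix and population labels
.amovaComponents <- function(d, pops) {
  N <- length(pops)
  P <- length(unique(pops))
  tot <- sum(d[upper.tri(d)]) / N
  within <- 0
  np <- numeric(0)
  for (p in unique(pops)) {
    idx <- which(pops == p)
    np <- c(np, length(idx))
    dp <- d[idx, idx, drop = FALSE]
    within <- within + sum(dp[upper.tri(dp)]) / length(idx)
  }
  among <- tot - within
  dfA <- P - 1
  dfW <- N - P
  msA <- among / dfA
  msW <- within / dfW
  nBar <- (N - sum(np^2) / N) / dfA
  s2w <- msW
  s2a <- (msA - msW) / nBar
  phi <- if (s2a + s2w <= 0) 0 else s2a / (s2a + s2w)
  list(sigmaAmong = s2a, sigmaWithin = s2w, phiST = phi,
       ss = c(total = tot, among = among, within = within),
       df = c(among = dfA, within = dfW))
}

#' @export
print.StructureResult <- function(x, ...) {
  cat(sprintf("AMOVA: Phi-ST = %.4f (p = %s; %d permutations)\n", x$phiST,
              format(x$p, digits = 3), x$nPerm))
  cat(sprintf("  sigma^2 among = %.4f, within = %.4f\n",
              x$sigmaAmong, x$sigmaWithin))
  invisible(x)
}

#' Mantel test of isolation by distance
#'
#' Correlates linearized genetic differentiation, Phi-ST / (1 - Phi-ST),
#' with the logarithm of great-circle distance, by the Mantel matrix
#' permutation test (rows/columns permuted jointly).
#'
#' @param genDist Square symmetric matrix of pairwise Phi-ST (order >= 4).
#' @param geoDist Square symmetric matrix of pairwise distances in km.
#' @param nPerm Permutations (default 10000).
#' @param rngSeed Optional seed.
#' @param linearize Apply Phi/(1 - Phi) to \code{genDist} (default TRUE).
#' @param logGeo log-transform \code{geoDist} (default TRUE).
#' @param cap Replacement value where Phi-ST = 1 makes the linearization
#'   infinite (default 1000, with a warning).
#' @return List with \code{r}, \code{r2}, \code{p}, \code{flagged} (TRUE when
#'   a zero-variance matrix makes the correlation undefined).
#' @export
mantelTest <- function(genDist, geoDist, nPerm = 10000L, rngSeed = NULL,
                       linearize = TRUE, logGeo = TRUE, cap = 1e3) {
  genDist <- as.matrix(genDist); geoDist <- as.matrix(geoDist)
  stopifnot(nrow(genDist) == ncol(genDist), nrow(geoDist) == ncol(geoDist),
            nrow(genDist) == nrow(geoDist))
  if (nrow(genDist) < 4) stop("need matrices of order >= 4")
  if (linearize) {
    ones <- genDist >= 1
    genDist <- genDist / (1 - genDist)
    if (any(ones[upper.tri(ones)])) {
      warning("Phi-ST = 1 entries capped at ", cap, " after linearization")
      genDist[ones] <- cap
    }
  }
  if (logGeo) {
    g <- geoDist
    g[g > 0] <- log(g[g > 0])
    geoDist <- g
  }
  off <- upper.tri(genDist)
  if (sd(genDist[off]) == 0 || sd(geoDist[off]) == 0) {
    warning("zero variance in a distance matrix; Mantel r undefined")
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_, flagged = TRUE))
  }
  if (!is.null(rngSeed)) set.seed(rngSeed)
  mt <- vegan::mantel(stats::as.dist(genDist), stats::as.dist(geoDist),
                      permutations = nPerm)
  list(r = unname(mt$statistic), r2 = unname(mt$statistic)^2,
       p = mt$signif, flagged = FALSE)
}
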