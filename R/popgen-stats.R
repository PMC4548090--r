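#' Collapse aligned sequences into haplotypes
#'
#' Sequences that are identical site-by-site share a haplotype. Long indels
#' (contiguous gap runs of at least \code{minIndelLen} positions) are treated
#' as one evolutionary event: for pairwise-difference counting each coded run
#' contributes a single presence/absence character, while the gap positions
#' themselves fall under pairwise deletion. Shorter gap runs are treated
#' site-wise.
#'
#' @param aln A \linkS4class{HaplotypeAlignment}.
#' @param popmap Optional \linkS4class{PopulationMap}; when given, per-population
#'   haplotype counts are tabulated.
#' @param codeIndels Code long gap runs as single characters (default TRUE).
#' @param minIndelLen Minimum run length for indel coding (default 2).
#' @return An object of class \code{HaplotypeTable}: list with
#'   \code{haplotype} (id per sample, ordered by first occurrence),
#'   \code{counts} (overall counts per haplotype), \code{perPop} (data.frame
#'   pop, n, k), \code{popCounts} (list of per-population count tables) and
#'   \code{indelRuns} (coded runs, for difference counting).
#' @export
collapseHaplotypes <- function(aln, popmap = NULL, codeIndels = TRUE,
                               minIndelLen = 2L) {
  stopifnot(is(aln, "HaplotypeAlignment"), minIndelLen >= 1L)
  seqs <- as.character(aln@seqs)
  ids <- sampleIds(aln)
  hap <- match(seqs, unique(seqs))
  names(hap) <- ids
  counts <- as.integer(table(hap))
  names(counts) <- paste0("H", seq_along(counts))
  runs <- if (codeIndels) .gapRuns(seqs, minIndelLen) else
    matrix(integer(), ncol = 2)
  perPop <- NULL; popCounts <- NULL
  if (!is.null(popmap)) {
    pops <- popmap@assignment[ids]
    if (anyNA(pops))
      stop("samples missing from population map: ",
           paste(ids[is.na(pops)], collapse = ", "))
    popCounts <- lapply(split(hap, pops), table)
    perPop <- data.frame(pop = names(popCounts),
                         n = vapply(popCounts, sum, 0),
                         k = vapply(popCounts, length, 0),
                         row.names = NULL)
  }
  structure(list(haplotype = hap, counts = counts, perPop = perPop,
                 popCounts = popCounts, indelRuns = runs,
                 k = length(counts), n = length(hap)),
            class = "HaplotypeTable")
}

#' @export
print.HaplotypeTable <- function(x, ...) {
  cat(sprintf("HaplotypeTable: %d samples, %d haplotypes\n", x$n, x$k))
  if (!is.null(x$perPop)) print(x$perPop)
  invisible(x)
}

# distinct maximal gap runs of length >= minLen across all sequences,
# as a two-column matrix (start, end)
.gapRuns <- function(seqs, minLen) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (s in seqs) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minLen
    for (i in which(keep)) {
      key <- paste0(starts[i], ":", ends[i])
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        out[[length(out) + 1L]] <- c(starts[i], ends[i])
      }
    }
  }
  if (length(out) == 0) return(matrix(integer(), ncol = 2))
  do.call(rbind, out)
}

#' Pairwise sequence differences under pairwise deletion
#'
#' Counts, for every pair of sequences, the number of comparable sites
#' (both in A, C, G, T) that differ; gap and N positions are excluded
#' pair-by-pair. When \code{codeIndels} is on, each coded long gap run that
#' distinguishes the pair adds exactly one difference.
#'
#' @inheritParams collapseHaplotypes
#' @return List with integer matrices \code{d} (differences) and \code{L}
#'   (comparable sites per pair).
#' @export
pairwiseDifferences <- function(aln, codeIndels = TRUE, minIndelLen = 2L) {
  m <- alignmentMatrix(aln)
  n <- nrow(m)
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  L <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      L[i, j] <- L[j, i] <- sum(comp)
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp])
    }
  }
  if (codeIndels) {
    runs <- .gapRuns(as.character(aln@seqs), minIndelLen)
    if (nrow(runs) > 0) {
      for (r in seq_len(nrow(runs))) {
        span <- runs[r, 1]:runs[r, 2]
        has <- vapply(seq_len(n), function(i) all(m[i, span] == "-") &&
                        (runs[r, 1] == 1 || m[i, runs[r, 1] - 1] != "-") &&
                        (runs[r, 2] == ncol(m) || m[i, runs[r, 2] + 1] != "-"),
                      logical(1))
        diffr <- outer(has, has, FUN = "!=")
        d <- d + diffr
      }
    }
  }
  list(d = d, L = L)
}

#' Nei's unbiased haplotype diversity
#'
#' \eqn{h = \frac{n}{n-1}\left(1 - \sum_i \hat p_i^2\right)} with
#' \eqn{\hat p_i} the sample haplotype frequencies. A monomorphic sample
#' (k = 1) gives exactly 0.
#'
#' @param counts Integer vector of per-haplotype counts.
#' @param n Sample size; defaults to \code{sum(counts)}.
#' @return Haplotype diversity in [0, 1]; \code{NA} (with a warning) when
#'   n < 2, where the estimator is undefined.
#' @examples
#' haplotypeDiversity(c(11, 5))  # 0.4583...
#' @export
haplotypeDiversity <- function(counts, n = sum(counts)) {
  if (sum(counts) != n) stop("counts must sum to n")
  if (n < 2) {
    warning("haplotype diversity undefined for n < 2")
    return(NA_real_)
  }
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Nei's nucleotide diversity with sampling standard deviation
#'
#' Mean proportion of differing sites over all sequence pairs, under pairwise
#' deletion of gaps and ambiguous bases. The standard deviation is the square
#' root of Nei's (1987, eq. 10.7) total sampling variance
#' \deqn{V(\pi) = \frac{(n+1)\pi}{3(n-1)L} + \frac{2(n^2+n+3)\pi^2}{9n(n-1)},}
#' with L the mean number of comparable sites.
#'
#' @param aln A \linkS4class{HaplotypeAlignment}.
#' @param subset Optional sample ids to restrict to.
#' @inheritParams collapseHaplotypes
#' @return List with \code{pi}, \code{sd}, \code{n}, \code{L}.
#' @export
nucleotideDiversity <- function(aln, subset = NULL, codeIndels = TRUE,
                                minIndelLen = 2L) {
  if (!is.null(subset)) {
    keep <- sampleIds(aln) %in% subset
    aln <- HaplotypeAlignment(as.character(aln@seqs)[keep],
                              locusLabel = locusLabel(aln),
                              ploidyFactor = ploidyFactor(aln))
  }
  n <- length(aln@seqs)
  if (n < 2) stop("need at least 2 sequences")
  pd <- pairwiseDifferences(aln, codeIndels = codeIndels,
                            minIndelLen = minIndelLen)
  up <- upper.tri(pd$d)
  if (any(pd$L[up] == 0))
    stop("a sequence pair has zero comparable sites; pi undefined")
  pi <- mean(pd$d[up] / pd$L[up])
  L <- mean(pd$L[up])
  v <- (n + 1) * pi / (3 * (n - 1) * L) +
    2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))
  list(pi = pi, sd = sqrt(v), n = n, L = L)
}

#' Ewens sampling-formula probabilities for the number of haplotypes
#'
#' \eqn{\Pr(K = k \mid \theta, n) = |s(n,k)|\,\theta^k / \theta^{(n)}} with
#' unsigned Stirling numbers of the first kind and the rising factorial
#' \eqn{\theta^{(n)}}; computed in log space so it is stable for n in the
#' hundreds.
#'
#' @param n Sample size.
#' @param theta Scaled mutation parameter (> 0).
#' @return Numeric vector of probabilities for k = 1..n (sums to 1).
#' @export
ewensProbabilities <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  ls <- .logStirling1(n)
  logp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  exp(logp)
}

# log |s(n, k)| for k = 1..n via |s(m+1,k)| = |s(m,k-1)| + m * |s(m,k)|
.logStirling1 <- function(n) {
  l <- 0  # n = 1: |s(1,1)| = 1
  if (n == 1) return(l)
  for (m in 1:(n - 1)) {
    lnew <- numeric(m + 1)
    lnew[1] <- log(m) + l[1]
    if (m > 1)
      lnew[2:m] <- .pairLogSum(l[1:(m - 1)], log(m) + l[2:m])
    lnew[m + 1] <- l[m]
    l <- lnew
  }
  l
}

.pairLogSum <- function(a, b) {
  mx <- pmax(a, b)
  mx + log1p(exp(pmin(a, b) - mx))
}

.logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fu's FS neutrality statistic
#'
#' \eqn{S' = \Pr(K \ge k_{obs} \mid \hat\theta, n)} under the Ewens sampling
#' formula, and \eqn{F_S = \ln(S'/(1-S'))}. Strongly negative values indicate
#' an excess of rare haplotypes (population expansion or a selective sweep).
#' Significance is assessed by drawing the number of haplotypes from the Ewens
#' distribution at \eqn{\hat\theta} (Chinese-restaurant construction) and
#' computing the fraction of simulated \eqn{F_S} at or below the observed one
#' (with (b+1)/(m+1) smoothing); following Fu's convention the test is called
#' significant at p < 0.02.
#'
#' @param kObs Observed number of haplotypes.
#' @param n Sample size (>= 2).
#' @param thetaHat Mean number of pairwise differences (per locus, not per
#'   site); must be > 0.
#' @param nSim Ewens draws for the p-value (default 1000).
#' @param rngSeed Optional seed.
#' @return List with \code{FS}, \code{Sprime}, \code{p}, \code{theta}; FS is
#'   \code{+Inf} (flagged via \code{degenerate = TRUE}) when S' rounds to 1.
#' @export
fuFs <- function(kObs, n, thetaHat, nSim = 1000L, rngSeed = NULL) {
  stopifnot(n >= 2, kObs >= 1, kObs <= n)
  if (thetaHat <= 0) stop("Fu's FS undefined for thetaHat <= 0")
  if (!is.null(rngSeed)) set.seed(rngSeed)
  p <- ewensProbabilities(n, thetaHat)
  fsOf <- function(k) {
    sp <- sum(p[k:n])
    if (sp >= 1 - 1e-12) return(Inf)
    if (sp <= 1e-300) return(-Inf)
    log(sp / (1 - sp))
  }
  fs <- fsOf(kObs)
  # Ewens draws of K: sum of Bernoulli(theta / (theta + i - 1))
  i <- seq_len(n)
  ksim <- vapply(seq_len(nSim), function(b)
    sum(runif(n) < thetaHat / (thetaHat + i - 1)), 0L)
  fssim <- vapply(unique(ksim), fsOf, 0)
  names(fssim) <- unique(ksim)
  pval <- (sum(fssim[as.character(ksim)] <= fs) + 1) / (nSim + 1)
  list(FS = fs, Sprime = sum(p[kObs:n]), p = pval, theta = thetaHat,
       degenerate = !is.finite(fs))
}

#' Mean pairwise differences (theta-pi, per locus)
#' @inheritParams nucleotideDiversity
#' @return Mean number of pairwise differences.
#' @export
meanPairwiseDifferences <- function(aln, subset = NULL, codeIndels = TRUE,
                                    minIndelLen = 2L) {
  if (!is.null(subset)) {
    keep <- sampleIds(aln) %in% subset
    aln <- HaplotypeAlignment(as.character(aln@seqs)[keep],
                              locusLabel(aln), ploidyFactor(aln))
  }
  pd <- pairwiseDifferences(aln, codeIndels, minIndelLen)
  mean(pd$d[upper.tri(pd$d)])
}

#' Effective population size from the coalescent parameter theta
#'
#' theta = 2 mu Ne for a haploid genome and 4 mu Ne for a diploid genome, so
#' Ne = theta / (2 * ploidyFactor * mu).
#'
#' @param theta Coalescent mutation parameter (same mutation-rate units as
#'   \code{mu}).
#' @param mu Mutation rate per generation (> 0).
#' @param ploidyFactor 1 (haploid) or 2 (diploid).
#' @return Effective population size.
#' @examples
#' thetaToNe(0.0294, 0.0294 / (2 * 40788.9), 1)  # 40788.9
#' @export
thetaToNe <- function(theta, mu, ploidyFactor = 1) {
  if (mu <= 0) stop("mu must be > 0")
  stopifnot(ploidyFactor %in% c(1, 2), theta >= 0)
  theta / (2 * ploidyFactor * mu)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param a,b Coordinates as c(lat, lon) in decimal degrees.
#' @return Distance in km.
#' @export
haversineKm <- function(a, b) {
  if (abs(a[1]) > 90 || abs(b[1]) > 90 || abs(a[2]) > 180 || abs(b[2]) > 180)
    stop("coordinates out of range (lat in [-90,90], lon in [-180,180])")
  geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]), r = 6371)
}

#' Pairwise great-circle distance matrix for a PopulationMap
#' @param popmap A \linkS4class{PopulationMap} with coordinates.
#' @return Symmetric km matrix with population names.
#' @export
populationDistances <- function(popmap) {
  cc <- popmap@coords
  if (nrow(cc) < 2) stop("need coordinates for at least 2 populations")
  n <- nrow(cc)
  d <- matrix(0, n, n, dimnames = list(cc$pop, cc$pop))
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- haversineKm(c(cc$lat[i], cc$lon[i]),
                                        c(cc$lat[j], cc$lon[j]))
  d
}
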