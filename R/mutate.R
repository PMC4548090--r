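#' Discrete-gamma rate categories (mean-of-bin)
#'
#' Four equiprobable categories by default, each represented by its
#' conditional mean, for a gamma with shape \code{alpha} and mean 1.
#'
#' @param alpha Shape parameter (> 0).
#' @param k Number of categories (default 4).
#' @return Numeric vector of k category rates with mean 1.
#' @export
discreteGammaRates <- function(alpha, k = 4L) {
  stopifnot(alpha > 0, k >= 1)
  q <- qgamma(seq(0, 1, length.out = k + 1), shape = alpha, rate = alpha)
  # E[X ; X <= q] = pgamma(q, alpha + 1, rate = alpha) for mean-1 gamma
  cum <- pgamma(q, shape = alpha + 1, rate = alpha)
  k * diff(cum)
}

# HKY rate matrix scaled to one expected substitution per site per unit time
.hkyMatrix <- function(kappa, freqs) {
  b <- c("A", "C", "G", "T")
  freqs <- freqs[b]
  Q <- matrix(0, 4, 4, dimnames = list(b, b))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ti <- (b[i] %in% c("A", "G") && b[j] %in% c("A", "G")) ||
          (b[i] %in% c("C", "T") && b[j] %in% c("C", "T"))
    Q[i, j] <- if (ti) kappa * freqs[j] else freqs[j]
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q / scale
}

# simulate mutations on a genealogy; returns only the variant columns
# (rows = tips, integer codes 1..4 for A,C,G,T) plus the root bases, which is
# all the summary statistics need -- untouched sites are identical across tips
.mutateVariants <- function(gen, locus, rngSeed = NULL) {
  if (!is.null(rngSeed)) set.seed(rngSeed)
  tr <- gen$tree
  L <- locus@length
  mu <- locus@mu
  freqs <- locus@baseFreqs[c("A", "C", "G", "T")]
  rates <- if (is.na(locus@alpha)) 1 else discreteGammaRates(locus@alpha)
  siteRate <- rates[sample.int(length(rates), L, replace = TRUE)]
  Q <- .hkyMatrix(locus@kappa, freqs)
  lambda <- max(-diag(Q))
  P <- diag(4) + Q / lambda  # uniformized jump kernel (self-jumps allowed)

  nTip <- length(tr$tip.label)
  edges <- tr$edge
  lens <- tr$edge.length
  totRate <- lambda * mu * sum(siteRate)
  nEv <- rpois(nrow(edges), totRate * lens)
  tot <- sum(nEv)
  if (tot == 0 || mu == 0) {
    return(list(tips = matrix(integer(), nrow = nTip, ncol = 0),
                rootBase = integer(), sites = integer(), L = L,
                rootSeq = sample.int(4, L, replace = TRUE, prob = freqs)))
  }
  evSite <- sample.int(L, tot, replace = TRUE, prob = siteRate)
  sites <- sort(unique(evSite))
  nVar <- length(sites)
  rootSeq <- sample.int(4, L, replace = TRUE, prob = freqs)
  rootBase <- rootSeq[sites]

  evByEdge <- split(match(evSite, sites), rep(seq_len(nrow(edges)), nEv))
  # preorder traversal carrying the variant-site state
  state <- matrix(NA_integer_, nrow = nTip + tr$Nnode, ncol = nVar)
  root <- nTip + 1L
  state[root, ] <- rootBase
  for (e in seq_len(nrow(edges))) {   # cladewise order: parents before children
    p <- edges[e, 1]; ch <- edges[e, 2]
    s <- state[p, ]
    ev <- evByEdge[[as.character(e)]]
    if (!is.null(ev)) {
      for (v in ev) s[v] <- sample.int(4, 1, prob = P[s[v], ])
    }
    state[ch, ] <- s
  }
  list(tips = state[seq_len(nTip), , drop = FALSE], rootBase = rootBase,
       sites = sites, L = L, rootSeq = rootSeq)
}

#' Evolve sequences along a genealogy
#'
#' The root sequence is drawn from the model's base frequencies; each site is
#' assigned a discrete-gamma rate multiplier; mutation events are Poisson
#' along branches (rate mu per site per generation, times the site's rate
#' class) and substitutions follow the HKY (or JC) kernel via exact
#' uniformization. Branch lengths are in generations.
#'
#' @param gen A Genealogy from \code{\link{backwardCoalescent}}.
#' @param locus A \linkS4class{LocusModel}.
#' @param rngSeed Optional seed.
#' @return A \linkS4class{HaplotypeAlignment} of the tip sequences.
#' @export
mutateGenealogy <- function(gen, locus, rngSeed = NULL) {
  mv <- .mutateVariants(gen, locus, rngSeed)
  bases <- c("A", "C", "G", "T")
  rootChars <- bases[mv$rootSeq]
  nTip <- nrow(mv$tips)
  seqs <- character(nTip)
  for (i in seq_len(nTip)) {
    s <- rootChars
    if (length(mv$sites) > 0) s[mv$sites] <- bases[mv$tips[i, ]]
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- gen$tree$tip.label
  HaplotypeAlignment(seqs, locusLabel = locus@label,
                     ploidyFactor = locus@ploidyFactor)
}
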