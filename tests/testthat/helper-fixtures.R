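# shared fixtures, all built in code

# alignment from explicit sequences with optional population labels
alnFrom <- function(seqs, pops = NULL, label = "cp", ploidy = 1L) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("s%02d", seq_along(seqs))
  aln <- HaplotypeAlignment(seqs, locusLabel = label, ploidyFactor = ploidy)
  if (is.null(pops)) return(aln)
  list(aln = aln, popmap = PopulationMap(setNames(pops, names(seqs))))
}

# random gap-free alignment
randomAln <- function(n, L, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  alnFrom(seqs)
}

# small locus / sampling configurations for fast simulation tests
tinyLocus <- function(mu = 1e-5, L = 300L, model = "JC", ploidy = 1L,
                      alpha = NA_real_) {
  LocusModel("cp", L, model = model, alpha = alpha, mu = mu,
             ploidyFactor = ploidy)
}

# brute-force nucleotide diversity: mean over pairs of differing fraction
# among sites where both sequences have a plain base (independent of the
# package's pairwiseDifferences path)
bruteForcePi <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
    vals <- c(vals, sum(m[i, ok] != m[j, ok]) / sum(ok))
  }
  mean(vals)
}

# brute-force one-level AMOVA variance components from first principles
bruteForcePhi <- function(d, pops) {
  N <- length(pops); P <- length(unique(pops))
  ssTot <- sum(d[upper.tri(d)]) / N
  ssW <- 0; np <- c()
  for (p in unique(pops)) {
    i <- which(pops == p); np <- c(np, length(i))
    dp <- d[i, i, drop = FALSE]
    ssW <- ssW + sum(dp[upper.tri(dp)]) / length(i)
  }
  msA <- (ssTot - ssW) / (P - 1)
  msW <- ssW / (N - P)
  nBar <- (N - sum(np^2) / N) / (P - 1)
  s2a <- (msA - msW) / nBar
  s2a / (s2a + msW)
}
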