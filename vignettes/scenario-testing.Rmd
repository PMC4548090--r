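---
title: "Demographic scenario testing for savanna trees: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic scenario testing: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The question the package answers

A widespread Neotropical savanna tree was sampled in 21 populations, sequenced
at a ~2100 bp chloroplast alignment and a ~527 bp nuclear ITS alignment, and
found to be strongly structured with low within-population diversity. Did its
range expand, stay stable, or contract since the Last Glacial Maximum (LGM,
~21 ka), or did it persist in multiple refugia? `CoalScenarios` implements the
simulation side of that multi-model inference: each hypothesis is encoded as a
structured-coalescent model, summary statistics of simulated data are compared
with the observed ones through an empirical-distribution likelihood, and the
hypotheses are ranked by AIC weights. Alongside, it post-processes ensembles
of ecological niche model (ENM) projections — the independent line of evidence
the demographic hypotheses come from — and provides the classical diversity
and structure statistics (Nei's *h* and *π*, AMOVA Φ~ST~, Mantel tests, Fu's
*F~S~*).

# The four demographic scenarios

All scenarios share 21 demes observed at present with effective size N0 each
(we use the published grid N0 ∈ {100, 1000, 10000}), simulated backward in
time for t_end = 1750 generations — 21 ka at the species' 12-year generation
time (`yearsToGenerations(21000, 12)`). Deme sizes follow
N(t) = round(N0 · e^{rt}) with r = ln(N(t_end)/N0)/t_end, so both endpoints
are exact. Migration is 0.01 per lineage per generation.

* **Range stability.** Constant sizes; backward in time each lineage outside
  refugial deme 1 moves there with probability 0.01 per generation (the
  backward image of colonisation out of a single source).
* **Range expansion.** Sizes shrink backward to N(t_end) = N0/10 (the forward
  reading: a ten-fold population expansion since the LGM), same sink-to-deme-1
  migration.
* **Range retraction.** The range was *larger* at the LGM: refugial deme 1
  grows backward to N(t_end) = 5·N0 (e.g. 50,000 at N0 = 10,000), while each
  of the other demes shrinks backward until extinction at t_end, its ancestry
  coalescing inside the dwindling deme before the survivors are absorbed into
  deme 1. This "shrink until extinction" reading is deliberate: it is the
  forward-time founder effect of populations being (re)seeded from a large
  glacial range, and it is the only mechanism consistent with the empirical
  behaviour this scenario must reproduce — *simulated diversities uniformly
  below the observed mean*. The alternative reading (all demes large at the
  LGM with gradual migration into deme 1) provably produces the opposite:
  with migration 0.01/generation every lineage reaches deme 1 within a few
  hundred generations and then coalesces at depth ~5·N0 generations,
  saturating haplotype diversity. Under that reading the scenario could never
  yield all-lower diversities no matter the mutation rate, so we treat the
  absorption-at-extinction mechanism as the intended model; the per-generation
  migration rate remains configurable for the other scenarios.
* **Multiple refugia.** Constant sizes, finite island model: each lineage
  moves to a uniformly chosen other deme with probability 0.01 per generation.

Beyond t_end, sizes are held at N(t_end); sink scenarios place all remaining
ancestry in deme 1 (so a most recent common ancestor is guaranteed), and the
island model continues unchanged. This post-LGM regime is the minimal
extension of the published design that closes the genealogy.

## The simulation engine

The coalescent is simulated as an *exact* discrete Wright–Fisher process:
each generation every lineage draws a parent uniformly among the
ploidy-adjusted gene copies of its deme, so multiple and simultaneous mergers
occur with their exact probabilities. This matters because the scenarios
visit very small demes (N(t_end) = 10 under expansion at N0 = 100; the
retraction extinction path), where the Kingman approximation (at most one
merger per generation) is wrong. After t_end, when sizes are constant, empty
generations are skipped by drawing the waiting time to the next eventful
generation geometrically and realising that generation by rejection — an
algebraically exact shortcut, implemented in C++, that makes deep genealogies
(pairwise times of ~400,000 generations under the island model) cheap.

Sequences evolve along the genealogy under HKY with four discrete-gamma rate
categories (mean-of-bin; shape 1.87 for the chloroplast locus, the published
model choice) or JC for ITS. Mutations are laid down by uniformization:
Poisson events at the dominating rate with the jump kernel I + Q/Λ, which is
exact for any HKY parameterisation. ITS is sampled as one gene copy per
individual (the study found no heterozygotes) coalescing in a pool of 2N
copies; the chloroplast locus as one copy in a pool of N.

## Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| t_end | 1750 | generations | 21 ka / 12 yr per generation |
| N0 | 10,000 | individuals per deme | published grid; 1000 and 100 supported |
| migration | 0.01 | per lineage per generation | published rate |
| chloroplast locus | 2100 bp, HKY+Γ(1.87), κ = 2, uniform frequencies | — | published alignment length and model; κ and frequencies are not printed, so neutral defaults, configurable |
| ITS locus | 527 bp, JC | — | published |
| μ (chloroplast) | 2.4 × 10⁻⁸ | subst/site/generation | 2 × 10⁻⁹ subst/site/yr — the literature scale for plant chloroplast spacers in trees — times 12 yr/generation. The study used rates from a sister species without printing them. |
| μ (ITS) | 4.8 × 10⁻⁸ | subst/site/generation | 4 × 10⁻⁹ subst/site/yr, literature scale for plant ITS |
| samples | published per-population N column | individuals | note the printed column sums to 301, not the stated 285; we take the column, since per-deme counts are what the simulator consumes |
| replicates | 2000 | — | published; 500 for desk-scale runs (the acceptance script's default), which resolves the likelihood ordering comfortably |

All rates are echoed into every output so a run is self-describing.

# Model choice on empirical distributions

For each scenario × locus × statistic, the likelihood of the observed value
is read off a Gaussian kernel density (Silverman bandwidth, recorded) of the
simulated per-replicate cross-population means. The default likelihood is the
**product of the density height at the observation and the distribution's
maximum height** — the definition used by the serial-coalescent tool this
design follows. We keep the normalised **ratio** f(obs)/max f behind a flag
(`method = "ratio"`), but it is not the default for a substantive reason: the
ratio only measures where the observation sits within a scenario's own
distribution, so a scenario that is diffuse (range stability, whose simulated
mean haplotype diversity spans 0.06–0.8) can outscore a scenario that is
dense near the observation. The product also weighs the concentration of the
distribution, and in our reproduction it is what ranks range expansion first
— the published outcome — while the ratio does not.

An observation outside [min − bw, max + bw] of a scenario's simulated values
is *undefined* under either method (the scenario cannot produce it) and is
reported as a dash, exactly how the retraction row behaves.

AIC = −2 ln L + 2k with k equal across scenarios (all four have the same
free-parameter structure, so k cancels; we use k = 0), ΔAIC relative to the
best defined scenario, AICw = exp(−0.5 ΔAIC) (best model 1, the published
convention) plus a normalised column. ΔAIC < 2 is flagged "equally
plausible". One-tailed P is reported under two conventions, both labeled,
because the published definition is not explicit: the default counts
simulated values at least as extreme as the observation on the side of the
simulated median it falls on, with (b+1)/(B+1) smoothing; `P_below` is the
acceptance-style fraction of simulated values at or below the observation.
`bestScenario()` offers a combined-evidence assignment (summed ΔAIC across
statistics, impossibility treated as an infinite penalty) for recovery
experiments; the per-statistic table remains the primary output.

# Diversity and structure statistics

Nei's unbiased haplotype diversity h = n(1 − Σp̂²)/(n−1); nucleotide
diversity as the mean over sequence pairs of the differing fraction of
comparable sites (pairwise deletion of gaps and Ns), with the SD from Nei's
total sampling variance (this reproduces the published per-population SDs,
e.g. π = 0.0127 → SD 0.0066 at n = 16, L = 2100). Long indels (gap runs of
≥ 2 bp by default; the study says "usually more than 5 bp", which is vague,
so the cut is configurable) are coded as one evolutionary event: one
presence/absence character per distinct run, the gapped columns falling under
pairwise deletion. Fu's F~S~ = ln(S′/(1−S′)) with S′ the Ewens-formula
probability of at least the observed number of haplotypes given θ̂ (mean
pairwise differences per locus); Stirling numbers are computed in log space
(stable to n in the hundreds), and the p-value simulates 1000 Ewens draws at
θ̂, significance called at 0.02 per Fu's convention. AMOVA is the one-level
Excoffier decomposition on pairwise difference counts with a 10,000-label
permutation test; Mantel correlates Φ~ST~/(1−Φ~ST~) (entries at Φ~ST~ = 1
capped at 10³ with a warning) against log great-circle distance via
`vegan::mantel`. Populations with n < 5 are flagged as too small for
demographic parameters, mirroring the study's exclusions.

# ENM post-processing

Layers (suitability per 0.5° grid cell, one layer per ENM algorithm × climate
model × period) are filtered at TSS ≥ 0.5, ensembled per period as the
TSS-weighted mean, and each (ENM, AOGCM) pair is classified by its range
shift between the LGM and the present: |shift| within 5% of the larger range
is Stability (the study never quantifies "no difference"; 5% is our
configurable default), positive shifts are Expansion, negative Retraction.
The historical refugium is the set of cells with ensemble suitability ≥ 0.5
in *all three* periods — monotonically nested in the threshold, which is what
makes the published sensitivity analysis (0.4/0.5/0.6/0.7) coherent. The
hierarchical ANOVA partitions per-cell suitability into time, ENM-within-time,
AOGCM-within-time and the residual ENM × AOGCM interaction (the design has no
replicates), per cell and averaged across cells; grid geometry is metadata
only — cells are abstract ids.

# What the synthetic generators emulate

`makeHaplotypeDataset` builds alignments from template haplotypes placed at
prescribed pairwise distances (star-additive difference matrices, realised
exactly with no back-mutation) and prescribed per-population counts, so Nei's
statistics have hand-computable truth. `makeSuitabilityStack` builds layer
stacks from an additive per-cell model with chosen component variances,
range-shift offsets per (ENM, AOGCM) pair, an optional designed refugium
block and occurrence samples, recording expected variance proportions as
truth. `makePseudoObserved` runs one coalescent replicate under a named
scenario and packages its summaries as pseudo-observations. What these do
*not* emulate: recombination, selection, spatial clines within demes,
ascertainment in sampling, real climate surfaces, or the correlation
structure of real ENM ensembles — so green tests certify the machinery and
the statistical logic, not field realism.

# Numerical and testing choices

* Exact endpoint arithmetic for trajectories (rounded exponential
  interpolation); sizes never drop below 1.
* The MRCA guard is 100·t_end + 50·(total gene copies), generous enough that
  island-model genealogies essentially never hit it; aborted replicates are
  logged and re-drawn from reserve sub-seeds.
* Replicates are keyed by (batch seed, replicate index) — every replicate is
  reproducible in isolation and no seed is reused.
* Degenerate cases: a monomorphic sample has h = π = 0 exactly; h is
  undefined (NA with a warning) at n < 2; an all-equal simulated distribution
  has likelihood 1 at that value and is undefined elsewhere; a zero-variance
  distance matrix flags the Mantel correlation rather than returning a number.
* Test problem sizes: the scenario-comparison checks run 500 replicates per
  scenario at the full 21-deme design; the self-recovery experiment runs
  400-replicate batches and 50 pseudo-observations per scenario at 12 demes
  (the same N0, t_end, migration and locus models on both loci) — below ~10
  demes the cross-population mean haplotype diversity hits its h = 0 boundary
  often enough under retraction to distort the kernel-density likelihoods, so
  the deme count is reduced no further; the coalescent oracle uses 10,000
  two-sample replicates plus an independent discrete-time Wright–Fisher
  simulation in msprime at identical parameters.

# Known limitations

* The observed cross-population mean π (0.0093 for the chloroplast) is
  dominated by one highly divergent population and is mutually inconsistent
  with the observed mean h (0.220) under any single-history neutral model —
  ~20 mean pairwise differences next to 80% identical pairs. The π columns of
  the comparison table therefore come out largely undefined in our runs; the
  haplotype-diversity columns carry the signal, as they do in the study.
* Scenario inference shares the usual caveat of simulation-based model
  choice: it ranks the four encoded hypotheses, not all possible histories.
  The expansion and retraction scenarios overlap observationally: an
  expansion genealogy whose lineages coalesce mostly in the small ancestral
  deme produces the same low, concentrated diversities as a retraction
  founder history, so in self-recovery experiments a few percent of
  expansion-generated datasets are legitimately assigned to retraction by
  every likelihood convention. Recovery rates stay well above majority for
  all four scenarios, but absolute separation of these two is not achievable
  from these summary statistics alone.
* The mutation-rate defaults are literature-scale, not species-measured;
  conclusions that hinge on absolute (not relative) diversity levels should
  be read with that in mind, and both rates are single-call configurable.
* No recombination (justified for the organellar locus and supported for ITS
  by the absence of heterozygotes, but an assumption nonetheless) and no
  serial sampling.
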