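#' @import methods
#' @importFrom stats density median quantile rbinom runif rnorm setNames aov
#'   approx cor dist sd var qgamma pgamma rpois dnorm bw.nrd0
#' @importFrom utils read.table write.table head
#' @importFrom Rcpp sourceCpp
#' @useDynLib CoalScenarios, .registration = TRUE
NULL

#' Aligned haplotype sequences for one locus
#'
#' Thin wrapper around a \linkS4class{DNAStringSet} holding an alignment of
#' haplotype sequences (alphabet A, C, G, T, \code{-}, N), the locus label and
#' the ploidy factor of the genome the locus sits on (1 for organellar /
#' haploid loci such as chloroplast spacers, 2 for nuclear loci).
#'
#' @slot seqs A \code{DNAStringSet}; all elements must have equal width > 0.
#' @slot locusLabel Single character label for the locus.
#' @slot ploidyFactor Integer, 1 (haploid) or 2 (diploid).
#' @export
setClass("HaplotypeAlignment",
  slots = c(seqs = "DNAStringSet", locusLabel = "character",
            ploidyFactor = "integer"))

setValidity("HaplotypeAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  if (length(w) == 0L) return("alignment contains no sequences")
  if (length(unique(w)) != 1L) return("ragged alignment: unequal sequence lengths")
  if (w[1] <= 0L) return("alignment length must be > 0")
  if (!(object@ploidyFactor %in% c(1L, 2L))) return("ploidyFactor must be 1 or 2")
  if (length(object@locusLabel) != 1L) return("locusLabel must be a single string")
  TRUE
})

#' Sample-to-population assignment with optional coordinates
#'
#' @slot assignment Named character vector mapping sample id to population id.
#' @slot coords data.frame with columns \code{pop}, \code{lat}, \code{lon}
#'   (decimal degrees); may have zero rows when coordinates are unknown.
#' @export
setClass("PopulationMap",
  slots = c(assignment = "character", coords = "data.frame"))

setValidity("PopulationMap", function(object) {
  if (is.null(names(object@assignment)) || any(names(object@assignment) == ""))
    return("assignment must be a named character vector (sample -> population)")
  cc <- object@coords
  if (nrow(cc) > 0) {
    if (!all(c("pop", "lat", "lon") %in% names(cc)))
      return("coords needs columns pop, lat, lon")
    if (any(abs(cc$lat) > 90 | abs(cc$lon) > 180, na.rm = TRUE))
      return("coordinates out of range")
  }
  TRUE
})

#' One demographic hypothesis for the structured coalescent
#'
#' The four scenarios share 21 demes of present size \code{N0} evolving over
#' \code{tEnd} generations back to the last glacial maximum, and differ in the
#' deme-size trajectory and migration regime:
#' \describe{
#'   \item{stability}{constant sizes, sink migration toward refugial deme 1.}
#'   \item{expansion}{sizes shrink backward to \code{N0/10} (forward-time
#'     population growth since the glacial), sink migration toward deme 1.}
#'   \item{retraction}{refugial deme 1 grows backward to \code{5 * N0};
#'     source demes shrink backward to extinction at \code{tEnd}, their
#'     surviving ancestral lineages being absorbed into deme 1 (the
#'     forward-time founder effect of recolonisation).}
#'   \item{multiple_refugia}{constant sizes, finite island migration among all
#'     demes.}
#' }
#'
#' @slot name One of \code{"stability"}, \code{"expansion"},
#'   \code{"retraction"}, \code{"multiple_refugia"}.
#' @slot nDemes Number of demes (default 21).
#' @slot N0 Present-day deme size (effective individuals).
#' @slot NEnd Deme size at \code{tEnd} for the scenario trajectory.
#' @slot tEnd Generations from present back to the glacial maximum.
#' @slot migrationRate Per-lineage per-generation migration probability.
#' @slot migrationMode \code{"sink_deme1"}, \code{"sink_then_extinction"} or
#'   \code{"island"}.
#' @export
setClass("ScenarioSpec",
  slots = c(name = "character", nDemes = "integer", N0 = "numeric",
            NEnd = "numeric", tEnd = "integer", migrationRate = "numeric",
            migrationMode = "character"))

setValidity("ScenarioSpec", function(object) {
  if (!(object@name %in% c("stability", "expansion", "retraction",
                           "multiple_refugia")))
    return("unknown scenario name")
  if (object@N0 < 1 || object@NEnd < 1) return("deme sizes must be >= 1")
  if (object@migrationRate < 0 || object@migrationRate > 1)
    return("migration rate must be in [0, 1]")
  if (!(object@migrationMode %in% c("sink_deme1", "sink_then_extinction",
                                    "island", "none")))
    return("unknown migration mode")
  if (object@nDemes < 1 || object@tEnd < 0) return("bad nDemes or tEnd")
  TRUE
})

#' Substitution model and mutation rate for one locus
#'
#' @slot label Locus label.
#' @slot length Number of sites.
#' @slot model \code{"HKY"} or \code{"JC"} (JC is HKY with kappa 1 and
#'   uniform frequencies).
#' @slot alpha Discrete-gamma shape for among-site rate heterogeneity
#'   (\code{NA} for rate homogeneity); 4 categories, mean-of-bin.
#' @slot kappa Transition/transversion rate ratio.
#' @slot baseFreqs Named base frequencies (A, C, G, T) summing to 1.
#' @slot mu Substitution rate per site per generation.
#' @slot ploidyFactor 1 (organellar) or 2 (nuclear).
#' @export
setClass("LocusModel",
  slots = c(label = "character", length = "integer", model = "character",
            alpha = "numeric", kappa = "numeric", baseFreqs = "numeric",
            mu = "numeric", ploidyFactor = "integer"))

setValidity("LocusModel", function(object) {
  if (object@length < 1L) return("locus length must be >= 1")
  if (!(object@model %in% c("HKY", "JC"))) return("model must be HKY or JC")
  if (!is.na(object@alpha) && object@alpha <= 0) return("alpha must be > 0")
  if (object@kappa <= 0) return("kappa must be > 0")
  if (abs(sum(object@baseFreqs) - 1) > 1e-8 || any(object@baseFreqs < 0))
    return("base frequencies must be non-negative and sum to 1")
  if (object@mu < 0) return("mu must be >= 0")
  if (!(object@ploidyFactor %in% c(1L, 2L))) return("ploidyFactor must be 1 or 2")
  TRUE
})

#' Per-deme sample sizes and generation time
#'
#' @slot counts Integer vector of sampled individuals per deme.
#' @slot generationTime Generation time in years (default 12).
#' @export
setClass("SampleConfig",
  slots = c(counts = "integer", generationTime = "numeric"))

setValidity("SampleConfig", function(object) {
  if (any(object@counts < 0L)) return("sample counts must be >= 0")
  if (sum(object@counts) < 2L) return("need at least 2 samples in total")
  if (object@generationTime <= 0) return("generation time must be > 0")
  TRUE
})

#' Batch of simulated summary statistics for one scenario
#'
#' @slot stats data.frame with one row per (replicate, locus): columns
#'   \code{rep}, \code{locus}, \code{mean_h}, \code{mean_pi} (cross-deme
#'   means over demes with n >= 2).
#' @slot scenario The generating \linkS4class{ScenarioSpec}.
#' @slot seed Integer seed the batch was generated from.
#' @slot params List echoing loci and sample configuration.
#' @export
setClass("SimulationSummary",
  slots = c(stats = "data.frame", scenario = "ScenarioSpec", seed = "integer",
            params = "list"))

#' Scenario comparison table (empirical likelihood, AIC, one-tailed P)
#'
#' @slot table data.frame with one row per (scenario, locus, statistic):
#'   columns \code{scenario}, \code{locus}, \code{statistic}, \code{logL},
#'   \code{AIC}, \code{dAIC}, \code{AICw}, \code{AICw_norm}, \code{P},
#'   \code{P_below}, \code{defined}, \code{equally_plausible}.
#' @slot observed Named list of observed summary values.
#' @slot meta List with bandwidths, replicate counts and seeds.
#' @export
setClass("ModelComparison",
  slots = c(table = "data.frame", observed = "list", meta = "list"))

#' Stack of suitability layers indexed by (ENM, AOGCM, period)
#'
#' @slot cells data.frame with columns \code{cell_id}, \code{x}, \code{y}.
#' @slot values Numeric matrix, cells x layers, suitabilities in [0, 1].
#' @slot layers data.frame with columns \code{enm}, \code{aogcm},
#'   \code{period}, \code{tss} (one row per column of \code{values}).
#' @slot occurrences Vector of cell ids holding occurrence records.
#' @export
setClass("SuitabilityStack",
  slots = c(cells = "data.frame", values = "matrix", layers = "data.frame",
            occurrences = "character"))

setValidity("SuitabilityStack", function(object) {
  if (!all(c("cell_id", "x", "y") %in% names(object@cells)))
    return("cells needs columns cell_id, x, y")
  if (nrow(object@values) != nrow(object@cells))
    return("values rows must match cells")
  if (ncol(object@values) != nrow(object@layers))
    return("one layers row per values column required")
  if (!all(c("enm", "aogcm", "period", "tss") %in% names(object@layers)))
    return("layers needs columns enm, aogcm, period, tss")
  v <- object@values
  if (any(v < 0 | v > 1, na.rm = TRUE)) return("suitability must be in [0, 1]")
  if (any(object@layers$tss < -1 | object@layers$tss > 1))
    return("TSS must be in [-1, 1]")
  TRUE
})

# ---- show methods ----

setMethod("show", "HaplotypeAlignment", function(object) {
  cat(sprintf("HaplotypeAlignment: %d sequences x %d sites, locus '%s' (ploidy %d)\n",
              length(object@seqs), Biostrings::width(object@seqs)[1],
              object@locusLabel, object@ploidyFactor))
})

setMethod("show", "ScenarioSpec", function(object) {
  cat(sprintf("ScenarioSpec '%s': %d demes, N0=%g -> N(tEnd)=%g over %d generations, m=%g (%s)\n",
              object@name, object@nDemes, object@N0, object@NEnd, object@tEnd,
              object@migrationRate, object@migrationMode))
})

setMethod("show", "SimulationSummary", function(object) {
  cat(sprintf("SimulationSummary: scenario '%s', %d replicates, loci: %s\n",
              object@scenario@name, length(unique(object@stats$rep)),
              paste(unique(object@stats$locus), collapse = ", ")))
})

setMethod("show", "ModelComparison", function(object) {
  cat("ModelComparison across", length(unique(object@table$scenario)),
      "scenarios\n")
  print(object@table, digits = 4)
})

setMethod("show", "SuitabilityStack", function(object) {
  cat(sprintf("SuitabilityStack: %d cells, %d layers (%d ENM x %d AOGCM x %d periods), %d occurrence cells\n",
              nrow(object@cells), nrow(object@layers),
              length(unique(object@layers$enm)),
              length(unique(object@layers$aogcm)),
              length(unique(object@layers$period)),
              length(object@occurrences)))
})
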