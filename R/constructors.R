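#' Construct a HaplotypeAlignment
#'
#' @param seqs Character vector of aligned sequences (A, C, G, T, -, N) or a
#'   \code{DNAStringSet}; names are the sample ids.
#' @param locusLabel Locus label.
#' @param ploidyFactor 1 (organellar/haploid) or 2 (nuclear/diploid).
#' @return A \linkS4class{HaplotypeAlignment}.
#' @examples
#' aln <- HaplotypeAlignment(c(s1 = "ACGT", s2 = "ACGA"), "demo", 1)
#' @export
HaplotypeAlignment <- function(seqs, locusLabel = "locus", ploidyFactor = 1L) {
  if (is.character(seqs)) {
    if (is.null(names(seqs)))
      names(seqs) <- paste0("seq", seq_along(seqs))
    if (length(unique(nchar(seqs))) > 1L)
      stop("ragged alignment: unequal sequence lengths")
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  new("HaplotypeAlignment", seqs = seqs, locusLabel = as.character(locusLabel),
      ploidyFactor = as.integer(ploidyFactor))
}

#' Construct a PopulationMap
#'
#' @param assignment Named character vector (sample id -> population id), or a
#'   data.frame with columns \code{sample}, \code{pop} and optionally
#'   \code{lat}, \code{lon}.
#' @param coords Optional data.frame with columns \code{pop}, \code{lat},
#'   \code{lon}.
#' @return A \linkS4class{PopulationMap}.
#' @export
PopulationMap <- function(assignment, coords = NULL) {
  if (is.data.frame(assignment)) {
    df <- assignment
    assignment <- setNames(as.character(df$pop), as.character(df$sample))
    if (is.null(coords) && all(c("lat", "lon") %in% names(df))) {
      coords <- unique(df[, c("pop", "lat", "lon")])
    }
  }
  if (is.null(coords))
    coords <- data.frame(pop = character(), lat = numeric(), lon = numeric())
  new("PopulationMap", assignment = assignment,
      coords = as.data.frame(coords))
}

#' @rdname HaplotypeAlignment
#' @param x A HaplotypeAlignment.
#' @export
sampleIds <- function(x) names(x@seqs)

#' @rdname HaplotypeAlignment
#' @export
alignmentLength <- function(x) Biostrings::width(x@seqs)[1]

#' @rdname HaplotypeAlignment
#' @export
ploidyFactor <- function(x) x@ploidyFactor

#' @rdname HaplotypeAlignment
#' @export
locusLabel <- function(x) x@locusLabel

#' Alignment as a character matrix (rows = samples, columns = sites)
#' @param x A HaplotypeAlignment.
#' @return Character matrix of single characters.
#' @export
alignmentMatrix <- function(x) {
  m <- t(vapply(as.character(x@seqs),
                function(s) strsplit(s, "", fixed = TRUE)[[1]],
                character(alignmentLength(x))))
  rownames(m) <- sampleIds(x)
  m
}

#' Construct a LocusModel
#'
#' Defaults mirror the two loci of the study system: call
#' \code{organellarLocus()} for the 2100 bp chloroplast-like locus (HKY,
#' discrete-gamma shape 1.87) and \code{nuclearLocus()} for the 527 bp
#' ITS-like locus (JC). Default substitution rates are literature-scale rates
#' for woody plants (chloroplast spacers 2e-9/site/year, ITS 4e-9/site/year)
#' times the 12-year generation time.
#'
#' @param label Locus label.
#' @param length Sites.
#' @param model "HKY" or "JC".
#' @param alpha Discrete-gamma shape (NA = homogeneous rates).
#' @param kappa Transition/transversion ratio (ignored for JC).
#' @param baseFreqs Base frequencies (ignored for JC).
#' @param mu Substitution rate per site per generation.
#' @param ploidyFactor 1 or 2.
#' @return A \linkS4class{LocusModel}.
#' @export
LocusModel <- function(label, length, model = c("HKY", "JC"), alpha = NA_real_,
                       kappa = 2.0, baseFreqs = c(A = .25, C = .25, G = .25, T = .25),
                       mu, ploidyFactor = 1L) {
  model <- match.arg(model)
  if (model == "JC") {
    kappa <- 1.0
    baseFreqs <- c(A = .25, C = .25, G = .25, T = .25)
  }
  new("LocusModel", label = label, length = as.integer(length), model = model,
      alpha = alpha, kappa = kappa, baseFreqs = baseFreqs, mu = mu,
      ploidyFactor = as.integer(ploidyFactor))
}

#' @rdname LocusModel
#' @export
organellarLocus <- function(length = 2100L, mu = 2.4e-8, alpha = 1.87) {
  LocusModel("cp", length, model = "HKY", alpha = alpha, kappa = 2.0, mu = mu,
             ploidyFactor = 1L)
}

#' @rdname LocusModel
#' @export
nuclearLocus <- function(length = 527L, mu = 4.8e-8) {
  LocusModel("its", length, model = "JC", mu = mu, ploidyFactor = 2L)
}

#' Per-deme sample sizes of the study design
#'
#' The default reproduces the 21-population sampling design (at most 16 adult
#' individuals per population) and the 12-year generation time.
#'
#' @param counts Integer vector of samples per deme.
#' @param generationTime Years per generation.
#' @return A \linkS4class{SampleConfig}.
#' @export
SampleConfig <- function(counts = defaultSampleCounts(), generationTime = 12) {
  new("SampleConfig", counts = as.integer(counts),
      generationTime = generationTime)
}

#' @rdname SampleConfig
#' @export
defaultSampleCounts <- function() {
  c(16L, 14L, 18L, 12L, 17L, 16L, 15L, 22L, 8L, 14L, 16L, 16L, 16L, 16L, 16L,
    15L, 3L, 4L, 14L, 17L, 16L)
}

#' Construct a SuitabilityStack
#'
#' @param cells data.frame with columns \code{cell_id}, \code{x}, \code{y}.
#' @param values Matrix (cells x layers) of suitabilities in [0, 1].
#' @param layers data.frame with columns \code{enm}, \code{aogcm},
#'   \code{period}, \code{tss}.
#' @param occurrences Cell ids with occurrence records.
#' @return A \linkS4class{SuitabilityStack}.
#' @export
SuitabilityStack <- function(cells, values, layers, occurrences = character()) {
  cells$cell_id <- as.character(cells$cell_id)
  new("SuitabilityStack", cells = as.data.frame(cells),
      values = as.matrix(values), layers = as.data.frame(layers),
      occurrences = as.character(occurrences))
}

#' Accessors for SuitabilityStack
#' @param x A SuitabilityStack.
#' @export
stackLayers <- function(x) x@layers

#' @rdname stackLayers
#' @export
stackCells <- function(x) x@cells

#' @rdname stackLayers
#' @export
stackValues <- function(x) x@values

#' @rdname stackLayers
#' @export
occurrenceCells <- function(x) x@occurrences

#' Accessors for SimulationSummary and ModelComparison
#' @param x Object.
#' @export
batchStats <- function(x) x@stats

#' @rdname batchStats
#' @export
comparisonTable <- function(x) x@table
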