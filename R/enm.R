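#' Drop suitability layers with poor predictive skill
#'
#' Removes every (ENM, AOGCM, period) layer whose True Skill Statistic falls
#' below \code{tssMin} (default 0.5, the conventional cut for usable models).
#'
#' @param stack A \linkS4class{SuitabilityStack}.
#' @param tssMin Minimum TSS to retain a layer.
#' @return Filtered stack; the number of dropped layers is reported via
#'   message.
#' @export
filterBySkill <- function(stack, tssMin = 0.5) {
  keep <- stack@layers$tss >= tssMin
  if (!any(keep)) stop("TSS filter removed all layers: empty stack")
  if (any(!keep))
    message(sum(!keep), " layer(s) removed by TSS < ", tssMin)
  SuitabilityStack(stack@cells, stack@values[, keep, drop = FALSE],
                   stack@layers[keep, , drop = FALSE], stack@occurrences)
}

#' TSS-weighted ensemble consensus for one period
#'
#' Per-cell weighted mean of the period's layers, weighted by each layer's
#' TSS. Invariant to layer order and to uniform rescaling of the weights.
#'
#' @param stack A \linkS4class{SuitabilityStack}.
#' @param period Period label.
#' @return data.frame with cell_id, x, y, suitability.
#' @export
ensembleMap <- function(stack, period) {
  sel <- which(stack@layers$period == period)
  if (length(sel) == 0) stop("no layers for period '", period, "'")
  w <- stack@layers$tss[sel]
  if (sum(w) <= 0) stop("zero total TSS weight for period '", period, "'")
  cons <- as.vector(stack@values[, sel, drop = FALSE] %*% w) / sum(w)
  cbind(stack@cells, suitability = cons)
}

#' Range size of a suitability map
#' @param map data.frame with a \code{suitability} column (or numeric vector).
#' @param threshold Suitability cut in [0, 1].
#' @return Number of cells at or above the threshold.
#' @export
rangeSize <- function(map, threshold = 0.5) {
  stopifnot(threshold >= 0)
  v <- if (is.data.frame(map)) map$suitability else map
  sum(v >= threshold)
}

#' Classify a predictive map pair into a range-shift scenario
#'
#' Compares predicted range size at the glacial maximum against the present:
#' a relative difference within \code{stabilityTol} of the larger range is
#' Stability; a larger present-day range is Expansion; a larger glacial range
#' is Retraction.
#'
#' @param sizeLGM,sizePresent Range sizes in cells (same threshold).
#' @param stabilityTol Relative tolerance for "no difference" (default 0.05).
#' @return "Stability", "Expansion", "Retraction", or NA (flagged with a
#'   warning) when both ranges are empty.
#' @export
classifyMap <- function(sizeLGM, sizePresent, stabilityTol = 0.05) {
  if (sizeLGM == 0 && sizePresent == 0) {
    warning("both range sizes are 0; label undefined")
    return(NA_character_)
  }
  shift <- sizePresent - sizeLGM
  if (abs(shift) <= stabilityTol * max(sizeLGM, sizePresent)) return("Stability")
  if (shift > 0) "Expansion" else "Retraction"
}

#' Range-shift scenario frequencies across (ENM, AOGCM) map pairs
#'
#' For every retained (ENM, AOGCM) combination, computes the range size at
#' the glacial maximum and at present from that combination's own layers,
#' classifies the shift, and reports the percentage of maps per label.
#'
#' @param stack A \linkS4class{SuitabilityStack} containing "LGM" and
#'   "present" periods.
#' @param threshold Binarisation threshold for range size (default 0.5).
#' @param stabilityTol Stability tolerance, see \code{\link{classifyMap}}.
#' @return List with \code{records} (data.frame enm, aogcm, size_lgm,
#'   size_present, shift, label) and \code{percent} (named percentages,
#'   one decimal).
#' @export
scenarioFrequencies <- function(stack, threshold = 0.5, stabilityTol = 0.05) {
  ly <- stack@layers
  pairs <- unique(ly[, c("enm", "aogcm")])
  if (nrow(pairs) == 0) stop("no (ENM, AOGCM) pairs in stack")
  rec <- list()
  for (i in seq_len(nrow(pairs))) {
    e <- pairs$enm[i]; a <- pairs$aogcm[i]
    iLGM <- which(ly$enm == e & ly$aogcm == a & ly$period == "LGM")
    iPre <- which(ly$enm == e & ly$aogcm == a & ly$period == "present")
    if (length(iLGM) != 1 || length(iPre) != 1) next
    sL <- rangeSize(stack@values[, iLGM], threshold)
    sP <- rangeSize(stack@values[, iPre], threshold)
    rec[[i]] <- data.frame(enm = e, aogcm = a, size_lgm = sL,
                           size_present = sP, shift = sP - sL,
                           label = classifyMap(sL, sP, stabilityTol))
  }
  rec <- do.call(rbind, rec)
  pct <- round(100 * table(factor(rec$label,
                                  levels = c("Stability", "Expansion",
                                             "Retraction"))) / nrow(rec), 1)
  list(records = rec, percent = c(pct))
}

#' Map the historical refugium
#'
#' Grid cells whose ensemble suitability is at or above the threshold in
#' every time period: climatically suitable throughout the glacial cycle.
#' Refugia are nested across thresholds (a higher threshold gives a subset).
#'
#' @param consensusMaps Named list of consensus maps (data.frames from
#'   \code{\link{ensembleMap}}), one per period, identical cell sets.
#' @param threshold Suitability threshold (default 0.5).
#' @return Character vector of refugium cell ids.
#' @export
refugium <- function(consensusMaps, threshold = 0.5) {
  stopifnot(length(consensusMaps) >= 1)
  ids <- consensusMaps[[1]]$cell_id
  for (m in consensusMaps)
    if (!identical(m$cell_id, ids)) stop("consensus maps differ in cell sets")
  ok <- Reduce(`&`, lapply(consensusMaps, function(m) m$suitability >= threshold))
  as.character(ids[ok])
}

#' Percentile of a threshold within occurrence-cell suitabilities
#'
#' The percentile rank of \code{threshold} among the consensus suitability
#' values at the occurrence cells (so a threshold at the 10th percentile
#' excludes the lowest 10 percent of occurrence suitabilities). The inverse
#' lookup (\code{percentileToThreshold}) returns the suitability value at a
#' given percentile for sensitivity runs.
#'
#' @param map Consensus map (data.frame cell_id, suitability).
#' @param occurrences Occurrence cell ids (non-empty).
#' @param threshold Suitability threshold.
#' @return Percentile in [0, 100].
#' @export
occurrencePercentile <- function(map, occurrences, threshold = 0.5) {
  if (length(occurrences) == 0) stop("no occurrence cells")
  v <- map$suitability[match(as.character(occurrences), map$cell_id)]
  if (anyNA(v)) stop("occurrence cells missing from map")
  100 * mean(v < threshold)
}

#' @rdname occurrencePercentile
#' @param percentile Percentile in [0, 100].
#' @export
percentileToThreshold <- function(map, occurrences, percentile) {
  if (length(occurrences) == 0) stop("no occurrence cells")
  v <- map$suitability[match(as.character(occurrences), map$cell_id)]
  unname(quantile(v, percentile / 100, type = 1))
}

#' Hierarchical variance partition of a suitability stack
#'
#' Per grid cell, a hierarchical ANOVA of suitability with ENM and AOGCM
#' nested in the time component but crossed in a two-way factorial within
#' each period: SS(time) between period means; SS(ENM within time) and
#' SS(AOGCM within time) as main effects within each period summed over
#' periods; and, the design having no replicates, the residual
#' SS(total) - SS(others) is the ENM x AOGCM interaction within periods.
#' Proportions are SS / SS(total); the summary is their mean across cells.
#'
#' @param stack A complete \linkS4class{SuitabilityStack} (every ENM x AOGCM
#'   x period combination present exactly once).
#' @return Object of class \code{VariancePartition}: list with \code{perCell}
#'   (data.frame of proportions), \code{summary} (mean proportions),
#'   \code{nConstant} (cells with constant response, excluded).
#' @export
variancePartition <- function(stack) {
  ly <- stack@layers
  enms <- sort(unique(ly$enm)); aogcms <- sort(unique(ly$aogcm))
  periods <- sort(unique(ly$period))
  E <- length(enms); A <- length(aogcms); P <- length(periods)
  idx <- array(NA_integer_, dim = c(E, A, P))
  for (l in seq_len(nrow(ly))) {
    idx[match(ly$enm[l], enms), match(ly$aogcm[l], aogcms),
        match(ly$period[l], periods)] <- l
  }
  if (anyNA(idx)) stop("incomplete ENM x AOGCM x period design")
  nc <- nrow(stack@cells)
  out <- matrix(NA_real_, nc, 4,
                dimnames = list(NULL, c("time", "enm_time", "aogcm_time",
                                        "residual")))
  nConst <- 0L
  for (ci in seq_len(nc)) {
    y <- array(stack@values[ci, idx], dim = c(E, A, P))
    g <- mean(y)
    ssTot <- sum((y - g)^2)
    if (ssTot < .Machine$double.eps * 100) { nConst <- nConst + 1L; next }
    pm <- apply(y, 3, mean)
    ssTime <- E * A * sum((pm - g)^2)
    em <- apply(y, c(1, 3), mean)   # E x P
    ssE <- A * sum(sweep(em, 2, pm)^2)
    am <- apply(y, c(2, 3), mean)   # A x P
    ssA <- E * sum(sweep(am, 2, pm)^2)
    ssRes <- ssTot - ssTime - ssE - ssA
    out[ci, ] <- c(ssTime, ssE, ssA, ssRes) / ssTot
  }
  ok <- !is.na(out[, 1])
  structure(list(perCell = data.frame(cell_id = stack@cells$cell_id, out),
                 summary = colMeans(out[ok, , drop = FALSE]),
                 nConstant = nConst,
                 design = c(E = E, A = A, P = P)),
            class = "VariancePartition")
}

#' @export
print.VariancePartition <- function(x, ...) {
  cat("Hierarchical variance partition (mean proportion across cells):\n")
  print(round(x$summary, 4))
  if (x$nConstant > 0)
    cat(x$nConstant, "constant cell(s) excluded\n")
  invisible(x)
}
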