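#' Convert calendar years to generations
#'
#' @param yearsBp Years before present (> 0).
#' @param generationTime Generation time in years (> 0, default 12).
#' @return Integer number of generations, \code{floor(yearsBp / generationTime)}.
#' @examples
#' yearsToGenerations(21000, 12)  # 1750: present back to the glacial maximum
#' @export
yearsToGenerations <- function(yearsBp, generationTime = 12) {
  if (yearsBp <= 0 || generationTime <= 0)
    stop("yearsBp and generationTime must be > 0")
  as.integer(floor(yearsBp / generationTime))
}

#' Build one of the four demographic scenarios
#'
#' Encodes the deme-size endpoints and migration regime of each hypothesis:
#' expansion reaches a ten-fold smaller size at the glacial maximum
#' (N(tEnd) = N0/10), retraction a five-fold larger one (N(tEnd) = 5 N0),
#' stability and multiple refugia keep sizes constant. Sink scenarios send
#' lineages to refugial deme 1; the multiple-refugia scenario is a finite
#' island model. See \linkS4class{ScenarioSpec} for the retraction mechanism
#' (source demes shrink backward to extinction, founder-effect style).
#'
#' @param name Scenario name.
#' @param N0 Present-day deme size (default 10000).
#' @param nDemes Number of demes (default 21).
#' @param tEnd Generations back to the glacial maximum (default 1750,
#'   i.e. 21 ka at a 12-year generation time).
#' @param migrationRate Per-lineage per-generation migration probability
#'   (default 0.01).
#' @return A \linkS4class{ScenarioSpec}.
#' @examples
#' buildScenario("expansion", 10000)   # N(tEnd) = 1000
#' buildScenario("retraction", 10000)  # N(tEnd) = 50000
#' @export
buildScenario <- function(name = c("stability", "expansion", "retraction",
                                   "multiple_refugia"),
                          N0 = 10000, nDemes = 21L, tEnd = 1750L,
                          migrationRate = 0.01) {
  name <- match.arg(name)
  spec <- switch(name,
    stability        = list(NEnd = N0,     mode = "sink_deme1"),
    expansion        = list(NEnd = N0 / 10, mode = "sink_deme1"),
    retraction       = list(NEnd = 5 * N0, mode = "sink_then_extinction"),
    multiple_refugia = list(NEnd = N0,     mode = "island"))
  new("ScenarioSpec", name = name, nDemes = as.integer(nDemes), N0 = N0,
      NEnd = spec$NEnd, tEnd = as.integer(tEnd),
      migrationRate = migrationRate, migrationMode = spec$mode)
}

#' Deme-size trajectory of a scenario
#'
#' N(t) = round(N0 exp(r t)) with r = ln(N(tEnd)/N0) / tEnd for
#' 0 <= t <= tEnd, and N(t) = N(tEnd) beyond; never below 1. Endpoints are
#' exact: N(0) = N0 and N(tEnd) = NEnd.
#'
#' @param spec A \linkS4class{ScenarioSpec}.
#' @param t Generations before present (vectorised).
#' @return Deme sizes (effective individuals).
#' @export
demeSize <- function(spec, t) {
  stopifnot(is(spec, "ScenarioSpec"), all(t >= 0))
  r <- if (spec@tEnd > 0) log(spec@NEnd / spec@N0) / spec@tEnd else 0
  n <- ifelse(t >= spec@tEnd, spec@NEnd, round(spec@N0 * exp(r * t)))
  pmax(1, n)
}

#' @rdname demeSize
#' @export
growthRate <- function(spec) {
  if (spec@tEnd == 0) return(0)
  log(spec@NEnd / spec@N0) / spec@tEnd
}

# gene-copy trajectory matrix ((tEnd+1) x nDemes) and post-tEnd copies.
# In the retraction scenario the canonical trajectory (growth to NEnd)
# applies to refugial deme 1; source demes decline exponentially from N0 to
# extinction (size 1) at tEnd, where their lineages are absorbed into deme 1.
.engineConfig <- function(spec, ploidyFactor) {
  tt <- 0:spec@tEnd
  canon <- demeSize(spec, tt) * ploidyFactor
  D <- spec@nDemes
  traj <- matrix(rep(canon, D), ncol = D)
  post <- rep(spec@NEnd * ploidyFactor, D)
  absorb <- FALSE
  migMode <- 0L
  m <- spec@migrationRate
  if (spec@migrationMode == "sink_deme1") {
    migMode <- 1L
    absorb <- TRUE
  } else if (spec@migrationMode == "island") {
    migMode <- 2L
  } else if (spec@migrationMode == "sink_then_extinction") {
    migMode <- 0L          # absorption happens at extinction, not gradually
    absorb <- TRUE
    if (D > 1 && spec@tEnd > 0) {
      rdecl <- log(1 / spec@N0) / spec@tEnd
      decl <- pmax(1, round(spec@N0 * exp(rdecl * tt))) * ploidyFactor
      traj[, 2:D] <- decl
      post[2:D] <- 0
    }
  }
  list(traj = traj, post = post, m = m, migMode = migMode, absorb = absorb)
}

#' Simulate a genealogy under a demographic scenario
#'
#' Exact backward-in-time Wright-Fisher structured coalescent: each
#' generation, lineages migrate according to the scenario's regime and then
#' draw parents uniformly from their deme's gene-copy pool (ploidyFactor *
#' deme size), so multiple and simultaneous mergers occur with their exact
#' Wright-Fisher probabilities. Sizes follow the scenario trajectory to
#' \code{tEnd} and are constant afterwards; sink scenarios place all
#' remaining ancestry in deme 1 at \code{tEnd}.
#'
#' @param spec A \linkS4class{ScenarioSpec}.
#' @param samples A \linkS4class{SampleConfig}; \code{counts} must have one
#'   entry per deme.
#' @param ploidyFactor Gene copies per individual (1 organellar, 2 nuclear).
#' @param rngSeed Optional seed.
#' @param maxGen Abort guard: give up if no MRCA by this generation
#'   (default \code{100 * tEnd + 50 * total gene copies}).
#' @return Object of class \code{Genealogy}: list with \code{tree} (an
#'   \code{ape::phylo}, tips contemporaneous at time 0, branch lengths in
#'   generations), \code{tipDeme}, \code{tmrca}, \code{mergeDemes}.
#' @export
backwardCoalescent <- function(spec, samples, ploidyFactor = 1L,
                               rngSeed = NULL, maxGen = NULL) {
  stopifnot(is(spec, "ScenarioSpec"), is(samples, "SampleConfig"))
  counts <- samples@counts
  if (length(counts) == 1L) counts <- rep(counts, spec@nDemes)
  if (length(counts) != spec@nDemes)
    stop("sample counts must have one entry per deme")
  if (!is.null(rngSeed)) set.seed(rngSeed)
  cfg <- .engineConfig(spec, ploidyFactor)
  if (is.null(maxGen))
    maxGen <- 100 * spec@tEnd + 50 * sum(cfg$post[cfg$post > 0]) +
      50 * spec@nDemes * spec@N0 * ploidyFactor
  lineageDeme <- rep(seq_len(spec@nDemes), counts)
  res <- .sim_coalescent_cpp(as.integer(lineageDeme), cfg$traj, cfg$post,
                             cfg$m, cfg$migMode, spec@tEnd, cfg$absorb,
                             maxGen)
  if (!is.null(res$error)) stop("coalescent simulation failed: ", res$error)
  n <- res$n_tips
  tipDeme <- lineageDeme
  tree <- .buildPhylo(n, res$parent, res$child, res$node_time)
  structure(list(tree = tree, tipDeme = tipDeme, tmrca = res$tmrca,
                 mergeDemes = res$merge_deme, nodeTimes = res$node_time,
                 scenario = spec@name),
            class = "Genealogy")
}

# assemble an ape phylo from the engine's merge records; internal nodes are
# renumbered so the root (last merge) is node n+1 as ape expects
.buildPhylo <- function(n, parent, child, nodeTime) {
  nNode <- length(nodeTime) - n
  remap <- function(x) ifelse(x <= n, x, n + 1 + (n + nNode - x))
  p <- remap(parent); ch <- remap(child)
  tm <- numeric(n + nNode)
  tm[remap(seq_along(nodeTime))] <- nodeTime
  edge <- cbind(p, ch)
  len <- tm[p] - tm[ch]
  tr <- list(edge = edge, edge.length = len,
             tip.label = paste0("t", seq_len(n)), Nnode = nNode)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "nodeTimes") <- tm
  tr
}

#' @export
print.Genealogy <- function(x, ...) {
  cat(sprintf("Genealogy (%s scenario): %d tips, TMRCA = %g generations\n",
              x$scenario, length(x$tree$tip.label), x$tmrca))
  invisible(x)
}

#' Export a genealogy as newick with deme annotations
#' @param gen A Genealogy.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
writeGenealogy <- function(gen, file) {
  tr <- gen$tree
  tr$tip.label <- paste0(tr$tip.label, "_deme", gen$tipDeme)
  ape::write.tree(tr, file)
  invisible(file)
}
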