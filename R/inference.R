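#' Observed summary statistics (cross-population means)
#'
#' Defaults are the study's observed cross-population mean haplotype and
#' nucleotide diversities for the organellar (cp) and nuclear (its) loci.
#'
#' @param cp_h,cp_pi,its_h,its_pi Observed means.
#' @return Named list, one element per locus, each with \code{mean_h} and
#'   \code{mean_pi}.
#' @export
observedSummary <- function(cp_h = 0.220, cp_pi = 0.0093,
                            its_h = 0.089, its_pi = 0.0006) {
  list(cp = list(mean_h = cp_h, mean_pi = cp_pi),
       its = list(mean_h = its_h, mean_pi = its_pi))
}

#' Empirical-distribution likelihood of an observed value
#'
#' The likelihood of an observed summary statistic under a scenario is read
#' off the simulated values' Gaussian kernel density (Silverman's rule-of-
#' thumb bandwidth) at the observation. The default, \code{method =
#' "product"}, is the height of the empirical frequency distribution at the
#' observed value multiplied by the distribution's maximum height -- it
#' rewards scenarios that are both concentrated and dense at the observation.
#' \code{method = "ratio"} instead normalises the height by the maximum,
#' L = f(obs) / max f in (0, 1], which only measures relative position within
#' a scenario's own distribution and therefore favours diffuse scenarios;
#' both are kept so the choice is auditable. When the observation falls
#' outside [min - bw, max + bw] of the simulated values the likelihood is
#' undefined under either method (the scenario cannot produce the
#' observation), mirroring the dashes of the scenario-comparison table.
#'
#' @param values Simulated statistic values (one per replicate; at least 50
#'   recommended for a stable density).
#' @param obs Observed value.
#' @param method "product" (default) or "ratio".
#' @return List with \code{L}, \code{logL}, \code{bw}, \code{defined}.
#' @export
empiricalLikelihood <- function(values, obs, method = c("product", "ratio")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 simulated values")
  if (length(values) < 50)
    warning("fewer than 50 simulated values; density estimate is unstable")
  if (max(values) - min(values) < .Machine$double.eps * 10) {
    defined <- isTRUE(all.equal(obs, values[1]))
    return(list(L = if (defined) 1 else NA_real_,
                logL = if (defined) 0 else NA_real_,
                bw = 0, defined = defined))
  }
  bw <- stats::bw.nrd0(values)
  if (obs < min(values) - bw || obs > max(values) + bw)
    return(list(L = NA_real_, logL = NA_real_, bw = bw, defined = FALSE))
  fobs <- mean(stats::dnorm(obs, mean = values, sd = bw))
  dd <- stats::density(values, bw = bw, n = 1024)
  fmax <- max(dd$y)
  L <- if (method == "ratio") min(fobs / fmax, 1) else fobs * fmax
  list(L = L, logL = log(L), bw = bw, defined = TRUE)
}

#' One-tailed probability of an observed value
#'
#' Under the median-side convention (default) the tail is the side of the
#' simulated median the observation falls on, and P is the smoothed fraction
#' of simulated values at least as extreme: (b + 1) / (B + 1). An observation
#' exactly at the median gives 0.5. The alternative convention
#' \code{"below"} reports the smoothed fraction of simulated values at or
#' below the observation (an acceptance-style probability; both are reported
#' by \code{\link{compareScenarios}}).
#'
#' @param values Simulated values.
#' @param obs Observed value.
#' @param convention "median_side" or "below".
#' @return Probability in (0, 1).
#' @export
oneTailedP <- function(values, obs, convention = c("median_side", "below")) {
  convention <- match.arg(convention)
  B <- length(values)
  if (convention == "below")
    return((sum(values <= obs) + 1) / (B + 1))
  med <- median(values)
  if (obs == med) return(0.5)
  b <- if (obs > med) sum(values >= obs) else sum(values <= obs)
  (b + 1) / (B + 1)
}

#' AIC table from empirical likelihoods
#'
#' AIC = -2 logL + 2k with the parameter count k equal across scenarios (the
#' four hypotheses have the same free-parameter structure, so the AIC ranking
#' equals the likelihood ranking); dAIC = AIC - min AIC over the defined
#' scenarios; AICw = exp(-0.5 dAIC) (so the best model has weight 1), with a
#' normalised column summing to 1 alongside. Scenarios whose likelihood is
#' undefined stay undefined. dAIC < 2 flags a scenario as equally plausible.
#'
#' @param logL Named numeric vector of log-likelihoods (NA = undefined).
#' @param k Parameter count (default 0).
#' @return data.frame with scenario, logL, AIC, dAIC, AICw, AICw_norm,
#'   defined, equally_plausible.
#' @export
aicTable <- function(logL, k = 0) {
  if (all(is.na(logL))) stop("all likelihoods undefined; comparison undefined")
  aic <- -2 * logL + 2 * k
  daic <- aic - min(aic, na.rm = TRUE)
  w <- exp(-0.5 * daic)
  data.frame(scenario = names(logL), logL = unname(logL), AIC = unname(aic),
             dAIC = unname(daic), AICw = unname(w),
             AICw_norm = unname(w / sum(w, na.rm = TRUE)),
             defined = !is.na(logL),
             equally_plausible = !is.na(daic) & daic < 2,
             row.names = NULL)
}

#' Compare demographic scenarios against observed diversity
#'
#' For each locus and statistic (cross-population mean haplotype and
#' nucleotide diversity), evaluates each scenario's empirical-distribution
#' likelihood at the observed value, converts to AIC / dAIC / AICw, and
#' attaches the one-tailed P under both conventions. The layout mirrors the
#' scenario-comparison table: scenario rows; per-locus, per-statistic
#' dAIC / AICw / P columns, with undefined entries reported as NA (rendered
#' "-" in the TSV output).
#'
#' @param batches Named list of \linkS4class{SimulationSummary}, one per
#'   scenario.
#' @param observed Observed summary as from \code{\link{observedSummary}}
#'   (names must match the loci in the batches).
#' @param statistics Which statistics to compare.
#' @param method Likelihood method, see \code{\link{empiricalLikelihood}}.
#' @return A \linkS4class{ModelComparison}.
#' @export
compareScenarios <- function(batches, observed = observedSummary(),
                             statistics = c("mean_h", "mean_pi"),
                             method = "product") {
  stopifnot(length(batches) >= 1)
  if (is.null(names(batches)))
    names(batches) <- vapply(batches, function(b) b@scenario@name, "")
  loci <- unique(batches[[1]]@stats$locus)
  for (b in batches)
    if (!identical(sort(unique(b@stats$locus)), sort(loci)))
      stop("batches disagree on loci; mismatched batch shapes")
  rows <- list()
  meta <- list()
  for (lc in loci) {
    if (is.null(observed[[lc]]))
      stop("no observed summary for locus '", lc, "'")
    for (st in statistics) {
      obs <- observed[[lc]][[st]]
      vals <- lapply(batches, function(b) {
        s <- b@stats
        s[s$locus == lc, st]
      })
      lik <- lapply(vals, empiricalLikelihood, obs = obs, method = method)
      logL <- vapply(lik, `[[`, 0, "logL")
      names(logL) <- names(batches)
      tab <- if (all(is.na(logL))) {
        data.frame(scenario = names(logL), logL = NA_real_, AIC = NA_real_,
                   dAIC = NA_real_, AICw = NA_real_, AICw_norm = NA_real_,
                   defined = FALSE, equally_plausible = FALSE)
      } else aicTable(logL)
      tab$P <- vapply(seq_along(vals), function(i)
        if (is.na(logL[i])) NA_real_ else oneTailedP(vals[[i]], obs), 0)
      tab$P_below <- vapply(vals, oneTailedP, 0, obs = obs,
                            convention = "below")
      tab$locus <- lc
      tab$statistic <- st
      rows[[paste(lc, st)]] <- tab
      meta[[paste(lc, st)]] <- list(bw = vapply(lik, `[[`, 0, "bw"),
                                    nReps = vapply(vals, length, 0L))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- tab[, c("scenario", "locus", "statistic", "logL", "AIC", "dAIC",
                 "AICw", "AICw_norm", "P", "P_below", "defined",
                 "equally_plausible")]
  new("ModelComparison", table = tab, observed = observed,
      meta = list(perStat = meta, method = method,
                  seeds = vapply(batches, function(b) b@seed, 0L)))
}

#' Combined-evidence scenario assignment
#'
#' Assigns an observation to one scenario by summing dAIC over all (locus,
#' statistic) entries of a \linkS4class{ModelComparison}. A scenario whose
#' likelihood is undefined for a statistic cannot have produced that
#' observation and is treated as infinitely penalised there (statistics where
#' every scenario is undefined are dropped). Note this combined score is a
#' convenience for recovery experiments; the per-statistic table is the
#' primary output.
#'
#' @param cmp A \linkS4class{ModelComparison}.
#' @return Name of the winning scenario (NA if no scenario is defined for any
#'   statistic).
#' @export
bestScenario <- function(cmp) {
  tab <- cmp@table
  tab$key <- paste(tab$locus, tab$statistic)
  keep <- vapply(split(tab$defined, tab$key), any, TRUE)
  tab <- tab[keep[tab$key], , drop = FALSE]
  if (nrow(tab) == 0) return(NA_character_)
  sc <- unique(tab$scenario)
  score <- vapply(sc, function(s) {
    d <- tab$dAIC[tab$scenario == s]
    if (anyNA(d)) Inf else sum(d)
  }, 0)
  if (all(!is.finite(score))) {
    # every scenario undefined somewhere: fall back to most dAIC = 0 wins
    wins <- vapply(sc, function(s)
      sum(tab$dAIC[tab$scenario == s] == 0, na.rm = TRUE), 0)
    return(sc[which.max(wins)])
  }
  sc[which.min(score)]
}
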