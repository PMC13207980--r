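#' End-to-end entropy pipeline for one sex
#'
#' Convenience wrapper chaining the standard analysis path on a cohort:
#' per-bin fragment counting, group-minimum downsampling (grouped by sex),
#' per-ecotype entropy profiles, the freshwater-minus-marine delta of the
#' between-individual component, DI assignment by central CpG, and a
#' Wilcoxon comparison of delta inside divergence islands against the
#' background.
#'
#' @param cohort an \code{epiCohort} from \code{\link{simulateCohort}}, or a
#'   list with elements \code{epireads}, \code{windows}, \code{diRegions}.
#' @param sex which sex to analyze (sexes are processed independently).
#' @param minReads,perSampleMin entropy coverage minima.
#' @param binSize coverage bin length.
#' @param seed seed for the downsampling streams.
#' @return list: \code{profileFresh}, \code{profileMarine}, \code{delta},
#'   \code{assignment}, \code{test} (DI vs background
#'   \code{\link{compareGroups}} row), \code{downsampled}.
#' @export
runEntropyPipeline <- function(cohort, sex = "male", minReads = 32L,
                               perSampleMin = 8L, binSize = 1000L,
                               seed = 1L) {
  epi <- cohort$epireads
  windows <- cohort$windows
  cov <- countFragmentsPerBin(epi, binSize = binSize)
  targets <- groupMinimumTargets(cov, cohortDesign(epi), groupBy = "sex")
  ds <- downsampleReads(epi, targets, seed = seed)
  tally <- tallyEpialleles(ds, windows)
  pf <- entropyProfile(ds, windows, sex = sex, ecotype = "freshwater",
                       minReads = minReads, perSampleMin = perSampleMin,
                       tally = tally)
  pm <- entropyProfile(ds, windows, sex = sex, ecotype = "marine",
                       minReads = minReads, perSampleMin = perSampleMin,
                       tally = tally)
  delta <- deltaBetween(pf, pm)
  asg <- assignWindows(windows, cohort$diRegions)
  di <- delta$delta[asg$zone == "core"]
  bg <- delta$delta[asg$zone == "background"]
  test <- if (any(is.finite(di)) && any(is.finite(bg)))
    compareGroups(di, bg) else NULL
  list(profileFresh = pf, profileMarine = pm, delta = delta,
       assignment = asg, test = test, downsampled = ds)
}
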