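# Gamma-method TMRCA estimation. Under a star genealogy each carrier's
# ancestral haplotype extends an Exponential(g)-per-Morgan distance to
# either side of the mutation, so the sum of n two-sided lengths is
# Gamma(2n, g) distributed; the MLE is g-hat = 2n / sum(L) with exact
# gamma-quantile confidence bounds.

#' Gamma-method TMRCA from shared ancestral haplotype lengths
#'
#' @details In `independent` (star-genealogy) mode with two-sided lengths,
#' \eqn{\sum L \sim \Gamma(2n, g)} (lengths in Morgans), giving the MLE
#' \eqn{\hat g = 2n / \sum L} and the exact interval
#' \eqn{[Q(\alpha/2; 2n, 1)/\sum L,\; Q(1-\alpha/2; 2n, 1)/\sum L]}.
#' One-sided lengths (segments truncated at a chromosome end) use shape
#' n. `correlated` mode handles shared ancestry more recent than the
#' common ancestor of all samples by discounting the effective number of
#' independent lengths with an exchangeable-correlation adjustment
#' \eqn{n_{eff} = n / (1 + (n-1)\rho)}; at `rho = 0` it reduces exactly
#' to independent mode.
#'
#' @param lengthsCm positive haplotype lengths in cM (the lengths of the
#'   IBD segments carrying the mutation).
#' @param mode `"independent"` or `"correlated"`.
#' @param rho exchangeable correlation between lengths (correlated mode
#'   only), in [0, 1).
#' @param oneSided lengths are one-sided (shape n instead of 2n).
#' @param biasCorrected use (shape - 1)/sum instead of the MLE.
#' @param conf confidence level, default 0.95.
#' @param generationTime years per generation (default 20), used by the
#'   show method and [generationsToYears()].
#' @return a [TMRCAEstimate-class].
#' @examples
#' gammaTMRCA(20)                      # single 20 cM segment: g-hat = 10
#' gammaTMRCA(rep(20, 5))              # five segments: g-hat = 10, tighter CI
#' @export
gammaTMRCA <- function(lengthsCm, mode = c("independent", "correlated"),
                       rho = 0, oneSided = FALSE, biasCorrected = FALSE,
                       conf = 0.95, generationTime = 20) {
  mode <- match.arg(mode)
  .assert(length(lengthsCm) >= 1L, "no haplotype lengths supplied",
          class = "datingError")
  .assert(all(lengthsCm > 0), "haplotype lengths must be positive",
          class = "datingError")
  .assert(rho >= 0 && rho < 1, "rho must be in [0, 1)",
          class = "datingError")
  n <- length(lengthsCm)
  S <- sum(lengthsCm) / 100  # Morgans
  nEff <- if (mode == "correlated") n / (1 + (n - 1) * rho) else n
  shape <- if (oneSided) nEff else 2 * nEff
  gHat <- if (biasCorrected && shape > 1) (shape - 1) / S else shape / S
  alpha <- (1 - conf) / 2
  ciLow <- stats::qgamma(alpha, shape = shape, rate = 1) / S
  ciHigh <- stats::qgamma(1 - alpha, shape = shape, rate = 1) / S
  new("TMRCAEstimate", nLengths = as.integer(n), totalMorgans = S,
      gHat = gHat, ciLow = ciLow, ciHigh = ciHigh, mode = mode,
      generationTime = as.numeric(generationTime))
}

#' Convert generations to years
#'
#' @param g generations (>= 0), vectorised.
#' @param generationTime years per generation, default 20.
#' @return years.
#' @examples
#' generationsToYears(11)  # 220
#' generationsToYears(17)  # 340
#' @export
generationsToYears <- function(g, generationTime = 20) {
  .assert(all(g >= 0), "generations must be non-negative",
          class = "datingError")
  g * generationTime
}

#' TMRCA estimate as an integer generation/year range
#'
#' CI bounds rounded half-up to integers, with the matching year range.
#'
#' @param est a [TMRCAEstimate-class].
#' @return list `generations` (length 2) and `years` (length 2).
#' @export
tmrcaRange <- function(est) {
  gen <- .roundHalfUp(c(est@ciLow, est@ciHigh))
  list(generations = gen,
       years = generationsToYears(gen, est@generationTime))
}

#' Select samples for mutation dating
#'
#' The Gamma method assumes (approximately) independent lineages, so close
#' relatives must not both enter the calculation. Greedy selection: one
#' sample per family — the one with the highest number of locus-network
#' connections (ties by smallest sample id) — then samples closer than
#' `minDegree` to an already retained sample are dropped, in decreasing
#' connection-count order.
#'
#' @param network a [LocusNetwork-class].
#' @param cluster cluster label to select within.
#' @param families named character vector sample -> family id; samples
#'   missing from it are treated as their own (sporadic) family.
#' @param pairs pairwise relatedness table ([pairwiseRelatedness()]);
#'   pairs absent from it are treated as unrelated.
#' @param minDegree minimum pairwise degree among retained samples
#'   (default 6).
#' @return character vector of retained sample ids.
#' @export
selectDatingSamples <- function(network, cluster, families, pairs,
                                minDegree = 6) {
  nodes <- network@nodes[network@nodes$cluster == cluster, , drop = FALSE]
  .assert(nrow(nodes) > 0L, "cluster '%s' not in network", cluster)
  fam <- unname(families[nodes$sample])
  fam[is.na(fam)] <- paste0("sporadic:", nodes$sample[is.na(fam)])
  # one representative per family: most connected, ties by id
  ord <- order(fam, -nodes$degree, nodes$sample)
  reps <- nodes[ord, ][!duplicated(fam[ord]), , drop = FALSE]
  degOf <- function(a, b) {
    hit <- (pairs$sample_a == a & pairs$sample_b == b) |
      (pairs$sample_a == b & pairs$sample_b == a)
    if (!any(hit)) return(Inf)
    min(degreeNumber(pairs$degree_hat[hit]))
  }
  reps <- reps[order(-reps$degree, reps$sample), , drop = FALSE]
  kept <- character()
  for (s in reps$sample) {
    if (all(vapply(kept, function(k) degOf(s, k) >= minDegree,
                   logical(1))))
      kept <- c(kept, s)
  }
  .assert(length(kept) > 0L,
          "no samples retained for cluster %s; try a lower minDegree",
          cluster, class = "datingError")
  sort(kept)
}
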