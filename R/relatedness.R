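# Degree-of-relatedness estimation from genome-wide IBD sharing.
# Kinship is phi-hat = (0.25 * IBD1 + 0.5 * IBD2) / map length, and the
# degree follows the convention phi = 2^(-d-1) (d = 1 full siblings,
# d = 3 first cousins, d = 5 second cousins, d = 7 third cousins).

#' Degree-estimation parameters
#'
#' @param poIbd1Frac minimum genome fraction in IBD1 to call a pair
#'   parent-offspring (default 0.95).
#' @param poIbd2Max maximum genome fraction in IBD2 for a PO call
#'   (default 0.02): siblings carry IBD2, parent-offspring essentially
#'   none, which disambiguates the two kinship-0.25 relationships.
#' @param urKinship kinship below which a pair is called unrelated;
#'   default `2^-13`, i.e. beyond 11th degree.
#' @param maxDegree largest reported degree (default 11).
#' @return list of parameters for [estimateDegree()].
#' @export
degreeParams <- function(poIbd1Frac = 0.95, poIbd2Max = 0.02,
                         urKinship = 2^-13, maxDegree = 11L) {
  list(poIbd1Frac = poIbd1Frac, poIbd2Max = poIbd2Max,
       urKinship = urKinship, maxDegree = as.integer(maxDegree))
}

#' Kinship coefficient from an IBD profile
#'
#' \eqn{\hat\varphi = (0.25 L_{IBD1} + 0.5 L_{IBD2}) / L_{map}} where the
#' lengths are in cM over the full analysed genome.
#'
#' @param profile output of [ibdProfile()] for one pair.
#' @param map the [GeneticMap-class] defining the total map length.
#' @return kinship estimate, a value between 0 and 0.5.
#' @export
kinshipFromProfile <- function(profile, map) {
  total <- mapLengthCM(map)
  .assert(total > 0, "zero-length genetic map")
  len <- profile$end_cm - profile$start_cm
  l1 <- sum(len[profile$state == 1L])
  l2 <- sum(len[profile$state == 2L])
  (0.25 * l1 + 0.5 * l2) / total
}

#' Map kinship (and IBD fractions) to a degree of relatedness
#'
#' A pair is `"PO"` when IBD1 covers at least `poIbd1Frac` of the genome
#' with IBD2 at most `poIbd2Max`; `"UR"` when the kinship falls below the
#' unrelated threshold (or there is no sharing); otherwise the degree is
#' `round(-log2(kinship)) - 1` (half-up rounding, so ties at the
#' `2^(-d-0.5)` midpoints go to the closer degree), clamped to
#' `[1, maxDegree]`.
#'
#' @param kinship kinship estimate (vectorised).
#' @param ibd1Frac,ibd2Frac genome fractions in IBD1/IBD2.
#' @param params see [degreeParams()].
#' @return character vector: `"PO"`, `"UR"` or `"1".."11"`.
#' @examples
#' estimateDegree(1/16, 0.25, 0)   # first cousins -> "3"
#' estimateDegree(2^-8, 0.03, 0)   # third cousins -> "7"
#' @export
estimateDegree <- function(kinship, ibd1Frac, ibd2Frac,
                           params = degreeParams()) {
  n <- length(kinship)
  out <- character(n)
  po <- ibd1Frac >= params$poIbd1Frac & ibd2Frac <= params$poIbd2Max
  ur <- kinship < params$urKinship
  d <- pmin(pmax(.roundHalfUp(-log2(pmax(kinship, 1e-300))) - 1, 1),
            params$maxDegree)
  out[] <- as.character(d)
  out[po] <- "PO"
  out[ur & !po] <- "UR"
  out
}

#' Numeric rank of a degree label
#'
#' `"PO"` maps to 1 (a first-degree relationship), `"UR"` to `Inf`;
#' numeric labels map to their value. Used for within-plus/minus-one
#' concordance and degree thresholds.
#'
#' @param degree character degree labels.
#' @return numeric vector.
#' @export
degreeNumber <- function(degree) {
  out <- suppressWarnings(as.numeric(degree))
  out[degree == "PO"] <- 1
  out[degree == "UR"] <- Inf
  out
}

#' Pairwise relatedness table from IBD segments
#'
#' Builds the IBD profile of every sample pair present in `segments`
#' (plus, optionally, all remaining pairs of `samples` as zero-sharing
#' rows), computes total IBD1/IBD2 cM, the kinship estimate and the
#' estimated degree.
#'
#' @param segments genome-wide segment data.frame.
#' @param map a [GeneticMap-class].
#' @param samples optional sample ids; when given, pairs without segments
#'   are included as `"UR"` rows.
#' @param reported optional truth/pedigree degrees: data.frame
#'   `sample_a, sample_b, degree` (canonical pair order not required).
#' @param params see [degreeParams()].
#' @return data.frame `sample_a, sample_b, total_ibd1_cm, total_ibd2_cm,
#'   kinship_hat, degree_hat` (+ `reported_degree` when supplied).
#' @export
pairwiseRelatedness <- function(segments, map, samples = NULL,
                                reported = NULL, params = degreeParams()) {
  .validateSegmentFrame(segments)
  total <- mapLengthCM(map)
  key <- paste(segments$sample_a, segments$sample_b, sep = "\r")
  pairs <- unique(key)
  rows <- lapply(pairs, function(k) {
    sub <- segments[key == k, , drop = FALSE]
    prof <- ibdProfile(sub, map)
    len <- prof$end_cm - prof$start_cm
    l1 <- sum(len[prof$state == 1L])
    l2 <- sum(len[prof$state == 2L])
    data.frame(sample_a = sub$sample_a[1], sample_b = sub$sample_b[1],
               total_ibd1_cm = l1, total_ibd2_cm = l2,
               kinship_hat = (0.25 * l1 + 0.5 * l2) / total,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows) %||%
    data.frame(sample_a = character(), sample_b = character(),
               total_ibd1_cm = numeric(), total_ibd2_cm = numeric(),
               kinship_hat = numeric())
  if (!is.null(samples) && length(samples) >= 2L) {
    cmb <- utils::combn(sort(samples), 2L)
    have <- paste(tab$sample_a, tab$sample_b, sep = "\r")
    want <- paste(cmb[1, ], cmb[2, ], sep = "\r")
    miss <- which(!(want %in% have))
    if (length(miss))
      tab <- rbind(tab, data.frame(
        sample_a = cmb[1, miss], sample_b = cmb[2, miss],
        total_ibd1_cm = 0, total_ibd2_cm = 0, kinship_hat = 0,
        stringsAsFactors = FALSE))
  }
  tab$degree_hat <- estimateDegree(tab$kinship_hat,
                                   tab$total_ibd1_cm / total,
                                   tab$total_ibd2_cm / total, params)
  if (!is.null(reported) && nrow(tab)) {
    repKey <- c(stats::setNames(reported$degree,
                                paste(reported$sample_a,
                                      reported$sample_b, sep = "\r")),
                stats::setNames(reported$degree,
                                paste(reported$sample_b,
                                      reported$sample_a, sep = "\r")))
    tab$reported_degree <- unname(
      repKey[paste(tab$sample_a, tab$sample_b, sep = "\r")])
  }
  rownames(tab) <- NULL
  tab
}

#' Find novel relatives across families
#'
#' Returns pairs from different families (or involving sporadic samples,
#' i.e. samples with no family) whose estimated degree does not exceed
#' `maxDegree` — the candidates for previously unrecognised relatedness.
#'
#' @param pairs output of [pairwiseRelatedness()].
#' @param families named character vector sample -> family id; samples
#'   missing from it (or with `NA`) are treated as sporadic.
#' @param maxDegree largest reported degree (default 7, the practical
#'   accuracy limit of IBD-based degree estimation).
#' @param mutations optional named character vector of mutation labels.
#' @return data.frame `family_a, sample_a, family_b, sample_b, degree_hat,
#'   mutation_a, mutation_b`, sorted by increasing degree.
#' @export
findNovelRelatives <- function(pairs, families, maxDegree = 7,
                               mutations = NULL) {
  famOf <- function(s) {
    f <- unname(families[s])
    ifelse(is.na(f), paste0("sporadic:", s), f)
  }
  mutOf <- function(s) {
    if (is.null(mutations)) return(rep(NA_character_, length(s)))
    unname(mutations[s])
  }
  if (nrow(pairs) == 0L) keep <- logical(0) else {
    fa <- famOf(pairs$sample_a)
    fb <- famOf(pairs$sample_b)
    dn <- degreeNumber(pairs$degree_hat)
    keep <- fa != fb & dn <= maxDegree
  }
  sub <- pairs[keep, , drop = FALSE]
  out <- data.frame(family_a = famOf(sub$sample_a), sample_a = sub$sample_a,
                    family_b = famOf(sub$sample_b), sample_b = sub$sample_b,
                    degree_hat = sub$degree_hat,
                    mutation_a = mutOf(sub$sample_a),
                    mutation_b = mutOf(sub$sample_b),
                    stringsAsFactors = FALSE)
  out <- out[order(degreeNumber(out$degree_hat), out$sample_a), ]
  rownames(out) <- NULL
  out
}

#' Concordance between reported and estimated degrees
#'
#' Per reported degree, the number of pairs and the fraction estimated
#' within one degree of the report (PO counting as first degree).
#'
#' @param pairs output of [pairwiseRelatedness()] with a
#'   `reported_degree` column.
#' @return data.frame `reported_degree, n_pairs, frac_within_one`, plus an
#'   `"overall"` attribute with the pooled fraction.
#' @export
concordanceSummary <- function(pairs) {
  .assert("reported_degree" %in% names(pairs),
          "pairs must carry a reported_degree column")
  sub <- pairs[!is.na(pairs$reported_degree), , drop = FALSE]
  repN <- degreeNumber(sub$reported_degree)
  estN <- degreeNumber(sub$degree_hat)
  ok <- abs(estN - repN) <= 1
  ok[is.infinite(repN) & is.infinite(estN)] <- TRUE
  lev <- unique(sub$reported_degree[order(repN)])
  out <- do.call(rbind, lapply(lev, function(d) {
    sel <- sub$reported_degree == d
    data.frame(reported_degree = d, n_pairs = sum(sel),
               frac_within_one = mean(ok[sel]), stringsAsFactors = FALSE)
  })) %||% data.frame(reported_degree = character(), n_pairs = integer(),
                      frac_within_one = numeric())
  attr(out, "overall") <- if (nrow(sub)) mean(ok) else NA_real_
  out
}
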