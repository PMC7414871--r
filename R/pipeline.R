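# End-to-end orchestration: simulate (or read) -> detect -> relate ->
# network -> founder haplotypes -> date, with study-shaped report tables.

#' Expected related pairs per family
#'
#' Within a family of n sequenced carriers every unordered 2-sample
#' combination is an expected related pair, i.e. C(n, 2).
#'
#' @param familySizes named non-negative integer vector family -> count.
#' @return list with `per_family` (data.frame `family, n, pairs`) and
#'   `total`.
#' @examples
#' expectedRelatedPairs(sod1FamilySizes())$total  # 625
#' @export
expectedRelatedPairs <- function(familySizes) {
  .assert(all(familySizes >= 0), "family sizes must be non-negative")
  tab <- data.frame(family = names(familySizes) %||%
                      as.character(seq_along(familySizes)),
                    n = as.integer(familySizes),
                    pairs = choose(as.integer(familySizes), 2L),
                    stringsAsFactors = FALSE)
  list(per_family = tab, total = sum(tab$pairs))
}

#' Family sizes of the Australian SOD1 ALS cohort
#'
#' Numbers of sequenced mutation carriers per family among the 83
#' familial cases (25 families) of the Australian SOD1 cohort; the three
#' sporadic carriers have no family. These counts give 625 expected
#' related pairs in total (e.g. 496 for family 18, 105 for family 12).
#'
#' @return named integer vector family id -> carrier count.
#' @export
sod1FamilySizes <- function() {
  c(`3` = 6L, `12` = 15L, `18` = 32L, `35` = 1L, `43` = 2L, `76` = 1L,
    `95` = 2L, `98` = 1L, `106` = 1L, `123` = 1L, `124` = 2L, `130` = 1L,
    `131` = 1L, `132` = 3L, `197` = 2L, `213` = 1L, `259` = 1L,
    `267` = 1L, `270` = 1L, `274` = 1L, `286` = 1L, `334` = 2L,
    `374` = 2L, mq10 = 1L, mq36 = 1L)
}

#' Descriptive anchors of the original SOD1 cohort
#'
#' Headline quantities reported for the restricted clinical cohort the
#' pipeline was designed around. They depend on patient data that are not
#' publicly available, so they are documentation anchors only — nothing in
#' this package recomputes them, and the synthetic cohorts are not
#' calibrated to reproduce them.
#'
#' @return data.frame `name, value, units, note`.
#' @export
cohortAnchors <- function() {
  data.frame(
    name = c("genomewide_segments", "chr21_segments", "sharing_pairs",
             "expected_pairs", "founder_haplotype_snps",
             "report_interval_kb", "report_interval_cm",
             "tmrca_pV149G_low", "tmrca_pV149G_high",
             "tmrca_pI114T_C1_low", "tmrca_pI114T_C1_high",
             "tmrca_pI114T_C4_low", "tmrca_pI114T_C4_high"),
    value = c(16414, 1204, 954, 625, 350, 481, 0.56,
              3, 11, 5, 18, 1, 11),
    units = c("segments >= 3 cM", "segments >= 3 cM", "pairs", "pairs",
              "SNPs", "kb", "cM", rep("generations", 6)),
    note = c(rep("restricted cohort; not recomputable", 7),
             rep("95% interval, 20-year generation time", 6)),
    stringsAsFactors = FALSE)
}

#' Ancestral haplotype lengths for dating a cluster
#'
#' Per selected sample, the length (cM) of its longest locus-overlapping
#' IBD segment with another selected sample — the inferred extent of the
#' shared ancestral haplotype carrying the mutation.
#'
#' @param segments segment data.frame.
#' @param locus a [LocusSpec-class].
#' @param samples the selected (approximately independent) samples.
#' @return numeric cM lengths, one per sample with at least one
#'   qualifying segment.
#' @export
datingLengths <- function(segments, locus, samples) {
  ov <- segments$chrom == locus@chrom &
    segments$start_bp <= locus@endBp & segments$end_bp >= locus@startBp &
    segments$sample_a %in% samples & segments$sample_b %in% samples
  sub <- segments[ov, , drop = FALSE]
  lens <- vapply(samples, function(s) {
    sel <- sub$sample_a == s | sub$sample_b == s
    if (!any(sel)) NA_real_ else max(sub$length_cm[sel])
  }, numeric(1))
  unname(lens[!is.na(lens)])
}

# wrap a pipeline stage so failures carry the stage name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("stage %s: %s", name, conditionMessage(e),
           class = "pipelineError"))
}

#' Run the full founder-event pipeline
#'
#' Simulates (or loads) a phased cohort, detects IBD segments, estimates
#' pairwise relatedness, builds the locus network, extracts founder
#' haplotypes, flags discordant edges, reports novel relatives and dates
#' each datable cluster. Deterministic given the seed and inputs.
#'
#' @param config list with elements
#'   \describe{
#'     \item{sim}{a [SimConfig-class] (synthetic run), or}
#'     \item{vcf, map, mutations}{paths to a phased VCF, a PLINK map and
#'       an optional 2-column sample/mutation TSV,}
#'     \item{mask}{optional BED of masked regions,}
#'     \item{detector}{a [DetectorParams-class] (default
#'       `detectorParams()`),}
#'     \item{locus}{a [LocusSpec-class] or `"chrom:start-end"` string,}
#'     \item{dating}{list: `minDegree` (default 6), `mode`, `rho`,
#'       `generationTime`, `minSamples` (default 3),}
#'     \item{outDir}{optional output directory.}
#'   }
#' @return list: `summary` (character lines), `segments`, `pairs`,
#'   `novel`, `network`, `haplotypes`, `flagged`, `tmrca`, and `truth`
#'   for synthetic runs.
#' @export
runAll <- function(config) {
  detector <- config$detector %||% detectorParams()
  locus <- config$locus
  if (is.character(locus)) locus <- locusSpec(locus)
  .assert(!is.null(locus), "config$locus is required")
  dating <- config$dating %||% list()
  minDegree <- dating$minDegree %||% 6
  minSamples <- dating$minSamples %||% 3L
  seed <- if (!is.null(config$sim)) config$sim@seed
          else as.integer(config$seed %||% 1L)

  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- .stage("simulate", simulateCohort(config$sim))
    cohort <- sim$cohort; map <- sim$map; truth <- sim$truth
    families <- stats::setNames(truth$clusters$family,
                                truth$clusters$sample)
    reported <- truth$degrees
  } else {
    cohort <- .stage("input", readPhasedVcf(config$vcf))
    map <- .stage("input", readGeneticMap(config$map))
    families <- NULL
    reported <- NULL
    if (!is.null(config$mutations)) {
      mt <- utils::read.table(config$mutations, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
      cohort@mutations <- stats::setNames(mt[[2]], mt[[1]])
    }
  }

  segments <- .stage("ibd_detect", detectIBD(cohort, map, detector))
  if (!is.null(config$mask)) {
    mask <- .stage("mask", readMaskBed(config$mask))
    segments <- .stage("mask",
                       applyMask(segments, mask, map, detector@minCm))
  }

  pairs <- .stage("relate",
                  pairwiseRelatedness(segments, map, reported = reported))
  novel <- if (!is.null(families))
    .stage("relate", findNovelRelatives(pairs, families,
                                        mutations = mutationLabels(cohort)))
  else NULL

  edges <- .stage("network", segmentsAtLocus(segments, locus))
  network <- .stage("network",
                    buildNetwork(edges, locus, mutationLabels(cohort)))
  haplotypes <- .stage("founder",
                       founderHaplotypes(cohort, network, segments, locus))
  flagged <- .stage("network",
                    flagDiscordantEdges(network, haplotypes$core, cohort))

  tmrca <- list()
  for (cl in sort(unique(network@nodes$cluster))) {
    members <- network@nodes$sample[network@nodes$cluster == cl]
    if (length(members) < minSamples) next
    sel <- tryCatch(
      selectDatingSamples(network, cl, families %||% character(),
                          pairs, minDegree),
      error = function(e) members)
    # a short synthetic genome can make all cluster members look like
    # close kin; fall back to one representative per family
    if (length(sel) < 2L)
      sel <- tryCatch(
        selectDatingSamples(network, cl, families %||% character(),
                            pairs, 0),
        error = function(e) members)
    lens <- datingLengths(segments, locus, sel)
    if (length(lens) < 2L) next
    tmrca[[cl]] <- gammaTMRCA(
      lens, mode = dating$mode %||% "independent",
      rho = dating$rho %||% 0,
      generationTime = dating$generationTime %||% 20)
  }

  nAtLocus <- nrow(edges)
  sizes <- table(network@nodes$cluster)
  summary <- c(
    sprintf("founderscan run (seed %d)", seed),
    sprintf("samples: %d, SNPs: %d", nSamples(cohort),
            nrow(variantTable(cohort))),
    sprintf("IBD segments >= %.3g cM genome-wide: %d", detector@minCm,
            nrow(segments)),
    sprintf("pairs sharing the locus: %d", nAtLocus),
    sprintf("clusters at locus: %d", length(sizes)),
    sprintf("cluster sizes: %s",
            paste(sprintf("%s=%d", names(sizes), as.integer(sizes)),
                  collapse = " ")),
    sprintf("flagged discordant edges: %d", nrow(flagged)),
    if (length(tmrca)) vapply(names(tmrca), function(cl) {
      r <- tmrcaRange(tmrca[[cl]])
      sprintf("TMRCA %s: %d-%d generations (%d-%d years)", cl,
              r$generations[1], r$generations[2], r$years[1], r$years[2])
    }, character(1)))

  out <- list(summary = summary, segments = segments, pairs = pairs,
              novel = novel, network = network, haplotypes = haplotypes,
              flagged = flagged, tmrca = tmrca, truth = truth)

  if (!is.null(config$outDir)) {
    dir <- config$outDir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cfgFile <- tempfile()
    yaml::write_yaml(list(seed = seed,
                          window = detector@windowSnps,
                          minCm = detector@minCm), cfgFile)
    hash <- unname(tools::md5sum(cfgFile))
    unlink(cfgFile)
    hdr <- .headerComment(seed, sprintf("# config: %s", hash))
    writeSegments(segments, file.path(dir, "segments.tsv"), comments = hdr)
    for (nm in c("pairs", "novel", "flagged")) {
      if (is.null(out[[nm]])) next
      con <- file(file.path(dir, sprintf("%s.tsv", nm)), "w")
      writeLines(hdr, con)
      utils::write.table(out[[nm]], con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
    }
    writeNetworkJson(network, file.path(dir, "network.json"), seed)
    writeClusterHaplotypes(haplotypes$pruned, cohort,
                           file.path(dir, "haplotypes.tsv"), comments = hdr)
    jsonlite::write_json(
      lapply(tmrca, function(e) {
        r <- tmrcaRange(e)
        list(g_hat = e@gHat, ci_low = e@ciLow, ci_high = e@ciHigh,
             generations = r$generations, years = r$years,
             n = e@nLengths, mode = e@mode)
      }),
      file.path(dir, "tmrca.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    writeLines(c(hdr, summary), file.path(dir, "summary.txt"))
  }
  out
}
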