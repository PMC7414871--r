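#' @import methods
NULL

#' Genetic map with linear bp to cM interpolation
#'
#' Holds per-chromosome anchor points (physical position in bp, map position
#' in cM). All segment lengths in the pipeline are expressed in cM through
#' this map; it is the coordinate currency of IBD analysis.
#'
#' @slot anchors data.frame with columns `chrom` (character), `bp`
#'   (numeric, 1-based), `cm` (numeric). Within each chromosome positions
#'   are strictly increasing and cM non-decreasing, with at least two
#'   anchors.
#' @seealso [readGeneticMap()], [interpolateCM()], [mapLengthCM()]
#' @export
setClass("GeneticMap", slots = c(anchors = "data.frame"))

setValidity("GeneticMap", function(object) {
  a <- object@anchors
  req <- c("chrom", "bp", "cm")
  if (!all(req %in% names(a))) return("anchors must have chrom, bp, cm")
  if (nrow(a) == 0L) return("genetic map has no anchors")
  msgs <- character()
  for (ch in unique(a$chrom)) {
    sub <- a[a$chrom == ch, ]
    if (nrow(sub) < 2L)
      msgs <- c(msgs, sprintf("chromosome %s has fewer than 2 anchors", ch))
    if (is.unsorted(sub$bp, strictly = TRUE))
      msgs <- c(msgs, sprintf("chromosome %s: bp not strictly increasing", ch))
    if (is.unsorted(sub$cm))
      msgs <- c(msgs, sprintf("chromosome %s: cM decreasing", ch))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneticMap from an anchor table
#'
#' @param anchors data.frame with columns `chrom`, `bp`, `cm`.
#' @return A [GeneticMap-class] object.
#' @examples
#' gm <- geneticMap(data.frame(chrom = "1", bp = c(1e6, 2e6), cm = c(1, 2)))
#' interpolateCM(gm, "1", 1.5e6)
#' @export
geneticMap <- function(anchors) {
  anchors <- as.data.frame(anchors)
  anchors$chrom <- as.character(anchors$chrom)
  o <- order(anchors$chrom, anchors$bp)
  new("GeneticMap", anchors = anchors[o, c("chrom", "bp", "cm"), drop = FALSE])
}

#' Phased biallelic SNP cohort
#'
#' Samples by variants by two phased haplotypes, alleles coded 0 (reference)
#' / 1 (alternate). Haplotype rows `2*i - 1` and `2*i` are copies 0 and 1 of
#' sample `i`.
#'
#' @slot samples character vector of unique sample ids.
#' @slot variants data.frame with columns `chrom`, `pos` (bp, 1-based),
#'   `id`, `ref`, `alt`, ordered by chromosome then position; positions are
#'   unique within a chromosome.
#' @slot haplotypes integer matrix, `2 * length(samples)` rows by
#'   `nrow(variants)` columns, entries 0/1.
#' @slot mutations named character vector mapping a subset of sample ids to
#'   a mutation label (e.g. `"p.I114T"`); may be empty.
#' @seealso [readPhasedVcf()], [simulateCohort()]
#' @export
setClass("PhasedCohort",
         slots = c(samples = "character", variants = "data.frame",
                   haplotypes = "matrix", mutations = "character"))

setValidity("PhasedCohort", function(object) {
  v <- object@variants
  h <- object@haplotypes
  msgs <- character()
  if (!all(c("chrom", "pos", "id", "ref", "alt") %in% names(v)))
    return("variants must have chrom, pos, id, ref, alt")
  if (anyDuplicated(object@samples))
    msgs <- c(msgs, "duplicate sample ids")
  if (nrow(h) != 2L * length(object@samples))
    msgs <- c(msgs, "haplotype matrix must have 2 rows per sample")
  if (ncol(h) != nrow(v))
    msgs <- c(msgs, "haplotype matrix columns must match variant count")
  if (nrow(v) && any(tapply(v$pos, v$chrom, anyDuplicated) > 0L))
    msgs <- c(msgs, "duplicate positions within a chromosome")
  if (length(h) && !all(h %in% c(0L, 1L)))
    msgs <- c(msgs, "haplotype alleles must be 0/1")
  if (length(object@mutations) &&
      !all(names(object@mutations) %in% object@samples))
    msgs <- c(msgs, "mutation labels refer to unknown samples")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PhasedCohort
#'
#' @param samples character vector of sample ids.
#' @param variants variant table (`chrom`, `pos`, `id`, `ref`, `alt`).
#' @param haplotypes integer 0/1 matrix with two rows per sample.
#' @param mutations optional named character vector of mutation labels.
#' @return A [PhasedCohort-class] object.
#' @export
phasedCohort <- function(samples, variants, haplotypes,
                         mutations = character()) {
  variants <- as.data.frame(variants)
  variants$chrom <- as.character(variants$chrom)
  storage.mode(haplotypes) <- "integer"
  new("PhasedCohort", samples = as.character(samples), variants = variants,
      haplotypes = haplotypes, mutations = mutations)
}

#' IBD detector parameters
#'
#' @slot windowSnps integer, SNPs per window (>= 8); windows are
#'   consecutive, non-overlapping blocks along each chromosome.
#' @slot maxMismatch integer, allowed allele mismatches per window
#'   (0 = exact hashing).
#' @slot minCm numeric, minimum reported segment length in cM (> 0).
#' @export
setClass("DetectorParams",
         slots = c(windowSnps = "integer", maxMismatch = "integer",
                   minCm = "numeric"))

setValidity("DetectorParams", function(object) {
  msgs <- character()
  if (object@windowSnps < 8L) msgs <- c(msgs, "windowSnps must be >= 8")
  if (object@maxMismatch < 0L) msgs <- c(msgs, "maxMismatch must be >= 0")
  if (object@minCm <= 0) msgs <- c(msgs, "minCm must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @param windowSnps SNPs per hash window; default 64.
#' @param maxMismatch allowed mismatches per window; default 0 (exact).
#' @param minCm minimum segment length in cM retained; default 3.
#' @rdname DetectorParams-class
#' @export
detectorParams <- function(windowSnps = 64L, maxMismatch = 0L, minCm = 3) {
  new("DetectorParams", windowSnps = as.integer(windowSnps),
      maxMismatch = as.integer(maxMismatch), minCm = as.numeric(minCm))
}

#' Target locus coordinates
#'
#' @slot chrom chromosome name.
#' @slot startBp,endBp 1-based inclusive bp coordinates, start <= end.
#' @export
setClass("LocusSpec",
         slots = c(chrom = "character", startBp = "numeric",
                   endBp = "numeric"))

setValidity("LocusSpec", function(object) {
  if (object@startBp > object@endBp) "locus start > end" else TRUE
})

#' @param chrom chromosome, or a single string `"chrom:start-end"`.
#' @param startBp,endBp 1-based inclusive coordinates (ignored when `chrom`
#'   carries the full region string).
#' @rdname LocusSpec-class
#' @examples
#' locusSpec("21:33031935-33041243")
#' @export
locusSpec <- function(chrom, startBp = NULL, endBp = NULL) {
  if (is.null(startBp) && grepl(":", chrom)) {
    parts <- strsplit(chrom, "[:-]")[[1]]
    .assert(length(parts) == 3L, "cannot parse locus string '%s'", chrom)
    chrom <- parts[1]
    startBp <- as.numeric(parts[2])
    endBp <- as.numeric(parts[3])
  }
  new("LocusSpec", chrom = as.character(chrom), startBp = as.numeric(startBp),
      endBp = as.numeric(endBp))
}

#' Founder haplotype of a relatedness cluster
#'
#' The allele sequence shared (on at least one phased copy) by every member
#' of a cluster over a core interval, together with which copy matches in
#' each carrier.
#'
#' @slot clusterId cluster label, e.g. `"C1"`.
#' @slot chrom chromosome.
#' @slot startBp,endBp interval endpoints (bp, 1-based inclusive).
#' @slot positions bp positions of the SNPs in the interval.
#' @slot alleles integer 0/1 allele at each SNP.
#' @slot carriers sample ids of cluster members.
#' @slot hapIndex named integer, per carrier the phased copy (0/1) carrying
#'   the haplotype; 0 when both copies match (autozygous stretch).
#' @export
setClass("ClusterHaplotype",
         slots = c(clusterId = "character", chrom = "character",
                   startBp = "numeric", endBp = "numeric",
                   positions = "numeric", alleles = "integer",
                   carriers = "character", hapIndex = "integer"))

setValidity("ClusterHaplotype", function(object) {
  msgs <- character()
  if (length(object@positions) != length(object@alleles))
    msgs <- c(msgs, "positions/alleles length mismatch")
  if (length(object@carriers) &&
      !setequal(names(object@hapIndex), object@carriers))
    msgs <- c(msgs, "hapIndex must be named by carriers")
  if (length(msgs)) msgs else TRUE
})

#' Locus relatedness network
#'
#' Nodes are samples sharing at least one IBD segment over the locus with
#' some other sample; edges connect pairs inferred IBD over the locus;
#' clusters are connected components labelled C1..Ck by decreasing size
#' (ties broken by smallest member id).
#'
#' @slot nodes data.frame: `sample`, `cluster`, `mutation`, `degree`
#'   (number of incident edges).
#' @slot edges data.frame: `sample_a`, `sample_b`, `n_segments`, `cluster`.
#' @slot edgeSegments list, per edge the row indices of its supporting
#'   segments in the segment table the network was built from.
#' @slot locus the [LocusSpec-class] the network is anchored to.
#' @seealso [buildNetwork()], [segmentsAtLocus()]
#' @export
setClass("LocusNetwork",
         slots = c(nodes = "data.frame", edges = "data.frame",
                   edgeSegments = "list", locus = "LocusSpec"))

setValidity("LocusNetwork", function(object) {
  msgs <- character()
  if (nrow(object@edges) != length(object@edgeSegments))
    msgs <- c(msgs, "edgeSegments must align with edges")
  if (nrow(object@nodes) &&
      !all(c(object@edges$sample_a, object@edges$sample_b) %in%
           object@nodes$sample))
    msgs <- c(msgs, "edge endpoints missing from nodes")
  if (length(msgs)) msgs else TRUE
})

#' Time to the most recent common ancestor, Gamma method
#'
#' @slot nLengths number of haplotype lengths used.
#' @slot totalMorgans summed length in Morgans.
#' @slot gHat point estimate of the TMRCA in generations.
#' @slot ciLow,ciHigh confidence interval (default 95 percent level) in
#'   generations.
#' @slot mode `"independent"` (star genealogy) or `"correlated"`.
#' @slot generationTime years per generation used for the year scale.
#' @seealso [gammaTMRCA()]
#' @export
setClass("TMRCAEstimate",
         slots = c(nLengths = "integer", totalMorgans = "numeric",
                   gHat = "numeric", ciLow = "numeric", ciHigh = "numeric",
                   mode = "character", generationTime = "numeric"))

setValidity("TMRCAEstimate", function(object) {
  msgs <- character()
  if (!(object@ciLow <= object@gHat && object@gHat <= object@ciHigh))
    msgs <- c(msgs, "CI must bracket the point estimate")
  if (any(c(object@gHat, object@ciLow, object@ciHigh,
            object@totalMorgans) <= 0))
    msgs <- c(msgs, "estimate, interval and total length must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Simulation configuration
#'
#' Defines the synthetic study conditions: chromosome geometry and marker
#' density, allele-frequency bounds, founder clusters (size, generations to
#' founder, planted mutation), relative-pair specs and background samples.
#'
#' @slot seed integer RNG seed.
#' @slot chromosomes data.frame: `chrom`, `length_bp`, `length_cm`,
#'   `n_snps` (one row per simulated chromosome, linear map).
#' @slot mafBounds length-2 numeric in (0, 1): alternate-allele frequencies
#'   are drawn uniformly within these bounds.
#' @slot clusters data.frame: `cluster_id`, `n_carriers`, `g` (generations
#'   from founder, >= 1), `mutation_chrom`, `mutation_bp`, `label`,
#'   `n_families`.
#' @slot pairs data.frame: `degree` ("PO" or "1".."11"), `n_pairs`.
#' @slot nUnrelated integer count of background samples.
#' @slot errorRate per-allele flip probability in [0, 1), default 0.
#' @seealso [simConfig()], [simulateCohort()]
#' @export
setClass("SimConfig",
         slots = c(seed = "integer", chromosomes = "data.frame",
                   mafBounds = "numeric", clusters = "data.frame",
                   pairs = "data.frame", nUnrelated = "integer",
                   errorRate = "numeric"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  mb <- object@mafBounds
  if (length(mb) != 2L || any(mb <= 0) || any(mb >= 1) || mb[1] > mb[2])
    msgs <- c(msgs, "mafBounds must lie in (0, 1) with low <= high")
  if (object@errorRate < 0 || object@errorRate >= 1)
    msgs <- c(msgs, "errorRate must be in [0, 1)")
  cl <- object@clusters
  if (nrow(cl)) {
    if (any(cl$g < 1)) msgs <- c(msgs, "cluster g must be >= 1")
    for (i in seq_len(nrow(cl))) {
      ch <- object@chromosomes
      row <- ch[ch$chrom == cl$mutation_chrom[i], ]
      if (nrow(row) != 1L || cl$mutation_bp[i] < 1 ||
          cl$mutation_bp[i] > row$length_bp)
        msgs <- c(msgs, sprintf("cluster %s: mutation position outside %s",
                                cl$cluster_id[i], cl$mutation_chrom[i]))
    }
  }
  pr <- object@pairs
  if (nrow(pr)) {
    dnum <- suppressWarnings(as.integer(pr$degree))
    bad <- !(pr$degree == "PO" | (!is.na(dnum) & dnum >= 1 & dnum <= 11))
    if (any(bad)) msgs <- c(msgs, "pair degree must be PO or 1..11")
  }
  if (length(msgs)) msgs else TRUE
})
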