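# accessor generics, methods and show methods

#' Sample ids of a phased cohort
#' @param x a [PhasedCohort-class].
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Number of samples in a phased cohort
#' @param x a [PhasedCohort-class].
#' @return integer.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Variant table of a phased cohort
#' @param x a [PhasedCohort-class].
#' @return data.frame `chrom, pos, id, ref, alt`.
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' Haplotype matrix of a phased cohort
#'
#' Rows `2*i - 1` and `2*i` are copies 0 and 1 of sample `i`.
#' @param x a [PhasedCohort-class].
#' @return integer 0/1 matrix.
#' @export
setGeneric("hapMatrix", function(x) standardGeneric("hapMatrix"))

#' Mutation labels of a phased cohort
#' @param x a [PhasedCohort-class].
#' @return named character vector (sample -> mutation label).
#' @export
setGeneric("mutationLabels", function(x) standardGeneric("mutationLabels"))

#' Anchor table of a genetic map
#' @param x a [GeneticMap-class].
#' @return data.frame `chrom, bp, cm`.
#' @export
setGeneric("mapAnchors", function(x) standardGeneric("mapAnchors"))

#' Chromosomes present in an object
#' @param x a [GeneticMap-class] or [PhasedCohort-class].
#' @return character vector of chromosome names.
#' @export
setGeneric("chromosomeNames", function(x) standardGeneric("chromosomeNames"))

#' Node table of a locus network
#' @param x a [LocusNetwork-class].
#' @return data.frame `sample, cluster, mutation, degree`.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Edge table of a locus network
#' @param x a [LocusNetwork-class].
#' @return data.frame `sample_a, sample_b, n_segments, cluster`.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Cluster membership of a locus network
#' @param x a [LocusNetwork-class].
#' @return named character vector sample -> cluster label.
#' @export
setGeneric("clusterMembership", function(x) standardGeneric("clusterMembership"))

#' TMRCA point estimate in generations
#' @param x a [TMRCAEstimate-class].
#' @return numeric.
#' @export
setGeneric("gHat", function(x) standardGeneric("gHat"))

#' TMRCA confidence bounds in generations
#' @param x a [TMRCAEstimate-class].
#' @return numeric length 2 (low, high).
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "PhasedCohort", function(x) x@samples)

#' @rdname nSamples
#' @export
setMethod("nSamples", "PhasedCohort", function(x) length(x@samples))

#' @rdname variantTable
#' @export
setMethod("variantTable", "PhasedCohort", function(x) x@variants)

#' @rdname hapMatrix
#' @export
setMethod("hapMatrix", "PhasedCohort", function(x) x@haplotypes)

#' @rdname mutationLabels
#' @export
setMethod("mutationLabels", "PhasedCohort", function(x) x@mutations)

#' @rdname mapAnchors
#' @export
setMethod("mapAnchors", "GeneticMap", function(x) x@anchors)

#' @rdname chromosomeNames
#' @export
setMethod("chromosomeNames", "GeneticMap",
          function(x) unique(x@anchors$chrom))

#' @rdname chromosomeNames
#' @export
setMethod("chromosomeNames", "PhasedCohort",
          function(x) unique(x@variants$chrom))

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "LocusNetwork", function(x) x@nodes)

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "LocusNetwork", function(x) x@edges)

#' @rdname clusterMembership
#' @export
setMethod("clusterMembership", "LocusNetwork", function(x) {
  stats::setNames(x@nodes$cluster, x@nodes$sample)
})

#' @rdname gHat
#' @export
setMethod("gHat", "TMRCAEstimate", function(x) x@gHat)

#' @rdname confInt
#' @export
setMethod("confInt", "TMRCAEstimate", function(x) c(x@ciLow, x@ciHigh))

setMethod("show", "GeneticMap", function(object) {
  a <- object@anchors
  cat(sprintf("GeneticMap: %d chromosome(s), %d anchors\n",
              length(unique(a$chrom)), nrow(a)))
  for (ch in unique(a$chrom)) {
    sub <- a[a$chrom == ch, ]
    cat(sprintf("  %s: %.0f-%.0f bp, %.2f-%.2f cM\n", ch,
                min(sub$bp), max(sub$bp), min(sub$cm), max(sub$cm)))
  }
})

setMethod("show", "PhasedCohort", function(object) {
  cat(sprintf("PhasedCohort: %d samples x %d SNPs (%d chromosome(s))\n",
              length(object@samples), nrow(object@variants),
              length(unique(object@variants$chrom))))
  if (length(object@mutations))
    cat(sprintf("  mutation carriers: %d (%s)\n", length(object@mutations),
                paste(unique(object@mutations), collapse = ", ")))
})

setMethod("show", "LocusNetwork", function(object) {
  cat(sprintf("LocusNetwork over %s:%d-%d\n", object@locus@chrom,
              as.integer(object@locus@startBp),
              as.integer(object@locus@endBp)))
  cat(sprintf("  %d nodes, %d edges, %d cluster(s)\n",
              nrow(object@nodes), nrow(object@edges),
              length(unique(object@nodes$cluster))))
  if (nrow(object@nodes)) {
    sizes <- sort(table(object@nodes$cluster), decreasing = TRUE)
    cat("  sizes:", paste(sprintf("%s=%d", names(sizes), sizes),
                          collapse = " "), "\n")
  }
})

setMethod("show", "TMRCAEstimate", function(object) {
  lo <- .roundHalfUp(object@ciLow)
  hi <- .roundHalfUp(object@ciHigh)
  gt <- object@generationTime
  cat(sprintf(
    "TMRCA (%s, n = %d): %.1f generations, CI %d-%d generations (%d-%d years at %g y/generation)\n",
    object@mode, object@nLengths, object@gHat, lo, hi,
    as.integer(lo * gt), as.integer(hi * gt), gt))
})

setMethod("show", "ClusterHaplotype", function(object) {
  cat(sprintf("ClusterHaplotype %s: %s:%.0f-%.0f, %d SNPs, %d carriers\n",
              object@clusterId, object@chrom, object@startBp, object@endBp,
              length(object@positions), length(object@carriers)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: seed %d, %d chromosome(s), %d cluster(s), %d pair spec(s), %d unrelated\n",
              object@seed, nrow(object@chromosomes), nrow(object@clusters),
              nrow(object@pairs), object@nUnrelated))
})
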