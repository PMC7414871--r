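# Founder-haplotype extraction: per-cluster core interval (intersection of
# pairwise IBD segments), the singular haplotype shared by every member
# over that interval, a common cross-cluster reporting interval, and
# pruning of SNPs uninformative for distinguishing founder events.

#' Core interval of a cluster
#'
#' The founder-haplotype endpoints of a cluster are the intersection of
#' the IBD segments inferred between its member pairs: each edge
#' contributes its longest locus-overlapping segment, and the interval is
#' `[max of starts, min of ends]`. The result must still overlap the
#' target locus.
#'
#' @param network a [LocusNetwork-class].
#' @param cluster cluster label (e.g. `"C1"`).
#' @param segments the segment data.frame the network was built from.
#' @param locus a [LocusSpec-class].
#' @return list `chrom, startBp, endBp`.
#' @export
clusterCoreInterval <- function(network, cluster, segments, locus) {
  sel <- which(network@edges$cluster == cluster)
  .assert(length(sel) > 0L, "cluster '%s' has no edges", cluster)
  starts <- numeric(length(sel)); ends <- numeric(length(sel))
  for (i in seq_along(sel)) {
    rows <- network@edgeSegments[[sel[i]]]
    sub <- segments[rows, , drop = FALSE]
    ov <- sub$chrom == locus@chrom &
      sub$start_bp <= locus@endBp & sub$end_bp >= locus@startBp
    sub <- sub[ov, , drop = FALSE]
    .assert(nrow(sub) > 0L, "edge %s-%s has no locus-overlapping segment",
            network@edges$sample_a[sel[i]], network@edges$sample_b[sel[i]])
    best <- which.max(sub$length_cm)
    starts[i] <- sub$start_bp[best]
    ends[i] <- sub$end_bp[best]
  }
  s <- max(starts); e <- min(ends)
  if (s > e) {
    worst <- which.max(starts)
    .stopf("empty core for cluster %s: segment intersection vanishes at pair %s-%s",
           cluster, network@edges$sample_a[sel[worst]],
           network@edges$sample_b[sel[worst]], class = "EmptyCore")
  }
  .assert(s <= locus@endBp && e >= locus@startBp,
          "core interval of cluster %s does not overlap the locus", cluster,
          class = "EmptyCore")
  list(chrom = locus@chrom, startBp = s, endBp = e)
}

#' Extract the singular shared haplotype of a cluster
#'
#' Finds the allele sequence carried by at least one phased copy of every
#' member across the interval. Exactly one such sequence must exist: none
#' raises `NoSharedHaplotype`, several (possible over very short
#' intervals) raise `AmbiguousHaplotype`. A member whose both copies match
#' (an autozygous stretch) records copy 0 by convention.
#'
#' @param cohort a [PhasedCohort-class].
#' @param members sample ids of the cluster.
#' @param chrom,startBp,endBp the core interval (1-based inclusive).
#' @param clusterId label stored on the result.
#' @return a [ClusterHaplotype-class].
#' @export
extractSharedHaplotype <- function(cohort, members, chrom, startBp, endBp,
                                   clusterId = "C1") {
  v <- cohort@variants
  cols <- which(v$chrom == chrom & v$pos >= startBp & v$pos <= endBp)
  .assert(length(cols) > 0L, "no SNPs in interval %s:%s-%s", chrom,
          format(startBp, scientific = FALSE),
          format(endBp, scientific = FALSE))
  rows0 <- 2L * match(members, cohort@samples) - 1L
  .assert(!anyNA(rows0), "unknown cluster member(s)")
  sub <- cohort@haplotypes[sort(c(rows0, rows0 + 1L)), cols, drop = FALSE]

  # candidate sequences: the first member's two copies; a sequence shared
  # by all members must appear in member 1
  cand <- unique(lapply(1:2, function(h) sub[h, ]))
  keyOf <- function(x) paste(x, collapse = "")
  shared <- list()
  hapIdxFor <- function(seqv) {
    idx <- integer(length(members))
    for (i in seq_along(members)) {
      m0 <- all(sub[2L * i - 1L, ] == seqv)
      m1 <- all(sub[2L * i, ] == seqv)
      if (m0) idx[i] <- 0L
      else if (m1) idx[i] <- 1L
      else return(NULL)
    }
    idx
  }
  for (sq in cand) {
    idx <- hapIdxFor(sq)
    if (!is.null(idx)) shared[[keyOf(sq)]] <- list(seq = sq, idx = idx)
  }
  if (length(shared) == 0L)
    .stopf("no haplotype shared by all %d members of %s over %s:%s-%s",
           length(members), clusterId, chrom,
           format(startBp, scientific = FALSE),
           format(endBp, scientific = FALSE), class = "NoSharedHaplotype")
  if (length(shared) > 1L)
    .stopf("ambiguous shared haplotype for %s: %d distinct candidate sequences (%s)",
           clusterId, length(shared),
           paste(substr(names(shared), 1, 20), collapse = ", "),
           class = "AmbiguousHaplotype")
  hit <- shared[[1]]
  new("ClusterHaplotype", clusterId = clusterId, chrom = chrom,
      startBp = as.numeric(v$pos[cols[1]]),
      endBp = as.numeric(v$pos[cols[length(cols)]]),
      positions = as.numeric(v$pos[cols]), alleles = as.integer(hit$seq),
      carriers = members,
      hapIndex = stats::setNames(hit$idx, members))
}

#' Common reporting interval across cluster haplotypes
#'
#' The intersection of all cluster core intervals, with the SNP set
#' present in every haplotype inside it; reporting all founder haplotypes
#' over the same interval (hence the same biallelic SNPs) makes them
#' directly comparable.
#'
#' @param haps list of two or more [ClusterHaplotype-class] objects on the
#'   same chromosome.
#' @return list `chrom, startBp, endBp, positions`.
#' @export
commonReportInterval <- function(haps) {
  .assert(length(haps) >= 2L, "need at least 2 cluster haplotypes")
  chrom <- unique(vapply(haps, function(h) h@chrom, character(1)))
  .assert(length(chrom) == 1L, "cluster haplotypes span chromosomes")
  s <- max(vapply(haps, function(h) h@startBp, numeric(1)))
  e <- min(vapply(haps, function(h) h@endBp, numeric(1)))
  .assert(s <= e, "cluster intervals share no reporting window",
          class = "EmptyReportInterval")
  pos <- Reduce(intersect, lapply(haps, function(h)
    h@positions[h@positions >= s & h@positions <= e]))
  .assert(length(pos) > 0L, "no SNP common to all haplotypes in %s:%s-%s",
          chrom, format(s, scientific = FALSE),
          format(e, scientific = FALSE), class = "EmptyReportInterval")
  list(chrom = chrom, startBp = s, endBp = e, positions = sort(pos))
}

#' Restrict a cluster haplotype to a SNP set
#'
#' @param hap a [ClusterHaplotype-class].
#' @param positions bp positions to retain (must be a subset of the
#'   haplotype's SNPs).
#' @return the restricted [ClusterHaplotype-class].
#' @export
subsetHaplotype <- function(hap, positions) {
  i <- match(positions, hap@positions)
  .assert(!anyNA(i), "positions not all present in haplotype %s",
          hap@clusterId)
  new("ClusterHaplotype", clusterId = hap@clusterId, chrom = hap@chrom,
      startBp = min(positions), endBp = max(positions),
      positions = as.numeric(positions), alleles = hap@alleles[i],
      carriers = hap@carriers, hapIndex = hap@hapIndex)
}

#' Drop SNPs uninformative for founder comparison
#'
#' Removes the SNPs at which every founder haplotype carries the same
#' allele; the remaining positions are the ones that distinguish founder
#' events. All haplotypes must be on an identical SNP set.
#'
#' @param haps list of [ClusterHaplotype-class] on the same SNP set.
#' @return list of pruned [ClusterHaplotype-class]; a warning is emitted
#'   if every SNP is uninformative (zero-length report).
#' @export
dropUninformativeSnps <- function(haps) {
  .assert(length(haps) >= 1L, "no haplotypes")
  pos <- haps[[1]]@positions
  for (h in haps)
    .assert(identical(h@positions, pos),
            "haplotypes are not on an identical SNP set")
  alle <- do.call(rbind, lapply(haps, function(h) h@alleles))
  keep <- apply(alle, 2L, function(x) length(unique(x)) > 1L)
  if (!any(keep)) {
    warning("all SNPs identical across founder haplotypes; zero-length report")
    keep <- rep(FALSE, length(pos))
  }
  lapply(haps, function(h) {
    new("ClusterHaplotype", clusterId = h@clusterId, chrom = h@chrom,
        startBp = h@startBp, endBp = h@endBp,
        positions = h@positions[keep], alleles = h@alleles[keep],
        carriers = h@carriers, hapIndex = h@hapIndex)
  })
}

#' Extract, report and prune founder haplotypes for all clusters
#'
#' Driver over a locus network: per cluster the core interval and shared
#' haplotype; across clusters (when more than one) the common reporting
#' interval, re-reporting on the shared SNP set and pruning of
#' uninformative SNPs.
#'
#' @param cohort a [PhasedCohort-class].
#' @param network a [LocusNetwork-class].
#' @param segments the segment table the network was built from.
#' @param locus a [LocusSpec-class].
#' @return list with `core` (per-cluster [ClusterHaplotype-class] on its
#'   own core interval), `reported` (on the common interval/SNP set),
#'   `pruned` (after dropping uninformative SNPs) and `reportInterval`.
#' @export
founderHaplotypes <- function(cohort, network, segments, locus) {
  clusters <- unique(network@nodes$cluster)
  .assert(length(clusters) > 0L, "network has no clusters")
  core <- list()
  for (cl in sort(clusters)) {
    iv <- clusterCoreInterval(network, cl, segments, locus)
    members <- network@nodes$sample[network@nodes$cluster == cl]
    core[[cl]] <- extractSharedHaplotype(cohort, members, iv$chrom,
                                         iv$startBp, iv$endBp,
                                         clusterId = cl)
  }
  if (length(core) >= 2L) {
    ri <- commonReportInterval(core)
    reported <- lapply(core, subsetHaplotype, positions = ri$positions)
    pruned <- dropUninformativeSnps(reported)
  } else {
    ri <- list(chrom = core[[1]]@chrom, startBp = core[[1]]@startBp,
               endBp = core[[1]]@endBp, positions = core[[1]]@positions)
    reported <- core
    pruned <- core
  }
  list(core = core, reported = reported, pruned = pruned,
       reportInterval = ri)
}
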