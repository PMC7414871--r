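# Locus-anchored relatedness network: nodes are samples, an edge joins two
# samples inferred IBD over the target locus, clusters are connected
# components. Component extraction is the testable core; layout is
# cosmetic and left to igraph.

#' Edges of the locus relatedness network
#'
#' A pair contributes an edge iff at least one of its IBD segments
#' overlaps the locus by >= `minOverlapBp` base pairs (default 1, i.e.
#' partial or complete overlap); multiple haplotype-pair segments collapse
#' to one edge.
#'
#' @param segments segment data.frame.
#' @param locus a [LocusSpec-class].
#' @param minOverlapBp minimum overlap in bp (default 1).
#' @return data.frame `sample_a, sample_b, n_segments` with a
#'   `segmentRows` list attribute giving, per edge, the supporting row
#'   indices into `segments`.
#' @export
segmentsAtLocus <- function(segments, locus, minOverlapBp = 1) {
  .validateSegmentFrame(segments)
  ov <- segments$chrom == locus@chrom &
    pmin(segments$end_bp, locus@endBp) -
      pmax(segments$start_bp, locus@startBp) + 1 >= minOverlapBp
  idx <- which(ov)
  key <- paste(segments$sample_a[idx], segments$sample_b[idx], sep = "\r")
  byPair <- split(idx, key)
  edges <- do.call(rbind, lapply(byPair, function(rows)
    data.frame(sample_a = segments$sample_a[rows[1]],
               sample_b = segments$sample_b[rows[1]],
               n_segments = length(rows), stringsAsFactors = FALSE))) %||%
    data.frame(sample_a = character(), sample_b = character(),
               n_segments = integer())
  rownames(edges) <- NULL
  attr(edges, "segmentRows") <- unname(byPair)
  edges
}

#' Build the locus relatedness network
#'
#' Connected components are computed with \pkg{igraph} and labelled
#' C1..Ck by decreasing node count, ties broken by the smallest member
#' sample id. Samples sharing no segment over the locus with any other
#' sample do not appear.
#'
#' @param edges edge table from [segmentsAtLocus()].
#' @param locus the [LocusSpec-class] the edges were computed against.
#' @param mutations optional named character vector sample -> mutation
#'   label, attached to the nodes.
#' @return a [LocusNetwork-class].
#' @export
buildNetwork <- function(edges, locus, mutations = NULL) {
  segRows <- attr(edges, "segmentRows") %||%
    rep(list(integer()), nrow(edges))
  if (nrow(edges) == 0L) {
    return(new("LocusNetwork",
               nodes = data.frame(sample = character(), cluster = character(),
                                  mutation = character(), degree = integer()),
               edges = data.frame(sample_a = character(),
                                  sample_b = character(),
                                  n_segments = integer(),
                                  cluster = character()),
               edgeSegments = list(), locus = locus))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("sample_a", "sample_b")], directed = FALSE)
  comp <- igraph::components(g)
  ids <- names(comp$membership)
  # deterministic cluster labels: size desc, then smallest sample id
  minId <- vapply(seq_len(comp$no), function(k)
    min(ids[comp$membership == k]), character(1))
  ord <- order(-comp$csize, minId)
  lab <- character(comp$no)
  lab[ord] <- sprintf("C%d", seq_len(comp$no))
  cluster <- stats::setNames(lab[comp$membership], ids)
  deg <- igraph::degree(g)
  nodes <- data.frame(
    sample = ids, cluster = unname(cluster),
    mutation = if (is.null(mutations)) NA_character_
               else unname(mutations[ids]),
    degree = as.integer(deg[ids]), stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$cluster, nodes$sample), ]
  rownames(nodes) <- NULL
  edges$cluster <- unname(cluster[edges$sample_a])
  new("LocusNetwork", nodes = nodes, edges = edges,
      edgeSegments = segRows, locus = locus)
}

#' Flag discordant network edges
#'
#' An edge is flagged when (a) its two samples carry different mutation
#' labels, or (b) founder haplotypes are supplied and one of the samples
#' has no phased copy matching its cluster's founder haplotype over the
#' founder interval — the signature of a false-positive IBD call
#' connecting unrelated lineages. Flagged edges are reported, not
#' removed.
#'
#' @param network a [LocusNetwork-class] with mutation labels on nodes.
#' @param founderHaps optional named list of [ClusterHaplotype-class]
#'   (names = cluster labels) for check (b).
#' @param cohort the [PhasedCohort-class] (required for check (b)).
#' @return data.frame `sample_a, sample_b, cluster, reason` (possibly
#'   zero rows); edges with a missing mutation label are skipped with a
#'   warning.
#' @export
flagDiscordantEdges <- function(network, founderHaps = NULL,
                                cohort = NULL) {
  edges <- network@edges
  nodes <- network@nodes
  mut <- stats::setNames(nodes$mutation, nodes$sample)
  out <- list()
  matchesFounder <- function(sample, fh) {
    v <- cohort@variants
    cols <- which(v$chrom == fh@chrom & v$pos %in% fh@positions)
    r <- 2L * match(sample, cohort@samples) - 1L
    any(all(cohort@haplotypes[r, cols] == fh@alleles),
        all(cohort@haplotypes[r + 1L, cols] == fh@alleles))
  }
  for (i in seq_len(nrow(edges))) {
    a <- edges$sample_a[i]; b <- edges$sample_b[i]
    ma <- mut[[a]]; mb <- mut[[b]]
    if (is.na(ma) || is.na(mb)) {
      warning(sprintf("edge %s-%s skipped: missing mutation label", a, b))
      next
    }
    if (ma != mb) {
      out[[length(out) + 1L]] <- data.frame(
        sample_a = a, sample_b = b, cluster = edges$cluster[i],
        reason = "discordant_mutation", stringsAsFactors = FALSE)
      next
    }
    if (!is.null(founderHaps) && !is.null(cohort) &&
        edges$cluster[i] %in% names(founderHaps)) {
      fh <- founderHaps[[edges$cluster[i]]]
      if (!matchesFounder(a, fh) || !matchesFounder(b, fh))
        out[[length(out) + 1L]] <- data.frame(
          sample_a = a, sample_b = b, cluster = edges$cluster[i],
          reason = "haplotype_mismatch", stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(sample_a = character(), sample_b = character(),
               cluster = character(), reason = character())
  rownames(res) <- NULL
  res
}

#' Serialise a locus network to JSON
#'
#' Plain edge-list plus cluster-membership document.
#'
#' @param network a [LocusNetwork-class].
#' @param path output path.
#' @param seed optional seed recorded in the document.
#' @return invisibly, `path`.
#' @export
writeNetworkJson <- function(network, path, seed = NULL) {
  doc <- list(
    locus = sprintf("%s:%d-%d", network@locus@chrom,
                    as.integer(network@locus@startBp),
                    as.integer(network@locus@endBp)),
    seed = seed,
    nodes = network@nodes,
    edges = network@edges)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
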