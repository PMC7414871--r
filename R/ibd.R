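# GERMLINE-style IBD detection: slide fixed-size SNP windows along each
# chromosome, bucket haplotypes by exact window content (bit-packed hash,
# then verified groups), merge runs of consecutive matching windows into
# segments, and filter by genetic length.

# pack a window of 0/1 alleles into a compact character key (chunks of 30
# sites -> exact doubles, pasted); identical keys <=> identical windows
.windowKeys <- function(M, idx) {
  chunks <- split(idx, ceiling(seq_along(idx) / 30))
  parts <- lapply(chunks, function(cc)
    as.vector(M[, cc, drop = FALSE] %*% 2^(seq_along(cc) - 1)))
  do.call(paste, c(parts, sep = "_"))
}

# all haplotype-row pairs within one hash group that span distinct samples
.groupPairs <- function(rows) {
  if (length(rows) < 2L) return(NULL)
  cmb <- utils::combn(rows, 2L)
  sa <- (cmb[1, ] + 1L) %/% 2L
  sb <- (cmb[2, ] + 1L) %/% 2L
  cmb[, sa != sb, drop = FALSE]
}

#' Detect IBD segments in a phased cohort
#'
#' For every pair of haplotypes from distinct samples, maximal runs of
#' consecutive windows with identical haplotype content are merged into
#' candidate segments; segment bp endpoints are the first/last SNP of the
#' run, cM endpoints come from the genetic map, and only segments of at
#' least `minCm` are returned. With `maxMismatch = 0` windows are matched
#' exactly through hashing; with a positive allowance windows are compared
#' directly (quadratic in haplotypes, intended for small noisy cohorts).
#'
#' The trailing SNPs of a chromosome that do not fill a whole window form a
#' final shorter window, so a fully shared chromosome yields a segment
#' spanning the entire map.
#'
#' @param cohort a [PhasedCohort-class] (complete, phased).
#' @param map a [GeneticMap-class] covering the cohort chromosomes.
#' @param params a [DetectorParams-class].
#' @return segment data.frame with columns `sample_a, hap_a, sample_b,
#'   hap_b, chrom, start_bp, end_bp, start_cm, end_cm, length_cm`; pairs
#'   are canonically ordered (`sample_a < sample_b`).
#' @seealso [applyMask()], [ibdProfile()]
#' @export
detectIBD <- function(cohort, map, params = detectorParams()) {
  validObject(params)
  v <- cohort@variants
  M <- cohort@haplotypes
  .assert(nrow(M) > 0L, "cohort has no samples")
  nH <- nrow(M)
  samples <- cohort@samples
  out <- list()

  for (ch in unique(v$chrom)) {
    cols <- which(v$chrom == ch)
    w <- params@windowSnps
    .assert(length(cols) >= w,
            "chromosome %s has %d SNPs, fewer than one %d-SNP window; use a smaller window",
            ch, length(cols), w)
    Mc <- M[, cols, drop = FALSE]
    pos <- v$pos[cols]
    cmv <- interpolateCM(map, ch, pos)
    starts <- seq(1L, length(cols), by = w)
    ends <- pmin(starts + w - 1L, length(cols))
    nwin <- length(starts)

    hits <- vector("list", nwin)
    for (k in seq_len(nwin)) {
      idx <- starts[k]:ends[k]
      if (params@maxMismatch == 0L) {
        keys <- .windowKeys(Mc, idx)
        dup <- keys %in% keys[duplicated(keys)]
        if (!any(dup)) next
        grp <- split(which(dup), keys[dup])
        prs <- lapply(grp, .groupPairs)
        prs <- prs[!vapply(prs, is.null, logical(1))]
        if (length(prs)) hits[[k]] <- do.call(cbind, prs)
      } else {
        Mw <- Mc[, idx, drop = FALSE]
        agree <- tcrossprod(Mw) + tcrossprod(1L - Mw)
        ok <- which(length(idx) - agree <= params@maxMismatch &
                      upper.tri(agree), arr.ind = TRUE)
        if (nrow(ok)) {
          sa <- (ok[, 1] + 1L) %/% 2L
          sb <- (ok[, 2] + 1L) %/% 2L
          ok <- ok[sa != sb, , drop = FALSE]
          if (nrow(ok)) hits[[k]] <- t(ok)
        }
      }
    }

    nhit <- vapply(hits, function(x) if (is.null(x)) 0L else ncol(x),
                   integer(1))
    if (sum(nhit) == 0L) next
    I <- unlist(lapply(hits, function(x) x[1, ]))
    J <- unlist(lapply(hits, function(x) x[2, ]))
    W <- rep.int(seq_len(nwin), nhit)
    pid <- (I - 1) * nH + J
    byPair <- split(seq_along(pid), pid)

    segs <- lapply(byPair, function(sel) {
      ws <- sort(W[sel])
      i <- I[sel[1]]; j <- J[sel[1]]
      runId <- cumsum(c(1L, diff(ws) != 1L))
      lapply(split(ws, runId), function(run) {
        sSnp <- starts[run[1]]
        eSnp <- ends[run[length(run)]]
        c(i = i, j = j, s = sSnp, e = eSnp)
      })
    })
    segs <- do.call(rbind, lapply(unlist(segs, recursive = FALSE), rbind))
    if (is.null(segs)) next

    startCm <- cmv[segs[, "s"]]
    endCm <- cmv[segs[, "e"]]
    keep <- (endCm - startCm) >= params@minCm
    if (!any(keep)) next
    segs <- segs[keep, , drop = FALSE]
    startCm <- startCm[keep]; endCm <- endCm[keep]

    ia <- (segs[, "i"] + 1L) %/% 2L
    ib <- (segs[, "j"] + 1L) %/% 2L
    hapA <- (segs[, "i"] + 1L) %% 2L
    hapB <- (segs[, "j"] + 1L) %% 2L
    sa <- samples[ia]; sb <- samples[ib]
    swap <- sb < sa
    df <- data.frame(
      sample_a = ifelse(swap, sb, sa),
      hap_a = ifelse(swap, hapB, hapA),
      sample_b = ifelse(swap, sa, sb),
      hap_b = ifelse(swap, hapA, hapB),
      chrom = ch,
      start_bp = pos[segs[, "s"]], end_bp = pos[segs[, "e"]],
      start_cm = startCm, end_cm = endCm,
      length_cm = endCm - startCm, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- df
  }

  res <- do.call(rbind, out) %||% .emptySegments()
  res <- res[order(res$sample_a, res$sample_b, res$chrom, res$start_bp), ]
  rownames(res) <- NULL
  res
}

#' Remove or trim IBD segments overlapping mask regions
#'
#' A segment fully inside a mask interval is removed; a segment straddling
#' a mask boundary is trimmed to its unmasked part (a mask splitting a
#' segment leaves both flanking pieces). cM lengths are recomputed from the
#' map and pieces shorter than `minCm` are dropped, so the minimum-length
#' contract holds globally after masking.
#'
#' @param segments segment data.frame.
#' @param mask `GRanges` of masked intervals (1-based, e.g. from
#'   [readMaskBed()]).
#' @param map a [GeneticMap-class].
#' @param minCm minimum retained piece length in cM.
#' @return filtered/trimmed segment data.frame.
#' @export
applyMask <- function(segments, mask, map, minCm = 3) {
  .validateSegmentFrame(segments)
  if (nrow(segments) == 0L || length(mask) == 0L) return(segments)
  maskCh <- as.character(GenomicRanges::seqnames(mask))
  out <- list()
  for (r in seq_len(nrow(segments))) {
    seg <- segments[r, ]
    mCh <- which(maskCh == seg$chrom)
    if (!length(mCh)) { out[[length(out) + 1L]] <- seg; next }
    segIR <- IRanges::IRanges(seg$start_bp, seg$end_bp)
    pieces <- BiocGenerics::setdiff(segIR,
                                    IRanges::ranges(mask[mCh]))
    for (p in seq_along(pieces)) {
      s <- IRanges::start(pieces)[p]
      e <- IRanges::end(pieces)[p]
      cm <- interpolateCM(map, seg$chrom, c(s, e))
      if (cm[2] - cm[1] >= minCm) {
        piece <- seg
        piece$start_bp <- as.numeric(s); piece$end_bp <- as.numeric(e)
        piece$start_cm <- cm[1]; piece$end_cm <- cm[2]
        piece$length_cm <- cm[2] - cm[1]
        out[[length(out) + 1L]] <- piece
      }
    }
  }
  res <- do.call(rbind, out) %||% .emptySegments()
  rownames(res) <- NULL
  res
}

#' Piecewise IBD0/IBD1/IBD2 profile for one sample pair
#'
#' Partitions each map chromosome (on the cM scale) by the segment
#' endpoints of the pair and counts, on every piece, the distinct
#' haplotype pairings covered. A point is IBD2 when two segments with
#' disjoint haplotype use (pairings \{(0,0),(1,1)\} or \{(0,1),(1,0)\})
#' cover it, IBD1 when at least one segment covers it, IBD0 otherwise.
#' Lengths are conserved: IBD0 + IBD1 + IBD2 = total map length.
#'
#' @param segments segment data.frame for a single sample pair.
#' @param map a [GeneticMap-class]; every map chromosome contributes to
#'   the profile (chromosomes without segments are IBD0 throughout).
#' @return data.frame `chrom, start_cm, end_cm, state` (state 0/1/2).
#' @export
ibdProfile <- function(segments, map) {
  .validateSegmentFrame(segments)
  if (nrow(segments)) {
    prs <- unique(paste(segments$sample_a, segments$sample_b))
    .assert(length(prs) == 1L,
            "ibdProfile expects segments of a single sample pair (got %d)",
            length(prs))
  }
  out <- list()
  for (ch in chromosomeNames(map)) {
    a <- map@anchors[map@anchors$chrom == ch, ]
    lo <- min(a$cm); hi <- max(a$cm)
    sub <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_cm = lo, end_cm = hi, state = 0L,
        stringsAsFactors = FALSE)
      next
    }
    bp <- sort(unique(c(lo, hi, sub$start_cm, sub$end_cm)))
    bp <- bp[bp >= lo & bp <= hi]
    for (i in seq_len(length(bp) - 1L)) {
      mid <- (bp[i] + bp[i + 1L]) / 2
      cov <- sub$start_cm <= mid & sub$end_cm >= mid
      pairing <- unique(paste0(sub$hap_a[cov], sub$hap_b[cov]))
      state <- if (all(c("00", "11") %in% pairing) ||
                   all(c("01", "10") %in% pairing)) 2L
               else if (length(pairing) >= 1L) 1L else 0L
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_cm = bp[i], end_cm = bp[i + 1L], state = state,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
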