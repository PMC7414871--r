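#' Write IBD segments to TSV
#'
#' Tab-delimited with one header line; columns exactly `sample_a, hap_a,
#' sample_b, hap_b, chrom, start_bp, end_bp, start_cm, end_cm, length_cm`.
#' `readSegments(writeSegments(x))` round-trips losslessly.
#'
#' @param segments segment data.frame (see [detectIBD()]).
#' @param path output path.
#' @param comments optional character vector of `#`-prefixed header
#'   comment lines written before the column header.
#' @return invisibly, `path`.
#' @export
writeSegments <- function(segments, path, comments = character()) {
  seg <- .validateSegmentFrame(segments)[, .segmentColumns, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(comments, con)
  utils::write.table(seg, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read IBD segments from TSV
#'
#' @param path path written by [writeSegments()].
#' @return segment data.frame; rows violating the segment invariants
#'   (e.g. `end_bp < start_bp`) raise a validation error.
#' @export
readSegments <- function(path) {
  .assert(file.exists(path), "segment file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  .assert(length(lines) >= 1L, "segment file '%s' has no header", path,
          class = "segmentParseError")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  unknown <- setdiff(header, .segmentColumns)
  .assert(length(unknown) == 0L, "unknown segment column(s): %s",
          paste(unknown, collapse = ", "), class = "segmentParseError")
  classes <- c(sample_a = "character", hap_a = "integer",
               sample_b = "character", hap_b = "integer",
               chrom = "character", start_bp = "numeric",
               end_bp = "numeric", start_cm = "numeric",
               end_cm = "numeric", length_cm = "numeric")
  seg <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = classes[header])
  .validateSegmentFrame(seg)
  seg
}

#' Read mask regions from BED
#'
#' BED intervals (0-based half-open on disk) are imported via
#' \pkg{rtracklayer} into 1-based `GRanges` and merged to non-overlapping
#' form. Zero-width rows (`start == end`) are rejected.
#'
#' @param path path to a 3+ column BED file.
#' @return a reduced `GRanges` of masked intervals.
#' @seealso [applyMask()]
#' @export
readMaskBed <- function(path) {
  .assert(file.exists(path), "mask BED not found: %s", path)
  if (file.size(path) == 0L ||
      all(!nzchar(trimws(readLines(path)))))
    return(GenomicRanges::GRanges())
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  .assert(ncol(raw) >= 3L, "BED '%s' needs at least 3 columns", path,
          class = "bedParseError")
  .assert(all(raw[[3]] > raw[[2]]),
          "BED interval with start >= end in '%s'", path,
          class = "bedValidationError")
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::reduce(gr)
}

#' Write cluster founder haplotypes to TSV
#'
#' One row per retained SNP per cluster: `cluster_id, chrom, pos, ref,
#' alt, allele`.
#'
#' @param haps list of [ClusterHaplotype-class] objects.
#' @param cohort the [PhasedCohort-class] supplying ref/alt alleles.
#' @param path output path.
#' @param comments optional `#` header comment lines.
#' @return invisibly, `path`.
#' @export
writeClusterHaplotypes <- function(haps, cohort, path,
                                   comments = character()) {
  v <- cohort@variants
  rows <- lapply(haps, function(h) {
    i <- match(h@positions, v$pos[v$chrom == h@chrom])
    sub <- v[v$chrom == h@chrom, ][i, ]
    data.frame(cluster_id = h@clusterId, chrom = h@chrom, pos = h@positions,
               ref = sub$ref, alt = sub$alt, allele = h@alleles,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows) %||%
    data.frame(cluster_id = character(), chrom = character(),
               pos = numeric(), ref = character(), alt = character(),
               allele = integer())
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(comments, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
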