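#' Read a PLINK-style genetic map
#'
#' Parses a whitespace-delimited 4-column map file (chromosome, marker id,
#' map position in cM, physical position in bp) into a [GeneticMap-class].
#' Lines must be sorted by position within each chromosome.
#'
#' @param path path to the `.map` file.
#' @return A [GeneticMap-class].
#' @examples
#' f <- tempfile(fileext = ".map")
#' writeLines(c("1 rs1 1.0 1000000", "1 rs2 2.0 2000000"), f)
#' readGeneticMap(f)
#' @export
readGeneticMap <- function(path) {
  .assert(file.exists(path), "map file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  .assert(length(lines) > 0L, "genetic map '%s' has no anchors", path,
          class = "mapValidationError")
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  .assert(length(bad) == 0L,
          "malformed map line %d in '%s' (need 4 columns)",
          if (length(bad)) bad[1] else 0L, path, class = "mapParseError")
  rec <- do.call(rbind, fields)
  cm <- suppressWarnings(as.numeric(rec[, 3]))
  bp <- suppressWarnings(as.numeric(rec[, 4]))
  bad <- which(is.na(cm) | is.na(bp))
  .assert(length(bad) == 0L,
          "malformed map line %d in '%s' (non-numeric cM/bp)",
          if (length(bad)) bad[1] else 0L, path, class = "mapParseError")
  anchors <- data.frame(chrom = rec[, 1], bp = bp, cm = cm,
                        stringsAsFactors = FALSE)
  for (ch in unique(anchors$chrom)) {
    sub <- anchors[anchors$chrom == ch, ]
    .assert(!is.unsorted(sub$cm),
            "chromosome %s: cM values not non-decreasing", ch,
            class = "mapValidationError")
    .assert(!is.unsorted(sub$bp, strictly = TRUE),
            "chromosome %s: bp positions not strictly increasing", ch,
            class = "mapValidationError")
    .assert(nrow(sub) >= 2L, "chromosome %s has fewer than 2 anchors", ch,
            class = "mapValidationError")
  }
  geneticMap(anchors)
}

#' Interpolate genetic map position
#'
#' Linear interpolation between flanking anchors; positions outside the
#' anchored range are clamped to the terminal cM values rather than
#' extrapolated, which avoids negative or runaway lengths at chromosome
#' ends.
#'
#' @param map a [GeneticMap-class].
#' @param chromosome chromosome name (single value).
#' @param positionBp bp position(s), 1-based; vectorised.
#' @return numeric cM value(s), non-decreasing in `positionBp`.
#' @export
interpolateCM <- function(map, chromosome, positionBp) {
  a <- map@anchors
  sub <- a[a$chrom == as.character(chromosome), ]
  .assert(nrow(sub) > 0L, "chromosome '%s' not in genetic map", chromosome,
          class = "mapLookupError")
  stats::approx(sub$bp, sub$cm, xout = positionBp, rule = 2,
                ties = "ordered")$y
}

#' Genetic length of a chromosome
#'
#' @param map a [GeneticMap-class].
#' @param chromosome chromosome name; when omitted, the summed length over
#'   all chromosomes in the map.
#' @return length in cM.
#' @export
mapLengthCM <- function(map, chromosome = NULL) {
  a <- map@anchors
  chroms <- if (is.null(chromosome)) unique(a$chrom) else as.character(chromosome)
  sum(vapply(chroms, function(ch) {
    sub <- a[a$chrom == ch, ]
    .assert(nrow(sub) > 0L, "chromosome '%s' not in genetic map", ch,
            class = "mapLookupError")
    max(sub$cm) - min(sub$cm)
  }, numeric(1)))
}

#' Write a genetic map in PLINK 4-column format
#'
#' @param map a [GeneticMap-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeGeneticMap <- function(map, path) {
  a <- map@anchors
  ids <- sprintf("a%d", seq_len(nrow(a)))
  writeLines(sprintf("%s %s %.8g %d", a$chrom, ids, a$cm,
                     as.integer(a$bp)), path)
  invisible(path)
}
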