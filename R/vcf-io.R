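#' Read a phased VCF into a PhasedCohort
#'
#' Loads a VCF (via \pkg{vcfR}) and extracts phased biallelic SNP genotypes.
#' Records that are not biallelic SNPs are skipped and counted (reported in
#' the `skipped` attribute and via a message); an unphased or missing
#' genotype is a hard error, since every downstream stage assumes complete
#' phased data.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @return A [PhasedCohort-class]; attribute `skipped` carries the number
#'   of non-biallelic-SNP records dropped.
#' @seealso [writePhasedVcf()]
#' @export
readPhasedVcf <- function(path) {
  .assert(file.exists(path), "VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gtRaw <- v@gt
  # vcfR may or may not retain the FORMAT column depending on version
  if (!is.null(gtRaw) && identical(colnames(gtRaw)[1], "FORMAT"))
    gtRaw <- gtRaw[, -1, drop = FALSE]
  .assert(!is.null(gtRaw) && ncol(gtRaw) >= 1L,
          "VCF '%s' has no sample genotype columns", path,
          class = "vcfParseError")
  samples <- colnames(gtRaw)

  isSnp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT != "." &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  skipped <- sum(!isSnp)
  if (skipped > 0L)
    message(sprintf("readPhasedVcf: skipped %d non-biallelic-SNP record(s)",
                    skipped))
  fix <- fix[isSnp, , drop = FALSE]
  gtRaw <- gtRaw[isSnp, , drop = FALSE]

  # GT is the first colon-separated field
  gt <- sub(":.*$", "", gtRaw)
  dim(gt) <- dim(gtRaw)
  gt[is.na(gt)] <- "."  # vcfR reads '.' genotypes as NA
  missing <- which(matrix(gt %in% c(".", "./.", ".|."), nrow(gt)),
                   arr.ind = TRUE)
  if (nrow(missing)) {
    .stopf("missing genotype at record %d (%s:%s), sample %s",
           missing[1, 1], fix$CHROM[missing[1, 1]], fix$POS[missing[1, 1]],
           samples[missing[1, 2]], class = "vcfGenotypeError")
  }
  unphased <- which(matrix(!grepl("|", gt, fixed = TRUE), nrow(gt)),
                    arr.ind = TRUE)
  if (nrow(unphased)) {
    .stopf("unphased genotype '%s' at record %d (%s:%s), sample %s",
           gt[unphased[1, 1], unphased[1, 2]], unphased[1, 1],
           fix$CHROM[unphased[1, 1]], fix$POS[unphased[1, 1]],
           samples[unphased[1, 2]], class = "vcfGenotypeError")
  }

  a0 <- substr(gt, 1L, 1L)
  a1 <- substr(gt, 3L, 3L)
  .assert(all(a0 %in% c("0", "1")) && all(a1 %in% c("0", "1")),
          "genotype alleles other than 0/1 in '%s'", path,
          class = "vcfGenotypeError")

  nSnp <- nrow(fix)
  hap <- matrix(0L, nrow = 2L * length(samples), ncol = nSnp)
  for (s in seq_along(samples)) {
    hap[2L * s - 1L, ] <- as.integer(a0[, s])
    hap[2L * s, ] <- as.integer(a1[, s])
  }
  variants <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                         id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                     sprintf("snp%d", seq_len(nSnp)), fix$ID),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  out <- phasedCohort(samples, variants, hap)
  attr(out, "skipped") <- skipped
  out
}

#' Write a PhasedCohort as a phased VCF
#'
#' Emits a minimal VCFv4.2 text file with phased GT fields (`0|1`
#' separator), one contig line per chromosome. Output is byte-deterministic
#' for a given cohort.
#'
#' @param cohort a [PhasedCohort-class].
#' @param path output path (plain text).
#' @return invisibly, `path`.
#' @export
writePhasedVcf <- function(cohort, path) {
  v <- cohort@variants
  hap <- cohort@haplotypes
  samples <- cohort@samples
  header <- c("##fileformat=VCFv4.2",
              "##source=founderscan",
              sprintf("##contig=<ID=%s>", unique(v$chrom)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "FORMAT", samples), collapse = "\t"))
  if (nrow(v)) {
    idx0 <- 2L * seq_along(samples) - 1L
    gtCols <- vapply(seq_along(samples), function(s) {
      paste0(hap[idx0[s], ], "|", hap[idx0[s] + 1L, ])
    }, character(nrow(v)))
    if (nrow(v) == 1L) gtCols <- matrix(gtCols, nrow = 1L)
    body <- paste(v$chrom, format(v$pos, scientific = FALSE, trim = TRUE),
                  v$id, v$ref, v$alt, ".", "PASS", "GT",
                  apply(gtCols, 1L, paste, collapse = "\t"), sep = "\t")
  } else body <- character()
  writeLines(c(header, body), path)
  invisible(path)
}
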