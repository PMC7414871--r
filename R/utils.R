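# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-up; base round() is banker's rounding, which would misplace
# kinship values falling exactly on a 2^(-d-0.5) midpoint
.roundHalfUp <- function(x) floor(x + 0.5)

.stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "founderscanError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

.assert <- function(ok, fmt, ..., class = NULL) {
  if (!isTRUE(ok)) .stopf(fmt, ..., class = class)
  invisible(TRUE)
}

# canonical ordering of a sample pair: lexicographic on the id strings
.orderPair <- function(a, b) {
  swap <- b < a
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b), swapped = swap)
}

# stable segment data.frame skeleton (shared schema across modules)
.segmentColumns <- c("sample_a", "hap_a", "sample_b", "hap_b", "chrom",
                     "start_bp", "end_bp", "start_cm", "end_cm", "length_cm")

.emptySegments <- function() {
  data.frame(sample_a = character(), hap_a = integer(),
             sample_b = character(), hap_b = integer(),
             chrom = character(),
             start_bp = numeric(), end_bp = numeric(),
             start_cm = numeric(), end_cm = numeric(),
             length_cm = numeric(), stringsAsFactors = FALSE)
}

.validateSegmentFrame <- function(seg) {
  .assert(is.data.frame(seg), "segments must be a data.frame")
  missing <- setdiff(.segmentColumns, names(seg))
  .assert(length(missing) == 0L,
          "segment table lacks column(s): %s", paste(missing, collapse = ", "),
          class = "segmentParseError")
  if (nrow(seg)) {
    .assert(all(seg$end_bp >= seg$start_bp),
            "segment with end_bp < start_bp", class = "segmentValidationError")
    .assert(all(seg$end_cm - seg$start_cm >= -1e-9),
            "segment with negative cM length", class = "segmentValidationError")
    .assert(all(seg$hap_a %in% 0:1) && all(seg$hap_b %in% 0:1),
            "haplotype indices must be 0 or 1", class = "segmentValidationError")
  }
  invisible(seg)
}

# file header comment written by the pipeline writers
.headerComment <- function(seed = NULL, extra = character()) {
  c(sprintf("# founderscan %s",
            as.character(utils::packageVersion("founderscan"))),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    extra)
}
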