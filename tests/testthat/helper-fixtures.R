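# shared fixtures: tiny maps, cohorts and an independent brute-force IBD
# oracle (direct scan of the raw haplotype matrix; no windows, no hashing)

linearMap <- function(chrom = "1", lengthBp = 100e6, lengthCm = 100) {
  geneticMap(data.frame(chrom = rep(chrom, each = 2),
                        bp = rep(c(1, lengthBp), length(chrom)),
                        cm = rep(c(0, lengthCm), length(chrom))))
}

# cohort with given haplotype rows (2 per sample) on an evenly spaced panel
toyCohort <- function(hap, chrom = "1", lengthBp = 100e6,
                      samples = NULL) {
  m <- ncol(hap)
  pos <- round(seq(1, lengthBp, length.out = m))
  samples <- samples %||% sprintf("S%d", seq_len(nrow(hap) / 2))
  phasedCohort(samples,
               data.frame(chrom = chrom, pos = pos,
                          id = sprintf("snp%d", seq_len(m)),
                          ref = "A", alt = "G", stringsAsFactors = FALSE),
               hap)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent oracle: maximal runs of identical alleles per haplotype pair
bruteForceIBD <- function(cohort, map, minCm = 3) {
  v <- variantTable(cohort)
  M <- hapMatrix(cohort)
  nH <- nrow(M)
  samples <- sampleIds(cohort)
  out <- list()
  for (ch in unique(v$chrom)) {
    cols <- which(v$chrom == ch)
    cmv <- interpolateCM(map, ch, v$pos[cols])
    for (i in seq_len(nH - 1L)) for (j in (i + 1L):nH) {
      si <- (i + 1L) %/% 2L; sj <- (j + 1L) %/% 2L
      if (si == sj) next
      r <- rle(M[i, cols] == M[j, cols])
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      lens <- cmv[ends] - cmv[starts]
      for (k in which(r$values & lens >= minCm)) {
        len <- lens[k]
        if (TRUE) {
          sa <- samples[si]; sb <- samples[sj]
          ha <- (i + 1L) %% 2L; hb <- (j + 1L) %% 2L
          if (sb < sa) { tmp <- sa; sa <- sb; sb <- tmp
                         tmp <- ha; ha <- hb; hb <- tmp }
          out[[length(out) + 1L]] <- data.frame(
            sample_a = sa, hap_a = ha, sample_b = sb, hap_b = hb,
            chrom = ch, start_bp = v$pos[cols][starts[k]],
            end_bp = v$pos[cols][ends[k]],
            start_cm = cmv[starts[k]], end_cm = cmv[ends[k]],
            length_cm = len, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out) %||% founderscan:::.emptySegments()
}

# overlap in cM between a segment row and a truth-segment row (same chrom)
cmOverlap <- function(seg, truthRow) {
  max(0, min(seg$end_cm, truthRow$end_cm) -
        max(seg$start_cm, truthRow$start_cm))
}

# default study-shaped five-cluster config with a given seed
fiveClusterConfig <- function(seed) simConfig(seed = seed)

studyLocus <- function() locusSpec("21:33031935-33041243")

# multi-chromosome relative-pair benchmark: simulates nPairs pairs of each
# requested degree per chromosome (independent assortment makes
# per-chromosome simulation exact), runs windowed detection, and returns
# the pairwise relatedness table joined with truth degrees
degreeBenchmark <- function(degrees, nPairs, nChrom = 22, cmPerChrom = 150,
                            snpsPerCm = 64, seed = 1) {
  emptyClusters <- simConfig()@clusters[0, ]
  segs <- list()
  reported <- list()
  maps <- list()
  for (di in seq_along(degrees)) {
    d <- degrees[di]
    for (k in seq_len(nChrom)) {
      cfg <- simConfig(
        seed = seed + 10000L * di + k,
        chromosomes = data.frame(chrom = as.character(k),
                                 length_bp = cmPerChrom * 1e6,
                                 length_cm = cmPerChrom,
                                 n_snps = as.integer(cmPerChrom * snpsPerCm)),
        clusters = emptyClusters,
        pairs = data.frame(degree = d, n_pairs = nPairs),
        nUnrelated = 0L)
      sim <- simulateCohort(cfg)
      segs[[length(segs) + 1L]] <- detectIBD(sim$cohort, sim$map)
      if (k == 1L) {
        reported[[di]] <- sim$truth$degrees
        if (di == 1L) maps <- lapply(seq_len(nChrom), function(kk)
          data.frame(chrom = as.character(kk), bp = c(1, cmPerChrom * 1e6),
                     cm = c(0, cmPerChrom)))
      }
    }
  }
  genomeMap <- geneticMap(do.call(rbind, maps))
  allSegs <- do.call(rbind, segs)
  reported <- do.call(rbind, reported)
  tab <- pairwiseRelatedness(allSegs, genomeMap)
  # truth pairs with no detected segment at all are unrelated calls
  full <- merge(reported, tab, by = c("sample_a", "sample_b"), all.x = TRUE)
  full$total_ibd1_cm[is.na(full$total_ibd1_cm)] <- 0
  full$total_ibd2_cm[is.na(full$total_ibd2_cm)] <- 0
  full$kinship_hat[is.na(full$kinship_hat)] <- 0
  full$degree_hat[is.na(full$degree_hat)] <- "UR"
  names(full)[names(full) == "degree"] <- "reported_degree"
  full
}
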