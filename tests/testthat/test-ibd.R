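# windowed IBD detection, masking and the IBD0/1/2 profile

test_that("a fully shared chromosome copy yields one full-map segment", {
  set.seed(31)
  m <- 500
  shared <- sample(0:1, m, TRUE)
  hap <- rbind(shared, sample(0:1, m, TRUE),
               shared, sample(0:1, m, TRUE))
  cohort <- toyCohort(hap)
  gm <- linearMap()
  seg <- detectIBD(cohort, gm, detectorParams(windowSnps = 64))
  full <- seg[seg$hap_a == 0L & seg$hap_b == 0L, ]
  expect_equal(nrow(full), 1L)
  expect_equal(full$start_bp, 1)
  expect_equal(full$end_bp, 100e6)
  expect_equal(full$length_cm, 100)
})

test_that("a planted identical stretch is recovered within one window", {
  set.seed(32)
  m <- 1200  # 100 cM -> 120 SNPs ~ 10 cM
  h1 <- sample(0:1, m, TRUE); h2 <- sample(0:1, m, TRUE)
  h3 <- sample(0:1, m, TRUE); h4 <- sample(0:1, m, TRUE)
  stretch <- 601:720  # 10 cM
  h3[stretch] <- h1[stretch]
  cohort <- toyCohort(rbind(h1, h2, h3, h4))
  gm <- linearMap()
  w <- 64L
  seg <- detectIBD(cohort, gm, detectorParams(windowSnps = w))
  expect_equal(nrow(seg), 1L)
  v <- variantTable(cohort)
  expect_lte(abs(seg$start_bp - v$pos[601]), v$pos[w + 1] - v$pos[1])
  expect_lte(abs(seg$end_bp - v$pos[720]), v$pos[w + 1] - v$pos[1])

  # brute-force longest-identical-run oracle agrees
  oracle <- bruteForceIBD(cohort, gm, minCm = 3)
  expect_equal(nrow(oracle), 1L)
  expect_gte(seg$start_cm, oracle$start_cm - 1e-9)
  expect_lte(seg$end_cm, oracle$end_cm + 1e-9)

  # a 2.5 cM stretch does not pass the 3 cM filter
  h5 <- sample(0:1, m, TRUE); h5[601:630] <- h1[601:630]
  cohort2 <- toyCohort(rbind(h1, h2, h5, h4))
  expect_equal(nrow(detectIBD(cohort2, gm, detectorParams())), 0L)
})

test_that("detector matches the brute-force oracle on random cohorts", {
  # every reported segment is an identical run; every identical run longer
  # than minCm + 2 windows is reported (slack <= 1 window per side)
  gm <- linearMap()
  set.seed(33)
  for (rep in 1:3) {
    m <- 800
    hap <- matrix(sample(0:1, 8 * m, TRUE), nrow = 8)
    # plant a few shared stretches across sample pairs
    hap[3, 101:250] <- hap[1, 101:250]   # 18.6 cM
    hap[6, 401:480] <- hap[2, 401:480]   # 9.9 cM
    cohort <- toyCohort(hap)
    w <- 64L
    params <- detectorParams(windowSnps = w)
    seg <- detectIBD(cohort, gm, params)
    oracle <- bruteForceIBD(cohort, gm, minCm = 3)
    windowCm <- 100 * w / m

    # (a) each reported segment lies inside an oracle run of the same pair
    for (i in seq_len(nrow(seg))) {
      hit <- oracle$sample_a == seg$sample_a[i] &
        oracle$sample_b == seg$sample_b[i] &
        oracle$hap_a == seg$hap_a[i] & oracle$hap_b == seg$hap_b[i] &
        oracle$start_cm <= seg$start_cm[i] + 1e-9 &
        oracle$end_cm >= seg$end_cm[i] - 1e-9
      expect_true(any(hit))
    }
    # (b) each long oracle run is reported with <= 1 window slack per side
    long <- oracle[oracle$length_cm >= 3 + 2 * windowCm, ]
    for (i in seq_len(nrow(long))) {
      hit <- seg$sample_a == long$sample_a[i] &
        seg$sample_b == long$sample_b[i] &
        seg$hap_a == long$hap_a[i] & seg$hap_b == long$hap_b[i] &
        seg$start_cm <= long$start_cm[i] + windowCm + 1e-9 &
        seg$end_cm >= long$end_cm[i] - windowCm - 1e-9
      expect_true(any(hit))
    }
  }
})

test_that("output is invariant to sample ordering", {
  set.seed(34)
  m <- 600
  hap <- matrix(sample(0:1, 6 * m, TRUE), nrow = 6)
  hap[5, 101:300] <- hap[1, 101:300]
  c1 <- toyCohort(hap, samples = c("alpha", "beta", "gamma"))
  perm <- c(3, 1, 2)
  rows <- as.vector(rbind(2 * perm - 1, 2 * perm))
  c2 <- toyCohort(hap[rows, ], samples = c("alpha", "beta", "gamma")[perm])
  gm <- linearMap()
  s1 <- detectIBD(c1, gm)
  s2 <- detectIBD(c2, gm)
  key <- function(s) do.call(paste, s[order(s$sample_a, s$sample_b,
                                            s$start_bp), ])
  expect_equal(key(s1), key(s2))
})

test_that("raising minCm never adds segments (monotonicity)", {
  cfg <- fiveClusterConfig(seed = 35)
  sim <- simulateCohort(cfg)
  s3 <- detectIBD(sim$cohort, sim$map, detectorParams(minCm = 3))
  s5 <- detectIBD(sim$cohort, sim$map, detectorParams(minCm = 5))
  expect_lte(nrow(s5), nrow(s3))
  key <- function(s) paste(s$sample_a, s$hap_a, s$sample_b, s$hap_b,
                           s$chrom, s$start_bp, s$end_bp)
  expect_true(all(key(s5) %in% key(s3)))
})

test_that("detection rejects a cohort smaller than one window", {
  cohort <- toyCohort(matrix(sample(0:1, 4 * 20, TRUE), nrow = 4))
  expect_error(detectIBD(cohort, linearMap(), detectorParams()),
               "smaller window")
})

test_that("mismatch allowance tolerates isolated errors in a window", {
  set.seed(36)
  m <- 600
  shared <- sample(0:1, m, TRUE)
  h3 <- shared; h3[300] <- 1L - h3[300]  # one genotype error
  hap <- rbind(shared, sample(0:1, m, TRUE), h3, sample(0:1, m, TRUE))
  cohort <- toyCohort(hap)
  gm <- linearMap()
  exact <- detectIBD(cohort, gm, detectorParams())
  lenient <- detectIBD(cohort, gm, detectorParams(maxMismatch = 1))
  sel <- function(s) s[s$hap_a == 0 & s$hap_b == 0, ]
  expect_equal(nrow(sel(exact)), 2L)   # error splits the segment
  expect_equal(nrow(sel(lenient)), 1L) # allowance bridges it
  expect_equal(sel(lenient)$length_cm, 100)
})

test_that("mask application removes, trims and splits segments", {
  gm <- linearMap()
  seg <- data.frame(sample_a = "A", hap_a = 0L, sample_b = "B", hap_b = 0L,
                    chrom = "1", start_bp = 1e6, end_bp = 2e6,
                    start_cm = 1, end_cm = 2, length_cm = 1,
                    stringsAsFactors = FALSE)
  seg$start_bp <- 1e6; seg$end_bp <- 20e6
  seg$start_cm <- 1; seg$end_cm <- 20; seg$length_cm <- 19

  mask <- GenomicRanges::GRanges("1", IRanges::IRanges(5000001, 8000000))
  out <- applyMask(seg, mask, gm, minCm = 3)
  expect_equal(nrow(out), 2L)
  expect_equal(out$end_bp[1], 5000000)   # trimmed to end before the mask
  expect_equal(out$start_bp[2], 8000001) # flanking piece kept
  expect_equal(out$length_cm, out$end_cm - out$start_cm)

  # a mask-boundary trim below minCm is dropped (re-filter contract)
  edge <- GenomicRanges::GRanges("1", IRanges::IRanges(1200001, 2500000))
  out1 <- applyMask(seg, edge, gm, minCm = 3)
  expect_equal(nrow(out1), 1L)
  expect_equal(out1$start_bp, 2500001)

  # fully inside the mask -> removed
  inside <- seg; inside$start_bp <- 5.3e6; inside$end_bp <- 7.4e6
  inside$start_cm <- 5.3; inside$end_cm <- 7.4; inside$length_cm <- 2.1
  expect_equal(nrow(applyMask(inside, mask, gm, minCm = 0.5)), 0L)

  # disjoint from all masks -> unchanged (cM re-interpolated from the map)
  far <- GenomicRanges::GRanges("1", IRanges::IRanges(90e6, 95e6))
  expect_equal(applyMask(seg, far, gm, minCm = 3), seg, tolerance = 1e-4)

  # trimmed piece shorter than minCm is dropped
  tight <- GenomicRanges::GRanges("1", IRanges::IRanges(3e6, 50e6))
  out2 <- applyMask(seg, tight, gm, minCm = 3)
  expect_equal(nrow(out2), 0L)
})

test_that("IBD profile states and length conservation", {
  gm <- linearMap()
  base <- data.frame(sample_a = "A", hap_a = 0L, sample_b = "B",
                     hap_b = 0L, chrom = "1", start_bp = 1,
                     end_bp = 50e6, start_cm = 0, end_cm = 50,
                     length_cm = 50, stringsAsFactors = FALSE)
  # one segment covering half the map
  prof <- ibdProfile(base, gm)
  len <- prof$end_cm - prof$start_cm
  expect_equal(sum(len[prof$state == 1L]), 50)
  expect_equal(sum(len[prof$state == 2L]), 0)
  expect_equal(sum(len), 100)  # conservation

  # complementary full-length pairings -> IBD2 everywhere
  two <- rbind(base, base)
  two$hap_a <- c(0L, 1L); two$hap_b <- c(0L, 1L)
  two$end_bp <- 100e6; two$end_cm <- 100; two$length_cm <- 100
  prof2 <- ibdProfile(two, gm)
  expect_equal(sum((prof2$end_cm - prof2$start_cm)[prof2$state == 2L]), 100)

  # same haplotype of A shared with both haplotypes of B is IBD1, not IBD2
  sameHap <- two; sameHap$hap_a <- c(0L, 0L)
  prof3 <- ibdProfile(sameHap, gm)
  expect_equal(sum((prof3$end_cm - prof3$start_cm)[prof3$state == 2L]), 0)

  # no segments -> IBD0 over the whole map
  prof4 <- ibdProfile(base[0, ], gm)
  expect_equal(prof4$state, 0L)
  expect_equal(sum(prof4$end_cm - prof4$start_cm), 100)

  # mixed pairs are rejected
  mixed <- rbind(base, base); mixed$sample_b <- c("B", "C")
  expect_error(ibdProfile(mixed, gm), "single sample pair")
})

test_that("detected segments cover >= 95% of truth tracts (simulated)", {
  # marker density chosen so a 64-SNP window is ~0.33 cM, well below the
  # 3 cM segment floor (real WGS panels are denser still)
  cfg <- simConfig(seed = 37,
                   chromosomes = data.frame(chrom = "21",
                                            length_bp = 46.7e6,
                                            length_cm = 65,
                                            n_snps = 12600L))
  sim <- simulateCohort(cfg)
  segs <- detectIBD(sim$cohort, sim$map)
  tr <- sim$truth$segments
  tc <- sim$truth$clusters
  # pairwise truth IBD within a cluster = intersection of founder tracts;
  # compare detected pair segments against that for sizeable tracts
  covered <- c(); total <- c()
  for (cl in unique(tc$cluster)) {
    ids <- tc$sample[tc$cluster == cl]
    sub <- tr[tr$sample_a %in% ids, ]
    cmb <- utils::combn(sort(ids), 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      ta <- sub[sub$sample_a == a, ]
      tb <- sub[sub$sample_a == b, ]
      s <- max(ta$start_cm, tb$start_cm); e <- min(ta$end_cm, tb$end_cm)
      if (e - s < 5) next  # below detectability, not informative
      det <- segs[segs$sample_a == a & segs$sample_b == b, ]
      ov <- sum(pmax(0, pmin(det$end_cm, e) - pmax(det$start_cm, s)))
      covered <- c(covered, min(ov, e - s)); total <- c(total, e - s)
    }
  }
  expect_gt(length(total), 100)
  expect_gte(sum(covered) / sum(total), 0.95)
})
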