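# founder-haplotype extraction: core intervals, singular shared sequence,
# common reporting interval, uninformative-SNP pruning

# tiny hand-built network: one cluster with explicit edges/segments
miniNetwork <- function(segs, locus) {
  buildNetwork(segmentsAtLocus(segs, locus), locus)
}

coreSeg <- function(a, b, s, e) {
  data.frame(sample_a = a, hap_a = 0L, sample_b = b, hap_b = 0L,
             chrom = "21", start_bp = s, end_bp = e,
             start_cm = s / 1e6, end_cm = e / 1e6,
             length_cm = (e - s) / 1e6, stringsAsFactors = FALSE)
}

test_that("core interval is the intersection of pairwise segments", {
  locus <- locusSpec("21:30000000-31000000")
  one <- coreSeg("A", "B", 10e6, 50e6)
  net <- miniNetwork(one, locus)
  iv <- clusterCoreInterval(net, "C1", one, locus)
  expect_equal(c(iv$startBp, iv$endBp), c(10e6, 50e6))

  two <- rbind(coreSeg("A", "B", 10e6, 50e6), coreSeg("B", "C", 20e6, 60e6))
  net2 <- miniNetwork(two, locus)
  iv2 <- clusterCoreInterval(net2, "C1", two, locus)
  expect_equal(c(iv2$startBp, iv2$endBp), c(20e6, 50e6))

  # disjoint contributions -> EmptyCore naming a pair
  locus3 <- locusSpec("21:5000000-45000000")
  disj <- rbind(coreSeg("A", "B", 10e6, 20e6), coreSeg("B", "C", 30e6, 40e6))
  net3 <- miniNetwork(disj, locus3)
  expect_error(clusterCoreInterval(net3, "C1", disj, locus3),
               class = "EmptyCore")
})

test_that("a pair's longest locus-overlapping segment feeds the core", {
  locus <- locusSpec("21:30000000-31000000")
  segs <- rbind(coreSeg("A", "B", 29e6, 32e6),   # short, overlaps locus
                coreSeg("A", "B", 25e6, 45e6))   # long, overlaps locus
  segs$hap_b <- c(0L, 1L)
  net <- miniNetwork(segs, locus)
  iv <- clusterCoreInterval(net, "C1", segs, locus)
  expect_equal(c(iv$startBp, iv$endBp), c(25e6, 45e6))
})

test_that("extraction recovers the singular shared haplotype", {
  m <- 60
  founder <- as.integer(rep(c(0L, 1L), length.out = m))
  set.seed(61)
  others <- matrix(sample(0:1, 3 * m, TRUE), nrow = 3)
  hap <- rbind(founder, others[1, ],
               others[2, ], founder,
               founder, others[3, ])
  cohort <- toyCohort(hap, chrom = "21", lengthBp = 6e6)
  v <- variantTable(cohort)
  h <- extractSharedHaplotype(cohort, c("S1", "S2", "S3"), "21",
                              v$pos[1], v$pos[m], clusterId = "CX")
  expect_equal(h@alleles, founder)
  expect_equal(unname(h@hapIndex), c(0L, 1L, 0L))

  # a single mutated member breaks the sharing
  hap2 <- hap; hap2[4, 30] <- 1L - hap2[4, 30]
  cohort2 <- toyCohort(hap2, chrom = "21", lengthBp = 6e6)
  expect_error(extractSharedHaplotype(cohort2, c("S1", "S2", "S3"), "21",
                                      v$pos[1], v$pos[m]),
               class = "NoSharedHaplotype")
})

test_that("autozygous members record copy 0; ambiguity raises an error", {
  m <- 40
  founder <- as.integer(rep(c(1L, 0L), length.out = m))
  set.seed(62)
  hap <- rbind(founder, founder,             # S1 autozygous
               founder, sample(0:1, m, TRUE))
  cohort <- toyCohort(hap, chrom = "21", lengthBp = 4e6)
  v <- variantTable(cohort)
  h <- extractSharedHaplotype(cohort, c("S1", "S2"), "21",
                              v$pos[1], v$pos[m])
  expect_equal(unname(h@hapIndex["S1"]), 0L)

  # two distinct sequences shared by everyone (both copies common to all)
  a <- founder; b <- as.integer(1L - founder)
  hap2 <- rbind(a, b, a, b)
  cohort2 <- toyCohort(hap2, chrom = "21", lengthBp = 4e6)
  expect_error(extractSharedHaplotype(cohort2, c("S1", "S2"), "21",
                                      v$pos[1], v$pos[m]),
               class = "AmbiguousHaplotype")
})

test_that("common reporting interval intersects cluster intervals", {
  mk <- function(id, s, e, pos, alleles) {
    new("ClusterHaplotype", clusterId = id, chrom = "21",
        startBp = s, endBp = e, positions = pos,
        alleles = as.integer(alleles),
        carriers = "x", hapIndex = c(x = 0L))
  }
  h1 <- mk("C1", 1e6, 10e6, seq(1e6, 10e6, by = 1e6), rep(0L, 10))
  h2 <- mk("C2", 5e6, 20e6, seq(5e6, 20e6, by = 1e6), rep(1L, 16))
  ri <- commonReportInterval(list(h1, h2))
  expect_equal(c(ri$startBp, ri$endBp), c(5e6, 10e6))
  expect_equal(ri$positions, seq(5e6, 10e6, by = 1e6))

  h3 <- mk("C3", 30e6, 40e6, seq(30e6, 40e6, by = 1e6), rep(0L, 11))
  expect_error(commonReportInterval(list(h1, h3)),
               class = "EmptyReportInterval")
})

test_that("uninformative SNPs are dropped, informative ones retained", {
  mk <- function(id, alleles) {
    pos <- seq_along(alleles) * 1e5
    new("ClusterHaplotype", clusterId = id, chrom = "21",
        startBp = pos[1], endBp = pos[length(pos)], positions = pos,
        alleles = as.integer(alleles), carriers = "x", hapIndex = c(x = 0L))
  }
  # haplotypes 0101 and 0011: SNPs 1 and 4 identical -> dropped
  pr <- dropUninformativeSnps(list(mk("C1", c(0, 1, 0, 1)),
                                   mk("C2", c(0, 0, 1, 1))))
  expect_equal(length(pr[[1]]@positions), 2L)
  expect_equal(pr[[1]]@alleles, c(1L, 0L))
  expect_equal(pr[[2]]@alleles, c(0L, 1L))

  # identical haplotypes: everything dropped, with a warning
  expect_warning(all0 <- dropUninformativeSnps(list(mk("C1", c(1, 1)),
                                                    mk("C2", c(1, 1)))),
                 "zero-length")
  expect_equal(length(all0[[1]]@positions), 0L)
})

test_that("pipeline haplotypes equal planted founders and distinguish clusters", {
  for (seed in c(63, 64)) {
    sim <- simulateCohort(fiveClusterConfig(seed))
    segs <- detectIBD(sim$cohort, sim$map)
    locus <- studyLocus()
    net <- buildNetwork(segmentsAtLocus(segs, locus), locus,
                        mutationLabels(sim$cohort))
    fh <- founderHaplotypes(sim$cohort, net, segs, locus)
    truthOf <- stats::setNames(sim$truth$clusters$cluster,
                               sim$truth$clusters$sample)
    for (cl in names(fh$pruned)) {
      h <- fh$pruned[[cl]]
      tcl <- unname(truthOf[h@carriers[1]])
      planted <- sim$truth$founders[[tcl]]
      i <- match(h@positions, planted@positions)
      expect_equal(h@alleles, planted@alleles[i])
      # the reported sequence occurs verbatim in every carrier
      cols <- match(h@positions, variantTable(sim$cohort)$pos)
      for (s in h@carriers) {
        r <- 2L * match(s, sampleIds(sim$cohort)) - 1L + h@hapIndex[[s]]
        expect_equal(unname(hapMatrix(sim$cohort)[r, cols]), h@alleles)
      }
    }
    # pruned haplotypes pairwise distinct
    keys <- vapply(fh$pruned, function(h) paste(h@alleles, collapse = ""),
                   character(1))
    expect_false(any(duplicated(keys)))
  }
})

test_that("core interval shrinks as pairs are added (property)", {
  locus <- locusSpec("21:30000000-31000000")
  set.seed(65)
  segs <- do.call(rbind, lapply(1:6, function(i) {
    s <- runif(1, 20e6, 29e6); e <- runif(1, 31e6, 45e6)
    coreSeg("A", sprintf("B%d", i), s, e)
  }))
  ivAll <- clusterCoreInterval(miniNetwork(segs, locus), "C1", segs, locus)
  for (k in 2:5) {
    sub <- segs[1:k, ]
    ivSub <- clusterCoreInterval(miniNetwork(sub, locus), "C1", sub, locus)
    expect_gte(ivAll$startBp, ivSub$startBp)
    expect_lte(ivAll$endBp, ivSub$endBp)
  }
})
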