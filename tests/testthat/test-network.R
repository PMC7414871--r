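# locus relatedness network: edges, components, discordance flags

segRow <- function(a, b, chrom = "21", s = 30e6, e = 34e6,
                   ha = 0L, hb = 0L) {
  data.frame(sample_a = a, hap_a = ha, sample_b = b, hap_b = hb,
             chrom = chrom, start_bp = s, end_bp = e,
             start_cm = s / 1e6, end_cm = e / 1e6,
             length_cm = (e - s) / 1e6, stringsAsFactors = FALSE)
}

test_that("locus edges need >= 1 bp overlap and collapse per pair", {
  locus <- studyLocus()  # 21:33031935-33041243
  segs <- rbind(
    segRow("A", "B", s = 30e6, e = 33031935),          # 1 bp overlap
    segRow("A", "C", s = 30e6, e = 33031934),          # misses by 1 bp
    segRow("B", "D", chrom = "5", s = 33e6, e = 34e6), # other chromosome
    segRow("C", "D", s = 33e6, e = 34e6, ha = 0L),
    segRow("C", "D", s = 32e6, e = 35e6, ha = 1L))     # same pair, 2nd seg
  edges <- segmentsAtLocus(segs, locus)
  expect_equal(nrow(edges), 2L)
  ab <- edges[edges$sample_a == "A", ]
  expect_equal(ab$sample_b, "B")
  cd <- edges[edges$sample_a == "C", ]
  expect_equal(cd$n_segments, 2L)
})

test_that("components are labelled by size with deterministic ties", {
  locus <- studyLocus()
  segs <- rbind(segRow("A", "B"), segRow("B", "C"),  # component of 3
                segRow("X", "Y"),                    # component of 2
                segRow("P", "Q"))                    # component of 2
  net <- buildNetwork(segmentsAtLocus(segs, locus), locus)
  memb <- clusterMembership(net)
  expect_equal(unname(memb[c("A", "B", "C")]), rep("C1", 3))
  # ties by smallest sample id: {P,Q} before {X,Y}
  expect_equal(unname(memb[c("P", "Q")]), rep("C2", 2))
  expect_equal(unname(memb[c("X", "Y")]), rep("C3", 2))

  # no edges -> empty network
  empty <- buildNetwork(segmentsAtLocus(segs[0, ], locus), locus)
  expect_equal(nrow(networkNodes(empty)), 0L)

  # one edge -> one component of two
  one <- buildNetwork(segmentsAtLocus(segRow("A", "B"), locus), locus)
  expect_equal(nrow(networkNodes(one)), 2L)
  expect_equal(unique(networkNodes(one)$cluster), "C1")
})

test_that("five founder clusters are recovered as five components", {
  sim <- simulateCohort(fiveClusterConfig(seed = 51))
  segs <- detectIBD(sim$cohort, sim$map)
  locus <- studyLocus()
  net <- buildNetwork(segmentsAtLocus(segs, locus), locus,
                      mutationLabels(sim$cohort))
  memb <- clusterMembership(net)
  truth <- stats::setNames(sim$truth$clusters$cluster,
                           sim$truth$clusters$sample)
  expect_equal(length(unique(memb)), 5L)
  # detected partition refines the truth partition exactly: every detected
  # component maps to one truth cluster and no two components share one
  crossTab <- table(truth[names(memb)], memb)
  expect_true(all(colSums(crossTab > 0) == 1))
  expect_true(all(rowSums(crossTab > 0) == 1))
  # network nodes only omit carriers whose ancestral tract fell below the
  # detection floor; all retained nodes are carriers
  expect_true(all(names(memb) %in% sim$truth$clusters$sample))
})

test_that("removing an edge never decreases the component count", {
  locus <- studyLocus()
  segs <- rbind(segRow("A", "B"), segRow("B", "C"), segRow("A", "C"),
                segRow("X", "Y"))
  full <- buildNetwork(segmentsAtLocus(segs, locus), locus)
  # components counted on the nodes that remain in the network (dropping a
  # pendant component's only edge removes its nodes, since isolated
  # samples are omitted by definition)
  for (drop in 1:3) {  # the triangle edges
    sub <- buildNetwork(segmentsAtLocus(segs[-drop, ], locus), locus)
    expect_gte(length(unique(networkNodes(sub)$cluster)),
               length(unique(networkNodes(full)$cluster)))
    expect_equal(nrow(networkNodes(sub)), 5L)
  }
})

test_that("discordant mutation labels and haplotype mismatches are flagged", {
  locus <- studyLocus()
  segs <- rbind(segRow("A", "B"), segRow("B", "C"))
  net <- buildNetwork(segmentsAtLocus(segs, locus), locus,
                      c(A = "p.I114T", B = "p.I114T", C = "p.V149G"))
  flags <- flagDiscordantEdges(net)
  expect_equal(nrow(flags), 1L)
  expect_equal(flags$reason, "discordant_mutation")
  expect_setequal(c(flags$sample_a, flags$sample_b), c("B", "C"))

  # all concordant -> no flags
  net2 <- buildNetwork(segmentsAtLocus(segs, locus), locus,
                       c(A = "p.I114T", B = "p.I114T", C = "p.I114T"))
  expect_equal(nrow(flagDiscordantEdges(net2)), 0L)

  # missing label -> edge skipped with a warning
  net3 <- buildNetwork(segmentsAtLocus(segs, locus), locus,
                       c(A = "p.I114T", B = "p.I114T"))
  expect_warning(f3 <- flagDiscordantEdges(net3), "missing mutation label")
  expect_equal(nrow(f3), 0L)
})

test_that("an injected false-positive segment between clusters is flagged", {
  sim <- simulateCohort(fiveClusterConfig(seed = 52))
  segs <- detectIBD(sim$cohort, sim$map)
  locus <- studyLocus()
  tc <- sim$truth$clusters
  # join a C1 carrier to a C3 carrier with a fabricated locus segment
  # (different mutations: p.I114T vs p.E101G)
  a <- sort(tc$sample[tc$cluster == "C1"])[1]
  b <- sort(tc$sample[tc$cluster == "C3"])[1]
  fake <- segRow(a, b, s = 32e6, e = 34e6)
  withFake <- rbind(segs, fake)
  net <- buildNetwork(segmentsAtLocus(withFake, locus), locus,
                      mutationLabels(sim$cohort))
  flags <- flagDiscordantEdges(net)
  expect_true(any(flags$sample_a == a & flags$sample_b == b))
  expect_equal(flags$reason[flags$sample_a == a & flags$sample_b == b],
               "discordant_mutation")
})

test_that("haplotype-mismatch flagging uses the founder haplotypes", {
  sim <- simulateCohort(fiveClusterConfig(seed = 53))
  segs <- detectIBD(sim$cohort, sim$map)
  locus <- studyLocus()
  tc <- sim$truth$clusters
  # same-mutation clusters C1 and C4 both carry p.I114T: a fake edge
  # between them passes the label check but fails the haplotype check
  a <- sort(tc$sample[tc$cluster == "C1"])[1]
  b <- sort(tc$sample[tc$cluster == "C4"])[1]
  withFake <- rbind(segs, segRow(a, b, s = 32.9e6, e = 33.2e6))
  net <- buildNetwork(segmentsAtLocus(withFake, locus), locus,
                      mutationLabels(sim$cohort))
  # the fake edge merges C1 and C4 into one component; check its members
  # against the planted C1 founder haplotype over the C1 core region
  tr1 <- sim$truth$segments[sim$truth$segments$sample_a %in%
                              tc$sample[tc$cluster == "C1"], ]
  fh <- sim$truth$founders[["C1"]]
  core <- fh@positions[fh@positions >= max(tr1$start_bp) &
                         fh@positions <= min(tr1$end_bp)]
  fhCore <- subsetHaplotype(fh, core)
  lab <- unname(clusterMembership(net)[a])
  flags <- flagDiscordantEdges(net, stats::setNames(list(fhCore), lab),
                               sim$cohort)
  expect_true(any(flags$sample_a == a & flags$sample_b == b &
                    flags$reason == "haplotype_mismatch"))

  # clean network: no haplotype mismatches
  netClean <- buildNetwork(segmentsAtLocus(segs, locus), locus,
                           mutationLabels(sim$cohort))
  hapsClean <- founderHaplotypes(sim$cohort, netClean, segs, locus)
  flagsClean <- flagDiscordantEdges(netClean, hapsClean$core, sim$cohort)
  expect_equal(nrow(flagsClean), 0L)
})

test_that("network JSON serialisation round-trips nodes and edges", {
  locus <- studyLocus()
  segs <- rbind(segRow("A", "B"), segRow("B", "C"))
  net <- buildNetwork(segmentsAtLocus(segs, locus), locus)
  f <- withr::local_tempfile(fileext = ".json")
  writeNetworkJson(net, f, seed = 5)
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(doc$seed, 5)
  expect_equal(nrow(doc$nodes), 3)
  expect_equal(nrow(doc$edges), 2)
})
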