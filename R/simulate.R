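# Gene-dropping simulator: founder clusters, relative pairs, unrelated
# background. Every founder chromosome carries a unique integer lineage
# label that is propagated through meioses alongside the alleles, so true
# IBD between any two simulated haplotypes is exact label identity.

# mutable counter handing out unique founder-haplotype labels
.labelCounter <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env
}

.nextLabel <- function(env) {
  env$n <- env$n + 1L
  env$n
}

# draw a fresh haplotype from per-site alternate-allele frequencies
.drawHap <- function(freqs, env, genotypes = TRUE) {
  list(a = if (genotypes) as.integer(stats::rbinom(length(freqs), 1L, freqs)),
       l = rep.int(.nextLabel(env), length(freqs)))
}

# Haldane crossover template on the cM scale: crossover count is
# Poisson(map length in Morgans), positions uniform in map distance,
# snapped to the nearest inter-SNP boundary; an even number of crossovers
# falling in one gap cancels out.
.crossoverSrc <- function(cmv) {
  n <- length(cmv)
  span <- cmv[n] - cmv[1]
  k <- stats::rpois(1L, span / 100)
  start <- sample.int(2L, 1L)
  src <- rep.int(start, n)
  if (k > 0L) {
    xo <- stats::runif(k, cmv[1], cmv[n])
    b <- findInterval(xo, cmv)
    b <- b[b >= 1L & b < n]
    if (length(b)) {
      tb <- table(b)
      b <- sort(as.integer(names(tb))[tb %% 2L == 1L])
      if (length(b)) {
        bounds <- c(0L, b, n)
        who <- start
        for (i in seq_len(length(bounds) - 1L)) {
          src[(bounds[i] + 1L):bounds[i + 1L]] <- who
          who <- 3L - who
        }
      }
    }
  }
  list(src = src, k = k)
}

# one gamete from a labelled parent (pair of labelled haplotypes)
.gamete <- function(h1, h2, cmv) {
  xo <- .crossoverSrc(cmv)
  two <- xo$src == 2L
  a <- h1$a
  l <- h1$l
  if (!is.null(a)) a[two] <- h2$a[two]
  l[two] <- h2$l[two]
  list(a = a, l = l, src = xo$src, k = xo$k)
}

# maximal runs of identical labels between two label vectors
.labelRuns <- function(lA, lB) {
  r <- rle(lA == lB)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Draw a pool of unrelated founder haplotypes
#'
#' Per-SNP alternate-allele frequencies are drawn uniformly within
#' `mafBounds`; haplotypes are drawn independently per site from those
#' frequencies (no background linkage disequilibrium).
#'
#' @param nHaplotypes number of haplotypes (>= 2).
#' @param nSnps number of SNPs.
#' @param mafBounds length-2 numeric in (0, 1).
#' @param seed optional RNG seed for a reproducible pool.
#' @return list with `haplotypes` (nHaplotypes x nSnps 0/1 matrix) and
#'   `freqs` (per-SNP alternate-allele frequency).
#' @export
makeFounderPool <- function(nHaplotypes, nSnps, mafBounds = c(0.05, 0.5),
                            seed = NULL) {
  .assert(nHaplotypes >= 2L, "need at least 2 haplotypes",
          class = "configError")
  .assert(length(mafBounds) == 2L && all(mafBounds > 0) &&
            all(mafBounds < 1) && mafBounds[1] <= mafBounds[2],
          "mafBounds must lie inside (0, 1)", class = "configError")
  if (!is.null(seed)) set.seed(seed)
  freqs <- stats::runif(nSnps, mafBounds[1], mafBounds[2])
  hap <- matrix(stats::rbinom(nHaplotypes * nSnps, 1L,
                              rep(freqs, each = nHaplotypes)),
                nrow = nHaplotypes)
  storage.mode(hap) <- "integer"
  list(haplotypes = hap, freqs = freqs)
}

#' Simulate one meiosis (Haldane model, no interference)
#'
#' The crossover count is Poisson with mean equal to the map length in
#' Morgans; crossover positions are uniform on the cM scale and mapped to
#' the nearest inter-SNP boundary; the gamete alternates parental source at
#' each crossover, starting from a fair-coin parent.
#'
#' @param hap1,hap2 the parent's two haplotypes (equal-length 0/1 vectors).
#' @param cm per-SNP genetic map positions in cM (non-decreasing), e.g.
#'   `interpolateCM(map, chrom, positions)`.
#' @return integer gamete vector with attributes `origin` (1/2 parental
#'   source per SNP) and `crossovers` (Poisson draw).
#' @export
meiosis <- function(hap1, hap2, cm) {
  .assert(length(hap1) == length(hap2), "parent haplotypes differ in length")
  .assert(length(cm) == length(hap1), "cm must align with haplotypes")
  g <- .gamete(list(a = as.integer(hap1), l = integer(length(hap1))),
               list(a = as.integer(hap2), l = integer(length(hap2))), cm)
  structure(g$a, origin = g$src, crossovers = g$k)
}

#' Simulate lengths of shared ancestral haplotypes
#'
#' One-sided lengths are Exponential(g) per Morgan (the ancestral tract on
#' one side of the mutation survives g meioses unbroken); two-sided lengths
#' are the sum of two independent sides.
#'
#' @param g generations to the common ancestor (>= 1).
#' @param n number of lengths.
#' @param twoSided sum two sides (default) or one side only.
#' @return lengths in cM.
#' @export
simulateSegmentLengths <- function(g, n, twoSided = TRUE) {
  .assert(g >= 1 && n >= 1, "g and n must be >= 1", class = "configError")
  len <- stats::rexp(n, rate = g)
  if (twoSided) len <- len + stats::rexp(n, rate = g)
  100 * len
}

#' Gene-drop a founder cluster
#'
#' A founder haplotype carrying a planted mutation is passed through `g`
#' independent meioses to each of `nCarriers` carriers (star genealogy),
#' recombining against fresh unrelated haplotypes each generation; every
#' gamete is conditioned to retain the mutation. The retained ancestral
#' tract around the mutation therefore has one-sided lengths distributed
#' Exponential(g) per Morgan. Each carrier's second chromosome is a fresh
#' background draw.
#'
#' @param nCarriers number of carriers.
#' @param g generations from the founder (>= 1).
#' @param map a [GeneticMap-class].
#' @param chrom chromosome name.
#' @param positions SNP bp positions.
#' @param freqs per-SNP background alternate-allele frequencies.
#' @param mutationBp bp position of the planted mutation; must be one of
#'   `positions`.
#' @param clusterId label for the cluster (default `"C1"`).
#' @param sampleIds optional carrier ids.
#' @param labelEnv internal label counter (created when NULL).
#' @param founder optional labelled founder haplotype to reuse.
#' @return list with `haplotypes` (2*nCarriers x nSnps matrix, rows
#'   carrier copies 0/1), `sampleIds`, `founderAlleles`, `founderLabel`,
#'   `tracts` (per-carrier truth segment around the mutation, cM and bp),
#'   and `labels` (lineage labels of carrier copy 0, for truth queries).
#' @export
simulateFounderCluster <- function(nCarriers, g, map, chrom, positions,
                                   freqs, mutationBp, clusterId = "C1",
                                   sampleIds = NULL, labelEnv = NULL,
                                   founder = NULL) {
  .assert(g >= 1, "g must be >= 1", class = "configError")
  mutIdx <- match(mutationBp, positions)
  .assert(!is.na(mutIdx),
          "mutation position %s is not at a simulated SNP",
          format(mutationBp, scientific = FALSE), class = "configError")
  env <- labelEnv %||% .labelCounter()
  cmv <- interpolateCM(map, chrom, positions)
  m <- length(positions)
  if (is.null(founder)) {
    founder <- .drawHap(freqs, env)
    founder$a[mutIdx] <- 1L
  }
  fLab <- founder$l[1]
  ids <- sampleIds %||% sprintf("%s_%02d", clusterId, seq_len(nCarriers))
  hap <- matrix(0L, nrow = 2L * nCarriers, ncol = m)
  labels0 <- matrix(0L, nrow = nCarriers, ncol = m)
  tracts <- vector("list", nCarriers)
  for (i in seq_len(nCarriers)) {
    cur <- founder
    for (k in seq_len(g)) {
      mate <- .drawHap(freqs, env)
      gam <- .gamete(cur, mate, cmv)
      if (gam$l[mutIdx] != fLab) {
        # take the complementary meiotic product, which carries the mutation
        two <- gam$src == 1L
        gam$a <- cur$a; gam$l <- cur$l
        gam$a[two] <- mate$a[two]; gam$l[two] <- mate$l[two]
      }
      cur <- list(a = gam$a, l = gam$l)
    }
    other <- .drawHap(freqs, env)
    hap[2L * i - 1L, ] <- cur$a
    hap[2L * i, ] <- other$a
    labels0[i, ] <- cur$l
    isF <- cur$l == fLab
    r <- .labelRuns(cur$l, rep.int(fLab, m))
    run <- r[r[, "start"] <= mutIdx & r[, "end"] >= mutIdx, , drop = FALSE]
    s <- run[1, "start"]; e <- run[1, "end"]
    tracts[[i]] <- data.frame(
      sample_a = ids[i], hap_a = 0L,
      sample_b = sprintf("%s.founder", clusterId), hap_b = 0L,
      chrom = chrom, start_bp = positions[s], end_bp = positions[e],
      start_cm = cmv[s], end_cm = cmv[e],
      length_cm = cmv[e] - cmv[s], stringsAsFactors = FALSE)
  }
  list(haplotypes = hap, sampleIds = ids, founderAlleles = founder$a,
       founderLabel = fLab, tracts = do.call(rbind, tracts),
       labels = labels0)
}

# minimal connecting pedigree for a relative pair of the given degree under
# the kinship convention phi = 2^(-d-1): d = 1 full siblings, d >= 2 adds
# d - 1 meioses below one sibling (so first cousins are d = 3, second
# cousins d = 5, third cousins d = 7); "PO" is parent-offspring.
.dropPair <- function(degree, freqs, cmv, env, genotypes = TRUE) {
  draw <- function() .drawHap(freqs, env, genotypes)
  gam <- function(ind) {
    g <- .gamete(ind[[1]], ind[[2]], cmv)
    list(a = g$a, l = g$l)
  }
  if (identical(degree, "PO")) {
    parent <- list(draw(), draw())
    child <- list(gam(parent), draw())
    return(list(A = parent, B = child))
  }
  d <- as.integer(degree)
  .assert(!is.na(d) && d >= 1L && d <= 11L,
          "unsupported degree '%s'", as.character(degree),
          class = "configError")
  father <- list(draw(), draw())
  mother <- list(draw(), draw())
  sib1 <- list(gam(father), gam(mother))
  sib2 <- list(gam(father), gam(mother))
  cur <- sib1
  for (k in seq_len(d - 1L)) cur <- list(gam(cur), draw())
  list(A = cur, B = sib2)
}

#' Simulate a relative pair of known degree
#'
#' Builds the minimal connecting pedigree for the requested degree (see
#' Details), gene-drops founder chromosomes through it and returns the two
#' samples plus the true IBD segments between them (from lineage labels).
#'
#' @details Degrees follow the kinship convention \eqn{\varphi =
#' 2^{-d-1}}: `"PO"` parent-offspring, 1 full siblings, 3 first cousins,
#' 5 second cousins, 7 third cousins. Degree d >= 2 is realised as a
#' sibling pair with d - 1 further meioses below one sibling.
#'
#' @param degree `"PO"` or an integer 1..11.
#' @param map a [GeneticMap-class].
#' @param chrom chromosome name.
#' @param positions SNP bp positions.
#' @param freqs background allele frequencies (may be omitted when
#'   `genotypes = FALSE`).
#' @param sampleIds length-2 character, ids for the two samples.
#' @param genotypes when FALSE only lineage labels are propagated (cheap
#'   realized-IBD studies without allele data).
#' @param labelEnv internal label counter.
#' @return list with `haplotypes` (4 x nSnps matrix: A0, A1, B0, B1; NULL
#'   when `genotypes = FALSE`), `sampleIds`, `degree`, and `truth`
#'   (segment data.frame of true IBD between the two samples).
#' @export
simulateRelativePair <- function(degree, map, chrom, positions,
                                 freqs = NULL,
                                 sampleIds = c("A", "B"), genotypes = TRUE,
                                 labelEnv = NULL) {
  .assert(!genotypes || !is.null(freqs),
          "freqs is required when genotypes = TRUE")
  if (is.null(freqs)) freqs <- rep(0, length(positions))
  env <- labelEnv %||% .labelCounter()
  cmv <- interpolateCM(map, chrom, positions)
  pr <- .dropPair(degree, freqs, cmv, env, genotypes)
  m <- length(positions)
  segs <- list()
  for (ia in 1:2) for (ib in 1:2) {
    runs <- .labelRuns(pr$A[[ia]]$l, pr$B[[ib]]$l)
    if (nrow(runs)) {
      s <- runs[, "start"]; e <- runs[, "end"]
      segs[[length(segs) + 1L]] <- data.frame(
        sample_a = sampleIds[1], hap_a = ia - 1L,
        sample_b = sampleIds[2], hap_b = ib - 1L,
        chrom = chrom, start_bp = positions[s], end_bp = positions[e],
        start_cm = cmv[s], end_cm = cmv[e], length_cm = cmv[e] - cmv[s],
        stringsAsFactors = FALSE)
    }
  }
  hap <- NULL
  if (genotypes) {
    hap <- rbind(pr$A[[1]]$a, pr$A[[2]]$a, pr$B[[1]]$a, pr$B[[2]]$a)
    storage.mode(hap) <- "integer"
  }
  list(haplotypes = hap, sampleIds = sampleIds,
       degree = as.character(degree),
       truth = do.call(rbind, segs) %||% .emptySegments())
}

#' Default simulation configuration
#'
#' The defaults emulate the shape of the motivating study: a single
#' chromosome 21 (46.7 Mb, 65 cM linear map, 4,200 SNPs so that a 64-SNP
#' window spans about 1 cM), five founder clusters of sizes 22/33/6/3/3
#' whose planted mutations all fall inside the SOD1 locus
#' (chr21:33,031,935-33,041,243), generation depths 10/7/4/5/6, and 20
#' unrelated background samples.
#'
#' @param seed RNG seed.
#' @param chromosomes chromosome geometry data.frame (`chrom`,
#'   `length_bp`, `length_cm`, `n_snps`).
#' @param mafBounds alternate-allele frequency bounds.
#' @param clusters founder cluster specs (`cluster_id`, `n_carriers`, `g`,
#'   `mutation_chrom`, `mutation_bp`, `label`, `n_families`).
#' @param pairs relative-pair specs (`degree`, `n_pairs`).
#' @param nUnrelated background sample count.
#' @param errorRate per-allele flip probability, default 0.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L,
                      chromosomes = data.frame(
                        chrom = "21", length_bp = 46.7e6,
                        length_cm = 65, n_snps = 4200L),
                      mafBounds = c(0.05, 0.5),
                      clusters = data.frame(
                        cluster_id = paste0("C", 1:5),
                        n_carriers = c(22L, 33L, 6L, 3L, 3L),
                        g = c(10, 7, 4, 5, 6),
                        mutation_chrom = "21",
                        mutation_bp = c(33032000, 33035000, 33037000,
                                        33039000, 33041000),
                        label = c("p.I114T", "p.V149G", "p.E101G",
                                  "p.I114T", "p.E101G"),
                        n_families = c(21L, 2L, 1L, 3L, 1L)),
                      pairs = data.frame(degree = character(),
                                         n_pairs = integer()),
                      nUnrelated = 20L,
                      errorRate = 0) {
  new("SimConfig", seed = as.integer(seed),
      chromosomes = as.data.frame(chromosomes),
      mafBounds = as.numeric(mafBounds),
      clusters = as.data.frame(clusters),
      pairs = as.data.frame(pairs),
      nUnrelated = as.integer(nUnrelated),
      errorRate = as.numeric(errorRate))
}

# SNP panel for one chromosome: random unique positions, mutation sites
# forced onto the panel with background frequency 0 (the alternate allele
# at a disease site exists only on the founder lineage)
.makePanel <- function(chromRow, mafBounds, mutationBp = numeric()) {
  m <- as.integer(chromRow$n_snps)
  mutationBp <- sort(unique(mutationBp))
  pos <- sort(sample.int(as.integer(chromRow$length_bp), m))
  pos <- setdiff(pos, mutationBp)
  # swap the nearest background SNP for each mutation site, keeping m SNPs
  for (mb in mutationBp) pos <- pos[-which.min(abs(pos - mb))]
  pos <- sort(c(pos, mutationBp))
  freqs <- stats::runif(length(pos), mafBounds[1], mafBounds[2])
  freqs[pos %in% mutationBp] <- 0
  list(pos = pos, freqs = freqs)
}

#' Simulate a complete phased cohort with truth tables
#'
#' Composes founder clusters, relative pairs and unrelated background
#' samples into one phased cohort. Deterministic under the config seed.
#'
#' @param config a [SimConfig-class].
#' @return list with elements
#'   \describe{
#'     \item{cohort}{[PhasedCohort-class] (with mutation labels).}
#'     \item{map}{[GeneticMap-class] (linear per chromosome).}
#'     \item{truth}{list: `segments` (true IBD segments: carrier ancestral
#'       tracts against the cluster founder, and pairwise segments for
#'       relative pairs), `degrees` (true pairwise degrees), `clusters`
#'       (sample, cluster, family, mutation), `founders` (list of
#'       [ClusterHaplotype-class], full-chromosome founder haplotypes),
#'       `tmrca` (cluster, g).}
#'   }
#' @export
simulateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  cl <- config@clusters
  pr <- config@pairs

  # sample registry
  clusterIds <- list(); families <- list()
  for (i in seq_len(nrow(cl))) {
    ids <- sprintf("%s_%02d", cl$cluster_id[i], seq_len(cl$n_carriers[i]))
    clusterIds[[i]] <- ids
    nf <- max(1L, as.integer(cl$n_families[i] %||% 1L))
    families[[i]] <- sprintf("F%s.%d", cl$cluster_id[i],
                             ((seq_along(ids) - 1L) %% nf) + 1L)
  }
  pairIds <- list()
  if (nrow(pr)) for (i in seq_len(nrow(pr))) {
    pairIds[[i]] <- lapply(seq_len(pr$n_pairs[i]), function(k)
      sprintf("D%s.P%03d.%s", pr$degree[i], k, c("A", "B")))
  }
  urIds <- if (config@nUnrelated > 0L)
    sprintf("UR%03d", seq_len(config@nUnrelated)) else character()
  allIds <- c(unlist(clusterIds), unlist(pairIds), urIds)
  .assert(!anyDuplicated(allIds), "duplicate sample ids across specs",
          class = "configError")
  nS <- length(allIds)

  anchors <- do.call(rbind, lapply(seq_len(nrow(config@chromosomes)),
    function(i) {
      r <- config@chromosomes[i, ]
      data.frame(chrom = as.character(r$chrom), bp = c(1, r$length_bp),
                 cm = c(0, r$length_cm), stringsAsFactors = FALSE)
    }))
  map <- geneticMap(anchors)

  env <- .labelCounter()
  variantList <- list(); hapList <- list()
  truthSegs <- list(); founderInfo <- list()

  for (ci in seq_len(nrow(config@chromosomes))) {
    chromRow <- config@chromosomes[ci, ]
    ch <- as.character(chromRow$chrom)
    mutHere <- cl$mutation_bp[cl$mutation_chrom == ch]
    panel <- .makePanel(chromRow, config@mafBounds, mutHere)
    m <- length(panel$pos)
    hap <- matrix(0L, nrow = 2L * nS, ncol = m)
    rowOf <- function(id) 2L * match(id, allIds) - 1L

    for (i in seq_len(nrow(cl))) {
      res <- simulateFounderCluster(
        nCarriers = cl$n_carriers[i], g = cl$g[i], map = map, chrom = ch,
        positions = panel$pos, freqs = panel$freqs,
        mutationBp = cl$mutation_bp[i], clusterId = cl$cluster_id[i],
        sampleIds = clusterIds[[i]], labelEnv = env)
      for (j in seq_along(clusterIds[[i]])) {
        r <- rowOf(clusterIds[[i]][j])
        hap[r, ] <- res$haplotypes[2L * j - 1L, ]
        hap[r + 1L, ] <- res$haplotypes[2L * j, ]
      }
      truthSegs[[length(truthSegs) + 1L]] <- res$tracts
      founderInfo[[cl$cluster_id[i]]] <- new(
        "ClusterHaplotype", clusterId = cl$cluster_id[i], chrom = ch,
        startBp = panel$pos[1], endBp = panel$pos[m],
        positions = panel$pos, alleles = as.integer(res$founderAlleles),
        carriers = clusterIds[[i]],
        hapIndex = stats::setNames(rep(0L, cl$n_carriers[i]),
                                   clusterIds[[i]]))
    }

    if (nrow(pr)) for (i in seq_len(nrow(pr))) {
      for (k in seq_len(pr$n_pairs[i])) {
        ids <- pairIds[[i]][[k]]
        res <- simulateRelativePair(pr$degree[i], map, ch, panel$pos,
                                    panel$freqs, sampleIds = ids,
                                    labelEnv = env)
        for (j in 1:2) {
          r <- rowOf(ids[j])
          hap[r, ] <- res$haplotypes[2L * j - 1L, ]
          hap[r + 1L, ] <- res$haplotypes[2L * j, ]
        }
        truthSegs[[length(truthSegs) + 1L]] <- res$truth
      }
    }

    for (id in urIds) {
      r <- rowOf(id)
      hap[r, ] <- .drawHap(panel$freqs, env)$a
      hap[r + 1L, ] <- .drawHap(panel$freqs, env)$a
    }

    variantList[[ci]] <- data.frame(
      chrom = ch, pos = panel$pos,
      id = ifelse(panel$pos %in% mutHere,
                  sprintf("mut_%s", format(panel$pos, scientific = FALSE,
                                           trim = TRUE)),
                  sprintf("%s_snp%d", ch, seq_len(m))),
      ref = "A", alt = "G", stringsAsFactors = FALSE)
    hapList[[ci]] <- hap
  }

  hap <- do.call(cbind, hapList)
  variants <- do.call(rbind, variantList)
  if (config@errorRate > 0) {
    flip <- matrix(stats::runif(length(hap)) < config@errorRate,
                   nrow = nrow(hap))
    hap[flip] <- 1L - hap[flip]
  }

  mut <- character()
  for (i in seq_len(nrow(cl)))
    mut[clusterIds[[i]]] <- cl$label[i]

  cohort <- phasedCohort(allIds, variants, hap, mutations = mut)

  clustersTab <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i)
    data.frame(sample = clusterIds[[i]], cluster = cl$cluster_id[i],
               family = families[[i]], mutation = cl$label[i],
               stringsAsFactors = FALSE))) %||%
    data.frame(sample = character(), cluster = character(),
               family = character(), mutation = character())

  degs <- list()
  for (i in seq_len(nrow(cl))) {
    ids <- clusterIds[[i]]
    if (length(ids) >= 2L) {
      cmb <- utils::combn(ids, 2L)
      # star genealogy: two carriers are 2g meioses apart
      degs[[length(degs) + 1L]] <- data.frame(
        sample_a = cmb[1, ], sample_b = cmb[2, ],
        degree = as.character(2L * as.integer(cl$g[i]) - 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (nrow(pr)) for (i in seq_len(nrow(pr)))
    degs[[length(degs) + 1L]] <- data.frame(
      sample_a = vapply(pairIds[[i]], `[`, character(1), 1L),
      sample_b = vapply(pairIds[[i]], `[`, character(1), 2L),
      degree = pr$degree[i], stringsAsFactors = FALSE)
  degrees <- do.call(rbind, degs) %||%
    data.frame(sample_a = character(), sample_b = character(),
               degree = character())

  truth <- list(
    segments = do.call(rbind, truthSegs) %||% .emptySegments(),
    degrees = degrees,
    clusters = clustersTab,
    founders = founderInfo,
    tmrca = data.frame(cluster = cl$cluster_id, g = cl$g,
                       stringsAsFactors = FALSE))
  list(cohort = cohort, map = map, truth = truth)
}

#' Write a simulated cohort and its truth tables to disk
#'
#' Emits `cohort.vcf`, `genetic.map`, `truth_segments.tsv`,
#' `truth_degrees.tsv`, `truth_clusters.tsv` and `truth_haplotypes.tsv`
#' under `dir`.
#'
#' @param sim result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param seed seed recorded in file header comments.
#' @return invisibly, `dir`.
#' @export
writeCohort <- function(sim, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .headerComment(seed)
  writePhasedVcf(sim$cohort, file.path(dir, "cohort.vcf"))
  writeGeneticMap(sim$map, file.path(dir, "genetic.map"))
  writeSegments(sim$truth$segments, file.path(dir, "truth_segments.tsv"),
                comments = hdr)
  for (nm in c("degrees", "clusters")) {
    con <- file(file.path(dir, sprintf("truth_%s.tsv", nm)), "w")
    writeLines(hdr, con)
    utils::write.table(sim$truth[[nm]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  writeClusterHaplotypes(sim$truth$founders, sim$cohort,
                         file.path(dir, "truth_haplotypes.tsv"),
                         comments = hdr)
  invisible(dir)
}
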