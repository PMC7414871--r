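---
title: "Resolving founder events from identity-by-descent sharing"
author: "founderscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving founder events from identity-by-descent sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderscan)
```

## The problem

When the same rare disease mutation appears in many nominally unrelated
families, two explanations compete: recurrent mutation, or a single founder
event whose descendants have lost track of their shared ancestry. The two
are distinguishable from phased genome data, because descendants of one
founder still carry pieces of the founder's chromosome around the mutation
— segments identical by descent (IBD). `founderscan` implements the full
chain of reasoning as one tested pipeline:

1. **IBD segment detection** on phased SNP haplotypes (windowed exact
   matching in the GERMLINE style, merged and filtered at 3 cM);
2. **degree-of-relatedness estimation** from genome-wide IBD sharing;
3. **locus relatedness networks**: samples sharing an IBD segment over the
   target locus form edges; connected components are candidate founder
   clusters;
4. **founder-haplotype extraction**: the singular haplotype shared by all
   members of a cluster over the intersection of their segments;
5. **mutation dating** with the Gamma method for the time to the most
   recent common ancestor (TMRCA).

The motivating application is SOD1-linked amyotrophic lateral sclerosis,
where clusters of carriers of p.I114T, p.V149G and p.E101G mutations over
the SOD1 locus (chr21:33,031,935–33,041,243, hg19) indicate founder
events linking familial and apparently sporadic cases. The original
patient-level data are restricted, so the package ships a gene-dropping
simulator that reproduces the *structure* of such a study with full truth
tables, giving every downstream stage an oracle.

## The simulator defines the study conditions

`simConfig()` fixes the synthetic conditions; its defaults are the
package's standing study design, not tuning knobs:

* one chromosome 21 of 46.7 Mb with a 65 cM linear map and 4,200 SNPs, so
  that a 64-SNP detection window spans about 1 cM;
* alternate-allele frequencies uniform on (0.05, 0.5), haplotypes drawn
  site-independently (no background LD — see *Limitations*);
* five founder clusters of sizes 22/33/6/3/3 with generation depths
  g = 10, 7, 4, 5 and 6 — echoing the dated ranges of the motivating
  study (point estimates near 10 and 7 generations for the two large
  clusters, mid-single digits for the small ones) and all inside the
  plausible 3–12 generation window for a 19th-century founder;
* each cluster's mutation planted at a SNP inside the SOD1 locus, with
  the alternate allele present only on the founder lineage;
* 20 unrelated background samples; genotype error rate 0 by default.

Descent is simulated as a *star genealogy*: each carrier receives the
founder chromosome through g independent meioses (Haldane model — Poisson
crossover counts with mean equal to the map length in Morgans, positions
uniform on the cM scale), recombined against fresh unrelated haplotypes
and conditioned to retain the mutation. Consequently the retained
ancestral tract extends an Exponential(g)-per-Morgan distance to each
side of the mutation — exactly the model the Gamma dating method assumes,
which makes tract lengths analytically checkable. A correlated
(pedigree-shaped) genealogy generator is deliberately out of scope.

Every founder haplotype carries a hidden integer lineage label propagated
through all meioses, so true IBD between any two samples is label
identity — the truth tables are exact, not approximate.

Relative pairs of degree d (kinship 2^(−d−1); d = 1 full siblings, 3
first cousins, 5 second cousins, 7 third cousins) are realised as a
sibling pair plus d − 1 further meioses below one sibling, parent–
offspring ("PO") separately. Multi-chromosome genomes are simulated one
chromosome at a time; independent assortment makes this exact.

## Detection and its numerical conventions

`detectIBD()` partitions each chromosome into consecutive 64-SNP windows,
buckets haplotypes by exact window content (bit-packed keys, groups are
exact so output is collision-free), merges runs of consecutive matching
windows and keeps segments of at least `minCm = 3` cM. Conventions that
matter for reproducibility:

* segment endpoints snap to SNP positions (first/last SNP of the matched
  run), so lengths are recomputable from the map alone;
* the trailing partial window of a chromosome participates, so a fully
  shared chromosome yields a full-map segment;
* a per-window mismatch allowance (`maxMismatch`) exists for noisy data
  but is off by default — the simulator's default error rate is 0;
* masking (`applyMask()`) removes segments inside masked intervals, trims
  or splits straddling ones, and re-filters the pieces against `minCm`,
  so the minimum-length contract holds globally;
* window quantisation costs up to one window per segment end. The window
  is therefore kept well below `minCm`: about 1 cM at the default density
  and 0.33 cM (12,600 SNPs) in the detector-fidelity and
  founder-extraction suites, where detected segments must cover at least
  95% of pairwise truth tracts and the pairwise-segment intersection must
  stay anchored on the 9.3 kb locus (a snapped boundary landing inside
  the locus voids the core interval, which `clusterCoreInterval()`
  reports as an `EmptyCore` error naming the pair). Real WGS panels
  (roughly 1,000 SNPs per cM) are denser than either.

Relatedness uses kinship φ̂ = (0.25·IBD1 + 0.5·IBD2)/L over the analysed
map, with degree d̂ = round(−log2 φ̂) − 1 (half-up, so ties at the
2^(−d−0.5) midpoints go to the nearer degree), PO called when IBD1 covers
at least 95% of the genome with at most 2% IBD2 (siblings carry IBD2,
parent–offspring essentially none), and pairs below kinship 2^(−13) —
beyond 11th degree — called unrelated. These cut-points are declared
surrogates for the reference tool's undisclosed internals; they are
validated by simulation recovery (degrees PO and 1–6 estimated within ±1
for well over 90% of pairs on a 22-chromosome genome), not by
bit-compatibility.

## Networks, founder haplotypes, dating

An edge joins two samples whose segments overlap the locus by at least
1 bp ("partially or completely"); samples sharing with no one are omitted
by definition, which is also why a carrier whose ancestral tract fell
below the 3 cM detection floor can be absent from its cluster. Clusters
are connected components, labelled C1…Ck by decreasing size with ties
broken by smallest member id, so reports are reproducible. Edges joining
samples with different mutation labels, or samples that do not carry
their cluster's founder haplotype, are *flagged* but never removed — they
are the signature of false-positive IBD calls and are reported for
inspection.

Founder haplotypes follow the published extraction procedure: the cluster
core interval is the intersection of the longest locus-overlapping
segment of every member pair (an empty intersection is an error naming
the offending pair); the founder haplotype is the *singular* allele
sequence present on at least one phased copy of every member over that
interval (none or several is an error; a member matching on both copies —
an autozygous stretch — records copy 0 by convention); all cluster
haplotypes are then re-reported over the intersection of their intervals
on the common SNP set, and SNPs with identical alleles across all founder
haplotypes are pruned as uninformative. On error-free simulations the
pruned haplotypes equal the planted founders and pairwise-distinguish all
clusters.

Dating: with n two-sided ancestral lengths (in Morgans) the total
ΣL ~ Gamma(2n, g), giving the MLE ĝ = 2n/ΣL and exact 95% bounds
[Q(0.025; 2n)/ΣL, Q(0.975; 2n)/ΣL]; with this model the interval's
coverage is exactly nominal, which the calibration suite confirms
empirically (0.93–0.97 over 1,000 replicates at g = 8, n = 10). A
one-sided switch (shape n) handles segments truncated at chromosome
ends, and the bias-corrected variant (2n−1)/ΣL is available behind a
flag. Generation intervals are rounded half-up and converted to years at
20 years per generation by default.

Two modelling notes, decided here as design choices:

* **Correlated genealogies.** When some samples share an ancestor more
  recent than the MRCA of all of them, their lengths are positively
  correlated and the nominal interval is too narrow. The package's
  `correlated` mode applies an exchangeable-correlation adjustment,
  n_eff = n/(1 + (n − 1)ρ), to the gamma shape; at ρ = 0 it reduces
  exactly to the independent mode. This is an effective-sample-size
  approximation of the published correction, chosen because it is
  transparent, monotone in ρ and exactly calibrated at the boundary; the
  independent mode is the fully specified surface that the test suite
  calibrates. The practical mitigation is the same as in the motivating
  study: date only approximately independent carriers, which
  `selectDatingSamples()` enforces (one best-connected sample per family,
  then dropping samples closer than `minDegree`, default 6th degree).
* **What a pairwise segment estimates.** The pipeline, like the study it
  follows, feeds the lengths of inferred pairwise IBD segments into the
  estimator. Under a star genealogy the segment between two carriers is
  the intersection of their founder tracts, whose sides are
  Exponential(g_i + g_j); ĝ from pairwise segments therefore refers to
  the meiotic path between the pair, not the generation depth of a
  single lineage. The calibration suites use per-lineage lengths
  (`simulateSegmentLengths()`), where the correspondence is exact.

## Problem sizes in the shipped suites

The test and acceptance suites run entirely on synthetic cohorts at desk
scale, chosen once: the 87-sample five-cluster cohort above (20 seeded
replicates for cluster recovery, 3 for founder-haplotype fidelity); a
12,600-SNP replicate for detector fidelity; 100 pairs per degree for PO
and degrees 1–6 over 22 chromosomes of 150 cM for degree recovery; 1,000
replicates at g = 8, n = 10 for dating calibration. Headline quantities
of the motivating study that depend on its restricted patient data
(16,414 genome-wide segments, 1,204 on chromosome 21, 954 sharing pairs,
the 350-SNP founder haplotypes over the 481 kb / 0.56 cM reporting
interval, and the published TMRCA ranges) are carried as descriptive
anchors in `cohortAnchors()` and are never recomputed.

## Limitations

* Background haplotypes are drawn site-independently: there is no
  population LD, so the false-IBD structure of real data (and hence the
  realistic false-positive edge rate of the network stage) is not
  emulated. Passing suites demonstrate correctness of the machinery, not
  real-data error rates.
* Phasing is taken as given and error-free; phasing-switch artefacts are
  out of scope.
* The star genealogy makes within-cluster relationships exchangeable;
  pedigree-shaped (correlated) descent is generated nowhere, which is
  precisely why the correlated dating mode is an approximation rather
  than a simulated, validated regime.
* Single-population cohorts only: no admixture, no ancestry filtering.

## A short workflow

```{r workflow, eval = FALSE}
library(founderscan)

res <- runAll(list(
  sim   = simConfig(seed = 1),
  locus = "21:33031935-33041243"))

cat(res$summary, sep = "\n")
networkNodes(res$network)        # cluster membership per sample
res$haplotypes$pruned            # distinguishing founder haplotypes
res$tmrca                        # per-cluster TMRCA estimates
```

The same stages run from the shell through `inst/cli/founderscan.R`
(subcommands `simulate`, `ibd`, `relate`, `network`, `founder`, `date`,
`run`).
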