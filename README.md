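# founderscan

Founder-event analysis from identity-by-descent (IBD) sharing in phased
SNP data, for statistical geneticists studying rare disease mutations
that recur across nominally unrelated families — the motivating case
being *SOD1*-linked ALS, where carriers of p.I114T, p.V149G and p.E101G
cluster over the *SOD1* locus (chr21:33,031,935–33,041,243, hg19) and
apparently sporadic cases turn out to be unrecognised members of
extended families.

The package implements, as one tested pipeline:

* **IBD detection** — GERMLINE-style windowed exact matching of phased
  haplotypes (64-SNP windows, hashed, merged, filtered at ≥ 3 cM), with
  BED mask support;
* **relatedness** — kinship from genome-wide sharing,
  φ̂ = (0.25·IBD1 + 0.5·IBD2)/L, mapped to a degree via
  d̂ = round(−log₂ φ̂) − 1 (so φ = 2^(−d−1): d = 3 first cousins, d = 7
  third cousins), PO/sibling disambiguation through IBD2, and a
  Table-2-style report of novel cross-family relatives;
* **locus networks** — samples sharing a segment over the locus form
  edges; connected components are founder clusters; edges discordant in
  mutation or haplotype are flagged, not removed;
* **founder haplotypes** — per cluster, the singular allele sequence
  carried by every member over the intersection of its pairwise
  segments, re-reported across clusters on a common SNP set and pruned
  of uninformative SNPs;
* **mutation dating** — the Gamma method: n two-sided ancestral lengths
  give ΣL ~ Gamma(2n, g), ĝ = 2n/ΣL, exact gamma-quantile 95% bounds,
  years at 20 per generation;
* **a gene-dropping simulator** (star genealogies, Haldane
  recombination, lineage-label truth tracking) that generates phased
  cohorts with founder clusters, relative pairs of known degree and
  unrelated background — every stage has an exact oracle.

## Worked example

```r
library(founderscan)

res <- runAll(list(sim = simConfig(seed = 7),
                   locus = "21:33031935-33041243"))
cat(res$summary, sep = "\n")
```

```
founderscan run (seed 7)
samples: 87, SNPs: 4200
IBD segments >= 3 cM genome-wide: 770
pairs sharing the locus: 679
clusters at locus: 5
cluster sizes: C1=31 C2=21 C3=5 C4=3 C5=2
flagged discordant edges: 0
TMRCA C1: 5-44 generations (100-880 years)
TMRCA C2: 8-15 generations (160-300 years)
```

The synthetic cohort plants five founder events (22/33/6/3/3 carriers,
g = 10/7/4/5/6 generations) whose mutations all fall inside the locus:
detection finds 770 segments ≥ 3 cM, the locus network resolves exactly
five clusters matching the planted ones (a few carriers whose ancestral
tract fell under the 3 cM floor are omitted, as the network definition
requires), no edge is discordant, and the Gamma method dates the
datable clusters — e.g. C2 here (the 22-carrier, g = 10 cluster) at
8–15 generations from 20 one-per-family pairwise segment lengths.
Founder haplotypes are in `res$haplotypes$pruned`; each equals its
planted founder sequence and distinguishes all five clusters.

The same stages are scriptable via `inst/cli/founderscan.R`
(`simulate | ibd | relate | network | founder | date | run`).

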