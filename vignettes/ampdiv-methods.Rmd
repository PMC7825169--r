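---
title: "Methods behind ampdiv: intra-lineage microdiversity and phylogeography from long-read rRNA amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind ampdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampdiv)
```

## The problem

Short 16S rRNA gene amplicons resolve bacterioplankton to roughly the
genus level: organisms sharing more than 97% 16S identity collapse into
one "lineage". Long-read amplicons spanning the near-full-length 16S
gene, the internal transcribed spacer (ITS), and the 5' end of the 23S
gene — roughly 2 kb — carry enough signal to resolve populations *within*
such lineages at single-nucleotide resolution, because most intra-lineage
variation concentrates in the hypervariable ITS. Once such amplicons have
been denoised into exact amplicon sequence variants (ASVs), the questions
become: how many sequence-discrete populations live inside each lineage,
how are they distributed across habitats (lakes, regions, water layers),
and can the variant calls be trusted?

`ampdiv` implements the downstream analysis as a reusable, tested
pipeline. Denoising itself (e.g. DADA2 on PacBio CCS reads) is upstream
and out of scope: the pipeline's input is an ASV FASTA plus an
ASV-by-sample count table and sample metadata.

## Pipeline stages and their assumptions

### Region partitioning

Each amplicon is split into 16S / ITS / 23S spans by semi-global
alignment of two bundled references (a ~1450-nt 16S reference and a
~110-nt 23S 5'-fragment): the whole reference must align, while the
amplicon provides a free-ending substring. Because a primer-trimmed
amplicon starts inside the 16S gene and ends inside the 23S gene, the 16S
span is extended to the amplicon start, the 23S span to the amplicon end,
and the ITS is the remainder; the three intervals tile the amplicon
exactly. An amplicon in which the two spans overlap, or whose ITS would
be shorter than `min_its` (default 1 nt), is rejected as a putative
unlinked or aberrant rRNA operon.

The bundled references are *synthetic*, generated once under a fixed seed
with primer-compatible ends (shipped as
`inst/extdata/*_synthetic.fasta`). They are placeholders a user analysing
real data should replace with taxon-appropriate references; with
real references, boundaries may shift by a few bases relative to an
alignment against a curated rRNA database, which can shift region-relative
SNP labels equally. Boundary placement is robust to point substitutions
(tested), which is what matters for the synthetic study conditions.

### Alignment and identity

Pairwise identity is the workhorse of clustering. The substrate is
global Needleman–Wunsch alignment with affine gaps (match +2, mismatch
−3, gap open −5, gap extend −2; a gap of length L costs 5 + 2L), computed
by `Biostrings::pairwiseAlignment`. Identity is defined as matching
columns divided by alignment columns *excluding terminal-gap columns*;
internal gaps count against identity. This matches the default identity
semantics of the greedy clustering tools used in the field. Identity of
near-identical amplicons is insensitive to the exact scoring scheme, and
all parameters are exposed through `align_scoring()`.

Two exact fast paths avoid the dynamic program where its result is
provable: byte-identical sequences have identity 1, and equal-length
sequences whose gapless score already attains the ceiling for any gapped
alignment (under the defaults this is provable for Hamming distance
m ≤ 3) take the gapless identity. Ties between co-optimal
alignments are resolved by the aligner's deterministic backtrack, so all
outputs are bit-reproducible.

### Dual-threshold greedy clustering

Extracted 16S regions are clustered twice, mirroring the two ecological
units:

* **SSU-ASV** (100% identity): ASVs whose 16S regions are exactly
  identical (their ITS may differ). At threshold 1.0 greedy clustering
  reduces to exact deduplication and is computed by hashing.
* **OTU / lineage** (97% identity): greedy centroid clustering. Inputs
  are processed in (length descending, abundance descending, id
  ascending) order; a sequence joins the *first* centroid at or above
  threshold, else founds a new centroid. The ordering tie-breaks
  (abundance, then id) are our choice for reproducibility — length-first
  is what the field's tools do, but they do not document tie handling.

Re-assignment of all ASVs back to centroids (`map_to_centroids()`)
deliberately uses different semantics: the *best* centroid at or above
threshold, ties to the earlier centroid. Greedy first-fit and global
best-fit are distinct steps in the workflow this package encodes, and we
keep both faithful. A cluster's representative is a consensus: members
are anchored to the most abundant member, each column emits the majority
state (ties alphabetically A<C<G<T, strict gap majority deletes the
column), and insertions present in more than half the members are kept.

### Lineage profiles and dominance

For each OTU, a member-ASV × sample count profile is built, and samples
with fewer than 20 reads assigned to that OTU are excluded from all
further analysis of that lineage — the floor is applied per lineage, so a
sample can pass for one lineage and fail for another. "Dominant"
lineages are those detected (≥ 1 read, counted *before* the 20-read
floor) in at least 9 samples and holding at least 301 reads — the
literal reading of "more than eight samples" and "more than 300 reads";
both knobs are configurable. Dominance statistics are per-sample top-k
(k = 1, 2, 3) read proportions after sorting member counts, averaged
over *included* samples only; whether sparse samples should enter these
averages is genuinely ambiguous, and the included-samples rule is the
assumption we fixed (it is also the only one consistent with the floor's
stated purpose).

### Phylogeography

Per dominant lineage, pairwise Bray–Curtis dissimilarity
(1 − 2Σmin(a,b)/(Σa+Σb)) of ASV composition is computed among included
samples, by default on within-lineage *proportions* — in which case it
equals half the L1 distance between composition vectors. Proportions
guard against the strongly uneven per-sample depths (190–4515 reads in
the conditions we emulate); a raw-count mode is retained for sensitivity
analysis. The per-lineage matrices are averaged entry-wise over the
lineages in which *both* samples are included, with the per-pair count of
contributing lineages recorded as support. Pairs never co-covered are
left missing rather than imputed — the least-assumption choice — and the
clustering step refuses incomplete matrices; `drop_unsupported()`
removes the fewest samples needed to obtain a complete core.

The averaged matrix is clustered with Ward.D2 (`stats::hclust`, the same
implementation practitioners use), i.e. the Lance–Williams update on
squared dissimilarities with square-root heights. Tests verify the merge
heights against an independent naive Lance–Williams implementation to
1e-10. `cut_tree()` extracts k clusters, renumbered in dendrogram
first-leaf order. Trees are written as Newick with the ultrametric
half-height convention (a two-leaf tree merged at height h becomes
`(A:h/2,B:h/2);`), so cophenetic path lengths reproduce merge heights.

### SNP concordance

The validation stage asks whether variants *expected* from ASVs are
*detected* in an independent metagenomic pileup. Expected sites come
from a reference-anchored MSA of all lineage ASVs present in a sample: a
reference column with ≥ 2 states (gap included) among members, with
state proportions weighted by ASV read abundance. Detected sites come
from per-position base counts: a position is variable when at least two
states each pass count ≥ 2 *and* frequency ≥ 1% at depth ≥ 10. No
thresholds are stated for the manual inspection workflow this
formalizes, so these defaults were chosen to suppress singleton
sequencing errors while retaining the rare (< 10%) variants the analysis
is designed to see; all are configurable and recorded in the report.
Sites are classified `both` / `expected_only` / `detected_only` over the
union of the two sets, and base proportions at concordant sites are
compared by total-variation distance. Deletions in the pileup map to the
MSA gap state; ASV insertions relative to the reference have no
reference column and stay in the MSA's insertion records.

SAM input is tallied with Rsamtools using primary, non-duplicate,
non-supplementary reads at mapping quality ≥ 0 by default — the upstream
filters are deliberately configurable because no single convention is
standard before visual inspection.

## The simulator: what it emulates and what it does not

`simulate_community()` generates ground-truthed data with the structure
the analysis assumes. Its defaults *are* the study conditions the
pipeline targets, and tests that scale parameters down say so explicitly:

* 11 lineage templates, pairwise ≥ 8% diverged in 16S (lineage-private
  substitution sets on the bundled reference guarantee the bound);
  random 250–500-nt ITS per lineage; shared 23S fragment.
* 7–101 genotypes per lineage, each 1–6 substitutions from its template,
  80% of them in the ITS, plus a 1-bp ITS indel with probability 0.1 —
  mirroring observed within-lineage variation: a handful of ITS
  positions, occasional 1-bp gaps.
* Three regions (7/3/2 lakes) × two water layers = 24 samples; each
  genotype belongs to one region's pool and prefers one layer.
  A region-level mean mixture per lineage is drawn from a symmetric
  Dirichlet (concentration 0.3 by default: a few genotypes dominate);
  a sample resamples that mean (concentration 10) after tilting towards
  genotypes preferring its layer (non-preferred weight 0.3). Pool-external
  genotypes leak in with probability `dispersal` (default 0.05, 0 =
  strict allopatry). We model layers as an affinity tilt *within* a
  region pool rather than as separate pools: with fully private
  region × layer pools, all between-pool dissimilarities would saturate
  at 1 and a cut at k = number of regions would be arbitrary — under the
  tilt model, region recovery at zero dispersal is exact and testable.
* Per-sample depths drawn log-uniformly over 190–4515, reproducing the
  right-skewed depth spread; counts are multinomial, so column sums equal
  depths exactly.
* Pileups are simulated per reference position: a genotype is drawn from
  the mixture, its state (via the anchored MSA) is emitted, and bases are
  flipped uniformly to another base at `error_rate`.

Deliberate simplifications: a uniform substitution model with no rate
heterogeneity beyond the ITS bias; no chimeras or PCR bias (chimera
removal is upstream); no unlinked rRNA operons (they would be rejected at
partitioning); no read-level (FASTQ) simulation; every simulated genotype
belongs to some lineage, so the dominant lineages can hold ~100% of reads
in small communities, unlike real communities with a rare biosphere.
Passing recovery tests on these data therefore demonstrates correctness
of the algorithms under the stated statistical structure — not robustness
to chimeras, contamination, or taxonomically pathological operons.

## Numerical and design choices

* All external coordinates are 1-based inclusive; intervals are closed.
* Identity fast paths are applied only where the gapless score provably
  attains the affine bound; everything else runs the full DP.
* `hclust`'s and `pairwiseAlignment`'s internal tie-breaks stand in for
  bespoke tie rules; both are deterministic, keeping outputs
  bit-identical across runs, which is the property the bespoke rules were
  meant to secure.
* Matrix TSVs carry 15 significant digits (round-trips are exact to 12
  decimals); TSV writers emit a `# ampdiv <version>` header line. FASTA
  and Newick writers do not: neither format has a comment syntax that
  mainstream readers tolerate.
* Averaging policy (support mask + `min_support`, default 1) is reported
  alongside results rather than silently imputed, because how lineages
  absent from a sample should contribute to an averaged dissimilarity is
  not a settled question.
* The pipeline writes a `manifest.json` (package version, full
  configuration, md5 of every artifact); identical inputs and
  configuration yield byte-identical bundles.

## Problem sizes used in tests and the acceptance script

The test suite exercises every stage at desk scale (3–4 lineages, 4–9
genotypes each, 8–12 samples, depths of a few hundred) so the default run
finishes in well under five minutes, with property checks against
independent oracles: a from-scratch affine-gap recursion for alignment
scores (500 random short pairs), a naive Lance–Williams agglomerator for
Ward.D2 heights (100 random 8×8 matrices, 1e-10), closed forms for
Bray–Curtis, and ground-truth recovery (adjusted Rand index 1) for
clustering and phylogeography. `scripts/acceptance.R` runs the full
default study conditions (11 lineages, 7–101 genotypes, 24 samples,
depths 190–4515) end to end and reports only quantities it computes at
run time.

## Known limitations

* Greedy clustering outcomes near the 97% boundary depend on processing
  order and identity semantics; counts of clusters on real data are
  sensitive to these choices, which is why they are pinned down and
  documented here.
* The synthetic references make region boundaries exact by construction;
  real-data boundaries inherit whatever reference the user supplies.
* The SNP stage validates variant *sites* and proportions; it does not
  phase haplotypes across sites.
* No ordination, PERMANOVA, distance–decay regression, rarefaction or
  figure rendering: the package produces the matrices, trees and tables
  those analyses would consume.
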