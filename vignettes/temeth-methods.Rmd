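---
title: "Methods: TE-family expression and context-specific methylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE-family expression and context-specific methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temeth)
```

## The problem

Maize mutants of the chromomethylase (CMT) genes *Zmet2*/*Zmet5* and of the
RNA-directed DNA methylation (RdDM) components *Mop1*/*Mop3* cause partial,
context-specific losses of DNA methylation — CHG for CMT, CHH for RdDM — while
leaving plants viable. The analytical question is which genes and transposable
element (TE) families change expression when this methylation is perturbed,
and whether those changes track methylation at specific sequence contexts.
Answering it requires a set of bespoke computations that standard RNA-seq
tooling does not provide: a disjoint TE annotation in which every base has a
single owner, hierarchical assignment of multi-mapping reads to TE *families*
rather than elements, a shared reads-per-million scale over genes plus
families, tile-based methylation summaries with strict published gates for
differentially methylated regions (DMRs) and mCHH islands, and the
association logic connecting the two data types. `temeth` implements that
pipeline as composable tibble-in/tibble-out functions, together with a
synthetic-data generator whose planted ground truth makes every stage
testable without any sequencing download.

## Annotation resolution

TE annotations are nested and overlapping; counting requires that each
genomic base belong to exactly one feature. `resolve_te_annotation()` applies
three steps:

1. **Helitron removal.** Helitrons capture gene fragments, which makes read
   assignment to them unreliable; they are dropped before any counting (but
   kept out of counting only — the generator still places them so the filter
   is exercised).
2. **Overlap resolution.** Every base covered by at least one element is
   assigned to exactly one. Contested bases go to the *shorter* element, with
   exact ties broken lexicographically by element id. The rationale is
   biological: a nested element is a younger insertion that interrupted the
   older, longer copy, so the DNA at that position is the nested element's.
   The rule is deterministic and testable; the union of output bases always
   equals the union of input bases. How the original annotation resolution
   ordered contested bases is not documented anywhere we could verify, so
   this package states its own rule rather than guessing another tool's.
3. **Exon masking.** Gene exons are subtracted from TE-owned intervals, so no
   TE base overlaps any exon. Elements that lose every base remain in the
   family index flagged `fully_masked`, keeping family-size statistics stable.

Coordinates are 0-based half-open internally; GFF3 and SAM conversion happens
only at the I/O boundary.

## Read assignment and counting

Records are merged mate pairs (fragments), with up to 20 reported hits.
Improperly paired records and records with more than 20 hits are dropped. A
record is *unique* if it has one hit (or, for real aligner output, MAPQ >= 50,
mirroring a `samtools -q 50` filter).

- Unique records overlapping exons of exactly one gene count for that gene
  (union mode); exons of two or more genes make the record ambiguous and it
  counts nowhere.
- Unique records overlapping TE-owned bases (and no exon) count for that
  element, and hence its family.
- Multi-mapped records whose TE-overlapping hits all fall in a single family
  count for that family; hits in two or more families are discarded as
  ambiguous.
- Any record with at least one hit overlapping a gene exon is excluded from
  TE counting (`gene_te_conflict`). This is the package's reading of the rule
  that reads mapping to both gene and TE annotation are excluded from TE
  analysis: it prevents gene transcription from being scored as TE
  expression. The behaviour is localized in `assign_te_reads()` if a
  different reading is wanted.
- Counting is unstranded; overlap means at least one shared base.

Family counts are unique plus multi reads; RPM divides by the per-library
total of gene plus family reads (so each library's RPM column sums to 10^6),
and a feature is *expressed* when RPM exceeds 1 in at least three libraries.

## The differential expression engine

The published analysis used a full shrinkage-based NB framework; replicating
that machinery numerically is explicitly out of scope here, and the
scientific content this package targets is the thresholds and consistency
logic applied on top. The engine is therefore a deliberately small NB Wald
test:

- **Size factors**: median-of-ratios over features with positive counts in
  every library.
- **Dispersion**: per-feature pooled within-group method of moments,
  `alpha = (s^2 - mu) / mu^2` with variance `mu + alpha mu^2`. With three
  replicates per side this estimate has four degrees of freedom, so raw
  values are extremely noisy in both directions. Each estimate is floored at
  the across-feature median (and at 1e-8) and capped at twice that median.
  The floor prevents spuriously small dispersions from inflating
  significance; the cap prevents spuriously large ones from destroying power
  for individual features. Both bounds are robust across-feature statistics,
  so no single feature influences them appreciably.
- **Fold change**: `log2((mutant mean + 0.5) / (control mean + 0.5))` on
  normalized counts — raw, not shrunken; the published fold-change cutoff is
  taken to apply to raw estimates.
- **Test**: two-sided Wald against a normal reference;
  Benjamini–Hochberg FDR.

The acceptance suite verifies on a 2,000-feature synthetic null (3 vs 3) that
the raw p < 0.05 fraction stays within [0.03, 0.07], and that planted
|log2FC| = 2 features at means >= 100 are recovered by the consistency rule in
more than 90% of cases with below 1% false consistent calls.

Calls use strict gates: `up` iff FDR < 0.05 and log2FC > 1. Consistency
requires the same direction in at least two contrasts of the same pathway
(CMT or RdDM); opposite directions never merge. For mutations introgressed
from another background, DE genes whose midpoint lies within 40 Mb of the
declared mutation locus on the same chromosome are reset to `ns` — linked
cis-regulatory variation, not methylation response. TE families are exempt
from this filter because a family is not point-localized. Contrasts without a
declared locus (uncharacterized backgrounds) skip the filter with a warning.

## Methylation tiles, DMRs and mCHH islands

Per-cytosine calls are summarized per 100-bp non-overlapping tile and context
(CG/CHG/CHH). Each called cytosine is its own site — symmetric CG/CHG
positions are *not* collapsed across strands, matching methratio-style
caller output — and the tile level is read-weighted:
`sum(mc) / sum(total)`, not the mean of per-site ratios. The final partial
tile of a chromosome is retained.

DMR gates between two genotypes, all strict, in both genotypes:

| gate | CG/CHG | CHH |
|---|---|---|
| sites per tile | > 6 | > 6 |
| coverage | mean reads/site > 2 | same |
| level | difference > 60 points | < 5% in one and > 25% in the other |

"2X coverage" is interpreted as mean reads per covered site within the tile
(the per-tile mean is the common convention in tiling analyses; a strictly
per-site requirement would discard tiles for one shallow site). For CHH DMRs
the coverage and site gates are required in *both* genotypes — requiring them
in only one would let an uncovered genotype pass on noise. An mCHH island is
a tile with CHH level strictly above 25% and at least 10 informative reads,
where informative reads are the total reads over the tile's CHH sites.
Panel-wide DMRs are the union of reference-vs-genotype pairwise calls,
deduplicated by (tile, context) and tagged with the supporting pairs.

## Association analyses

- **Metaprofiles** collect per-context levels in 100-bp bins spanning 2 kb on
  each side of the TSS and TTS, oriented in the direction of transcription
  (minus-strand profiles flipped). Gene bodies are kept in absolute
  coordinates rather than rescaled to a fixed bin count; short genes simply
  contribute to fewer informative bins. Bin values weight each overlapping
  tile's reads by its overlap fraction.
- **TSS methylation class** is the read-weighted level over the first 400 bp
  downstream of the TSS: high > 50%, low < 20%, `no_data` when uncovered.
- **Island proximity**: a feature is island-associated iff an island tile
  intersects the feature span extended symmetrically by 2 kb.
- **DMR near TSS**: per context, any DMR tile intersecting the half-open
  window [TSS − 200, TSS + 200); for minus-strand genes the TSS is the
  annotation end.
- **Enrichment**: 2x2 chi-squared without continuity correction (the
  intended use has large counts); `enriched` additionally requires the set
  proportion to exceed the background (a significant depletion is not
  enrichment). Zero expected cells raise an error pointing at exact tests.
- **Epiallele correlation**: per gene, Pearson correlation between
  methylation at the promoter DMR and expression across panel genotypes,
  significant at p < 0.05; fewer than 4 genotypes or zero variance yield an
  undefined, never-significant result.

## TE family characterization

Family summaries report member counts and size classes (single = 1,
small = 2–9, medium = 10–99, large >= 100), mean LTR similarity (an
insertion-age proxy: younger elements have more similar LTRs; taken from the
annotation, not recomputed by alignment), mean GC content, and mean distance
to the nearest gene (0 when overlapping). Attribute shifts of a family subset
against the genome-wide distribution use Welch's t-test at p < 0.01.

Expression-pattern classification follows the published testability rule: a
family qualifies only with fewer than 10 members and at least 50% of its
reads uniquely assignable to elements. Among testable families, the pattern
is `locus_specific` when one element holds at least 90% of the unique reads
and `coordinate` otherwise. The 90% dominance threshold is this package's
quantification of "a single expressed member" — the original account shows
single-element dominance without stating a number — and is exposed as a
parameter.

## The synthetic data generator

The generator is first-class, tested code; every downstream stage is
validated against its planted truth. It emulates:

- a multi-chromosome toy genome (default 2 x 150 kb) with non-overlapping
  gene models (1–3 exons) and multi-copy TE families carrying the full
  element → family → superfamily → class hierarchy, including helitrons, at
  least one cross-family nested insertion, and at least one TE overlapping an
  exon;
- **multi-mapping by exact duplication**: all copies of a family share one
  length, and an interior read reports one equally-scored hit per copy. This
  tests the assignment logic — the analytical contribution — without
  simulating an aligner. Interior reads are drawn only at offsets that are
  clean in *every* copy (inside the element, clear of other elements and
  exons), which guarantees that truth-label counts and assignment counts must
  agree exactly; deliberate ambiguous reads are planted across nested-element
  boundaries to exercise the discard path;
- **junction reads**: a configurable fraction (default 0.6) of TE reads
  straddle one copy's element/flank boundary and therefore report a single
  hit — the way element-level evidence arises in real data. Families
  alternate between a locus-specific regime (all junction reads from one
  donor copy) and a coordinate regime (spread over copies). The default
  fraction is chosen so that family-level unique-read fractions clear the 50%
  testability gate, emulating the testable families of the original study;
- NB-distributed counts with variance `mu + alpha mu^2` (default
  `alpha = 0.1`, standard for RNA-seq biological replicates), log-normal
  baseline means, and planted fold changes of 2^2 shared across contrasts,
  with three libraries per genotype as in the study design;
- per-cytosine methylation with maize-like context backgrounds (CG 0.80,
  CHG 0.65, CHH 0.02), site positions drawn once per genome and shared across
  genotypes, binomial methylated-read draws, and planted DMR/island tiles
  given enough sites and coverage to clear the calling gates — whether a
  planted tile is *called* still depends on its realized draws;
- a diversity-panel generator planting the epiallele pattern: bimodal
  methylation across genotypes with expression silenced on the methylated
  side, next to null genes with identical methylation structure but
  independent expression.

It does **not** emulate sequence-level realism: no read sequences, no
sequencing error, no bisulfite conversion chemistry, no mappability
structure, no strand-specific library artefacts, and copy divergence within
families is represented only through junction reads. Passing tests therefore
demonstrate the correctness of the assignment, calling and association
*logic* under the stated statistical models, not robustness to alignment
artefacts in real data.

## Numerical choices and degenerate inputs

- All published thresholds are strict inequalities, applied exactly as
  quoted (RPM > 1, log2FC > 1, FDR < 0.05, > 6 sites, > 2x coverage,
  > 60 points, < 5% / > 25%, > 25% with >= 10 reads).
- Ties in overlap resolution break lexicographically; the dominant element of
  a unique read spanning two same-family intervals is the one with the larger
  overlap.
- All-zero features get log2FC 0 and p 1; zero-variance correlation inputs
  are flagged undefined; zero library denominators and empty gene sets raise
  errors rather than propagating NaN.
- Every generator is a deterministic function of its seed; the pipeline
  manifest records parameters, seed and output checksums, and reruns are
  byte-identical.

## Validation problem sizes

The test and acceptance suites run at desk scale, chosen to keep the full
suite under a few minutes while leaving no stage untested: ten 50,000-read
assignment datasets; 1-Mb chromosomes for the per-base bitmap oracle of the
annotation resolver; a 2,000-feature null and a 600-feature planted-DE panel
for the engine; two-genotype methylomes over 2 x 150 kb; and a 600-gene,
10-genotype epiallele panel. The paper-scale headline counts (hundreds of
consistent DE genes, >200,000 DMRs) depend on the full maize genome and SRA
libraries and are not reproducible at this scale; the validation targets are
the properties above, not those counts.

## Known limitations

- The NB engine is intentionally simpler than shrinkage-based packages; on
  real data with strong mean-dispersion trends its moderation by a single
  across-feature median is cruder than a fitted trend.
- Exon-masked counting ignores strand; strand-specific protocols lose a
  little specificity for antisense TE transcription.
- The gene/TE conflict rule discards reads a fractional-assignment method
  would partially use; this matches the original discard-based design.
- `load_annotations()` expects the family/superfamily hierarchy as GFF3
  attributes; annotations carrying it elsewhere need a small adapter.
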