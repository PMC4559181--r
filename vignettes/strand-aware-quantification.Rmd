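---
title: "Strand-aware gene quantification: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-aware gene quantification: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandlap)
```

This vignette is the package's account of its methods: the quantities it
computes and their exact definitions, the counting model and its
parameters, what the simulator does and does not emulate, and the design
decisions taken where more than one reasonable choice existed.

## Gene models and coordinates

A gene model is the union of its exons over all transcripts. All overlap
arithmetic runs on the *flattened* exons: the merged, sorted, disjoint
interval set covering exactly the gene's exonic bases. Two conventions
matter:

* **Coordinates are 1-based closed** throughout, the native convention of
  `IRanges`/`GenomicRanges` and of GTF itself. Delegating interval
  arithmetic to `IRanges` removes every off-by-one opportunity, and GTF
  input needs no coordinate conversion at either boundary.
* **Adjacent exons merge.** In closed coordinates, `[a, b]` and
  `[b + 1, c]` cover contiguous bases; flattening merges them because every
  downstream quantity (exonic length, overlap bases, read overlap) is
  defined on base coverage, not on interval identity.

The GTF reader builds genes from `exon` feature lines only; `gene` and
`transcript` lines carry no extra information for this purpose. Records
with `end < start` or an unrecognized strand symbol are rejected
individually (counted in the parse metadata) rather than failing the file;
a structurally broken line — wrong number of tab-separated fields — is an
error naming the line. Genes whose exons span several chromosomes (rare
annotation artifacts) are excluded with a warning. `.` strands are kept as
unstranded genes: they are counted in gene totals but can never be a
member of a same- or opposite-strand pair, since their relation to any
partner is undefined.

## The overlap atlas

For genes $i, j$ on one chromosome with flattened exon base sets $E_i,
E_j$, the pair is *overlapping* when $|E_i \cap E_j| \ge 1$. Three
summaries are computed, each split by strand relation (same vs opposite):

* **Gene level** — the fraction of genes participating in at least one
  overlapping pair of the relation. Both members of a pair count.
* **Nucleotide level** — on *strand-specific bases*: the denominator is
  $|U_+| + |U_-|$, where $U_s$ is the union of flattened exons of strand
  $s$; a genomic base exonic on both strands contributes twice, once per
  strand. The same-strand numerator counts strand-bases covered by two or
  more genes of that strand. The opposite-strand numerator counts bases in
  $U_+ \cap U_-$ once per strand (doubled): this makes the percentage read
  as "the fraction of transcribed strand-bases that face an antisense
  partner", which is the quantity a read-ambiguity comparison needs,
  since a fragment from either strand of such a base is ambiguous under
  unstranded counting. `count_once = TRUE` switches to counting each
  genomic base once, for sensitivity analysis.
* **Pair level** — the overlap ratio $r_{ij} = |E_i \cap E_j| / \min(|E_i|,
  |E_j|)$, with $r = 1$ exactly when the shorter gene's exonic bases are a
  subset of the partner's. Histograms use 20 equal-width right-closed bins
  on $[0, 1]$ by default (a display choice; configurable); medians use
  linear interpolation (type-7 quantiles). *Containment* counts distinct
  genes that are the shorter member of at least one ratio-1 pair; a gene
  contained in several hosts counts once, and when both members of a
  ratio-1 pair have equal exonic lengths (identical base sets), both
  count.

Overlap detection uses flattened **exon** overlap, not gene-span overlap:
two genes whose introns interleave but whose exons never share a base
produce no read ambiguity in exon-level counting, so span overlap would
overstate the phenomenon of interest. All atlas statistics are verified in
the test suite against a per-base boolean-array brute force on random
annotations.

## The counting model

A paired-end fragment is assigned by these rules, in order:

1. **Filters.** Not uniquely mapped, missing a mapped mate (when
   `require_both_ends`), or chimeric (mates on different chromosomes, when
   `discard_chimeric`) → *filtered*. From SAM input, "uniquely mapped"
   means a primary alignment with MAPQ ≥ 50 for both mates — a threshold
   that accepts the 255 convention some spliced aligners use for unique
   mappers and rejects their multi-mapper values; it is configurable
   because uniqueness is ultimately the aligner's notion.
2. **Candidates.** A gene is a candidate when the fragment's exonic
   overlap reaches `min_overlap_bases` (default 60). Overlap is summed
   over the two mates against the gene's flattened exons; a genomic base
   covered by both mates counts once per mate. Mates are represented by
   their per-exon genomic blocks, so intronic bases of a junction-spanning
   mate never count. A `per_mate` mode (any single mate reaching the
   threshold) is available because paired-end minimum-overlap semantics
   differ between published counters; the summed-mate rule is the default
   as the natural reading of a per-fragment threshold.
3. **Strand rule.** Under `reverse_stranded` (the dUTP convention), a
   candidate must have read 1 aligned **antisense** to the gene. Only
   mate 1 is tested: for a proper pair the mates' strands are opposite, so
   testing mate 2 is redundant. Under `unstranded`, no strand test.
4. **Category.** 0 candidates → *no-feature*; exactly 1 → *assigned*;
   ≥ 2 → *ambiguous* (excluded from counts, with the candidate set kept).

Two structural properties follow and are enforced as tests: the four
categories partition every input (conservation), and the reverse-stranded
ambiguous set is a subset of the unstranded one — the strand test can only
remove candidates, so stranded counting resolves ambiguity and never
creates it.

## Expression comparison

Counts are compared between protocols on a shared gene universe:

* **Units.** CPM $= 10^6 \, c_{gs} / (N_s f_s)$ and RPKM $= 10^9 \,
  c_{gs} / (N_s \ell_g)$ with library size $N_s$, optional normalization
  factor $f_s$ and exonic length $\ell_g$. Log transforms use pseudocount
  0.5.
* **TMM factors** are authored in-package to the standard recipe:
  reference column by 75th-percentile CPM closest to the mean; per sample,
  genes nonzero in both sample and reference are doubly trimmed (30 % each
  tail on M-values, 5 % on A-values) and the factor is 2 to the
  precision-weighted mean M; factors are rescaled to geometric mean 1.
  The test suite cross-checks against an established independent
  implementation to within 2 %.
* **Expressed filter**: keep genes with max CPM strictly greater than 1
  across all samples — strict, so a gene at exactly 1 CPM everywhere is
  dropped.
* **Discordance.** Per-gene log2 fold change is the difference of group
  means of log2(CPM + 0.5) after TMM; significance is a Welch t-test with
  Benjamini–Hochberg adjustment; a gene is *discordant* when |FC| > 1.5
  and adjusted p < 0.05. The moderated empirical-Bayes fits used by
  full-scale differential pipelines are deliberately out of scope — they
  are another package's estimator, not a quantity this package defines —
  so absolute discordant-gene counts here are not comparable to
  moderated-model counts; the Welch substitute is honest about that and is
  validated instead by a planted-effect benchmark (4× effects, 4 vs 4
  replicates, 200 genes: sensitivity ≥ 0.9, false flags ≤ 0.05).
  With fewer than two replicates per group the report degrades to
  fold-change-only mode and says so.
* **Breakdown and tests.** Gene types collapse to seven categories
  (protein_coding, antisense, pseudogene — any biotype containing
  "pseudogene" —, lincRNA, processed_transcript, sense_intronic, other);
  each row crosses discordance with participation in ≥ 1 opposite-strand
  pair, and the four cells sum to the row's expressed-gene total.
  Enrichment uses the base-R two-proportion and 2×2 chi-square tests
  (both with Yates continuity correction); p-values below 2.2e-16 are
  additionally reported with the conventional floor string.

## The simulator

The simulator is the package's instrument for making every claim above
falsifiable without external data.

* **Annotations** are built from locus templates that realize their
  relation *exactly*: a `partial_opposite_strand` locus with overlap
  fraction $f$ produces, by construction, one opposite-strand pair with
  ratio $f$; `nested_*` loci produce ratio-1 containment. Geometry is a
  pure function of the configuration, so identical configurations
  serialize to byte-identical GTF.
* **Fragments.** Source genes are drawn with probability ∝ expression
  weight × exonic length; the fragment is placed uniformly on the gene's
  spliced (flattened-exon) coordinate line; fragment lengths follow a
  normal truncated at the read length below and the gene's exonic length
  above. Read 1 is antisense to the source gene (`stranded_dutp`) or a
  fair coin (`non_stranded`); in genomic coordinates the reverse-strand
  mate sits at the downstream end of the fragment. Mates spanning exon
  junctions are emitted as per-exon blocks. Defaults — 2 × 100 base reads,
  fragment mean 170, SD 40 — describe a short-insert stranded library in
  which about 4 % of fragments fall below the read length before
  truncation; non-stranded libraries of the same material tend to run
  ~30 bases longer, representable by raising `fragment_mean`.
* **Analytic expectations.** `expected_summary()` integrates the
  assignment category over the exact discrete (length × start) space per
  gene, treating each gene's exonic space as one contiguous interval —
  exact for single-exon genes, an approximation for multi-exon ones (the
  Monte-Carlo agreement tests therefore use single-exon configurations).
  This gives the closed-form ambiguous fraction that the empirical
  pipeline must hit within sampling error, and the analytic value of the
  central ordering: stranded ambiguity ≤ non-stranded ambiguity, with the
  difference equal to the opposite-strand ambiguity mass.

**The default study** (`default_study_config()`) fixes the standing
conditions used by the analysis scripts, the acceptance script and the
protocol-ordering tests: 200 genes in 172 loci, with 9 % of genes
overlapping a same-strand partner and 19 % an opposite-strand partner
(the genome-wide gene-level proportions a human annotation shows), partial
overlap fractions of 0.47 (same) and 0.19 (opposite) matching the observed
median overlap ratios, a minority of fully nested loci, a spread of
biotypes across the disjoint loci, and 4 + 4 replicate samples of 10,000
fragments. On these conditions stranded counting shows ≈ 2.9 % ambiguity
versus ≈ 6.7 % non-stranded — the same direction and similar magnitude to
what genome-scale data shows — and the discordant genes are dominated by
antisense genes in opposite-strand overlaps. Problem sizes (200 genes,
10,000 fragments per sample, 100-annotation oracle sweeps) were chosen as
the smallest at which the binomial error bars are comfortably inside the
tested margins.

### What the simulator does not emulate

No sequence content (and hence no mapping error or mismatches), no
pseudogene sequence similarity — simulated "pseudogenes" are ordinary
disjoint loci with a pseudogene label, so the read-level mapping
uncertainty that makes real pseudogene quantification hard is absent —
no coverage non-uniformity, GC or polyA-selection bias, no adapter
contamination, and no biological variance between replicates (samples are
true technical replicates of the same abundance vector). Passing tests
therefore demonstrate the correctness of the interval arithmetic, the
counting semantics and the statistical machinery under the stated model,
not robustness to alignment artifacts.

## Numerical and degenerate-input choices

* Ratio histograms: right-closed bins, `include.lowest`; medians and
  percentiles by linear interpolation.
* Welch test with zero variance in both groups: p = 1 when the means are
  equal, 0 otherwise.
* TMM: proportional columns short-circuit to factor 1 (all M-values are
  zero); a sample sharing no nonzero gene with the reference gets
  factor 1; an all-zero column is an error.
* Empty inputs: an empty GTF parses to an empty annotation; an empty
  fragment set counts to an all-zero column with zero totals; an empty
  pair list is an error for `ratio_distribution` ("no pairs") but fine
  everywhere else.
* Unknown chromosomes in queries or fragments are empty results /
  no-feature, never errors.
* A fragment longer than its source gene's exonic length is truncated to
  the gene with a warning, rather than rejected — the analogous physical
  fragment would still be sequenced.

## Known limitations

Genome-scale annotation statistics depend on dialect details (patch
scaffolds, biotype filters) that are not part of any formal definition;
the atlas therefore exposes `feature_filter` and a primary-chromosome
restriction in the genome-scale driver rather than hard-coding a policy.
The exact denominator convention for nucleotide-level overlap is likewise
stated explicitly above and kept toggleable, since published figures of
this kind rarely print their denominator. SAM ingest assumes a
well-formed, name-consistent pairing produced by a modern aligner; exotic
flag combinations (supplementary-only pairs, secondary-primary mixtures)
are excluded rather than repaired.
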