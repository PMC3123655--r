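---
title: "Identifying miRNA loci under long-range developmental regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying miRNA loci under long-range developmental regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Key developmental transcription factors sit inside *genomic regulatory
blocks* (GRBs): synteny-preserved regions where arrays of highly conserved
non-coding elements (HCNEs) act as long-range enhancers on a single target
gene. GRB target genes share recognizable genomic hallmarks — a dense local
field of HCNEs, large CpG islands (CGIs) extending into the gene body, and
"bivalent" promoters carrying both H3K4me3 and H3K27me3 in embryonic cell
types. Many microRNAs show the same tightly staged, tissue-specific
expression as these genes, and for the miR-9 family enhancer assays have
shown direct HCNE regulation. `mirgrb` implements a genome-wide screen for
miRNA loci with GRB-target-like regulatory landscapes, together with a
synthetic-genome generator that lets the whole chain be validated against
planted ground truth.

## The analysis chain

**Self-transcribed (ST) miRNAs.** Only miRNAs with their own promoter can be
screened by promoter-linked features. A pre-miRNA is *intragenic* when it
shares at least 1 bp with a protein-coding gene body (host gene = maximal
overlap; ties broken by smallest gene id for determinism). The ST set is:
intergenic miRNAs, plus intragenic miRNAs whose zebrafish ortholog is
intergenic — after the teleost whole-genome duplication such loci survived
without their host, so the host is dispensable for transcription — minus
Pol III-transcribed miRNAs (supplied as an id list, never recomputed from
sequence). Co-stranded ST loci under 10 kb apart (boundary gap, strict `<`)
are merged into clusters sharing one promoter, represented by the 5'-most
member. The 10 kb rule is applied between interval boundaries; clusters
never span strands, since the shared-promoter assumption requires
co-orientation (the source text leaves this open; we treat it as an explicit
assumption).

**Orthology.** Catalogs are compared all-vs-all by exact Smith–Waterman
local alignment under BLASTN-like scoring (match +2, mismatch −3, gap open
5, gap extend 2; both subject strands searched). At miRNA lengths exact DP
is fast and fully reproducible, so no seeded heuristic search is needed.
Precursor hits must align ≥ 56% of the query with ≤ 10 gapped columns;
mature-level fallback hits must align ≥ 80% of the query with ≤ 3
mismatches and an intact seed (query positions 2–8 aligned without mismatch
or gap — applied at the mature level only). Percent thresholds are compared
as integer cross-products (`aligned * 100 >= 56 * len`) so boundary cases
are exact. "Gap size" is interpreted as total gapped columns; the count is
configurable. A pair is reported only when each side is the other's unique
top-scoring passing hit; score ties make a query ambiguous and yield no
pair, so the map is one-to-one by construction.

**Search windows.** Annotated pri-miRNAs place 93% of TSSs within 50 kb
upstream and 90% of transcript ends within 20 kb downstream of the
precursor, so the locus windows default to −50 kb/+20 kb (full, for CGI
counting), −50 kb (promoter-only, for bivalent association), or the
annotated transcript where a model exists. Windows are strand-aware,
clipped at chromosome ends, and truncated by protein-coding gene bodies
± 1 kb; the locus's own host gene never truncates. Truncation removes the
padded gene but keeps remainder segments on both sides — the alternative
(cut at the first gene) is available via `cut_at_first_gene = TRUE` since
the source description is ambiguous; keeping remainders is the default
because exclusion of genes, not of distal sequence, is what the truncation
is for.

**Enhancer density.** Density is the percentage of bases covered by
(merged) HCNEs or p300 peaks in a 300 kb window centered on the anchor:
pre-miRNA midpoint for miRNA loci (the anchor is only specified for genes —
their TSS — so midpoint is our documented, configurable choice), cluster
representative's midpoint for clusters. Windows clipped at chromosome ends
keep the nominal 300 kb denominator so values remain comparable along the
chromosome; the alternative normalization is a flag. p300 peaks can be
filtered to exclude those overlapping HCNEs with identity ≥ 98% and length
≥ 50 bp, which shows enhancer enrichment is not a conservation artifact.

**Matched controls.** Null densities come from random regions that
reproduce the reference set exactly, stratum by stratum: each control
copies its reference locus's length and intergenic/intragenic class
(intergenic = no overlap with a protein-coding gene body; intragenic =
contained in one — synthetic gene models carry no exon structure, so
containment stands in for "intronic") and must fall in the same
gene-density bin (genes overlapping the 300 kb window, binned
{0,1,…,9,≥10}). This is the strongest testable reading of "distributions
equal": length multisets, class counts and binned gene-density histograms
match exactly, per replicate. Rejection sampling is capped per feature and
errors with the offending stratum when a genome cannot satisfy it. The full
analysis uses 10000 non-coding / 200 protein-coding sets; scripts and tests
default to 100, which already pools thousands of control densities.

**Statistics.** Enrichment is tested with a two-sided bootstrapped
Kolmogorov–Smirnov test: `nboot` statistic replicates from pairs of
with-replacement resamples of the pooled data, `p = #{D* ≥ D_obs}/nboot`.
Density samples are heavily tied (many zero-density windows), which
invalidates the classical KS null distribution; the pooled bootstrap is
tie-robust. `p` is reported as `r/nboot` so exact zeros are representable
(the conservative `(r+1)/(nboot+1)` variant is a flag). The enriched/poor
comparison uses `median_split`: ids sorted by density descending, top
⌈n/2⌉ enriched, boundary ties broken by id order — 125 loci split 63/62.
Bivalent association rates are compared with a one-sided Fisher exact test
(upper hypergeometric tail, enrichment direction; the two-sided variant sums
tables no more probable than the observed one). For the published table
(15/63 vs 5/62) the one-sided value is ≈ 0.0145 and the two-sided ≈ 0.026;
the printed 0.03 is consistent only with the latter, so both are exposed
and no guess is made about which was run. CpG-ratio and transcript-length
comparisons use a one-sided Wilcoxon rank-sum test (exact for small
untied samples, normal approximation with continuity correction otherwise).

**Epigenome features.** A locus is bivalent-associated in a cell type iff
any domain of that type overlaps its truncated promoter window by ≥ 1 bp.
For the enriched-vs-poor contingency analysis intragenic loci return NA and
are excluded — their chromatin cannot be attributed to the miRNA rather
than the host gene. At the genome-wide prediction stage, however, flags are
evaluated for *all* ST loci (`intragenic_na = FALSE`): the final target
table includes intronic ST loci with their bivalent cell types, which
matches how the published predictions list intronic cases such as the
miR-9-1-type locus. The CpG-to-gene ratio divides CGI bases overlapping the
transcript (CGIs merged, overlap clipped to the transcript) by transcript
length, so it is bounded by 1; clipping rather than whole-CGI length is
used because observed ratio medians are far below 1. CGI counts in the full
window count each CGI once even when truncation splits the window around
it. CGI features are annotation only — they are never a prediction
criterion, since most loci lack transcript models.

**Prediction.** A cluster is a putative GRB target iff it is
HCNE-enriched in at least one lineage comparison (a stricter quorum is the
`min_lineages` knob; one is the minimum-evidence reading of "across
different lineage comparisons") and bivalent in at least one cell type. A
locus absent from a lineage's split (not conserved there) counts as not
enriched in it. Prediction is monotone in evidence by construction.

## The synthetic genome

`generate_bundle()` draws 4 chromosomes × 30 Mb with 900 non-overlapping
protein-coding genes (2–50 kb) and 140 miRNA loci arranged so that exactly
120 are ST: 119 intergenic − 4 Pol III + 5 intragenic loci with an
intergenic zebrafish ortholog. 20 loci are planted targets; one of them is
the intragenic miR-9-style worked case, which by construction carries
bivalent domains in every cell type (that co-occurrence is part of the
case's definition, not a draw). HCNEs form a Poisson field (15 elements/Mb,
50–300 bp, identity 90–100%) whose intensity is multiplied by
`hcne_target_fold` (default 5) within ±150 kb of planted loci; p300 peaks
are analogous. Planted promoters carry a bivalent domain with probability
0.8 (1–2 cell types among hES/mES) versus 0.1 for background promoters;
additional scattered domains are kept out of promoter zones so the realized
background association rate equals the configured one, and miRNA loci are
spaced ≥ 60 kb apart so one locus's promoter domains cannot leak into
another's 50 kb window. Pri-miRNA models cover 45% of loci with
exponential TSS/TES offsets calibrated so the expected within-50 kb and
within-20 kb fractions are 0.93 and 0.90. Ortholog sequences are derived by
mutating the human ones (8% substitutions, 2% indels; mature seeds
protected), giving the alignment filters true positives and negatives. One
global seed drives independent per-track substreams, so bundles are
byte-identical across runs and adding a track leaves the others unchanged.

What the generator does *not* emulate: nucleotide composition, repeats,
real conservation structure, exon models, or correlated placement of genes
and regulatory elements. Passing tests therefore demonstrate that the
*machinery* — classification, matching, statistics, prediction — is
correct and calibrated, not that the biological conclusions transfer to any
particular genome.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; GFF is converted on read.
  Overlap always means ≥ 1 shared base.
* Bootstrap and sampling seeds are explicit arguments; every stochastic
  result records its seed, and same-seed runs are byte-identical.
* KS bootstrap comparisons use a `1e-12` slack on `D* ≥ D_obs` to absorb
  floating-point noise in the ECDF arithmetic.
* Degenerate inputs: empty element tracks give density 0; windows fully
  erased by truncation are flagged empty rather than erroring; an empty
  control stratum errors with the feature and stratum named.
* Problem sizes in the tests — 100 control replicates, `nboot` 200–1000,
  500 null pairs for calibration, 20 null genomes — were chosen as the
  smallest sizes at which the checked properties are statistically stable.

## Limitations

Orthology here is sequence-only (no synteny); the host-gene call ignores
exon structure; the bivalent-domain model has no peak-level noise; and the
planted-recovery figures (precision/recall ≈ 0.8 at default effect sizes)
are properties of the synthetic conditions, not guarantees on real data.
The real-data results this machinery was built to reproduce depend on
external genome-scale datasets and are out of scope here.
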