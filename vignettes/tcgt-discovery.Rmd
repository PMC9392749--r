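---
title: "Discovering TE-driven chimeric gene transcripts with tcgtscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering TE-driven chimeric gene transcripts with tcgtscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

A transpochimeric gene transcript (TcGT) is an mRNA that initiates inside a
transposable element (TE) and splices into exons of an annotated gene. In
tumors, epigenetic derepression can turn a normally silent TE — typically
the LTR of an endogenous retrovirus — into an active promoter; the
resulting chimera can restore, truncate, extend or frameshift the
downstream gene's protein. `tcgtscan` takes per-sample transcript
assemblies (GTF), a reference gene annotation (GTF with CDS and frames), a
RepeatMasker repeat annotation and a genome FASTA, and produces the
cohort-level catalogue of recurrent tumor-restricted TcGTs with per-gene
occurrence statistics and protein-product classes.

The pipeline is a deterministic rule system, not a statistical model; every
rule is stated below together with the decisions taken where the procedure
was genuinely open.

## Repeat curation

RepeatMasker reports one row per aligned fragment, so a single old
insertion interrupted by later transposition appears as several rows, and
a proviral ERV appears as LTR / internal / LTR pieces. Two curation steps
produce the units against which promoter usage is assessed:

* **Fragment fusion** (`fuseFragments`). Rows on the same chromosome and
  strand with the same repeat name fuse into one unit when they share the
  RepeatMasker linkage ID. Some `.out` exports renumber IDs per chromosome
  or omit them; when the ID column carries no information (absent or
  all-distinct), a positional fallback fuses same-name neighbours separated
  by at most `maxGap` = 10 kb — wide enough to span typical nested-insertion
  interruptions, narrow enough not to bridge unrelated copies. Fusion is
  base-conserving: the unit keeps the original pieces as fragments, and the
  union of fragment bases equals the union of input bases.
* **LTR–internal grouping** (`pairLtrInternal`). A unit whose name ends in
  `-int` (class `LTR/…`) is grouped with same-strand LTR units immediately
  adjacent on either side (gap ≤ 2 kb, no unit of another family in
  between), yielding strand-aware roles `ltr5`/`internal`/`ltr3` under a
  shared ERV group id; unpaired LTRs are `solo`. A user-supplied pairing
  table can override the name-suffix heuristic, since Repbase LTR–internal
  pairings are not universal.

Downstream, promoter overlap is always tested against *fragments*, never
the fused span: the span may contain interior bases that are not repeat
sequence. Roles are recorded but detection treats all curated units
equally; whether solo LTRs behave differently from proviral LTRs is left to
the user's stratification.

## Per-sample detection

For each stranded transcript, in order:

1. **TSS in TE** — the 1-bp 5'-most base must overlap a curated TE fragment
   (either TE strand; an LTR can promote in both orientations). The TSS is
   deliberately a single base, not the whole first exon: the first-exon and
   TSS tests below need distinct anchors.
2. **First exon intergenic** — the first exon must not overlap any
   annotated gene *body* (any strand). Gene bodies rather than exons are
   the default mask because a chimera initiating inside another gene's
   intron is not distinguishable from readthrough at assembly level; the
   alternative (`firstExonMask = "exons"`) is exposed.
3. **Coding target** — some downstream exon must overlap ≥ 1 bp of coding
   exons of a gene on the same strand (a chimeric mRNA must read the
   gene's coding strand). The target is the gene with maximal coding
   overlap; ties break by total gene-body overlap, then lexicographic gene
   id, so output is deterministic.

Failures are tallied per reason (`unstranded`, `tss_not_te`,
`first_exon_in_gene`, `no_coding_target`) and the accounting identity
`n_input = n_calls + sum(discards)` always holds. Unstranded assemblies are
excluded up front because strand concordance with the target is undefined
for them.

**Mono-exonic transcripts** are a deliberate special case: a retrogene's
chimeric transcript can be a single exon that necessarily overlaps the
target gene, so the verbatim first-exon test would always discard it.
Instead, the 5' stretch of the exon up to (but excluding) the first
coding-overlap base must lie outside all gene bodies; such calls are
flagged `monoexonic = TRUE` so they can be separated downstream.

The 1-bp overlap threshold everywhere reflects that no minimum is part of
the procedure; closed 1-based GRanges semantics are used throughout, with
GTF/RepeatMasker/BED conventions converted only at the I/O boundary (the
single-convention rule that prevents off-by-one drift between stages).

## Cohort aggregation and the recurrence filter

Calls of the same gene (same chromosome and strand) whose TSSs are within
100 bp of each other aggregate into one unit. "Within each other" is read
as a pairwise relation, so clustering is its transitive closure —
single-linkage chaining on the sorted TSS positions (`--cluster
fixed-window` behaviour is available as `method = "fixed-window"`).
Aggregate ids are deterministic (`gene@chrom:minTSS`).

Occurrence is the number of *distinct* samples per group contributing at
least one member call (isoforms of one sample count once). An aggregate
passes the recurrence filter when

> tumor fraction > 0.20 **and** normal fraction < 0.10,

both strict ("more than", "less than"): an aggregate at exactly 20 % of
tumors or exactly 10 % of normals fails. The per-gene
summary unions distinct samples across the gene's *passing* aggregates
(`geneUnion = "all"` switches to all aggregates of a passing gene);
percentages are rounded half-up to one decimal, the rule that reproduces
the published percentage columns from their counts (e.g. 186/286 → 65.0,
11/286 → 3.8, 159/286 → 55.6). Group labels beyond tumor/normal (tissues,
cancer types) are carried through counting but do not drive the filter.

## Protein-product classification

There is no single standard rule for calling the ORF of a chimeric
transcript, so this package states its own: the predicted ORF is the
**longest ATG-initiated ORF terminated by an in-frame stop within the
transcript**, ties broken 5'-most, minimum 30 codons (`minOrfCodons`) to
screen spurious micro-ORFs. An ORF without a stop codon inside the
transcript does not count.

Classification compares the predicted ORF's *genomic* CDS segments and
codon frames with the canonical CDS — not protein strings — so isoforms
sharing residues by coincidence are not mislabelled. With frames agreeing
over the shared bases:

| start vs canonical | stop vs canonical | class |
|---|---|---|
| equal | equal | `canonical` (exact segment identity) |
| upstream | equal | `N-ext` |
| downstream | equal | `N-trunc` |
| equal | downstream | `C-ext` |
| equal | upstream | `C-trunc` |
| downstream | upstream | `N-C-trunc` |

When at least half of the genomically shared bases are read in a different
frame the call is `out-of-frame` (the 50 % threshold is a deterministic
tie-break for partial frameshifts caused by alternative splicing); no ORF,
or an ORF with zero genomic overlap with the canonical CDS, is
`non-coding`. Two corners the table does not cover are resolved
deterministically and documented here: frame-preserving mixed combinations
(extended at one end, truncated at the other) take the N-side label, and an
anchors-equal ORF whose interior splice differs from the canonical CDS
falls to `N-C-trunc`. For the extension/truncation classes,
protein-string containment is asserted as a secondary check and a warning
is raised if it fails. A gene table cell can show several classes; these
come from different member transcripts of one gene and are reported as a
set, never merged.

## The synthetic cohort generator

`generateReference`/`generateCohort` build a fully self-contained test
world: a 200 kb single-contig genome carrying six 3-exon protein-coding
genes (90-codon CDS), a mono-exonic retrogene, a gene-desert LTR66 with
downstream AluSx1/LTR33/L2b/MLT1F1 copies, a fragmented LTR12C (two
RepeatMasker rows sharing a linkage ID), an LTR43–LTR43-int–LTR43 provirus
and Alu copies used by the decoys. Three event templates are planted at
design-controlled prevalences with TSS jitter:

* **E1** — LTR66 → Alu/LTR33/L2b/MLT1F1 → retrogene, product `canonical`
  (tumor prevalence 0.40, normal 0.00);
* **E2** — proviral 5' LTR → gene G1 from an internal in-frame ATG,
  product `N-trunc` (0.25 / 0.05);
* **E3** — Alu copy → gene G3 with a +1 frameshift, product `out-of-frame`
  (0.10 / 0.00 — deliberately below the 20 % threshold).

These default prevalences, the 50 tumor / 50 normal cohort size and the
200 kb genome are the generator's fixed study conditions. Every sample also
carries the canonical transcripts of all genes and three decoys mirroring
the discard reasons one-to-one (TSS one base outside a TE; TSS inside an
intronic TE so the first exon sits in a gene body; TE start with no coding
target), which makes the per-sample discard tallies exactly predictable.

Two idealisations matter for interpreting green tests. First, the genome
background alphabet is {A, C, G}: outside planted signals there is no T,
hence no ATG and no stop codon, and each event's ORF — and product truth —
is exact by construction. Second, prevalences are realized as recorded
Bernoulli draws and all expectations (counts, aggregate structure, the
gene table) are computed from the *realized* draws, which removes sampling
noise from stage comparisons. Real data differ in every way that matters:
assembly noise, ambiguous TSSs, overlapping annotation, repeat-driven
multi-mapping upstream of assembly. Passing the synthetic suite therefore
demonstrates that the rule system is implemented exactly as specified, not
that the rules are robust to noisy assemblies.

TSS jitter is uniform on `[0, jitter]` (or two-point `{0, jitter}` when
`bimodal`), letting tests exercise the 100-bp clustering: jitter ≤ 100
yields one aggregate per event, a forced bimodal 300-bp jitter yields two.
Each template documents the maximum jitter its geometry supports and the
design constructor enforces it.

`endToEndCheck` stages everything through files (FASTA, GTF, `.out`, TSV),
so the format round trips are part of the check, then diffs every stage
against ground truth; the expectation on any generated cohort is zero
false positives and zero false negatives at every stage.

## Numerical and degenerate-input choices

* Coordinates: GRanges (1-based, closed) everywhere inside; conversions
  only at I/O.
* Rounding: half-up at one decimal for percentage columns (`roundHalfUp`),
  because banker's rounding does not reproduce printed cohort tables.
* Ties: target gene by (coding overlap, gene-body overlap, gene id); TSS
  TE unit by lowest unit id; ORF by (length, 5' position). All outputs are
  byte-deterministic for identical inputs.
* Degenerate inputs: empty call sets propagate as header-only TSVs and
  empty tables; an empty curated TE set or gene annotation at detection is
  an error (a missed curation step, not a valid state); genes without CDS
  classify as `non-coding` with a warning; negative gaps/windows and
  out-of-range fractions are parameter errors.
* When a gene annotation holds several transcripts per gene, the canonical
  CDS is the transcript with the longest total CDS.

## Problem sizes used by the test suite

The packaged suite runs the oracle-equivalence checks at 200 transcripts
(detection), 100 TSSs (clustering) and 10 kb (ORF enumeration), and the
end-to-end planted-recovery check on the default 50/50 cohort; these sizes
were chosen as the smallest at which every code path (ties, chaining,
multi-aggregate genes, all discard reasons) is exercised.

## Known limitations

* Detection consumes assemblies; events lost upstream (alignment,
  assembly, expression thresholds) are invisible to it.
* The "annotated gene" mask is exactly the supplied annotation; including
  or excluding lncRNA genes changes the first-exon discard and is the
  user's choice of input.
* The ORF rule is a convention (longest ATG-initiated); transcripts using
  non-AUG starts or leaky scanning are outside its scope.
* No expression quantification, survival modelling or subtype
  stratification is performed here; the output table is the input to such
  analyses.
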