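---
title: "Measuring micro-divergence between clonal genome assemblies"
author: "clonediv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring micro-divergence between clonal genome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonediv)
```

## The problem

A haploid, asexually propagating microorganism kept in laboratory
culture for years accumulates a small number of mutations — often just
a handful of SNVs and short indels across tens of megabases.  Detecting
them by comparing whole-genome assemblies of serial isolates is
conceptually trivial and practically treacherous: the assemblies are
built with different technologies, so the *technical* differences
(homopolymer-length miscalls from long reads, undetermined `N`
stretches, collapsed repeats) outnumber the *biological* ones by an
order of magnitude.  Standard variant callers, which expect reads
rather than assemblies and have no model for assembly-specific error,
are of little help.

`clonediv` implements an assembly-vs-assembly workflow for a trio of
serial isolates A → B → C, where B is the best-curated genome and
carries the gene annotation:

1. **polish** — close `N` gaps in a draft using the flanking-consensus
   of two relative assemblies;
2. **divergence** — genome-wide identity metrics that separate
   substitution signal from indel and homopolymer noise;
3. **genes** — a per-gene mutation-calling funnel that classifies,
   filters, and polarizes coding mutations;
4. **simulate** — a synthetic trio generator with exact ground truth,
   so every stage is testable without any external data.

## Divergence metrics

For a pair of assemblies the package aligns each shared chromosome with
unique k-mer anchors (k = 15 by default, unique in *both* genomes),
chains them collinearly, and closes the inter-anchor regions with a
banded Needleman–Wunsch–Gotoh alignment (match +1, mismatch −1, gap of
length $L$ costing $2 + L$).  Two summary statistics are computed over
the retained blocks:

* **gap-excluded identity** $= m / (m + x)$, where $m$ and $x$ are
  match and mismatch columns among gap-free (and optionally N-free)
  columns — an estimate of the substitution load that ignores indels
  entirely;
* **gap-compressed divergence** $= (x + g) / (m + x + g)$, where $g$
  is the number of *maximal indel runs*: an indel of any size counts
  once.  This is always at least as large as the gap-excluded rate.

Both are also reported per Mb of their own denominator.  Because
homopolymer run-length errors dominate comparisons involving long-read
assemblies, both metrics can be recomputed after deleting every run of
five or more identical bases from *both* genomes and re-aligning
(`strip_homopolymers()`).  Deleting a run can fuse its neighbours into
a new qualifying run, so deletion iterates to a fixed point; the output
provably contains no run of `min_run` identical bases.  A block-length
filter (default 1 Mb, as appropriate for chromosome-scale comparisons;
reduce it for small test genomes) limits the confounding effect of
repeated sequence.

`expected_change_count(rate, size_mb, fraction)` converts a per-Mb
rate into an expected change count for a genome compartment — e.g.
at 5 changes/Mb on a 31.14 Mb genome, introns at 5% of the genome are
expected to carry ~8 changes and exons at 40% about 62, below 70.
`divergence_spacing(pct)` converts a percent divergence into bases per
difference (0.002% ↔ one per 50 kb).

## Gap polishing by flanking consensus

`polish_assembly()` reproduces a conservative manual workflow: for
every maximal `N` run in the draft, the 1,000 bases on each side are
located in both relative assemblies (≥95% identity over the full
flank, mismatch-only matching, flank Ns as wildcards; a second hit
scoring within 5% of the best marks the flank ambiguous).  The
sequence between the placed flanks is then compared between relatives:

| relatives' inter-flank sequence | verdict |
|---|---|
| identical | `fill_identical` — copy it in |
| equal length, ≤10 differing positions | `fill_consensus` — copy with `N` at each disagreement |
| equal length, >10 differences | `skip_too_ambiguous` |
| different lengths | `skip_length_mismatch` — never arbitrate |
| flanks overlap in both relatives | `trim_overlap` — delete the duplicated draft span (smaller overlap; conservative) |

Disagreeing consensus positions always become `N`; a relative's base is
never chosen arbitrarily.  Gaps at chromosome ends (single flank) are
never filled.  Edits are applied right-to-left per chromosome, so
non-N draft bases are never touched outside trim spans, and the report
(bases added/removed, fills, trims, skips by reason, remaining Ns) is
recomputed from the emitted assembly.

## The gene funnel

Gene models live on the middle strain B.  `sequential_map()` walks the
genes in chromosome order and places each locus in strains A and C
inside a sliding synteny window (default 500 kb) that starts at the
previous gene's placement; a gene missing from its window is sought on
the whole chromosome before being reported unplaced, and a
non-monotonic placement clears `synteny_ok`.  Placement reuses the
k-mer-anchored aligner with free target end-gaps, so each gene yields a
gapped locus-to-locus alignment directly.

Candidate genes (any difference to A or C) then flow through the
funnel, in this order:

1. genes identical in all three strains are set aside;
2. genes that are unplaced or contain `N` in any strain are removed;
3. genes whose differences are all intronic are removed (splice-site
   dinucleotide changes count as exonic);
4. genes whose exonic differences are all synonymous are removed;
5. genes whose remaining differences are all homopolymer-length
   artifacts are removed;
6. the rest are confirmed.

The stage counts telescope (`funnel_report()` enforces this), and the
derived percentages are *truncated* to one decimal — with 8,701 genes
and 456 candidates the identical share is 94.759…%, reported as 94.7%,
which matches the printed convention of the study this workflow
follows.

Each difference site is polarized by the three-allele logic table
(`polarize_mutation()`): a = b ≠ c places the mutation on the B→C
interval, a ≠ b = c on A→B, a = c ≠ b is a conflict (possible
reversion, or independent artifacts in A and C).  Effects are
classified by re-translating the ancestral and derived CDS —
synonymous, missense, nonsense, frameshift, in-frame indel — with
protein changes rendered as `Ser(AGC) 347 Thr(ACC)`, `Premature stop`,
or `Restores reading frame` (a frameshifting deletion whose *loss*
rescues a truncated frame, as when a tandem duplication reverts).

The homopolymer screen (`flag_homopolymer_artifact()`) flags an indel
whose bases extend or shrink a run of ≥5 identical bases in the
*pre-mutation* context (so an insertion turning a 4-run into a 5-run is
not flagged), and a substitution that creates or extends such a run at
its boundary.  Inside the funnel the screen is applied against the
curated reference context for both non-reference alleles: the two
derived assemblies are perturbed independently, and when both carry
different length errors in the same run, the resulting three-allele
conflict would otherwise slip past an ancestral-context check.

Optional short-read support (`kmer_support()`) counts exact
occurrences, on both strands, of the k-mers (default k = 31) spanning
the site in the reference- and alternate-allele contexts; an allele is
considered present when its best spanning k-mer reaches `min_count`
(default 3).  Verdicts are `supported`, `refuted`, `mixed` (both
alleles present — population heterogeneity), or `untested`.  Verdicts
annotate the output but do not move genes between funnel stages.

## The synthetic world

`generate_ancestor()` builds a haploid genome whose annotated fractions
match a compact fungal genome: 40% exonic and 5% intronic sequence by
construction, genes fully coding (ATG … stop, no internal stop), introns
bounded by GT…AG, strands random, homopolymer tracts (5–10 bp) embedded
in intergenic sequence at a configurable per-kb rate and in ~40% of
introns.  `plant_variants()` derives strain B from A and C from B —
mirroring serial culture, so every variant has a well-defined
appearance interval by construction — and verifies each coding plant's
class label by re-translation at planting time.  Planted sites are kept
≥50 bp apart, away from splice dinucleotides, and outside homopolymer
context, so that ground truth is unambiguous: recovered alignments are
then essentially unique and precision/recall can be required to be
exactly 1.  `inject_artifacts()` perturbs the *observed* copies of A
and C with ±1/±2 length errors restricted to runs ≥5 and with `N`-gap
stretches, emulating long-read assembly defects while the clean
assemblies remain as truth.

What the generator deliberately does **not** emulate: repeats and
transposons (the real motivation for the 1 Mb block filter), collapsed
segmental duplications, GC-skew and coverage-dependent error, structural
variation beyond tandem duplications, and read-level error profiles.  A
green test therefore establishes the correctness of the *calling and
filtering logic* on collinear near-identical genomes, not robustness to
repeat-rich assemblies.

Default rates in the packaged tests (tens of SNVs/Mb) are far above the
real-world handful per genome; they are chosen so that a desk-scale
genome (0.1–0.3 Mb) carries enough events to exercise every funnel
branch, while staying sparse enough (≥50 bp spacing) that alignments
are unambiguous.

## Numerical choices and edge cases

* Coordinates are 0-based half-open everywhere internally; 1-based
  only in rendered reports (mutation strings, GFF3, VCF).
* Alignment scoring is fixed at +1/−1, gap open 2, extend 1 — the same
  scheme as the independent full-matrix oracle used in the tests, so
  optimal scores are directly comparable.
* The alignment band is auto-widened to at least the length difference
  plus 64; anchors bound the inter-anchor problems so the band is
  essentially always sufficient for clonal genomes.
* Ties in anchor chaining are broken toward the leftmost query start;
  inversions are out of scope (the genomes compared are collinear).
* `N` handling: with `mask_n` (default), any gap-free column containing
  `N` is excluded from both numerator and denominator of the identity
  metrics; translation renders N-containing codons as `X` and the
  effect as indeterminate, which removes the gene at the funnel's
  N stage.
* Determinism: every stochastic routine takes an explicit seed; a
  configuration (including its seed) reruns to byte-identical FASTA,
  GFF3, truth tables and reports.

## Known limitations

* The flank-placement search is mismatch-only; a true indel inside a
  flank (rare between near-identical relatives) degrades identity and
  may leave a fillable gap unfilled — conservative, never incorrect.
* Exact reproduction of published per-Mb difference tables for the real
  assemblies additionally depends on the aligner's block decomposition
  and the unstated normalization of the original tables; the package
  pins one self-consistent convention.
* `sequential_map()` assumes conserved gene order; a genuinely
  translocated gene is found by the whole-chromosome fallback but
  flagged `synteny_ok = FALSE` rather than re-anchored.
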