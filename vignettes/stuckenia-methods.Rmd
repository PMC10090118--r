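---
title: "Methods: ITS1-ITS2 barcode identification in Stuckenia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ITS1-ITS2 barcode identification in Stuckenia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stuckenia)
```

## The identification problem

Pondweeds of the genus *Stuckenia* are notoriously hard to identify from
morphology: the characters used in keys (leaf, stem and fruit anatomy) vary
strongly with growth conditions, hybrids are frequent, and at least one
species (*S. pectinata*) hides substantial cryptic molecular diversity. The
nuclear ribosomal ITS1–ITS2 region behaves much better: within this genus it
carries a small, stable set of diagnostic differences that separate

* *S. vaginata* from the *S. pectinata* clade — three indels (two of 1 nt,
  one of 9 nt) plus sixteen 1-nt and two 2-nt substitution runs, and a
  restriction-site contrast (one strict CfoI `GCGC` site instead of two);
* two cryptic haplotype groups inside *S. pectinata*, called type A and
  type B — five 1-nt and one 2-nt substitution runs;
* *S. macrocarpa* from type B — a single 2-nt state change at a diagnostic
  dinucleotide (historically reported at alignment positions 102–103:
  `GC` in type B, `TA` in *S. macrocarpa*);
* *S. chakassiensis* from type B — one T/C substitution (historically
  position 524).

Interspecific hybrids between type B and *S. macrocarpa* are visible
directly in Sanger consensus sequences: at each position where the parents
differ the chromatogram shows both peaks, which base callers encode as the
IUPAC ambiguity covering both parental bases (`K` = G/T at the first
dinucleotide position, `M` = A/C at the second). This *additivity pattern*
is the hybrid diagnostic.

The package implements the whole inference as a reusable pipeline: read and
validate sequences, align, compute distance matrices and a
bootstrap-supported tree, profile pairwise differences into events, apply
the diagnostic key, detect hybrids, partition samples into the tree groups,
and report morphology/molecule discordance.

## Alignment

The aligner is a progressive profile method: pairwise global alignment with
affine gap penalties (Gotoh's three-state recursion), merged along a UPGMA
guide tree built from shared 4-mer distances. Profile columns are scored as
the mean pairwise symbol score between the two column populations, computed
as a single matrix product before the dynamic program, so profile size does
not affect the DP cost.

Scoring defaults are match +2, mismatch −1, gap open −5, gap extend −1 (a
gap of *k* columns costs 5 + (*k* − 1)). They were chosen once, so that
indels of the sizes seen in this locus (1 and 9 nt) align as single
contiguous blocks; all four numbers are exposed in `scoring_scheme()`.
Ambiguity codes score as a match whenever their base sets intersect — a
hybrid's `K` should not be penalized against either parent's `G` or `T`.

Determinism is part of the contract. Traceback ties are broken diagonal >
up > left everywhere; sequences are canonically sorted by id before guide
tree construction, so the alignment is invariant under permutation of the
input rows. Users with an externally produced alignment (e.g. a ClustalW
product) can inject it through the pipeline's `aligned =` import mode,
which bypasses the internal aligner entirely.

## Diagnostic positions are anchored by context, not column number

Historically the diagnostic positions of this locus are quoted as columns
of one particular master alignment (102, 103, 524). Column numbers are an
artifact of that alignment run and cannot be reproduced without its exact
program and parameters. The key therefore anchors every rule by a 10-nt
5′ context string taken from a named reference haplotype; the rule's
target is the residue at a fixed offset after the anchor, mapped into
alignment coordinates through the reference row. Anchors must occur
exactly once in the reference or the key refuses to apply. The historical
column numbers are retained as nominal metadata only.

## The classifier

Decision order, applied per sample:

1. if every vaginata-diagnostic position shows the *S. vaginata* state, the
   call is *S. vaginata*. The large difference set is primary evidence; the
   strict CfoI count (expected 1) corroborates it, and any disagreement is
   recorded as a conflict rather than changing the call — ambiguity codes
   in a consensus sequence can mask single sites, so the dual-evidence
   arrangement is deliberately asymmetric;
2. otherwise, if every A/B separator position shows the type-A state, the
   call is *S. pectinata* type A;
3. otherwise the diagnostic dinucleotide decides within the B-like clade:
   the type-B state leads to the subgroup position (T → type B, C →
   *S. chakassiensis*); the macrocarpa state gives *S. macrocarpa*; the
   exact additivity pattern at **both** positions gives the hybrid call.
   Additivity at only one position is deliberately *unresolved* with a
   "partial hybrid signal" flag — a single ambiguous site is indistinguishable
   from a sequencing artifact;
4. anything else is unresolved, with all partial evidence retained.

Which of T/C marks *S. chakassiensis* is a key-file parameter, not a
constant: the shipped synthetic key assigns C to *S. chakassiensis* as an
explicit, documented choice. Gaps at non-diagnostic positions never block a
call (rare haplotypes with private deletions remain classifiable); a gap at
a diagnostic position simply fails that rule.

Samples whose overall ambiguity fraction exceeds a threshold (default
0.005, i.e. more than ~3 ambiguous residues in a 700-nt sequence) are
flagged "polymorphic". This separates genuinely messy consensus sequences
(many superimposed peaks) from hybrids, which carry exactly two ambiguous
positions.

## Distances and trees

Two distance estimators are provided: the uncorrected p-distance and the
Tamura–Nei (TN93) correction with per-pair empirical base frequencies.
Ambiguity codes are treated as missing data for distances — hybrid
additivity codes would otherwise inflate divergence. The default deletion
policy is pairwise (a column is dropped only for pairs in which either row
has a gap or ambiguity), which preserves information across the 9-nt indel;
complete deletion is available. Saturated pairs (non-positive logarithm
argument) are flagged, never silently dropped.

The tree is neighbor-joining on TN93 distances with nonparametric bootstrap
(default 1000 column-resampling replicates, the conventional value for this
kind of study), *not* a maximum-likelihood topology search. The quantities
this pipeline is accountable for are group membership and split support,
which NJ reproduces at desk scale while staying fully deterministic; the
substitution model enters through the distances. This surrogate choice is
stated prominently here because it is the one methodological deviation from
the classical MEGA-style workflow this package mirrors.

Numerical details of the NJ implementation: ties on the Q criterion are
broken toward the smallest label-order pair; negative branch lengths are
clamped to zero with the deficit moved to the sister branch; on an additive
matrix the generating tree and its branch lengths are recovered exactly
(property-tested against random trees of up to 8 leaves). Before support
values are computed, zero-length internal edges of the point tree are
collapsed into polytomies so that an arbitrary tie-break resolution can
never appear supported. Support values are displayed only when strictly
greater than 50 %.

## The synthetic-data generator

`build_haplotype_panel()` constructs a five-haplotype panel embodying the
difference structure listed at the top of this vignette, on a random base
sequence of 700 nt (the natural size of the locus; configurable down to
600). Placement rules: no two edit events closer than three positions (so
maximal runs never merge), the 9-nt indel at least 20 nt from any
diagnostic position or motif, two `GCGC` motifs planted and all accidental
`GCGC` occurrences scrubbed from the base, and one vaginata substitution
forced onto the third base of the second motif — reproducing the 2-vs-1
restriction-site contrast mechanistically. The three vaginata indels are
realised as insertions, so the panel alignment has exactly base length + 11
columns. Vaginata substitutions sit only at columns where types A and B
agree, which is how the 16 + 2 inventory is conventionally counted for this
locus. After construction the panel is *re-measured* through the public
profiling functions; if any invariant fails, placement is retried with a
derived sub-seed (deterministically per seed).

`simulate_samples()` emulates the study design: 28 specimens by default,
with morphology labels splitting 7/7/9/5 across the four species while the
molecular truths are 2 vaginata, 2 type A, 7 type B, 8 macrocarpa, 3
hybrids and 6 chakassiensis — including six misidentified specimens, so the
discordance report has something real to find. Hybrids are the positionwise
IUPAC union of the type-B and macrocarpa haplotypes. Optional noise is
substitution-only (Sanger consensus errors in this setting present as
miscalls or double peaks, not indels) and never touches diagnostic or motif
positions, so the simulated truth stays well-defined; one sample may
receive extra ambiguity injections (default rate 0.01 per site) to emulate
a polymorphic, many-peaked consensus.

What the generator does **not** emulate: real intragenomic rDNA variation,
alignment-ambiguous repeat regions, PCR chimeras, chromatogram-level error
structure, or any coalescent process. Passing the synthetic suite therefore
demonstrates that the pipeline's logic is correct under the documented
difference structure — not that the locus itself will behave this cleanly
in every new population.

## Problem sizes and reproducibility

The shipped test suite and the acceptance script run entirely on synthetic
data: panels of 700 nt, sample sets of 10–28 sequences, bootstrap
replicates between 25 (pipeline tests) and 1000 (the acceptance run), and a
20-seed recovery battery; these sizes were chosen as the smallest that
exercise every code path at full fidelity. All randomness flows from
explicit integer seeds (generator, noise, bootstrap are separately seeded;
the pipeline derives its streams from one configuration seed), and a
pipeline run is bit-reproducible across all text artifacts except the run
log, which records wall-clock timings.

## Known limitations

* The classifier is a deterministic key, not a probabilistic assigner: it
  reports evidence and conflicts but no posterior probabilities.
* Restriction sites are counted as motif occurrences; fragment lengths are
  not simulated.
* The A-vs-B and vaginata separators read a small number of key positions;
  a sample with ambiguity codes exactly on those positions will come out
  unresolved rather than guessed.
* NJ + bootstrap is a surrogate for ML tree search (see above); likelihoods
  and rate heterogeneity are out of scope.
* Building a key for real reference sequences requires resolving the T/C
  orientation of the subgroup position from curated material; the package
  ships only the synthetic key and deliberately does not guess.
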