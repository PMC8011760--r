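---
title: "lincberry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lincberry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincberry)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the parameters that matter (with defaults and
why), what the synthetic-data generators do and do not emulate, the
numerical choices, and the known limitations. Everything quantitative
shown here is computed by the code in front of you; nothing is quoted
from elsewhere.

## The problem

Long noncoding RNAs (lncRNAs) in plants — transcripts longer than 200 nt
with no substantial protein-coding capacity — are identified genome-wide
by filtering assembled transcript models against a reference annotation,
then characterized by expression pattern, co-expression context, and
interactions with miRNAs. A lncRNA carrying a miRNA binding site can act
as an *endogenous target mimic* (eTM): by binding the miRNA it
sequesters it away from its protein-coding targets. Canonical eTMs carry
a three-nucleotide bulge opposite the miRNA's position 10–11 cleavage
site, which blocks slicing; a *noncanonical* mimic is itself cleavable —
often at a shifted bond, e.g. between miRNA nucleotides 12 and 13 as
read out by 5' RLM-RACE — yet still competes by stoichiometry. The
package implements this full analysis chain at desk scale, with seeded
generators that plant ground truth so each stage's recovery is a testable
claim rather than a hope.

## Coordinates and containers

All genomic intervals are Bioconductor `GRanges`/`IRanges`: 1-based,
closed, with explicit strand. This is a deliberate divergence from the
0-based half-open convention common in Python tooling: in R, interval
algebra (overlaps, set differences, containment) should be done by
IRanges rather than re-derived, and keeping a single convention
everywhere eliminates the off-by-one class of bug the half-open
convention is usually chosen to avoid. Conversion happens exactly once,
at the BED boundary (`write_bed`), where the format dictates 0-based
half-open. Minus-strand spliced sequences are reverse-complemented at
extraction (`spliced_seq`) so ORF and miRNA scans always operate 5'→3'
in transcript space. Assembled transcripts without an explicit strand
are rejected rather than guessed, because positional classification is
strand-dependent.

## Discovery

`discover_lncrnas` applies three independent predicates, in order:

1. **Length**: spliced length strictly greater than `min_length_nt`
   (default 200). A 200-nt transcript is dropped; a 201-nt transcript
   passes. "Longer than" is read literally, and the boundary cases are
   pinned in tests so the choice is explicit.
2. **Position** (`classify_position`): any same-strand exonic overlap
   with an annotated gene discards the transcript; otherwise
   opposite-strand overlap touching at least one exonic base is
   `exonAS`; opposite-strand overlap confined to intronic bases is
   `intronAS`; same-strand full containment in a single intron is
   `INTRONIC`; no overlap with any gene span is `LINC`. Priorities run
   discard > exonAS > intronAS > INTRONIC, which makes multi-gene
   overlaps deterministic. A same-strand overlap that is neither exonic
   nor intron-contained (a transcript straddling a gene boundary through
   an intron) is discarded with an explanatory evidence string: the
   retained classes are exactly the antisense and intronic geometries,
   and anything else touching a gene on its own strand is treated as a
   fragment of that gene's transcription.
3. **Coding potential** (`find_orfs` + `coding_filter`): a transcript is
   dropped if any internal ORF exceeds 100 aa or any terminal ORF
   exceeds 50 aa (both strict). ORF length counts codons from the ATG
   inclusive and excludes the stop. *Terminal* covers both stop-less 3'
   runoff ORFs and ATG-less 5' runoff frames that end in a stop (in full
   codons): both are fragments of potentially longer coding regions
   truncated by the transcript boundary, which is why the tighter 50-aa
   bound applies to them. Codons containing N never count as start or
   stop. Database homology screening is a pluggable predicate
   (`homology_hook`) defaulting to "never fires" — sequence-similarity
   search needs an external database and is out of scope here.

Because the three predicates are independent, the kept set is invariant
to filter order (asserted in tests); the pipeline applies them in the
order above only so each dropped transcript carries its first failing
verdict.

## Expression

`tmm_normalize` computes per-sample scaling factors as precision-weighted
trimmed means of M-values against a reference sample (the one whose
upper-quartile expression is closest to the mean upper quartile), with
two-sided trimming on M (fraction 0.30) and A (0.05), then rescales the
factors to geometric mean 1 and divides counts by
`lib_size x factor / 1e6`. One deliberate difference from textbook TMM:
M-values are taken on **raw counts**, not library-size-adjusted ones, so
the factor absorbs sequencing depth as well as composition bias — a
size-factor-style behaviour under which columns that are exact scalar
multiples of one another recover those scalars exactly (a property the
test suite asserts to 1e-6). On equal-depth libraries the two
definitions coincide, which is how the implementation is cross-checked
against edgeR in the test suite. Variance-stabilizing transformations
and factor-based batch removal are intentionally replaced by
`log2(cpm + 1)` for correlation and co-expression input; this keeps the
stack dependency-light and transparent, at the cost of less aggressive
variance control for very low counts.

`presence_filter` keeps a feature iff it has strictly more than
`min_reads` (10) reads in strictly more than `min_fraction` (0.6) of
samples; the integer threshold is `floor(0.6 x n)`, so with 72 samples a
kept feature needs at least 44 qualifying samples (threshold 43). Both
strict inequalities are pinned by boundary tests.

`call_patterns` labels each feature from its stage-mean CPM against an
`expressed_cpm` threshold of 1.0 — the conventional "expressed" cutoff
at CPM scale, configurable because it is a judgement call: expressed in
exactly one stage gives `stage_specific:<stage>`, in all stages
`constitutive`, in none `silent`, otherwise `other`.

The landscape statistics are intentionally plain: Pearson correlation of
`log2(cpm + 1)` between samples (zero-variance samples yield NA rather
than an error); per-feature length / exon count / GC; two-sided Wilcoxon
rank-sum tests comparing lncRNAs to genes (no multiplicity correction —
three tests reported at face value); 100-kb bin densities keyed on
feature starts; and signed lincRNA-to-nearest-gene distances measured
from the lincRNA TSS, negative on the gene's 5' side and positive on its
3' side, zero on overlap.

## Co-expression

Adjacency is signed-absolute `|r|^beta` with `beta = 6`, the customary
soft-threshold power for unsigned networks; topological overlap is the
standard `(l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`. Modules come from
average-linkage clustering of `1 - TOM` with a **static** tree cut —
deterministic and fully parameterized, in place of dynamic hybrid
cutting, whose result depends on implementation details that are not
worth importing for a desk-scale tool. The default `cut_height = 0.7`
reflects the scale of TOM dissimilarities: tightly co-expressed planted
blocks sit well below 0.5 while unrelated features merge near 0.9, so
0.7 separates structure without fragmenting it (any cut in roughly
0.5–0.8 recovers the planted two-block design perfectly; the default
sits mid-range). Clusters below `min_module_size` (10) become
"unassigned". The module eigengene is the unit-norm first right singular
vector of the standardized member-by-sample matrix, signed so its mean
correlation with members is non-negative; by construction it explains at
least as much member variance as any single member profile used as a
surrogate. Enrichment is the upper-tail hypergeometric `P(X >= k)`
against a user-supplied two-column feature-term map, flagged at p < 0.05
with no correction by default (BH is an option): the plain-p rule
mirrors common practice for exploratory GO screens, and the tests pin
the exact 1/252 enumeration case.

## Target scanning and mimicry

Two external target predictors are, by design, replaced by two in-package
scoring schemes that differ only in how far the seed-proximal doubling
region extends (miRNA positions 2–13 for scheme A, 2–12 for scheme B),
preserving the consensus-intersection idea: only sites passing both
schemes (`cutoff 4.0` each, span midpoints within ±3 nt) are reported.
Penalties are mismatch 1, G:U wobble 0.5, bulged nucleotide 2, with at
most one bulge of at most 4 nt per duplex — enough to represent perfect
sites, mismatched mutants, and 3-nt-bulge eTMs while keeping the
alignment search exactly enumerable (the test suite checks the scorer
against an exhaustive enumerator). Two scoring details are worth
stating. First, doubling applies to *paired positions only*: a bulge
sits between miRNA positions rather than at one, and doubling it would
make the canonical eTM geometry (3-nt bulge between 10–11) never
optimal under scheme B — relocating the bulge just outside the doubling
region would always be cheaper. Second, with a bulge the optimal
placement can be degenerate when inserted bases coincidentally pair;
ties resolve to the smallest bulge position, and the site generator
(`plant_target_sites`) picks eTM insertion bases by deterministic
first-fit search so the planted geometry is the unique optimum under
both schemes.

Duplex energy is a simplified nearest-neighbour sum over contiguously
stacked Watson-Crick pairs using a packaged 16-entry stacking table
(indexed by the miRNA dinucleotide step), a flat mild term for stacks
involving G:U, and a fixed +2 kcal/mol per mismatched or bulged
nucleotide. Absolute values are not comparable to full Turner-parameter
tools; only orderings are asserted (a contiguous decoy site is at least
as stable as the equivalent 3-nt-bulged eTM site).

Cleavage prediction is purely geometric: the canonical scissile bond
lies between the target bases pairing miRNA nucleotides 10 and 11, so it
requires matches at positions 9–11 and target contiguity through 10–11;
an eTM bulge there yields no prediction. `classify_mimic` then labels a
consensus site `canonical_eTM` (3-nt bulge at 10–11), `cleavable_target`
(contiguous), or `noncanonical_mimic` (contiguous *and* RACE evidence
placing the modal bond away from 10/11). Conservation of a site across
homologs is per-column identity under global alignment (match +1,
mismatch −1, gap −2 per nt).

## RACE tallying and the anthocyanin index

A clone's 5' end marks the first base of the 3' cleavage fragment, so
the scissile bond is immediately 5' of it; a clone at the target base
pairing miRNA nt k therefore implies a bond between miRNA nts k and
k+1, reported as offset k ("10" means "between the 10th and 11th").
Ties on the modal position break toward the smaller transcript position
and are flagged. The anthocyanin index is `(A530 - 0.25 x A657) / M`:
the 0.25-scaled 657-nm reading corrects for chlorophyll absorbance at
530 nm, and M normalizes per gram of tissue. Negative values are
reported with a warning rather than clipped — a negative index is a
sign of a failed extraction, not a zero.

## What the generators emulate — and what they do not

Each generator is a pure function of its parameters and seed (the
caller's RNG state is restored). Default scales are chosen so the whole
suite runs in seconds: 2 chromosomes of roughly 50 kb, 10 genes with 1–5
exons (exons 150–400 nt, introns 400–900 nt so intron-resident
transcripts longer than 200 nt fit), 13 planted transcripts covering
every positional class plus sense-overlap decoys, and a 3-stage × 3
replicate negative-binomial count design (dispersion 0.1; stage-specific
features at mean 500 in their stage and ~0 elsewhere; constitutive
baselines log-normal around 100) mirroring a small fruit-ripening
experiment with three biological replicates per stage. Planted
lncRNA placements are redrawn until their extracted sequence is free of
disqualifying ORFs, so class-recovery tests isolate the classification
stage; the ORF filter itself is exercised by independently planted
boundary ORFs (`plant_orf`, whose interior codons use a fixed
start/stop-free filler so the planted frame is exactly what its
coordinates claim). Planted co-expression modules share a per-sample
latent log-scale factor (amplitude 1.5), which yields unambiguous
two-block structure at the default noise.

The generators do **not** emulate read-level artifacts (no FASTQ, no
aligner or assembler error modes), positional sequencing biases,
isoform mixtures, octoploid subgenome homology, or batch structure
beyond an optional multiplicative shift. Passing the recovery tests
therefore demonstrates that the *algorithms* implement their
definitions correctly on clean inputs — it does not certify performance
on real libraries, where assembly fragmentation and annotation
incompleteness dominate error budgets.

## Numerical choices and degenerate inputs

Strict inequalities at every published threshold; floor-based integer
thresholds in the presence filter; first-fit tie-breaking toward the
smaller bulge position in duplex scoring; lexicographic tie-breaking of
equal-weight edges; modal RACE ties toward the smaller position with a
flag; TMM trimming by ranked M and A with ties broken by first rank;
zero-variance features excluded from adjacency with a warning, and
zero-variance samples producing NA correlations rather than errors.
Degenerate inputs are exercised in tests: empty transcript sets, empty
GTFs, single-gene annotations, all-zero samples (an error naming the
sample), cut height 0 (everything unassigned), and single-clone RACE
tables.

## Limitations

The coding filter is rule-based (no learned coding-potential score and
no protein-database search unless hooked in); the co-expression module
detector is a static cut, so very unequal module sizes may need a
per-dataset cut height; duplex energies are rankings, not calibrated
free energies; and the consensus target cutoffs are practice-derived
defaults, not fitted values — with the default 4.0, a canonical eTM
(bulge penalty 6) is deliberately *not* a consensus "target", matching
the biology that an eTM is not a cleavage substrate; scan for mimics
with a raised cutoff when that is the question being asked.
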