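---
title: "Comparative mitogenome architecture with mitoarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenome architecture with mitoarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarch)
```

## The problem

Animal mitochondrial genomes are small circular molecules (14–18 kb in
amphipod crustaceans) carrying a nearly fixed gene complement — 13
protein-coding genes (PCGs), 2 rRNAs, ~22 tRNAs and one major non-coding
control region (CR) — but a highly variable *architecture*: gene order,
strand composition bias, tRNA copy number, and non-coding content all
rearrange over evolutionary time. Comparative studies of clades such as the
Lake Baikal amphipod radiation summarize each genome with a standard set of
statistics and compare them across species. `mitoarch` implements that
analysis set as reusable, testable functions, together with a synthetic
genome generator that plants every kind of signal with known ground truth.

## Statistics and their definitions

**Strand composition.** For a sequence with base counts $A, C, G, T$:

$$\mathrm{AT\text{-}skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\text{-}skew} = \frac{G - C}{G + C}, \qquad
  \mathrm{AT\%} = 100\,\frac{A + T}{A + C + G + T}.$$

Both skews flip sign under reverse complement, so genes encoded on the
(−) strand show the mirrored bias when read in coding sense. Per-gene
statistics are therefore computed on coding-sense sequences
(`gene_composition_table()`): a genome whose (+) strand has negative
GC-skew shows positive coding-sense GC-skew for its (−)-strand genes, the
classic strand-bias signature. Skews are undefined (reported `NA`) when the
denominator is zero, and `N` bases are excluded from every count — relevant
for partially sequenced genomes. Sliding-window profiles
(`sliding_window_profile()`) default to 100 b.p. windows advanced in 10
b.p. steps; on circular sequences windows wrap the origin so every position
is covered.

**Codon usage and ENC.** Codon statistics use the invertebrate
mitochondrial code (translation table 5), in which AGA/AGG code for serine
and ATA for methionine, leaving 62 sense codons in 20 synonymous families.
Wright's effective number of codons is built from per-family codon
homozygosities

$$\hat F = \frac{n \sum_i \hat p_i^2 - 1}{n - 1},$$

with $n$ the family's codon count and $\hat p_i$ the within-family codon
frequencies; Nc sums, over degeneracy classes, the number of families in
the class divided by the class mean $\hat F$. Families with fewer than two
codons (or non-positive $\hat F$) are imputed with the class mean, or with
the reciprocal degeneracy when a whole class is missing; Nc is capped at
the sense-codon count. Under the default convention the 6-codon leucine and
8-codon serine families are kept whole, each forming its own degeneracy
class, giving the partition 12×2-fold + 6×4-fold + 1×6-fold + 1×8-fold, so
Nc ranges from 20 (one codon per family) to 62 (uniform usage). The
alternative 2+4/4+4 split is available via `split_families = TRUE`; the two
conventions differ by well under one Nc unit on realistic usage, but the
choice is exposed because ENC implementations disagree on it. GC3s is the
G+C fraction at third positions of codons in synonymous families — under
table 5 every sense codon qualifies, so the synonymous-only and all-sites
definitions coincide there (both are implemented; `all_sites = TRUE`
ignores the partition). Stops and incomplete trailing codons are excluded
from usage tables, Nc and GC3s.

**Nucleotide diversity.** $\pi$ is the plain mean over all sequence pairs
of the per-site difference proportion, after removing every column holding
a gap or `N` in any row (complete deletion, the convention of the standard
desktop tool for this statistic); no $n/(n-1)$ correction is applied.
Pairwise deletion is available as an option. Alignments are first-class
inputs (aligned FASTA via `read_gene_alignment()`); for convenience a
minimal codon-aware aligner (`codon_aware_align()`: translate under table
5, center-star protein alignment, back-translate) is included for
desk-scale use, but real studies should feed alignments from a dedicated
aligner.

**Gene order.** A genome's order is reduced to a signed signature
(`gene_order_signature()`): features in the chosen scope (PCG-only,
PCG+rRNA, or all 37 + CR) sorted by position, rotated so the anchor gene
(default *cox1*) leads, and reflected with signs flipped if the anchor lies
on the (−) strand — making the signature invariant under genome rotation
and full reflection. Comparison against a reference (by default the
pancrustacean ground pattern, transcribed once as a versioned in-code
fixture) counts **breakpoints**: signed adjacencies, including the circular
closure and up to reverse-complement equivalence, present in one signature
but not the other. Because the two adjacency sets have equal size over the
shared labels, the count is symmetric, and it satisfies the triangle
inequality (it is half the symmetric difference of adjacency sets).
"Translocated" is defined operationally as a label whose unsigned neighbor
pair differs from the reference — this marks the moved gene *and* the
flanks of its old and new sites, which matches how rearranged genes are
read off a gene-map figure but is deliberately a superset of the moved set.
"Inverted" is a sign flip. Duplicated tRNAs are distinguished by copy index
rather than forced into a bijection; labels private to one genome are
reported and excluded from the distance.

**tRNA duplication and remolding.** Duplicate tRNA labels are compared
against every other tRNA in the genome with global (Needleman–Wunsch)
alignment: match +1, mismatch −1, gap −2 (linear), deterministic traceback
preferring diagonal, then vertical, then horizontal moves; identity is
100·matches/columns to 2 d.p. A duplicated tRNA whose best non-cognate
("donor") identity reaches 65% is called a *remolded-candidate* — the copy
likely arose from the donor and switched identity by anticodon mutation.
Otherwise it is a *recent-duplicate* when the copies are at least 85%
identical **or** closer to each other than to any donor; otherwise
*ambiguous*. The second clause matters: an old in-place duplication can
fall below 85% while still being closest to its own cognate, and that
pattern is evidence for in-place origin, not remolding. Both thresholds are
arguments.

**Control-region detection.** Candidate regions (unannotated intervals
≥ 50 b.p., plus annotated CRs) are scanned for the four feature classes
typical of invertebrate CRs: a poly-T stretch (≥ 10 T on either strand),
tandem repeats, hairpin-forming inverted repeats (stem ≥ 6 exact
Watson–Crick pairs, loop 3–30 nt, maximal stems only), and AT enrichment
(≥ 5 percentage points over the whole genome). The score simply counts
classes present (0–4) — the literature gives no basis for weighting them —
and candidates are ranked by score, then length. The tandem detector
compares the sequence with itself at each candidate period (10–200 b.p.),
requires a 12-match seed, extends while cumulative adjacent-copy identity
stays ≥ 80%, and keeps the fundamental call among overlapping ones (most
copies, then longest span) — harmonics of a true period tie on span but
halve the copy count. Microsatellite-scale periods are detectable by
lowering `min_period` and `seed` together; the defaults stay quiet on
random sequence, which is what the CR score needs. Sequences containing `N`
runs are effectively scanned per N-free block, since `N` matches nothing in
any detector.

## The synthetic genome generator

`generate_genome()` builds an annotated circular genome from the ground
pattern plus a list of edits, and records every planted fact. Design
choices:

* **Replication-strand skew model.** Target skews apply to the (+) strand
  of every region. Genome-wide skews then meet the targets directly, and
  (−)-strand genes show the sign-flipped coding-sense skew — the empirical
  strand-bias structure — as an emergent property rather than by
  construction per gene.
* **PCG codon structure.** Codons are sampled i.i.d. with
  position-specific AT (defaults `at_percent + (−10, −2, +12)`,
  reproducing the position-1 < position-2 < position-3 AT ordering seen in
  real PCGs) and strand-adjusted skews; the start codon is drawn from the
  six observed mitochondrial starts and the stop is TAA/TAG. Internal stop
  codons are *not* filtered: filtering would bias composition off target,
  and none of the implemented statistics require translatable ORFs.
  Synthetic PCGs are statistical emulations, not gene models.
* **Planted facts hold exactly, not just in expectation.** tRNA duplicates
  and repeat-copy noise are planted as exact substitution counts
  (`round(L·(1−identity/100))` positions), and the tandem-repeat unit's
  composition is constrained to within 3 points of the CR target — one
  51-mer copied four times has only ~51 b.p. of compositional freedom, and
  an unconstrained unit can wash out the planted AT excess.
* **Star-tree alignments.** `generate_alignment()` mutates each taxon
  independently from one ancestor with per-site substitution probability
  $q = \tfrac34\left(1 - \sqrt{1 - \tfrac43 p}\right)$, the solution of
  $p = 2q - \tfrac43 q^2$, so the expected pairwise difference equals the
  target $p$ (valid for $p \le 0.75$). A star tree exercises the $\pi$
  estimator without confounding phylogenetic correlation — appropriate
  because $\pi$ is a summary statistic here, not a tree inference.
* **Determinism.** All randomness flows from `spec$seed` through a local
  RNG scope, so identical specs give byte-identical genomes and the
  caller's RNG stream is untouched.

What the generator does **not** emulate: among-gene and among-site rate
heterogeneity, phylogenetic correlation between genomes, realistic tRNA
secondary structure, gene overlap, and sequencing artifacts. Passing the
recovery suite therefore shows the *estimators* are correct on data with
known structure; it does not validate biological conclusions drawn from
real genomes.

## Numerical and interface conventions

* Internal coordinates are 0-based half-open on the (+) strand; all file
  formats (GenBank, feature-table TSV) are 1-based inclusive. An
  origin-spanning feature is encoded as `start > end` and normalized only
  at extraction, preserving deposited coordinates.
* Reports round skews to 3 d.p. and percents to 2 d.p. (the precision such
  tables are conventionally printed at); returned objects keep full
  precision, and `run_all()` writes a full-precision JSON sidecar next to
  the rounded TSVs.
* Degenerate inputs: empty or all-`N` sequences, windows longer than the
  sequence, alignments with no usable site, fewer than two sense codons,
  and zero-variance correlations are errors, not silent `NaN`s. Unknown
  gene labels warn and pass through verbatim.
* Alignment traceback ties are broken deterministically
  (diagonal > up > left), so identities are reproducible across platforms.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script simulations use full-size genomes
(~14.5–15 kb, the 37-gene complement) — generation and a complete analysis
pass take well under a second per genome — with 20 randomized
recovery runs, alignments up to 10 × 10 kb for diversity calibration, and
exhaustive-enumeration oracles confined to the input sizes where
enumeration is exact and fast (alignments ≤ 6 nt, signatures ≤ 12 genes,
hairpin scans ≤ 100 b.p.). The acceptance script simulates a ten-genome
panel whose composition targets, rearrangement scenarios, duplication
identities and per-gene diversities follow the published comparative
values for the Baikal amphipod clade, then recomputes every reported
quantity from scratch.

## Known limitations

* The GenBank reader targets single-record flat files with the feature
  keys used by organelle submissions (`CDS`, `tRNA`, `rRNA`, `D-loop`,
  `misc_feature`); multi-record files and exotic location operators are
  out of scope.
* Remolding calls are sequence-identity heuristics; they suggest, but
  cannot prove, an anticodon-switch history, and tRNA secondary structure
  is not modeled.
* Breakpoint distance is reported as a dissimilarity; no attempt is made
  to infer rearrangement event scenarios or ancestral gene orders.
* CR boundary calling is not attempted: candidates are reported at the
  extent of the unannotated region (or annotated CR), ranked by feature
  content.
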