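---
title: "The LTRcensus method: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The LTRcensus method: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`LTRcensus` implements a census of LTR retrotransposons in assembled
genomes: structural detection, superfamily classification, family building,
library re-annotation, RT/RNaseH phylogeny with clade definition,
similarity-based clade assignment, and summary tables. This vignette
explains the models behind each stage, the parameters that matter, the
numerical choices, and what the synthetic benchmark does and does not show.

## The element model and the synthetic generator

An LTR retrotransposon is modelled as `LTR - internal - LTR`: two identical
direct terminal repeats around an internal region that carries a pol-like
coding sequence whose RT/RNaseH segment is the phylogenetic marker. The
three superfamilies differ in where the integrase sits: upstream of RT for
Copia, downstream of RNaseH for BEL/Pao and Gypsy; the generator reproduces
that domain order.

`buildElementLibrary()` radiates the sequence space hierarchically at the
protein level: one ancestral pol protein per superfamily, clade ancestors at
`cladeDivergence` amino-acid substitutions per site (default 0.3), family
proteins at `familyDivergence` (default 0.05). Family nucleotide sequences
are produced by back-translation with uniformly random synonymous codons, so
coding regions can never contain an internal stop by construction, and the
nucleotide divergence between families is substantially larger than their
amino-acid divergence (synonymous positions are randomised independently per
family). Each family gets its own random LTR (length sampled in 250-400 bp
by default) and random UTRs sized so that the LTR start-to-start distance
always falls inside the 2500-11000 bp detection window; a blueprint that
cannot satisfy the window is a configuration error. The labelled reference
panel — `panelRefsPerClade` RT/RNaseH sequences per clade drawn around each
clade ancestor — doubles as the classification database and as the
reference-anchoring set for the trees.

`plantCopies()` draws copies per family, mutates each copy part-wise
(substitutions at `subRate`, geometric-length indels at `indelRate`,
insertions and deletions equiprobable), optionally truncates (a uniform
20-80% cut from a random end, which always removes one terminal repeat and
makes the copy structurally undetectable), reduces to a solo LTR, nests a
full copy of another family inside a host's internal region, and
reverse-complements half the copies. Copies are packed into uniform-random
background contigs separated by at least `minGap` of background. The default
`minGap` of 12 kb deliberately exceeds the maximum inter-LTR distance:
without it, the repeats of two adjacent near-identical copies of one family
can pair *across* elements at an in-window spacing and create spurious
candidates — an ambiguity real detectors face in tandem element arrays,
which the benchmark is not designed to probe. Every planted copy is recorded
in a truth `GRanges` (family, clade, superfamily, state, exact LTR spans
where meaningful); mutating the three parts separately keeps those truth
coordinates exact even with indels.

What the generator does **not** emulate: realistic base composition and
repeat landscapes (background is i.i.d.), transposition dynamics over time,
gene models or other repeat classes, and sequencing/assembly artifacts.
Passing tests therefore demonstrate the correctness of the algorithms under
the declared window and divergence regimes, not field performance on real
assemblies.

## Structural detection

Detection is exhaustive exact k-mer seeding (default k = 20) restricted to
spacings inside the inter-LTR window, followed by co-linear chaining with a
positional and diagonal tolerance of `maxBand` (50 bp) and global alignment
of the chained repeat pair. A candidate must satisfy all four bounds: both
repeat lengths in [`ltrMin`, `ltrMax`], the distance in
[`distMin`, `distMax`], and pair identity at least `ltrIdentityMin`; the
identity denominator counts every alignment column, gaps included, which
keeps the comparator consistent with the 80-80-80 family rule. Overlapping
candidates are resolved by higher identity, then longer element, then
leftmost start — the published procedure is silent here and a deterministic
rule is required. Whether "distance between LTRs" means start-to-start or
end-to-start is equally unstated; both readings are supported
(`distanceMode`), start-to-start being the default.

One subtlety the truth set exposes: the maximal exact repeat of a planted
copy extends into the flanking background whenever the bases adjacent to
both repeat occurrences coincide (probability 1/4 per side per step, i.e. a
geometric ~0.33 bp per boundary). The detector reports the maximal repeat —
correct behaviour — so recall tests compare boundaries with a small
tolerance and exactness is asserted on a constructed fixture whose flanks
cannot extend.

At zero mutation, recall of full-state plants is 100% by construction
(recoverability invariant); with 5% per-copy substitutions the seed-survival
probability per position is `0.905^k ≈ 0.135`, chains break with probability
below 1e-3 per position, and recall remains effectively complete — measured,
not asserted.

## The search engine and its statistics

All homology steps run on one Smith-Waterman affine-gap kernel (gap of
length `k` costs `gapOpen + k·gapExtend`), exact full dynamic programming
for small problems and seed-and-extend with banded alignment for large ones.
Six-frame translation uses the standard code with stops rendered as `*`.
E-values are analytic: λ solves the Karlin-Altschul identity to a residual
below 1e-9 (Newton-polished root), and K comes from the ungapped lattice
approximation (σ-series over convolutions of the step-score distribution,
with the lattice span δ equal to the gcd of the score values). Both
parameters reproduce the published ungapped values of the reference
implementation for the match/mismatch schemes used here and for BLOSUM62
(λ = 0.3176, K = 0.1365). Gapped scores are deliberately evaluated with
ungapped parameters: the E-values serve fixed thresholds (1e-5, 1e-10,
1e-40, 1e-70), where a constant-factor miscalibration is immaterial, and the
analytic route keeps everything deterministic. Default matrices are
BLOSUM62 with gaps 11/1 for protein and +2/-3 with gaps 5/2 for DNA —
conventional defaults, configurable because the original analyses did not
record theirs.

The tandem-repeat masker is a simple period scan (periods 1-50, at least 3
units at 80% identity between adjacent units). A minimum masked-array span
of 24 bp is imposed: without it, period-1 and period-2 windows mask roughly
a fifth of random sequence by chance, which silently drags scan identities
below the divergence cut-off. Parity with dedicated tandem-repeat tools is
a non-goal.

## Families

Two copies belong together when they align at ≥80% identity over ≥80 bp
covering ≥80% of each sequence's length; clusters are connected components
under that relation (single linkage), computed with banded global alignments
whose band covers the length difference plus 150 bp. Curation removes
copy-specific insertions: a copy's positions that fall inside an internal
alignment gap longer than 20 bp against *every* cluster mate are excised —
a pairwise-intersection formulation that recovers a nested insertion exactly
without requiring a full cluster multiple alignment. Clusters whose longest
members (representatives) still pass the comparator are merged under
transitive closure; representative-versus-representative is the
deterministic reading of "elements from two clusters share more than 80%
identity", and both the ≥80 readings of the cluster check and the merge rule
are implemented as ≥80.0 on aligned columns. Orphans become one-member
families only with a translatable RT/RNaseH domain (a panel hit whose
aligned query segment has no internal stop and at least 100 residues).
Families are named `<Superfamily>-<n>_<species>`.

## Re-annotation

The scan library pools the curated cluster families of all species (plus any
externally referenced families); orphans are excluded from the scan library
because single unvalidated sequences may carry contaminating fragments, but
they are included in the assignment database. Scanning is seeded nucleotide
search (k = 12) of each representative and its reverse complement; hits with
divergence above 20% (one minus identity over aligned columns — a monotone
proxy, no substitution-model correction) are dropped. Fragments of the same
superfamily and strand on a contig merge when strictly fewer than 500
intervening bases separate them, integrating the central sequence; 499 bp
merges, 500 does not, and different superfamilies never merge. Copies take
the family of their best nucleotide hit at E ≤ 1e-10; a best hit from
another species flags the copy as a cross-species candidate, and candidates
with a translatable domain cluster into new `annotation_derived` families,
after which all copies are re-assigned against the augmented library. The
strand of a merged copy is that of its highest-scoring fragment. Genomic
proportions divide the per-group union of copy intervals by genome length.

## Phylogeny and clades

Domains are the translated envelopes of the best panel hit,
frame-corrected; a frameshift inside the domain yields hits in two frames of
the same strand, which are spliced in element order with the overlapping
prefix trimmed, reconstructing a chimeric protein within a couple of
residues of the uninterrupted translation. Alignment is progressive: 3-mer
Jaccard distances feed a UPGMA guide tree and profiles merge by
profile-profile global alignment under BLOSUM62 — adequacy, not parity with
any external aligner, is the goal. Distances use pairwise deletion and,
by default, a gamma-corrected model distance `d = α((1-p)^{-1/α} - 1)` with
shape α = 1 (the shape used in the original analyses is unrecorded;
p-distance mode exists for oracle tests; p is capped at 0.95 to keep
saturated pairs finite). Neighbor joining is the standard Q-criterion
agglomeration with lexicographic tie-breaking by node creation order and
negative branch lengths clamped to zero with the deficit moved to the
sibling; on additive matrices it reproduces topology and branch lengths
exactly. Bootstrap support is the percentage of 100 column-resampled
replicates containing each bipartition of the full-data tree.

Clade definition follows two criteria — families from at least two species,
bootstrap support strictly above 70 — plus an anchoring rule. On an
unrooted tree, the "maximal well-supported group" is ill-defined: the far
side of any clade's edge is also well-supported, and the arbitrary root of
the NJ display can fall inside a clade. The package therefore puts the
labelled panel references into every superfamily tree (as the original
procedure did) and works on bipartitions: both sides of each internal edge
are candidates, any side mixing references of two or more known clades is
vetoed as composite, and clades are the maximal qualifying candidates under
containment, named after the references they contain; qualifying unions of
accepted clades are reported as lineages, and an override list can force a
group in despite low support (the analyst's documented exception). Without
references only the rooted descendant sides are considered, which makes the
calls dependent on the display root — reference anchoring is the
recommended mode. Unplaced families fall to `"other"`.

Families without a tree placement go through the five-best-hit similarity
rule: assigned to a clade when the five best hits are all from that clade
and the best other-clade E-value is separated from the best same-clade
E-value by more than 1e-10. The separation clause is implemented two ways.
The arithmetic difference is the rule exactly as printed, but for strongly
homologous queries both E-values underflow toward zero and their difference
can never exceed 1e-10 — the printed reading rejects nearly everything with
a deep database. The log10 mode requires ten orders of magnitude between
the two E-values instead, stays informative for strong hits, and is what the
pipeline uses; the mode is recorded in every result. Database mining uses
translated search at E ≤ 1e-70 with query coverage above 80%, relaxed to
1e-40 and 50% for the scarce Copia queries, and overlapping fragments of one
family can be assembled into a chimeric domain by majority-vote overlap
merging (at least 20 residues at 90% identity per junction).

## Problem sizes and determinism

Every stochastic step takes an explicit seed and restores the caller's RNG
state; identical seeds give byte-identical libraries, genomes, bootstrap
supports and pipeline manifests. The test suite and the acceptance script
run on deliberately compact instances chosen to exercise each property with
comfortable statistical margins: a 5 Mb ten-contig genome with 90 planted
copies for detection recall, 30 copies over 6 families across 5 seeds for
family recovery, a 9-clade library (3 Gypsy clades, 12 family domains plus
36 references in the tree) for clade recovery, 200 seeded queries for the
similarity route, and a two-species pipeline in which three of nine families
are planted only as truncated copies in one species for the re-annotation
gain. These sizes are the package's benchmark settings, not limits of the
implementation.

## Known limitations

* The search engine reports one best local alignment per subject (plus
  multi-hit scanning for genome annotation); HSP chaining across several
  local alignments and composition-based statistics are out of scope.
* E-values use ungapped parameters for gapped alignments; absolute parity
  with external search tools is not claimed beyond the threshold semantics.
* Clade definition without reference anchoring depends on the NJ display
  root; supply labelled references (the default pipeline behaviour) for
  root-independent calls.
* The generator's background is compositionally uniform; detectors facing
  real heterochromatin will see seed statistics these tests do not probe.
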