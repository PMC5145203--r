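---
title: "Methods: domain-architecture classification and GH2C phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain-architecture classification and GH2C phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gh2arch)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. The pipeline classifies family 2 glycoside
hydrolases (GH2) by domain architecture (DA), relates the DA types to the
phylogeny of the catalytic GH2C module, and profiles active-site
conservation. Everything below is computed by the package; no claim here
goes beyond what the test suite and `scripts/acceptance.R` verify.

## Coordinates and input contracts

All domain coordinates are 1-based inclusive Pfam *envelope* coordinates,
converted (if ever) only at the I/O boundary. `model_coverage` is the
fraction of the domain model matched: carried as data in the `tsv` dialect,
and computed as `(hmm_to − hmm_from + 1) / model_length` for HMMER
`domtblout` records. Residues outside the 20 canonical amino acids plus X
are rejected at load time rather than silently remapped, because downstream
identity computations must be well defined. Where the choice between
envelope and alignment coordinates matters (the 70% coverage filter), the
package standardises on envelope coordinates with model-span coverage.

## The DA vector

Each architecture is encoded over a repeat-aware slot vocabulary: one slot
per (domain, occurrence ordinal), labelled `Domain_k`. Bit `(d, k)` is set
iff the protein carries at least `k` copies of `d`, which makes repeat bits
monotone by construction and the encode/decode pair exactly invertible on
occurrence multisets (property-tested on 1000 random architectures). A pure
presence/absence vector cannot encode arbitrary domain order, so order lives
in the `Architecture` table; the vocabulary's canonical slot order — domains
sorted by their median envelope midpoint relative to sequence length —
merely makes the vector read roughly N- to C-terminal and is deterministic
under permutation of the input.

Overlapping hits (competing models for the same region) are resolved when
the overlap exceeds half the shorter envelope, keeping the higher model
coverage (ties: longer span, then lexicographic name). Pfam envelopes rarely
overlap more heavily except for competing models, which is why 50% of the
shorter span is the default.

## The classifier

The selection filter requires exactly one GH2C at model coverage ≥ 0.70 —
the boundary is inclusive because the protocol says *at least* 70% — and no
additional catalytic module (hybrid enzymes are excluded via a configurable
blacklist). The five-way decision order is:

1. Bgal_Small_N downstream of GH2C ⇒ type 3. Subtypes: `3-canonical`
   (DUF4981 linker present, core canonical), `3-appended` (decoration
   domains such as LamG3/NPCBM/F5-F8 attached), `3-replaced` (linker or GH2d
   replaced by an unannotated stretch of similar length). Bgal_Small_N takes
   precedence over DUF4982 because it is the type-3 signature.
2. DUF4982 immediately downstream of GH2C with an extension ≥ 60 residues or
   further identified modules ⇒ type 5.
3. A bare unannotated C-terminal extension ≥ 60 residues ⇒ type 4. Sixty
   residues is the smallest extension treated as meaningful, matching the
   lower end of the reported type-4 extension range (60–1053).
4. Otherwise the call is `1or2`: types 1 and 2 share the same single-gene
   architecture and can only be separated by external evidence. A LacM
   partner locus or membership of a subcluster tagged bicistronic resolves
   to type 2; absent evidence the call defaults to type 1, mirroring the
   fact that architecture alone cannot prove bicistrony.

The GH2d-sized-gap rule (`gh2d_like_gap`) accepts a missing GH2d when the
unannotated stretch between GH2N and GH2C falls within 0.7–1.3 times a
reference GH2d length. "Similar length" is not quantified in the source
protocol; the reference defaults to the dataset median GH2d span and both
window and reference are configurable. N-terminal decorations (lectin and
surface-anchoring signals) are recorded as flags and never change the type.

## C-terminal extensions and BIG1 tagging

Extensions are clustered first by length band (defaults 60–300 and
301–1100 residues), then by single-linkage on pairwise global-alignment
identity with a 0.30 threshold. Single linkage on a thresholded identity
graph is exactly connected components — the same partition a tree cut over
an extension alignment produces — but simpler and deterministic; the
threshold is config-exposed because the original subcluster cutoffs are not
published. Identity for clustering uses the shorter-sequence denominator so
terminal overhangs dilute similarity. BIG1 tagging uses the reference-based
denominators (identity = matches / aligned reference positions, coverage =
aligned reference positions / reference length) with strict bounds
(> 0.40 identity, > 0.60 coverage), because the rule is defined by
comparison *against* reference BIG1 exemplars; both bounds are monotone by
construction (lowering either can only add tags). The type-5 letter grammar
is under-specified in the source material; the implementation ships the two
well-attested splits (BIG1-bearing vs BIG1-free extensions, plus
module-decorated C-termini) as a configurable default.

## Alignment

The aligner is an in-house Needleman–Wunsch–Gotoh implementation (Rcpp),
BLOSUM62 with gap open −11 and extend −1 (the community default for global
protein alignment); a gap of length k costs `open + (k−1)·extend`, and
adjacent gaps in opposite sequences each pay the opening penalty. Traceback
ties break deterministically (match/mismatch over gap-in-a over gap-in-b).
The multiple aligner is guide-tree progressive: 3-mer count distances feed a
UPGMA guide tree and profiles merge leaf-to-root with affine
profile–profile alignment; for two sequences it reduces exactly to the
pairwise aligner, and degapping any output row always reproduces its input
(asserted at run time). This stage deliberately replaces an external
aligner binary so the pipeline has no system dependency; aligned FASTA
import (`read_alignment()`) exists for users wanting exact parity with a
third-party MSA, and PHYLIP export supports external maximum-likelihood
cross-checks. Pairwise scores are cross-checked in the test suite against
both an exhaustive enumeration oracle (short sequences) and an independent
affine-gap implementation.

## Distances, neighbor joining, bootstrap

Observed distances are p-distances (differing / comparable columns;
pairwise deletion by default, complete deletion available). The default
correction is the Kimura protein transform d = −ln(1 − p − 0.2p²), with
Poisson and uncorrected options; arguments at or past the domain bound are
flagged saturated rather than clamped. Tree building is Saitou–Nei neighbor
joining with the standard Q criterion: ties break to the lowest index pair
and negative branch lengths are clamped to zero with the deficit logged —
both choices exist purely for reproducibility. NJ here is the package's own
tree stage (an off-the-shelf ML run is deliberately out of scope); on
additive matrices it is exact in topology and branch lengths, which the
tests verify against brute-force least-squares over all 15 five-taxon
topologies and against an independent NJ implementation.

Bootstrap supports resample alignment columns with replacement (100
replicates by default, seed mandatory), rebuild a tree per replicate, and
score each internal edge of the full tree by the fraction of replicates
containing the same bipartition; replicates with saturated distances are
dropped and counted. Condensation contracts edges with support strictly
below the threshold (default 0.5 — "below 50%" reads strictly, so an edge at
exactly 0.5 survives); children of a collapsed node keep their own branch
lengths, and the operation is idempotent.

Concordance between DA labels and the tree is evaluated on the unrooted
topology: a label is monophyletic when some split separates exactly its
leaves; the smallest containing clade (either side of any split) gives
clade size and purity; and the nesting relation reports whether all of
label A's leaves sit strictly inside label B's smallest clade — the formal
version of "bicistronic enzymes emerge from branches of the canonical
clade".

## Conservation profiling

Anchors are (reference id, ungapped position, expected residue) triples;
mapping to an alignment column counts non-gap reference positions, and a
residue mismatch at the mapped column is a hard error to guard against
off-by-one anchor definitions. Column identity defaults to the modal
(consensus) residue with identity-to-reference available, since the source
figures do not define the denominator; gaps never match and are counted in
the denominator by default (configurable). Banding is strict: 100% ⇒
`"100"`, strictly above 50% ⇒ `">=50"`, 50% and below ⇒ `"<50"`. Catalytic
anchor presets for two well-characterised reference enzymes ship as
documented data (`gh2_default_anchors()`), not as hard-coded behaviour.

## The synthetic generator

The generator emulates the domain-gain evolutionary scenario the analysis
presumes: a random bifurcating tree (uniform topology, exponential branch
lengths, mean 0.3 substitution-time units); one ancestral sequence per
module evolving independently site-by-site (substitution probability
1 − e^(−rate·t) per branch, uniform replacement among the 19 alternatives);
the root state is the three-domain core, one well-separated clade gains the
small-subunit module (within it, a strictly internal subclade is emitted as
two loci with a partner map, so bicistronic leaves emerge from *inside* the
canonical radiation), and disjoint clades gain DUF4982 + extension or a
bare extension. Clade choice prefers candidate nodes with long stem edges —
a domain-gain scenario presumes well-separated lineages — which also makes
the painted clades recoverable at moderate rates. Seven GH2C positions are
planted invariant within the type-5-like clade to mimic conserved
active-site residues. Defaults: 60 taxa, rate 0.1 substitutions/site/unit
branch, module lengths near their Pfam model lengths (GH2N 180, GH2d 300,
GH2C 320, DUF4981 100, DUF4982 90, Bgal_Small_N 220, BIG1 100).

Annotation noise is applied only after truth is frozen, so every corruption
is auditable: per-hit dropout, uniform coverage jitter clipped to [0, 1],
and contaminants (an extra blacklist-domain hit, or a duplicated GH2C hit)
that the filter must reject. What the generator does *not* emulate —
insertions/deletions within modules (alignment difficulty is not the
target), an empirical amino-acid exchangeability matrix (the uniform model
is fully specified in-repo; a JTT-like matrix is an extension point),
rate heterogeneity across sites, or horizontal transfer — bounds what
passing tests show about real data: they validate the machinery and the
logic of the classification and concordance analysis, not the aligner's
robustness to gappy homology or the realism of branch-length estimates.

## Problem sizes and determinism

The shipped checks run the default 60-taxon scenario (about 46 GH2C-bearing
records in the tree stage), 100 bootstrap replicates, five replicate
scenario seeds for the concordance claim, 1000 random architectures for the
encoding round-trip, and 200 random additive matrices (4–12 taxa) for the
NJ oracle — sizes chosen so the whole suite completes in a few minutes on a
single core while keeping each claim statistically meaningful. Every
stochastic stage takes an explicit seed and restores the caller's RNG
state; identical seeds give byte-identical simulated datasets, identical
bootstrap supports, and identical representative selections. Classification
agreement under annotation dropout and clade recovery at a given rate are
stochastic quantities: their values fluctuate a few percent across seeds,
which is why the package reports them with the problem size rather than as
constants.

## Known limitations

* DA types 1 and 2 are indistinguishable without companion-locus or
  subcluster evidence; the default to type 1 under-counts bicistronic
  enzymes by design.
* Purity and nesting are computed on splits of the reconstructed tree; a
  basal misplacement of a nested subclade (possible at low rates or short
  stems) turns a true nesting into a sister relation.
* The progressive aligner is a faithful but basic implementation — no
  iterative refinement, no consistency scoring — and is not expected to
  reproduce any specific external aligner's output.
* The 69-slot vocabulary of the original GH2 survey is reproducible only
  from its deposited per-sequence tables, not from first principles; the
  package reproduces the construction rule, not that historical snapshot.
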