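# gh2arch

Domain-architecture classification and catalytic-domain phylogenetics for
family 2 glycoside hydrolases (GH2), in R.

## The scientific problem

GH2 is a large family of retaining glycosidases (β-galactosidases,
β-glucuronidases, β-mannosidases, ...) built around a shared three-domain
core: two N-terminal β-sandwich domains (Pfam `Glyco_hydro_2_N`,
`Glyco_hydro_2` — here GH2N and GH2d) and the catalytic TIM-barrel
(`Glyco_hydro_2_C`, GH2C). What distinguishes the family's functional groups
is the C-terminal side of the molecule: canonical β-galactosidases carry a
DUF4981 linker plus the Bgal_Small_N domain, bicistronic enzymes split that
arrangement over two loci (LacL + LacM), and a divergent group — including
the industrially important high-transglycosylation β-galactosidases — carries
DUF4982 followed by Ig-like modules such as BIG1. `gh2arch` implements the
comparative pipeline behind this picture for anyone classifying GH2-like
datasets or studying C-terminal-domain-driven evolution:

* **DA encoding** — each protein's *domain architecture* (DA: its N→C ordered
  domain composition from Pfam-style envelope coordinates) is encoded as a
  repeat-aware binary vector over a canonical slot vocabulary
  (`Domain_k` slots, bit `(d,k) = 1` iff ≥ k copies of domain `d`).
* **Five-way DA classification** — a sequence enters the analysis with
  exactly one GH2C covering ≥ 70% of the Pfam model and no extra catalytic
  module; it is then typed: **1** core only (β-glucuronidase-like),
  **2** bicistronic large subunit (resolved via a companion LacM locus or a
  tagged GH2C subcluster), **3** canonical β-galactosidase (Bgal_Small_N
  downstream of GH2C), **4** unannotated C-terminal extension ≥ 60 residues,
  **5** DUF4982 linker plus C-terminal extensions.
* **C-terminal extension analysis** — extensions are extracted, clustered by
  length band and single-linkage sequence identity (`Ct_<band>_<k>` labels),
  and tagged **BIG1** when global-alignment identity to a BIG1 reference
  exceeds 40% with reference coverage above 60% (both strict).
* **Catalytic-domain phylogeny** — GH2C regions are aligned (in-house
  progressive aligner, BLOSUM62, affine gaps −11/−1), distances corrected
  with the Kimura protein formula *d* = −ln(1 − p − 0.2p²), trees built by
  neighbor joining with 100 bootstrap replicates and condensed below 50%
  support, then scored for DA-vs-tree concordance (monophyly, clade purity,
  nesting — e.g. bicistronic enzymes emerging from inside the canonical
  clade).
* **Active-site conservation** — reference catalytic residues (e.g. the
  acid/base Glu, nucleophile Glu and acceptor-site Trp of the *B. circulans*
  enzyme) are mapped through the alignment and banded at >50% / 100%
  identity.
* **Synthetic generator** — a fully specified domain-gain evolutionary
  scenario (core-only root; clades gaining Bgal_Small_N, DUF4982+extension,
  bare extensions; one subclade split bicistronically; planted invariant
  active-site columns; annotation noise) so every stage is testable offline
  against known truth.

## Worked example

Simulate the default scenario (60 taxa), classify, build the supported GH2C
tree and check DA-vs-tree concordance:

```r
library(gh2arch)

sim   <- simulate_gh2(synth_config(seed = 42))
calls <- gh2_classify(sim$sequences, sim$hits, companion = sim$partners)
tally_da_types(calls)
#> # A tibble: 5 × 2
#>   da_type     n
#>   <chr>   <int>
#> 1 1          30
#> 2 2           2
#> 3 3          10
#> 4 4           8
#> 5 5          10

msa  <- progressive_align(gh2c_sequences(sim$sequences, sim$hits))
tree <- bootstrap_support(msa, n_replicates = 100, seed = 43) |>
  condense_tree(0.5)
glance(tree)
#> # A tibble: 1 × 5
#>   n_tips n_internal_edges mean_support min_support n_replicates
#> 1     60               57        0.923         0.5          100

truth <- subset(sim$truth, da_type != "lacM")
cc <- concordance(tree, setNames(truth$da_type, truth$seq_id))
tidy(cc)
#> # A tibble: 5 × 5
#>   label     n monophyletic clade_size purity
#> 1 1        30 FALSE                48  0.625
#> 2 2         2 TRUE                  2  1
#> 3 3        10 FALSE                12  0.833
#> 4 4         8 TRUE                  8  1
#> 5 5        10 TRUE                 10  1

subset(cc$nesting, inner == "2" & outer == "3")
#> # A tibble: 1 × 3
#>   inner outer nested
#> 1 2     3     TRUE
```

Reading the output: all 60 planted DA types are recovered exactly (the two
type-2 calls come from the bicistronic partner table); after condensation the
tree keeps 57 internal edges with mean support 0.92; types 4 and 5 are
monophyletic, type 3 is *not* pure on its own because the bicistronic type-2
leaves emerge from inside it — exactly the nesting relation reported in the
last table — while the core-only type 1 is paraphyletic background, as a
root-state label should be. `autoplot()` methods draw the supported tree,
per-type counts and conservation profiles.

A shell interface wrapping the same functions is installed at
`inst/cli/gh2arch` (`simulate | encode | classify | cluster-ct | tree |
conserve | report`).

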