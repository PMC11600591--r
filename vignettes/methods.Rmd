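---
title: "Detecting convergent degeneration of conserved noncoding elements: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergent degeneration of conserved noncoding elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnedegen)
```

# The scientific problem

Conserved noncoding elements (CNEs) are short genomic segments — here tens of
bp to a few kb — kept nearly intact across a clade by purifying selection,
most of them presumed regulatory. When a trait is lost, the elements that
regulated it are expected to decay: substitutions accumulate or the sequence
disappears. Limb loss is a natural experiment for this idea because it
happened independently at least four times among tetrapods (caecilians,
snakes, and separate limbless-lizard lineages), so the same element can be
examined for *convergent* decay across independent lineages. `cnedegen`
implements the detection of such degenerated CNEs (dCNEs), the convergence
classification and rate estimates, the neutral-drift contrast, the enrichment
statistics, a limited-intron-expansion screen for large genomes, and the
annotation layers used to interpret candidate elements.

# Detection model

## Unit of analysis and ancestors

Each element is one gapped multi-species alignment over a common column frame
(`cne_alignment`). All scoring is against reconstructed ancestral sequences.
Ancestors are filled by **Fitch parsimony with gap as a fifth character
state** (`reconstruct_ancestors()`): deterministic, dependency-free, exact for
binary trees, and adequate at CNE-scale divergences where the parsimony root
is essentially the truth (the test suite verifies > 99% identity between
reconstructed and simulated-true roots under the cohort conditions).
A probabilistic reconstruction can be substituted by supplying per-element
ancestor FASTA files (`reconstruct_all(ancestor_override = ...)`); the
scientific content of the method lies in the thresholds, not the ancestral
engine. Because parsimony needs no placeholder tricks to keep fully deleted
sequences in the frame, species that are absent or entirely gapped in an
element are simply treated as uninformative leaves — algebraically identical
to pruning them — and an element with fewer than two informative species is
flagged unreconstructable and excluded.

Two tie-breaks make reconstruction deterministic: in the top-down pass a node
keeps its parent's state when that state is in its candidate set, otherwise it
takes the first state in the fixed order `A, C, G, T, -`; the root uses the
same first-state rule.

## Windows and criteria

Windows are laid on the **ungapped coordinates of the comparison ancestor**
(default: the tetrapod ancestor, i.e. the root of the demo tree) and mapped
back to alignment columns. Laying windows on raw alignment columns instead
would dilute every window with gap columns contributed by unrelated species;
the thresholds are stated in bp of the ancestral element, so that is the scale
the windows must live on.

A limbless species is degenerated in an element when **any** window fires
either criterion (step 1 bp):

| parameter | default | meaning |
|---|---|---|
| `window_short` | 20 bp | short-window width |
| `limbed_conserved_min_short` | 18 | matches a limbed species needs to support a short window |
| `limbless_identity_max_short` | 14 | focal matches at or below which criterion (i) fires |
| `window_long` | 50 bp | long-window width |
| `limbed_conserved_min_long` | 30 | limbed support threshold for the long window |
| `min_limbed_species` | 29 | limbed species required to support a window |
| `absent_fraction` | 1.0 | fraction of focal window positions that must be gap/N for "absent" |
| `lineage_minima` | snake 3, caecilian 2, else 1 | degenerated member species for a lineage call |
| `min_cne_length` | 30 bp (strict >) | retention length filter |
| `gene_link_distance` | 1,000,000 bp | CNE-to-TSS link radius |

Identity is a **count of matching unambiguous bases** over the window; a gap
or `N` in either sequence is a comparable mismatch. Counts, not fractions:
the criteria are defined at 18/20, 14/20 and 30/50, and fractions would blur
the boundary cases the acceptance suite pins down.

Design choices where the published description is open:

* **Comparison node for the focal species.** The limbed-conservation clause
  names the tetrapod ancestor; whether the limbless identity is measured
  against that same node or each lineage's own ancestor is not stated. Both
  are supported (`comparison_node = "tetrapod"` or `"lineage"`); the default
  is the tetrapod ancestor, the node the criteria sentence names.
* **Per-window limbed support.** The ≥ 29-species support is evaluated in
  every window (rather than once per element), following the sentence
  structure of the criteria; a window only counts when conservation and focal
  decay co-occur at the same position.
* **"Absent" = fully gap/N** across the focal window; `absent_fraction`
  exposes a softer reading but defaults to 1.
* **One qualifying window suffices**, and all qualifying windows are recorded
  as evidence (`WindowEvidence` rows), so calls are auditable.
* **Species missing from an element count as not degenerated** at the lineage
  level — the lineage minima exist to guard against assembly artifacts, and
  letting missing data vote for degeneration would defeat that purpose. (In
  the per-species scan, an absent species can still satisfy criterion (ii),
  which explicitly describes loss.)
* **Strict boundary readings** everywhere a threshold is printed as an
  inequality: length "more than 30 bp" means ≥ 31; exon deviation "more than
  40%" rejects only above 0.40; "less than twice the median" is a strict `<`;
  enhancer scores must strictly exceed 2.

## Convergence and rates

Lineage calls aggregate species calls per element; an element degenerated in
*k* ≥ 2 lineages is convergent (class `convergent_k`), with the full
combination table (UpSet-style) reported. The per-species rate divides the
number of convergent elements **in which that species itself is degenerated**
by its time since limb loss. The species-level count (rather than a
lineage-level one) is the only reading under which rates can differ within a
lineage, which the published per-species ranges require.

# Synthetic data: what it emulates, and what it does not

`build_demo_tree()` reproduces the study design: 31 limbed species, 4
caecilians (limb loss ~192 Mya), 6 snakes (~170 Mya) and two single-species
limbless-lizard lineages (40 and 35 Mya), on an ultrametric tree with the
tetrapod crown at 352 Mya and caecilians/snakes attached inside amphibians
and squamates respectively, so each loss is an independent origin.
Per-species substitution rates are drawn log-normally around
1e-3 subs/site/Myr, the order observed for vertebrate neutral rates.

`simulate_cne_set()` evolves each element under GTR (default Jukes-Cantor —
the study's own GTR parameter estimates are not published, so the neutral
default is uninformative and configurable) with branch lengths
`Myr × rate × rate_scale`. Per-branch rates are the mean of the rates of the
leaves below the branch, falling back to the tree-wide mean. `rate_scale`
defaults to **0.03**: conserved elements evolve at a few percent of the
neutral rate, which is what keeps ≥ 90% windowed identity across a
350-Myr-deep clade — the defining property of a CNE. The root sequence is
drawn from the stationary frequencies (the standard assumption), and element
lengths are log-uniform in the configured range because real CNE length
distributions are strongly right-skewed. Elements are spaced 2.1 Mb apart on
a synthetic chromosome so that each element has its own gene neighborhood
relative to the 1 Mb link radius.

`plant_degeneration()` writes ground truth: a *substitution burst* rewrites
the affected interval to an exact target identity against the true tetrapod
ancestor (default 0.55 over 60 bp in the demo scenarios — comfortably below
the 14/20 boundary without being caricature), and a *deletion* replaces the
interval with gap columns, preserving the column frame as an aligner would.
Planted truth is re-measured before being returned.

What the generator deliberately does **not** emulate: realistic indel
processes (no indel length distributions; deletions are planted, not
evolved), context-dependent substitution, rate variation across sites,
alignment error, and assembly artifacts. Consequently, passing the recovery
tests shows the detector implements its stated criteria correctly and
recovers decay under idealised alignments; it does not certify performance on
real whole-genome alignments, where alignment and assembly noise dominate the
false-positive budget (that is precisely why the lineage minima exist).

Feature fixtures (`generate_feature_fixtures()`) follow the same philosophy:
genes at controlled TSS distances with exact boundary instances at 999,999
and 1,000,001 bp; enhancer tracks with scores straddling the threshold
(including one interval at exactly 2.0); an ortholog table in which
designated sets of 127/323/327 genes are limited-expansion per focal species
with a planted 49-gene triple intersection; and an outgroup presence matrix
with known origin ranks. The ortholog fixture *self-verifies*: the emitted
table is re-filtered and re-screened, and generation aborts on any mismatch.

# Statistics

Standard machinery is delegated to R's own implementations behind the module
surface: `stats::fisher.test` (two-sided, probability-mass summation),
`stats::p.adjust(method = "BH")`, `stats::phyper` upper tails, and Welch
`stats::t.test`. The tests validate these surfaces against independent
enumeration oracles (all 2×2 tables at margins ≤ 30; the hand-computed BH
step-up case), so the package's behavior is pinned regardless of the backend.
Odds ratios are reported as the sample `ad/bc`, with the Haldane–Anscombe
+0.5 variant alongside whenever a cell is zero. The limb-gene overlap test
counts **CNEs** as units with the entire CNE set as background (a gene-unit
variant is available behind a flag). Region-set enrichment counts elements,
not bp, matching the convention of region-enrichment tools.

The Monte Carlo overlap test draws each species' gene set independently and
uniformly without replacement — independence across species *is* the null
being tested. The empirical p is add-one smoothed, `(x+1)/(n+1)`, so it can
never be exactly zero; when no trial reaches the observed overlap the report
says so explicitly alongside the smoothed value. The universe size N is a
required input because the filtered ortholog universe it refers to is not
itself published; the z-score therefore reproduces the published *procedure*,
not the published number. The closed-form mean `n1·n2·n3/N²` is used as the
oracle for the trial mean.

The neutral contrast evolves each element's compared ancestor forward for the
ancestor's age (elapsed time = divergence time of the node, not time since
limb loss — branch length is rate × divergence time) at the species' own
neutral rate, 10 replicates per element by default, and compares the three
identity distributions (non-dCNE, convergent dCNE, neutral) pairwise by Welch
t-tests with histogram summaries.

# Annotation layers

Enhancer activity requires ≥ 1 bp overlap with a track interval whose
−log10 p strictly exceeds 2. Pleiotropy is activity in ≥ 2 tissues — the
minimal multi-tissue reading, since no formal definition is published — and
the cohort fraction is computed among elements active somewhere. Origin
assignment takes the deepest hit-bearing outgroup's divergence node on a
configurable ladder (no hits → tetrapod ancestor); it is monotone by
construction (more hits can only deepen the origin). The convergent
amino-acid scan requires a limbed consensus (gap in any limbed species
disqualifies the column), a different residue in *every* member of both
lineages, and ≥ 7 fully conserved columns among the 10 flanking (5 each side,
counted jointly); lineages need not share the same derived residue — the
`identical_derived` flag lets the stricter reading be filtered downstream.

# Numerical and reproducibility choices

* One run seed; every stochastic operation forks its own stream by name
  (`derive_seed()`), so adding a stage never perturbs earlier draws, and
  identical seed + config give byte-identical outputs (the test suite checks
  the end-to-end demo report against a checked-in copy).
* GTR transition matrices come from the symmetrised eigendecomposition
  available for any reversible rate matrix; rows are clamped at zero and
  renormalised against rounding error.
* All genomic coordinates are 0-based half-open internally; GFF is shifted by
  exactly 1 at the boundary, and TSS extraction honors strand.
* Degenerate inputs have defined behavior: zero-variance groups in the Welch
  comparison return t = 0, p = 1 when means agree; a zero Monte Carlo SD is
  flagged and z reported as 0/±Inf; empty interval files parse to empty sets
  with a warning; zero median exon lengths reject the gene with a warning.

# Problem sizes

The cohort sizes used by the tests and the acceptance script are the
package's own validation design: 1,000 random elements (≤ 120 columns, 43
species) for the detector-vs-enumeration equivalence; 500 planted elements
for sensitivity (≥ 0.95 required), per-species false-positive rate (≤ 0.01)
and exact convergence-class recovery; 10,000 bp sequences for the
Jukes-Cantor closed-form checks; 20,000 Monte Carlo trials for the overlap
mean (100,000 in the analysis driver, as published); 200 replicates for the
type-I-error control of the enrichment machinery; and a 120-element
end-to-end demo.

# Known limitations

* Fitch parsimony yields a single point reconstruction; ambiguity is resolved
  deterministically rather than integrated over, which can bias identity
  slightly upward toward the retained states at deep, poorly constrained
  columns.
* The detector assumes the alignment column frame is correct; it has no model
  of alignment error.
* Multifurcating trees are not supported by the reconstruction stage
  (binary-tree check); resolve polytomies upstream.
* The neutral simulator is site-independent GTR without indels, matching the
  published simulation setup but not the full complexity of noncoding
  evolution.
* The intron screen treats "intron length" as the per-gene total; a
  per-intron-median variant would need per-intron tables, which the input
  format does not carry.
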