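---
title: "Methods: ITS-barcode authentication of Dendrobium species"
author: "dendrobarcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ITS-barcode authentication of Dendrobium species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrobarcode)
```

# The problem and the workflow

Medicinal *Dendrobium* orchids of sections *Formosae* and *Chrysotoxae* are
morphologically confusable, and market material is frequently mislabelled.
The nuclear ribosomal internal transcribed spacer (ITS) region —
ITS1–5.8S–ITS2, roughly 630–650 nt in these species — is the standard
barcode used to tell them apart: the 5.8S gene is strongly conserved while
the two spacers accumulate substitutions and small indels at species-level
rates.

`dendrobarcode` implements the complete analysis that such a barcoding
study performs, as composable functions plus numbered drivers under
`analysis/`:

1. partition each amplicon into ITS1 / 5.8S / ITS2 and tabulate lengths and
   GC contents per region and per taxonomic section;
2. align the sequences and count variable (polymorphic) sites per region;
3. estimate pairwise Kimura 2-parameter (K2P) distances;
4. build neighbor-joining (NJ) and maximum-parsimony (MP) trees with
   nonparametric bootstrap support, rooted on an out-group
   (*Pholidota yunnanensis* in the study design);
5. extract angle / stem-length / loop-count features from the four-helix
   ITS2 secondary structure of each taxon and cluster the 12-element
   feature vectors with Manhattan ("Block") distance under average
   ("between-groups") linkage.

Because the study's sequences live in GenBank and this package must be
fully exercisable offline, two kinds of inputs are bundled or generated:
the *printed* 14-taxon K2P matrix and per-species region statistics ship as
plain-text fixtures (`dendrobium_table3()`, `dendrobium_table2()`), and a
synthetic-data generator (`simulate_alignment()`, `simulate_structures()`)
produces sequence sets and structures with the statistical shape the
analysis assumes. A helper, `fetch_genbank_its()`, can download the 13
accessions once on a connected machine, after which
`reproduce_from_accessions()` runs the whole accession-based comparison
offline.

# Region partitioning

The source tables never state how the ITS1/5.8S/ITS2 boundaries were fixed,
so the package adopts a reproducible convention: the 5.8S gene is located
by best semi-global alignment of a user-replaceable 5.8S reference
(`ref_5p8s_path()` bundles a synthetic 163-nt stand-in at the gene's
typical length and GC; replace it with a real 5.8S for real data). The
reference must align with at least 80% identity (`min_identity`,
configurable) or partitioning fails rather than guessing. Boundaries sit at
the first and last reference-aligned columns; ITS1 is everything 5' of the
anchor, ITS2 everything 3' of it, and each region must be non-empty. When a
primer pair is supplied, bases outside the primer footprint are trimmed
first. GenBank records that carry ITS1/5.8S/ITS2 feature annotations use
them directly.

Coordinates are 0-based half-open everywhere internally; reports print
1-based lengths only. GC content is computed over unambiguous bases only —
IUPAC ambiguity codes are excluded from numerator *and* denominator
(a fractional-counting toggle exists) — and is rounded half-up to one
decimal, matching how such tables are conventionally printed
(`round_half_up()`; `base::round()`'s round-half-to-even would differ at
exactly .05). Section summaries average the *unrounded* per-record GC
values and round once at the end.

# Alignment and variable sites

Pairwise alignment is global Needleman–Wunsch with affine gaps; a gap of
length $L$ costs $g_{open} + (L-1)\,g_{ext}$. Defaults are match $+1$,
mismatch $-1$, $g_{open} = -4$, $g_{ext} = -1$. Traceback ties prefer
diagonal, then up, then left, so results are deterministic. The row sweep
is vectorised via a running-maximum identity for the horizontal gap state,
valid whenever $g_{open} \le g_{ext}$; a scalar sweep covers the remaining
corner of parameter space.

The multiple alignment is ClustalW-style progressive: K2P guide distances
from all pairwise alignments (p-distance fallback where K2P saturates), an
NJ guide order, and profile–profile dynamic programming where column–column
scores are mean sum-of-pairs values (gap-vs-base scores $g_{ext}$,
gap-vs-gap 0, ambiguity codes neutral). The original software named in the
study is a GUI package whose exact heuristic is unspecified; exact
replication of its alignments is a non-goal, and the acceptance tolerance
on variable-site counts (±5%) absorbs the heuristic dependence.

A column is *variable* iff it contains at least two distinct states among
`A,C,G,T,-`: the gap counts as a state by default, because the published
per-region percentages imply denominators longer than the shortest
sequence, consistent with counting indel polymorphism. A
`substitutions_only` mode ignores gaps. Ambiguity codes never count as
states. Region ranges within the alignment are obtained by projecting a
designated reference row's partition through its gaps; columns that are
gap-only in the reference attach to the following region (leading columns
to ITS1, trailing to ITS2). Per-section counts are computed on per-section
alignments (the alternative — slicing a global alignment — is available by
passing the global alignment and section row subsets, but per-section
alignment is the default interpretation).

# K2P distances

For two aligned rows, sites where either row holds a gap or ambiguity code
are skipped (pairwise deletion, the default; complete deletion removes
every column with any gap/ambiguity once for all pairs — both policies are
exposed because the study does not state which was used). With transition
proportion $P$ (A↔G, C↔T) and transversion proportion $Q$,

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q),$$

defined while $1-2P-Q > 0$ and $1-2Q > 0$; saturated pairs yield `NaN`
plus a warning instead of aborting the matrix, and `neighbor_joining()`
refuses `NaN` inputs with an instruction to re-estimate. Distances are kept
at full precision and rounded to three decimals only for presentation.
`parse_printed_matrix()` reads a published lower-triangular 3-decimal
layout back into a symmetric matrix, which is how the packaged
`dendrobium_table3()` fixture is loaded.

# Trees and support

`neighbor_joining()` is the Saitou–Nei agglomeration: join the pair
minimising $(m-2)\,d_{ij} - R_i - R_j$, with ties broken by the lowest
taxon-index pair; branch lengths come from the standard two-point formulas,
and negative lengths are clamped to zero with the deficit moved to the
sibling edge (standard practice, logged via `message()`). The result is
unrooted; `root_on_outgroup()` places the root on the out-group's pendant
edge.

`fitch_score()` sums per-column Fitch small-parsimony counts, treating
gaps and `N` as missing (full state set) and IUPAC codes as their state
subsets; the trifurcated root of an unrooted tree is combined
child-by-child, which leaves the unrooted score unchanged. `mp_search()`
hill-climbs by nearest-neighbor interchange from the NJ start tree
(p-distance start when K2P saturates), scanning neighbors in a fixed order
and accepting the first neighbor attaining the best strictly-improving
score until a local optimum; equally parsimonious neighbors never replace
the incumbent. Branch lengths are not estimated for MP topologies.

The study reports "interior branch test" percentages, a t-statistic
specific to the original GUI software. The package deliberately replaces it
with standard nonparametric bootstrap proportions (resample columns with
replacement, rebuild, count bipartitions of the point tree), which is the
reproducible, widely understood support measure and matches the "percent
similarity" scale of the reported values; B = 1000 replicates is the
default throughout, and every stochastic operation takes an explicit seed —
there is no wall-clock seeding anywhere.

# ITS2 structure features

ITS2 secondary structures enter as Vienna dot-bracket or CT files (the
package converts CT losslessly); structure *prediction* is out of scope —
the study used a dedicated web service — but `fold_fallback()` provides a
Nussinov maximum-base-pairing folder (minimum hairpin loop 3, deterministic
leftmost-first traceback) so the feature pipeline can always be exercised.
It is a crude combinatorial folder, not a thermodynamic one, and its
structures should not be mistaken for biological ITS2 folds.

The canonical ITS2 layout is a "four-fingered hand": helices I–IV around a
central loop. `decompose_helices()` finds the central loop (the exterior
loop when two or more stems emanate from it, otherwise the first
multibranch loop reached by descending the single exterior stem) and
treats each emanating stem plus everything distal as one arm, numbered
I–IV in 5'→3' order; extra arms are truncated and missing arms padded with
`(0,0,0)`, both with a warning. An arm's *stem length* is the number of
base pairs along its main stack path (at a branch, the sub-stack with the
most pairs, first on ties); its *loop count* is the number of loops met
along that path — bulges, internal loops, multibranch openings — plus the
terminal hairpin. "Shape" of loops, which the source text mentions but
never defines, is deliberately not quantified.

The study measured helix *angles* from drawn figures; no formula exists to
recover them. The package therefore defines an explicit convention: walking
the central loop 5'→3', every position (unpaired base or helix attachment)
occupies an equal arc of 360°, a helix's angle is its attachment position's
arc, and helix I anchors 0°. Angles are therefore multiples of
$360/n$ for a central loop of $n$ positions, and pairwise angle differences
are invariant under rotation of the sequence start. What is validated
against the published findings is the *clustering* built on these features,
not raw angle values.

`feature_vector()` emits the fixed-order 12-vector
$[\text{angle I–IV}, \text{stem I–IV}, \text{loops I–IV}]$.

# Feature clustering

"Between-groups linkage" is the SPSS name for average linkage, and the
"Block method" is the Manhattan metric; `between_groups_cluster()`
implements exactly that agglomeration with a deterministic tie-break
(smallest original leaf index among candidate pairs) — written in-package
rather than delegated to `stats::hclust()` so the tie-break is guaranteed,
and cross-checked against `hclust(..., "average")` in the tests. Feature
scaling is **off** by default, matching the apparent direct use of measured
values; because raw angles (0–360) would otherwise dominate stem counts, a
per-feature min–max option (`scaling = "minmax"`) is provided, and neither
mode is asserted to be the study's. Dendrograms serialize as ultrametric
Newick with the two children of a height-$h$ node at depth $h/2$.

# The synthetic-data generator

`simulate_alignment()` draws a root sequence with configurable GC bias
(default 0.53, the observed ITS composition scale) and evolves it along a
tree under the K2P model with transition/transversion *rate* ratio
$\kappa$ (default 2), per-region rate multipliers (defaults 1.5 / 0.3 / 1.2
for ITS1 / 5.8S / ITS2, making the 5.8S five-fold slower than ITS1), and
optional spacer-only indels with geometric lengths (the 5.8S stays
exactly 163 nt, mirroring the observed conservation; spacer defaults
230 / 163 / 247 nt follow the observed region lengths). The analysis
drivers simulate along the NJ tree rebuilt from the printed distance
matrix, so section-structured divergence (within-section distances of
roughly 0.003–0.18, out-group 0.23–0.28) holds by construction.
`simulate_structures()` builds dot-bracket structures realizing requested
stem lengths and loop counts exactly and angles snapped to an equal-arc
grid (default 72 positions, 5° resolution), returning the realized feature
vectors; generator and extractor are exact mutual inverses on that feature
subspace, which the tests assert.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: concerted evolution of rDNA repeats, intragenomic
ITS polymorphism, alignment-heuristic artefacts of the original GUI
software, base-composition heterogeneity across lineages, and real ITS2
folding energetics. The accession-based checks in
`reproduce_from_accessions()` exist precisely to close that gap when the
GenBank records are available.

# Numerical choices and problem sizes

* Rounding is half-up at one decimal (statistics tables) and three
  decimals (distance presentation); computation always uses full precision.
* Alignment traceback, NJ joins, MP scanning and cluster merges all carry
  explicit deterministic tie-breaks, so every pipeline rerun with the same
  seed is byte-identical (asserted in the tests).
* The test and acceptance problem sizes are chosen to estimate each
  quantity tightly while keeping a full run interactive: two-taxon K2P
  recovery uses 5 kb sites and 200 replicates per true distance
  (standard error well under the 5% band); topology recovery uses 100
  seeded 6-taxon simulations on a fixed tree with 0.02–0.04 internal
  edges ("moderate divergence": pairwise distances 0.04–0.14, inside the
  study's within-genus range); bootstrap demonstrations use B = 1000 where
  support values are reported and smaller B where only the resampling
  mechanics are under test.

# Known limitations

* The 5.8S anchor convention can shift a boundary by a base or two
  relative to annotation-based boundaries when the spacer ends resemble
  the reference ends; with the bundled synthetic reference this is moot,
  but real-data work should supply a curated 5.8S.
* The progressive aligner has no iterative refinement; heavily gapped,
  highly divergent sets (beyond the ~0.3 distances seen here) will show
  heuristic differences against other aligners, which is why variable-site
  comparisons carry a tolerance.
* `fold_fallback()` maximizes pair counts, not free energy; its folds are
  placeholders for structure input, not predictions.
* NJ negative-branch clamping redistributes length locally; path lengths
  on clamped trees are no longer exactly the matrix entries.
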