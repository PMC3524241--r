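---
title: "Fold-specific structure networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold-specific structure networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psnfold)
```

## The problem and the model

Large folds — the NAD(P)-binding Rossmann fold is the canonical example —
are populated by families whose sequences share little detectable
similarity. Sequence-level conservation scores are therefore weak signals
of what holds the fold together. `psnfold` instead measures the
conservation of *interactions*: residue pairs whose side chains pack
against each other in structure after structure, regardless of which
amino acids happen to realize the contact.

The unit of analysis is the protein structure network (PSN). Residues are
nodes. For a residue pair $(i, j)$ the raw contact count $n_{ij}$ is the
number of side-chain heavy-atom pairs within the contact cutoff (4.5 Å),
and the percent interaction strength is

$$I_{ij} = \frac{n_{ij}}{\sqrt{N_i N_j}} \times 100,$$

where $N_i$ is a residue-type normalization factor expressing how many
side-chain contacts a residue of that type can typically sustain (a
tryptophan can make roughly twice as many atom contacts as an alanine, so
raw counts are not comparable across types). An edge connects $(i, j)$
when $I_{ij}$ strictly exceeds the cutoff $I_{min}$.

Assumptions worth stating explicitly:

* only heavy atoms count — hydrogens are rarely present in crystal
  structures and a 4.5 Å heavy-atom criterion is the established
  convention for side-chain contacts;
* glycine has no side chain and is represented by its C$\alpha$ alone;
  the terminal carboxyl oxygen OXT is treated as backbone;
* covalent neighbours (adjacent in chain order, same chain, author
  numbering differing by at most one) are never connected — their
  proximity is a property of the backbone, not of packing. Chain breaks
  and numbering gaps therefore never suppress a genuine contact;
* the graph is unweighted downstream of the cutoff: betweenness and
  cliques use geodesics on the thresholded graph, not $I_{ij}$-weighted
  paths.

## From one structure to a fold: NAM and f-CAM

Structures of different lengths are made comparable through a gapped
multiple alignment (produced externally, e.g. by MUSTANG; any equal-length
gapped FASTA is accepted). The $k$-th non-gap character of a structure's
alignment row maps its $k$-th residue to that column. Each PSN's adjacency
matrix is expanded to alignment length by inserting all-zero rows and
columns at the gap positions ("phantom residues"), giving the normalized
adjacency matrix (NAM); phantoms have degree zero by construction and are
additionally filtered from all candidate sets. The elementwise sum of the
ensemble's NAMs is the fold-specific combined adjacency matrix (f-CAM):
entry $(c_1, c_2)$ counts the structures whose networks contain that
column-pair interaction.

## Consensus parameters and hot spots

Four parameter sets over alignment columns are intersected:

| parameter | definition | default |
|---|---|---|
| conserved edges | f-CAM pairs in $\ge$ `min_frac` of structures, top `top_k` kept | 0.5, 20 |
| fold-specific hubs | columns with degree $\ge$ `hub_degree` in $>$ `hub_frac` of structures (strict) | 4, 0.5 |
| NB consensus | per-structure top-`k` node-betweenness columns, counted; top `m` ranks kept | 20, 30 |
| EB consensus | per-structure top-`k` edge-betweenness edges, both endpoints counted; top `m` ranks | 20, 30 |

The degree-4 hub cutoff reflects the steric packing limit of side chains:
degree distributions of side-chain PSNs drop sharply above 4. The
half-the-dataset thresholds balance sensitivity against the high sequence
diversity such ensembles are chosen to have; both are configuration, not
constants. Columns supported by all four parameters or by any three are
reported as fold-specific hot spots; the Venn regions are labelled 1 (all
four) and 2–5 (the four triples) in the report tables, everything else
"other".

Where an ordering of hot spots is needed (e.g. the top-25 overlap with
clique participation), they are ranked by number of supporting parameters,
then hub weight, then column index. This ordering is a package choice —
several orderings are defensible and none changes set membership.

## Numerical and tie-breaking choices

* **Contact cutoff is inclusive** ($d \le 4.5$ Å): "within a distance"
  read inclusively; configurable. On crystallographic coordinates the
  boundary set has measure zero, so the choice is documented rather than
  consequential.
* **$I_{min}$ is strict** ($I_{ij} > I_{min}$): an edge must exceed the
  cutoff. A pair at exactly 2% is excluded.
* **All top-$k$ selections are deterministic**: value descending, then
  ascending column (or column pair); exactly $k$ kept. Ties beyond the
  cut are dropped, never carried. The same rule orders the cross-ensemble
  frequency lists. This makes every report reproducible byte for byte.
* **Betweenness is a raw sum** over unordered pairs (endpoint pairs
  included for edges), with no pair-count normalization: only rank order
  is consumed downstream, and ranks are invariant to constant scaling.
* **Alternate locations** resolve to the highest-occupancy conformer,
  ties by altloc identifier; only model 1 of multi-model files is read;
  MSE is read as MET; other modified amino acids are excluded with a
  warning.
* **Degenerate inputs**: empty networks yield empty (not missing)
  reports; the $I_{min}$ overlap of two empty hot-spot sets is reported
  as 0 with a warning; residues without side-chain heavy atoms are kept
  as isolated nodes.

## Normalization factors

The $N_i$ values are configuration with two modes, recorded in every
output header. The default table is the standard side-chain normalization
set of the PSN literature (derived from a statistical survey of contact
capacities per residue type). The `derived` mode computes $N_i$ as the
maximum $n_{ij}$ observed for type $i$ across the input ensemble, making
an analysis self-contained when the dataset is unusual (engineered
residues, unusual packing); types never observed fall back to the default
table with a warning.

## Secondary-structure niches

Conserved edges are classified by the H/E/L labels of their endpoint
residues, per structure. Labels default to the coordinate file's
HELIX/SHEET records — the assignment source is deliberately pluggable (a
two-column external annotation overrides), since record-based assignment
is a stand-in for whatever assignment tool a study prefers, not a claim of
equivalence to any of them. Strand–strand contacts split into mid-strand
(EE_m) and terminus (EE_t) classes: an edge is EE_t when either endpoint
lies within `terminus_window` residues of its strand's end. The default
window of 1 means the first or last residue of the strand run; "strand
terminus" has no universal definition, so the window is exposed.

## Cliques

Only $k = 3$ cliques (triangles) are enumerated — higher-order cliques
are rare in side-chain networks. Two triangles are adjacent for
percolation when they share an edge ($k - 1 = 2$ nodes), the strict
Palla-style criterion; communities are connected components of that
adjacency. A column participates in cliques in a structure when its
residue is in at least one triangle there; columns participating in at
least half the ensemble form the clique-participation set.

## Conservation scores

Per-column Shannon entropy uses base 20 (the amino-acid alphabet), so the
normalized entropy lies in $[0, 1]$; the reported score is $1 - H$, higher
meaning more conserved. Gaps are excluded from both the propensity and
entropy denominators; columns with more than 70% gaps are flagged as
gap-heavy but never dropped, and all-gap columns score `NA`. With few
sequences the entropy has a ceiling ($H \le \log_ {20} n$), so scores have
a floor of $1 - \log_{20} n$ — comparisons against an absolute threshold
such as 0.2 are only meaningful for ensembles of a few dozen structures
or more. The correlation between hub weight and conservation is Pearson
by default (Spearman available); the estimator choice is configuration
because the relationship is monotone but not necessarily linear.

## The planted-ensemble generator

`make_planted_ensemble()` emulates the statistical structure of a domain
ensemble without any geometry: weighted NAMs with planted edges at known
occurrence frequencies, planted hub columns (wired to four private partner
columns so that forced structures reach exactly degree 4), planted
triangles, gap columns, and dominant-residue conservation at the hub
columns with dominance increasing with hub frequency. The reference
defaults are 10 structures over 100 columns with 30 planted edges at
frequencies evenly spaced from 0.3 to 1.0, zero background edges, a 10%
gap rate, planted interaction strengths of 5–10% (all above the 2–4%
cutoff range, so hot spots are invariant across that range by
construction), hub frequencies 1/0.9/0.8/0.6/0.4 and triangle frequencies
1/0.8/0.6. Planting is deterministic — a feature of frequency $f$ appears
in exactly $\mathrm{round}(f \cdot n)$ structures chosen by the seed — so
recovery tests are exact identities, not statistical checks; a Bernoulli
mode exists for stochastic testing.

What the generator does **not** emulate: real side-chain geometry and
rotamers, correlated edges along strands, alignment errors, or the
long-tailed degree distributions of real domains. Passing the planted
recovery suite therefore demonstrates that the bookkeeping — projection,
counting, ranking, intersection — is exact, not that the biological
thresholds are optimal for any particular fold. The toy-structure
generator (`make_toy_structure()`) covers the geometric half: schematic
coordinate files whose engineered contacts are recovered through the full
PDB-parsing and contact-counting path.

## Problem sizes used in validation

The test suite runs entirely on generated fixtures: 200 random graphs of
up to 12 nodes against an exhaustive geodesic-enumeration betweenness
oracle, 100 random graphs against a brute-force triangle scan, 50 random
gapped projections for the NAM invariants, and the reference planted
ensemble for end-to-end recovery. These sizes give exact oracle
comparisons in seconds; the algorithms themselves are polynomial
(betweenness via igraph's Brandes implementation) and handle real domain
ensembles of hundreds of residues per structure without special handling.

## Known limitations

* Interaction strengths are contact counts, not energies; an
  energy-weighted variant is out of scope.
* Betweenness is unweighted; no weighted-geodesic option.
* $k > 3$ clique percolation is unsupported.
* The structural alignment is consumed, never computed; alignment quality
  bounds everything downstream, and column-level results are only as
  comparable as the aligner made them.
* Statistical significance of edge conservation is not assessed — the
  method uses fixed occurrence thresholds by design.
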