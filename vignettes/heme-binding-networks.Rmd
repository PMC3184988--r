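---
title: "Predicting heme-binding residues from residue interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting heme-binding residues from residue interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemenet)
```

## The problem and the model

Heme cofactors (non-covalently bound *b*-type, HEM, and covalently
attached *c*-type, HEC) sit in surface pockets whose residues are hard to
enumerate by eye and expensive to map experimentally. `hemenet` treats a
protein chain as a **residue interaction network**: every amino-acid
residue is a node, and two residues are connected when *any* pair of their
heavy atoms lies strictly below 5 Å — an approximate upper limit for
attractive London–van der Waals contact. On this graph four node measures
are computed with unit edge lengths:

* **degree** $k_i = \sum_j a_{ij}$ — local packing;
* **closeness** $C_i = (N-1)/\sum_{j \ne i} d_{ij}$ — inverse mean
  geodesic distance, a global centrality;
* **betweenness**
  $B_i = \left[\sum_{j<k,\, j \ne i \ne k} g_{jk}(i)/g_{jk}\right] \big/ \tfrac{(N-1)(N-2)}{2}$
  — the normalized fraction of shortest paths routed through $i$;
* **clustering coefficient** $CC_i = e_i / \tfrac{k_i(k_i-1)}{2}$ — how
  clique-like $i$'s neighbourhood is ($0$ when $k_i < 2$).

Residues lining a heme pocket are typically central (high $k$, $C$, $B$)
but loosely packed locally (low $CC$). Raw values are not comparable
between a 60-residue cytochrome and a 500-residue peroxidase, so each
feature is standardized **per structure**, $z_i = (V_i - \bar V)/\sigma$,
before any cross-protein use; $\sigma$ is the *population* standard
deviation over all residues of the structure (the standardization
describes a whole, observed distribution — it is not a sample estimate —
and the choice is fixed for reproducibility). A constant feature maps to
all-zero z-scores. Sections `high` ($z \ge 1$), `medium`
($-1 \le z < 1$), `low` ($z < -1$) summarise the class distributions.

The classifier combines three feature subsets over a **structural window**
of a target residue plus its 14 spatially nearest residues (Cα–Cα
distance; heavy-atom centroid when a residue lacks a Cα):

* **N** — the four topology z-scores;
* **G** — relative accessible surface area plus six-statistic atom depth
  (DPX) and protrusion (CX) profiles;
* **C** — the 20-column PSI-BLAST PSSM row of the position.

Every feature is squashed to $(0,1)$ by the standard logistic
$1/(1+e^{-x})$ *except* RASA, which is already a fraction and enters
unscaled. The model is a C-classification SVM with RBF kernel
$K(x,y) = \exp(-\gamma \lVert x-y \rVert^2)$, $C = 2$,
$\gamma = 0.03125$, trained on all binding residues plus an equal-sized
random draw of non-binding residues (class balancing), and evaluated by
**chain-level** 5-fold cross-validation so homologous residues of one
chain never straddle a fold boundary.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| contact cutoff | 5.0 | Å | heavy-atom contact rule defining network edges (strict `<`) |
| ligand cutoff | 4.5 | Å | heavy-atom distance calling a surface residue heme-binding |
| heme codes | HEM, HEC | — | *b*- and *c*-type hemes; configurable for other porphyrins |
| window neighbours | 14 | residues | spatial context of the target residue |
| probe radius | 1.4 | Å | water probe for the accessibility quadrature |
| quadrature points | 960 | — | golden-spiral sphere sampling per atom |
| CX radius / volume | 10 / 20.1 | Å / Å³ | protrusion sphere and mean heavy-atom volume |
| SVM C, γ | 2, 0.03125 | — | penalty and RBF width used for all predictors |
| decision threshold | 0 | — | sign of the decision value; expose for recall/precision trade-offs |

All of these live in `hemenet_config()` and round-trip through YAML.

## Numerical and design choices

**PDB input.** Only `ATOM`/`HETATM` records are read; waters are dropped;
only the first `MODEL` of NMR-style files is used; alternate locations
resolve to the highest-occupancy conformer with ties broken by altloc
character order (deterministic, standard practice). Insertion codes are
part of residue identity and residue order is file order.
Selenomethionine is treated as methionine; other non-standard residues
are excluded from the node set but remain available as ligand candidates.

**Accessibility and shape.** ASA is computed by Shrake–Rupley quadrature
with a deterministic golden-spiral point set and element radii C 1.87,
N 1.65, O 1.40, S 1.85, 1.80 otherwise (probe 1.4 Å). Residue ASA is
divided by the residue type's Gly-X-Gly tri-peptide maximum and clamped to
$[0,1]$. DPX of an atom is 0 when its ASA is positive, otherwise the
distance to the nearest solvent-accessible atom; CX is
$(V_{sphere} - V_{int})/V_{int}$ with $V_{int}$ the count of heavy atoms
within 10 Å (self included) times 20.1 Å³. These are reimplementations of
the standard definitions, not bit-compatible with any particular external
program — downstream comparisons therefore use tolerances, never
bit-equality. The "buried" filter is exact `ASA = 0` (an epsilon is
configurable).

**Disconnected networks.** Chain breaks can disconnect the graph, where
the plain closeness definition degenerates. The Wasserman–Faust component
correction
$C_i = \frac{n_c-1}{\sum_{j \in comp} d_{ij}} \cdot \frac{n_c-1}{N-1}$
is used ($n_c$ = size of $i$'s component); it reduces exactly to the plain
definition on connected graphs. Betweenness counts only intra-component
pairs; its normalizer stays $(N-1)(N-2)/2$.

**Windows.** Window membership draws on *all* residues, buried ones
included: burial filters which residues are classified, not which provide
context. Ties in neighbour distance break by sequence order. Chains
shorter than 15 residues yield short windows whose missing slots are
exact zeros — distinguishable from real values because logistic-scaled
features are strictly positive.

**Binding labels.** Contacts are called by a plain distance criterion
(any residue heavy atom within 4.5 Å of any heme heavy atom, any heme
group counts). This is a deliberate, configurable approximation of
interface-contact servers used in curated datasets; label-level
disagreement of a residue or two near the cutoff is expected.
`import_labels()` lets an apo chain inherit its holo partner's labels.

**Statistics.** The discriminatory F-score is
$F = |\bar x^+ - \bar x^-| / (\sigma^+ + \sigma^-)$ with population SDs;
group comparisons use Welch's two-sided t-test (switchable to pooled);
paired predictor comparisons use the two-sided Wilcoxon signed-rank test
with zero differences dropped and a normal approximation beyond 25 pairs.
No multiple-testing correction is applied (raw p-values are reported).
ROC curves sweep the continuous decision values with ties grouped; AUC is
trapezoidal and equals the normalized Mann–Whitney U statistic (checked in
the tests). MCC and F1 define $0/0 = 0$.

## What the synthetic generator emulates — and what it does not

Because curated heme-protein datasets require downloads and
database-derived PSSMs, the package ships generators that make every
stage testable in isolation:

* `make_chain()` builds line / helix / cage / random-cloud pseudo-protein
  chains whose contact graphs, buried atoms and surface geometry are known
  by construction (e.g. a 4 Å-spaced line under a 5 Å cutoff *is* a path
  graph; the cage centre *is* buried at depth equal to the cage radius).
* `make_complex()` places ligand atoms at stated distances, so binding
  labels have ground truth.
* `make_random_graph()` and `oracle_metrics()` provide Erdős–Rényi
  substrates and fully independent recomputations (Floyd–Warshall
  distances, exhaustive shortest-path enumeration, $A^3$ triangle
  counting) against which the production BFS/Brandes code is verified
  exactly.
* `make_labeled_dataset()` emulates the *statistical* signature of heme
  interfaces: binding residues draw topology z-scores from unit-SD
  normals shifted by $(+\delta, +\delta, +\delta, -\delta)$, non-binding
  residues from standard normals, at 240 surface residues per chain with
  a 14.7 % binding rate — the class geometry of the published benchmark
  (141 chains, 5035 binding / 29234 non-binding). Only topology features
  are drawn: the generator's null case ($\delta = 0$) must carry *no*
  signal, which forbids independently shifted conventional features.

Passing tests on these fixtures demonstrate correctness of the graph
measures, the geometry code, the labelling logic, the learning loop and
the statistics. They do **not** demonstrate real-data performance:
synthetic chains have no rotamer chemistry, no real heme stereochemistry,
no evolutionary signal and Gaussian rather than empirical feature
distributions. Benchmark-scale figures require the curated chain sets and
database PSSMs those studies used.

A note on attainable accuracy under the synthetic conditions: with
$\delta = 2$ and 14.7 % prevalence, the Bayes-optimal rule at the
balanced operating point has a population MCC of about 0.91, and the
pipeline's cross-validated MCC measures about 0.86 (AUC 0.997) — the
imbalance, not the ranking, is the binding constraint on MCC at the
default threshold. Problem sizes throughout the test-suite (10 chains ×
240 residues; graphs to 50 nodes; 16-residue helices for geometry) were
chosen as the smallest sizes at which each property is informative.

## Known limitations

* mmCIF input, assembly expansion and hydrogen placement are out of
  scope; single chains are analysed independently (no inter-chain
  network edges).
* ASA/DPX/CX values differ slightly from specific external
  implementations (different radii tables and quadratures).
* The distance-based binding labels approximate curated interface
  contacts; residues at the cutoff boundary can differ.
* PSSMs are parsed, never generated: running an iterative profile search
  is the caller's responsibility.
* The Wilcoxon pairing unit (per-residue scores vs per-chain metrics) is
  left to the caller; the package provides the generic paired test.
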