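---
title: "Ranking structure-determining residues: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking structure-determining residues: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdri)
```

## The problem

Which residues of a folded macromolecule hold the structure together? Mutating
a buried, highly connected, conformationally restricted residue tends to be
destabilizing; mutating a floppy surface loop rarely is. This package ranks
every residue (or nucleotide) of a structure by a single score, the
**structure-determining residue identifier (SDRI)**, computed from a
conformational ensemble — an NMR model set or molecular-dynamics frames stored
as a multi-model PDB file. High SDRI marks rigid, well-connected nodes
predicted to be critical for global stability; the complementary profile
`1 - SDRI` tracks disorder propensity along the sequence.

## The model

Each amino-acid residue (or nucleotide) is a network node. For one frame, the
interaction strength of nodes $i$ and $j$ is measured by the **normalized
distance**

$$\bar d_{ij} = \frac{d_{ij}}{r_{vdW_i} + r_{vdW_j}},$$

where $d_{ij}$ is the distance between the nodes' mass-weighted centers of
mass (all atoms of the node) and $r_{vdW}$ is a whole-residue van der Waals
radius. Values below 1 mean the two residue spheres interpenetrate — a strong
contact. Averaging over frames and inverting gives the weighted adjacency

$$a_{ij} = \frac{1}{\operatorname{mean}_t \bar d_{ij}(t)}, \qquad a_{ii}=0,$$

a dense, cutoff-free, symmetric weight matrix: every pair is connected, with
weight decaying smoothly with separation. Row-normalizing $A$ yields a Markov
transition matrix $P$ ($p_{ij} = a_{ij}/\sum_k a_{ik}$); its stationary
distribution solves $\pi P = \pi$, and the **dynamical entropy** of node $i$ is

$$H_i = -\pi_i \sum_j p_{ij} \log p_{ij},$$

its contribution to the chain's entropy rate. Because $A$ is symmetric the
chain is reversible and $\pi_i \propto \sum_j a_{ij}$ exactly — a closed form
the eigen-solver is verified against at every run.

Connectivity alone ignores rigidity, so each node's entropy is divided by its
root mean square fluctuation over the superposed ensemble:

$$\mathrm{SDRI}_i = \frac{H_i}{\mathrm{RMSF}_i}.$$

Scores are min-max normalized to $[0,1]$ and ranked (rank 1 = highest).
A separate, simpler descriptor — the contact **grade** $K_i$, the number of
nodes with any heavy-atom pair within 5 Å — is reported alongside for
comparison; it needs a cutoff and saturates for large residues, which is
precisely what the entropy score avoids.

For stability experiments the package also fits the two-state thermal
unfolding model

$$F(T) = \frac{(y_n + m_n T) + (y_d + m_d T)\,e^{K}}{1 + e^{K}},
\qquad K = \frac{\Delta H_m}{R T_m} - \frac{\Delta H_m}{R T},$$

and evaluates mutant-vs-wild-type stability differences
$\Delta\Delta G = \frac{\Delta H_{m,\mathrm{WT}}}{T_{m,\mathrm{WT}}}\,
(T_{m,\mathrm{MUT}} - T_{m,\mathrm{WT}})$ (thermal) and
$\Delta\Delta G = m_\mathrm{WT}(C_{m,\mathrm{MUT}} - C_{m,\mathrm{WT}})$
(chemical).

## Parameters that matter

* **Radius table** (`vdw_radii()`, Å). Whole-residue radii derived from
  published residue partial volumes under a spherical approximation,
  $r = (3V/4\pi)^{1/3}$. Every downstream score depends on this table; a
  user table can be supplied via `read_radius_table()`. Rankings are fairly
  robust to the parameterization because the radii act as a smooth pairwise
  scale, but absolute weights are table-dependent.
* **`weight_mode`** (`"inverse-of-mean"`, default). Whether frames are
  averaged before or after inverting the normalized distance. The two modes
  differ (Jensen's inequality); inverse-of-mean is the default, with
  mean-of-inverse exposed for sensitivity analysis.
* **`round_decimals`** (4, default). Adjacency weights are rounded
  half-to-even to 4 decimals before normalization; set `NULL` to disable.
  The effect on ranks is negligible for well-formed ensembles.
* **`cutoff`** (5 Å). Heavy-atom contact threshold for the grade only; the
  entropy network is cutoff-free.
* **`log_base`** (`"e"`). Entropy units (nats vs bits). A constant factor:
  normalized scores and ranks are invariant, so the choice is cosmetic and is
  recorded in the output metadata.
* **Superposition** (`"guide"`: Cα / C1′ onto the iterated ensemble mean,
  two refinement passes). RMSF — and therefore SDRI — depends on the fitting
  frame; the selection is recorded in the output metadata. External
  per-residue RMSF (e.g. chemical-shift-derived) can replace the ensemble
  route via `rmsf_file=`; values are consumed as given, in Å.
* **Gas constant** $R = 1.987204 \times 10^{-3}$ kcal mol⁻¹ K⁻¹, matching the
  kcal units of all reported stability differences; overridable.

## Numerical choices

* Stationary distribution: dense eigen-decomposition of $P^\top$, eigenvector
  at the eigenvalue nearest 1, negligible negative components (< 1e-12)
  clipped, renormalized; verified against the residual
  $\max|\pi P - \pi| \le 10^{-10}$ with power iteration as fallback. For the
  symmetric adjacencies produced here the row-sum closed form makes this
  essentially exact.
* $0 \log 0 := 0$ in the entropy sum; the zero diagonal of $A$ survives into
  $P$, so the chain never rests on a node.
* SDRI ranks break ties by node index (stable, deterministic).
* Degenerate inputs fail loudly: zero-weight rows (singular nodes), coincident
  centers of mass, zero RMSF (a static node would give infinite SDRI —
  masking it with an epsilon would silently corrupt the ranking), constant
  score vectors, melting curves without a transition in range.
* Two-state fits: Levenberg–Marquardt with data-driven starts (baselines from
  the outer 20% of points, $T_m$ at the steepest smoothed slope,
  $\Delta H_m = 100$ kcal/mol). A fitted $T_m$ outside the sampled range is
  rejected as a no-transition curve.
* Distribution statistics use bias-corrected sample skewness and excess
  kurtosis (the common statistics-package convention) and the standard
  Shapiro–Wilk W. Skewness and kurtosis are affine-invariant, so raw and
  normalized scores give identical values.

## What the synthetic generator emulates — and what it does not

`make_ensemble()` builds pseudo-residues (glycine-named, 4 heavy atoms) on a
packed lattice, a helical trace, or a two-domain layout (packed core +
extended tail), and jitters each node rigidly and isotropically with per-node
Gaussian amplitude. Defaults for the two-domain case — 30 nodes, 25 frames,
core σ = 0.3 Å, tail σ = 2.0 Å — emulate the fluctuation contrast between a
well-packed core sampled by nanosecond dynamics and a disordered tail. Because
jitter is rigid per node, the node-COM fluctuation equals the injected σ√3 in
expectation, which makes RMSF exactly checkable.

What it does *not* emulate: bonded geometry and excluded volume (nodes can
approach arbitrarily), side-chain size diversity (all nodes are glycine-like,
so radius-table effects are invisible), correlated collective motions, and
anisotropic fluctuations. Passing tests on these fixtures therefore
demonstrate the correctness of the computation and the qualitative
core-vs-tail behavior of the score — not quantitative agreement with any
force-field trajectory of a real protein. Likewise, RMSF from a real MD
engine depends on its superposition conventions, so externally computed
per-residue SDRI values are reproducible only up to that convention.

Problem sizes used in the test-suite and acceptance runs (random-matrix
solver checks up to N = 200; 30–48-node fixtures with 25 frames; 200
replicate melting-curve fits at 1% noise) were chosen as the smallest sizes at
which the checked properties are not trivially satisfied.

## Design choices where the design was open

* **One network per assembly.** All chains form a single network (inter-chain
  contacts matter for complexes); `chain=` filters *before* network
  construction, which changes the network — by design.
* **Node = whole residue.** Centers of mass and radii use all atoms of the
  residue, for nucleotides too (the full nucleotide, not the base alone).
* **RMSF on node centers of mass**, consistent with the node abstraction, not
  the per-atom average; hydrogens contribute to the COM when present and are
  never counted in the grade.
* **Min-max normalization** of SDRI: both extremes are attained, so the
  disorder profile spans the full unit interval and the most rigid node has
  disorder exactly 0.
* **Waters excluded always; ions optionally nodes** (`include_hetero=`),
  since structural metals can be genuine network members.

## Known limitations

* Dense eigen-decomposition is O(N³): fine for the intended a-few-hundred-node
  assemblies, not for megacomplexes.
* Scores from a short or unconverged ensemble reflect that ensemble, not the
  molecule's equilibrium; the tool cannot detect undersampling beyond the
  stationarity and frame-count diagnostics it reports.
* The grade treats all heavy-atom contacts equally; no hydrogen-bond,
  electrostatic or energy weighting.
* Chemical unfolding is closed-form only (midpoints and slope in, ΔΔG out);
  denaturation-curve fitting is out of scope.
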