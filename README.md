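# sdri — ranking structure-determining residues from conformational ensembles

Identifying the residues that hold a protein (or protein–nucleic-acid
complex) together usually means mutating them one by one. `sdri` ranks every
residue of a structure computationally, from a conformational ensemble — an
NMR model set or molecular-dynamics frames stored as a multi-model PDB file —
so that mutagenesis, stabilization and disorder analyses can be targeted. It
is aimed at structural bioinformaticians and protein engineers who have an
ensemble and want a per-residue importance profile without any
sequence-alignment or topology prior.

## The score

Each residue (or nucleotide) is a node. Per frame, node interactions are
measured by the normalized distance *d̄ᵢⱼ = dᵢⱼ / (r_vdWᵢ + r_vdWⱼ)* between
residue centers of mass; frame-averaged and inverted, these give a dense,
cutoff-free weighted adjacency *A*. Row-normalizing *A* gives a Markov chain
*P* with stationary distribution *π* (*πP = π*), and each node's dynamical
Shannon entropy

> *Hᵢ = −πᵢ Σⱼ pᵢⱼ log pᵢⱼ*

measures its connectivity. Dividing by the node's root mean square
fluctuation over the superposed ensemble yields the
**structure-determining residue identifier**:

> *SDRIᵢ = Hᵢ / RMSFᵢ*

High SDRI = highly connected and movement-restricted = predicted critical for
global stability; *1 − SDRI* (normalized) profiles disorder propensity. The
package also computes the contact grade *Kᵢ* (neighbors within 5 Å,
heavy atoms), distribution statistics of the score (skewness, excess
kurtosis, Shapiro–Wilk W), correlation reports against experimental ΔΔG or
K_D data, and two-state thermal-unfolding fits with closed-form ΔΔG for
thermal and chemical denaturation.

## Worked example

Score a synthetic two-domain ensemble — a rigidly packed 15-node core with a
floppy 15-node tail, 25 frames — and inspect the extremes:

```r
library(sdri)
library(dplyr)

ens  <- make_ensemble(30, "two-domain", n_frames = 25, seed = 42)
prof <- run_score(ens)

prof |> arrange(rank) |> select(node, grade, H, rmsf, sdri, sdri_norm, rank) |> head(5)
#>    node grade     H  rmsf  sdri sdri_norm  rank
#> 1    14     8 0.140 0.569 0.246     1         1
#> 2     5    10 0.146 0.595 0.245     0.997     2
#> 3     4     7 0.125 0.538 0.232     0.937     3
#> 4    15     8 0.134 0.597 0.224     0.903     4
#> 5     3     9 0.136 0.618 0.219     0.884     5
```

The top ranks are all core nodes: many contacts (`grade` 7–10), high entropy
(`H`, nats), sub-Å fluctuation. The bottom of the table is the tail —
few contacts, large RMSF, normalized scores near 0 (disorder near 1):

```r
prof |> arrange(desc(rank)) |> head(3)
#>    node grade      H  rmsf   sdri sdri_norm  rank
#> 1    29     1 0.0541  3.68 0.0147   0          30
#> 2    30     1 0.0470  2.78 0.0169   0.00933    29
#> 3    25     4 0.0744  3.65 0.0204   0.0245     28

distribution_stats(prof)
#>       n skewness kurtosis shapiro_w shapiro_p
#> 1    30   0.0915    -1.98     0.764 0.0000157
```

The low Shapiro–Wilk W flags the bimodal core/tail score distribution — the
signature of a partly disordered chain, in contrast to the near-normal
distributions compact globular structures produce.

Real input works the same way: `run_score("ensemble.pdb", out =
"scores.tsv", color_pdb = "heatmap.pdb")` writes a per-residue score table
(with the full run configuration in its header) and a PDB whose B-factor
column carries the normalized score for structure coloring. Thermal
stability, from fluorescence melting curves:

```r
wt  <- fit_thermal_unfolding(make_unfolding_curve(Tm = 330, dHm = 100, noise_sd = 4, seed = 1))
mut <- fit_thermal_unfolding(make_unfolding_curve(Tm = 325, dHm = 90,  noise_sd = 4, seed = 2))
wt
#> <two_state_fit> Tm = 330.04 K, dHm = 101.0 kcal/mol (sigma = 3.66)
ddg_thermal(wt, mut$par[["Tm"]])
#> -1.530  # kcal/mol: the 5 K lower melting point costs ~1.5 kcal/mol
```

A thin command-line wrapper with subcommands `score`, `grade`, `stats`,
`validate`, `thermo-fit` and `synth` is installed at `inst/cli/sdri.R`.

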