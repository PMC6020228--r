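---
title: "Portal-region dynamics and interaction networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Portal-region dynamics and interaction networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(portalwatch)
library(dplyr)
```

## Scope and model system

Fatty acid binding proteins (FABPs) are ten-stranded antiparallel β-barrels
with a helix-turn-helix lid and an internal ligand cavity. Ligand entry and
exit are thought to proceed through the *portal region* — helix α2 together
with the β3-β4 and β5-β6 loops — gated in the myelin protein P2 by the
Phe57 side chain at the tip of the β3-β4 loop. `portalwatch` implements the
trajectory- and structure-analysis layer used to characterise such a
gatekeeper mutant (e.g. P2-F57A): superposition and RMSF, dynamic
cross-correlation maps (DCCM), loop-distance barrel-opening detection,
contact-based residue interaction networks (RINs) with centrality Z-scores,
and the one-site equilibrium membrane-binding fit. It does not run
molecular dynamics itself; trajectories arrive as multi-model PDB files or
from the package's own generators.

A note on numbering: residue numbers are taken verbatim from the input PDB
(conventional FABP numbering, portal gatekeeper at 57). Some mutation
reports count one higher; the package never renumbers, so the user must
supply ranges in file numbering.

## Superposition and fluctuations

Rigid-body superposition uses the Kabsch algorithm (SVD of the 3×3
cross-covariance of the centred point sets), with the reflection case
corrected by flipping the smallest singular vector so the rotation is
always proper. Weights are uniform: all downstream fluctuation analyses
are Cα-level, where mass weighting is immaterial.

`align_trajectory()` aligns each frame by its own best-fit transform
computed on the fit atoms (default: all Cα of standard residues) and
applied to the whole frame. The default reference is the *iterative mean*:
starting from the raw ensemble mean, frames are aligned, the mean is
recomputed, and the cycle repeats until the mean moves by less than the
tolerance (default 1e-9 Å, at most 10 passes). Starting from the mean
rather than the first frame makes alignment idempotent — re-aligning an
aligned trajectory changes nothing — and the result is invariant, up to a
global pose, to any rigid transform applied uniformly to the input. A
`"first-frame"` reference is available as a flag.

Per-residue RMSF is `sqrt(mean_t |r_i(t) − ⟨r_i⟩|²)` about the mean
structure. The DCCM uses the scalar-product (isotropic) definition

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
  {\sqrt{\langle |\Delta r_i|^2\rangle \langle |\Delta r_j|^2\rangle}},
  \qquad \Delta r_i = r_i(t) - \langle r_i \rangle ,$$

computed on Cα atoms over the whole retained window, with no
block-averaging. Residues with zero fluctuation produce `NA` entries
rather than an arbitrary value. `discard_equilibration()` drops the
leading fraction of frames before analysis; the default 1/6 mirrors the
common practice of discarding the first 0.5 µs of a 3 µs trajectory and
analysing the last 2.5 µs.

Segment-level statistics summarise a DCCM block between two named
segments (mean, min, max and the count of pairs at or below an
anti-correlation threshold, default −0.3, exposed as a flag). The shipped
portal segment ranges — α1 14–22, α2 26–34, β3-β4 loop 55–60, β5-β6 loop
74–79 — are editable defaults, not constants: structure annotations vary,
so every report echoes the ranges actually used, and
`default_segments()` accepts overrides. `anticorrelation_loss()` compares
the same block between a reference and a variant; on anti-correlated
blocks a positive Δmean is the signature of lost coupling, as when a
portal mutation decouples the β5-β6 loop from the rest of the portal.

## Distances and opening events

Loop-tip and gate distances are computed on *unaligned* coordinates —
inter-atomic distances are rigid-invariant, so geometry does not depend on
superposition. Three modes are supported: single Cα, group centroid, and
minimum heavy-atom pair distance. The "tip" of a loop defaults to the Cα
of a configured tip residue (β3-β4: 57, β5-β6: 77), echoed in every
report. `gate_distance()` tracks the gate residue's side-chain centroid
against the helix α2 Cα centroid, falling back to Cα (with a warning) for
side-chain-less residues such as the alanine of a gatekeeper mutant.

`detect_opening()` turns a distance series into events: maximal runs of
frames strictly above a threshold, kept when they last at least
`min_dwell` frames. With `min_dwell = 1` the events exactly partition the
frames above threshold; raising the threshold can only lower the open
fraction. The default threshold of 13 Å sits midway between the
synthetic generator's closed (10 Å) and open (16 Å) levels and cleanly
separates them at the default noise; real systems print no such constant,
so it is a tunable flag, and no automatic threshold selection is
attempted.

## Residue interaction networks

Contacts join two residues when the minimum over their heavy-atom pairs
lies in a distance window, default [2.5, 5.0] Å with both endpoints
inclusive (the conservative reading of a printed "2.5–5 Å" window; both
endpoints are configurable). Hydrogens are ignored, water is never a
node, and hydrogen bonds are deliberately not a separate edge type —
these are contact networks only. Sequence-adjacent residues are kept by
default with a flag to exclude them. Edges are unweighted for path
computations; the stored minimum distance is metadata.

Two centralities are reported. *Betweenness* is normalized shortest-path
betweenness with fractional counting over equal-length paths
(normalization `(n−1)(n−2)/2`). *Removal impact* — the interpretation
implemented here of "residue centrality" — is the relative drop in global
network efficiency when a node is deleted,
`(E(G) − E(G∖i))/E(G)`, where `E` is the mean over node pairs of the
inverse shortest-path length and disconnected pairs contribute zero.
Z-scores use the population SD over nodes, and the central set is
`Z ≥ 2` by default, computed on the removal-impact metric with
betweenness selectable — the two rank hubs similarly but not
identically, and neither is claimed to reproduce any specific external
tool node-for-node.

Ligand handling follows the observation that a bound fatty acid, touching
many strands at once, dominates the network when present:
`centrality_report()` flags (and warns) when the ligand node holds the
top betweenness, and analyses are intended to be run with and without
ligand inclusion. `compare_centrality()` reports residues *gained*
(central in at least one variant structure but not the reference — the
union rule, matching how several independent mutant monomers from
different crystal forms are summarised) and *lost* (central in the
reference, in no variant).

## One-site binding fit

Equilibrium surface-binding responses follow `Y = B_max X / (K_d + X)`.
The fit is unweighted nonlinear least squares (Levenberg–Marquardt) with
positivity enforced by log-parameterization; initial guesses are
`B_max⁰ = max(Y)`, `K_d⁰ = median(X)`. Standard errors come from the
linearized covariance at the optimum, mapped to the natural scale by the
delta method, and `R² = 1 − SS_res/SS_tot`. Duplicate injections are
averaged per concentration before fitting (a flag fits raw replicates
instead; with noisy duplicates the two differ slightly, and pooled
averaging is the default because equilibrium points from the same cycle
are not independent observations). The fit is scale-equivariant in the
response and units-equivariant in the concentration, and on noise-free
model data it returns the generating parameters to machine precision.

## Synthetic data: what it emulates, and what it does not

The generators make every stage testable without external data, with
analytic ground truth wherever the downstream estimator can be checked
against one:

- `build_toy_barrel()` places Cα/Cβ pseudo-residues on a cylinder (10
  strands × 6 residues by default, radius 7.5 Å so the inter-strand
  spacing ~4.7 Å falls inside the contact window, mimicking β-sheet
  geometry), with an optional 16-carbon ligand spiralling the cavity
  wall. Full side chains are intentionally absent; RIN tests treat the
  pseudo-atoms as heavy atoms.
- `enm_covariance()` builds the anisotropic elastic-network (ANM)
  Hessian on Cα (cutoff 12 Å, uniform springs), removes the six
  rigid-body modes by eigenvalue truncation (tolerance 1e-8 relative),
  and returns `kT·H⁺` with its analytic DCCM. The anisotropic form is
  used, rather than the isotropic Gaussian variant, so sampled ensembles
  carry directional correlations as real MD does.
- `coupled_block_covariance()` is a one-factor model giving an *exact*
  between-block correlation of `−coupling` — the closed-form ground
  truth used for the loop anti-correlation contrast, which an ENM cannot
  provide in closed form.
- `sample_ensemble()` draws seeded Gaussian frames from any PSD
  covariance; `simulate_opening()` emits a hidden two-state Markov
  distance series (defaults: levels 10/16 Å, transition probabilities
  0.02/0.08 giving a stationary open fraction of 0.2 with mean dwells of
  50/12.5 frames, noise 1.2 Å = 20% of the level separation) and returns
  the true labels; `simulate_binding()` adds Gaussian noise to the
  one-site curve. All generators restore the caller's RNG state and
  embed parameters and seed in their output metadata.

What passing these tests shows — and does not. The ensembles are
Gaussian, stationary and harmonic: they validate the estimators
(alignment, RMSF, DCCM, segment statistics) against known covariances,
but say nothing about anharmonic, multi-basin or slowly-converging
features of real µs MD. The opening simulator validates event detection
against known labels, not the physics of barrel opening. Toy barrels
validate contact detection and centrality exactly, but their pseudo-atom
geometry is far simpler than a real packing. Wet-lab scale quantities
(melting temperatures, crystallographic statistics, µs-scale event
counts) are out of reach at desk scale and are not claimed.

## Numerical choices and problem sizes

DCCM validation ensembles use 5000 frames: the max-abs DCCM estimation
error scales as `1/sqrt(F)` and sits near 0.03 there, against the 0.05
documented bound. The noisy-binding recovery uses 100–200 seeded
replicates at 2% noise. Centrality oracles sweep random graphs of up to 8
nodes, where exhaustive path enumeration is exact. Kabsch is checked
against an independent quaternion-eigenvalue oracle at 1e-9 on random
point clouds. Degenerate inputs fail loudly and early: fewer than 3 or
collinear fit points, fewer than 2 frames, empty selections, dmin ≥ dmax,
non-PSD covariances, all-equal responses, single-residue self-blocks.
Alternate locations other than blank/"A" are dropped at parse time;
insertion codes are an explicit parse error rather than a silent guess.

## Command-line layer

Every analysis is also reachable through `pw_cli()` (and the installed
`exec/portalwatch` wrapper): `rmsf`, `dccm`, `dccm-compare`, `opening`,
`rin`, `rin-compare`, `fit-binding`, `simulate`. A flat YAML config
carries segment ranges and thresholds; flags override the config; unknown
keys are rejected. Result files embed the package version, seed and every
threshold used — and no timestamps, so identical runs are byte-identical.
Exit codes: 0 success, 1 module error, 2 usage error, 3 config error.

## Known limitations

No mmCIF or binary trajectory formats (multi-model PDB only); no PCA or
time-lagged correlations; no kinetic sensorgram fitting; no
energy-weighted or hydrogen-bond networks; no automatic opening-threshold
selection; chains are analysed independently, with no cross-chain
pairing. The removal-impact definition of residue centrality is this
package's documented interpretation and should be compared with
betweenness (both are always computed) when central sets drive
conclusions.
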