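---
title: "Current-flow analysis of residue contact networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Current-flow analysis of residue contact networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathflow)
```

## The model

Allosteric communication in a membrane receptor — how a ligand event at one
site is felt at a distant site — can be quantified by treating the protein's
time-averaged contact network as a resistor network.  `pathflow` implements
this analysis for molecular dynamics (MD) trajectories of receptors with
bound lipids or ligands, the motivating system being a class F GPCR with two
sterol-binding sites (one in the extracellular cysteine-rich domain, one in
the seven-helix transmembrane bundle, roughly 45 Å apart) whose coupling is
probed by injecting "information" at the extracellular sterol pocket and
extracting it at the intracellular ionic-lock residues on helices α6/α7.

**Nodes.**  Every amino-acid residue is one node holding all of its heavy
atoms.  Every selected ligand/lipid molecule (e.g. one cholesterol) is one
*interactor* node holding all of its heavy atoms, so flow *through a
molecule* is a single per-node number.  Waters and monoatomic ions are never
nodes; glycans and other unselected hetero molecules are excluded.

**Edges.**  The contact weight between nodes $i$ and $j$ is the time average
of a Gaussian-smoothed step of the minimum heavy-atom distance $d_{ij}(t)$:

$$ s(d) = \tfrac12\,\mathrm{erfc}\!\left(\frac{d - c}{\sigma\sqrt2}\right),
\qquad
w_{ij} = \frac1T \sum_{t=1}^{T} s\big(d_{ij}(t)\big), $$

with cutoff $c = 4.5$ Å and smoothing SD $\sigma = 1.38$ Å (configuration
accepts `"0.45 nm"`-style values and converts).  $s$ is exactly $0.5$ at
$d=c$, point-symmetric about $(c, 0.5)$, and monotone nonincreasing, so
$w_{ij} \in [0,1]$ is a smoothed contact frequency.  Weights below
`prune_below` ($10^{-4}$) are stored as exact zeros.

**Flow.**  The weighted graph Laplacian $L = D - W$ is the conductance
matrix of a resistor network.  One unit of current is injected, split
equally across the source nodes ($+1/|S|$ each), and extracted equally
across the sinks ($-1/|T|$ each); potentials solve $Lv = b$ with the gauge
fixed by grounding the lexicographically first sink.  Edge currents are
$i_{ij} = w_{ij}(v_i - v_j)$; the throughflow of an interior node is
$F_k = \tfrac12\sum_j |i_{kj}|$ (the current-flow betweenness convention),
and of a source/sink node the magnitude of its net injection.  The
effective resistance is the mean source potential minus the mean sink
potential per unit injected current.  All flows are reported per unit
injected current, which makes values comparable across ligand-occupancy
states; absolute comparability to any particular published flow axis is not
claimed, since such axes are generally in arbitrary units.

## Design choices in detail

Several choices were genuinely open; the package fixes them as follows.

- **Smoothing form.**  A cutoff plus an SD defines a Gaussian-smoothed
  Heaviside step; the complementary-error-function form above is the unique
  choice with midpoint at $c$ and Gaussian width $\sigma$.  Contact
  frequency is the only edge weighting; dynamical-coupling multipliers
  (e.g. generalized correlation) are deliberately out of scope.
- **Node-pair distance.**  Minimum heavy-atom distance, not centroid
  distance: centroid distances miss side-chain contacts, which carry real
  allosteric pathways.  Sequence-adjacent residues keep their edges, since
  backbone-mediated flow (e.g. along a helix extension) is physically
  meaningful.
- **Averaging order.**  Smoothing is applied per frame and then averaged
  (not distance-averaged then smoothed), preserving the contact-frequency
  interpretation.
- **Multi-source/multi-sink convention.**  Equal current split across
  sources and sinks rather than a zero-resistance supernode; per-source
  potentials stay meaningful and conservation is testable node by node.
- **Solver.**  Direct sparse factorization of the grounded Laplacian
  (`Matrix::solve`), with a residual guard of $10^{-9}$ on
  $\lVert Lv-b\rVert_\infty$.  A dense Moore–Penrose pseudoinverse solve is
  kept in the test suite as an independent oracle; the two agree on
  throughflow to better than $10^{-8}$ on hundreds of seeded random graphs.
- **Periodic boundaries.**  Trajectories must arrive whole-molecule imaged;
  the package does not unwrap periodic images.
- **Units.**  Ångström internally everywhere; `"nm"`-suffixed inputs are
  converted on load by a textual decimal shift so unit choice cannot change
  any bit of the result.

## Observables

Alongside flow, the package computes the standard activation observables
used to interpret such simulations:

- **RMSF** per residue after two-pass iterated-mean Kabsch superposition on
  all protein Cα atoms (the whole receptor, not the analyzed subset, so
  domain fluctuations are measured relative to the common frame).
- **Cα pair-distance series** with density-normalized histograms (0.5 Å
  bins anchored at 0), the classic activation metric for outward helix
  movement.  Pairwise distances need no superposition.
- **Hydrogen-bond occupancy** with a 3.0 Å donor–acceptor heavy-atom cutoff
  as the primary criterion; a 150° D–H···A angle criterion is applied only
  when the topology contains hydrogens, since heavy-atom-only topologies
  cannot support it.
- **Ligand stability**: per-frame center-of-mass displacement and heavy-atom
  RMSD of an interactor after protein-based superposition on the first
  frame — a drifting center of mass distinguishes unstable binding from
  in-place reorientation.
- Residue-numbering offsets between species constructs (human versus mouse
  numbering of the same receptor) are handled by a per-chain integer offset
  in configuration, never hardcoded.

## What the synthetic generators emulate

MD ensembles of the scale behind published flow maps (5 replicates × 300 ns
of an atomistic membrane system) are not reproducible on a desktop, and the
original trajectories are not deposited.  The package therefore ships
generators whose ground truth is known by construction, so every analysis
stage is testable end to end through the same public file interfaces
(multi-model PDB plus a YAML ground-truth sidecar):

- `sample_enm_trajectory()` draws frames with per-coordinate covariance
  $(k_BT/\gamma)\,\Gamma^{+}$ from the Kirchhoff matrix $\Gamma$ of an
  elastic network (10 Å cutoff, Cα helix by default), giving the closed
  form $\mathrm{RMSF}_i = \sqrt{3\,(k_BT/\gamma)\,(\Gamma^{+})_{ii}}$
  against which the empirical RMSF must converge (within 5% at 5,000
  frames).
- `generate_bottleneck_system()` builds a source patch and a sink patch
  joined only by a serial bridge (6 Å spacing; dangling background nodes at
  8.5 Å offsets), so every bridge node must carry throughflow 1.  A
  cut-vertex check on the base geometry rejects specs that accidentally
  create a bypass; stray weights below $10^{-3}$ (three orders under the
  path weights) are treated as negligible.
- `generate_two_path_system(r)` emits two disjoint two-edge routes with
  conductance ratio $r$, so the midnode split must be $1/(1+r)$ versus
  $r/(1+r)$.  Keeping the geometry clean (all unintended atom pairs beyond
  the pruning range) caps the per-edge weight near $s(7.1\,\text{Å})
  \approx 0.028$; ratios are exact even though the absolute weights are
  small.
- `generate_state_series()` builds the four-condition occupancy design
  (none / site A / site B / both): site A is an interactor bead lying on
  the source→sink path, site B bridges a side region onto it.  By
  construction, flow through A exceeds flow through B when both are bound,
  and adding B drains flow from A — the qualitative ordering expected when
  a second parallel route opens.
- Synthetic residues are single-heavy-atom beads and interactors are rigid
  3-atom beads, the smallest systems that exercise the real minimum-distance
  and multi-atom-node code paths.  Contact persistence is realized by
  0.2 Å coordinate jitter around base geometries far inside or far outside
  the cutoff.  Per-replicate seeds are `base_seed + replicate`, so replicate
  SEMs are reproducible.

What these generators do *not* emulate: real side-chain packing, lipid
bilayers, force-field energetics, anharmonic conformational transitions, or
the correlation structure of real MD.  Passing the recovery tests shows the
*analysis* is correct, not that any particular biological conclusion is.

A worked structural example ships as
`inst/extdata/smo_two_sterol_synthetic.pdb`: a *synthetic*, clearly-labelled
stand-in containing a Cα helix and two full 28-heavy-atom cholesterol
templates whose centroids are placed 45 Å apart, the separation reported
between the two sterol sites of the motivating receptor.  It exercises PDB
parsing, interactor-node construction (28 heavy atoms per cholesterol) and
the centroid-separation computation; because the geometry is constructed,
the 45 Å figure validates the pipeline, not the deposited structure.

## Numerical conventions and degenerate inputs

- Laplacian solves error (rather than warn) on residuals above $10^{-9}$ or
  on sources and sinks in different components, listing the components.
- Nodes outside the source/sink component get `NA` potentials and zero
  throughflow.
- B-factor output rounds half-away-from-zero to two decimals; min–max
  scaling maps the maximum to exactly 99.99 so values always fit the
  fixed-width column.
- SEM over a single replicate is reported missing (`NA`), never 0.
- Flow tables are written with 6 significant digits; contact graphs are
  serialized at full precision (`%.17g`) and reload bit-exactly, and the
  run manifest records an MD5 of the canonical edge list.
- Trajectory frames concatenate in the order the files are listed, then the
  stride is applied; a topology/frame atom-count mismatch names the file
  and frame.

## Problem sizes used by the tests

The suite and the acceptance script use 5–12-node random graphs (200 of
them for the solver-oracle comparison), 13-node bottleneck systems with 20
frames, 3 replicates of the 13-node occupancy series, and a 20-residue
elastic network sampled for 5,000 frames — sizes chosen so the whole suite
runs in seconds while every statistical recovery claim (5% RMSF tolerance,
90% bridge-flow concentration) still has headroom.

## Known limitations

- XTC trajectories are not read; use multi-model PDB or DCD.
- Hydrogen-bond detection infers attached hydrogens by distance (< 1.25 Å,
  same residue) because PDB input carries no bond table.
- The contact graph is dense in memory (fine for receptor-scale systems;
  not intended for megacomplexes).
- No statistical tests beyond mean/SEM/delta are computed across
  conditions; replicate counts in this field (typically 5) do not support
  more.
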