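---
title: "Methods: from planted trajectories to allosteric networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from planted trajectories to allosteric networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodyn)
```

# The problem and the model

A point mutation far from a binding interface can weaken binding through an
allosteric network: correlated residue fluctuations that carry a
perturbation across the structure. The concrete system behind this package
is the H-Ras–NS1–GDP complex — NS1 is a fibronectin-scaffold monobody that
binds the α4-β6-α5 face of H-Ras and blocks Ras dimerisation, and the
R135K mutation in H-Ras weakens that binding. The analysis chain that makes
this mechanism quantitative is:

1. **Fluctuation statistics** (RMSD/RMSF) to establish equilibration and
   locate flexible regions.
2. **Dynamic cross-correlation** of Cα displacement vectors,
   $X_{ij} = \langle \Delta r_i \cdot \Delta r_j\rangle /
   \sqrt{\langle \Delta r_i^2\rangle\langle \Delta r_j^2\rangle}$,
   and essential-dynamics PCA of the $3N \times 3N$ Cartesian covariance.
3. **A residue network** with edge length $d_{ij} = -\ln |X_{ij}|$ on
   contact pairs, in which optimal (Dijkstra) and suboptimal paths between
   residue pairs quantify allosteric coupling strength.
4. **Interface interaction detection** (hydrogen bonds, salt bridges,
   cation-π) and a per-residue census.
5. **MM/GBSA end-state bookkeeping**,
   $\Delta G_{bind} = \Delta E_{vdW} + \Delta E_{ele} + \Delta E_{int}
   + \Delta G_{GB} + \Delta G_{SURF} - T\Delta S$, with per-residue
   decomposition differences flagged above 0.3 kcal/mol.

Real production trajectories for this system are not distributed with the
package. Instead, a first-class synthetic-data module generates ensembles
with *planted* statistical structure, so that every estimator in the chain
can be validated against an analytic ground truth; the shipped reference
tables (component means, interface distances, path statistics) supply the
published summary-level numbers that the ledger and comparison stages
consume.

# The synthetic-trajectory generator

`sample_correlated_trajectory()` draws frame $t$ as
$r_i(t) = \mathrm{ref}_i + A\,\eta_i(t)\,u_i$ with $\eta(t)$ i.i.d.
standard-normal vectors of correlation $C$ (the planted matrix, factorised
by a symmetric eigendecomposition square root with eigenvalues clipped at
$-10^{-10}$), amplitude $A$ in Å and unit directions $u_i$. Two design
choices matter:

* **A single common direction by default.** With one shared $u$, the
  3-D dot product in the DCCM reduces to a scalar Pearson correlation and
  the *expected* DCCM equals the planted matrix exactly, making parameter
  recovery analytic. Per-site directions are available (used for planting
  PCA modes).
* **Determinism.** The generator seeds R's RNG locally (restoring the
  caller's state), so a model is reproduced bit-identically from its seed,
  and pipeline systems derive their seeds from one top-level seed.

What the generator does *not* emulate: rigid-body diffusion, anharmonic or
multi-basin dynamics, time autocorrelation (frames are independent), and
any force-field physics. Passing recovery tests therefore demonstrates
estimator correctness, not realism of the ensemble.

The study conditions used throughout tests and the acceptance script:
planted correlations $\{0, \pm0.3, \pm0.5, \pm0.9\}$ at $2\times10^4$
frames (Fisher sampling error $\approx (1-\rho^2)/\sqrt{n} \le 0.007$, so
the 0.05 recovery band is comfortably attainable), amplitude 1 Å — a
typical Cα fluctuation scale. The analysis drivers use 24-residue helices
at 2,000 frames, and the unit-test fixtures 3–14 residues at 50–20,000
frames; these sizes were chosen so the full chain (including the
brute-force path oracles) runs in seconds while leaving sampling error
well inside every asserted band.

# Superposition and why recovery runs with it off

`kabsch_superpose()` is the SVD solution of the orthogonal Procrustes
problem; when the optimal orthogonal map is a reflection the smallest
singular direction is flipped, so a proper rotation (det $+1$) is always
returned. RMSD defaults to fitting on the analysis selection with frame 1
(or a supplied structure) as reference; RMSF, DCCM and PCA fit onto the
window-mean structure with one refinement pass (fit to the first frame,
re-fit to the resulting mean).

The DCCM/RMSF/PCA *recovery* experiments disable superposition. The
planted frames already share a reference frame — the generator adds no
rigid-body motion — and least-squares fitting at small $N$ removes the
ensemble common mode, which biases pairwise correlations by $O(1/N)$
(about $-0.07$ at $N = 14$). That bias is a property of fitting, not of
the estimator, so the recovery checks measure the estimator alone; on real
data, where rigid-body motion is present, superposition stays on (the
default).

# Network construction and path enumeration

* **Edges.** A pair gets an edge when it is in contact *and*
  $|X_{ij}| > 0$; $|X| = 0$ contacts are dropped with a warning (infinite
  distance). The published convention reports integer path lengths, so raw
  $-\ln|X|$ weights are scaled by 100 and rounded half-away-from-zero:
  $|X| = 0.5 \mapsto 69$, $|X| = 1 \mapsto 0$. Natural log is used; both
  the base and the scale are configurable. A suboptimal offset of 20 then
  means 0.2 in raw units.
* **Contact gating.** The contact criterion (heavy-atom minimum distance
  ≤ 4.5 Å in ≥ 75% of frames, sequence neighbours $|i-j| \le 2$ excluded;
  Cα mode 8.0 Å) follows the standard dynamical-network protocol; it is a
  package convention, fully configurable, since published analyses often
  leave the gating unstated.
* **Optimal paths** use igraph's Dijkstra; among co-optimal paths the
  result is made deterministic by preferring fewer nodes, then
  lexicographic node order. Disconnected pairs yield an explicit
  `found = FALSE` row, not an error.
* **Suboptimal paths** are all simple paths within `offset` of the
  optimum, enumerated by depth-first search with admissible pruning: a
  branch is extended only while its length plus a reverse-Dijkstra lower
  bound to the sink stays within the budget. A `max_paths` cap marks
  results as truncated lower bounds. The count excludes the optimal path
  itself; node frequencies are tallied over the full enumerated set. An
  independent, unpruned enumerator lives in the test suite as the oracle.
* **Interpretation.** Shorter optimal length, fewer involved residues and
  more suboptimal paths each vote for a stronger allosteric relationship.
  `compare_pathways()` names a system only on a unanimous vote; mixed
  signals return `"ambiguous"` with the majority recorded, because
  published practice adjudicates such cases narratively.

# Interaction detection

Thresholds (hydrogen bond donor–acceptor ≤ 3.9 Å, salt bridge ≤ 4.0 Å,
cation-π centroid ≤ 6.0 Å within 45° of the ring normal) sit within common
structural-biology conventions and were chosen to admit every distance in
the shipped reference geometry (largest hydrogen bond 3.75 Å, largest salt
bridge 3.96 Å); all are arguments. Hydrogen-free structures are judged on
heavy-atom distance alone; when the donor carries explicit hydrogens a
D-H···A angle ≥ 120° is additionally required. Detection scans both chain
orders and de-duplicates, so it is symmetric; aromatic rings with missing
atoms are skipped with a warning.

# Energetics

The ledger is exact bookkeeping: each term is differenced per frame as
complex − receptor − ligand, and
$\Delta G_{bind} = \Delta G_{gas} + \Delta G_{solv} - T\Delta S$ holds
identically by construction (the test suite asserts closure to $10^{-12}$
and the shipped component rows reproduce the published totals to 0.01).
Decisions:

* The **GB polar term is consumed, never computed** — continuum
  electrostatics solvers are out of scope, and keeping the term as input
  keeps the ledger honest and testable.
* $\Delta E_{int} = 0$ by default (single-trajectory end-state convention:
  internal terms cancel).
* $-T\Delta S$ defaults to 0; only relative orderings of binding energies
  are interpreted.
* SDs are population (1/N) SDs, here and in all windowed statistics.
* The per-residue flag uses a **strict** inequality (difference
  > 0.3 kcal/mol), so a printed 0.31 flags and an exact 0.30 does not.
* Nonbonded energies use 332.0637 kcal·Å·mol⁻¹·e⁻², Lorentz–Berthelot
  combining, and plain truncation at 10 Å (no switching function).
* SASA is Shrake–Rupley with 960 golden-spiral points and Bondi radii
  (names no algorithm is standard in end-state reports; this one is
  deterministic and converges to < 0.5% on point doubling).

The shipped component table prints two internally inconsistent
decompositions of the same totals (its polar/nonpolar *solvation* rows
disagree slightly with its GB/SURF *component* rows); the package treats
the component rows as primary, since they sum exactly to the printed gas
and binding totals for both systems.

# Degenerate inputs and numerical conventions

* Zero-variance residues get defined DCCM output (0 off-diagonal, 1 on the
  diagonal) plus a warning instead of NaN.
* DCCM entries are clamped to $[-1, 1]$ against rounding; the matrix is
  exactly symmetric by construction.
* PDB I/O parses by fixed columns via bio3d; per-model atom counts are
  validated before parsing (a mismatch is an error, not a silent recycle),
  altlocs collapse to the highest-occupancy copy (ties: first in file),
  and insertion codes stay part of the residue identity. Coordinates
  round-trip at the format's 3-decimal precision.
* Windowed statistics discard the first 25% of frames by default as
  equilibration burn-in; the window is always explicit in outputs.

# Known limitations

* Correlation-based networks cannot distinguish direct from mediated
  coupling; the $-\ln|X|$ edge length is a convention, not a physical
  distance.
* Suboptimal-path counts grow combinatorially; on dense graphs the cap
  will truncate and the reported counts become lower bounds (flagged).
* The interaction detectors are geometric only — no energetic scoring, no
  protonation-state logic.
* With frames drawn independently, autocorrelation-aware error estimates
  are unnecessary here but would be required on real MD data.
* The SASA implementation is $O(N^2)$ per structure; it is intended for
  the toy systems and modest complexes, not for thousands of frames.
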