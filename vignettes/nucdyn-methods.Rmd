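---
title: "Methods: comparative nucleosome trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative nucleosome trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucdyn)
```

This vignette is the package's own account of what it computes, which knobs
matter, what the synthetic generator does and does not emulate, and where the
design was genuinely open. Nothing below states an empirical result that the
test suite does not itself compute.

## The measurement model

All analyses operate on a `MolecularSystem` (atom identities + one reference
coordinate set, Å) and a `TrajectorySegment` (frames × atoms × 3 array,
times in ns, and a 1-based inclusive analysis window `[start, end]`). The
default window keeps the **final 40 %** of frames: production nucleosome
simulations take hundreds of nanoseconds to equilibrate, and analysing the
stable tail of a 1 µs run (its last 400 ns) is the convention this mirrors.
Every stage that needs a body frame first removes rigid-body motion with
`fit_trajectory`: a Kabsch superposition (SVD of the weighted
cross-covariance, determinant-corrected so a reflection is never selected)
computed on a fit selection — Cα atoms by default, uniform weights — and
applied to all atoms.

When no external reference is supplied the alignment reference is the
*converged window average*: align onto the first window frame, average,
re-align onto that average (two iterations). The energy-minimized references
used in the original workflow are not distributed with trajectory data, so a
self-consistent internal reference is the reproducible default; callers can
pass `reference =` to reproduce an external protocol exactly.

### Local fluctuations and the thirds rule

`site_rmsf` computes, per site group (one Cα per residue, or pooled heavy
atoms per basepair),

RMSF(g) = sqrt( mean over frames of mean over atoms in g of
|x − x̄|² ),

against the window-average structure. Significance of a *difference* between
two systems uses the trajectory-thirds procedure: the window is cut into
three equal contiguous frame blocks (remainder frames dropped at the end —
the simplest way to cut a window into thirds), each third is re-centred on
its own
average and its RMSF computed, and the per-site SD across thirds is taken.
The comparison threshold is **2 × max(SD)** over both systems. With
per-third SDs of ~0.3 Å this generalizes the familiar rule that RMSF
differences above 0.6 Å are highly significant; the package recomputes the
threshold from the data rather than hard-coding 0.6.

Each third is re-centred on its own block average (rather than the
full-window average) so that every per-third estimate is internally
consistent; the cost is that slow drifts inflate the full-window RMSF
relative to the thirds, which is exactly the instability the SD is meant to
flag. Note RMSF²(window) is *not* asserted to exceed the mean per-third
RMSF²; that inequality is not generally true, and the property tests instead
check agreement within sampling error for stationary planted processes.

Chains of different length (the centromeric variant's two-residue loop-1
insertion) are put in register by global sequence alignment
(Needleman–Wunsch, match +2 / mismatch −1 / gap −2) before RMSF deltas are
taken; unmapped sites are reported, never silently dropped.

### Global fluctuations

`com_distance_series` tracks the distance between the **mass-weighted**
centers of two disjoint groups per frame ("centers-of-mass" is taken
literally, while the average *structure* is an unweighted geometric mean —
both documented because the two conventions are easy to conflate). The
standard pairings are the homotetramer (H3-like/H4 vs H3-like′/H4′) and the
two heterotetramers; the open question of whether published dimer COM
distances used all atoms or heavy atoms only is resolved here as **all atoms
of the two chains**, the difference being well below reported SDs.

### Contacts and salt bridges

A residue pair is in contact in a frame iff the minimum distance between
their non-hydrogen atoms is **strictly less than** the 3.6 Å cutoff; strict
inequality makes boundary cases bit-reproducible. Occupancy = contact frames
/ window frames. Contact *counting* is per residue pair: one close atom pair
suffices. In two-system comparisons a pair is **lost** when occupancy ≥ 0.5
in A and < 0.05 in B, **weakened** when the occupancy drop is ≥ 0.25 while
still present, **gained** symmetrically; these thresholds are declared
package conventions (the qualitative source language has no published
cutoffs) and are surfaced in every report. Salt bridges default to 4.0 Å
between basic head-group nitrogens (Lys NZ; Arg NH1/NH2/NE) and acidic
oxygens (Asp OD1/OD2; Glu OE1/OE2), with the charge-center variant (Arg CZ ↔
Glu CD) available for the acidic-patch analyses.

### Essential dynamics and free-energy landscapes

`fit_pca` diagonalizes the 3N×3N covariance (sample covariance, n−1
divisor) of the aligned Cα coordinate vector — unweighted Cartesian PCA on
the Cα coordinates, the standard essential-dynamics choice; mass-weighting
(a common alternative) is deliberately not implemented. A full symmetric
eigendecomposition is used: nucleosome-scale problems (≤ ~1000 Cα, 3N ≤
3000) are comfortably within dense-solver range, so no iterative machinery
is warranted. Eigenvector signs are fixed (largest-magnitude component
positive) for run-to-run reproducibility. The trace identity Σλ = total
positional variance is asserted at 1e−6 relative in the tests.

Mode animations displace a base structure (by default the representative
frame: argmin RMSD to the window average, ties to the earliest frame) by
`s·sqrt(λ)·v` for 21 scalars in [−5, +5], written as multi-model PDB.

`free_energy_landscape` bins the top-2 projections (default 50×50 over the
data range padded 5 %) and sets F = −ln(count/max count) in kBT, so the
deepest bin sits at 0; only relative free energies are meaningful and
unsampled bins are +Inf. `find_basins` sweeps occupied bins in ascending F:
a bin with no previously-assigned 8-neighbour seeds a basin, others join
their lowest neighbouring basin; the first time two basins' components touch
fixes their **bottleneck (minimax-path) saddle** — union-find bookkeeping
makes this exact. Three conventions, all declared because published barrier
numbers of this kind are rarely accompanied by a measurement procedure:

- `min_depth` (default 1 kBT): basins shallower than this relative to their
  lowest saddle merge into the neighbour across that saddle.
- `min_count` (default 3): bins with fewer observations are ignored during
  segmentation — a rim bin holding 1–3 frames is sampling noise, and treating
  it as a "basin" would make basin counts diverge with trajectory length.
  For very sparse landscapes the floor degrades to the maximum observed
  count rather than emptying the grid.
- disconnected basins: a basin with no accessible saddle to any other is
  kept only if its own F-range spans at least `min_depth` (a genuine
  disconnected basin does; an isolated noise island does not). Barriers
  across true gaps are reported as *not accessible*, never extrapolated.

The reported `barrier` is saddle − min(F*ᵢ, F*ⱼ); the saddle height and both
basin minima are returned too, so the alternative convention — measuring
from the shallower basin's minimum instead — is recoverable from the same
output. Both conventions appear in practice and coincide for balanced
basins.

### Events and coincidence

DNA-segment detachment — usually described only qualitatively, as a segment
becoming completely exposed — is operationalized here: the per-frame minimum
heavy-atom distance from the basepair range to the protein core must exceed
**8 Å** for at least **1 % of the window** consecutively, with **1 Å
hysteresis** on re-attachment. Side-chain "swings" are distance series
thresholded at the 3.6 Å contact cutoff. `event_coincidence` matches episode
*starts* within ± a window (default 2 % of frames) and reports the rate,
counts and signed lags; a rate with zero A-episodes is `NA` (undefined), not
0. All constants are config-exposed and echoed in outputs. Coincidence is
temporal association only — no causal claim.

## The synthetic world

`build_toy_nucleosome` places Cα-only protein chains (default: the eight
tailless-construct histone chains, e.g. H3-like 40–135, H4 24–102, H2A
13–117, H2B 27–122) on a helical trace of radius ~34 Å inside a DNA
superhelix of radius 41.8 Å, pitch 23.9 Å, ~89 bp per superhelical turn —
the real particle's dimensions — with two antiparallel strands of
3-proxy-atom pseudo-nucleotides (P, C1′, N1) paired across the dyad at the
DNA midpoint. The inner/outer radii put DNA 3–6 Å from the core, so
contact- and detachment-style analyses behave as they would on real
coordinates. One root seed expands into independent per-stream seeds
(geometry / sequence / noise / modes / switching / events), so adding one
randomness stream never perturbs another; all generators are
bit-reproducible given (spec, seed).

Trajectory generators plant *statistics, not physics*:

- `gaussian_fluctuation_traj`: iid isotropic per-site noise; a site with
  per-coordinate σ has expected RMSF σ√3.
- `planted_mode_traj`: mean + Σ aᵢ(t)·vᵢ with aᵢ ~ N(0, λᵢ) on internally
  orthonormalized directions, plus an optional noise floor — ground truth
  for PCA recovery.
- `two_state_traj`: symmetric Markov switching between two conformations —
  ground truth for basin counting.
- `detachment_scenario_traj`: scripted radial displacement of a basepair
  segment during given frames plus a residue swing starting a fixed lag
  later — ground truth for event detection and coincidence.

What the generator does **not** emulate: solvent, force-field energetics,
sequence-dependent DNA mechanics, autocorrelated dynamics (frames are
conditionally independent given the state), histone tails, and experimental
artefacts. A green test therefore establishes that each estimator recovers
what was planted at the stated sampling — not that any biological claim
about real nucleosomes is true.

## Numerical choices and degenerate inputs

- Superposition requires ≥ 3 non-collinear atoms; collinearity is detected
  via the second singular value and errors rather than returning an
  arbitrary rotation.
- PDB parsing keeps altloc ' '/'A', folds insertion codes into the residue
  key, takes elements from the element column with a name-based fallback,
  and enforces (chain, resnum, atomname) uniqueness. Coordinates round-trip
  at PDB precision (1e−3 Å).
- DCD reading auto-detects endianness and tolerates header frame-count
  mismatches (frames are read until EOF); writing is single-precision, which
  bounds round-trip error at ~1e−5 Å on nucleosome-scale coordinates.
- Ties in representative-frame selection break to the earliest frame;
  eigenvector signs and bin edges are deterministic; reports round to 3
  decimals (Å), 2 decimals (kBT), 3 decimals (fractions).
- Windows are 1-based inclusive `[start, end]` — idiomatic R, deviating
  from the language-agnostic 0-based half-open convention the design
  originally suggested; all window arithmetic is documented at the API
  boundary (`window_final_fraction(10 frames, 0.4)` keeps frames 7–10).
- Rebuilt/variant loop residues are *included* in analysis selections by
  default (exclusion is a caller-side residue filter if wanted).

## Known limitations

- No periodic-box re-imaging: inputs are assumed whole molecules, as
  produced by standard post-processing.
- No XTC reader (DCD covers the binary-trajectory contract here; XTC's
  compression scheme was out of proportion to its value in this scope).
- Barrier estimates inherit histogram noise; the minimax saddle is biased
  slightly low in sparsely sampled saddle regions (visible, and tolerated,
  in the analytic-mixture acceptance test).
- The crystal-structure acceptance checks run against synthetic stand-ins
  that plant the documented facts (147 vs 121 bp, a 2-residue loop-1
  insertion, ≤ 2 Å core agreement) because the real entries cannot be
  downloaded in the build environment; they validate machinery, not
  crystallography. Pointing the same tests at the real PDB files requires
  only replacing the fixture paths.
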