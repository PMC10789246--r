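---
title: "Trajectory maps: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory maps: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmaps)
```

## The model

A trajectory map represents a protein MD trajectory as a residues ×
frames matrix of *shifts*. The shift of residue $r$ at frame $t$ is the
Euclidean distance between the residue's backbone center of mass at $t$
and at a reference frame $t_{ref}$:

$$s(r, t, t_{ref}) = \sqrt{(x_{r,t}-x_{r,t_{ref}})^2 +
  (y_{r,t}-y_{r,t_{ref}})^2 + (z_{r,t}-z_{r,t_{ref}})^2}$$

The point tracked per residue is the mass-weighted center of mass of the
backbone heavy atoms Cα, C, O and N. Using the four-atom COM rather than
the Cα position alone damps intra-residue vibrations and gives the map's
colour axis better dynamic range; `point = "ca_only"` is available for
comparison. Masses come from the topology when it carries them (PRMTOP)
and from standard atomic weights otherwise (C 12.011, N 14.007,
O 15.999 u).

Two reference modes exist:

* **fixed frame** (default: the first frame) — the map shows cumulative
  displacement; a stable conformational change is a horizontal band whose
  left edge marks the onset.
* **previous step** — each frame is referenced to its predecessor. A held
  conformational change contributes only a single column at its onset,
  while an increase in fluctuation amplitude elevates all subsequent
  columns. The two modes together therefore discriminate "moved and
  stayed" from "became floppier", a distinction RMSF alone cannot make.
  Because consecutive-frame differences scale with the sampling interval,
  the stride chosen when loading is critical for this mode.

### Assumptions

* **Alignment is an upstream precondition.** Shifts are raw coordinate
  distances; whole-system rotation/translation must already be removed
  (`gmx trjconv`, `cpptraj align`). The loader warns when the protein
  centroid drifts by more than 10 Å (configurable) over the trajectory,
  the usual signature of unaligned input. Consistently, the Cα RMSD
  overlay performs **no superposition**: a superposing RMSD would
  silently disagree with the map's frame of reference.
* All internal lengths are angstroms; GROMACS-format inputs (nm) are
  converted on read.
* Residues are renumbered 1..R in chain-concatenated order ("map
  serials"), so a homodimer reads e.g. 1–141 and 142–282 continuously;
  original author numbering is retained as row labels in the topology.

## Map algebra

Maps of equal shape support element-wise averaging (2 or 3 replicates —
the arity the workflow exposes; comparing differently shaped systems is
an error, never an implicit resampling) and differencing
(`kind = "difference"`, signed, positive where shifts are stronger in
the first operand). The difference of replicate averages
$(\mathrm{avg}(A,A') - \mathrm{avg}(B,B')) = (A+A'-B-B')/2$ is the
standard four-simulation comparison (apo vs holo, mutant vs wild type).
Region shift-graphs are unweighted means over the selected rows —
unweighted because each row is already a per-residue summary — and
commute with differencing, so the series of a difference map equals the
difference of the series.

Smoothing uses a **centered** moving average with symmetric edge
truncation (window 1 is the identity; output length equals input
length). Centered rather than trailing, because a trailing window lags
event onsets, and onset times are precisely what one reads off a map.
For even windows the extra point falls on the right.

## Rendering

All automatic figure decisions are factored into the pure function
`resolve_style()` so they are testable without reading pixels:

* shift/average maps: sequential scale (default `"Viridis"`) from 0 to
  the observed maximum ([0, 1] Å fallback for an all-zero map);
* difference maps: divergent scale (default `"Blue-Red 3"`,
  blue–white–red) symmetric about zero unless both bounds are set
  explicitly, so zero always maps to the colormap midpoint
  ([−1, 1] Å fallback for an all-zero map);
* values outside explicit bounds are clipped, never an error;
* ticks anchor at frame 0 / serial 1; serial 1 sits at the bottom;
* the RMSD overlay uses its own right-hand axis and never rescales the
  colour mapping.

## The synthetic generator

`generate_fixture()` builds an idealized pre-aligned backbone: 3.8 Å Cα
spacing (extended chain, or an α-helical spiral with 1.5 Å rise and
100°/residue twist), four backbone atoms per residue at fixed
intra-residue offsets. Frame 1 is the exact unperturbed geometry; every
later frame adds independent isotropic Gaussian jitter per atom, plus
programmable ground-truth events: **step displacements** (translation of
a region from an onset frame, optionally ramped linearly — the
displacement multiplier at frame $t \ge$ onset is
$\min(1, (t-\mathrm{onset}+1)/(\mathrm{ramp}+1))$, so ramp 0 gives the
full step at the onset) and **fluctuation changes** (the region's jitter
switches to a new σ).

Defaults (30 residues, 600 frames, σ = 0.3 Å, 4 Å events) are the
validation conditions used across the test suite: frame counts in the
regime where maps read best, jitter that keeps the COM noise floor well
below, but not negligible against, a 4 Å conformational step.

The jitter model is deliberately minimal: independent across atoms and
frames, no temporal correlation, no bonded constraints, no solvent.
Under it the noise floor is analytic — per-atom jitter σ on the four
mass-weighted atoms gives per-coordinate COM noise
$\sigma_c = \sigma\sqrt{\sum_i w_i^2}$ ($\approx \sigma/2$ for
near-equal weights), and the null previous-step shift is a 3-dof chi
variable scaled by $\sigma_c\sqrt2$ — and the tests verify that
expectation by scalar Monte Carlo rather than trusting it. What passing
these tests does **not** show: real trajectories have correlated,
anisotropic motion, so the noise floor of a real map is structured;
ground-truth recovery here validates the computation, not the
statistical significance of any real-data feature.

## Numerical and design choices

* Double precision throughout; vectorized shift computation is checked
  against an independent scalar brute-force oracle to 1e−9 Å in the
  tests (observed agreement ~1e−14).
* Equality tolerances: 1e−9 Å for exact-arithmetic cases, 1e−6 Å across
  the CSV round trip (values are printed with six decimals), 1e−3 Å
  across trajectory-file round trips (float32 NetCDF is ~1e−5 Å at
  protein-scale coordinates; the 0.01 Å text-GRO grid is the coarsest
  supported format).
* Frame indices are 1-based in the R API, as is idiomatic; the CSV frame
  axis is 0-based (`f0`, `f1`, ...), and the previous-step map defines
  the first column as zero.
* A residue missing some backbone atoms (terminal variants, incomplete
  models) uses the COM of the atoms it has; a residue with none of the
  four is dropped with a warning. For PDB alternate locations the first
  altLoc is kept, with a warning.
* Formats: DCD, AMBER NetCDF and multi-frame text GRO trajectories with
  PDB, GRO or PRMTOP topologies, via bio3d/ncdf4 readers (GRO parsed
  natively). XTC is intentionally not parsed; the loader's error message
  points to standard conversion routes.
* The CLI is a single entry point with subcommands rather than separate
  shell scripts; a plain-text config file supplies reusable inputs, and
  explicit flags override it. `--max-frames` computes the stride
  $\lceil F/\mathrm{target}\rceil$ for the 500–1000-frame readability
  guidance.

## Problem sizes used in validation

Oracle-agreement checks run on 100 random ensembles of up to 10 residues
× 20 frames; event-recovery runs the 30 × 600 default fixture; the
statistical assertions use 4-standard-error bands around Monte-Carlo
expectations computed with ≥ 2×10⁴ scalar draws. These sizes make the
full suite run in seconds while keeping every statistical band narrow
enough to be meaningful.

## Known limitations

* No PBC imaging, no solvent or ligand analysis, no multi-model-PDB
  trajectories, no automatic band detection (bands are identified
  visually, by design).
* Difference maps require equal shapes; frame-count matching (e.g.
  truncation of unequal replicates) is left to the user.
* The previous-step map's sensitivity depends on stride; compare only
  maps computed at the same stride.
```{r session}
sessionInfo()
```
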