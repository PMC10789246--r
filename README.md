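# trajmaps

Trajectory maps for protein molecular dynamics: residue-by-frame heatmaps
of backbone displacements, with map algebra, region shift-graphs and RMSD
overlays.

## The method

Classical MD summaries (RMSD, RMSF, R_gyr) are statistical: they tell you
*how much* a structure moved, but not *where* or *when*. A **trajectory
map** answers all three at once. For every residue *r* and frame *t* of a
pre-aligned trajectory it computes the **shift**

    s(r, t, t_ref) = || x(r, t) − x(r, t_ref) ||₂        [angstrom]

where x(r, t) is the mass-weighted center of mass of the residue's
backbone heavy atoms (Cα, C, O, N) and the reference t_ref is by default
the first frame. The residues × frames matrix of shifts is drawn as a
heatmap: x = simulation time, y = residue serial, colour = shift
magnitude. A conformational change appears as a horizontal band whose
left edge is the event's onset time.

Because maps are matrices, they support algebra:

* **replicate averages** — the mean course of a duplicate/triplicate;
* **difference maps** — A − B (e.g. apo − holo, mutant − wild type),
  including the difference of replicate averages
  (avg(A, A′) − avg(B, B′)) = (A + A′ − B − B′)/2, rendered with a
  divergent blue–white–red scale so white is "no difference";
* **region shift-graphs** — the mean shift of a residue range over time
  (a y-slice of the map with the colour scale promoted to the y axis),
  with a centered moving average superposed;
* **previous-step maps** — each frame referenced to its predecessor:
  insensitive to stable conformational changes, sensitive to fluctuation
  amplitude, which separates "moved to a new conformation" from "became
  floppier";
* **RMSD overlays** — the Cα RMSD (no superposition, matching the map's
  frame of reference) drawn over the map to attribute RMSD jumps to
  individual events.

Inputs must be aligned upstream (rotation/translation removed with
`gmx trjconv`, `cpptraj`, ...). Supported pairs: DCD+PDB, NetCDF+PRMTOP,
NetCDF+PDB, and multi-frame text GRO with a GRO or PDB topology. Maps
read best at roughly 500–1000 frames; use `stride`/`--max-frames` to
downsample longer trajectories.

## Worked example

The package ships a small synthetic fixture (`inst/extdata/example.gro`):
6 residues, 20 frames, 0.2 Å jitter, and a programmed (3, 4, 0) Å step —
a 5 Å displacement — on residues 2–4 from frame 11 on
(`example_manifest.json` records the ground truth).

```r
library(trajmaps)
gro <- system.file("extdata", "example.gro", package = "trajmaps")
lt  <- load_trajectory(gro, gro)        # GRO doubles as its own topology
m   <- compute_shift_matrix(lt$topology, lt$ensemble)
m
#> Shift matrix [shift]: 6 residues x 20 frames
#>   values (angstrom): min 0, max 5.307
#>   reference_mode = fixed_frame
#>   point = backbone_com
#>   reference_frame = 0

s <- moving_average(region_shift_series(m, "2-4"), 5)
s
#> Shift series for region '2-4': 20 frames, mean 2.559 angstrom (smoothed, window 5)
round(s$smoothed[8:14], 2)
#> [1] 0.15 1.12 2.08 3.03 4.01 4.98 4.97

render_map(m, map_style(overlay = rmsd_series(lt$topology, lt$ensemble)),
           "example_map.png")
render_shift_graph(s, NULL, "example_graph.png")
```

The map's maximum (≈ 5.3 Å) is the programmed 5 Å step plus jitter; the
smoothed region series climbs from the noise floor to ≈ 5 Å across the
onset, which is exactly how a conformational event reads off a map.

## Command line

The same workflow is exposed as subcommands (launcher in `inst/exec/`),
split into the two steps that make iteration cheap: `preprocess` (slow,
trajectory → CSV shift matrix) and `map` (fast, CSV → figure, re-runnable
to fine-tune the colour scale):

```sh
trajmaps preprocess --traj sim.nc --top sim.prmtop --out sim.csv --max-frames 800
trajmaps map        --in sim.csv --out sim.png --zmax 8
trajmaps average    --in a.csv,a2.csv --out avgA.csv
trajmaps diff       --a avgA.csv --b avgB.csv --out d.csv
trajmaps region     --in d.csv --region '30-40,171-181' --window 10 \
                    --out-csv dna_binding.csv --out-image dna_binding.png
trajmaps simulate   --out-dir fixtures --step '10-20:300:4;0;0'
```

Flags can live in a `key = value` config file (`--config run.cfg`);
explicit flags override it.

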