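# hydrashell

Hydration-shell structure and dynamics from molecular-dynamics
trajectories, in R.

Water at a protein surface is not passive solvent: discrete, long-lived
hydration sites stabilize structure and participate in catalysis, and
how hydration changes with temperature is central to understanding how
thermophilic proteins work. `hydrashell` provides a tested, reusable
implementation of the standard surface-hydration analysis tool chain
for people who have MD trajectories (mesophile-vs-thermophile
comparisons, restrained-MD validation, hydration-site mapping) and want
numbers they can trust:

* **Water density grid** — bulk-normalized 3D water-oxygen density
  ρ(x)/ρ_bulk on a 0.5 Å grid, with ρ_bulk estimated in an 8–10 Å shell
  from the protein surface.
* **Hydration sites (MDHS)** — local density maxima within 1.4 Å with
  ρ/ρ_bulk ≥ 2, classified into first/second hydration shells.
* **Surface G(r)** — water density vs distance from the protein
  surface, sampled in a 4 Å cylinder scanned over Euler angles (20°
  steps) through the center of mass.
* **Residence times** — per-site occupancy autocorrelation
  P(τ) = ⟨δ(W(t), W(t+τ))⟩ fitted with exp(−τ/τ_res); sites with
  τ_res > 1 ns are flagged "superstructured" and excluded from shell
  averages.
* **H-bond lifetimes, RMSF, S², Rg, Cα-RMSD, SASA** — the
  protein-dynamics metrics used to establish corresponding dynamical
  states between homologs.
* **Chemical-shift restraint energetics** — the flat-bottom harmonic
  V = K·ΣᵢΣⱼ max(0, |δᵢⱼ^exp − δᵢⱼ^calc| − εᵢⱼ)² over the six backbone
  shifts, its gradient, and the linear K-ramp schedule
  (K_max = 300 kJ·mol⁻¹·ppm⁻²).
* **Synthetic-data generator** — water trajectories with planted shell
  peaks, Markov hydration sites with exponential dwell times, and
  ground truth, so every stage has a recovery test without external
  data.

Trajectory input is text-based: multi-model PDB or GRO series (convert
XTC/DCD with e.g. `gmx trjconv` first). Orthorhombic boxes only.

## Worked example

Generate a synthetic system with five planted hydration sites on a
spherical scaffold and analyze it end to end:

```r
library(hydrashell)

ctr  <- c(16.5, 16.5, 16.5)   # box center, Angstrom
dirs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1))
sites <- lapply(1:5, function(i)
  planted_site(ctr + dirs[i,] * 7.8,   # 1.8 A from the scaffold surface
               dwell_time = 60,        # ps
               occupancy = 0.9, capture_radius = 0.5))

spec <- synthetic_spec(
  scaffold = list(type = "single_sphere", radius = 6, n_atoms = 256),
  n_bulk_waters = 4911, box = 33, n_frames = 2500, dt = 2,
  sites = sites, seed = 11)
sys <- generate_system(spec)

report <- run_analysis(sys$trajectory,
                       analysis_config(grid_padding = 10.5, max_lag = 400),
                       out_dir = "analysis_out")

report$mdhs$n_total            # 5   : all planted sites found, none spurious
report$mdhs$n_by_shell$first   # 5   : all at 1.8 A -> first shell
report$residence$per_site$tau_ps
# 61.7 53.7 60.1 78.3 56.5     : single-exponential fits of the planted
#                                60 ps dwell (~75 dwell events/site at
#                                this trajectory length -> ~25% spread)
report$residence$by_shell
#   shell mean   sd n n_excluded
#   first  62.1 9.6 5          0
```

`analysis_out/` then contains `report.json`, the OpenDX density map
(`density.dx`), MDHS pseudo-atoms (`mdhs.pdb`, B-factor = peak density),
`gr.csv` and per-site survival curves — all deterministic: rerunning
with the same inputs reproduces `report.json` byte for byte.

The same pipeline runs from the command line:

```sh
Rscript inst/cli/hydrashell.R simulate --spec spec.json --seed 4 --out sim
Rscript inst/cli/hydrashell.R analyze  --topology sim.gro --config cfg.json --out out/
Rscript inst/cli/hydrashell.R compare  a/report.json b/report.json
```

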