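# lipidlens

Trajectory analysis of triglyceride (TG) dynamics around membrane protein
complexes, for people studying lipid-droplet biogenesis with molecular
dynamics. Toroid-shaped assemblies in the ER membrane — an outer ring of
seipin protomers with an inner ring of LDAF1 — capture TG, slow its lateral
diffusion, and concentrate it into a nascent oil lens. `lipidlens` provides
the estimators needed to quantify that behaviour from a trajectory, plus
synthetic generators with known ground truth so every estimator can be
validated without running MD.

## What it computes

* **Dissociation constant** from bound/unbound frame counts:
  `K_D = [TG] · N_unbound / N_bound`, with hysteresis state classification
  from glycerol–residue distance series and a moving-block bootstrap CI
  (`binding_analysis()`, `estimate_kd()`).
* **Lateral diffusion coefficients** from the time-origin-averaged mean
  squared displacement of the TG glycerol beads,
  `D = ¼ d/dt ⟨|r(t₀+τ) − r(t₀)|²⟩_{t₀}` in the XY plane, computed
  separately for TG *within* the protein complex and in the *bulk*
  membrane, with the fold reduction between them
  (`diffusion_analysis()`, `msd()`, `fit_diffusion()`).
* **Per-residue interaction scores** with the logistic contact kernel
  `s = Σᵢⱼ 2/(1 + e^{0.5 rᵢⱼ})` over all TG-bead/residue-bead pairs,
  including an all-atom → coarse-grained mapping step applied before
  scoring (`interaction_score()`, `map_to_cg()`, `profile_peaks()`).
* **Lens nucleation**: single-linkage clustering of TG under periodic
  boundaries, coalescence verdicts, onset frames and chamber localisation
  (`cluster_tg()`, `nucleation_series()`).
* **Lumenal-domain tilt angles** between a residue-pair vector and the
  membrane normal (`tilt_angle()`).

Synthetic ground truth comes from `gen_brownian_trap()` (two-regime 2-D
Brownian dynamics), `gen_two_state()` (exact two-state binding chain) and
`gen_toroid()` (C11 double-ring fixture with planted TG clusters). Units
are Angstrom and nanosecond throughout; trajectories load from GRO, DCD or
a plain-text columnar format (`read_trajectory()`).

## Worked example

Recover two diffusion regimes from a trap trajectory with known
coefficients 1.1 and 0.2 Å²/ns:

```r
library(lipidlens)

cfg  <- brownian_config(n_particles = 300, box_xy = 400, dt = 1, n_frames = 1000,
                        d_bulk = 1.1, d_trap = 0.2, trap_center = c(200, 200),
                        trap_radius = 50, n_trap_init = 100, seed = 42)
traj <- gen_brownian_trap(cfg)
sel  <- build_selection(list(tg = list(resname = "TG")), traj$atoms)
res  <- diffusion_analysis(traj, sel, region_model(c(200, 200), 50, 60),
                           window = 250)
res$fits$bulk
#> D(bulk) = 1.121 +/- 9e-04 A^2/ns   (R^2 = 0.9999, window 25-125 ns)
res$fits$complex
#> D(complex) = 0.1762 +/- 0.00092 A^2/ns   (R^2 = 0.9973, window 25-125 ns)
```

The fitted coefficients bracket the ground truth; the ratio (here
6.36 ± 0.03) is the fold reduction in TG mobility inside the complex.
A dissociation constant from a two-state binding series with
`KD_true = k_off/k_on = 0.5`:

```r
bs <- gen_two_state(two_state_config(k_on = 0.02, k_off = 0.01, tg_conc = 1,
                                     dt = 1, n_frames = 2e5, seed = 42))
estimate_kd(bs, n_boot = 400, seed = 1)
#> KD = 0.5186 (same unit as [TG] = 1)
#>   95% block-bootstrap CI: [0.4849, 0.5539]  (block 300 frames, 400 reps)
#>   N_bound = 131697  N_unbound = 68303  transitions = 2667
```

The KD carries the unit of `[TG]` verbatim (mol% in a typical setup), and
the transition count flags how well the binding equilibrium was sampled.

The full battery — diffusion, binding, interaction profile, lens detection,
tilt — runs through one YAML-configured call, `run_all()`, which writes a
`report.json` echoing every default, unit and seed; a thin command-line
front end lives in `inst/cli/lipidlens.R` (verbs `generate`, `analyze`,
`validate`).

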