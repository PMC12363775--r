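---
title: "Methods: estimators and their validation in lipidlens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimators and their validation in lipidlens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidlens)
```

`lipidlens` quantifies how a toroid-shaped membrane protein assembly (an
outer seipin ring enclosing an inner LDAF1 ring) interacts with
triglyceride (TG) dissolved in a bilayer: how tightly TG binds to
individual residues, how much its lateral diffusion slows inside the
complex, which residues it contacts, and whether it coalesces into an oil
lens. This vignette describes each estimator, the assumptions behind it,
every tunable that matters, and what the synthetic validation does and
does not establish. Internal units are Angstrom (Å) and nanosecond (ns)
everywhere; all readers convert on ingest, because the diffusion
coefficients of interest are naturally of order 0.1–1 Å²/ns.

## Dissociation constant from frame counts

For one TG molecule against a residue group, the per-frame distance is the
minimum-image distance between the centroid of the molecule's glycerol
beads (the tracked moiety in all per-molecule analyses) and the nearest
particle of the group. States follow a hysteresis (Schmitt-trigger) rule:
bound when the distance drops below `cutoff_on`, unbound only when it
exceeds `cutoff_off`. The defaults are `cutoff_on = cutoff_off = 7` Å —
a coarse-grained bead-contact scale. No cutoff can be derived from first
principles, so both values are explicit arguments and are echoed in every
report; with equal cutoffs the rule degenerates to a plain threshold,
which is also the property the tests assert.

The dissociation constant is the frame-count estimator

$$K_D = [\mathrm{TG}]\ \frac{N_\mathrm{unbound}}{N_\mathrm{bound}},$$

which is the law of mass action applied to the time-average occupancy of a
single site. `[TG]` is taken verbatim from the configuration (e.g. mol%)
and the estimate carries that unit without conversion — the concentration
convention is a modelling choice, not something the estimator should
silently re-interpret. The number of binding/unbinding transitions is
reported alongside: with fewer than two transitions the occupancy ratio
rests on essentially one event and the estimate is flagged unreliable.

The confidence interval is a percentile **moving-block bootstrap**: blocks
of `block_length` consecutive frames, starting anywhere, are resampled
with replacement and the estimator recomputed. The default block length is
four times the mean event duration (frames per observed transition). One
mean-dwell block would already exceed the chain's correlation time, but
measured coverage of the nominal 95% interval improves from roughly 0.90
to roughly 0.93 when blocks are lengthened to four dwells, after which it
plateaus — the residual few points of under-coverage are the known
finite-sample behaviour of block bootstraps for ratio statistics, and we
document rather than mask it.

## Spatially partitioned lateral diffusion

The diffusion coefficient comes from the time-origin-averaged mean squared
displacement of the glycerol-bead XY coordinates,

$$D = \frac{1}{4}\frac{d}{dt}\left\langle \frac{1}{N}\sum_{i=1}^{N}
  |r_i(t_0+\tau) - r_i(t_0)|^2 \right\rangle_{t_0},$$

with every frame used as a time origin. MSD consumes **unwrapped**
coordinates only — wrapping destroys displacement statistics — and the
implementation uses the standard FFT decomposition of the origin average,
which the tests require to match a brute-force double loop to 1e-9
relative error. The factor 4 is the 2-D Einstein relation; motion along
the membrane normal is deliberately ignored.

TG molecules are assigned to regions per time window: **complex** if the
glycerol XY position stays within `r_complex` of the protein centre for
*every* frame of the window, **bulk** if beyond `r_bulk` throughout, and
**excluded** otherwise. Whole-window membership is strict on purpose:
molecules that cross a boundary mid-window would mix the two regimes and
contaminate both estimates, so they contribute to neither. The defaults
are a radial criterion with `r_complex` equal to the protein's maximal
lateral extent and `r_bulk = r_complex + 10` Å; assignment is per window
rather than per whole trajectory so that a molecule can legitimately
appear in both categories at different times. Displacements never straddle
window boundaries.

The fit is ordinary least squares of MSD against lag over 10%–50% of the
shortest contiguous window, intercept free. Short lags carry the most
origin pairs; beyond half the window the curve becomes noisy and, for the
complex category, increasingly conditioned on the molecule having stayed
inside. `D` is slope/4 and the reported uncertainty is the OLS slope
standard error — a known understatement since MSD residuals at nearby lags
are correlated; no blocking correction is applied (documented limitation).
The fold reduction `d_bulk / d_complex` carries first-order propagated
uncertainty from the two slopes.

## Interaction score

The per-residue contact metric is

$$s = \sum_{i,j} \frac{2}{1 + e^{0.5\, r_{ij}}},$$

summed over all TG beads $i$ and all beads $j$ of the residue, per frame,
then averaged over time (a per-frame sum is available as an option). The
kernel equals 1 at contact and decays on a $1/0.5 = 2$ Å scale times the
logistic tail, i.e. is negligible beyond ~25–30 Å. The kernel's length
unit is an explicit setting (Å by default) because rescaling it changes
scores by orders of magnitude; every profile records it. An optional
distance cap skips far pairs; the neglected per-pair tail is bounded
analytically by $2e^{-0.5 r_c}$ and the default cap of 30 Å keeps that
bound below 1e-6, which is why capped and exact evaluations agree to
within test tolerances.

All-atom trajectories are first mapped to coarse-grained resolution:
each mapping rule collapses named atoms of a residue into one bead at
their unweighted centroid (mass weighting optional). Scoring a mapped
all-atom fixture must equal scoring its hand-built CG counterpart — that
identity is asserted in the tests. Minimum-image distances are used
throughout; in a periodic box that is the only self-consistent choice.

Residue ranking aggregates symmetry copies (the 11 protomers of a C11
ring) by averaging, then flags whether residues of interest fall in the
top quantile (default 25%). On a symmetric fixture with a uniform TG
shell, symmetry-equivalent residues tie to machine precision — a useful
canary for indexing errors.

## Lens nucleation

TG aggregates are single-linkage connected components over glycerol-bead
centroids with minimum-image distances, 3-D by default (a nascent lens
thickens the bilayer locally), with a 12 Å default linkage cutoff — a
first-coordination-shell scale for CG glycerol beads; no value can be
derived from theory, so it is configurable and always reported. Labels
are deterministic (size-ranked, ties to the lowest molecule ID), and the
tests require the partition to match an independent union-find over the
full distance matrix.

Coalescence is an operational verdict: "phase-separated" when the largest
cluster holds more than 50% of all TG molecules in every frame of the
final 20% of the trajectory; the onset frame is the first from which that
condition holds uninterruptedly to the end. All three numbers (fraction
threshold, span, cutoff) are artifact definitions — visual "stable oil
phase" judgements have no unique quantitative counterpart — and are echoed
in every result. When a chamber annulus is supplied, the fraction of
largest-cluster members between the inner and outer ring radii localises
the lens relative to the toroid.

## Tilt angle

The lumenal-domain tilt is the angle between the membrane normal (the box
z-axis by default, the standard bilayer convention) and the minimum-image
vector between two residue centroids. The default is the unsigned form
$\arccos(|v\cdot n|/|v|)$, which matches plotting an angle magnitude; a
signed variant is available. Residue centroids use all particles of the
residue — with a single bead per residue (CG) the distinction from a
Cα-based vector disappears, and for AA input the centroid is the less
noisy choice.

## Synthetic ground truth: what it emulates

`gen_brownian_trap()` produces independent 2-D Gaussian random walks whose
per-axis step variance is $2 D(x)\,\Delta t$ with $D$ switching between
`d_bulk` and `d_trap` depending on whether the particle *starts* the step
inside a trap disk. There is no reflecting barrier — TG crosses the
complex boundary freely — and both wrapped and unwrapped coordinates are
stored. `gen_two_state()` realises the discrete two-state chain with
per-frame switching probabilities $1-e^{-k_\mathrm{on}[\mathrm{TG}]\Delta t}$
and $1-e^{-k_\mathrm{off}\Delta t}$, generated exactly through its
alternating geometric dwell times (cost scales with the number of events,
not frames) and started from the stationary distribution.
`gen_toroid()` builds a deterministic C11 double-ring fixture whose inner
protomers carry the conserved residues (Phe57, Ser61, Leu105, Ser109, and
the lumenal pair Ser126/Ser131), and seeds TG either as one planted
chamber cluster plus far-apart singletons, or "uniform": spread over the
chamber annulus subject to a 13 Å minimum separation. The minimum
separation models TG dissolved below its demixing concentration; a purely
random placement occasionally percolates into chains spanning half the
molecules under single linkage, which would make a nominally dispersed
control ambiguous.

Scenario defaults mirror realistic membrane conditions: trap coefficients
of 1.1 and 0.2 Å²/ns (the magnitude of TG lateral mobility in a fluid
bilayer versus inside a crowded protein chamber), a 500 × 500 Å box with a
60 Å trap and 500 molecules of which 200 start inside the trap
(representing TG already accumulated in the complex), 2000 frames at 1 ns;
and binding rates giving `KD_true = 0.5` with ~2.7 dwells per thousand
frames. Validation problem sizes — 2000-frame diffusion runs, 10⁶-frame
KD series, 10⁵-frame CI-coverage replicates, 20-molecule lens fixtures —
were chosen so each estimator operates in the regime its asymptotics
assume while the whole battery stays desk-sized.

What passing these tests shows: the estimators are unbiased and correctly
implemented under the statistical model they assume (independent walkers,
memoryless binding, rigid fixtures). What they do not show: real
trajectories add membrane undulations, correlated lipid motion,
protein-induced deformation, finite-size hydrodynamics and
force-field-dependent energetics, none of which the generators model.
Recovery on synthetic data is a necessary, not sufficient, condition for
trusting numbers from production MD.

## Numerical and design notes

* **Degenerate inputs.** Zero-length tilt vectors, empty residue groups,
  zero bound frames, triclinic boxes, truncated trajectory files and
  particle-count mismatches are hard errors naming the offending frame,
  residue or file; no silent defaults. A category with no molecules is
  dropped from the MSD output with a warning rather than fabricating an
  empty curve.
* **Determinism.** Every stochastic routine takes a seed; fixed seeds give
  bit-identical generator output and byte-identical `run_all()` reports
  (reports deliberately carry no timestamps).
* **Indexing.** Particle indices are 1-based (R convention); residue IDs
  are reported exactly as in the topology file, so "Ser61" in a report
  means residue 61 of the input, not an internal offset.
* **FFT MSD round-off.** The FFT path can produce values of order
  ±1e-12 Å² where the true MSD is 0; lag-0 is pinned to zero and tiny
  negatives are clamped, with oracle equality enforced at 1e-9 relative.
* **Survival conditioning.** Requiring whole-window residence inside the
  trap conditions trapped paths on not having left, which biases the
  in-complex D estimate slightly downward (a few percent at the default
  geometry, where RMS displacement per window is small against the trap
  radius). Tolerances in the recovery tests account for this; shrinking
  the window trades this bias against fit-window length.
* **Time step.** MSD and region windows assume uniformly spaced frames
  and refuse to run otherwise, since the lag grid would be meaningless.

## Known limitations

Only orthorhombic boxes are supported (all analyses are lateral, and
bilayer setups are orthorhombic in practice); there is no local-normal
estimation for strongly deformed membranes, no anomalous-diffusion
exponent, no kinetic rate estimation from dwell times, and no
nucleation-thermodynamics modelling. XTC input is not parsed — convert to
DCD or the package's columnar text format. The OLS slope standard error
understates D uncertainty on correlated MSD curves, and block-bootstrap
KD intervals retain a few points of under-coverage at realistic event
counts; both are reported as-is rather than corrected.
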