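---
title: "Modelling tumour control under fractionated radiotherapy with radca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tumour control under fractionated radiotherapy with radca}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`radca` simulates an orthotopic tumour (calibrated for PC3-like prostate
xenografts in mice) as a cellular automaton on a square lattice, and asks
how fractionated irradiation schedules translate into tumour control
probability (TCP). Each pixel is one cell-sized patch of tissue (15 µm,
225 µm²) in one of six states: empty space, viable tumour (labelled
normoxic or hypoxic for display), quiescent normal tissue, a blood vessel
crossing the plane, or a tumour cell carrying lethal damage that will die
at its next division (mitotic catastrophe). One time step is one day, the
approximate cell-cycle time of the modelled line.

The simulation couples four mechanisms:

1. **Growth by peripheral division.** Only cells within `n_layers`
   (default 3) of the tumour boundary divide, implemented morphologically:
   the non-dividing core is the n-fold binary erosion of the tumour mask
   (3×3 structuring element, 8-connectivity) and the available space is
   the n-fold dilation minus normal cells, vessels and the tumour itself.
   Layers divide outermost-first; each dividing cell places one daughter
   on a uniformly random free site of the growth area while free sites
   remain. A lethally damaged cell selected to divide is instead removed —
   this is how mitotic catastrophe clears cells, and why tumours shrink
   only when they are free to cycle.
2. **Steady-state oxygen.** Vessels are single pixels placed uniformly at
   random over the whole domain (density 3.8%), including inside the
   tumour, which must be perfused for the observed oxygenation to arise.
   The O2 field is the vessel indicator image (scaled by per-vessel leak
   multipliers) convolved with a peak-normalized isotropic Gaussian of
   `sigma` = 2.4 px, so an isolated vessel yields
   `O2(x) = s exp(-x²/2σ²)` with `s` the wall concentration;
   contributions sum and the summed field saturates at 5% O2. Homeostasis
   is assumed (no explicit consumption term), so the field only changes
   when vessels change.
3. **Radiation kill.** Each fraction of dose `D` kills a tumour cell with
   probability `1 − exp(−α Deq − β Deq²)` where `Deq = D / HRF(O2)` and
   the Howard-Flanders hypoxia reduction factor
   `HRF = (mK + O2)/(K + O2)` (m = 2.804, K = 0.001076 on the O2-fraction
   scale) raises radioresistance up to 2.8-fold at anoxia. Killed cells
   become lethally damaged, not absent. All cells are growth-arrested for
   `9 h/Gy` (36 h after 4 Gy), and vessels respond in two ways: each
   fraction "hits" a vessel with an endothelial LQ probability, after
   which its oxygen output is multiplied by the leak factor 1.5 (hits do
   not compound), and doses above 6 Gy kill vessels outright with a
   probability rising linearly to 1 at 35 Gy (dead vessels become empty
   space and stop sourcing oxygen).
4. **Cohorts and TCP.** An "in-silico mouse" is one seeded realization:
   20 days of unchallenged growth from a 1.5 mm disk (7845 cells), then
   the protocol. A tumour is controlled when no viable cell remains —
   an absorbing condition, since nothing recreates viable cells — and
   TCP(total dose) is the controlled fraction of the cohort evaluated
   after each fraction. The curve is summarized by the sigmoid
   `TCP(Dt) = 1/(1 + exp(−λDt + δ))`; `TCP50 = δ/λ` with a delta-method
   (or bootstrap) confidence interval.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `grid_side` | 600 | px | domain size (9 × 9 mm) |
| `tumour_radius_px` | 50 | px | initial disk, 7845 cells |
| `normal_fraction` | 0.20 | — | obstacles outside the tumour |
| `vessel_density` | 0.038 | — | vessels per pixel, whole domain |
| `n_layers` | 3 | layers | dividing rim thickness |
| `sigma` | 2.4 | px | oxygen kernel width (D = σ² = 5.76 px²) |
| `s` | 0.02356 | O2 fraction | wall amplitude (calibrated, below) |
| `cap` | 0.05 | O2 fraction | saturation |
| `hypoxia_threshold` | 0.002 | O2 fraction | display/metric split only |
| `alpha`, `beta` | 0.0441, 0.0898 | 1/Gy, 1/Gy² | tumour LQ at 21% O2 |
| `hrf_m`, `hrf_K` | 2.804, 0.001076 | —, O2 fraction | Howard-Flanders curve |
| `alpha_ec`, `beta_ec` | 0.28, 0.045 | 1/Gy, 1/Gy² | vessel hit LQ (surrogate) |
| `leak_factor` | 1.5 | — | O2 boost of hit vessels |
| `vessel_death_threshold/max` | 6 / 35 | Gy | vessel-death ramp |
| `arrest_slope` | 9 | h/Gy | growth-arrest duration |

`alpha_ec`/`beta_ec` deserve emphasis: they are *surrogate* values of the
magnitude typical for endothelial clonogenic survival. They belong to the
configuration, not to the calibrated core, and should be refitted when
endothelial data are available. At conventional fraction sizes nearly all
vessels are hit within the first two fractions, so the downstream effect
of their exact values is modest.

# Calibration pipelines

Four free quantities are pinned by `calibrate_*`/`fit_*` functions, each
of which has a noise-free self-consistency test (generate from the model,
recover exactly):

- `fit_o2_profile()` fits `s` and `sigma` to single-vessel O2-vs-distance
  measurements (µm or px; mmHg converted as fractions of 760 mmHg).
- `calibrate_amplitude()` fixes `s` so mean tumour O2 at initialization is
  3%, averaged over seeded vessel placements. Because the pre-cap field is
  linear in `s`, one convolution per seed suffices and bisection on the
  capped mean (continuous, non-decreasing) is exact to tolerance 1e-6.
  The shipped default 0.02356 is this calibration at the default geometry
  with seeds 1–5.
- `calibrate_diffusion()` sweeps `sigma` over the profile-fit range,
  re-calibrating `s` at each candidate (a deliberate choice: the
  amplitude is a nuisance parameter of the tissue-level conditions, so it
  is re-anchored rather than frozen at the single-vessel fit), and keeps
  candidates whose mean hypoxic fraction (< 0.2% O2) stays below 1%;
  among them it returns the mean-O2-closest, ties toward the smallest
  sigma.
- `fit_hrf()` fits (m, K) of the Howard-Flanders curve, by default from
  the standard starting point (2.7, 0.002).
- `calibrate_leak_factor()` and `calibrate_growth_layers()` are parameter
  sweeps against a hypoxic-fraction time series (2 Gy daily reference
  protocol) and an unirradiated growth curve; both recover their
  generating value exactly in round-trip tests because the simulator is
  seed-deterministic.

# Numerical choices

- **Kernel.** Peak-normalized (value 1 at zero lag), truncated at 4σ;
  neglected contributions are < e⁻⁸ of the peak. Zero boundary: tissue
  outside the domain sources no oxygen. The 2D convolution is computed as
  two banded-Toeplitz sparse products (the separable form), identical to
  direct 2D convolution to machine precision and fast enough to refresh
  the field whenever vessels change; growth days reuse the cached field,
  which is exact because growth moves no vessels.
- **Morphology.** Erosion/dilation run on the tumour bounding box padded
  with an explicit zero frame, so lattice borders behave as empty tissue;
  site ordering inside the box is column-major like the full grid, which
  keeps the sampled growth bitwise identical to a whole-lattice
  implementation (verified against a naive per-pixel loop oracle).
- **Arrest ordering.** Within a day: fraction first, then growth if no
  arrest is pending, then the timer loses 24 h. Gating growth on the
  *pre-decrement* timer makes any same-day fraction block that day's
  division even when its arrest is shorter than 24 h (18 h at 2 Gy).
  The alternative (decrement first) would let daily 2 Gy tumours grow
  every day, contradicting the observed treatment-phase growth arrest the
  arrest mechanism exists to produce; weekends then re-open the cycle,
  clearing lethally damaged rim cells and re-expanding surviving ones.
- **Degenerate inputs.** Empty tumours make hypoxic/mean-O2 metrics
  undefined (explicit errors); all-0 or all-1 TCP curves refuse the
  sigmoid fit; a fraction of 0 Gy changes nothing while still consuming
  the same random draws, which keeps RNG streams aligned across biology
  scenarios (this alignment is also why disabling vessel death below
  6 Gy/fraction is bitwise inert).
- **Seeds.** Mouse `i` of a cohort uses `base_seed + i − 1`; every random
  choice flows from the run seed, making trajectories and cohorts
  bitwise reproducible.

# What the synthetic generators emulate

`make_fixtures()` produces calibration tables from the model's own
equations (optionally with multiplicative noise) plus growth and
hypoxia-series trajectories from a scaled-down tissue (240 px grid, 20 px
tumour). They exercise schema handling and parameter recovery; they do
not stand in for real measurements — real O2 profiles have non-Gaussian
tails and anisotropy, real growth curves plateau, and real hypoxia series
carry measurement noise that the round-trip tests deliberately exclude.
Passing those tests shows the fitting machinery is correct, not that the
biology is.

The test suite runs the full physics on reduced problem sizes (50–300 px
grids, cohorts of 5–24 mice) chosen so the entire suite completes in a
few minutes; the absolute-scale quantities (calibrated field metrics and
the 100-mouse TCP cohort at 600 px) are recomputed by
`scripts/acceptance.R`.

# Known limitations

- **The hypoxia condition is marginal at σ = 2.4.** The calibrated field's
  hypoxic fraction (tumour area below 0.2% O2 at initialization) is
  heavy-tailed across random vessel placements (roughly 1.0–1.3% on
  average with a seed-to-seed standard deviation of ~0.7 percentage
  points), so whether a batch of twenty placements averages just below or
  just above 1% depends on the seeds. σ = 2.4 sits at the feasibility
  boundary of the two tissue-level oxygen conditions rather than
  comfortably inside it.
- **Near-anoxic pockets dominate late control.** At σ = 2.4 with the
  amplitude calibrated to 3% mean tumour O2, random vessel placement
  leaves a small tail of tumour pixels (a few per ten thousand) below
  0.1% O2, where the HRF approaches its anoxic maximum and per-fraction
  survival at 3 Gy exceeds 0.8. The dose needed to control the *last*
  viable cell is therefore set by this tail, not by the tumour bulk: the
  acceptance cohort (3 Gy daily, full biology) puts TCP50 near 67 Gy,
  roughly 25 Gy above what the bulk kill rate alone would give. Pocket
  depth falls steeply as σ grows, so conclusions about absolute TCP50
  levels — though not about protocol orderings — are sensitive to the
  oxygen-kernel width within its measurement uncertainty.
- 2D cross-section with a spherical volume extrapolation
  (`V = 4/(3√π) s_c^{3/2} N^{3/2}`); no 3D lattice.
- No senescence or apoptosis (mitotic catastrophe is the only death
  mode), no cell migration or cycle phases, no vascular regrowth, no
  normal-tissue complication modelling, and no adaptation to repeated
  exposure.
- Growth is linear-front; real tumours saturate, so the model applies
  below the sigmoidal inflection of real growth curves.
- Uniform dose across the grid; no sub-daily scheduling.

# Session

```{r}
library(radca)
geom <- geometry_params()
ox <- oxygen_params()
radio <- radiobiology_params()
prot <- protocol(frac_dose = 3, total_dose = 60)
traj <- run_simulation(geom, ox, radio, prot, seed = 1)
tail(traj)
```
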