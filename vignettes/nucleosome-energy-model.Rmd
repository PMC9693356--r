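---
title: "Deformation-energy models of nucleosome positioning with rotpos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformation-energy models of nucleosome positioning with rotpos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotpos)
```

## The model

A nucleosome wraps ~147 bp of DNA into a tight superhelix.  Whether a
given stretch of genome tolerates that wrapping depends on sequence: each
of the 16 dinucleotide steps has its own preferred geometry (equilibrium
values of the six base-pair step parameters — twist, roll, tilt, shift,
slide, rise) and its own stiffness.  rotpos scores a window of DNA by the
harmonic cost of deforming every step from its equilibrium geometry onto a
superhelical template:

$$E \;=\; \frac{1}{L-1}\sum_{j=1}^{L-1} \tfrac{1}{2}\,
\bigl(\theta_t(j)-\theta_0(d_j)\bigr)^{\!\top} F(d_j)
\bigl(\theta_t(j)-\theta_0(d_j)\bigr)$$

in units of kT per base-pair step (kT/bps).  Two restrictions of the
quadratic form are computed: **bending energy** keeps only the roll/tilt
block (the rotational channel — which helical face contacts the histones)
and **shearing energy** keeps only the shift/slide block (the
translational channel).  Cross-terms between the two groups, and all
twist/rise terms, are excluded: the two energies are meant to be
independent read-outs of the two positioning modes, and mixing the blocks
would let the dominant twist cost swamp both.

The template imposes roll and tilt sinusoids in quadrature at the helical
frequency $\Omega = 2\pi/\text{period}$ with amplitude $\rho$
(degrees/step), i.e. a uniformly curved superhelix, plus a small slide
sinusoid in phase with roll and zero shift for the shearing channel.
Defaults: period 10.0 bp/turn, $\rho = 4.5^\circ$/step (approximating the
1.65-turn crystallographic superhelix), window 101 bp.  The 101-bp window
is a deliberate compromise: the natural 147-bp footprint is longer than
many linkers and smears narrow nucleosome-depleted regions, while much
shorter windows make the energy too noisy.  Windows of 75 and 129 bp are
selectable; the template is always rebuilt at the requested length with
unchanged $\rho$ and $\Omega$.

From the energy track (normalized per genome to $[-1,1]$), two occupancy
estimators are derived:

* **Model 1** — Boltzmann scores $p_i = e^{-\beta E_i}$ (default $\beta =
  1$) convolved with the Gaussian center weight $w_k = e^{-\frac12
  (k/20)^2}$, $k \in [-73, 73]$.  Computed from shearing energy by
  default, the stronger occupancy channel.
* **Model 2** — the **rotational positioning index** (RPI): the real part
  of the inner product between 147 consecutive bending-derived scores and
  the wave packet $f(k) = e^{-k^2/800} e^{\,2\pi i k/P}$ (default $P =
  9.906$ bp).  The RPI oscillates with ~10-bp period and peaks where a
  dyad would sit with the energetically favored helical face toward the
  histones; its value doubles as a *nucleosome center score*.  The upper
  contour of the RPI landscape — local maxima joined by monotone
  piecewise-cubic interpolation, floored at 0 — is the model-2 occupancy.

Two diagnostics quantify rotational-positioning strength directly: the
sliding-window standard deviation of bending energy (population flavor;
default window 147 bp, 50 bp for gene-profile work) and the magnitude of
the discrete-Fourier component of the mean-subtracted windowed energies at
the bin nearest 10 bp.

For experimental chemical-mapping data the package processes per-base
nucleosome-center-positioning (NCP) scores: center-weighted occupancy with
the same Gaussian kernel, and greedy dyad calling that repeatedly accepts
the highest-scoring position and discards competitors strictly closer than
`min_dist` (10 bp for the redundant map; 107 bp — a field convention for
non-overlapping nucleosomes, not a dataset-derived value — for the unique
map).  Metagene profiling averages any per-base track in gene direction
around TSS/TTS/midpoint anchors, stratified by free-text class labels.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| window `L` | 101 | bp | energy window; 75/129 selectable |
| helical period | 10.0 | bp/turn | template frequency $\Omega$ |
| curvature $\rho$ | 4.5 | deg/step | superhelix bend amplitude |
| $\beta$ | 1 | — | Boltzmann factor on normalized energy |
| wave-packet $P$ | 9.906 | bp | RPI periodicity |
| wave-packet $\sigma^2$ | 400 | bp$^2$ | envelope width ($e^{-k^2/800}$) |
| strength window | 147 / 50 | bp | std / Fourier diagnostics |
| `min_dist` | 10 / 107 | bp | redundant / unique dyad calling |
| flank | 1000 | bp | metagene half-width |

The wave-packet period default of 9.906 bp (rather than a round 10)
preserves the conventional slightly-sub-10 helical repeat of nucleosomal
DNA; it is configurable, and the synthetic tests deliberately plant
signals at 10.0 bp so that the pipeline is exercised under a small period
mismatch.

## The packaged parameter table is a constructed stand-in

The elastic parameterization (equilibrium step geometries and force
constants) is shipped as a plain-text table,
`inst/extdata/bpstep_params_synthetic.tsv`, and is swappable via
`read_step_params()`.  It is **not** a published crystallographic
compilation: it is a constructed set with crystallography-scale
magnitudes, exact reverse-complement symmetry (tilt and shift flip sign
under strand reversal; couplings involving exactly one of them would flip
too, though the shipped matrices are diagonal), and the canonical
rotational-positioning rule: the A/T dinucleotide class (AA/TT/TA/AT) is
soft in roll/tilt with positive equilibrium roll, the G/C class
(GG/CC/GC/CG) stiff with negative equilibrium roll.  Consequently A/T
steps are favored where the template roll is maximal (defined here as
phase 0 relative to the dyad) and G/C steps at half phase.  The package's
validation surface is therefore *relational* — oracle equivalence, phase
discrimination, recovery of planted dyads — never absolute energy values,
which are meaningful only relative to a particular published force field.

## What the synthetic generators emulate

`generate_periodic_sequence()` builds the stated test world: `n` dyads a
fixed spacing apart (default 50 dyads, 200 bp — i.e. ~53-bp linkers,
ordinary for compact chromatin); within ±73 bp of each dyad, phase-0
positions receive AA/TT/TA with probability `signal` and half-phase
positions GC/CG/GG, over a uniform background.  `generate_ncp_track()`
emits score peaks at the planted dyads (Gaussian positional jitter,
uniform low-score background noise at 1% of positions by default — sparse
enough that true peaks dominate, as in deeply sequenced chemical maps).
`generate_gene_fixture()` adds gene structure: an A-tract NDR upstream of
each TSS and a phased array downstream, built identically in gene-local
coordinates for both strands.

What the generators do **not** emulate: realistic mouse base composition,
CpG islands, nuclease sequence bias, fragment-length effects, or
remodeler-imposed phasing.  A green test therefore establishes that the
algorithms recover what the deformation model itself encodes — not that
the model predicts any particular organism's chromatin.

## Numerical and design choices

* **Discrete template center.**  An odd window of length $L$ has $L-1$
  steps and no exact central step; rotpos uses $c = (L-1)/2$, the step
  ending at the central base, so the template roll is exactly $\rho$
  there.  The one-step asymmetry shifts recovered dyads by a systematic
  +1 bp (well inside the ±2 bp evaluation tolerance) and makes
  strand-reversed energy tracks agree only to ~1 bp; the strand tests use
  tolerances accordingly.
* **Real part, not modulus.**  The RPI is the real part of the complex
  inner product: phase-sensitive, hence able to report the rotational
  setting, and an oscillating signed landscape is exactly what an upper
  envelope presupposes.  Because the imaginary kernel is odd in $k$, the
  result is independent of the sign convention of the complex frequency.
* **Envelope algorithm.**  Strict 3-point local maxima (plateaus counted
  once at their midpoint; equal neighboring peaks resolved leftmost) as
  knots; `splinefun(method = "monoH.FC")` between knots (monotone
  Hermite — interpolates the knots exactly and cannot undershoot between
  two equal knots); boundary knot values held constant outside the span;
  floor at 0.  Fewer than two maxima degrades to the constant
  $\max(\mathrm{RPI}, 0)$ with a warning.
* **Ambiguous bases.**  Windows containing non-ACGT are undefined (`NA`)
  by default — the energy there is simply not sequence-determined — with
  an opt-in `average` policy substituting the mean step cost.
* **Edge contract.**  An $L$-bp window track has exactly
  $\mathrm{len} - L + 1$ values; each 147-tap kernel stage shrinks the
  defined region by 73 bp per side.  All tracks are 0-based internally;
  bedGraph output is 0-based half-open, wig 1-based.
* **Rolling statistics.**  The sliding standard deviation uses
  cumulative sums with a cancellation guard that clamps relative
  variances below $10^{-12}$ to zero, so constant windows report exactly
  0.  The Fourier statistic evaluates the exact windowed DFT bin via a
  phase-rotation identity (no FFT length padding, no taper); mean
  subtraction is a no-op at nonzero integer bins and is documented rather
  than computed.
* **Greedy dyad calling** is deterministic (score descending, then
  position ascending) and is validated against exhaustive enumeration on
  small instances: it never exceeds the spacing-feasible optimum and
  always satisfies the spacing constraint.
* **Seeding.**  Every generator takes an explicit seed and
  saves/restores the caller's RNG state, so generators are pure functions
  of their arguments.

## Known limitations

* Absolute energies depend on the stand-in parameter table; only ordering
  and phase structure are validated.
* Twist and rise deformations, protein–DNA contact energetics,
  methylation effects and thermodynamic (partition-function) positioning
  models are out of scope.
* The unique-map spacing (107 bp) is a convention, not a fitted value.
* Multi-chromosome inputs are handled as one track per sequence;
  single-file multi-chromosome bedGraph import is intentionally rejected.

## A minimal worked example

```{r example, eval = FALSE}
g <- generate_periodic_sequence(synthetic_spec(n_nucleosomes = 20, seed = 7))
bend <- energy_track(g$sequence, build_nucleosome_template(101),
                     default_step_params(), "bending")
p <- positioning_scores(normalize_unit_range(bend))
rpi <- rotational_positioning_index(p)
evaluate_dyads(rpi, g$truth$dyads, half_width = 5, tol = 2)
occ2 <- envelope_occupancy(rpi)
```

Every empirical number quoted in the package documentation is produced by
the test suite (`tests/testthat/`) or the acceptance report
(`scripts/acceptance.R`); the vignette states none that they do not
compute.
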