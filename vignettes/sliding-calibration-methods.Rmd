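---
title: "Models and methods: sliding calibration and homology-recognition kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sliding calibration and homology-recognition kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slidefret)
```

# The system and the measurement

A RecA filament assembled on single-stranded DNA searches double-stranded DNA
for sequence homology. In the single-molecule assay this package models, the
filament construct is immobilized with a FRET acceptor at the ssDNA/dsDNA
junction, a donor-labeled duplex docks onto the filament, and the donor and
acceptor emission channels are recorded in 30 ms camera frames. Rapid
anticorrelated intensity fluctuations report one-dimensional diffusion
("sliding") of the duplex along the filament; their time scale, quantified by
the donor-acceptor cross-correlation time, grows with filament length and
shrinks with the sliding diffusion coefficient. The package provides the full
computational chain around that observation:

* a Monte Carlo simulator of 1D sliding rendered as noisy, camera-binned
  intensity traces (two- and three-color),
* intensity corrections and FRET efficiency computation,
* cross-correlation analysis with single-exponential fitting,
* a simulated calibration surface $\tau(L; D)$ inverted to estimate the
  sliding diffusion coefficient $D_\mathrm{slide}$,
* a continuous-time Markov generator and Gaussian-emission HMM/TDP analysis
  for homology-recognition kinetics, and
* the analytic facilitated-search model (sliding length and rate
  enhancement).

# Coordinates and the distance model

Positions along the filament are expressed in *register* units: one
nucleotide of the RecA-stretched single strand, with an axial rise of
$d = 5.1$ Å (B-form 3.4 Å stretched 1.5-fold; `stretched_span(1)` recovers
it). The donor-acceptor distance between register coordinates $x$ and $x_0$
is

$$L = \sqrt{r^2 + \bigl(d\,|x - x_0|\bigr)^2},$$

where $r$ is a fixed lateral offset capturing the filament radius plus dye
linkers. No value of $r$ is established for this geometry; the default is
20 Å and it is exposed in `filament_geometry()`. Distance is converted to
FRET efficiency with the standard Förster relation
$E = 1/(1 + (L/R_0)^6)$. $R_0$ defaults to 56 Å for the primary (Cy3/Cy5
class) pair and 38 Å for the far-red (Cy3/Cy7 class) pair — literature
values for these dye classes; every quantitative result in the package that
matters for calibration is either $R_0$-independent or tested as a property
(orderings, recovery), so these defaults set the scale of simulated FRET but
not the conclusions.

With two acceptors, donor excitations are partitioned by Förster rate ratios
$k_i = (R_{0,i}/L_i)^6$: acceptor $i$ receives the fraction
$k_i/(1 + k_1 + k_2)$ and the donor keeps $1/(1 + k_1 + k_2)$.
Acceptor-acceptor transfer is neglected, mirroring an experimental design
that places the two acceptors 33 nt apart. This partition is algebraically
consistent with the ratiometric efficiency
$E_i = I_{A,i}/(\sum_j I_{A,j} + I_D)$ used in analysis, so noiseless
simulated traces round-trip exactly.

## Unit conventions for the diffusion coefficient

Two base-pair conventions coexist and differ by more than a factor of two:
`diffusion_um2_to_bp2(D, rise_nm = 0.34)` uses the B-form contour
(0.9 × 10⁻³ μm²/s → 7785 bp²/s, the convention in which sliding
coefficients are usually quoted), while the simulator internally uses the stretched register rise of
0.51 nm (the same D is 3460 register units²/s). The physical quantity in
μm²/s is always the anchor; both conversions are explicit.

# The sliding Monte Carlo model

The filament is a rigid rod (persistence length ≈ 784 nm, vastly longer than
any simulated filament), so sliding is a one-dimensional unbiased random
walk of the duplex register position with micro-step $\delta$ (default
0.1 bp, configurable down to 0.01 bp). The micro time step is fixed by the
random-walk/diffusion correspondence,

$$\tau_\mathrm{micro} = \frac{\delta^2}{2 D_\mathrm{register}},$$

so each ±δ move reproduces the requested $D$ exactly and one 30 ms frame
averages on the order of 10⁴–10⁵ micro-steps. Per frame, the mean FRET
efficiency over the frame's micro-steps allocates a fixed photon budget of
500 a.u.: $I_A = 500\,\bar E$, $I_D = 500\,(1 - \bar E)$, and Gaussian noise
of SD 40 a.u. is added independently per channel. The noiseless channel sum
is exactly the photon budget; shot-noise statistics per photon are not
modeled, matching the fixed-budget-plus-additive-noise recipe. The 40 a.u. noise
level is the scale seen in real traces of this kind; whether such a figure
means an SD, an amplitude or a peak-to-peak excursion is often ambiguous, so
this package defines it as the Gaussian SD per channel and exposes it as
`noise_sd`.

## Boundaries of the walk

The tracked coordinate is the junction-proximal end of the duplex. Its
domain is $[0,\; L_\mathrm{filament} - \mathrm{min\_overlap}]$ with
reflecting ends: the anchored duplex stem physically blocks sliding past the
junction at 0, while at the far end the duplex may overhang the free
filament end as long as at least `min_overlap` bp (default 9) remain in
contact. Two alternatives were considered and rejected:

* *Full-contact sliding* (range $|L_f - L_\mathrm{ds}|$) collapses to a
  static trace when the filament and duplex have equal length, contradicting
  the observed fluctuations in exactly that condition.
* *Symmetric minimal-overlap at both ends* (range
  $L_f + L_\mathrm{ds} - 2\,\mathrm{min\_overlap}$) places the junction
  acceptor exactly at the domain midpoint when $L_f = L_\mathrm{ds}$. The
  slowest diffusive relaxation mode is antisymmetric about the midpoint and
  then has zero projection onto the (symmetric) FRET observable, producing a
  spurious *dip* of the cross-correlation time at that length — the opposite
  of the monotone length dependence the measurement rests on.

With the junction-blocked domain the acceptor sits at a domain edge for
every filament length, the slowest mode always contributes, and the
cross-correlation time grows monotonically over the full length series
(21, 39, 69, 99 nt).

# Cross-correlation analysis

For two mean-subtracted series, $CC(\tau) = \langle \delta a(t)\,\delta
b(t+\tau)\rangle / (\sigma_a \sigma_b)$, evaluated at non-negative frame
lags; per-molecule curves are averaged with equal weights (trace lengths are
equal in all simulated cohorts, so length weighting is moot). The decay time
comes from a least-squares single-exponential fit, excluding lag 0 (which
carries the uncorrelated detection-noise spike). The curve is sign-corrected
before fitting — flipped so its initial decay is positive — rather than
taking the absolute value: rectifying the tail turns zero-mean noise into a
positive plateau that a single exponential chases toward absurdly long decay
times in fast-relaxing conditions. If the gradient-based fit fails, a
deterministic profiled least-squares search over the decay time (amplitude
solved in closed form per candidate) takes over.

Conditions whose relaxation is far below the frame time (e.g. a 21 nt
filament at 9 × 10⁻³ μm²/s relaxes in ~1 ms against 30 ms frames) leave no
resolvable decay; in the calibration table such cells are reported and
dropped rather than extrapolated.

# Calibration of the sliding diffusion coefficient

`build_calibration_table()` simulates `n_reps` molecules (default 30 × 1000
frames, the scale at which per-condition averages are accumulated in these
experiments) for every
(D, length) cell on a grid spanning two decades
({0.09, 0.9, 9} × 10⁻³ μm²/s by default) and the four filament lengths. Each
cell's τ is the exponential fit of the molecule-averaged cross-correlation —
the same reduction applied to measured curves — and its standard error comes
from refitting three molecule-subgroup averages, mirroring the common
practice of quoting errors over three independent datasets.

`estimate_D()` inverts the surface by least squares in $\log\tau$ across all
observed lengths jointly, interpolating linearly in $\log D$ (τ is
approximately ∝ 1/D, which log-log space linearizes). Predictions are
clamped at the grid edges — the estimator interpolates, never extrapolates.
An observed τ more than a factor `tolerance` (default 2) outside the
simulated range for its length is dropped from the joint fit with a warning;
if every observation is out of range the estimate is refused. How to combine
the filament lengths into a single estimate is an open design choice; this
package fits them jointly in log τ, and
parameter-recovery tests show it returns an interior-grid truth within a
factor of ~1.1 at the default trace budget (the acceptance suite asserts
×/÷ 1.5).

# Homology-recognition kinetics

`state_model()` describes the recognition dynamics as a continuous-time
Markov chain over three states with Gaussian FRET emissions: NH
(non-homologous sliding, E ≈ 0.1), HS2 (distal homology site, E ≈ 0.5) and
HS1 (proximal site, E ≈ 0.9). The default rates emulate the 6-nt-homology
regime: NH exit rate 2 s⁻¹ with a 55:45 branching toward HS2 (rates 1.1 and
0.9 s⁻¹), and a threefold lower total exit rate (2/3 s⁻¹, split evenly) from
either homology site — the reported qualitative structure of the 6-nt regime
(threefold stabilization by 6 bp of homology, ~55% recognition efficiency)
cast as the simplest rate matrix consistent with it. Dwells are Gillespie
sampled; frames straddling a transition take the occupancy-weighted mean of
the state means, mimicking camera integration.

`fit_hmm()` fits one Gaussian-emission HMM by Baum-Welch EM, pooled across
molecules with tied emission parameters (transition density plots aggregate
hundreds of molecules; pooling stabilizes the state means). Initialization is deterministic — means at evenly spaced
pooled quantiles, common SD, sticky transitions — so a fit is reproducible
without any random restart; restarts (perturbed, seeded) happen only on
degeneracy. The log-likelihood is recorded per iteration and is
non-decreasing. `idealize()` decodes the most probable joint state path
(Viterbi) and run-length encodes it into dwells.

## The straddled-frame artifact and `min_dwell`

A camera frame that straddles a direct NH→HS1 jump integrates part low, part
high intensity and lands near the middle state's mean; the decoder then
reports a spurious one-frame HS2 visit. Roughly half of all direct
low↔high transitions are converted this way, biasing $N(\mathrm{NH \to
HS1})$ by about −50% and inflating the apparent recognition efficiency. This
is a generic artifact of camera-integrated discrete-state data, not of this
implementation. `idealize(min_dwell = 2)` merges sub-threshold segments into
the preceding dwell and restores all six transition rates to within ~13% at
the default cohort size (200 traces × 2000 frames). The default remains
`min_dwell = 1` (retain everything), so the filter is an explicit analysis
choice; rate and recognition-efficiency analyses should use 2. The cost is
that genuine dwells shorter than one frame (≈ 2% of dwells at the default
rates) are absorbed, a small downward bias on all rates.

Transition rates use the exponential-exit estimator
$k(i \to j) = N(i \to j) / T_i$ (counts over occupancy time), which is
unbiased in expectation and robust at low counts; dwell-histogram fitting of
the same dwells is available through `fit_dwell_exponential()` as a
cross-check. The recognition efficiency is the NH-exit branching fraction
$N(\mathrm{NH \to HS2}) / (N(\mathrm{NH \to HS2}) + N(\mathrm{NH \to
HS1}))$. Transition density plots place one count per segment boundary at
(E before, E after); the axes use the fitted model means by default (exact
clustering, empty diagonal) or measured segment means (`axis = "segment"`)
to display empirical scatter — both conventions are in use in the field, so
both are offered.

# Photometry

Corrections apply in a fixed order: background subtraction per channel, then
leakage subtraction of the upstream corrected channel (donor → acceptor 1,
acceptor 1 → acceptor 2; defaults 0.12 and 0.05, typical dual-view values —
the true coefficients are instrument-specific inputs), then the γ factor
multiplying acceptor 2. `estimate_gamma()` locates the acceptor-2
photobleach step as the largest single-frame drop exceeding 5× the robust
noise SD (MAD of frame differences) and returns
$\gamma = \Delta I_{A1} / \Delta I_{A2}$ across the step, averaging 20
frames on each side; the estimate is invariant to overall intensity scaling.
Apparent efficiencies are clipped to [−0.2, 1.2] for storage (keeping noise
excursions for kinetics) and to [0, 1] for histogramming; frames with
non-positive total intensity are flagged invalid rather than propagated.

# The facilitated-search model

The sliding length per encounter is $s = \sqrt{D t}$. The
$\sqrt{Dt}$ (rather than $\sqrt{2Dt}$) convention is deliberate: with
D = 7700 bp²/s and encounter lifetimes of 0.5–10 s it gives 62–277 bp,
reproducing the 60–300 bp range reported for this system, which
$\sqrt{2Dt}$ (88–392 bp) cannot. The rate enhancement of target search due to sliding is

$$\frac{k_a^\mathrm{slide}}{k_a^{D=0}} =
\frac{1 + 2s}{1 + \dfrac{2s(1 - p_\mathrm{bind})}{1 + 2 s^2 p_\mathrm{bind}}},$$

where $p_\mathrm{bind}$ is the recognition probability per non-specific
encounter. The source equation is typeset on one line without unambiguous
grouping; the implemented parse is the unique reading that (a) equals 1 at
$s = 0$, (b) reduces to $1 + 2s$ at $p_\mathrm{bind} = 1$ (perfect
recognition scans $2s + 1$ sites), and (c) yields a few-hundred-fold
enhancement at $p_\mathrm{bind} \approx 0.01$ for $s$ in the 60–300 bp
range. At $s = 200$ bp and $p_\mathrm{bind} = 0.01$ it evaluates to
268-fold.

```{r search-model}
diffusion_um2_to_bp2(0.9e-3, rise_nm = 0.34)
sliding_length(7700, c(0.5, 10))
rate_enhancement(s = 200, p_bind = 0.01)
```

# Numerical choices and degenerate inputs

* **Seeds.** Every stochastic entry point takes a `seed`; compiled walk
  kernels draw per-molecule substreams from R's RNG, so one root seed fixes
  an entire pipeline run (`run_pipeline()` writes its resolved configuration
  and package version next to its outputs).
* **D = 0** yields a constant trajectory and a static (but still noisy, if
  enabled) trace; a zero-width sliding domain with D > 0 warns and is
  static.
* **Exponential dwell MLE.** Right-censored dwells contribute their duration
  to the likelihood: mean = total time / uncensored count, SE =
  mean/√n. All-censored input is an error (unidentifiable); fewer than 10
  uncensored dwells warns.
* **Binding-event detection** thresholds the total intensity at background
  mean + 4 SD with a two-pass robust background estimate; it assumes the
  trace is dark at least half the time.
* **HMM numerics.** Scaled forward-backward in double precision; emission
  densities floored at 10⁻³⁰⁰; state SDs floored away from 0 with degeneracy
  restarts; states relabeled ascending by mean after every fit.
* **Test problem sizes.** The property suite runs 100 unbounded walks of
  10⁵ micro-steps for the diffusion law, 30 molecules × 1000 frames per
  calibration cell over the 3 × 4 grid, and 200 traces × 2000 frames for the
  HMM recovery — the study-scale budgets, chosen once as the conditions the
  generators emulate.

# What the synthetic data do and do not capture

The generators reproduce the *mechanics* of the measurement: diffusive
distance dynamics, geometric FRET coupling, fixed photon budget, camera
binning, additive Gaussian channel noise, exponential state kinetics. They
deliberately omit photophysics (blinking, bleaching except as an explicit
step fixture, κ² orientation dynamics), shot-noise scaling with intensity,
baseline drift, and any microscopic base-pairing mechanism behind
recognition. Passing recovery tests therefore validate the analysis chain
under the stated noise model — they do not certify performance on real
traces with unmodeled photophysics, and the absolute FRET scale depends on
the assumed $R_0$ and lateral offset $r$, neither of which is
experimentally pinned for this geometry.

# Known limitations

* Off-axis motions (angle changes between duplex and filament) are not
  modeled; they would slow the apparent sliding time scale somewhat.
* Duplex flipping is excluded by design (ruled out experimentally).
* The boundary model (junction-blocked, minimum-overlap overhang) is a
  minimal mechanistic choice; absolute τ values depend on it, though the
  orderings in length and D that the calibration exploits do not.
* The CC time of fast conditions saturates at the frame-time floor; cells
  below the floor are dropped from calibration rather than guessed.
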