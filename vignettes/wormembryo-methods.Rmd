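---
title: "Methods: tracking and quantifying C. elegans embryonic behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking and quantifying C. elegans embryonic behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormembryo)
```

## The problem

In the final hours before hatching, a *C. elegans* embryo moves almost
continuously inside a rigid eggshell of roughly 50 x 30 x 30 um. Its posture
can be read out from the nuclei of the twenty seam cells — ten
anterior-to-posterior ranks (H0, H1, H2, V1–V6, T) on each side of the body —
imaged volumetrically at 3 Hz. Tracking those nuclei is hard for exactly the
reasons generic point trackers fail: the embryo twitches abruptly between
frames, detections are imperfect (missed nuclei, clutter), and trajectories of
different nuclei routinely intersect. `wormembryo` implements a tracking and
analysis stack for this regime, together with a synthetic-embryo generator
that reproduces the statistical structure the analyses assume, so that every
stage is testable without microscope data.

## Multiple-hypothesis hypergraph tracking (MHHT)

The tracker's state at frame $t$ is the posture $Z(t)$: the joint 3D position
of all twenty nuclei. Data association against a detection set is the gated
global-nearest-neighbor (GNN) problem: assigning detection $j$ to nucleus $i$
costs their squared displacement, detections outside a gate (default radius 6
um at 3 Hz) are inadmissible, a nucleus with an empty gate is declared
MISSING at cost $\text{gate}^2$, and unmatched detections are debris. Murty's
algorithm ranks the $K$ cheapest solutions of this problem; the package
implements it over a sparse shortest-augmenting-path assignment solver
(`solve_assignment()`, `murty_k_best()`, `gated_k_best_assignments()`).

Candidate postures are scored by how plausibly they continue the previous
posture. Four cost models are available, all non-negative and zero at the
identity:

* **GNN** — the gated association cost itself.
* **Embryo** — $f_E = \sum_j (\hat E_j(t) - E_j(t-1))^2$, the squared change
  of the $M = 46$ edge lengths of the anatomical lattice graph (9 side edges
  per side, 10 lateral edges, 18 diagonals across consecutive rank quads).
* **Posture** — $f_P = \Delta E^\top \hat\Sigma_P^{-1} \Delta E$, the
  Mahalanobis form with the edge-length-difference covariance estimated from
  an annotated corpus.
* **Movement** — $f_M = \Delta Z^\top \hat\Sigma_M^{-1} \Delta Z$ on the
  stacked $3n$ coordinate differences, with the movement covariance
  estimated the same way; **PM** is the additive combination $f_P + f_M$.

Covariances are estimated (`estimate_covariances()`) as the mean-centered
outer-product sum of frame-to-frame difference vectors scaled by the number
of transitions, then ridge-regularized (`1e-6` times the mean diagonal) to be
positive definite — finite corpora give rank-deficient estimates otherwise.

`track_mhht()` defers decisions: at each frame it expands a $K$-ary tree over
the next $N$ frames (each node's children are the $K$ best gated
assignments), graphically interpolates MISSING nuclei (previous position plus
the mean displacement of the nearest assigned graph neighborhood), prunes
hypotheses whose body midline self-intersects (non-adjacent midline segments
closer than 2 um; pruning is soft so the frontier never empties), and commits
only the first step of the cheapest path before re-rooting. With $K = N = 1$
the output is exactly the gated GNN baseline. Frames whose committed step
cost exceeds a user threshold are flagged for manual review.

Three scoring choices deserve note, because the underlying description of
the method leaves them open:

* *Unary costs.* The Embryo and Posture models are pure shape terms; as the
  tracker's objective they are combined with the gated association cost as a
  unary term (weight `unary_weight`, default 1). The Movement and PM models
  already price positional change, so they add only the $\text{gate}^2$
  penalty per MISSING nucleus. Without that penalty, declaring every nucleus
  missing and carrying the posture forward would cost nothing.
* *Commitment.* Only frame $t$ of the best path is committed before
  re-rooting (standard deferred decision); deeper frames are re-decided.
* *Search.* The tree search is exact: children are explored cheapest-first
  under branch-and-bound, which preserves the minimum-summed-cost semantics
  while pruning most of the $K^N$ expansion in practice.

An implementation lesson worth recording: ranking assignments by warm-starting
each Murty subproblem from the parent's dual potentials is *incorrect* for
rectangular problems (nonzero potentials on unmatched columns break the
extremeness invariant of successive shortest paths); subproblems are
re-solved from zero duals, and the test suite pins the ranking against
exhaustive enumeration.

## Posture analysis: bend angles and eigen-embryos

Each body side is interpolated with a natural cubic spline through its ten
nuclei, parameterized by chord length (`fit_side_midline()`). For each of the
nine gaps between adjacent nuclei on a side, with `mSide` the spline midpoint
of the gap and `mOpp` the midpoint of the same rank gap on the opposite side
(rank-gap pairing is the only symmetric choice of correspondence), the signed
dorsoventral bend is the dihedral angle

$$\operatorname{atan2}\big(((\vec v_1 \times \vec v_2) \times (\vec v_2
\times \vec v_3)) \cdot \tfrac{\vec v_2}{\lVert \vec v_2 \rVert},\;
(\vec v_1 \times \vec v_2) \cdot (\vec v_2 \times \vec v_3)\big)$$

where $\vec v_1$ runs from `mSide` to the gap's anterior nucleus, $\vec v_2$
from `mOpp` to `mSide`, and $\vec v_3$ from `mSide` to the posterior nucleus
— 18 angles per frame (`compute_bend_profile()`). Two symmetries are enforced
by construction and verified in the tests: rigid motion leaves the profile
unchanged, and swapping the left/right labels negates every angle.

`fit_eigen_embryos()` performs mean-centered PCA with no rescaling (all
angles share units). Component signs are fixed so the largest-magnitude
loading is positive; the dorsal/ventral semantics of PC1 are assigned
afterwards (`assign_dorsal_sign()`) from the late-stage dorsal coiling bias —
the sign that makes the late-window PC1 mean positive, with `+1` and a
warning in the degenerate symmetric case.

Flips — transitions between fully dorsal and fully ventral coiling — are
detected on the PC1 amplitude trace (`detect_flips()`). "Fully coiled" is not
quantified in the source description; the package operationalizes it as
$|PC1|$ at or above `coil_threshold` (default 0.5) times the 95th percentile
of $|PC1|$, and a flip is the interval from the last exit of one coil state
to the first entry of the opposite one. Transitions longer than 30 s are
discarded as non-flips. Motifs (`classify_flip_motif()`) take the PC (2 or 3)
with the larger mean absolute amplitude during the transition, suffixed by
its sign; ties go to PC2.

## Motion statistics

`compute_msd()` averages squared displacements over all overlapping pairs;
`estimate_diffusion_coefficient()` fits an ordinary least-squares line (with
intercept) over the first 30 lags (10 s at 3 Hz) and reports
$D = \text{slope}/6$. Embryo speed (`compute_speed_direction()`) uses the
seven lateral-pair midpoints H1–V5: displacement over 3 frames (1 s), a
weighted mean with weights proportional to the straight-line lengths of the
two adjacent midline segments (a per-segment volume term is not modeled; the
weighting hook is the place to add one), and direction $\bar\theta$ measured
against the local anterior tangent (midpoint $r{+}1$ to $r{-}1$). Frames are
classified pause (< 0.5 um/s, priority), forward ($\bar\theta < 45^\circ$),
backward ($\bar\theta > 135^\circ$) or other; maximal runs become bouts
(`segment_bouts()`), and `binned_stats()` reports 20-minute-bin means, SEMs
and coefficients of variation (sample SD over mean; a zero-mean bin is
flagged undefined).

## Brightfield twitch profiles and the SWT statistic

Motion in the high-throughput brightfield assay is the count of pixels in a
21 x 21 box around each embryo whose intensity changes by more than 25 counts
between consecutive 1 Hz frames (`compute_tally_trace()`, 441 possible).
Onset is the first 30-frame-smoothed tally above 120; hatch is the first
frame at which the smoothed embryo-box intensity reaches 0.92 of the
background-perimeter intensity (the 240-pixel outline of a 61 x 61 box);
frames where more than 40 perimeter pixels change by more than 35 counts are
excluded as contaminated. Smoothing is a centered 30-sample moving mean
truncated at the edges, which implies a localization uncertainty of about
±15 s on the onset and hatch calls. Excluded samples are filled by reversed
duplication of the immediately preceding interval of equal length
(`fill_missing()`), applied to the full masked trace before windowing.

The slow-wave-twitch (SWT) power ratio of a 15-minute window is

$$\frac{\sum_{20\,\text{mHz} \le f \le 40\,\text{mHz}} |Y(f)|^2}
       {\sum_{0 \le f \le 500\,\text{mHz}} |Y(f)|^2}$$

with $Y$ the DFT of the window; at the 1/900 Hz bin spacing the band edges
fall exactly on bins 18 and 36, and bin inclusion uses closed intervals. The
denominator includes the DC bin, exactly as defined; since tallies are
non-negative, DC dominates and ratios on raw traces are small. A `detrend`
option subtracts the window mean for sensitivity analyses (off by default).
`scan_peak_swt()` slides this window in 200 s steps from one hour after
onset until hatching and records the peak ratio and its timing, reported at
the window center in minutes post-fertilization under the convention that
onset is 430 mpf. The chance level of the ratio for zero-mean noise is the
band-bin fraction, $19/451 \approx 0.042$.

The shuffled baseline (`shuffled_baseline()`) partitions each window into
consecutive non-overlapping pairs of neighboring values and permutes the
order of the pairs (within-pair order preserved) before the DFT. This
reading destroys 20–40 mHz structure while preserving one-lag texture; the
alternative reading (swapping members within each pair) would leave the SWT
band intact and make the baseline meaningless, so it is exposed only through
the tests' expectations, not as a default. `scalogram()` provides an
analytic-Morlet continuous wavelet transform over 1–100 mHz for inspection;
the quantitative statistic is always the power ratio.

## Calcium transients and quiescence

`extract_cell_trace()` localizes the cell body per frame: subtract 100
camera counts (clamped at zero), Gaussian-filter every plane (sigma 5 px,
symmetric padding, implemented as separable convolution), take the brightest
voxel of the filtered mCherry volume, and read the filtered GCaMP value at
that voxel; featureless frames are flagged invalid. `compute_dr_over_r0()`
forms $R = \text{GCaMP}/\text{mCherry}$ and normalizes by the 10th percentile
of $R$ over the trace (linear-interpolation percentile), so by construction
roughly a tenth of samples sit below zero.

`detect_transients()` runs hysteresis thresholds on the span-4 moving mean:
open at $\Delta R/R_0 \ge 2$, close below $1.5$ (RIS cell bodies; ALA
neurites use $0.07/0.05$). The span-4 mean is trailing — an even-span
centered mean is ill-defined and a trailing mean preserves causality — which
shifts event times by at most 2 s. Amplitude is the smoothed peak; duration
is the full width at half that peak with linearly interpolated crossings, and
the half-peak onset is the alignment zero for event-triggered averages
(`align_to_transient_onset()`, median-normalized traces, window −30 to
+60 s). Quiescent bouts are maximal runs of at least 3 s with per-second
displacement at or below 0.5 um (`detect_quiescence()`). Uncertainty on
event-aligned means is estimated by a hierarchical bootstrap
(`hierarchical_bootstrap()`): resample embryos with replacement, then events
within each sampled embryo, statistic = across-event mean. Stimulus trials
are labeled `RIS_on` when the stimulus onset falls inside a detected event
(onset inclusive, offset exclusive), with configurable pre/stim/post window
means (`categorize_stimulus_trials()`); the pre/stim/post placements default
to 10 s each because the source labels them only graphically.

## The synthetic embryo generator

The generator exists so that every analysis above can be exercised, at its
own scale, on data whose ground truth is known. It emulates the *statistical
structure* the analyses assume, not microscopy: detections are points (no
intensity or PSF model), and bodies are lattices, not surfaces.

* **Geometry.** The body midline runs along an ellipse inset from the
  eggshell equator, with ten stations at fixed arc-length spacing (total arc
  90 um — a folded embryo; the inter-nucleus spacing is not specified
  anywhere authoritative, so it is a config default) and left/right nuclei
  offset 2 um from the midline. Configurations whose body length exceeds the
  track circumference are rejected. Dorsoventral displacement modes are
  driven by latent amplitudes; positions violating the eggshell inequality
  are clamped radially with a 2% margin.
* **Phases.** The flipping phase drives the coiling mode with a square wave:
  flip starts follow a renewal process sized to the nominal rate (default
  3.5/min), and each transition is a linear ramp whose half-amplitude
  crossing time is exponential with mean 7.21 s — the same duration
  convention the detector uses, so recovered durations estimate the drawn
  ones. The inactive phase is quiet. The mature phase combines a travelling
  wave (phase-shifted mode-2/mode-3 sinusoids) with bout-structured
  translation along the track; inside the SWT window, translation speed is
  gated multiplicatively at the SWT frequency — pausing, not slowing of the
  wave, is what generates the 20–40 mHz band. No quantitative model of
  immature kinematics beyond rate and duration exists, so the smooth ramp
  shape is the package's choice.
* **Corruption.** Detections are the true positions plus isotropic Gaussian
  jitter (0.5 um), dropped with probability 0.05, plus Poisson(1) uniform
  clutter per frame, shuffled, with a provenance map for evaluation. These
  defaults are of the order implied by the real pipeline's detection
  precision/recall.
* **Twitch traces.** Binomial tallies around a three-phase envelope
  (pre-onset 8, active 200, reduced 60, late active 250 of 441), with
  multiplicative sinusoidal gating (depth 0.9) inside the SWT window.
* **Calcium traces.** Transient onsets from a stationary renewal process
  (12 s refractory plus an exponential gap); each transient is a
  *trapezoidal* pulse (1 s rise/fall, FWHM exactly 10 s, peak 4). The
  compact support matters: with the 12 s refractory and span-4 smoothing, a
  Gaussian pulse of the same FWHM leaves adjacent events unresolved at the
  1.5 offset threshold about a tenth of the time, biasing recovered rates
  low. Speed couples to transients by multiplicative slowing of a 0.8 um/s
  random walk.
* **Movies.** A dark ellipse on a bright background whose texture toggles a
  designed number of box pixels per frame (each toggle exceeds the tally
  threshold, so the designed count equals the expected tally); hatch renders
  the ellipse vacating its position.

All generators draw from a stream seeded by `config$seed` and restore the
caller's RNG state; identical seeds give identical outputs.

What passing tests on these simulations does *not* show: robustness to
photobleaching, intensity-dependent detection failure, anisotropic jitter,
nucleus division or mis-segmentation into merged detections, or real posture
statistics beyond the low-dimensional modes the generator encodes.

## Calibration of the eigen-embryo recovery target

Synthetic bend profiles for the PCA-recovery check are $A s + \varepsilon$
with four orthonormal smooth modes. The latent variances are calibrated so
that the *population* principal components explain 60, 16, 8 and 4 percent
of total variance (88% cumulative) over an isotropic noise floor of 12%.
Because isotropic noise also contributes variance along the latent
directions, the calibration solves $\sigma^2 = 0.12/(18-4)$ and
$\lambda_k = \text{share}_k - \sigma^2$ (unit total variance); reading the
shares as the latent variances themselves would put the population top-4
explained variance at 90.7%, not 88%.

## Numerical choices and problem sizes

Ties in assignment cost are broken toward the lowest detection index (and
toward real detections over MISSING) by an index-proportional epsilon, so
outputs are deterministic. Strict inequalities are used where a boundary
rule is stated: self-intersection (closer *than* the separation), exclusion
masking (more *than* 40 pixels). The covariance ridge is scale-aware
(`ridge * mean(diag)`). Percentiles use R's default linear interpolation.

The test suite exercises the tracker benchmark at 50 simulated embryos of 15
frames each (flipping phase, calibrated corruption) with the PM model at
K = 5, N = 5 against the gated GNN baseline; the eigen-embryo check uses
10,000 profiles; the transient-rate check uses 40 embryos of 300 s; the
flip-duration check uses 500 flips. These sizes make the whole suite run in
minutes on one core while keeping the statistical targets inside their
stated tolerances; they are the package's chosen study scales, and the same
computations are reproduced by `scripts/acceptance.R`.

## Known limitations

* The tracker assumes a fixed population of 20 nuclei — no births, deaths,
  or track initiation/termination logic.
* Manual curation is out of scope: low-confidence frames are flagged and
  exported, not edited.
* The covariance models are stationary; a corpus from one developmental
  phase may not transfer to another.
* The scalogram is a visualization aid; its wavelet (analytic Morlet) is a
  fixed choice and no significance machinery is attached to it.
* Left/right (and hence dorsal/ventral) identity ultimately rests on the
  late-stage dorsal-bias convention, not on an independent marker.
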