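---
title: "Quantifying chemotaxis in optically generated gradients: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chemotaxis in optically generated gradients: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemotaxr)
```

# The assay and what the package computes

In the under-agarose uncaging assay, neutrophil-like cells (e.g.
differentiated PLB-985 cells) carrying fluorescent nuclear markers migrate
beneath a thin agarose gel containing a caged chemoattractant.  A defocused
UV exposure converts part of the caged pool into active attractant in a
radially symmetric pattern centered on the field of view, creating a
chemical gradient within seconds; small periodic "recharging" exposures
offset its dissipation by diffusion.  Wells are imaged every 30 s for 50
frames — 17 before the initial uncaging and 33 after — at 2.5 µm/px over a
1,024 × 1,280 field.

From each well's movie, the package measures, per cell step between
consecutive frames:

* **speed** — distance moved divided by the elapsed time (µm/min);
* **movement angle** θ ∈ [0°, 180°] — between the movement vector and the
  *optimal direction* unit vector pointing from the step origin at the
  gradient center (0° = straight at the center);
* **directed displacement** — the dot product of the movement vector with
  the optimal direction vector.

Per well, these aggregate into basal speed (pre-stimulus steps), stimulated
speed, directed speed, and **angular bias** = 90 − mean(θ): 0 for random
motion, 90 for perfect homing, negative for net movement away from the
center.  In screens, an siRNA-treated experimental population shares every
well with a control population carrying a different nuclear marker; robust
normalization against this in-well control turns raw well values into
**phenotype scores** (normalized value − 1), and a two-Gaussian model of
replicate error converts mean scores into confidence intervals and
P-values.

# Gradient simulation

The uncaged attractant obeys 2-D free diffusion in the thin gel layer,

$$\partial_t c = D\,\frac{1}{r}\,\partial_r\!\left(r\,\partial_r c\right),$$

with radial symmetry about the gradient center.  An uncaging pulse at time
$t_p$ converts the fraction $d\,e^{-r^2/2\sigma^2}$ of the *locally
remaining* caged reservoir $\kappa(r)$ into free attractant (reservoir
depletion is on by default; the caged pool diffuses with its own,
default-equal, coefficient).  Defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `D` | 300 | µm²/s | small-molecule-in-agarose order of magnitude; configurable because real systems are calibrated empirically against dye images |
| `profile_sigma` | 500 | µm | out-of-focus illumination width; no published profile exists, so this is a calibration parameter |
| `initial_dose` | 0.3 | — | conversion fraction of the 2.5-s initial exposure; calibration parameter |
| `recharge_ratio` | 0.008 | — | the 20 ms / 2.5 s exposure-time ratio of recharge to initial pulses |
| `recharge_interval` | 90 | s | one recharge every three 30-s frames |

Numerics: a cell-centered radial grid ($r_i = (i - \tfrac12)\,\Delta r$,
default $\Delta r$ = 5 µm out to 3 mm) with a conservative Crank–Nicolson
step (default $\Delta t$ = 1 s).  Because fluxes are evaluated on cell
faces, the discrete $r$-weighted mass is conserved exactly (observed drift
≈ 10⁻¹⁴ relative); against the closed-form Gaussian spreading law
$s^2 \mapsto s^2 + 2Dt$ the scheme is accurate to about 0.01% at the
default resolution.  The propagator matrix is precomputed once and applied
per step, so a 25-min simulation runs in well under a second.

Gradient quality is summarized by the **steepness**
$100\,[c(r) - c(r+L)]/c(r)$ over a probe of $L$ = 30 µm (about one
neutrophil length); at the default parameters the simulated post-pulse
steepness at $r$ = 300 µm falls in the few-percent range characteristic of
the assay.  `design_recharge()` scores candidate recharge dose ratios by
the temporal coefficient of variation of steepness and returns the
minimizer; with the defaults, recharging roughly halves the CV relative to
a single pulse.

# The synthetic-data generator

No raw screen images are publicly deposited, so every pipeline stage is
validated against a ground-truthed generator that emulates the assay's
statistical structure:

* **Motion model** — a biased persistent random walk.  At each step a
  target heading is drawn (uniform before the stimulus; von Mises with
  concentration `bias_kappa` around the direction to the gradient center
  after it) and blended with the previous heading using weight
  `persistence` (0.5 by default).  The field's measurements constrain only
  the *distribution* of movement angles — uniform when unbiased,
  concentrated when biased — and the von Mises family reproduces exactly
  that with a single parameter.  In the `bias_kappa = Inf` limit steps
  point exactly at the center, pinning the angular-bias ceiling of 90 for
  tests.  Step lengths are gamma (shape 2) with mean speed × Δt, so step
  lengths are realistically dispersed and the 10-µm minimum-move filter
  does real work.  Defaults of 10 µm/min basal and 20 µm/min stimulated
  speed emulate cells that double their speed on stimulation.
* **Nonmovers** — a 5% default fraction is pinned at its initial position
  plus localization noise (0.3 px s.d. per coordinate), so the
  "> 2 px from initial position" trajectory filter is genuinely exercised.
* **Rendering** — nuclei become isotropic Gaussian spots (s.d. 2 px, peak
  400 counts) on a tilted-plane background (level 100) with shot-like
  noise; at the default segmentation threshold the resulting object areas
  sit comfortably inside the (5, 75] px area filter.  There is no PSF,
  bleaching, cell division, or collision mechanics — passing tests show
  the *pipeline* is correct, not that it is robust to every real-world
  artifact.
* **Plates** — `make_plate()` gives both populations of a well one shared
  multiplicative speed factor (lognormal, log-s.d. 0.15, a realistic
  well-to-well variation for plate assays) and scales the experimental
  population's parameters by (1 + effect) per declared condition effect.
  Summaries are computed directly from ground-truth trajectories (with
  localization noise and the nonmover filter applied) rather than from
  rendered movies, which keeps a 96-well plate under two seconds; the
  imaging path is validated separately on rendered movies.

All randomness flows through one explicit seed; per-well substreams are
derived deterministically from (seed, well index).

# Imaging and tracking

* **Background** — per-frame 80th-percentile intensity in 32 × 32 px
  blocks, bilinearly interpolated between block centers, with clamping
  beyond the outermost centers (edge behavior is unstated in the field's
  descriptions; clamping keeps every interpolated value inside the block
  range).  Subtraction clamps negatives at zero so thresholding stays
  one-sided.
* **Segmentation** — a single manually chosen global threshold, then
  watershed on the inverted Euclidean distance transform of the mask to
  split touching nuclei (the standard substrate for blob splitting;
  EBImage provides the transform and watershed).  Centroids are unweighted
  means of member pixel coordinates, 0-based, x along columns.  Objects
  ≤ 5 px or > 75 px are discarded.
* **Tracking** — frame-to-frame mutual nearest neighbors only: a link
  exists iff each detection is the other's nearest neighbor in the
  opposite frame.  Equidistant ties are treated as ambiguous (no link), the
  conservative reading of "unambiguous matches only".  A step is dropped
  when the cell's nearest same-frame neighbor is within 40 µm (16 px) in
  *both* frames.  There is no gap closing, merging, or global assignment —
  frame-to-frame fidelity is the point.  Trajectories whose cell never
  exceeds 2 px displacement from its start are removed.

# Statistics: filters, epochs, and scores

* A step belongs to the *pre* epoch iff both frames precede the uncaging
  frame and to *post* iff both follow it; the single spanning step is
  excluded (the epoch boundary step is otherwise ill-defined).
* In-gradient statistics (stimulated speed, directed speed, angular bias)
  use only steps originating 250–1,625 µm from the gradient center, where
  the gradient is well formed; basal speed uses all pre-epoch steps since
  the pre-stimulus field is spatially homogeneous.
* Angles require ≥ 10 µm (4 px) of movement; angular bias averages
  per-step angles pooled across cells (a per-cell-mean variant would
  weight slow cells equally, but pooled step aggregation matches how the
  well statistics are defined).
* Normalization fits experimental ~ control per phenotype across a
  plate's wells by IRLS with Tukey bisquare weights (c = 4.685, ≤ 50
  iterations, tolerance 1e-8, via `MASS::rlm`); the per-well expected
  value comes from this trendline, and score = experimental / expected − 1.
  If Spearman correlation < 0.1 or the slope is negative — typical for
  angular bias, whose well-to-well variation is mostly statistical noise —
  scores fall back to division by the plate median.  The chemokinesis
  score is the robust residual of the stimulated-speed score on the
  basal-speed score, isolating the stimulus-specific speed boost from
  general motility.

# The replicate-error model

Measurement error of a phenotype score is modeled as a zero-mean
two-component Gaussian scale mixture.  Because the error distribution is
observed only through differences of replicate measurements, and the
difference of two independent mixture draws is itself a zero-mean mixture
with components $N(0, \sigma_i^2 + \sigma_j^2)$ and weights $w_i w_j$, the
model is fit by maximizing this closed-form convolution likelihood over
all unordered within-condition replicate pairs (a 3-replicate condition
contributes 3 differences).  Zero means are enforced throughout: symmetric
difference data cannot identify component means, and measurement error has
no reason to be biased.  The optimizer works on a logistic scale for the
weight and log scales for the s.d.s, polishing a Nelder–Mead pass with
BFGS from a deterministic grid of 12 moment-anchored starting points
(anchored at $\hat\sigma = \mathrm{sd}(\text{diffs})/\sqrt2$); a
deterministic grid gives the same multi-start robustness as random
restarts while making fits exactly reproducible.  σ₁ ≤ σ₂ is imposed after
convergence for identifiability.

The mean of $n$ replicate scores of a null condition is again a
closed-form mixture — component $k \in \{0..n\}$ has weight
$\binom{n}{k} w_1^k w_2^{n-k}$ and variance
$(k\sigma_1^2 + (n-k)\sigma_2^2)/n^2$ — so the symmetric 98% null interval
is found by root-finding on the exact CDF (tolerance 10⁻¹²), and two-sided
P-values are $2[1 - F(|m|)]$.  Error models are fit separately per
phenotype score type, since different scores have visibly different noise
scales.  With 1,000 simulated 3-replicate conditions the fitted interval's
empirical coverage sits within a point of the nominal 98%.

# Problem sizes and test design

The test-suite and acceptance computations run on deliberately compact
instances chosen to make Monte-Carlo tolerances meaningful at interactive
speeds: 10,000 steps for angular-bias null checks (s.e. ≈ 0.5°), 1,000
random instances for each brute-force oracle comparison (blockwise
background and mutual-NN matching), 1,000 × 3 simulated conditions for the
error-model fit with 10,000 fresh null conditions for coverage, 12-well to
48-well synthetic plates with 80–100 cells per population for
score-recovery checks, and 256 × 320 px rendered movies for
segmentation/tracking recall.  Statistical assertions use 3 × s.e. bounds
under fixed seeds; exact assertions (mass conservation, oracle
equivalence, definitional angles) use floating-point tolerances.

# Known limitations

* The gradient simulator is radial and 2-D: no axial diffusion,
  convection, photobleaching, or photochemistry beyond a single conversion
  fraction; illumination width and conversion fractions are calibration
  parameters, not measured constants.
* The generator's von Mises heading distribution is a modeling choice, not
  a claim about real cells' post-stimulus heading law.
* Rendering omits realistic optics; segmentation performance on real
  images depends on contrast and focus in ways synthetic tests cannot
  certify.
* Tracking is strictly frame-to-frame; dense fields lose steps to the
  crowding filter by design rather than attempting risky assignments.
* No multiple-testing correction is applied across conditions; the 98%
  interval and per-condition P-values mirror the screen's per-condition
  error control.
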