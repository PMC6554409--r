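---
title: "Excitable population dynamics of NREM sleep: models, detectors, and distribution matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitable population dynamics of NREM sleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nremdyn)
```

## The scientific problem

During NREM sleep, forebrain populations alternate between periods of
spiking and near-silence. In neocortex these are the UP and DOWN states of
the slow oscillation, with each DOWN state visible as a delta-band "slow
wave" in the LFP; in hippocampus the analogous alternation is between
sharp wave-ripple events (SWRs, brief population bursts) and quiescent
inter-SWR periods. `nremdyn` implements a complete analysis chain for
asking *what dynamical regime generates these alternations*: a mean-field
model of an adapting recurrent population, classification of its dynamical
regimes, stochastic simulation, UP/DOWN state detection on rate traces,
non-parametric matching of dwell-time distributions, and the LFP/spike
event detectors needed to extract the in-vivo dwell times in the first
place.

## The r–a model

The core model describes a population's mean rate $r(t)$ under slow
spike-frequency adaptation $a(t)$:

$$\tau_r \frac{dr}{dt} = -r + R_\infty\!\left(w r - b a + I + \xi(t)\right),
\qquad
\tau_a \frac{da}{dt} = -a + A_\infty(r),$$

with recurrent weight $w$, adaptation gain $b$, tonic drive $I$, and an
Ornstein–Uhlenbeck input noise $\xi(t)$. Both transfer functions are
logistic sigmoids. Four regimes of UP/DOWN dynamics arise, distinguished
by the location of stable fixed points on the folded rate nullcline:

* **oscillatory** — no stable fixed point; adaptation drives regular
  alternations (a relaxation limit cycle);
* **bistable** — stable UP and DOWN fixed points; only noise switches
  between them;
* **Excitable_UP** — a single stable UP state; noise evokes transient,
  stereotyped DOWN states (the neocortical NREM configuration);
* **Excitable_DOWN** — a single stable DOWN state; noise evokes transient
  UP states (the hippocampal SWR configuration).

```{r regimes}
classify_regime(rate_pop_params(w = 6.3, b = 1, I = 2.35))$label
classify_regime(rate_pop_params(w = 6.0, b = 1, I = 2.40))$label
classify_regime(rate_pop_params(w = 6.28, b = 1, I = 2.64))$label
```

### Transfer-function defaults and how they were chosen

The published account of this model prints the panel parameters $(w, b,
I)$ and the dwell-time statistics but not the sigmoid shapes. The
defaults here were therefore **calibrated once** against the printed
regime anchors, and are recorded in `rate_pop_params()`:

* $R_\infty$: logistic with gain 1, half-activation 5, saturation 1;
* $A_\infty$: logistic with gain 9, half-activation 0.5, saturation 1.

With these choices each recurrence level $w$ has an effective I/O curve
symmetric about $I_c(w) = 5 - w/2 + b/2$, which makes the printed panel
drives mutually consistent: $I = 2.35$ is exactly the curve centre for
$w = 6.3$ (the bistable panel) and $I = 2.5$ the centre for $w = 6$ (the
oscillatory panel). The calibration targets were: bistable with exactly
three fixed points (two stable, one saddle) at $(w{=}6.3, I{=}2.35)$;
Excitable_DOWN at $(6, 2.4)$; oscillatory at $(6, 2.5)$; Excitable_UP at
the neocortical best fit $(6.28, 2.64)$; Excitable_DOWN at the
hippocampal best fit $(6, 1.9)$; and no alternations for weak recurrence.
Every adaptation gain in roughly $[8.5, 9]$ satisfies all anchors; 9 is
used. Two printed panels share identical $(w, b, I)$ but different
captioned regimes, so some unprinted constant must differ between them;
those two panels are deliberately not used as calibration anchors.

Time constants: the model is non-dimensionalized with $\tau_r = 1$;
$\tau_a = 40$ reflects the printed 5 ms excitatory and 200 ms adaptation
time constants. The matching stage later estimates the physical
milliseconds per model time unit as a free parameter, so $\tau_a$ fixes
only the *ratio* of fast to slow dynamics.

## Stochastic simulation

Noise is an OU process generated by forward Euler on a fixed grid
($\theta = 0.05$, $\sigma = 0.25$, $dt = 0.1$ — the study conditions) and
held piecewise-constant within each step while the deterministic part is
advanced with Heun's method. Precomputing the noise makes a trace a pure
function of `(params, noise, seed)`; `solver_accuracy()` verifies that
halving the step changes dwell-time statistics by under 2%. Duration
statistics throughout use 60,000-time-unit simulations, the study's
reference length; some desk-scale tests use shorter runs.

```{r sim}
p <- rate_pop_params(w = 6.28, b = 1, I = 2.64)
tr <- simulate_rate(p, ou_params(), duration = 60000, seed = 1)
st <- detect_updown(tr)
duration_stats(st)
```

## UP/DOWN detection on rate traces

A trace is only segmented if its rate distribution is bimodal by a
Hartigan dip test. The dip statistic is computed exactly (half the
smallest maximal deviation of the empirical CDF from a convex-minorant /
concave-majorant pair over all candidate modes); its null distribution is
calibrated by parametric bootstrap from the **uniform** distribution, the
asymptotically least-favourable unimodal null and the standard reference
for the dip. (Bootstrapping from a fitted unimodal density was considered
and rejected: it requires a Grenander-type estimator whose own smoothing
choices would dominate the calibration, while the uniform null is
assumption-free and slightly conservative.) Null realizations depend only
on the sample size and are cached.

Transitions use a *sticky* (hysteresis) threshold pair derived from the
rate histogram: DOWN→UP at the midpoint of the high-rate peak and the
inter-peak trough, UP→DOWN at the midpoint of the low-rate peak and the
trough. Crossings of the trough that do not reach the far threshold cause
no transition, suppressing noise-induced flicker. Peaks are found on a
histogram with Freedman–Diaconis-derived bins clamped to 64–128 bins and
smoothed with a 3-bin moving average; adjacent maxima not separated by a
trough at least 50% below the smaller of them are merged. The clamping
and merging matter in strongly skewed excitable regimes, where an
unclamped bin rule resolves sampling noise inside the majority mode as
spurious "peaks". The trough of a wide empty valley is taken at the
centre of its minimal-density plateau. No minimum dwell time is imposed
on simulated states; hysteresis alone suppresses spurious crossings (the
40 ms floor in the LFP detector is a property of that detector, not of
the model analysis).

## Matching dwell-time distributions

Model and data are compared through dwell-time distributions only. For
UP and DOWN samples the similarity is

$$s = (1 - KS_{UP})\,(1 - KS_{DOWN}),$$

the product of complemented two-sample Kolmogorov–Smirnov statistics,
each computed exactly at every CDF step. A single free parameter — the
time-scale factor $\tau$, in ms per model time unit — is scanned over 1 ms
to 25 ms in 0.1 ms steps, keeping the scale that maximizes $s$ (first
maximum on ties). For hippocampal data the same machinery applies with
the label mapping SWR ↔ UP and inter-SWR ↔ DOWN. `similarity_map()`
evaluates a grid of simulated parameter sets against a list of recordings,
flags cells that fail the bimodality gate with $s = 0$ (keeping maps
comparable across recordings), and outlines the constraint region of
cells whose simulated CV$_{UP}$, CV$_{DOWN}$ and mean-duration ratio fall
within 2 experimental standard deviations.

The headline validation is a parameter-recovery experiment: duration
samples generated at a known $(I, w)$ cell are assigned, by best-tau
argmax over an 8×8 grid, to a cell within one grid step in at least 80%
of seeded runs. Two facts shape this experiment. First, the similarity
surface is genuinely degenerate along the direction of constant relative
drive $I - I_c(w)$ — a model property, not an implementation artifact —
so recovery is only meaningful transverse to that ridge. Second, each
map cell's sample is itself one finite simulation; map cells use
100,000-time-unit runs (observations use 60,000) so that cell-to-cell
sampling noise does not dominate the ridge structure.

## The E–I extension (adapting inhibition-stabilized network)

To ask how an *excitatory* input can end an UP state, the package also
implements the three-variable network in which fast inhibition stabilizes
a low-rate UP state and slow adaptation acts on E:

$$\tau_e \dot r_e = -r_e + R_{e,\infty}(w_{ee} r_e - w_{ei} r_i - b a + I_e + \xi_e),$$
$$\tau_i \dot r_i = -r_i + R_{i,\infty}(w_{ie} r_e - w_{ii} r_i + I_i + \xi_i),$$
$$\tau_a \dot a = -a + A_\infty(r_e),$$

with threshold power-law transfer (exponent 2), $\tau_e = \tau_i = 5$ ms
and $\tau_a = 200$ ms. The captioned weights print only "$w_e = 4$,
$w_i = 3$"; read as source-labelled weights onto E. A fully symmetric
completion is provably unstable at the UP state (the trace of the
fast-subsystem Jacobian is positive), so the unprinted entries were
calibrated: $w_{ie} = 4$, $w_{ii} = 2$, inhibitory gain 3, $I_i = -1$,
$I_e = 0.3$, $b = 0.7$. These deliver the reference structure: with
adaptation frozen the fast subsystem is bistable at low drive — stable
DOWN node, saddle, and a stable-*spiral* UP state whose complex
eigenvalues produce the damped E–I ripple at DOWN→UP transitions — and
the full system classifies Excitable_UP, where a brief **excitatory**
pulse to E recruits enough inhibition to evoke a transient DOWN state
(the paradoxical ISN response). The separatrix between the UP and DOWN
basins is computed by reverse-time integration from a $10^{-6}$ offset
along the saddle's stable eigendirection, terminated at the phase-plane
bounding box; points are assigned to basins by crossing parity of the
segment joining them to the UP fixed point.

```{r ei}
pe <- ei_params()
ei_fixed_points(pe, a_frozen = 0)$fixed_points[, 1:4]
ei_regime(pe)$label
```

## LFP event detection

The in-vivo half of the pipeline extracts dwell times from extracellular
recordings (1250 Hz multichannel LFP plus per-unit spike times):

* **NREM scoring** — FFT spectrogram in 10 s windows at 1 s steps on
  log-spaced 1–100 Hz frequencies, log-transformed, per-frequency
  z-scored, projected on a slow-wave weight vector (default: contrast of
  ≤ 6 Hz against ≥ 32 Hz, a fixed surrogate for dataset-derived principal
  component weights); the threshold is the trough between the metric's two
  modes, and a unimodal metric yields a warning and no NREM.
* **Slow-wave detection** — coincidence of a delta-band (0.5–8 Hz) peak
  and a high-gamma (100–400 Hz) power drop, each found with a dual
  peak/window threshold calibrated per recording from spiking: candidate
  delta peaks above 0.25 SD are binned by magnitude (0.1 SD bins); the
  spike PETH (±1 s, 20 ms bins) around each bin's peaks is normalized by
  the all-bin mean rate; the peak threshold is the smallest magnitude at
  which spiking at the peak falls below the sensitivity fraction (default
  0.5) of the mean; the window threshold is the average signal level at
  the sensitivity crossings. Gamma power is smoothed over 80 ms and
  normalized by a modified z-score, $(x - \mathrm{med})/(1.4826\,
  \mathrm{MAD})$, in a sliding 20 s window. Events shorter than 40 ms and
  DOWN candidates with within-event spiking above the sensitivity level
  are discarded.
* **SWR detection** — coincidence of a 2.5 SD sharp-wave excursion
  (2–50 Hz, deep channel, kept if 20–500 ms) and a 2.5 SD ripple-power
  excursion (80–250 Hz, pyramidal-layer channel, power smoothed 10 ms,
  kept if ≥ 25 ms), merged.
* **Delta stratification** — 1–4 Hz power in the 8 s window around each
  state, normalized to the median over NREM, with states split into
  quantile groups (default 6) for per-group duration statistics.

Band filtering uses a zero-phase filter with the squared-magnitude
response of a 4th-order Butterworth, applied spectrally: the time-domain
forward–backward recursion is numerically unstable at a 0.5 Hz edge on a
1250 Hz signal, while the spectral form is exact, stable at any band, and
keeps event times aligned to within a sample. All detector thresholds are
in normalized (SD or MAD) units, so detection is invariant to a global
gain on the LFP.

## Synthetic recordings: what they do and do not show

`synth_updown_recording()` and `synth_swr_recording()` generate
ground-truthed recordings so every detector is testable without data
downloads. Defaults are the in-vivo summary statistics: UP dwell times
lognormal (mean 1.7 s, CV 1.1), DOWN gamma (mean 0.21 s, CV 0.38), ~24
units at ~5 Hz in UP and silent in DOWN; SWRs of gamma-distributed
duration (mean 60 ms, floored at 30 ms since in-vivo SWR samples are
detector-defined and contain no sub-25 ms events) with a 150 Hz ripple
under a flat-top envelope and exponential ~2 s gaps. The LFP model is
deliberately phenomenological — a unit-SD noise floor plus a one-cycle
raised-cosine delta deflection spanning each DOWN state and band-limited
100–400 Hz activity during UP states. Passing detector tests on these
recordings demonstrates that the algorithms implement their stated rules
and recover events whose signatures match the assumed structure; it does
not demonstrate robustness to real-data nuisances (non-stationary
artifacts, volume conduction, spike-sorting errors, state transitions
within windows), which the visual-scoring quality control used with real
recordings would address.

## Numerical choices

* Fixed points: sign-change bracketing of the scalar steady-state
  residual on a 2000-point grid over the admissible range
  $[0, \max R_\infty]$, refined by bisection to $10^{-8}$; stability from
  the full Jacobian. For the E–I system the inner inhibitory nullcline is
  solved by monotone elementwise bisection (the residual is strictly
  increasing in $r_i$), vectorized over the scan grid.
* Folds of the logistic nullcline are closed-form (roots of
  $w\,g\,r(1 - r/r_{max}) = r_{max}$-scaled quadratic); they exist iff
  $w \cdot g \cdot r_{max} > 4$ and delimit the DOWN/middle/UP branches.
* Limit-cycle probe: noise-free run of $120\,\tau_a$ from a perturbed
  start, declaring a cycle when ≥ 5 consecutive inter-peak intervals
  agree within 5%. (A $50\,\tau_a$ window proved too short: the
  relaxation period reaches $\sim 8\,\tau_a$, leaving too few cycles to
  test the interval-consistency rule.)
* Saddle-node drives are reported at bracketing grid-cell edges; Hopf
  points at sign changes of the real part of a complex pair along a
  branch.
* Ties: first maximum in the tau scan and grid argmax; histogram peak
  ties resolve toward the larger mode.
* Degenerate inputs error early with named reasons (constant traces close
  the gate with a warning; a missing saddle names the structure found).

## Known limitations

* The five-fixed-point configuration beyond the pitchfork boundary is
  classified by stable-point location only; its sub-structure is not
  labelled.
* The hippocampal model reproduces SWR-state statistics but, as in the
  original account, understates inter-SWR variability (no SWR-burst
  mechanism).
* The NREM scorer's 10 s windows smear state boundaries by a few seconds;
  scoring agreement is evaluated on recordings whose states are long
  relative to the window.
* `evoked_probability()` at amplitude zero measures the spontaneous
  transition rate in the probe window, which is nonzero in noisy
  excitable regimes by design.
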