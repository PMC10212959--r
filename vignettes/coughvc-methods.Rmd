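---
title: "Estimating vital capacity from cough sounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating vital capacity from cough sounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coughvc)
```

## The problem

Vital capacity (VC, liters) — the largest volume a person can exhale after
a maximal inspiration — is a core index of lung function, but measuring it
requires a spirometer, a mouthpiece, and clinic attendance. Voluntary
cough sounds offer a contact-free surrogate: cough peak flow (CPF, L/min),
an index of airway-clearance ability, correlates with VC and leaves an
acoustic signature whose peak sound pressure level (SPL) can be captured
by an ordinary microphone. `coughvc` implements the full chain from raw
cough audio to a screening decision:

1. **acoustics** — band-pass filtering, peak-segment extraction, and
   session SPL (dB re 20 µPa) from microphone voltage;
2. **cough_flow** — cough peak flow computed from SPL and age ("CPS");
3. **reference_vc** — the LMS (lambda-mu-sigma) reference VC and its
   lower limit of normal (LLN);
4. **estimator** — a small tanh perceptron mapping `[CPS, VC_LMS]` (or
   `[SPL, VC_LMS]`) to estimated VC under nested leave-one-out
   cross-validation;
5. **evaluation** — agreement and diagnostic-accuracy statistics;
6. **synthetic_data** + **pipeline** — a seeded generator standing in for
   a real cohort, and a CLI orchestrating everything.

## Acoustic front end

The microphone model maps pressure to voltage through a sensitivity $S$
(dB re 1 V/Pa; default $-35$ dB, an in-ear electret): $V_s = 10^{S/20}$
V/Pa. The instantaneous level of a voltage recording $V_r(t)$ is

$$L_p(t) = 20\log_{10}\frac{|V_r(t)|}{P_0 V_s}, \qquad P_0 = 20\ \mu\text{Pa},$$

the per-trial statistic is $\max_t L_p(t)$ over a 5-s segment containing
the strongest cough, and the session SPL is the maximum over at least
three acceptable trials. Decisions where the procedure was underspecified:

* **Rectification.** $L_p(t)$ is undefined for non-positive voltages; we
  use $|V_r(t)|$. Since the statistic is a maximum this is inconsequential
  for any oscillatory signal; an optional short RMS window
  (`rms_window`) is available for noisy inputs.
* **Filter.** The 140–2000 Hz artifact-rejection band is implemented as a
  zero-phase (forward–backward) Butterworth band-pass, 4th order per
  pass. Zero-phase filtering preserves peak timing and amplitude;
  Butterworth gives a maximally flat passband. Order and band are
  configurable.
* **Segment placement.** The 5-s window is centered on the global
  rectified maximum, shifted only to stay inside the recording; ties go
  to the earliest maximum. This replaces the expert's manual selection
  with a deterministic rule that provably contains the maximum.
* **Processing order.** The full recording is filtered first, then
  segmented. Because boundary transients of a forward–backward filter
  cannot be fully suppressed when strong out-of-band components run
  through the record edges (reflection padding phase-kinks
  high-frequency content), `session_spl` additionally discards a
  settling margin (default 0.25 s) at each record end before the peak
  search. Coughs occur mid-trial, so the margin never clips real
  content.

## Cough peak flow from sound

Flow is tied to sound level and age through

$$\mathrm{CPS} = (a_1 + a_2\,\mathrm{age})\,(e^{\beta\,\mathrm{SPL}} - 1),$$

strictly increasing and convex in SPL, exactly zero at SPL = 0. The
constants are calibration outputs, not universal values; the published
source for this model does not print them. The packaged defaults
($a_1 = 42$ L/min, $a_2 = -0.2$ (L/min)/yr, $\beta = 0.025$/dB) were
chosen once so that synthetic cohorts produce cough SPLs near 95–102 dB
and flows near 250–450 L/min — realistic for healthy young and elderly
adults — and are clearly labeled as demonstration values.
`fit_cps_params()` refits them from `(age, SPL, CPF)` triples by ordinary
least squares on flow, with a deterministic initialisation (log-linear
regression for $\beta$, then a linear solve for $a_1, a_2$) so the fit has
no seed dependence; with a single distinct age only the combination
$a_1 + a_2\,\mathrm{age}$ is identified, and the fit says so. Flow is
reported in L/min throughout (the conventional cough-peak-flow unit).

## Reference VC and the lower limit of normal

The adult LMS reference median is log-linear in height and age with
sex-specific coefficients (male intercept $-8.8317$, $\ln h$ coefficient
$2.1043$, $\ln a$ coefficient $-0.1382$; female $-8.0707$, $1.9399$,
$-0.1678$), plus an age-dependent spline contribution $m - s$. The
published spline lookup tables are external data that this package does
not bundle; the spline defaults to zero and can be supplied as a function
or an interpolated `(age, m_minus_s)` table. The LLN is the LMS
percentile at $z$ (default $-1.645$, the 5th percentile):
$M(1 + L S z)^{1/L}$, reducing to $M(1 + Sz)$ at $L = 1$, with a
log-normal option $M e^{Sz}$. The spread $S$ (default 0.12) and skewness
$L$ (default 1) are conservative demonstration values used by the
generator and demos — not published reference constants.

## The neural estimator

A three-layer perceptron — identity input layer, $H$ tanh hidden units,
identity output — has exactly $4H + 1$ weights and biases. Features and
target are standardised on the training split only (population SD, which
keeps training exactly invariant under dataset duplication); the target
scaling is folded back into the output weights so predictions are in
liters. Training minimises RMSE by full-batch gradient descent with a
backtracking step (halve until the loss decreases, grow 1.1× on
acceptance), five seeded random restarts, and three stopping rules:
gradient norm $< 10^{-6}$, a maximum of 5000 epochs, and a loss plateau
(relative decrease $< 10^{-9}$ over 25 epochs). The plateau rule is an
addition to the originally planned pair: plain gradient descent zigzags
and practically never meets the gradient tolerance, so every fit used to
run to the epoch cap at identical results; the plateau stop cuts runtime
about six-fold and changed no checked RMSE by even one bit. All three
thresholds are configurable (`mlp_hyper()`).

**Nested cross-validation.** The outer loop is leave-one-out. For each
outer fold the $N-1$ training observations are shuffled (seeded) once and
split into halves of size $\lceil\cdot\rceil/\lfloor\cdot\rfloor$; for
each $H \in \{1,2,3\}$ both orientations (train on one half, validate on
the other) are evaluated and averaged, the best mean inner RMSE selects
$H$ (ties to the smallest $H$ — parsimony), and a final model trained on
all $N-1$ predicts the held-out observation. Every seed derives from the
master seed and fold/H indices only, never from data values, so a
held-out label cannot influence its own prediction — a property the
acceptance suite verifies directly.

## The synthetic cohort: what it emulates, what it does not

No public data exist for this task, so the generator states a simple
explicit world mirroring the kind of two-generation study this method is
validated on:

* two generations — 31 young (21.3 ± 0.5 y, 164.3 ± 8.4 cm, 19 male) and
  25 elderly (80.4 ± 6.1 y, 154.1 ± 8.3 cm, 11 male) — with ages clipped
  at 18 y and heights to 130–200 cm. The published design does not state
  per-sex height means, so group means are split by a `sex_height_offset`
  (default 10 cm, male taller) that preserves the pooled group mean; this
  is a documented free parameter.
* true VC is a log-normal perturbation of the LMS reference,
  $VC = VC_{\mathrm{LMS}} e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma_{\log})$ with $\sigma_{\log} = 0.12$ by
  default — the same coefficient of variation the reference model
  assumes, keeping VC positive and the below-LLN fraction near the
  nominal 5%.
* cough peak flow is affine in VC
  ($\mathrm{CPF} = 50 + 80\,VC + \text{aging} + N(0, 30)$ L/min, floored
  at 30), motivated by the significant VC–CPF partial correlation in this
  literature; `vocal_aging_slope` (default 0) adds an extra flow decline
  per year beyond age 20.
* each participant's target SPL is the exact inverse of the flow–sound
  model at their true flow; per-trial waveforms are decaying tone bursts
  (5 ms rise, 40 ms decay, in-band carrier) normalised so the raw peak
  pressure encodes the per-trial SPL exactly, with the first trial forced
  to zero jitter so the session maximum is the target — which makes
  round-trip tests deterministic. Contamination tones below 140 Hz and
  above 2 kHz exercise the band-pass.

A green test on this world establishes that the pipeline's *mechanics*
are correct — SPL round trips, flows invert, the estimator respects
leakage rules and recovers recoverable structure. It does **not**
establish clinical performance: the bursts are not physiological coughs
(no glottal dynamics, airway resonances, sputum or disease effects), the
VC–CPF link is linear by construction, and measured VC equals true VC
(no spirometry error).

### The CPS-versus-SPL mechanism

The claim that the flow-based input (`NNVC_CPS`) should beat the raw
sound-level input (`NNVC_SPL`) rests on the age term of the flow–sound
model correcting vocal aging. In the generator's world this holds when
`vocal_aging_slope` is non-zero but moderate: the acceptance test uses
$-0.7$ (L/min)/yr, i.e. an extra ~40 L/min decline over 60 years beyond
the VC-mediated decline, consistent with observed young-versus-elderly
cough-flow gaps. The property is *not* universal in slope: because
$\mathrm{SPL} = \ln(\mathrm{CPF}/(a_1 + a_2\,\mathrm{age}) + 1)/\beta$,
the SPL feature carries its own age coupling
($\partial\,\mathrm{SPL}/\partial\,\mathrm{age}$ at fixed VC
$\approx a_2\,\mathrm{CPF}/(a_1 + a_2\,\mathrm{age})$ in flow units,
$\approx +2$ (L/min)/yr at the defaults), and a flow-side aging slope
near $-2$ cancels it almost exactly, momentarily making SPL a sufficient
statistic. Away from that degenerate line the CPS variant wins clearly
(mean nested-CV RMSE 0.32 vs 0.39 L over ten seeds at the test
settings).

## Evaluation conventions

* Bland–Altman differences are `measured − estimated` (orientation
  stamped in every result); limits of agreement are mean ± **2** SD
  (2 rather than 1.96; configurable). Fixed bias: one-sample *t* on the
  differences; proportional bias: Pearson correlation of differences
  against means.
* Spearman correlation uses midranks; p-values are exact (full
  permutation) for $n \le 8$, else the *t*-approximation.
* The Friedman statistic includes the tie correction; Holm adjustment is
  the step-down rule returning values in input order.
* The signed-rank and Mann–Whitney tests drop zero differences, are
  exact by enumeration for small samples (which handles ties exactly,
  where textbook exact tables cannot), and otherwise use the normal
  approximation with tie and continuity corrections. Between-generation
  contrasts default to the unpaired test — independent groups of 31 and
  25 cannot be paired, so the pipeline logs the choice.
* Screening needs a continuous score but the decision rule is binary
  ("estimate below LLN"); the adopted score is `LLN − estimate`, whose
  zero threshold reproduces the decision rule while sweeping it traces
  the ROC. AUC is the tie-aware Mann–Whitney probability; the DeLong
  comparison uses placement-value covariances (verified against a
  delete-one jackknife, to which it is algebraically identical).
  `TPR + FNR = 1` by construction.

## Numerical and degenerate-input choices

* Filter design is the textbook chain (analog Butterworth prototype →
  low-pass-to-band-pass transform → bilinear transform with pre-warping),
  validated during development against an independent reference
  implementation to ~1e-16 coefficient agreement; filtering uses a
  direct-form-II-transposed loop with step-matched initial conditions.
* Exact zero samples map to a $-\infty$ SPL sentinel and are excluded
  from maxima; an all-silent trial is an error, not a number.
* `compute_cps` refuses ages where $a_1 + a_2\,\mathrm{age} \le 0$
  ("outside calibrated range") rather than extrapolating to negative
  flows; the inverse refuses ratios $\le -1$.
* Zero-variance differences in Bland–Altman leave the *t*-test undefined
  but still report the mean difference; a zero-variance DeLong difference
  reports p = 1 with a degeneracy flag.
* Single-class screening labels mark the ROC section unavailable and
  leave the rest of the report intact.

## Known limitations

* The generator's waveforms share one carrier and envelope family; they
  exercise the SPL path, not cough classification or detection.
* The flow–sound constants and LMS spread defaults are demonstration
  values; real deployments must supply calibrated constants and
  reference tables.
* The estimator reproduces the *architecture and protocol* of the
  method, not any specific proprietary optimizer; distinct optimizers
  reach slightly different weights at equal protocol.
* Sampling rates in tests are 16–20 kHz rather than the 100 kHz of the
  original acquisition; every quantity under test is band-limited below
  2 kHz, so this changes nothing but runtime.
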