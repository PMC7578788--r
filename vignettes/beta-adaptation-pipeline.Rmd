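---
title: "Pre-movement beta power across visuomotor adaptation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pre-movement beta power across visuomotor adaptation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betadapt)
library(dplyr)
```

betadapt studies one question: does sensorimotor beta-band (15–25 Hz)
power in the pre-movement preparatory window drop when the motor system
is adapting hardest — i.e., does reduced pre-movement beta index an
*adaptive drive*? The package provides the full measurement chain for
that question (simulation, preprocessing, spectral analysis, inference)
so that every stage can be validated against known ground truth without
any recorded data.

## The behavioural model

Human sessions follow a 200/200/200 baseline–adaptation–washout joystick
schedule with four diagonal targets presented pseudorandomly in balanced
20-trial blocks. During adaptation a clockwise cursor rotation
`r` (default 30°) perturbs the mapping. Behaviour is generated by a
single-rate error-driven state-space learner,

$$e_n = r_n - x_n + \varepsilon_n, \qquad
  x_{n+1} = A\,x_n + B\,(r_n - x_n),$$

with internal estimate $x_1 = 0$, retention $A$ and learning rate $B$.
The reported endpoint error is $-e_n$, so adaptation errors are
clockwise (negative) under a clockwise rotation and washout opens with a
counterclockwise (positive) negative aftereffect. The recursion in error
space is $e_{n+1} = r(1-A) + (A-B)e_n$: errors decay geometrically at
rate $A-B$ towards the fixed point $r(1-A)/(1-A+B)$. A two-rate learner
would add fast/slow dissociations (spontaneous recovery) that nothing
downstream consumes, so the single-rate form was kept and its ground
truth (state and perceived error per trial) is returned with the trial
table. One caveat discovered while testing: the *magnitude* of the error
is only monotone when $A \ge B$; when $B > A$ the learner overshoots and
$|e_n|$ rebounds towards the fixed point, although the distance to the
fixed point still decays monotonically for any $A, B \in [0,1]$.

Defaults $A = 0.99$, $B = 0.08$, motor noise SD 4° reproduce the
qualitative session shape: an initial error near the rotation magnitude,
decay to a few degrees of residual clockwise error over some tens of
trials, and an aftereffect of roughly minus the adapted state. Reaction
times and durations are normal draws (350 ± 50 ms and 300 ± 40 ms) with
small additive early-epoch shifts, because slowed early-adaptation
movements are exactly the confound the covariate-adjusted analysis
exists to handle.

Cat sessions are a hit/miss/reject stream: ~20 baseline reaches, a prism
block whose default miss probability decays so that accurate reaching
returns within about ten trials, an end rule of 20 consecutive hits, and
a short post-prism block. Pre-prism hits, prism misses and prism hits
map onto Baseline, early-adaptation and late-adaptation conditions.
Rejection rules are applied separately: reaction time under 150 ms,
duration more than 2 SD above the session mean, late-correction or
noise-artifact flags.

## Epochs

Five 72-trial epochs are fixed, consecutive index sets: Baseline (last
72 baseline trials), EA/LA (first/last 72 adaptation trials), EAft/LAft
(first/last 72 washout trials). The early epochs are *described* by
endpoint errors beyond 2 SD of baseline; because a fixed-length
consecutive block and a per-trial error criterion cannot jointly define
a selection, the 2 SD property is reported as a QC fraction per early
epoch rather than used as a filter. On default synthetic sessions the EA
fraction is high (most early-adaptation errors are far outside baseline
variability), which is the property the epoch is meant to have.

## The synthetic recording

Each channel is unit-SD $1/f^\alpha$ background noise (spectral
synthesis, $\alpha = 1.5$ by default, flattened below 1 Hz so variance
stays finite) plus a beta-band rhythm: a 20 Hz carrier with a per-trial
random phase, amplitude-modulated by a piecewise-constant envelope. The
rhythm is *tonic* — present throughout the trial — with two
modulations: the epoch gain multiplies it during the pre-movement
interval (target onset to movement initiation), and from the
desynchronization onset (default: movement initiation) until movement
end the amplitude is multiplied by $1 - d$ (default $d = 0.5$), the
movement-related desynchronization. The centre channel carries the full
rhythm; its four Laplacian neighbours receive a 0.3-attenuated copy, so
the Hjorth derivation both sharpens the rhythm (keeping 70 % of its
amplitude) and is actually exercised by the synthetic data.

Two choices here matter and were made deliberately:

* **Tonic rhythm, not a pre-movement-only burst.** The analysis
  z-scores each 2 s window by its own SD. If the beta rhythm existed
  only in the pre-movement segment, the gain being measured would also
  scale the window SD, and the normalisation would largely cancel the
  very contrast the pipeline estimates — in the high-SNR limit the
  statistic becomes scale-invariant and the recoverable deficit tops
  out near half its true value. With a tonic rhythm the window SD is
  dominated by gain-independent signal, the cancellation is small, and
  the pre-movement contrast survives normalisation. This is also the
  physiological picture: sensorimotor beta is an idling rhythm that is
  modulated, not gated, by events.
* **Amplitude, not burst rate.** Whether empirical pre-movement beta
  effects are amplitude or burst-rate changes cannot be decided from a
  window-mean band-power statistic, which is insensitive to burstiness
  at fixed mean power; the generator therefore exposes amplitude only.

The carrier amplitude default (3.5 noise-SD units) was calibrated once,
against a noise-only simulation, to put the rhythm ~20 dB above the
in-band $1/f$ floor at the carrier frequency after the Laplacian and
filter chain — a clearly resolvable sensorimotor rhythm. Trials are
laid out on a continuous timeline with margins chosen so that a 2 s
analysis window never overlaps a *neighbouring* trial's gain or
desynchronization segment (only its tonic rhythm), and the record gets
tonic lead-in/out padding; movement-initiation markers are aligned to
the 500 Hz analysis grid so event-locked windows are sample-exact.

What the generator does **not** emulate: ocular/muscle artifacts (the
corresponding cleaning stage is out of scope), burst dynamics, beta
rebound, cross-trial autocorrelation of rhythm amplitude, and volume
conduction beyond the single attenuated-copy neighbour model. Passing
tests therefore show the *measurement chain* is unbiased and calibrated
on data with known structure — not that real EEG satisfies these
assumptions.

## Preprocessing

The derivation stage is linear algebra on channels: Hjorth Laplacian
(centre minus the mean of its four neighbours) for scalp EEG, bipolar
difference for depth-probe LFP. Both commute with the subsequent linear
filters, which the suite checks numerically.

The filter chain is a zero-phase 4th-order Butterworth low-pass at
30 Hz at the native rate, resampling to 500 Hz, and a zero-phase
4th-order Butterworth high-pass at 10 Hz. Decisions:

* **Zero-phase (forward–backward) application**, because pre-movement
  windowing cannot tolerate group delay; the effective order doubles,
  which only widens the margin on every response-bound used in tests.
  The implementation is the standard odd-reflection scheme with
  steady-state initial conditions, with the per-sample recursion
  compiled (session-length series make an interpreted loop the
  bottleneck of the whole pipeline).
* **Low-pass before downsampling**, so the 30 Hz filter doubles as the
  anti-alias filter (new Nyquist 250 Hz ≫ 30 Hz).
* **Integer decimation when possible** (2500 → 500 takes every 5th
  sample), polyphase resampling otherwise.
* **Edge margin**: the first/last 0.25 s of a filtered record are
  treated as unusable; event windows are only cut where they clear that
  margin, and skipped events are logged, not fatal.

Windows are 2 s, centred sample-exactly on movement initiation, and
z-scored by their own mean and SD. Per-window (rather than per-channel)
normalisation follows the stated processing order of the method being
implemented; its interaction with amplitude contrasts is discussed
above and drove the tonic-rhythm design.

## Spectral analysis

The Morlet wavelet has nondimensional frequency $\omega_0 = 6$ (the
conventional reading of "k = 6"), unit-energy normalisation, and the
standard Fourier-factor scale mapping
$s = (\omega_0 + \sqrt{2 + \omega_0^2})/(4\pi f)$. The transform is
computed by frequency-domain multiplication with the signal zero-padded
past the wavelet support, so it equals the linear (non-circular)
convolution; the suite holds it to the explicitly-sampled time-domain
convolution at relative error $10^{-6}$. Each scale carries an
e-folding cone-of-influence mask and masked bins are excluded from every
downstream mean. Power is the natural log of the squared magnitude with
an $\varepsilon = 10^{-12}$ floor: the natural log makes an amplitude
ratio $g$ an exact additive offset of $2\ln g$, which is what the
acceptance analysis recovers. No baseline normalisation is applied
beyond the per-window z-score, since none is part of the described
method. The default grid is 15–25 Hz in 1 Hz steps.

The per-trial statistic is the mean log power over the band and the
trial's pre-movement interval: the full reaction-time interval
$[-rt, 0)$ in human mode, and a fixed EMG-informed window (default
−400 to −200 ms before paw lift) in cat mode, where the EMG-based
placement itself is out of scope and enters as configuration. Empty
intervals (zero reaction time) are flagged missing rather than zero;
reaction times longer than the 1 s pre-event half-window are truncated
to the overlap and flagged.

## Inference

The epoch analysis is a fixed-effects ANCOVA,
`beta ~ epoch + rt + duration (+ subject)`: the omnibus partial F for
the epoch factor, all pairwise contrasts of covariate-adjusted epoch
means (differences of epoch coefficients under treatment coding, t
tests on the coefficient covariance), and Bonferroni correction over
the 10 epoch pairs (3 in cat mode). The original repeated-measures
mixed-model formulation is deliberately replaced: its covariance
structure is not recoverable from the published description, a
fixed-effects model with subject as a factor estimates the same
adjusted contrasts, and the package's own contrast algebra is
cross-checked in the suite against independent reference
implementations (emmeans for adjusted means and pairwise tests, car for
the partial F). Degenerate zero-residual fits report F = 0 when the
epoch factor adds nothing and infinity otherwise, so noise-free
constructions behave as expected.

The balanced bootstrap equalises condition sizes before comparison:
each of 1000 replicates draws `m = min(n_k)` observations with
replacement from every condition and records condition means; reported
are bootstrap means/SEs, percentile 95 % CIs of pairwise differences,
and Bonferroni-adjusted empirical two-sided p values (floored at
$1/n_{boot}$). How the original analysis combined bootstrap replication
with its ANOVA F statistics is not described anywhere, so the package
does not guess: the ANCOVA and the bootstrap are reported side by side
in cat mode.

Spearman correlations (average ranks, t-approximation p values) and the
trial-wise regression of error magnitude on beta power complete the
battery.

## Numerical and reproducibility choices

* Every stochastic stage takes a seed; a session seed expands into
  per-stage sub-seeds through a fixed affine map, so stages can be
  re-run independently and a full pipeline run is byte-reproducible.
* Angles live in degrees (counterclockwise positive, measured from
  vertical; clockwise errors negative), times in ms in trial tables and
  seconds in signal metadata.
* The movement-initiation threshold (5 px) and both 2 SD rules use
  strict inequalities ("exceeded", "greater than"); boundary crossings
  are resolved by linear interpolation between the straddling samples,
  which is exact for piecewise-linear trajectories.
* The statistical acceptance properties run the full pipeline on
  72-trial-per-epoch sessions at a 1000 Hz acquisition rate (the filter
  chain's minimum input rate). The rate only sets the problem size;
  the analysis happens at 500 Hz after resampling either way. At these
  sizes one end-to-end run takes on the order of a second, and the
  suite's 500 seeded runs (100 effect-recovery, 200 null, 200
  covariate-immunity) complete in minutes.

## Known limitations

* The generator's epoch gain is a step function per epoch; real
  adaptation presumably modulates beta continuously with error size.
* Cat aftereffect analysis is not implemented (too few post-prism
  trials by design of the task), and the reversed single-animal effect
  reported for one cat is not modelled.
* The bootstrap balances group sizes but, like the original, does not
  address within-session autocorrelation.
* EDF import/export is not provided; recordings exchange as CSV plus a
  JSON sidecar.
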