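---
title: "Simulating and testing attention-gated timing-prediction effects in epoched EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and testing attention-gated timing-prediction effects in epoched EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatewave)
```

## The scientific setting

`gatewave` models a within-subject EEG experiment in which two factors are
crossed: **modality attention** (MA: a sensory modality is attended or
unattended) and **timing prediction** (TP: the second of two stimuli arrives
with no prediction, at the predicted moment, or violating the prediction —
NTP / MTP / VTP). Epochs are time-locked to the second stimulus (the *zero
point*), with the first stimulus 400 ms earlier. The analysis asks whether
TP-related differences in evoked responses and oscillatory phase locking are
*gated* by attention: present when the modality is attended, absent when it
is not.

The package provides a full, testable chain: a generative model of the
epochs, signal conditioning, ERP window amplitudes, time–frequency
statistics (ITC, ERSP), and the gated repeated-measures testing scheme.

## The generative model

Each trial of a subject × MA × TP cell is a sum of three parts.

**Evoked components** are Gaussian-windowed monophasic deflections

$$s(t) = A \exp\!\left(-\frac{(t - \mu)^2}{2 w^2}\right),$$

with peak latency $\mu$ relative to the locking stimulus, temporal SD $w$,
and signed amplitude $A$ (µV; negative = negativity). A Gaussian is the
minimal waveform that reproduces window-mean amplitudes, which is the only
ERP statistic the analysis consumes. Per-trial amplitude and latency jitter
are independent Gaussians.

**Oscillatory components** are amplitude-gated cosines whose phase at the
locking time is drawn per trial from a von Mises distribution with
concentration $\kappa$. $\kappa = 0$ gives uniform phases (no phase
locking); the expected resultant length of the drawn phases — and hence the
asymptotic ITC of a noise-free cell — is the Bessel ratio
$I_1(\kappa)/I_0(\kappa)$. The envelope is a rectangular gate with 20 ms
Gaussian-smoothed edges to avoid spectral splatter. Sampling uses the
Best–Fisher rejection algorithm.

**Background noise** is $1/f^{\alpha}$ noise (default $\alpha = 1$),
synthesised by shaping a white spectrum in the frequency domain and scaled
analytically (not empirically) so generation stays linear in the underlying
white draw — this is what makes the component-wise additivity property
testable exactly.

Randomness is routed through one named stream per (subject, cell), so
regenerating with the same seed is bit-identical and adding subjects or
cells never perturbs existing draws.

### Default study geometry and calibration

The defaults mirror the target design: 27 subjects, 38 qualified trials per
cell (the midpoint of the 35–40 range), 200 Hz sampling, epochs from −1.0 to
+0.8 s, channels O1/OZ/O2 (visual) or F1/FZ/F2 (auditory). The visual
scenario programs, in attended cells only, a VTP-specific reduction of the
second N1 (−3.5 vs −5 µV), an enhancement of N2 (−2 vs −1 µV) and a drop of
theta phase concentration ($\kappa$ 0.3 vs 1.5); unattended cells are
identical across TP ($\kappa$ 0.9), so any TP effect there is spurious by
construction. The auditory scenario programs an MTP-specific P2 and delta-ITC
enhancement when attended.

Two calibration points are worth recording. First, effect sizes were set
once, before freezing, so that the programmed interaction is reliably
detectable at the study's size: an earlier draft paired a large VTP N2
enhancement with a mild $\kappa$ drop, and the two contributions *cancel* in
the 0.2–0.3 s theta ITC window (the evoked deflection is itself perfectly
phase-locked and raises ITC exactly where the lost oscillatory locking
lowers it). The shipped values keep the evoked N2 effect modest and the
phase-concentration effect strong. Second, the background noise SD (4 µV
per channel) deliberately dominates the 2 µV oscillation: single-trial
phase estimates are noisy, so measured ITC values sit well below the
Bessel-ratio ceiling, as in real EEG.

What the generator does **not** emulate: ocular/muscle artifacts, volume
conduction and realistic topographies, continuous (non-epoched) recordings,
and any coupling between behaviour and the EEG within a trial. Passing
tests therefore validate the *analysis chain*, not claims about real
recordings.

## Preprocessing

The conditioning chain is a zero-phase low-pass FIR filter, integer-factor
downsampling, trial qualification, and baseline correction.

* The filter is a linear-phase Type I (odd-length, symmetric) Hamming-window
  design with cutoff 40 Hz; the order (`~3.3 fs / transition`, 10 Hz
  transition band) is the conventional EEG default. It is applied
  forward–backward with edge-reflection padding, so ERP latencies are not
  shifted and the effective attenuation doubles in dB.
* Downsampling (anti-alias filter at 0.4 × target rate, then decimation)
  keeps the zero point exactly on a sample. Synthetic data are generated at
  200 Hz, so in the default run these two stages are identity-adjacent but
  fully exercised by the tests at 1000 Hz.
* **Trial qualification**: a qualified trial is correct with a reaction time
  of at least 80 ms after the zero point. Button presses earlier than that
  cannot reflect discrimination of the second stimulus and are rejected as
  anticipations. No upper RT cap is imposed. (Reaction time here is measured
  from the second-stimulus onset to the button press.)
* **Baseline correction** uses a 100 ms pre-stimulus window per locking
  stimulus: (−0.5, −0.4) s for first-stimulus components, (−0.1, 0) s for
  second-stimulus components, because the analysis targets evoked responses
  rather than slow anticipatory potentials.

## ERP window amplitudes

An ERP measure is the mean amplitude over a closed temporal window of the
trial-averaged waveform, then the unweighted mean over the component's three
electrodes. Window endpoints are sample-inclusive with a quarter-sample
guard against floating-point boundary ties. The default windows are: visual
first N1 140–200 ms after the first flash (stored as −260 to −200 ms
relative to the zero point — the stimulus-relative definition is the
physiological one and is taken as primary), second N1 120–190 ms, second N2
200–300 ms; auditory first P2 −230 to −180 ms and second P2 110–250 ms
(these are specified zero-point-relative directly). Note the sample mean
converges on the analytic window mean only as the grid refines; at 200 Hz
the quantization deviation for a narrow (20 ms SD) component is a few
percent, which is why the measure is compared across conditions computed the
same way, never against continuous-time values.

## Time–frequency statistics

The decomposition is a complex Morlet wavelet convolution, unit-energy
normalised, on a 1 Hz frequency grid. Cycles rise linearly from 3 (up to
3 Hz) to 8 at 40 Hz — the community default for ITC/ERSP-style analyses —
and are capped so the wavelet (truncated at ±2.5 temporal SDs) fits the
epoch. Samples closer to an epoch edge than the wavelet half-support are
flagged invalid per frequency and excluded from every downstream statistic;
at 1 Hz in a 1.8 s epoch *no* sample is valid, so delta-band means rest on
the valid 2–3 Hz bins rather than silently contaminated ones.

**ITC** is the modulus of the across-trial mean of unit-normalised
coefficients,

$$\mathrm{ITC}(f,t) = \left| \frac{1}{N}\sum_{i=1}^{N}
\frac{F_i(f,t)}{|F_i(f,t)|} \right| \in [0, 1],$$

a phase-only statistic (amplitude-rescaling invariant). Perfect phase
locking gives 1; $N$ uniform phases give $\sqrt{\pi}/(2\sqrt{N})$ in
expectation. Zero coefficients are excluded from that bin's $N$.

**ERSP** is mean power in decibels relative to the 100 ms before the first
stimulus:

$$\mathrm{ERSP}(f,t) = 10\log_{10}\frac{P(f,t)}{B(f)},\qquad
P(f,t) = \frac{1}{N}\sum_i |F_i(f,t)|^2,$$

with $B(f)$ the mean of $P$ over the valid baseline bins at $f$. A doubling
of power reads +3.01 dB; doubling all trial amplitudes cancels in the
ratio. A frequency with no valid baseline bin yields NA with a warning; a
zero baseline power is an error naming the frequency.

Band × window measures are unweighted means over the band's frequency bins
(delta 1–3, theta 4–8, alpha 8–14, beta 15–30 Hz), the window's valid time
bins, and the electrodes. Default ITC windows are (−0.30, −0.15), (0.10,
0.20) and (0.20, 0.30) s (visual; the last is (0.20, 0.40) for auditory);
ERSP windows are (−0.20, −0.10), (0.10, 0.20) and (0.20, 0.40) s for both.

## The gated statistical scheme

Each measure is analysed with a balanced 2 × 3 within-subject ANOVA,
partitioning each effect against its own subject × effect interaction; with
27 subjects the TP and interaction effects carry df (2, 52) and MA df
(1, 26). No sphericity correction is applied by default (a
Greenhouse–Geisser flag exists); effect size is partial eta squared,
$SS_{\mathrm{eff}} / (SS_{\mathrm{eff}} + SS_{\mathrm{err}})$.

The decision tree runs at $\alpha = 0.05$ (the gate level is a package
choice; it matches the reporting convention of the design): test the MA × TP
interaction first. If significant, test the simple effect of TP within each
MA level and, where that is significant, report Bonferroni-corrected
pairwise TP contrasts ($p_{\mathrm{adj}} = \min(1, 3p)$ — the correction is
applied within each family of three pairs, not across measures). If the
interaction is not significant, test the two main effects instead, following
a significant TP main effect with its pairwise contrasts. Zero-variance
contrasts are reported as $p = 1$ rather than NaN so batch simulations stay
total. This nesting is what controls the false-positive rate of the *final*
pairwise claims under the global null — a property the test suite measures
directly over 2000 simulated null datasets.

Behavioural measures (per-subject mean RT over qualified trials; accuracy =
qualified / total trials) get one-way within-subject ANOVAs across TP per
attention level, Bonferroni pairs, and a paired t-test between modalities.
Degenerate cases (accuracy identically 1) are flagged non-testable rather
than erroring.

## Numerical choices and degenerate inputs

* von Mises sampling short-circuits $\kappa \ge 10^5$ to the point mass at
  the preferred phase (the rejection step is numerically meaningless there).
* The 1/f spectrum shaper zeroes the DC gain, so generated noise is
  mean-free by construction.
* The window-index helper treats both window endpoints as inclusive with a
  quarter-sample epsilon; all window conventions in the package share it.
* An epoch too short for the requested lowest-frequency wavelet raises an
  error stating the minimum epoch length instead of returning edge-dominated
  coefficients.
* `rm_anova_2way` on a zero-variance table reports F = 0, p = 1 rather than
  0/0.
* The epoch container stores time as (sampling rate, zero-point index), so a
  uniform grid cannot be corrupted by accumulated floating-point steps, and
  the payload is 64-bit floats so the write/read round trip is bit-exact.

## Problem sizes used by the test suite

The suite exercises the chain at several scales, chosen as the smallest
sizes at which each property is statistically meaningful: phase-recovery
checks at 2000 trials (Bessel-ratio tolerance ±0.02–0.03); the type-I
simulation at 2000 datasets of 12 subjects × 20 trials/cell on one channel;
effect recovery at the full 27-subject geometry over 100 seeded runs; ANOVA
oracle equivalence over 50 random balanced tables of up to 8 subjects. The
acceptance script re-runs the same computations with simulation counts
scaled to its own runtime (600 null datasets, 40 recovery runs) and reports
every quantity from a fresh computation.

## Known limitations

* The generator's phase-locked oscillation plus independent 1/f noise is a
  convenient approximation; real EEG phase locking arises partly from phase
  reset of ongoing rhythms, which this model does not distinguish from
  additive evoked oscillations — no test here can adjudicate between those
  accounts.
* ITC maps are not baseline-corrected (none is standard for ITC); ERSP's
  single pre-first-stimulus baseline means slow drifts between baseline and
  epoch end masquerade as power changes.
* The univariate ANOVA without sphericity correction is anti-conservative
  under strong non-sphericity; the GG flag is available but off by default
  to match the design's reporting convention.
* Edge-validity flags make delta-band windows rest on few (or at 1 Hz, no)
  valid bins in the 1.8 s epoch; longer epochs are the only principled fix.
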