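---
title: "Simulating and analysing automated bilayer single-channel recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing automated bilayer single-channel recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autobilayer)
```

## The problem

Artificial (planar) lipid bilayer recording reconstitutes ion channels in
a synthetic membrane and measures the picoampere currents through single
channels under voltage clamp. Automated instruments form such bilayers by
lowering a functionalized probe through a layer of lipid solution into an
aqueous chamber: the current stream shows a large transient when the probe
touches the lipid, a quiet baseline while the bilayer thins, discrete
gating steps once channels are in the membrane, and a sustained large
current if the membrane ruptures. The instrument's software must recognise
these signatures and drive the probe accordingly.

`autobilayer` implements this measurement system as pure software: a
simulator that generates acquisition streams with the statistical
structure above, the rule-based detector and feedback controller that
operate on them, and the downstream single-channel analysis (idealization,
unitary amplitudes, current–voltage conductance fits, blocker comparisons,
membrane geometry). Because the simulator's ground truth is known, every
analysis stage can be validated quantitatively — which is the package's
purpose.

## The gating model

Each channel is a two-state continuous-time Markov chain,
closed ⇌ open, with exponentially distributed dwell times of means
$\tau_o$ (`mean_open`) and $\tau_c$ (`mean_closed`). The stationary open
probability is $P_o = \tau_o / (\tau_o + \tau_c)$; a `channel_scenario`
keeps the three quantities mutually consistent (any two determine the
third). The initial state is drawn from the stationary law, so
time-averaged statistics need no burn-in. The renderer truncates the final
dwell at the trace end; no partial-dwell correction is applied.

A channel open at voltage $V$ contributes the unitary current

$$ i = g \,(V - E_{rev}) / 1000 \quad \text{[pA, with } g \text{ in pS
and } V \text{ in mV]}, $$

outward currents positive. $E_{rev} = 0$ mV by default, appropriate for a
K⁺ channel in symmetric 200 mM K⁺ solutions. Channels gate independently;
with noise disabled every sample is exactly $k\,i$ for an integer
$0 \le k \le$ channel count, which the tests exploit.

**Channel incorporation.** How many channels end up in a bilayer is
random; conditioned on a recording existing at all, at least one did. We
model the count as a zero-truncated Poisson law,
$P(K = k \mid K \ge 1)$, and default the intensity to $\lambda = 0.6$,
which gives conditional probabilities of roughly 73 % single, 22 % double,
and 5 % higher — close to the single/double/multiple split reported for
the hardware this emulates (71/20/9 %). This distribution family is a
modelling choice of this package, not a measured property.

**Kinetic defaults.** The source experiments did not quantify gating
kinetics, so the presets use synthetic values chosen to look like the
respective channels: the E71A-like presets use $P_o = 0.85$,
$\tau_o = 100$ ms (the mutant is used precisely because its open
probability is high); the wild-type presets use $P_o = 0.10$,
$\tau_o = 20$ ms. Only the conductances (103.6, 127.6, 90.2, 52.2 pS) are
published values.

**Noise.** Default background is Gaussian with 0.5 pA RMS (low-passed at
1 kHz), a slow linear drift of 0.2 pA/s, and sparse rectangular background
spikes (0.02 s⁻¹, 3 pA, 2 ms, random sign). The spike width is
deliberately below the detector's minimum return time so that a correct
detector classifies them as background. The real instrument's noise
spectrum was not quantified; these are stated defaults, not fits.

**TEA block.** The blocker's effect appears in the data as a smaller
apparent single-channel current; we model it as a reduced conductance
preset (52.2 vs 90.2 pS), not as resolved fast flicker. Analyses that
depend on flicker kinetics are therefore out of scope.

## The detection rule

The acquisition software's channel-current rule, applied at the 1 kHz
analysis rate (10 kHz archival data are block-mean decimated first):

> a current that changes by more than 2 pA within 10 ms and then returns
> to its original value within 0.01–1 s is a channel current.

Operationalization, since "original value" needs a tolerance and "within
10 ms" needs an anchor:

* the per-sample baseline is a trailing running median (100 ms window,
  rounded to an odd sample count), **frozen at candidate onset** so an
  event cannot contaminate its own reference;
* the onset criterion is satisfied when the span from the last
  baseline-conforming sample to the first sample beyond the 2 pA
  threshold is at most 10 ms;
* "returned" means re-entry into baseline ± 1 pA (half the amplitude
  threshold; the original tolerance is unspecified);
* both polarities qualify (channels at negative voltages give negative
  currents);
* overlapping candidates: first onset wins, search resumes after the
  winning event.

Excursions that return too early are classified `background_spike`; those
that never return adopt the shifted level as the new baseline (level
tracking) and are classified `background_spike`, or `contact_transient`
when they exceed the 100 pA contact threshold. After an event returns,
the frozen baseline is held until the running median re-converges, which
prevents the decaying median from firing a spurious mirror event after a
long excursion.

For noiseless rectangular pulses the implementation is provably an
indicator function of (amplitude > 2 pA) ∧ (10 ms ≤ duration ≤ 1 s); the
test suite verifies this exhaustively on an amplitude × duration grid
against a brute-force statement of the rule.

## The acquisition controller

The state machine mirrors the published control flow with its stated
constants: descend at 260 µm/s; on the contact transient (|I| > 100 pA)
stop for 10 s; then advance 10 µm every 2 s, analysing each 2-s window
with the rule above; terminate in `DETECTED_HOLD` on the first window
containing a channel event, `ABORTED_RUPTURE` on a sustained (≥ 2 s)
large current, or `FAILED_MAX_DEPTH` at the 5000 µm safety depth (the
real instrument's maximum is not stated). The search voltage defaults to
−60 mV. Time is simulated and advanced by the controller, so runs are
exactly reproducible; with contact at 2600 µm and bilayer formation at
2650 µm the arithmetic gives detection at
$2600/260 + 10 + 5 \times 2 = 30$ s, which the tests assert.

The simulated stream only produces channel current at probe depths at or
below the formation depth, enforces a single contact transient at first
arrival at the contact depth, and keeps gating state continuous across
the controller's chunked queries. A `periodic` gating mode (square wave
with the scenario's mean dwell times) exists solely to make
controller-timing fixtures deterministic; scientific runs use the Markov
mode.

## Idealization

Idealization converts a noisy trace into integer open-level counts per
sample. We use half-amplitude threshold logic: given a unitary amplitude
$u$, a sample belongs to level $k$ when $|I - b|$ falls within
$[(k-\tfrac12)|u|, (k+\tfrac12)|u|)$, where $b(t)$ is the closed-level
baseline. The practical difficulties are that $b(t)$ drifts (6 pA over a
30-s default trace — larger than some unitary currents) and that the
initial $u$ is only approximate. The algorithm:

1. **Seed amplitude.** `estimate_unitary()` runs the detector and takes
   the median absolute channel-event amplitude; the sign follows the
   holding voltage (event polarity alone cannot distinguish openings from
   closures when the channel is mostly open).
2. **Initial baseline.** Per 1-s segment, the low decile of the samples
   (high decile for negative $u$) sits inside the lowest occupied level's
   cluster, at worst one level off. Segment estimates are *snapped*:
   integer-$u$ jumps between neighbouring segments are removed, because
   true drift between segments (≈ 0.2 pA) is far below $|u|/2$ for any
   measurable amplitude. Linear interpolation gives $b(t)$.
3. **Refinement (two passes).** Re-estimate the baseline as the
   segmentwise median of closed-assigned samples (exactly on the baseline,
   immune to an inaccurate $u$; segments without enough closed samples
   fall back to the median of $I - k u$), reassign levels, then
   re-estimate $u$ as the median of $(I - b)/k$ over open samples — a
   robust statistic that ignores the misassigned tails a wrong seed
   produces. An estimate that shrinks below 40 % of the seed is rejected:
   the seed comes from events that cleared the detection threshold, so
   shrinkage that strong means the ladder has locked onto noise.
4. **Half-ladder guard.** A strongly underestimated $u$ can converge to
   $u/2$ with all openings on even levels; since real gating never leaves
   odd levels essentially empty (< 5 % of open samples), that pattern
   triggers a doubling of $u$ and reassignment.
5. **Anchoring and merging.** The ladder is shifted so the lowest level
   occupied ≥ 1 % of the trace is level 0, stray negatives are clamped,
   and dwells shorter than 2 samples are merged into their neighbours
   (the missed-event threshold: 0.2 ms at 10 kHz). Samples are median-3
   filtered before assignment.

With these safeguards the idealizer tolerates seed errors of ±30 % and
recovers noiseless dwell structures exactly wherever dwells are at least
2 samples long; sub-threshold dwells are merged *by design*, which is why
the exact-recovery tests exclude them and the refined amplitude is
asserted only to 0.1 %.

The refined **unitary amplitude** is the OLS slope of the
baseline-corrected current on the level count — identical to "mean open
current minus mean closed current" in the two-level case, and the
occupancy-weighted level spacing in general. Reported amplitudes are
signed.

## I–V fitting and condition comparison

`measure_iv()` runs the full pipeline per voltage over the default grid
−100…+100 mV in 20-mV steps (the published figures show ±100 mV ranges
without listing their grids) with 30-s recordings, and fits an unweighted
OLS line through the (V, i) points; the slope in pA/mV × 1000 is the
slope conductance in pS. Voltages whose seed amplitude is below the
detector's 2 pA threshold are reported `NA` and excluded — at those
voltages (near the reversal potential) openings are genuinely
indistinguishable from noise, exactly as in the real experiment, and a
half-amplitude idealization seeded below ~4 standard deviations of the
noise floor returns attenuated garbage rather than failing loudly. The
intercept is left free; dropping near-reversal points therefore does not
bias the slope.

`compare_conditions()` summarises per-recording conductances per
condition (mean, SD, n), reports the conductance ratio, and applies
Welch's unequal-variance t-test via `welch_t_from_summary()`
($t = (m_1 - m_2)/\sqrt{s_1^2/n_1 + s_2^2/n_2}$ with Welch–Satterthwaite
degrees of freedom) — the test the source experiments used for group
comparisons. Zero-variance corner cases are defined explicitly: equal
means give $t = 0$, unequal means an infinite-$t$ flag.

`membrane_area()` is the capacitance arithmetic
$A = C / c_{spec}$ with unit conversion (nF over µF/cm² → 0.1 mm² per
unit ratio): 1 nF at the conventional 0.4 µF/cm² gives 0.25 mm².

## What the synthetic tests do and do not establish

A green suite establishes that: the detector is exactly the printed rule
on clean pulses and behaves monotonically under the default noise; the
controller reproduces the stated timing arithmetic deterministically; and
the analysis pipeline recovers known conductances from realistic noise,
drift, spikes, stochastic gating, and random channel counts, within the
published dispersions, end to end — including through the full
controller-driven acquisition path.

It does **not** establish anything about real instrument hardware:
electrode chemistry, membrane mechanics, actual noise spectra, seal
quality, or detection success rates at near-threshold amplitudes (the
real system's reported difficulty below 5 pA depends on its particular
noise floor). The simulator's gating kinetics, contact-transient
magnitude, and noise parameters are stated defaults, so quantities that
depend on them (event counts per window, detection latencies within a
window) are internally consistent rather than field-calibrated.
Conductance recovery is meaningful precisely because it does *not* depend
on those choices.

## Numerical and design choices

* Detection at 1 kHz, recording at 10 kHz; decimation is block-mean.
* Baseline windows are rounded to odd sample counts (median symmetry).
* The running-median prefix uses an expanding median; windows longer than
  the trace degrade to the global median.
* The controller analyses the full 2-s chunk after each step; it does not
  attempt partial-chunk early termination. Failed runs terminate (the
  real system's retry behaviour is not described).
* Scenario JSON presets are the single source of preset parameters; the
  fixture generator's manifest repeats them and the tests assert the two
  agree.
* ATF 1.0 is the interchange format (time to 6 decimals, current to 4);
  the TSV dialect is the native format; ABF (binary) is out of scope.
* Seeds: every stochastic entry point takes an integer seed, sub-seeds
  are derived with a multiplicative-congruential scrambler kept below
  2³¹, and the caller's RNG state is always restored.

## Known limitations

* Two-state gating only; no bursts, no subconductance states, no
  hidden-Markov idealization.
* The TEA model scales amplitude; flicker-based blocker analyses cannot
  be exercised.
* Idealization assumes one unitary amplitude per trace (no mixed channel
  populations) and can, in principle, lock one level off for very high
  open probabilities with multiple channels — the maximum-level count is
  then conservative, although level *spacing* (hence conductance) is
  unaffected.
* The detector's amplitude estimate is a median over the event span;
  extremely short events at 1 kHz (1–2 samples) are attenuated by
  decimation, which slightly biases the seed amplitude at low voltages.
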