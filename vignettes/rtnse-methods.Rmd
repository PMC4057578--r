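---
title: "Methods: real-time ensemble-average spectral estimation"
author: "rtnse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-time ensemble-average spectral estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtnse)
```

## The estimator

The package implements a period-domain power spectral estimator for
uniformly sampled biomedical time series, aimed at dominant-frequency
analysis of fractionated atrial electrograms in the 3-12 Hz
electrophysiologic band. Instead of projecting the signal onto frequency
bins, the estimator asks directly, for every integer candidate period $w$:
how much does the signal reinforce itself when cut into consecutive
segments of length $w$ and averaged?

Let $x$ be the analysis window of $N$ samples, normalized to zero mean and
unit variance, and let $n = \lfloor N / w \rfloor$. Writing $x_{w,i}$ for
the $i$-th whole length-$w$ segment (the trailing $N - nw$ samples are
discarded), the ensemble mean is

$$\bar e_w = \frac{1}{n} \sum_{i=1}^{n} x_{w,i},$$

and the spectral point plotted at frequency $f = \mathrm{rate} / w$ is the
$\sqrt n$-scaled root-mean-square ensemble power in its implemented
$1/\sqrt N$ form:

$$S_w = \frac{1}{\sqrt N} \,\Bigl\lVert \sum_{i=1}^{n} x_{w,i} \Bigr\rVert.$$

For uncorrelated (noise) content the segment sums grow like $\sqrt n$, so
$E[S_w^2] = n w / N \approx 1$: the $\sqrt n$ scaling flattens the
white-noise baseline across periods, making teeth at different periods
directly comparable. For an exactly $w_0$-periodic unit-variance window
with $N = n w_0$, $S_{w_0} = \sqrt{n} = \sqrt{N / w_0}$. Both facts are
verified by the test suite (Monte-Carlo baseline flatness; closed-form
peak height to $10^{-6}$ relative).

The exact algebra of the RMS-power form yields a $1/\sqrt{n w}$ scaling;
the implemented form substitutes $1/\sqrt N$ under $n w \approx N$. We
follow the implemented form, whose relative deviation is below $w/N$, and
the offline path is tested against a naive loop transcription of the
defining sums at $10^{-9}$ relative tolerance.

At 977 Hz the 3-12 Hz band maps to $w = 325$ down to $81$ — a 245-point
spectrum whose mean frequency spacing, $\overline{\mathrm{rate}/w^2}
\approx 0.038$ Hz at nominal 1 kHz arithmetic, is more than three times
finer than the $0.122$ Hz bin spacing of an 8192-point DFT on the same
band (which covers it with only ~74 bins). Both band edges use
$\lfloor \mathrm{rate}/f \rfloor$, reproducing the 325..81 range even
though $977/81 = 12.06$ Hz slightly exceeds the nominal top edge —
fidelity to the published grid over strict band containment.

### The halved offline path

Because the segment-sum vector at period $w$ is the element-wise sum of
the two halves of the vector at $2w$, the offline computation can derive
the lower half of the period range from the upper half
(`nse_spectrum_offline_halved()`). The shortcut is exact whenever
$\lfloor N/w \rfloor = 2 \lfloor N/2w \rfloor$; when $\lfloor N/w \rfloor$
is odd it silently drops the final segment. The direct path is therefore
the default and the reference; the tests characterize the halved path
exactly, including the dropped-segment cases.

## The streaming form

The real-time form updates a full spectrum after **every** input sample
(moving size $M = 1$). Per period $w$ the state is a ring buffer of $w$
moving-average ensemble means $e$, a running power $P = \sum_j e_j^2$, and
a wrap index. One sample costs, per period: advance the index (mod $w$),
rewrite that single slot with

$$e \leftarrow c_1 e + c_2 x, \qquad c_1 = \frac{n-1}{n},\ c_2 = \frac{1}{n},$$

and adjust $P$ by the difference of squares (old slot value out, new slot
value in). The spectral point is $S_w = n \sqrt{\max(P, 0)} / \sqrt N$.
The update order — read old, write new, adjust $P$ — is fixed, and the hot
loop is implemented in C++; the test suite proves every ring-buffer slot
exactly equal to the scalar recursion applied to the subsampled series
$x_j, x_{j+w}, x_{j+2w}, \dots$, and re-synchronizes $P$ against a fresh
$\sum_j e_j^2$ at $10^{-6}$ relative tolerance. $P$ can drift marginally
negative through floating-point cancellation; it is clamped at zero before
the square root, with a warning.

Two deliberate semantics:

* **Warm-up.** The stream starts from a zero state and emits from the
  first sample; early spectra are rough. At $k = N$ each slot has been
  revisited about $n$ times, so the moving averages carry a cold-start
  attenuation of roughly $1 - (1 - 1/n)^n \approx 1 - e^{-1}$ relative to
  the block average — nearly uniform across $w$ (0.636-0.640 over this
  grid). Shape is preserved; absolute amplitude is not. Comparisons
  between offline and streaming spectra therefore first remove the common
  scale, either by min-max normalization to $[0,1]$ (`profile_rms()`, the
  package's agreement measure, the same normalization the MP/SP
  parameters use) or by standardizing to zero mean and unit variance
  (`standardize_spectrum()`, the overlay protocol). Parameters compared
  across the two implementations are extracted from standardized spectra
  for the same reason: DF, MP and SP are scale-invariant anyway, and DA
  becomes comparable.
* **Index phase.** The first sample lands on slot 1 of every buffer, so
  after $k$ samples the wrap index is $(k-1) \bmod w$. Any consistent
  phase yields identical spectra (the norm of the buffer is
  phase-invariant); this one is fixed and documented.

Emission is decoupled from computation: `run_stream(x, cfg, emit_every)`
always updates per sample but materializes spectra every `emit_every`
samples, which keeps desk-scale experiments light without changing any
state arithmetic.

## Spectral parameters

From one spectrum the package extracts the dominant frequency DF and
amplitude DA (global maximum over the band, ties broken toward the lowest
frequency) and the mean MP and population standard deviation SP of the
profile after min-max normalization to $[0,1]$. A peaky, organized
spectrum has large DA and small MP. No peak-width or harmonic guestimates
are involved.

Taking the global band maximum as "the fundamental" is a deliberate
simplification. A strictly periodic event train is also periodic at every
divisor period, and its half-rate tooth in the period domain can rival the
fundamental; conversely a tooth at rational multiples $({p}/{q})\,T$ of
the true period can benefit from better integer rounding (see
*Limitations*). Within the confined 3-12 Hz band and for the sustained,
broad activation complexes the generator produces, the global maximum
recovers the programmed rate in ≥95% of replicates under moderate jitter
and noise, which the acceptance suite verifies; no harmonic screening is
applied.

## The synthetic generator

Clinical recordings are not shipped; the generator stands in with known
ground truth. It emulates:

* repeating biphasic activation complexes (derivative-of-Gaussian, total
  extent $\pm 3\sigma$ equal to `complex_width_ms`) at a programmed
  dominant rate in 3-12 Hz;
* cycle-length jitter, as i.i.d. Gaussian perturbation of each
  activation's **time** around a regular lattice at the programmed rate
  (offsets clamped to $\pm 45\%$ of a cycle so events stay ordered);
* per-complex amplitude variation, additive broadband white noise, an
  optional secondary periodicity (split peaks), and an optional
  piecewise-constant rate schedule (transients); then normalization to
  zero mean and unit variance.

Two generator choices deserve their rationale:

* **Jitter on times, not intervals.** Perturbing inter-event intervals
  makes event times a random walk; over an ~8 s window the accumulated
  phase spread reaches a large fraction of a cycle and no ensemble average
  can recover the rate — the estimator's detection target would be
  destroyed by construction. Anchoring events to a rate lattice models a
  driver-paced process: cycle-to-cycle variability is preserved, long-run
  phase is not lost.
* **Complex duration 100 ms.** Fractionated complexes are prolonged,
  multicomponent deflections (tens to >100 ms), not impulses. Narrow
  (~20 ms) complexes on 85-280 ms cycles behave like impulse trains, whose
  period-domain combs carry rational-ratio teeth as tall as the
  fundamental once sample quantization attenuates incommensurate periods;
  dominant-frequency recovery then fails at any jitter. The 100 ms
  default reflects the sustained local activity the estimator was
  designed for and makes recovery a fair test of the estimator rather
  than of the fixture.

What the generator does **not** model: biophysical propagation, electrode
geometry, acquisition filtering, baseline wander, or the clinical cohort's
parameter magnitudes. Passing tests demonstrate correct arithmetic and
qualitative behavior (organized records score higher DA and lower MP than
disorganized ones), not clinical performance.

The two-class cohort defaults (persistent-like: jitter 0.03, noise 0.3;
paroxysmal-like: jitter 0.15, noise 1.0; per-record rates drawn within
±1.5 Hz of 6.5 / 5.5 Hz) encode only the directional contrast that
electrical activity is less organized in paroxysmal than persistent
atrial fibrillation.

## Numerical conventions and degenerate inputs

* Normalization uses the population variance (divisor $N$); "unit
  variance" is enforced to $10^{-6}$ and idempotence to machine precision.
* Constant signals, flat spectra, non-finite streaming samples, ragged or
  non-numeric input files all raise descriptive errors naming the channel,
  sample counter, or line at fault.
* All internal indexing is 0-based in the C++ core and 1-based at the R
  surface; segment $i$ of period $w$ covers samples $[iw, (i+1)w)$.
* Ties in peak picking go to the lowest frequency; SP uses the population
  convention.

## Problem sizes

The test suite and acceptance script run entirely on synthetic data at
the study's native scales where that is cheap (8192-sample windows, the
245-point grid, 100-replicate recovery experiments, 50-record agreement
cohorts) and at reduced scales for the exhaustive oracle checks (all
periods ≤ 50 for the exact ring-buffer equivalence; $N \le 2000$ for the
naive-transcription bound; $N \le 256$ for the brute-force DFT). The
multichannel design point is exercised as 16 channels × 4096-sample
window × 8192 per-sample updates with one spectrum per sample per
channel.

## Limitations

* The estimator's period grid is integer-valued: a periodicity whose true
  period is far from any integer (at the given rate) is attenuated by
  phase slip across segments, and for impulse-like signals a
  rational-ratio tooth can overtake it. Narrow-complex, low-rate signals
  may report a harmonic or rational multiple as DF; no harmonic screening
  is applied.
* The streaming estimate at a given instant is an exponentially weighted,
  cold-started version of the block estimate: absolute amplitudes are
  attenuated and slightly noisier; all cross-implementation comparisons
  are shape-based after normalization.
* Wall-clock timing (per-update cost, channel capacity) depends entirely
  on the host and is reported informationally by the benchmark
  subcommand; it is never asserted.
* Streaming input is assumed pre-normalized; running normalization is out
  of scope.
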