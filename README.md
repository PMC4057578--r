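# rtnse

Real-time ensemble-average spectral estimation for periodicity analysis of
biomedical time series — built for dominant-frequency (DF) mapping of
fractionated atrial electrograms during atrial fibrillation, where a full
spectral update is wanted for **every new input sample** across many
channels.

## The problem and the estimator

Sliding-window DFT analysis of an electrogram either skips samples (loses
time resolution) or shortens the window (loses frequency resolution), and
recomputing an 8192-point FFT per sample per channel is costly. This
package implements a period-domain alternative. For a normalized window
$x$ of $N$ samples and each integer candidate period $w$ (with
$n = \lfloor N/w \rfloor$ whole segments $x_{w,i}$), the spectral point at
frequency $f = \mathrm{rate}/w$ is

$$S_w = \frac{1}{\sqrt N}\,\Bigl\lVert \textstyle\sum_{i=1}^{n} x_{w,i} \Bigr\rVert ,$$

the $\sqrt n$-scaled RMS power of the ensemble mean: periodic content at
period $w$ reinforces under segment averaging, while noise averages out,
and the scaling flattens the white-noise baseline to ~1 across periods.
At 977 Hz the 3–12 Hz electrophysiologic band maps to periods
$w = 325\ldots81$ — a 245-point spectrum with ~0.038 Hz mean spacing,
more than 3× finer than the 0.122 Hz bins (~74 in band) of an
8192-point DFT.

The streaming form keeps, per period, a ring buffer of $w$ moving-average
ensemble means ($e \leftarrow \frac{n-1}{n} e + \frac{1}{n} x$, one slot
rewritten per sample) and an incrementally maintained sum of squares, so
one input sample costs one multiply-add and one difference-of-squares per
period — a full 245-point spectrum per sample, per channel (hot loop in
C++). The package also provides spectral parameters (DA, DF, MP, SP), a
deliberately unoptimized sliding-window radix-2 DFT baseline, a synthetic
fractionated-electrogram generator with known ground truth, plain-text
multichannel I/O, and a CLI.

## Worked example

```r
library(rtnse)

grid <- build_period_grid(977, 3, 12)
grid
#> <nse_grid> 245 periods, w = 325..81 (3.006-12.062 Hz) @ 977 Hz

## synthetic fractionated electrogram: 6.8 Hz driver, cycle jitter, noise
rec <- generate_electrogram(synthetic_spec(rate = 977, length = 16384,
                                           df = 6.8, seed = 42))

## offline (block) spectrum of the first 8192-sample window
win <- normalize_signal(nse_signal(rec$signal$samples[1:8192], 977))
s_off <- nse_spectrum_offline(win, grid)
extract_params(s_off)
#> DA = 5.211, DF = 6.785 Hz, MP = 0.0757, SP = 0.1248

## streaming: per-sample updates, spectra materialized every 2048 samples
cfg <- stream_config(grid, N = 8192)
spectra <- run_stream(rec$signal, cfg, emit_every = 2048)
spectral_params(spectra)
#>   time_index       DA       DF         MP        SP
#> 1       2048 1.230491 6.832168 0.19626918 0.1800440
#> 2       4096 2.148461 6.784722 0.13126903 0.1500816
#> 3       6144 2.881354 6.784722 0.10196469 0.1340712
#> 4       8192 3.439726 6.784722 0.08235114 0.1262977
#> ...
#> 8      16384 4.247044 6.784722 0.05786745 0.1107159

profile_rms(s_off, get_spectrum(spectra, 4))
#> [1] 0.0168
```

The programmed 6.8 Hz rate is recovered at the nearest grid frequency
(977/144 = 6.785 Hz) from the second emission on. DA grows and MP falls
over the first window as the moving averages warm up from the zero state;
after min–max alignment the streaming spectrum at k = 8192 differs from
the block spectrum by an RMS of 0.017 — the two implementations agree in
shape, and DF/MP/SP (which are scale-invariant) agree directly.

A command-line wrapper ships at `inst/cli/nse.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/nse.R", package = "rtnse"))')" \
  simulate --n 8 --length 8192 --seed 7 --out cohort.txt
Rscript .../nse.R stream  --input cohort.txt --window 8192 --out params.csv
Rscript .../nse.R compare --input cohort.txt --window 8192 --out agreement.csv
```

Subcommands: `offline`, `stream`, `compare`, `simulate`, `benchmark`
(per-update timing, informational only — it is host-dependent).

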