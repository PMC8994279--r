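---
title: "Methods: single-time-point circadian phase inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-time-point circadian phase inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaphase)
```

## The problem

Photoperiod — the length of the daily light phase — resets the plant
circadian clock, and with it the timing of thousands of cycling
transcripts. Measuring that phase change directly requires sampling a
time course around the clock in every condition, which is costly. The
molecular-timetable idea sidesteps this: if we know, for a panel of
"time-indicating" genes, the Zeitgeber time at which each gene normally
peaks, then the relative expression of those genes in a *single* sample
encodes the sample's internal circadian time. Samples collected two
hours after lights-on (ZT2) under long days (LD, 16 h light) and short
days (SD, 8 h light) can then be compared: a difference in their
inferred internal times is the photoperiod-induced phase shift.

`circaphase` implements that analysis end to end for snapshot RNA-seq
designs with several genotypes (e.g. a recipient background and
near-isogenic introgression lines), together with the supporting stages:
determining the cycling gene panel from diel time courses, cosinor
fitting, ANOVA on the inferred phases, rhythm extraction from
free-running leaf-movement traces, and a windowed heterozygosity scan
that delineates the introgressions themselves. A synthetic-data
generator with known ground truth drives every test, so each stage is
verified by parameter recovery rather than by fixture files.

## The generator and what it emulates

On the log2 scale a cycling gene follows

$$x_g(t) = m_g + A_g \cos\!\big(2\pi (t - \phi_g)/\tau\big) + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

with per-gene mesor $m_g \sim N(6, 1)$, amplitude $A_g \sim U(0.5, 2)$
(log2 units), period $\tau = 24$ h and acrophase $\phi_g$ drawn from a
circular mixture: two wrapped-normal components centred at ZT23 and
ZT11 with 2 h spread (40% weight each) plus a 20% uniform background.
This reproduces the strongly bimodal pre-dawn / pre-dusk phase
distribution of plant diel transcriptomes. A quarter of genes cycle by
default, roughly the fraction of expressed transcripts that pass
cycling filters in tomato seedlings. Noise is log-normal and
multiplicative on the count scale (additive Gaussian on log2, default
$\sigma = 0.2$); an optional Poisson layer produces integer counts.

Two designs are emitted:

* **Diel time course** — collections at 12, 16, 20, 24, 28 and 32 h
  with two replicates each. The replicate-to-second-day relabelling
  (add 24 h to replicate 2) is applied by the *cycling* module, not at
  generation, mirroring how such data are post-processed.
* **Snapshot** — genotypes × {SD, LD} × 3 replicates, all collected at
  ZT2. Each sample's expression is the diel model evaluated at internal
  time $\mathrm{ZT2} + \text{genotype offset} + \delta\,[\text{LD}]$,
  with $\delta = 0.8$ h by default — the long-day phase delay the
  analysis is designed to detect.

The generator does **not** emulate library-size or batch confounders,
count overdispersion beyond Poisson, multi-harmonic waveforms, or
asymmetric (sawtooth-like) peaks. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to every artefact of real RNA-seq.

Amplitude and noise magnitudes for real transcripts are not reported in
the source experiments; the defaults here were chosen once for
testability (signal-to-noise high enough that recovery failure signals
a defect, not bad luck) and are not revisited.

## Detecting cycling transcripts

After discarding transcripts with fewer than 10 summed reads and
log-normalising (`log2(CPM+1)` by default; median-of-ratios size
factors optional), each gene is fit by first-harmonic regression
$y = m + a\cos(2\pi t/T) + b\sin(2\pi t/T)$ at every period $T$ on a
0.5 h grid from 20 to 28 h. The SSE-minimising $T$ supplies the period,
amplitude $\sqrt{a^2+b^2}$ and acrophase estimates.

**Calibration vs selection.** Scoring the *selected* period with a
naive F-test is anticonservative: the minimum SSE over 17 correlated
candidate fits inflates the nominal 5% false-positive rate to roughly
13% on this design. `test_cycling()` therefore computes its p-value
from the harmonic fit at a fixed reference period (24 h by default),
whose null distribution is exactly $F(2, n-3)$ under Gaussian noise;
the measured type-I rate is then statistically indistinguishable from
the nominal level, at a modest power cost for genes whose true period
sits at the edge of the window. The selected-period score remains
available (`p_method = "best"`) for users who prefer to match
selection-based detectors. P-values are BH-adjusted across genes.

The filter cascade for the final panel mirrors standard practice for a
two-species design: adjusted $p < 0.05$ in both experiments
(configurable), period within 22–26 h in both, and amplitude and mean
expression within 2.5 SD of their across-gene means (two-sided, on the
scale of the input matrix — log2 here; the original convention is
scale-ambiguous, so the choice is stated rather than hidden). Phases
come from the designated reference experiment, rounded half-up to the
nearest hour, with 24 subtracted when the rounded value exceeds 23 so
bins lie in $\{0,\dots,23\}$. Half-hour ties rounding *up* is a stated
convention of this package.

## Cosinor core

`fit_cosinor()` fits $y = M + A\cos(2\pi(t-\phi)/\tau)$ at fixed
$\tau$ by OLS on the $\cos$/$\sin$ linearisation; $A$ and $\phi$ are
the polar form of the two coefficients and their standard errors are
delta-method transforms of the OLS covariance. The acrophase is
reported as the clock time of the curve maximum in hours (not the
negative-radian angle of the classical cosinor literature), matching
how phases are discussed for diel expression data. Degenerate inputs
are explicit: a constant series yields $A=0$ with an undefined
acrophase (flagged, never silently 0 h); times that coincide modulo
the period are a collinear design and an error.

## Phase inference from one time point — and a normalisation subtlety

For each sample, `estimate_sample_phase()` fits a 24 h cosinor with
the gene phase bins as "time" and the gene z-scores as response; the
fitted acrophase is the sample's internal time.

The z-score scope matters more than it first appears. All snapshot
samples are collected at almost the same internal time, so
standardising each gene *across the snapshot samples* removes exactly
the cosine component that carries the absolute phase; what survives is
its time-derivative, and the per-sample acrophase collapses to the mean
internal time ±6 h depending on the sign of the sample's offset. Any
LD−SD contrast computed this way lands near ±12 h regardless of the
true shift — an identifiability failure of the normalisation, not an
estimation error, and noise does not rescue it. In the degenerate
noise-free case every gene has zero variance across samples and no
z-score exists at all.

The classic molecular-timetable protocol avoids this by normalising
each time-indicating gene with its mean and SD from *reference*
time-course data. The cycling-gene panel built by this package already
carries both (mean expression and amplitude from the harmonic fit; over
a full cycle the cosine SD is $A/\sqrt2$), so
`zscore_genes(..., scope = "reference")` implements exactly that, and
the pipeline uses it by default. In the noise-free case the z-profile
of a sample at internal time $t^*$ is then exactly
$\sqrt2\cos(2\pi(t^*-\phi_g)/24)$ and the acrophase is recovered to
within the phase-binning error (&lt; 0.03 h with 500 genes). The
within-experiment scopes (`"all"`, `"genotype"`) are retained for
visualising relative differences, with their limitation documented.

## Phase-shift statistics

Per-replicate acrophases are unwrapped around their grand circular mean
(each value moved by a multiple of 24 h into the half-period window
around the mean) before linear modelling; with ZT2 sampling the phases
sit far from the wrap point, so this is a formality that nevertheless
makes the code safe for designs near midnight. The model is
`phase ~ genotype * photoperiod`; per-genotype LD−SD contrasts are
estimated marginal means with Šidák adjustment across genotypes, the
overall photoperiod contrast is reported alongside the per-genotype
average (the two coincide in balanced designs), and a compact letter
display over all genotype × photoperiod cells is built from Tukey
all-pairs comparisons. The sign convention is explicit: delaying the
long-day clock yields a positive shift.

## Leaf-movement rhythms

Free-running traces (vertical cotyledon position every 0.5 h for five
days) are detrended by a per-seedling polynomial (linear by default)
and fit with a single-component damped cosine
$y = A e^{-\lambda t}\cos(2\pi(t-\phi)/\tau)$ by Levenberg–Marquardt
least squares, initialised from a least-squares periodogram
(harmonic-regression $R^2$ on a 0.1 h period grid). A periodogram peak
outside the requested period window flags the trace arrhythmic. A
single damped component was chosen over multi-component
Fourier-decomposition fitting because only the dominant component's
period, phase, amplitude and quality metrics feed the downstream
comparisons; bit-compatibility with external curve-fitting services is
a non-goal. Two quality metrics are reported: the relative amplitude
error RAE = SE($A$)/$A$, and ERR = residual SD / signal SD clipped to
[0, 1] — an explicit, documented analogue of the error statistic whose
exact formula external services do not publish. Traces pass QC when
ERR &lt; 0.4 (configurable). Phases are rescaled to circadian time,
$\phi \cdot 24/\tau$, so seedlings with different endogenous periods
are comparable, and are reported relative to the reference genotype's
mean within each experiment batch, since absolute phases are only
comparable within a batch.

## Introgression scan

Genotype calls from a single-sample VCF are classified as homozygous
reference, heterozygous, homozygous alternate or missing; the
heterozygous fraction among non-missing calls is computed in
non-overlapping windows of a fixed number of SNPs (1000 genome-wide,
100 for zoomed views — SNP-count windows, not base-pair windows, so
marker density does not distort the profile). Maximal runs of at least
3 consecutive windows at ≥ 50% heterozygosity are merged into
segments; both thresholds are exposed because the level at which a run
of heterozygosity constitutes an introgression is a judgement call in
any real line. Missing genotypes never enter the denominator. Windows
are reported 1-based inclusive; BED export converts to 0-based
half-open.

## Numerical choices and degenerate inputs

* Round-half-up (`floor(x + 0.5)`) for phase bins; `.5` ties go up.
* Circular differences are reduced to $(-\tau/2, \tau/2]$; exact
  half-period differences resolve to $+\tau/2$.
* Constant genes: $p = 1$, amplitude 0 in the cycling test; dropped
  with a report in z-scoring; flagged in phase estimation.
* The BH step never reorders genes relative to their raw p-values.
* All simulation entry points are deterministic given a seed; the
  pipeline summary contains the full configuration, seed and package
  version, and repeated runs are byte-identical.

## Problem sizes used in the checks

The shipped verification suite works at desk scale, chosen so every
property is measured sharply: snapshot panels of 500–2000 cycling
genes, 200 repetitions for the photoperiod-shift recovery (true 0.8 h
delay; the mean estimate and the detection rate are both checked), 1000
white-noise genes for test calibration against the exact binomial
interval, 4000 genes for power at amplitude/noise 2, 100 damped-cosine
traces for rhythm recovery, and 20 random variant tables compared
against brute-force window/segment recomputation. Transcriptome-scale
inputs (~25,000 genes) run in minutes on a laptop but add nothing to
the verification.

## Known limitations

Single-time-point phase estimates are intrinsically less accurate than
full time-course methods — with one sample per replicate the estimator
leans entirely on the reference panel's phase annotations, and
systematic phase differences between the reference time course and the
snapshot conditions propagate directly into the inferred internal
times. The cycling detector models one harmonic; strongly
non-sinusoidal waveforms lose power and their "phase" is the phase of
the best cosine, not of the waveform peak. The rhythm module assumes
exponential amplitude decay; period lengthening over the run
(relaxation) is not modelled. The introgression scan assumes a single
sample and biallelic sites; it does not assign donor haplotypes.
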