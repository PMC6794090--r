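---
title: "Methods: circadian locomotor and molecular rhythm analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circadian locomotor and molecular rhythm analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circadam)
```

# Overview

`circadam` implements the complete analysis chain for a fly circadian
behavior study: DAM beam-break recordings are binned, phase-annotated,
scored for free-running rhythmicity with two periodograms, and summarized
as percent-rhythmic tables, rhythm power, periods, anticipation indices
and double-plotted actograms; expression time courses are tested for
rhythmic cycling with JTK-Cycle; qPCR dilution series yield primer
efficiencies and relative quantities; nuclear fluorescence is
background-subtracted and counted. This vignette is the package's own
account of the models behind those functions, the parameters that matter,
the numerical decisions taken where the field's conventions are ambiguous,
and the limits of what the synthetic-data tests can show.

# Time, phase and the DAM recording model

A recording is a vector of non-negative counts on a regular grid of
half-open bins `[t, t + w)` (bin-start timestamps). Phase labels are hours
after lights-on, in `[0, 24)`: Zeitgeber time on LD days, circadian time on
DD days. In DD, CT0 is the *projection* of the prior lights-on time — the
only convention supported; day boundaries always fall at phase 0, and the
first `n_ld_days` days of a record are LD, all later days DD. The phase
label advances by `w/60` per bin regardless of any fly's endogenous period;
the biology lives in the counts, not the labels.

Monitor files are the classic 42-column `Monitor*.txt` dialect (index,
`dd-mmm-yy` date, `HH:MM:SS` time, status code, six metadata columns, 32
channel counts). Other layouts are rejected, not guessed at. Rows whose
status code is not 1 are *kept with zero counts and flagged* rather than
dropped: both periodograms assume even sampling, and deleting rows would
silently break that. How real studies handle monitor dropouts is rarely
reported; flag-and-keep is this package's policy, and flagged-bin counts
appear in every per-fly table so the user can exclude flies instead.

Re-binning sums complete constituent bins (total counts are conserved
exactly — an integer identity, tested as such) and drops a trailing
partial bin with a message. The conventional widths are 15 min for
periodograms and 60 min for anticipation indices.

# Periodograms

## Lomb–Scargle

The package uses the floating-mean (least-squares) form: at candidate
period $p$ with $\omega = 2\pi/p$, the power is

$$P(p) = \frac{\mathrm{SS}_{\mathrm{null}} - \mathrm{SS}_{\mathrm{fit}}}{2\,s^2},$$

the reduction in sum of squares from fitting
$x \sim 1 + \cos\omega t + \sin\omega t$, over twice the sample variance
$s^2$ (denominator $N-1$). This form was chosen over the classical
mean-subtracted Scargle recipe because (i) it is *exactly* the
least-squares sinusoid statistic at every period — the identity the test
suite asserts to $10^{-8}$ against an independent `lm()` oracle — and
(ii) on a finite grid $\sum\cos\omega t \ne 0$, so refitting the intercept
is the honest normalization. On a pure sinusoid $P$ attains $(N-1)/2$; on
white noise each $P$ is approximately Exp(1). The significance line at
level $\alpha$ over $M$ tested periods uses the independent-frequency
approximation $-\ln(1-(1-\alpha)^{1/M})$, constant across periods.
Defaults: period grid 18–30 h in steps of one bin width, $\alpha = 0.001$
(the conventional circadian cutoff). No detrending is applied by default
(DD counts are treated as stationary); cohorts with strong day-by-day
damping should be windowed rather than detrended.

Degenerate inputs error early: constant series ("constant signal"), fewer
than 2 days of data, an empty period grid. When the cos/sin regressors are
numerically collinear the power falls back to a one-dimensional
projection; this only arises at periods near twice the record length,
outside the default grid.

## Chi-square (Sokolove–Bushell)

For a candidate period of $P$ bins, the series is folded into $P$ columns
over $K = \lfloor N/P \rfloor$ complete cycles — the trailing partial
cycle is *discarded* (the original method is ambiguous here; discarding
keeps every column mean an average of exactly $K$ values) — and

$$Q_P = \frac{K \sum_h (M_h - \bar M)^2}{\hat\sigma^2}, \qquad
\hat\sigma^2 = \frac{1}{N'}\sum_{i=1}^{N'} (x_i - \bar M)^2,$$

with $N' = KP$ retained bins. Under iid noise $Q_P$ is approximately
$\chi^2_{P-1}$ (checked distributionally in the tests); the significance
line is the $\chi^2_{P-1}$ quantile at $1-\alpha$, so it rises with $P$.
$Q_P$ is invariant to positive affine transforms of the counts. The
candidate grid is every integer multiple of the bin width in 18–30 h
(0.25-h resolution at 15-min bins), which bounds attainable period
accuracy at half a grid step in the best case.

A worked fixture pins the algebra: the alternating series 1,3,1,3,… with
$N = 96$, folded at $P = 2$, gives $Q_P = 96$ exactly and rhythm power
$96 - \chi^2_1(0.999) \approx 85.17$.

# Rhythmicity classification

The rhythmic/arrhythmic gate and the period readout deliberately use
*different* periodograms, mirroring standard practice: a fly is rhythmic
iff its Lomb–Scargle peak exceeds the significance line by more than a
cutoff $\Delta$; its reported period is the chi-square peak period; its
rhythm power is the chi-square peak height above the line, floored at 0
for reporting ("an animal cannot display negative rhythmicity") with the
raw value retained in all tables. Whether commercial software derives its
period readout from the LS or the chi-square peak is not documentable;
the chi-square choice here is a stated convention, not inferred intent.

The classic cutoff $\Delta = 150$ belongs to Clocklab's proprietary power
scale and is kept only as the documented default of `rhythm_config()`.
Under this package's normalization a rhythmic-vs-null gate needs a cutoff
on *this* scale, so `calibrate_delta_threshold()` simulates a seeded
cohort of flat Poisson flies with the same recording geometry (default
9 d DD, 15-min bins) and returns the 99.9th percentile of the null
peak-minus-threshold statistic. The calibrated cutoff is typically a small
negative number — under the null the peak rarely reaches the
$\alpha = 0.001$ line at all — and classification experiments in the
tests and the acceptance script use it throughout. The cutoff is a free
parameter everywhere; no numeric identity with any commercial scale is
claimed.

"Weakly rhythmic" is, in practice, a human actogram-scoring judgment. The
automated proxy is a band above the cutoff: weak iff
$0 < \delta - \Delta \le 2\Delta$ (band width configurable), clearly
labelled in outputs, with the conventional reporting rule that a weak
category under 10% of the cohort is merged into rhythmic. Period mean ±
SEM is computed over rhythmic (including weakly rhythmic) flies only.
Sustained rhythmicity splits the DD window into halves and requires both
to classify rhythmic independently with periods agreeing within 1 h
(default).

# Anticipation indices

With transitions at phase 0 (lights-on) and 12 (lights-off), on hourly
bins:

$$\mathrm{MAI} = \frac{\sum \text{counts, CT 21–23}}{\sum \text{counts, CT 18–23}},
\qquad
\mathrm{EAI} = \frac{\sum \text{counts, CT 9–11}}{\sum \text{counts, CT 6–11}}.$$

The sum-ratio and the mean-hourly-activity-ratio definitions are
algebraically identical because both windows contain whole hourly bins;
sums are implemented. Both indices lie in $[0,1]$ (numerator window is a
subset of the denominator window), equal 0.5 under flat activity, and are
invariant to rescaling the counts. Multi-day spans (e.g. DD days 3–9) sum
counts across days *before* dividing — robust to zero-activity days — with
a mean-of-daily-indices mode behind a flag. A zero 6-h denominator (dead
or inactive fly) makes the index undefined: it becomes `NA`, is excluded
from group statistics, and is written to the run log, since published
cohort n's typically reflect such exclusions silently.

# JTK-Cycle

The test asks whether a time course's *rank order* matches a cosine. For
each period in {20, 24, 28} h and each 4-h phase lag, the reference
pattern is the midrank vector of $\cos(2\pi(t-\mathrm{lag})/p)$ over the
timepoints (cosines rounded to 9 decimals before ranking so one-ulp noise
cannot split a genuine tie); duplicate patterns are deduplicated. The
7-timepoint design CT 1, 5, …, 25 spans one cycle plus one point: CT1 and
CT25 are distinct samples whose phases coincide mod 24, so they share a
rank in every period-24 pattern — this is deliberate and affects the tie
structure of the null.

Kendall's $S$ sums sign-concordances over pairs (ties contribute 0), and
$\tau = S/\sqrt{(n_0 - T_x)(n_0 - T_r)}$, the maximal attainable $|S|$
whenever either vector is tie-free. The exact null of $S$ against a tied
reference, for distinct data, is computed by dynamic programming: pairwise
concordance decomposes over reference tie groups into independent
interleaving-inversion counts, each distributed as partitions in an
$n \times m$ box (a Gaussian binomial), convolved exactly with plain
polynomial multiplication — no FFT, so tail probabilities are exact to
double precision; the suite checks the DP against exhaustive permutation
enumeration. Null distributions are cached by tie-group signature, which
makes 1000-simulation calibration runs cheap. Data ties (possible but
measure-zero for continuous expression values) are handled by testing
against the untied null and flagging; all-tied data yields a degenerate,
non-rhythmic result rather than an error.

The best alternative maximizes $|\tau|$, with ties broken by smaller
p-value, then earlier lag; the reported p-value is Bonferroni-adjusted
over the distinct alternatives ($p_{\mathrm{adj}} = \min(1, p \cdot
\#\text{alternatives})$), and `rhythmic` means $p_{\mathrm{adj}} < 0.05$.

One coarseness worth knowing: with a *noiseless* cosine at an acrophase
off the 4-h lag grid, accidental value ties can let a neighboring period's
pattern achieve a higher $\tau$ than the true period's best on-grid lag.
Recovery tests therefore probe the estimator at its design resolution
(grid-aligned acrophase); lag recovery within one step holds either way,
and any noise breaks the degeneracy.

# qPCR quantification

Replicate Cts are averaged per dilution (per-well mode by flag), then Ct
is regressed on $\log_{10}$ relative template. Slope $m < 0$ is required
("non-amplifying curve" otherwise); efficiency is $10^{-1/m} - 1$ reported
as a fraction (1.0 = 100%, slope $-3.3219$), with the per-cycle
amplification factor also emitted. Relative quantity inverts the line,
$10^{(Ct - b)/m}$, and target levels are normalized as plain ratios to a
reference gene measured the same way. Normalized levels are invariant to
global rescaling of both channels. All biological replicates are passed
through to JTK rather than being averaged per timepoint — the exact null
handles replicated timepoints natively, and averaging first would discard
within-timepoint variance.

# Image quantification

Masks are inputs, not outputs: the package quantifies hand-identified (or
synthetic ground-truth) nuclei and deliberately does no segmentation. Per
nucleus, net intensity = mask pixel mean − background mean. The default
background region is *every unmasked pixel* — chosen over ad-hoc ROI
placement because it uses all available background and makes the
add-a-constant invariance exact; any user ROI is accepted but must be
disjoint from the masks. Negative net intensities are retained raw and
floored only in display contexts, the same reporting philosophy as rhythm
power. Brains, not nuclei, are the statistical unit: per-brain unweighted
means feed the group comparisons, and marker-positive counting thresholds
net intensity (16 labeled neurons per brain being the canonical check for
the Pdf⁺ lateral-neuron population).

# Group statistics

Kruskal–Wallis (tie-corrected, via `stats::kruskal.test`) with Dunn's
mean-rank z-tests,

$$z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
\frac{\sum(t^3-t)}{12(N-1)}\right)\left(\frac{1}{n_i}+\frac{1}{n_j}\right)}},$$

Bonferroni-adjusted over all pairs (the usual meaning of "multiplicity
adjusted" Dunn reporting; Holm available), is the nonparametric route;
one-way ANOVA with Tukey's HSD (`aov` + `TukeyHSD`) the parametric one.
`select_test()` screens normality per group (Shapiro–Wilk) and recommends
a route, but is advisory only: analysis choices fixed per figure belong in
the run configuration, and an explicit override always wins. Observations
that are `NA` (undefined anticipation indices, empty brains) are dropped
listwise with a log entry before testing.

# The synthetic-data model

The generator exists so that every downstream stage has a ground truth.
One fly's expected rate at elapsed time $t$ (hours), with internal phase
$\phi = (\phi_0 + 24t/\tau) \bmod 24$, is

$$\lambda(t) = r_0\,\bigl[1 + A\,(w_M B_M(\phi) + B_E(\phi)) +
\mathrm{ramp}(\phi)\bigr]\,(1-d)^{\mathrm{day}},$$

with raised-cosine bumps $B$ of half-width 3 h centred at CT0 (morning)
and CT12 (evening), an optional linear ramp rising to `ramp_gain` over the
3 h before each projected transition, and per-minute Poisson draws (a
negative-binomial dispersion knob exists but defaults off — beam breaks
are sparse event counts and no published noise model exists to calibrate
overdispersion against).

Defaults, chosen once as what a fly lab would call a realistic strong
rhythm, and not revisited: baseline $r_0 = 1$ count/min (per-fly activity
magnitudes are essentially never published; this is a free calibration
constant), amplitude $A = 2$, morning weight $w_M = 0.5$, ramp gain 1,
damping 0. The morning weight matters: free-running fly activity is
evening-dominant, and a perfectly symmetric pair of antiphase bumps would
be a degenerate 12-h-periodic signal with *no* 24-h Lomb–Scargle
component at all — an instructive pathology, but not a realistic fly.
Cohorts add per-fly Gaussian jitter (period SD 0.2 h, phase SD 0.5 h,
both in the range of within-genotype variability) with per-fly seeds
derived from the master seed and the fly index, so reproducibility is
independent of cohort size. Every generator is a pure function of its
seed; the pipeline's outputs are byte-identical across reruns.

What the generator does *not* emulate — and therefore what green tests do
not certify about real data: light-driven (masked) activity and startle
responses in LD; activity consolidation, sleep bouts and bout structure;
inter-fly correlation within a monitor; non-stationary period drift;
monitor artifacts other than status-flagged rows. Classifier performance
numbers from these simulations (e.g. false-positive rates) characterize
the statistics under the stated model, not any particular laboratory's
recordings.

# Problem sizes and runtime choices

The test and acceptance runs use desk-scale sizes chosen to estimate each
property with useful precision while keeping a full run in tens of
seconds: 9-day DD windows at 15-min bins; n = 32 flies per cohort for
period recovery (four implanted periods, 23.0–24.5 h) and anticipation
contrasts; 300-fly calibration and 1000-fly null cohorts for
false-positive rates; 1000 flat simulations for JTK type-I error at the
7 × 4 design; 100-series oracles for the Lomb–Scargle identity and DAM
round-trips. The JTK null cache and vectorized periodograms are what keep
the larger loops cheap.

# Known limitations

- Periodogram period resolution is the grid step (0.25 h at 15-min bins);
  periods off the chi-square fold grid alias to the nearest multiple.
- The LS significance line treats tested periods as independent; on an
  oversampled grid it is conservative per period and approximately
  union-bounded at the peak — the null-calibrated $\Delta$ gate sidesteps
  the approximation where classification accuracy matters.
- The chi-square $\chi^2_{P-1}$ null is asymptotic in K; at the default
  9-day window and $P \le 120$ (K ≥ 7) the approximation is adequate but
  thresholds at much shorter windows should not be over-read.
- JTK's period grid is deliberately coarse (20/24/28 h); it detects
  cycling but is not a period estimator.
- No sleep-bout analysis, no multi-beam (DAM5M) formats, no wavelet or
  autocorrelation methods, no z-stack handling or automated nucleus
  segmentation.
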