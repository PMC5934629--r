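---
title: "Models and methods behind telotiming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind telotiming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telotiming)
```

telotiming packages the quantitative procedures of a budding-yeast
telomere / replication-timing workflow: a stochastic S-phase simulator, a
flow-cytometry-anchored estimate of how much of the genome has been
replicated, relative copy-number profiles in 1 kb bins, ChIP
quantification with a telomere-length correction and a sonication
co-fragmentation model, and terminal-restriction-fragment analysis of
telomere length. This vignette explains the models, their assumptions and
the numerical choices, in the order data flows through the package.

## The stochastic S-phase model

A `genome_model()` is a set of chromosomes, an origin table and a fork
speed. Each origin carries a median firing time, a firing-time spread and
a competence probability. In each simulated cell an origin is licensed
with its competence probability; licensed origins draw a firing time from
a normal distribution truncated at zero with the origin's median and
spread. Forks move bidirectionally at a constant speed and replicated
stretches merge. This is the standard stochastic-firing abstraction used
throughout the replication-timing literature; the truncated normal is the
simplest two-parameter family that keeps firing times positive while
letting spread be set per origin.

Passive replication needs no explicit rule: an origin overtaken by a fork
before its own drawn time would only generate an interval contained in
the overtaking fork's span, so the union of intervals is unchanged. The
replicated region of a cell at time $t$ is therefore the union of
$[x_i - v(t-t_i)^+,\; x_i + v(t-t_i)^+)$ over licensed origins, clipped
to chromosome bounds. Coordinates are 0-based and half-open everywhere
inside the package; bins are $[1000k, 1000(k+1))$; the wig writer alone
converts to the format's 1-based convention.

Defaults are chosen as ordinary budding-yeast figures: fork speed
1.5 kb/min, early origins firing around 20–25 min after release and
late ones around 30 min with spreads of ~5 min, competence 0.9. No
published parameter set is attached to any particular strain; the
bundled scenario is illustrative, not a calibration to a sequenced
genome.

Matched time courses (`simulate_time_course()`) reuse one firing draw
per cell across all time points, so each simulated cell is literally the
same cell observed later and per-cell replicated fractions are
non-decreasing in time — the property the tests verify.

## From populations to reads and flow events

`sample_read_counts()` emulates what binning uniquely mapped reads would
yield: one multinomial draw with per-bin probability proportional to
(1 + mean replicated fraction) × mappability weight × bin width. Reads
are positions, never sequences — no stage of the analysis consumes
nucleotide content, so none is simulated. Mappability is a per-bin
weight (default 1) standing in for the fraction of uniquely mappable
positions; GC bias and fragment-level effects are deliberately out of
scope, which means passing tests demonstrate correctness of the
estimator, not robustness to those real-data artifacts.

`simulate_flow_cytometry()` reports each cell's DNA content as
(1 + replicated fraction) × multiplicative noise, on a scale where
1C = 1 and 2C = 2. Noise is lognormal with mean exactly 1 and the
requested coefficient of variation, so it is positive, unbiased, and
collapses to the exact content at cv = 0. Singlet gating and histogram
deconvolution are not modelled; the simulator produces already-gated
events.

## Percent bulk replication and the Gompertz fit

`percent_bulk_from_mean()` places the mean DNA content linearly between
a 1C and a 2C reference and clamps to [0, 100] — slight overshoot is
measurement noise, not an error. By default the 1C reference is the mean
of the earliest (arrested) sample and the 2C reference is twice it.

The time course is summarised by a Gompertz curve
$A\,e^{-e^{-k(t-t_0)}}$ fitted by Levenberg–Marquardt least squares
(`minpack.lm`) with box constraints $0 < A \le 100$, $k > 0$. $A$ is
fitted rather than pinned at 100 because real courses plateau below full
replication. Start values are $A$ at the maximum observed value, $t_0$
at the first crossing of half-maximum, and $k = 4/\mathrm{range}(t)$,
which lands inside the basin of attraction for any course that actually
traverses S phase. Courses that never leave the low range or never reach
the high range are rejected as degenerate rather than fitted; with fewer
than four points the three-parameter fit is underdetermined and also
refused. On noiseless synthetic courses the generating parameters are
recovered to ~10⁻⁴ relative error; with 2 % additive noise on 8 points
the median $t_0$ error stays under 2 min (both are asserted in the
test suite).

```{r gompertz-example, eval = FALSE}
course <- tibble::tibble(time = seq(0, 80, 10))
course$percent <- gompertz(course$time, A = 95, k = 0.15, t0 = 35)
fit <- fit_gompertz(course)
glance(fit)
autoplot(fit)
```

## Relative copy-number profiles

`raw_ratio()` divides the replicating sample's per-bin count share by
the non-replicating sample's share — the read-number correction is
exactly the ratio of library totals. Bins with fewer than `min_count`
(default 10) reads in the non-replicating sample are masked: their ratio
variance is uncontrolled, and 10 counts caps the ratio's coefficient of
variation near 30 % before the replicating sample contributes.

`normalize_by_bulk()` then multiplies all ratios by one scalar chosen so
the coverage-weighted mean of unmasked bins equals $1 + f$, where $f$ is
the percent bulk replication divided by 100. This anchoring is what
makes the two ends of the scale meaningful: a bin replicated in no cell
sits near 1, a bin replicated in every cell near 2. Weighting by
non-replicating coverage makes the anchor estimate the genome-wide mean
copy number rather than an average over bins of unequal information. No
smoothing is applied by default — profiles are plotted as per-bin dots —
and no clamping is applied to per-bin values.

`rank_replication_order()` aggregates profiles into fixed windows
(default 10 kb) and ranks them from highest to lowest relative copy
number. At a late-S time point the last rank identifies the last region
of the genome to replicate, the readout used to show that an
origin-deleted chromosome arm replicates last. Ties share a `min`-style
rank, are flagged, and are broken by genomic order in the reported row
order.

For the recovery experiments in the test suite the package simulates
two chromosomes (316 kb and 270 kb, 586 one-kb bins), 100 cells, and a
mean bin coverage of 1000× for per-bin rank correlation or 100× for
window-level rank studies. One-kb-bin ratio noise at 100× is ~13 %,
which is ample for 10 kb windows but blurs per-bin ranks; 1000× is
still several-fold below the coverage a typical 30-million-read yeast
library provides per 1 kb bin, so the chosen sizes are conservative
relative to real experiments.

## The sonication model and co-fragmentation

Two views of fragmentation coexist and serve different purposes.

The **calibrated generator** (default of `simulate_sonication()`) draws
fragment lengths from a lognormal with mean equal to the model's
`mean_fragment_length` and log-scale spread 0.4. This reproduces the
endpoint a shearing protocol is run to — the operator sonicates,
inspects the size profile and continues until the great majority of
fragments sit inside the 50–500 bp window with a mean between 200 and
300 bp. At the default mean of 250 bp the theoretical in-window coverage
is 97.3 %. The spread parameter is fixed by that protocol window: it is
the dispersion at which a mean-250 bp distribution keeps ~95 % or more
of its mass inside 50–500 bp, as an accepted run does.

The **memoryless idealisation** (`method = "poisson"`) places breaks as
a Poisson process along each molecule, giving exponential inter-break
distances. It exists because it makes the co-fragmentation probability
closed-form: two loci $d$ apart stay on one fragment exactly when no
break falls between them, with probability $e^{-d/\lambda}$
(`cofragment_probability()`). A single-pass Poisson process cannot
reproduce the peaked protocol endpoint — an exponential with mean
250 bp necessarily leaves ~14 % of its mass above 500 bp — which is why
the two modes are kept distinct rather than forced into one model: the
calibrated mode is the realistic marginal length distribution, the
Poisson mode is the declared, testable model behind the distance-decay
bias. The test suite cross-checks the closed form against a Monte-Carlo
simulation of Poisson breakage at several distances.

`predict_qpcr_bias()` applies the decay to the situation where a
telomere-bound protein is assayed by a fixed subtelomeric amplicon:
elongating the telomere by 600 bp at a 250 bp mean fragment length
multiplies the expected apparent signal by $e^{-600/250} \approx 0.09$
even at unchanged occupancy — the reason dot-blot quantification against
total telomeric repeats, not ChIP-qPCR, is the right readout when strains
differ in telomere length.

## ChIP quantification

`percent_input_qpcr()` implements the efficiency-aware delta-Ct rule,
$100 \cdot f_{\mathrm{input}} \cdot E^{\,Ct_{\mathrm{input}} -
Ct_{\mathrm{ChIP}}}$, assuming perfect proportionality between template
and $E^{-Ct}$ — no plateau or limit-of-detection modelling. The input
fraction is kept explicit rather than folded into the Ct values, since
dilution bookkeeping varies between labs. `percent_input_dotblot()` is
the analogous intensity ratio. The forward model
(`simulate_chip_signals()`) emits both representations from one true
occupancy; at zero noise both quantifications invert it exactly, which
the tests assert, and a site with zero occupancy yields a zero blot
signal and an infinite ChIP Ct (no template ever amplifies), which maps
back to 0 %.

`per_telomere_binding()` applies the telomere-length correction:
dividing the input signal by the fold TG-length increase (equivalently,
multiplying the test strain's percent input by that factor) converts
percent-of-repeat-sequence pulled down into protein bound per chromosome
end, reported relative to the reference strain. The factor is a measured
input — typically the ratio of mean TG lengths estimated from Southern
data — never a constant baked into the package.

## Southern-blot telomere analysis

Terminal restriction fragments are the fixed subtelomeric offset plus
the TG tract length (`terminal_fragment_length()`). Lanes are rendered
directly in length space as a Gaussian kernel density
(`render_lane()`); gel migration physics would add calibration
parameters that none of the downstream inferences need, since every
conclusion is about fragment length. The symmetric kernel preserves the
mean, so `estimate_mean_length()` agrees between the lane route and the
raw-lengths route within grid tolerance.

`simulate_telomere_lengths()` draws per-telomere TG tracts from a normal
truncated at zero with mean = wild-type mean + elongation offset. The
default scenario (mean 300 bp, sd 75 bp, 32 telomeres, 3 isolates)
represents a typical haploid strain set; an elongation of ~600 bp is the
canonical long-telomere mutant phenotype, and the recovery tests check
that the pipeline re-estimates it within 50 bp from one simulated
experiment and within [550, 650] bp in median over 100 seeds.

`compare_strains()` uses the classic pooled-variance Student's t test on
per-isolate means by default (Welch by flag), reports the difference in
the order groups appear, and attaches the conventional significance
stars. The test suite checks the statistic against a brute-force
implementation of the definition on a thousand random inputs.

## Scenario orchestration and reproducibility

`run_scenario()` executes the whole pipeline from one YAML configuration
(see `system.file("extdata", "delta4ars.yaml", package = "telotiming")`):
schema validation reports every violation with its field path before any
stage runs; all randomness fans out deterministically from the single
config seed via labelled child seeds, so reruns are byte-identical; a
manifest with MD5 checksums covers every artifact; progress is logged to
standard error. The bundled scenario deletes every origin distal of
180 kb on one chromosome and samples late in S phase, when the fork
travelling into the terminal 90 kb is still inside the last windows in
most cells — the configuration under which the terminal window is the
genome's lowest-copy-number region.

## Known limitations

* Firing-time parameters are illustrative; nothing is calibrated to a
  particular sequenced strain.
* The read model has no GC bias, no duplicate structure and uniform
  mappability by default, so tests demonstrate estimator correctness,
  not robustness to alignment artifacts.
* Flow events are pre-gated singlets; histogram deconvolution into
  G1/S/G2 fractions is out of scope, and percent bulk derives from the
  event mean only.
* The co-fragmentation model is memoryless by construction; real
  re-sonication of long fragments makes true distance decay somewhat
  steeper than $e^{-d/\lambda}$ at large distances.
* Southern lanes ignore probe hybridisation efficiency and in-gel
  mobility calibration; estimates are about fragment length only.
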