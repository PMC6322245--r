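---
title: "Methods: quantitative EEG phenotypes and family-based association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative EEG phenotypes and family-based association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfbat)
```

`eegfbat` implements a two-stage analysis: extraction of quantitative
spectral phenotypes from resting-state EEG, followed by family-based
association testing of those phenotypes against a biallelic marker. This
vignette documents the statistical model, the signal-processing choices and
their defaults, the synthetic-data generators used for validation, and the
numerical decisions a maintainer should know about.

## The association model

### Conditioning on parental genotypes

The unit of analysis is the nuclear family: two genotyped parents and their
genotyped, phenotyped offspring. Under the null hypothesis of no linkage and
no association, an offspring's genotype given the parents follows Mendel's
law and is independent of the phenotype. All test moments are therefore
computed *conditionally on the parental mating type*, which immunizes the
tests against population stratification and phenotype-model misspecification:
the phenotypes are treated as fixed, and only the transmissions are random.

For a parent carrying $g \in \{0,1,2\}$ copies of the target allele, the
transmission probability of that allele is $g/2$; the offspring count is the
sum of two independent transmissions (`mating_distribution()`). The coded
genotype $x_i$ maps the count through the genetic model: recessive
($x = \mathbb{1}[g=2]$), additive ($x = g$), or dominant
($x = \mathbb{1}[g \ge 1]$). `conditional_moments()` returns
$E(x_i \mid p_{i1}, p_{i2})$ and $\mathrm{Var}(x_i \mid p_{i1}, p_{i2})$
under this distribution. A family is *informative* when that variance is
positive; uninformative families contribute exactly nothing to any statistic
(a tested invariant), so retaining or dropping them is immaterial to the
result and only affects logging.

### Univariate FBAT and multivariate FBAT-GEE

With traits $t_i$ (after the offset, below) the univariate statistic is

$$\chi^2 = \frac{(S - E(S))^2}{V_S}, \qquad
  S = \sum_i t_i x_i,\;
  E(S) = \sum_i t_i E(x_i \mid p_{i1}, p_{i2}),\;
  V_S = \sum_i t_i^2 \mathrm{Var}(x_i \mid p_{i1}, p_{i2}),$$

reported as a signed $Z = (S - E(S))/\sqrt{V_S}$ with a two-sided normal
p-value; the sign carries the direction of association for the tested
allele. The multivariate extension stacks $m$ phenotypes per offspring
(here the 8 scalp regions of one band/measure/condition cell):

$$\tilde S = \sum_i t_i\,(x_i - E(x_i \mid p_{i1}, p_{i2})), \qquad
  V = \sum_i t_i t_i^{t}\, \mathrm{Var}(x_i \mid p_{i1}, p_{i2}), \qquad
  \chi^2 = \tilde S^{t} V^{-} \tilde S,$$

asymptotically $\chi^2$ with degrees of freedom $\mathrm{rank}(V)$.

Numerical choices in this stage:

- **Generalized inverse.** Region phenotypes are strongly correlated, so $V$
  can be near-singular. $V^{-}$ is computed by symmetric eigendecomposition
  with reciprocal eigenvalues thresholded at a relative tolerance of
  $10^{-8}$ of the largest eigenvalue; the degrees of freedom equal the
  number of retained eigenvalues. This makes the statistic exactly invariant
  under duplication or invertible recombination of phenotype columns (tested
  to $10^{-10}$ relative tolerance), and reduces exactly to $Z^2$ at $m=1$.
- **Trait offset.** A constant subtracted from the traits changes power but
  not validity. The default is `grand_mean` — centering each phenotype at
  its mean over the tested offspring — which protects the statistic against
  arbitrary location shifts of log-scale phenotypes; `none` and
  `user_value` are available. The offset is a configurable analysis choice,
  not an estimate of any particular prior study's setting.
- **Degenerate scores.** If no family contributes genotype variance the test
  is refused ("uninformative") rather than returning a number. If
  informative transmissions exist but every contributing trait is zero, the
  score is degenerate at zero and the statistic is reported as
  $Z = 0,\ \chi^2 = 0,\ p = 1$.
- **Exclusions.** Families with a missing parental genotype are excluded
  with a warning (conditioning requires both parents; sufficient-statistic
  conditioning for missing parents is out of scope). Offspring with missing
  genotype or any missing phenotype are dropped listwise per test.
- **Allele frequencies** are estimated among genotyped *founders* only
  (`founder_allele_frequency()`): offspring frequencies in
  family-ascertained samples are distorted by the ascertainment itself.
  Both marker alleles are tested in turn, so association tables carry one
  row per allele.

The Monte-Carlo transmission null (`empirical_null()`) re-draws offspring
genotypes from each family's mating distribution holding traits fixed —
the exact conditional null the analytic $\chi^2$ approximates. It is a
validation oracle (the suite checks analytic and empirical tails agree
within Monte-Carlo error), not the reported inference.

## The spectral phenotypes

### Signal path

The path from a continuous recording to phenotypes is: zero-phase filtering
→ 2500 ms epoching → statistical artifact rejection → Welch relative PSD →
MBP / DFV per channel → region averaging → natural log.

- **Filters.** A cascade of order-2 Butterworth high-pass at 0.2 Hz,
  order-4 Butterworth low-pass at 150 Hz, and order-2 Butterworth band-stop
  over 59–61 Hz, each applied forward-backward (`signal::filtfilt`) for
  zero phase. The stages are applied separately because a single
  transfer-function band-pass spanning 0.2–150 Hz is numerically fragile at
  multi-kHz sampling rates. Steady-state attenuation at 60 Hz exceeds
  70 dB; finite-signal edge transients are unavoidable with
  forward-backward IIR filtering and are the reason filter-response tests
  measure the central portion of a test signal.
- **Artifact rejection.** Per trial-channel cell, the mean amplitude and
  log-variance are z-scored over surviving cells; a cell is rejected when
  either statistic exceeds 3 SD. Two passes are run, recomputing the
  reference moments on survivors, so gross artifacts cannot shelter milder
  ones. A zero-spread guard flags nothing when a statistic is constant, and
  the mask only grows. Stereotyped-artifact removal by ICA is deliberately a
  pluggable upstream step (pass externally cleaned recordings in); it is an
  expert-guided procedure, not reproducible automation.
- **Welch relative PSD.** Each clean epoch is split into two non-overlapping
  1250 ms windows (window = half the epoch; no overlap so that surviving,
  possibly non-adjacent epochs never share samples). Per window a
  Hann-tapered periodogram is computed and normalized so bins in
  (0, 100] Hz sum to one. The frequency resolution is the reciprocal of the
  window duration, 0.8 Hz at 1250 ms, and the package uses that value
  throughout; window length is configurable for users who want a different
  grid. The DC bin is excluded from the normalization (the 0.2 Hz high-pass
  removes it anyway), and the notch band is *not* excluded.
- **Band edges.** Bands are delta (< 4), theta (4–8), alpha (9–14), beta
  (14–30), low gamma (31–55), high gamma (65–100 Hz), assigned half-open
  $[low, high)$ with the top band closed at 100 Hz. The 14 Hz point belongs
  to beta; the 8–9, 30–31 and 55–65 Hz gaps between the printed ranges
  belong to no band. These conventions are encoded in `band_scheme()` and
  are tested.
- **MBP** is the arithmetic mean of the relative PSD bins in the band, from
  the per-subject Welch-averaged spectrum, per channel.
- **DFV** is computed per channel: each window's dominant frequency is the
  within-band argmax bin, and DFV is the mean absolute deviation of those
  frequencies (chosen over the SD to damp outlier windows). Region averaging
  happens *after* the per-channel DFV, i.e. at the feature level. DFV is
  invariant to positive rescaling of the signal because the argmax is
  power-monotone.
- **Region averaging** uses an explicit default map of a 32-channel 10/20
  cap onto the 8 regions (`region_scheme()`), fully overridable. Rejected
  channels are excluded from their region's mean.
- **Log transform.** Both phenotypes are natural-log transformed before
  testing, to better approximate normality. Relative MBP is strictly
  positive. A DFV of exactly 0 (perfectly stable peak) would give
  $-\infty$; it is floored at half the smallest nonzero DFV observable from
  $n$ windows on a grid of spacing $r$, i.e. $r(n-1)/n^2$
  (`dfv_floor()`) — strictly below any attainable nonzero value, so the
  ordering of observed values is preserved.

## Synthetic data: what it emulates, and what it does not

Three seedable generators cover the pipeline's input space.

- `simulate_pedigree()` draws founder genotypes from Hardy–Weinberg at a
  configurable allele frequency (default 0.165, a low-frequency variant
  segregating in a consanguineous-style cohort; default 8 families of 3
  offspring emulate a small field study) and transmits alleles by Mendel's
  law. Families are kept regardless of informativeness — selecting
  informative families is the analysis's job. Where validation needs a
  *fixed* number of informative families, `parent_counts = c(1, 1)`
  generates het×het matings directly.
- `simulate_phenotypes()` / `simulate_trait_matrix()` are the feature-level
  shortcut: phenotype = β·x + family intercept + Gaussian noise, on the
  log scale (defaults: noise SD 1, family SD 0.5, β keyed per
  band×measure). This path drives all statistical calibration because it
  isolates the test from the signal path.
- `simulate_eeg()` builds raw recordings as band-limited sinusoids — per
  2500 ms segment, frequency = center + N(0, jitter SD), jitter shared
  across channels (scalp rhythms are spatially coherent), phases
  independent — over 1/f background noise of configurable exponent.
  `inject_artifacts()` adds variance bursts or blink-like transients with
  bookkept epoch indices.

What the generators do **not** emulate: volume conduction and realistic
channel covariance, non-stationary amplitude dynamics, real artifact
morphologies (muscle, electrode pops), medication or age effects on
spectra, and linkage disequilibrium with ungenotyped causal variants.
Passing tests therefore demonstrate correctness of the estimators and
calibration of the tests under the stated generative model, not robustness
to every property of field EEG.

## Validation suites and problem sizes

The test suite checks, among others: exact agreement of the FBAT terms with
brute-force enumeration of the four parental transmissions for all nine
mating types × three models; FBAT-GEE/univariate equivalence at $m=1$ on
100 random datasets ($10^{-10}$ relative); type-I error of the univariate
test at $\alpha = 0.05$ within binomial 95% bounds over 1,000 null
replicates of 50 het×het trios; power above 0.9 for a 3-noise-SD recessive
effect across 8 phenotypes in 100 informative families (200 replicates);
unit-sum relative PSD on every window ($10^{-12}$); DFV against its closed
form and its monotone response to simulated peak jitter; and end-to-end
determinism under fixed seeds. Simulation sizes were chosen to estimate
each property with adequate Monte-Carlo precision while keeping the default
suite quick to run; `scripts/acceptance.R` recomputes the headline
quantities at the same sizes.

## Known limitations

- Missing-parent families are excluded rather than conditioned on
  offspring-based sufficient statistics; multi-marker/haplotype tests and
  X-linked markers are unsupported.
- The analytic null is asymptotic; with very few informative families the
  Monte-Carlo null (`empirical_null()`) is the safer reference.
- EDF ingestion is left to the caller (any reader that yields a
  channels × samples matrix plus sampling rate and labels feeds
  `eeg_recording()` directly); the package's own I/O covers linkage PED and
  TSV feature tables.
- No multiplicity correction is applied by default — the association tables
  flag $p < 0.05$ uncorrected, a hypothesis-generating convention for rare,
  hard-to-replicate cohorts — but `run_fbat(p_adjust = "bonferroni")` or
  `"fdr"` enable corrected flagging.
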