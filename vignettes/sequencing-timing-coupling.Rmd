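---
title: "Coupling of syllable sequencing and timing in birdsong: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling of syllable sequencing and timing in birdsong: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songgaps)
library(dplyr)
```

## The scientific question

Adult Bengalese finch song is a sequence of discrete acoustic elements
("syllables", bounded by at least 5 ms of silence) organised into
stereotyped chains — runs in which each pairwise transition occurs more than
95% of the time — and *branch points*, nodes where the next syllable varies
from rendition to rendition (typically 2–5 possible targets). Song tempo is
governed largely by the silent gaps between syllables. `songgaps`
implements a complete analysis of how *sequencing* (the transition
probability `p` of each branch-point transition) relates to *timing* (the
gap duration within that transition), and of whether long-term (age) and
acute (social-context) changes to the two are coupled.

The core statistical model is a linear mixed-effects regression of
log10-transformed median gap duration on transition probability,

$$\log_{10}(\text{gap}_{ijk}) = \beta_0 + \beta_1\, p_{ijk} + u_i + v_{ij} + \varepsilon_{ijk},$$

with a random intercept $u_i$ per bird and $v_{ij}$ per sequence (branch
point or chain) nested within bird, fitted by REML. The slope $\beta_1$ is
the coupling: a negative value means more prevalent transitions are produced
with shorter gaps. Change analyses difference the per-transition quantities
between two conditions and regress $\Delta\log_{10}(\text{gap})$ (and the
percent change in median gap) on $\Delta p$ with the same random structure.

## Pipeline stages and their assumptions

1. **Segmentation** (`compute_envelope()`, `segment_syllables()`,
   `measure_gaps()`). The envelope is the rectified waveform smoothed with a
   centred 5 ms square window and resampled to 1 kHz. Syllables are maximal
   above-threshold runs; below-threshold runs shorter than 5 ms are merged
   (the syllable definition), and candidates shorter than 10 ms are dropped.
   Boundaries are refined to the interpolated threshold crossing, so they
   are not quantised to the 1 ms envelope grid. The gap of a transition is
   the offset of its first syllable to the onset of the next.
2. **Syntax** (`exclude_repeats()`, `count_transitions()`,
   `resolve_contexts()`). Transition counts are per bird and condition;
   rendition-final syllables count as song terminations and are excluded
   from probability denominators. History dependence is assessed per
   order-1 context by a likelihood-ratio (G) test across order-2
   predecessors at $\alpha = 0.05$; rejection splits the context, otherwise
   predecessors are pooled. Contexts need at least 10
   (termination-excluded) occurrences to be analysed, and are classified
   stereotyped only when the maximal target probability strictly exceeds
   0.95 (a tie at exactly 0.95 stays a branch point).
3. **Timing** (`transition_timing()`). Each transition is summarised by the
   median of its gap instances; medians from fewer than 5 instances are
   discarded as unreliable.
4. **Coupling statistics** (`fit_coupling_model()`,
   `compare_transition_types()`, `residualize_amplitude()`,
   `categorize_changes()`, `change_coupling_analysis()`,
   `category_contrast()`, `screen_normality()`).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| envelope smoothing window | 5 | ms | field-standard square smoother |
| envelope rate | 1000 | Hz | canonical 1 kHz amplitude trace |
| segmentation threshold | 10% of corpus median syllable peak | – | fraction-of-peak keeps gap measures invariant to recording gain; no absolute value is standard |
| minimum silent interval | 5 | ms | the syllable definition |
| minimum syllable duration | 10 | ms | rejects click artefacts; no published value, documented assumption |
| occurrence filter | 10 | occurrences | branch points analysed only with at least 10 occurrences per condition |
| instance filter | 5 | gap instances | medians of smaller samples are unstable |
| stereotyped threshold | 0.95 | probability | strict inequality |
| test level $\alpha$ | 0.05 | – | all tests, no multiplicity correction across branch points |

## What the synthetic generator emulates

`generate_corpus()` and `generate_condition_pair()` produce corpora with
full ground truth, used by every validation in `tests/`. The defaults are
the study conditions throughout: 22 birds with 30 renditions each (the
scale of the age dataset), a grammar with four analysable branch points
(2–3 targets each) linked by stereotyped chains, and song terminations via
a reserved end token so that termination-exclusion logic is exercised.
Termination probabilities are set so bouts average roughly 35 syllables,
typical of the species.

Per-instance gaps follow
$\log_{10}(\text{gap}) = 2.15 - 0.240\,p + u + v + \varepsilon$: the slope
is the coupling reported for adult Bengalese finch song, and the intercept puts median gaps near
110 ms with a realistic spread (roughly 15–500 ms across transitions). The
variance components are not reported anywhere for these data, so they are
documented assumptions: bird sd 0.10, sequence sd 0.28 and residual sd 0.25
(log10 ms), chosen together so that (a) the spread of per-transition median
gaps spans the range reported for these birds (roughly 14-490 ms) and (b) the standard error of the fitted
coupling slope at study scale is of the order reported for such data (about 0.04).
Between-bird variation in branch probabilities is Dirichlet with
concentration $8 p$, giving the wide cross-bird spread of transition
probabilities these birds show. Syllable amplitudes are log-normal around a
per-label base with a mild positive coupling to transition probability
(coefficient 0.2) and noise sd 0.1 truncated at 2.5 sd — syllables have a
finite dynamic range (about 4× here).

Condition pairs share the bird and sequence random effects between
conditions. Condition B shifts each branch point's probabilities by
zero-centred normal perturbations (sd 0.18, the scale of probability shifts
these birds show across ages and social contexts) and changes gaps by mode: `coupled` applies
$\log_{10}(0.95) - 0.4\,\Delta p$ per transition (an overall 5% speed-up
plus an inverse dependence on the probability change; the coupling strength
was fixed a priori so the coupled/decoupled dissociation is unambiguous at
study scale, and so that a transition whose probability falls by ~0.11
lengthens its gap, the characteristic age-related pattern); `decoupled` applies the
uniform $\log_{10}(0.95)$ regardless of $\Delta p$; `null` applies nothing.
Amplitudes in condition B are generated from the baseline probabilities, so
amplitude changes are pure noise — matching the finding that amplitude
changes do not track sequencing changes.

What the generator does **not** emulate: spectral structure of syllables
(only amplitude envelopes matter to this pipeline), variable syllable
repeats (excluded from analysis by rule), bout-internal tempo drift,
correlated noise across neighbouring gaps, and hand-labelling errors.
Passing tests therefore show the pipeline is correct under the stated
generative model, not that real recordings meet its assumptions.

## Numerical and design choices

- **Waveform rendering** uses raised-cosine syllable edges of 4 ms on a
  3 kHz carrier. With the 5 ms smoother and the 10%-of-median-peak
  threshold, the interpolated threshold crossing sits within about 1 ms of
  the nominal envelope support across the full amplitude range, so
  segmentation accuracy tests run at sub-2-ms tolerances without tuning.
- **Satterthwaite denominator df.** Analyses of this design report F
  statistics with fractional denominator df, implying a Satterthwaite-type
  approximation;
  `lmerTest` provides it. Exact df will differ from other software by
  small amounts.
- **Variance components are bounded at zero.** The original analyses used
  unbounded REML; `lme4` constrains variances to be non-negative. Fits on
  the boundary are reported with `boundary = TRUE` in `glance()` rather
  than as negative estimates. For balanced designs this does not move the
  fixed effects. Degenerate fits that break the Satterthwaite machinery
  (for instance, an exactly linear response) fall back to model-based
  standard errors with residual df, visible as such in the result.
- **Change categorisation** uses the Pearson chi-square statistic on the
  2×2 table (target vs all other targets, condition A vs B) without
  continuity correction; an equivalent likelihood-ratio test is available
  via `test = "lrt"`.
  The 2×2 construction itself is not specified anywhere and is documented
  here as the package's choice.
- **Residual type.** Amplitude residualisation uses conditional residuals
  (observed minus fixed and predicted random effects); which residual the
  original software used is not stated.
- **Percent change** uses raw medians, $100\,(m_B - m_A)/m_A$, not
  back-transformed log means.
- **Pooling and gap attribution.** Gap durations are attributed to the
  *resolved* branch point: split contexts match on the order-2 context,
  pooled contexts on the order-1 context. Split branch points lose
  rendition-initial occurrences (those have no predecessor). Predecessors
  with fewer than 5 occurrences are pooled into an "other" group before the
  history test.
- **Matching across conditions** is by resolved context string; a
  transition whose split/pool decision differs between independently
  resolved conditions drops out of the change analysis.
- **Determinism.** One root seed drives per-bird substreams; a fixed seed
  reproduces corpora byte-for-byte. The analysis pipeline itself contains
  no randomness.

## Worked example

```{r example, eval = FALSE}
co <- generate_corpus(song_config(seed = 7))
res <- run_pipeline(co)
tidy(res$coupling$A)      # slope of log10 gap on transition probability
glance(res$coupling$A)    # variance components and boundary flag
autoplot(res$coupling$A)

pair <- generate_condition_pair(
  song_config(seed = 7, condition_effect = list(mode = "coupled")))
resc <- run_pipeline(pair)
tidy(resc$change$coupling$dlog10_fit)
plot_category_changes(resc$change$records)
```

## Validation scale and limitations

The test suite validates segmentation on 200 rendered renditions
(boundaries and gaps within 2 ms), probability estimation at ten thousand
branch-point visits (3-sigma binomial bands), calibration of the G-test
(2000 null replicates), slope recovery across 200 study-scale corpora
(mean within 5% of the injected slope; ±2 SE coverage at least 90%), the
coupled/decoupled dissociation (200 and 400 paired replicates), and exact
filter counts on a hand-built fixture. These sizes were chosen so the whole
suite completes in well under half an hour on one core while keeping
Monte-Carlo error small relative to the tolerances.

Known limitations: estimated transition probabilities enter the regression
as-is, so classical errors-in-variables attenuation shrinks the fitted
coupling slope by a few percent at realistic occurrence counts (visible in
the recovery simulations and equally present in any analysis of this
design); the >95% classification rule censors transitions that drift above
it between conditions; and the mixed models assume homoscedastic row noise
although medians from 5 instances are noisier than medians from 50.
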