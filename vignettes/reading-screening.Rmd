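---
title: "Screening for reading difficulties from silent-reading eye movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for reading difficulties from silent-reading eye movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(radarscreen)
```

## The screening problem

Readers with dyslexia show systematically different eye movements during
text reading than typically developing readers: longer and more numerous
fixations, shorter forward saccades, more short backward refixations, less
skipping of short words, and long gaze durations on many words. None of
these is diagnostic on its own, but together they form an oculomotor
signature that can be measured in a few minutes of silent reading with an
eye tracker. `radarscreen` implements a full screening pipeline on that
idea: raw 60 Hz gaze samples are turned into fixations and saccades, twelve
reading parameters are extracted per reader, and a two-class Gaussian
classifier converts the parameter vector into a *Total Reading Score* (TRS)
— the posterior probability that the reader belongs to the control
population — together with the diagnostic arithmetic a screening programme
needs (likelihood ratios and prevalence-conditional post-test
probabilities).

The package also ships a generative model of reading scanpaths. Real
recordings of school-age readers are not distributable with a package, so
every stage is developed and tested against simulated cohorts whose group
contrasts are calibrated to published control-vs-dyslexic differences. What
that does and does not establish is discussed at the end.

## From gaze samples to fixations and saccades

Fixations are found with the classic dispersion-threshold (I-DT) algorithm:
a moving window grows over consecutive valid samples while the cloud's
dispersion — `max(x-range, y-range)`, i.e. a square window — stays within
`d_max` = 45 px (1.5 degrees on the default 1366 px / 46.4 degree screen).
A window that spans at least `t_min` = 90 ms is emitted as a fixation at
the cloud centroid, with duration `t_last - t_first` (robust to dropped
frames, unlike `n/rate`). Runs of two or more invalid samples are blinks;
they terminate the current window and are excluded from clustering, and
fixations are never merged across them. Isolated single invalid frames are
treated as dropped frames and skipped.

Saccades are the transitions between consecutive fixations within one
uninterrupted segment. Length is the *signed x-displacement* of the
fixation centres (the natural axis for text), and a transition only counts
as a saccade if its speed exceeds 100 deg/s — at 60 Hz a two-character
(1.65 degree) movement across one 16 ms frame gives almost exactly that
bound (1.65/0.016 ≈ 103 deg/s). Slower transitions are dropped from saccade
statistics but do **not** merge their fixations; whether the original
instrumentation merged them is not documented, so the non-merging choice is
recorded here as ours. Line-return sweeps (leftward by more than 60% of the
line width, downward by at least half the line spacing) are flagged and
excluded from saccade-length statistics and refixation counts.

## The twelve parameters

**Non-word-specific.** Fixation durations pooled over the whole text are
fitted with an ex-Gaussian (the convolution of a Gaussian (μ, σ) with an
exponential of mean τ = 1/λ); the tail parameter τ (ms) is the screening
quantity, while μ and σ are computed but not used downstream (they
discriminate poorly). The fit is maximum likelihood on (μ, log σ, log τ),
moment-initialised, with box constraints that keep the optimiser inside the
numerically stable region; on non-convergence the moment estimates are
returned and flagged. Saccade lengths yield their empirical quartiles q25,
q50, q75 (linear CDF interpolation, signed lengths, line returns excluded —
whether backward saccades belonged in the published distribution is not
stated; we include them and record the choice). `R` counts backward
saccades shorter than 100 px (4 characters), the threshold that maximises
the ROC area over a 100–400 px grid (the package re-derives this by raw
grid argmax; no spline smoothing). `Fix` is the total fixation count.

**Word-specific.** Fixations are assigned to words by nearest line (within
half the line spacing) and horizontal containment (± half a character
width); unassigned fixations still count in `Fix` but are ignored here. The
first pass on a word is the maximal run of consecutive fixations starting
at its first visit; its summed duration is the first-pass gaze. `F0`, `F1`
and `Fge2` count words with zero, one, and two-or-more first-pass fixations
(`F0 + F1 + Fge2` = word count always; `F1` is excluded from the classifier
as it is determined by the other two). Per-word control norms (mean and SD
of first-pass gaze over controls who fixated the word; at least two
contributors required) turn an individual's gaze duration into a Gaussian
percentile score; words scoring strictly above 0.90 are counted into
word-length bins — `X_{L≤3}`, `X_{L=4,5}`, `X_{L=6,7}`, `X_{L≥8}` for the
basic text, `X_{L≤3}`, `X_{L=4}`, `X_{L=5}`, `X_{L≥6}` for the easy text
(bin edges are configuration data, not code). A control reader is always
scored against norms that exclude them, consistent with the circular
validation of the classifier.

## Parameter evaluation and the total score

Each parameter is evaluated by (i) its empirical ROC area between the
groups, with the orientation chosen so the area is ≥ 0.5 (the trapezoid
area equals the tie-corrected Mann–Whitney U/(n₁n₂)), and (ii) its
test-retest stability: the within-group mean absolute test-retest
difference. A parameter is retained when its area is at least 0.87 **and**
the absolute control–dyslexic mean difference is at least twice the larger
of the two retest differences. Per-parameter operating points use the ROC
point closest to (0, 1), ties resolved towards higher specificity.

The TRS models the standardised 12-parameter vector as multivariate
Gaussian in each class. Because d = 12 with ~32–37 readers per class makes
raw covariances ill-conditioned, each class covariance is shrunk towards
its diagonal, Σ̂ = (1−w)S + w·diag(S) with w = 0.2 by default, plus a tiny
ridge (10⁻⁶ of the mean diagonal) so near-constant count parameters cannot
produce a singular matrix. Class priors default to 0.5/0.5: in a screening
context the cohort's class balance is a recruitment artifact, not an
estimate of prevalence; priors are configurable. Scores are computed in log
space, so extreme vectors never return NaN. Validation is leave-one-out
("circular"): normalisation statistics and both class models are refitted
without the held-out reader on every fold. The word-norm stage is
leave-one-out for controls throughout, so no reader's own gaze contributes
to the norms they are scored against.

Screening arithmetic: with sensitivity and specificity on the percent
scale, L⁺ = sens/(100 − spec) and L⁻ = spec/(100 − sens); posterior odds
are the likelihood ratio times the prior odds, and probabilities follow as
odds/(1+odds). At the published operating point (93.8% / 94.6%) and 10%
prevalence this reproduces L⁺ = 17.37, P(dyslexic | positive) ≈ 0.66 and
P(non-dyslexic | negative) ≈ 0.993 — the arithmetic that makes a negative
result highly reassuring while a positive one narrows a large population
to a small high-risk group.

## The synthetic-reading generator

`simulate_reading()` is a word-serial generative model. For each word of
length L, the reader skips with probability `p_skip(L)` (decreasing in L:
short function words are skipped often, and more so by typical readers);
otherwise lands one first-pass fixation — deeper into the word for readers
with longer preferred advances — plus a second with probability
`p_extra_fix(L)` (increasing in L). After any fixation, with probability
`p_refix` the eye steps back by 2–3.9 characters (the source of short
backward refixations; the logged ground-truth word is the word
geometrically under the landing point). With probability `p_regress` per
word the eye launches a regression: a long backward saccade to a word 2–5
positions back on the line, followed by a forward re-read of the
intervening words — this is what gives struggling readers their large
fixation counts without making an implausible fraction of saccades
backward. Line ends produce return sweeps; screens advance in reading
order. Each planned fixation draws an ex-Gaussian duration (floored at
100 ms so that every planned event survives the 90 ms detector threshold)
and is emitted as `round(duration/frame)+1` samples with Gaussian jitter
(SD 3 px, far below the 45 px dispersion window). Blinks are inserted
between fixations as 100–300 ms runs of invalid samples at 4–5 per minute.
A single cyclopean gaze stream is simulated; the analysis is
monocular-equivalent.

The two built-in texts are synthetic pseudo-word layouts matching the
published text statistics (181 words, mean 5.4 characters, five screens of
up to six double-spaced lines for the basic text; 143 shorter words for the
easy text), on a monospaced grid of 24.75 px per character (from the
two-characters-per-1.65-degree anchor). Text margins are configurable since
only the approximate angular extent of the original display is documented.

Group defaults (control: μ=180, σ=40, τ=80 ms, advance 7.5 characters, low
refixation/regression rates; dyslexic: μ=220, σ=50, τ=170 ms, advance 4.5
characters, elevated skip-free reading, refixation and regression rates)
were calibrated once so that cohort contrasts reproduce the sign of all
twelve published group differences and approximate their magnitudes — e.g.
about −90 ms in τ, −215 fixations, −47 refixations (published: −91.3,
−235.6, −45.5). Between-subject variation multiplies the continuous
parameters by log-normal jitter (SD 0.18 on τ, half that on μ, σ and the
advance; SD 0.144 on probabilities, capped at 0.97). The published tables
give only retest SDs, not between-subject spreads, so this spread is a free
calibration knob: the chosen value yields retest correlations and ROC areas
in the published range (r(τ) ≈ 0.95, AUCs 0.9–1.0). Retest sessions re-use
the reader's individual profile with fresh noise.

**What the simulation does not emulate:** calibration drift and systematic
tracker error, head movement, vertical reading noise beyond jitter,
fatigue and attention lapses, second-pass rereading strategies beyond
single regressions, and any genuine lexical structure (pseudo-words have
lengths, not frequencies or meanings). Passing tests therefore demonstrate
that the pipeline's machinery is correct and that the classifier recovers
group structure of the stated shape and size — not that the published
sensitivity and specificity would be reproduced on real recordings. On the
clean synthetic cohorts the leave-one-out validation is typically perfect,
which is consistent with the near-perfect resubstitution performance
reported for the real cohort but should be read as an upper bound.

## Numerical choices and problem sizes

- Dispersion uses the box metric max(Δx, Δy); the additive Δx+Δy variant
  is noted in the literature but not used.
- Window growth is greedy left-to-right, first fit; segmentation is
  deterministic, and detection matches a brute-force reference
  implementation exactly on randomised streams.
- Quartiles use R's type-7 (linear CDF interpolation) definition.
- ROC ties: thresholds run over all observed values; trapezoid integration
  handles ties via midranks. Refixation-threshold optimisation uses a raw
  argmax with ties towards the smallest threshold.
- The ex-Gaussian optimiser is L-BFGS-B with bounds μ ∈ [min(x)−2s, max(x)],
  σ ∈ [s/50, 4s], τ ∈ [s/50, 6s] (s = sample SD); unbounded search can run
  into a region where the λ²σ²/2 and log-erfc terms cancel catastrophically.
- Degenerate inputs error early: zero-variance durations, fewer than four
  saccades, empty groups, zero normalisation SD, non-monotone gaze
  timestamps (reported with the offending line).
- Default testing sizes: unit tests run 8+8-reader cohorts; the
  acceptance-level checks run five independent 37+32 cohorts (the study's
  group sizes), which keeps the full suite around a minute on one core.

## Limitations

The package screens; it does not diagnose. The classifier is a two-class
Gaussian with shrinkage — no attempt is made to model reading-ability
subtypes, age trends (the published cohort spans four school years), or
non-Gaussian parameter distributions. The word-norm stage needs a control
cohort of a few dozen readers on the *same text* before an individual can
be scored. Easy-text support is configuration-complete (bins, layout) but
all defaults are calibrated to the basic text.
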