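---
title: "Methods: simulating central auditory tests and modelling cognitive trajectories"
author: "audcog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating central auditory tests and modelling cognitive trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audcog)
```

## The scientific problem

Central auditory tests (CATs) — gap detection, sentence recognition in noise,
and digit-triplet recognition in noise — probe neural processing beyond the
cochlea. Because speech-in-noise perception leans heavily on processing speed,
attention and working memory, CAT performance is a candidate low-cost marker
for tracking cognitive trajectories in populations at risk of neurocognitive
decline, such as people living with HIV. The canonical study design follows a
cohort of HIV-positive and HIV-negative adults over roughly 3.5 years of
visits at ~6-month intervals, classifies the HIV-positive subjects by their
combined CAT performance at their final visit, and asks whether the
poor-CAT subgroup shows a different *slope* of cognitive change over time
than their HIV-positive peers.

Raw data from such cohorts are typically not public. `audcog` therefore
implements the entire measurement-and-inference chain as reusable, tested
code, and validates it end to end against a synthetic cohort generator whose
ground truth is known: virtual listeners take the adaptive tests, their
scores flow through the selection filters, normative scoring, quantile
grouping, and the longitudinal mixed models, and the pipeline's outputs are
compared with the generating parameters.

## Virtual listeners

A listener is a logistic psychometric function
$p(x) = \gamma + (1-\gamma-\lambda)\,F(s(x-\theta))$ with threshold
$\theta$ (the 50%-corrected point), slope $s$, guess rate $\gamma$ and lapse
rate $\lambda$. We chose the cumulative logistic over the cumulative Gaussian
because it is closed-form and only the midpoint and steepness matter to any
downstream check. Guess rates follow task structure: 0 for open-set sentence
repetition, 0.1 per digit for the closed set of ten digits, 0 for the
single-staircase gap task.

Gap detection lives on a $\log_2(\text{gap in ms})$ axis — temporal
thresholds behave Weber-like, so a doubling of gap duration is one unit of
difficulty. `gap_listener()` hides the transform. A `deterministic_step`
mode turns the listener into an exact step function; these listeners are the
ground truth for the bit-level oracle tests, in which every procedure is
replayed against an independently written brute-force trace.

The study's subjects' psychometric slopes are unknown and unknowable from
aggregate reports; slopes here are free simulation parameters, not estimates
of any cohort.

## The four adaptive procedures

All presented levels are quantized to a 0.1-unit grid so that two
implementations of the same rules agree bit-for-bit.

**Pulse-tone tracking (Békésy-like).** While the tone is heard the level
falls — 4 dB steps until the first reversal, 2 dB after — and while unheard
it rises in 2 dB steps. "Good" reversals are all reversals after the first
direction change: the source protocol counts six good reversals without
defining "good", and excluding only the initial large-step reversal is the
conventional reading. The threshold estimate is the mean level at the good
reversals (the protocol names no formula; the mean is the standard choice),
rounded to the grid. Tracks pinned at a bound for 10 trials, or exceeding
the trial cap, are flagged non-converged.

**Gap staircase.** The gap shortens after two consecutive correct
identifications and lengthens — a reversal — after two consecutive misses or
the third cumulative miss. "Three misses overall" is ambiguous between
per-run and since-last-reversal counting; both are implemented
(`gap_config(miss_reset=)`), with since-last-reversal as default because a
whole-run counter makes late trials behave differently from early ones for
no physiological reason. The step schedule (start 20 ms, step 4 ms, halving
at reversals to a 1 ms floor, stop at 6 reversals, estimate from the last 4)
is config-exposed; the source protocol cites prior work without printing
steps, so these are the package's defaults, not quoted values. Because any
2-down-style rule converges above the 50% point, the estimate sits slightly
above $\theta$ by $\approx \mathrm{logit}(p^*)/s$; recovery tests therefore
use steep-but-realistic slopes (≥3 per log2 unit) where that offset is well
under the smallest step.

**HINT.** Twenty sentences adapt 1-up/1-down against noise fixed at
65 dB(A): 4 dB steps for sentences 1–4, 2 dB after (the standard protocol's
step sizes; the source omits them). The SRT is the mean presentation level
of sentences 5–20 — literally "all sentences after the first four", with no
virtual 21st sentence — expressed in dB SNR. The composite is the unweighted
mean of the noise-front/right/left SRTs; quiet is simulated but never enters
the composite; a missing condition propagates rather than being imputed.

**Digit triplets (TDT).** Presentations come in positive/negative-phase
masker pairs at one SNR, phase order randomized within pair, masker fixed at
75 dB SPL. After each pair the target moves 1.5 dB per digit: incorrect
digits up, correct digits down, evaluated on the positive-phase presentation
only (negative-phase responses are recorded but never drive levels or the
estimate). We read the protocol as 6 practice + 30 test presentations (3 + 15
pairs): an inclusive reading would leave only 12 positive-phase test
presentations, fewer than the 14 the SRT window requires. The SRT is the
mean SNR of the last 14 positive-phase test presentations.

## Ex-Gaussian response-time model

Response times rise fast and carry a long right tail; the ex-Gaussian
(Normal($\mu,\sigma^2$) convolved with Exponential($\tau$)) fits them well,
and the fitted $\mu$ indexes central processing speed. The textbook density
$\tau^{-1}\exp(\sigma^2/2\tau^2 - (x-\mu)/\tau)\Phi(z)$ loses all precision
when $\sigma/\tau$ grows (two enormous terms nearly cancel), and a naive
optimizer will happily walk into that region and "improve" the likelihood.
`dexgauss()` therefore evaluates the algebraically identical Mills-ratio
form $\log f = \log\phi_{\mu,\sigma}(x) + \log(\sigma/\tau) + \log\Phi(z) -
\log\phi(z)$, with an asymptotic series for $z < -10^4$ where even that
difference cancels. Fitting is maximum likelihood (the source does not state
the fitting algorithm; MLE is the implementer's choice and documented as
such) over $(\mu, \log\sigma, \log\tau)$, started from moment estimators
with $\tau_0$ from the skewness clipped to $[1\,\mathrm{ms}, s]$, using
Nelder–Mead plus a parameter-scaled BFGS polish; the result never falls
below the start's likelihood, and near-symmetric samples pin $\tau$ at its
floor with a warning. The plain mean of correct response times is exported
alongside, as the companion outcome.

## Selection filters

Four rules in a fixed order: (1) visits beyond 3.5 years (1278 days at
365.25 days/year) are dropped, so long-followed subjects do not gain
leverage; (2) subjects with fewer than 4 remaining visits are dropped —
"3 or less visits" read literally; (3) subjects with any retained-visit
threshold above 25 dB HL at 0.5–4 kHz in either ear, a tympanogram outside
types A/A$_s$/A$_d$, peak pressure outside [−100, +50] daPa, admittance
outside [0.3, 1.7] mmho, or missing tympanometry (distinct audit reason) are
dropped; (4) any positive history flag (ear drainage, concussion,
noise/chemical exposure, neurological disease, mental illness, ototoxic
antibiotics, chemotherapy) drops the subject. Hearing and history are
assessed over *any* retained visit by default — the conservative reading of
subject-level exclusion — with a baseline-only switch for the history rule.
The audit attributes a subject who would have met the visit count but lost
visits to the horizon to the horizon rule, keeping the four counts disjoint.
Filtering is idempotent and the order is pinned by tests: a subject with
four visits, one beyond the horizon, is excluded.

## Normative scoring and grouping

Z-scores use HIV-negative subjects as the reference sample. The reference
visit defaults to each subject's *last* retained visit, matching the visit
used for grouping: with a learning effect in the data, norming at baseline
while grouping at the final visit would mix learning stages into the
classification. Baseline norming remains available. Lower-is-better
variables (thresholds, SRTs, response times, error counts) are sign-flipped
so higher z is always better.

The combination CAT score is the unweighted mean of the three CAT z-scores
at the last visit and demands complete CAT data — grouping is the primary
classifier and must be unambiguous. Cut-points at the 0.20/0.80 empirical
quantiles (type-7, linear interpolation) are computed over the **entire
cohort** including HIV-negative subjects; within-HIV-positive cut-points are
available behind a switch. Boundary-equal scores go to the extreme group,
which is how ties can produce unequal group sizes. HIV-negative subjects
never receive CAT-based labels.

Global composites average direction-harmonized z-scores: executive =
Cogstate subtests except One Back; speed = the TOVA speed measures plus One
Back; CAT = the three auditory tests. The attention comparison score enters
no composite (neither global formula lists it) and is analyzed standalone.
MoCA is analyzed on its raw scale. Composites tolerate up to 50% missing
components (configurable); beyond that they are missing.

## Trajectory models

For each outcome,
$$y_{ij} = \beta_0 + \beta_g g_i + \beta_a a_i + \beta_t t_{ij}
  + \beta_{tg}(t_{ij}\times g_i) + \beta_{ag}(a_i \times g_i)
  + u_{0i} + u_{1i} t_{ij} + \varepsilon_{ij},$$
with group $g$, age-at-last-visit $a$ (subject-constant, as specified), time
$t$ in days from each subject's first visit, and correlated subject
intercept/slope random effects. Estimation is REML via `lme4` (ML
available); time is internally rescaled to years for a well-conditioned
optimization and all slopes are reported back in units/day, ×10⁻⁴ in the
report table to match the natural magnitude of day-scale slopes. Inference
is large-sample Wald z — the simplest defensible default at ~380 subjects;
no degrees-of-freedom correction is claimed. A singular intercept+slope fit
is refit intercept-only and flagged; if the mixed model cannot be fit at all
(e.g. degenerate zero-noise input) the fixed effects fall back to ordinary
least squares on the same design, flagged `random_structure = "none"`. The
reference group is HIV-positive; HIV-negative stays in the model but out of
the headline report. No multiple-testing correction is applied to the
per-outcome p-values; a Benjamini–Hochberg column is appended and explicitly
labelled as an extension.

## The synthetic cohort generator

The generator defines the study conditions the package is validated under:
class sizes 90/164/53/75 (HIV-negative, HIV-positive, and the
good/poor-CAT subgroups), class-specific age distributions (means 25.9 /
40.8 / 38.1 / 42.1 years, SDs 11.8 / 13.6 / 12.8 / 8.4, truncated to
18–70), visits every 182 days with 14-day Gaussian jitter over a 1400-day
window (longer than the analysis horizon, so the horizon filter has work to
do), and a 4% per-visit dropout hazard, which leaves roughly one subject in
seven below the four-visit minimum.

Outcomes are generated on a latent performance scale (reference-SD units,
higher = better) and mapped to natural units per outcome. Learning slopes
default to +4.0–4.5×10⁻⁴ SD/day for HIV-negative, HIV-positive and TopCATs —
about +0.5 SD over 3.5 years, a visible but unremarkable practice effect —
and near-flat for BottomCATs (−0.5×10⁻⁴ for MoCA and the CATs, +1.0×10⁻⁴
elsewhere). The implied HIV-positive−BottomCATs slope difference of
3–4.5×10⁻⁴ SD/day gives the time×group Wald test roughly 75–90% power at
the calibration sizes used in the tests; this is a calibration of the
synthetic conditions, not an estimate from any cohort. Random intercepts
(SD 0.8), slopes (SD 5×10⁻⁴/day, correlation −0.2) and residuals (SD 0.45)
are Gaussian. Age enters at −0.02 SD/year.

The three CAT outcomes share a subject-level latent ability (class means 0 /
0 / +1.2 / −2.0 reference-SD, within-class SD 0.7, per-test deviation SD
0.3) as their random intercept, so the grouping variable is genuinely linked
to the class being recovered. The −2.0 SD displacement of the declining
class deserves a note: a 0.20-quantile cut over the whole cohort recovers
only ~55–60% of a class displaced by one reference SD when within-class
spread is comparable to the reference SD — that is a property of overlapping
Gaussians, not of any implementation. A clearly impaired subgroup at −2 SD
with 0.7 within-class SD yields ~85–90% recovery, which is the regime the
end-to-end recovery check runs in.

When `use_cat_simulators = TRUE`, the raw CAT scores are measured by
actually running the gap staircase, the three HINT conditions, and the TDT
against listeners whose thresholds follow each subject's latent trajectory
(noise-front harder by +2 dB, lateral conditions easier by −1 dB, so the
three conditions average to the latent composite). This closes the loop from
psychometric function to published-style report table.

All randomness flows from one master seed split arithmetically into named
streams (demographics, visits, outcomes, peripheral, listeners), so each
component is reproducible on its own. Identical seeds give byte-identical
cohorts.

**What the generator does not emulate:** covariance between specific
Cogstate subtests beyond the shared class slopes; demographic confounding
beyond age; missing-at-random score gaps within completed visits;
administrator learning; floor/ceiling effects in bounded scores. Passing
tests therefore demonstrate that the chain recovers what it assumes —
linear-in-time latent trajectories with Gaussian heterogeneity — not that
real cohort data meet those assumptions.

## Numerical choices and problem sizes

- Levels quantized to 0.1 units; estimates are exact means of grid levels
  (Békésy's is additionally rounded to the grid, as its protocol describes a
  gridded threshold).
- Quantile ties break toward the extreme groups; group assignment is
  invariant to row order.
- Test replicate counts: 500 seeded runs per procedure for threshold
  recovery; 100 datasets of n = 2000 for ex-Gaussian recovery; 200
  replicates of ~90-subject cohorts for mixed-model size and coverage, with
  acceptance bands set to the exact binomial 99% regions around the nominal
  0.05 and 0.95. These sizes keep the default suite comfortably within a
  desktop run while leaving Monte-Carlo noise well below the tolerances
  being asserted.
- The end-to-end check runs the full ~380-subject default cohort once under
  a fixed seed.

## Known limitations

- Wald z inference ignores small-sample degrees-of-freedom corrections;
  at the default cohort sizes the type-I error measured by the calibration
  tests is nominal, but users fitting much smaller cohorts should expect
  mild anti-conservatism.
- The staircase simulators model psychometric behavior, not acoustics: no
  waveform synthesis, no masker phase-curvature signal processing, no
  binaural cues. The HINT spatial conditions differ only through listener
  thresholds.
- The attention comparison score and the Cogstate/MoCA/TOVA administration
  internals are opaque input columns; only the ex-Gaussian response-time
  model is computed here.
- `fit_exgauss` assumes independent response times; sequential effects in
  real data bias $\tau$ upward.
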