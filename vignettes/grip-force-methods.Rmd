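---
title: "Methods: simulating and analysing event-related bimanual grip force"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing event-related bimanual grip force}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gripscan)
```

## The measurement and the scientific question

In a bimanual grip-force paradigm, participants hold one force sensor in
each hand at a calibrated force between 1.5 and 3 N while visual stimuli
appear in a go/no-go task; the vertical compression force (Fz, in
milli-Newton) is recorded continuously at 1000 Hz together with a trigger
at each stimulus onset. Because analysis is restricted to correct no-go
trials, any condition difference in the force traces reflects covert
motor activity driven by stimulus processing rather than response
preparation. The scientific question is whether, when and in which
direction spatial information — a stimulus's physical side, an arrow's
direction, or a word's spatial meaning — modulates the force exerted by
each hand.

`gripscan` implements the full analysis chain for such data and, because
raw laboratory recordings are not redistributable, a generator that
produces fully synthetic experiments with known ground truth so that every
stage is testable end to end.

## The synthetic generator

`simulate_experiment()` composes, per participant and hand, a continuous
force trace:

* a holding force near 2250 mN (mid-calibration), with per-participant,
  per-hand offsets (sd 150 mN, truncated to the 1500–3000 mN band);
* a multiphasic evoked response added at every stimulus onset, modelled as
  a sum of Gaussian bumps. Defaults mimic the force
  morphology this paradigm elicits: for lateralised stimuli, peaks near 130, 330 and 600 ms with
  the 330 ms bump tallest; for arrows, 130/300/650 ms with the first bump
  tallest; for words, 130/250/350/850 ms. Gaussians were chosen because
  only peak latencies and relative heights are established, and sums of
  Gaussians are smooth and analytically convenient;
* the lateralised hand-by-side effect: a rectangular pulse over the effect
  window, convolved with a 20 ms Gaussian, scaled by
  `amplitude x side_code x hand_sign`. Under the `ipsilateral_positive`
  convention (stars: onset 60 ms, duration 400 ms, 10 mN; arrows: onset
  100 ms, duration 50 ms, 6 mN) the right hand gains force for right-side
  stimuli; under `contralateral_positive` (words: onset 250 ms, duration
  50 ms, 6 mN) the pattern reverses. Each participant and hand draws its
  own slope (sd 3 mN) around the population value, independently across
  hands;
* white sensor/physiological noise (sd 15 mN per sample) with a shared
  component across hands (correlation 0.3), emulating automatic inter-hand
  coordination;
* slow drift: an independent per-hand random walk (15 mN per square-root
  second, updated every 10 ms and linearly interpolated), emulating
  arousal and fatigue trends;
* rare movement artifacts (2% of trials): 100 ms half-sine excursions of
  800 mN in one hand;
* on go trials only, a smooth ramp diverging from no-go trials at 250 ms
  and saturating near 50/55/40 mN (stars/arrows/words).

Trial designs follow the paradigm's composition: 360 trials with 25% go
stimuli for stars and arrows (sides balanced to within one trial); 450
trials for words with 20% go words, 20% go symbol arrays, 40% critical
no-go words and 20% no-go symbol arrays (symbol arrays carry no side
code). Default sample sizes are 41 participants for stars and arrows and 27 for
words (the word task requires native speakers, hence the smaller pool).
The inter-trial interval defaults to 1000 ms after the epoch end, which
guarantees non-overlapping epochs. The no-go stimulus stays on for the 2000 ms
response deadline, so the full epoch lies within stimulus presentation.

What the generator does *not* emulate: real between-participant
variability in evoked-response shape (participant offsets vanish under
baseline correction, so random-intercept variances in window fits are
near zero and often singular — flagged, not an error), autocorrelated
muscle tremor spectra, eye- or head-movement artifacts, or any
stimulus-specific morphology beyond the Gaussian bumps. Passing recovery
tests therefore demonstrates that the analysis chain is correct and
calibrated under this generative model, not that it would detect effects
of a given size in any particular laboratory's data.

Randomness is reproducible: every stage derives sub-seeds from one master
seed (`derive_seed()`), and the heavy per-sample noise uses a portable
counter-seeded generator, so identical inputs give byte-identical outputs.

## Preprocessing

The chain mirrors standard psychophysiological practice and is audited by
provenance fields (running a stage out of order is an error):

1. **Filter** the continuous recording with a fourth-order low-pass
   Butterworth at 15 Hz applied forward and backward (zero phase; the
   effective amplitude response is the squared magnitude,
   $1/(1+(f/15)^8)$). Filtering precedes epoching so filter transients
   fall outside the epochs; edges are stabilised by odd-reflection padding
   long enough for the slowest filter pole to decay below numerical noise,
   which keeps a constant trace exactly constant.
2. **Epoch** from 200 ms before to 1000 ms after each onset. The window is
   half-open, `[-200, 1000)` ms, giving exactly 1200 samples with onset at
   index 201.
3. **Baseline-correct** by subtracting the mean over `[-20, 0)` ms, so
   force is expressed relative to the onset level and slow drift cancels.
4. **Reject** any trial in which either hand exceeds ±500 mN after
   baseline correction (thresholding after baselining, since the
   criterion is meant for event-related excursions, not holding-force
   offsets); participants losing more than 20% of critical trials are
   excluded. The denominator is the number of correct no-go critical
   trials.
5. **Select** correct no-go trials of the critical stimulus class (symbol
   arrays and error trials never enter the analysis) and **average** by
   hand and side within participants. Cells with no surviving trial
   propagate as missing; participants with missing cells are dropped from
   the scan with a message.

## The exploratory scan

At each of the 1200 epoch timepoints a classical two-way within-participant
ANOVA yields F statistics for Hand (df 1, n−1), Side (df 2, 2(n−1)) and
their interaction. The classical F statistic is a design choice; any pointwise
repeated-measures statistic could drive the enhancement step.

Each F trace is enhanced with threshold-free cluster enhancement:

$$\mathrm{TFCE}(t) = \sum_{h = dh, 2dh, \ldots}^{F(t)} e(t, h)^{E}\, h^{H}\, dh,$$

with the standard defaults $E = 0.5$, $H = 2$ and $dh$ set to 1/100 of the
observed maximum (reused unchanged for every permutation). $e(t,h)$ is the
length of the contiguous run of timepoints with $F \ge h$ containing $t$.
TFCE rewards both tall and temporally extended effects without committing
to a cluster-forming threshold.

The null distribution comes from within-participant permutation: the six
hand-by-side cell time courses are relabelled freely within each
participant, identically at every timepoint, so temporal autocorrelation
is preserved and exchangeability is assumed only across cells within a
participant. The maximum of the enhanced statistic over time is recorded
per permutation (5000 permutations for a full run; desk-scale work uses
200), and per-timepoint p-values use the add-one estimator
$p(t) = (1 + \#\{\max^* \ge \mathrm{TFCE}(t)\})/(1 + n_{\mathrm{perm}})$,
which cannot return zero and keeps the test family-wise valid through the
max-statistic correction. Windows are maximal runs of $p < .05$
("significant") and $p < .1$ ("close"), reported with half-open bounds in
ms.

Numerical conventions: degenerate timepoints with a zero error mean square
get $F = 0$; an all-zero scan enhances to zero and yields $p = 1$
everywhere; grid membership at a threshold uses a tolerance of
$10^{-12}dh$ so that values landing exactly on a threshold count as
suprathreshold.

## Confirmatory models

Condition means are averaged over a window (inclusive start, exclusive
end) to one row per participant, hand and side. Hand is sum-coded
(−0.5 left, +0.5 right), side is continuous (−1, 0, +1), and models are
fitted by REML with a participant random intercept. Fixed-effect p-values
are Wald t tests with Satterthwaite degrees of freedom, the standard
choice in this model class; the df method is recorded in every fit
object.

Backward elimination tests every currently droppable term by a
likelihood-ratio test between maximum-likelihood refits (REML likelihoods
are not comparable across fixed structures), drops the least significant
term with $p > .1$, and respects marginality: a main effect is never
dropped while its interaction remains. The elimination trail is returned
so every step can be re-checked.

Marginal and conditional R² follow the variance decomposition
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_r + \sigma^2_e)$ and
$R^2_c = (\sigma^2_f + \sigma^2_r) / (\sigma^2_f + \sigma^2_r +
\sigma^2_e)$, with random-slope terms contributing their design-weighted
variance.

The contralateral-covariate model regresses one hand's window mean on the
opposite hand's mean-centred force plus the side code, with a participant
random intercept. Centring is at the experiment-wide grand mean (centring within
participant would instead absorb participant means into the covariate).
The covariate absorbs the shared
inter-hand coordination signal; note that because the covariate itself
carries the (opposite-signed) lateralised effect, it is nearly collinear
with the side code, which widens the side coefficient's standard error
and makes single-experiment estimates noisier than the plain regression —
the cost of controlling for coordination.

Individual slopes are extracted from per-hand models with a random side
slope as the fixed coefficient plus the participant's conditional mode
(BLUP). The alternative reading — the deviation alone — was rejected
because cross-experiment correlations of deviations alone would discard
the common component and because the resulting values are then
interpretable as each participant's own mN-per-side-unit slope. With only
three side levels per participant these fits are often singular; singular
fits are flagged and retained. Pearson correlations between slope tables
are computed on pairwise-complete participants with the per-pair N
reported, mirroring the varying sample sizes across experiments.

## Problem sizes and calibration checks

The package's own acceptance suite works at these scales, chosen to give
stable Monte-Carlo estimates while remaining desk-sized: family-wise
error is estimated from 500 null simulations (20 participants,
300-sample epochs, 200 permutations) against the binomial band
[0.03, 0.07]; detection and sign-recovery use 100 simulated star-like
experiments (40 participants, full 360-trial recordings) and 6 word-like
experiments at the word study's 27 participants; TFCE is verified
exhaustively against brute-force threshold integration on all 9840 grid
signals of length ≤ 8. The same quantities are recomputed by
`scripts/acceptance.R` at slightly reduced replication (40 star seeds).

## Known limitations

* The permutation scheme assumes exchangeability of the six cells within
  participant under the null; systematic hand asymmetries that exist even
  under no side effect are part of the null being tested against for the
  interaction scan.
* Windows found by the scan and then confirmed by models on the same data
  inherit the usual circularity of this two-stage workflow; the package
  reproduces the workflow rather than correcting it.
* The generator's effect is a single smoothed pulse per experiment; real
  lateralised effects may wax and wane — appearing, vanishing during a
  force trough, and reappearing — which the recovery tests do not probe.
* Fixed-effect p-values rely on the Satterthwaite approximation; with 40
  participants and saturated 2×3 designs this is accurate, but very small
  samples should rely on the likelihood-ratio trail instead.
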