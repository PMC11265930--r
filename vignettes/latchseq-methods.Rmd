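---
title: "Methods: sequence analysis of multi-solution puzzle-box logs"
author: "latchseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence analysis of multi-solution puzzle-box logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latchseq)
```

## The problem

Field experiments on innovative problem-solving increasingly use
multi-compartment puzzle boxes monitored by RFID and video: a box with 24
locked doors, each secured by one of four latch mechanisms — a horizontal
side-pull bolt (`H`), a rod-removal latch (`R`), a vertical pull-down bolt
(`V`) and a rotating swivel (`S`), six doors per mechanism. Wild foragers
visit the box at night; every detection, door opening (with its latch
type, work time and an exploratory-diversity score from video) and
re-baiting event is logged with a timestamp. The analytical questions are:
who solved the task, which latches do solvers prefer, how *flexible* and
how *individual* is their extractive-foraging technique, and how does
group foraging (competition) reshape it.

`latchseq` turns such an event log into those answers. Everything
downstream of the log is deterministic, so the whole analysis is a pure
function of (inputs, configuration) — reruns are bit-identical.

## From events to trials and conditions

A **trial** is one individual's contiguous visit: within a (site, night),
an individual's consecutive events belong to one trial while inter-event
gaps stay below the absence threshold (default 60 s; a gap of exactly the
threshold starts a new trial, reading "absent for at least one minute" as
a closed bound). An individual is a **solver** of a latch type once it has
opened at least three doors of that type across all its trials, a
**flexible** solver if it solved at least two types.

Box state is tracked per (site, box, night): all doors closed at the
start of the night, openings accumulate, and every re-bait resets the box
and begins a new bait cycle. A trial is **unrestricted** when the focal
animal was the first solver to arrive in the bait cycle at a fully closed
box and no other solver produced any logged event inside the trial's time
window; otherwise it is **competitive** (the box may have been partially
solved, or another solver was present). Three scoping choices matter and
are deliberate:

* presence is temporal overlap of *logged events*, not proximity;
* only solvers (and, optionally, unidentified animals — off by default)
  count as competitors, because non-solvers scrounge rather than compete
  for doors;
* overlap is evaluated within the same site, box and night; a solver
  working the second box of a two-box site does not make a trial
  competitive.

Work time per door is analysed as an ordinal bin: `[0,5)`, `[5,16)`,
`[16,31)`, `[31,Inf)` seconds. The published bin labels leave (30, 31)
unassigned; we close the gap downwards (bin 3 is `[16,31)`).

## Sequence metrics

The ordered latch types opened during a trial form a categorical sequence
over the four-letter alphabet. Two per-sequence summaries combine into a
**complexity index**

$$C(s) = \sqrt{\frac{q(s)}{n-1} \cdot \frac{h(s)}{\log 4}},$$

where $q$ counts adjacent positions whose latch differs (transition
count) and $h$ is the Shannon entropy (natural log) of the
within-sequence latch distribution. $h_{max} = \log 4$ always uses the
full alphabet, even for sequences that use fewer states, so $C$ is
comparable across sequences. $C = 0$ exactly when one latch type was used;
$C = 1$ exactly when all four latches occur equally often and every
opening switches latch. A length-1 sequence has no scope for switching
and is defined to score 0 (such sequences are excluded by the length
filter in practice). The index is base-invariant because $h/h_{max}$ is.

Pairwise dissimilarity uses **optimal matching**: the minimum total cost
of insertions/deletions (cost 1) and substitutions transforming one
sequence into the other, computed by the standard dynamic programme.
Substitution costs come from observed transition rates pooled over all
analysed sequences ("TRATE"): $SC(i,j) = 2 - p(i\to j) - p(j\to i)$ for
$i \ne j$, zero diagonal, clipped below at zero. States that frequently
follow one another are cheap to exchange. Two conventions are worth
stating. First, a state never observed as a source has zero observed
rates for cost purposes (so a never-transitioning pair costs the full
constant 2), while the probabilistic transition matrix exposed to users
carries a uniform row there so it stays row-stochastic. Second, costs are
pooled across both social conditions by default (`cost_pooling =
"pooled"`), since condition-specific substitution economies would make
the two conditions' distances incommensurable; per-condition estimation
is available as a config choice.

Raw distances are normalised by the length of the longer sequence
(`normalization = "longest"`, the classic length normalisation for this
distance; `"sum"` and `"none"` are selectable), bounding typical values
near [0, 2]. Distances between each individual's own trials
(intra-individual) and between trials of different individuals
(inter-individual) are compared with Mann–Whitney tests, per condition,
plus an intra-vs-intra comparison across conditions.

A caution on geometry: optimal matching with arbitrary TRATE costs
satisfies identity, symmetry and nonnegativity, but the triangle
inequality can fail when the substitution costs themselves are
non-metric (a pair with cost 2 can be bridged through a state both
transition to cheaply). The test-suite therefore checks the triangle
inequality under uniform (metric) costs and the other axioms under TRATE
costs; no analysis in the pipeline requires metricity.

## Filters defining the analysed sequence sets

Mirroring the study design, sequences enter the complexity and
dissimilarity analyses only if the trial (i) is by a solver, (ii) has at
least 6 openings, (iii) begins after the individual has already opened
at least 6 doors in earlier trials (so not-yet-qualified solving is
excluded), and (iv) falls in the individual's first test year. Latch
*preference* uses a different subset: each solver's final five trials in
which it arrived first at a fully available box; the first-opened latch
and total latch counts over this subset are tested against uniformity
with a χ² goodness-of-fit test. All thresholds are `pipeline_config()`
fields; the defaults are the study profile.

## Model competition for solving success

Success (solver vs. non-solver) is modelled with binomial GLMs built
forward from the intercept-only model: at each step the candidate with
the largest deviance reduction is tried and retained only if it lowers
AICc ($AIC + 2k(k+1)/(n-k-1)$); ties go to input order. The visited path
is reported with ΔAICc, Akaike weights and a likelihood-ratio test of
the final model against the null. Confidence intervals are Wald
(±1.96 SE); profile-likelihood intervals are out of scope. Perfect
separation is detected (fitted probabilities at 0/1 or runaway
coefficients) and flagged rather than silently reported. Candidate
predictors in the pipeline are first-trial exploratory diversity, age
and sex; a candidate with missing values or no variation among the
tested individuals is dropped before fitting.

Mann–Whitney statistics are reported in R's W convention (rank sum of
the first sample minus $n_1(n_1+1)/2$, identical to that sample's U).
The p-value is exact by enumeration when $n_1+n_2 \le 12$ without ties,
otherwise a normal approximation with tie and continuity corrections.
Two-sided alternatives throughout.

## The synthetic generator: what it emulates, and what not

Because the field data are external, the package carries a seeded
generator whose output has the statistical structure the analysis
assumes. It is this package's own construction, fully parameterised by
`synthetic_config()` and exported to `truth.json` so recovery tests are
self-describing:

* **Latch difficulty.** Shared weights (S .295, H .269, V .262, R .174),
  the observed relative opening frequencies of the four mechanisms —
  swivel easiest, rod hardest.
* **Individual preference.** Each individual draws
  $\theta_i \sim \mathrm{Dirichlet}(\alpha w)$. The default
  $\alpha = 4$ gives moderate heterogeneity: individuals share the
  difficulty ordering but differ persistently in emphasis, which is what
  makes inter-individual dissimilarity exceed intra-individual
  dissimilarity. (Very small $\alpha$ collapses individuals onto a
  single latch and caricatures the behaviour.)
* **Sticky switching.** Each opening repeats the previous latch with
  probability $\kappa = 0.3$, else samples $\theta_i$ — a Markovian
  perseveration term.
* **Competition sharpening.** During competitive trials preferences are
  raised to $1/\tau$ and renormalised ($\tau = 0.5$ by default), making
  individuals *more* self-similar under competition; $\tau = 1$ switches
  the mechanism off and the two conditions become exchangeable draws.
* **Learning.** Work time is log-normal with mean log declining by
  $\lambda = 0.02$ per prior opening; exploratory diversity declines
  similarly. Solvers get higher first-trial diversity than non-solvers,
  giving the success GLM a recoverable signal.
* **Repertoire expansion.** "Knowledgeable" solvers (prior experience
  with the horizontal latch) know all four mechanisms from the start;
  "naive" solvers start with one and add one every 3 trials, in order of
  their own preference — mirroring a second latch type typically being
  learned within the first few visits. A forager whose known-latch doors
  are all open stops working (it cannot operate unlearned mechanisms),
  so single-repertoire trials score complexity 0 exactly.
* **Nightly structure.** Each night is a series of bouts: a re-bait,
  then either one solver alone (unrestricted by construction) or a
  partner solver arriving first and overlapping the focal (competitive
  for both). Non-solvers and occasional unidentified animals contribute
  detection-only scrounging visits. One RNG sub-stream per night is
  derived from the seed, so extending a simulation never perturbs
  earlier nights, and datasets are byte-identical given a config.

What the generator does *not* emulate: spatial movement and home ranges,
observational social learning, seasonal or weather-driven attendance,
door-handedness, and measurement error in video scoring. Passing
recovery tests therefore demonstrates that the pipeline detects the
targeted effects when present at realistic magnitudes — not that real
raccoon data contain them.

## Numerical and degenerate-input choices

* Trial-splitting uses a closed bound (gap ≥ threshold splits).
* The DP's cost ties need no tie-breaking: the distance value is unique.
* Sequences outside the alphabet error immediately; empty-vs-empty
  distance is 0; `d("H", "") = 1`.
* All-zero χ² counts, empty Mann–Whitney samples, non-nested LRT inputs
  and AICc at $n \le k+1$ are errors, not NaNs.
* Entropy of a single-state sequence is normalised to exactly `0`
  (IEEE negative zero is removed).
* Stepwise duplicate candidates resolve to input order (`which.max`).

## Problem sizes

The shipped tests run the generator at 15–30 individuals over 2–10
nights (hundreds of trials, ~100 analysed sequences per dataset), which
estimates transition costs from thousands of pooled transitions and
compares thousands of sequence pairs; the oracle suites cover 500+
brute-force alignment cases and 1000 LCS cases. These sizes were chosen
to match the scale of a single field season while keeping the whole
suite comfortably fast on one CPU.

## Known limitations

* Condition labels depend on detection completeness: a solver present
  but never logged cannot be counted as a competitor.
* TRATE costs are time-invariant; early and late trials share one
  substitution economy.
* The forward-stepwise path is greedy and, like all stepwise
  procedures, inherits selection instability at small n; the full
  visited path with weights is reported so readers can see the margin.
* Prior knowledge (naive vs knowledgeable) must be supplied in the
  roster — it reflects experience before the multi-solution phase and is
  not derivable from the log itself.
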