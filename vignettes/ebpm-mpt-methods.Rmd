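---
title: "Decomposing event-based prospective memory with multinomial processing trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing event-based prospective memory with multinomial processing trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebpmtree)
```

## The model and its assumptions

Event-based prospective memory (EBPM) tasks embed an intended action
("press B when the word *frog* appears") in an ongoing activity, here a
non-focal color-matching task. Every trial belongs to one of four types —
PM target or distractor, crossed with color match or non-match — and draws
one of three responses: "match", "nonmatch", or the PM key. A multinomial
processing tree (MPT) model expresses each response probability as a sum
of products of latent process probabilities along branches:

* `P` — the prospective component: the probability of engaging
  preparatory attentional processes on a trial;
* `M1`, `M2` — the retrospective component: recognizing a target as a
  target (`M1`, target trials) or a distractor as a non-target (`M2`,
  distractor trials);
* `C1` / `C2` — detecting a color match / non-match;
* `g` — guessing that the item is a PM target; `c` — guessing "match"
  when color detection failed.

On a target/match trial, for instance: with color detection (`C1`) and
preparatory attention (`P`), recognition (`M1`) or a lucky guess (`g`)
produces the PM response, otherwise the detected color drives a "match"
response; without preparatory attention the trial behaves like a pure
ongoing trial; when color detection fails, the ongoing response is a
`c`-guess. The full enumeration (42 branches) is data, not code —
`ebpm_branch_table()`, also shipped as `inst/extdata/ebpm_model.mpt` — so
normalization can be verified mechanically. Because every branch is
multilinear in the parameters, checking that each tree sums to one on all
0/1 corners of the parameter cube is an exact symbolic proof, and
`mpt_model()` performs it at construction.

The model assumes independent, identically structured trials within a
condition, a single parameter vector per condition (participants are
pooled, the convention for aggregate MPT fits), and stochastic
independence of the latent stages. Two closed forms follow and are used as
oracles in the tests: `p(pm | target) = P (M + (1 − M) g)` on both target
trees, and false alarms `p(pm | distractor) = P (1 − M) g`, independent of
the color parameters.

### Identifiability and the default constraints

Four trees with three categories give 4 × 2 = 8 independent proportions;
seven free parameters would leave the model unidentified in the counting
sense. The standard identifiable submodel sets `M1 = M2 = M` (the package
represents both as the single free symbol `M`; which tree family each
attaches to is immaterial under the constraint), and fixes the guessing
rates at `g = 0.1` and `c = 0.5` — `c = 0.5` because match and non-match
trials are equally frequent, `g = 0.1` the conventional low target-guess
rate for this paradigm. Both are arguments of `build_ebpm_model()` for
sensitivity analyses. The free parameters are then `P, M, C1, C2` and the
per-condition goodness-of-fit test has `8 − 4 = 4` degrees of freedom; a
pooled fit of nine conditions with all four parameters shared has
`72 − 4 = 68`.

## Estimation

`fit_mle()` minimizes the likelihood-ratio statistic
`G² = 2 Σ n ln(n / (N p))` — the same argmin as the multinomial maximum
likelihood — with bounded L-BFGS-B and an analytic gradient. Numerical
choices:

* parameters are kept in `[1e-6, 1 − 1e-6]` during search to avoid log
  singularities; estimates touching those bounds are treated as boundary
  solutions;
* multistart: the cube centre plus `n_starts − 1` uniform(0.05, 0.95)
  draws from a seeded generator (default `n_starts = 20`; the seed is a
  recorded input, and the caller's RNG stream is saved and restored);
* objective tolerance `1e-9`; zero cells use the `0·ln 0 = 0` convention
  and no continuity correction; a positive count on a zero-probability
  cell yields an infinite statistic with a warning rather than an error.

Confidence intervals are 95% Wald intervals from the inverse observed
information, with the Hessian of the log-likelihood taken by central
differences (step `1e-5`), truncated to `[0, 1]`. The choice of Wald
intervals is a package decision (the interval method behind published MPT
tables is typically unstated); output labels the method per parameter.
At boundary estimates the Wald approximation degenerates, so the package
falls back to profile-likelihood bounds (the parameter value at which the
profiled G² rises by the 0.95 χ²(1) quantile). In simulation at
N = 5000 per tree the intervals hold 92–98% coverage; the parameter
closest to the boundary (`M` near 0.96) is the weakest, as expected for
Wald intervals on bounded parameters.

## Cross-condition comparison

`delta_g2_test()` contrasts two conditions on one parameter:
`ΔG² = G²(constrained) − G²(free)`, referred to χ²(1) with the
conventional 3.84 criterion. The "free" baseline lets **all four**
parameters differ between the conditions (independent per-condition
fits), matching how per-condition estimates are tabulated; the
constrained model shares only the tested parameter. This baseline choice
is declared here because published ΔG² tables rarely state whether
nuisance parameters were pooled. To make the nesting inequality
`ΔG² ≥ 0` robust to optimizer noise, each fit is additionally started
from the other fit's solution. No multiplicity correction is applied by
default — `compare_conditions()` reports the number of tests and offers
Bonferroni — because the tabulated pairwise tests this mirrors are
uncorrected.

## Mediation stage

`baron_kenny()` runs the three-step OLS scheme on standardized variables:
`Y ~ X` (total effect), `W_j ~ X` per mediator, and `Y ~ X + W_1 + …`
(direct effect plus b-paths), followed by a Sobel test
`z = ab / √(a² se_b² + b² se_a²)` per mediator. Conventions, each of
which was a genuine design choice:

* duration enters as a numeric predictor in minutes (3/9/15), matching a
  single-slope linear regression rather than condition dummies;
* accuracy from two cue trials is granular (0, 0.5, 1); OLS is used
  regardless, as is conventional for this design (a logistic variant
  would change path scales but not the qualitative pattern, and is out of
  scope);
* both one- and two-tailed Sobel p-values are reported and labeled,
  because marginal calls in this literature are sometimes one-tailed and
  published z/p pairs are not always consistent with either tail; the
  package reproduces the formulas, not any particular printed pair.

## The synthetic-data generator

`simulate_experiment()` emulates the 3 × 3 between-subjects design:
filler duration × ongoing duration ∈ {3, 9, 15} minutes (some summaries
of this design say 3/6/9; the methods-level description is 3/9/15 and the
generator follows it), default cell sizes
29/33/22/29/25/24/21/19/21 (total n = 223). Per participant, the ongoing
task runs at 20 trials/min — a declared default: ~3 s of color display,
interstimulus interval and response per trial; total trial counts are not
published — with the first PM cue exactly at the ongoing duration, a
second cue 2 min later, and 2 more minutes of trials after it. Cue trials
are target trials (match/non-match with equal probability, the color
condition of cues being unspecified in the source design); the remaining
trials split evenly between match and non-match distractors. Responses
are sampled branch-by-branch from the trees, so each trial carries its
latent process record; reaction times are lognormal (median ≈ 650 ms).

Generating parameters: only marginal estimates by filler and by ongoing
duration are available, so the default for cell (f, o) is the mean of the
two marginal vectors (`default_condition_theta()`). Ratings are latent
Gaussian scores discretized to 1–5: self-reminding
`d1 = 3 + 0.02·filler + ε`, discriminability `d2 = 3 − 0.06·ongoing + ε`,
`ε ~ N(0, 1)`. The mediation structure couples a participant's
prospective component to their discriminability residual,
`P_i = P_cond + 0.2·ε₂` (clamped to (0, 1)): ongoing duration therefore
reaches accuracy through rated discriminability, while self-reminding has
no path into performance. The negative discriminability slope mirrors the
reported sign of that a-path; the effect sizes were fixed once, at values
a power analysis puts clearly above the detection threshold for n = 223,
because the generator's job is to make the qualitative pattern —
discriminability mediates, self-reminding does not — reliably testable.
What the generator does **not** emulate: participant heterogeneity beyond
the mediation coupling, practice or fatigue trends within the session,
RT–accuracy dependence, and item effects. Passing tests therefore
validate the estimation and testing machinery, not any claim about real
participants.

`trim_outliers()` implements the single-pass mean ± 3 SD rule used for
behavioral summaries (mean and SD computed once on the input, no
re-iteration). Note the rule is deliberately blunt: in a vector like
`c(1, 1, 1, 1, 100)` the outlier inflates the SD enough to keep itself
inside the band, and the function faithfully returns the input unchanged.

## Problem sizes in the test suite

The suite's simulation studies use sizes chosen to bound each check's
Monte-Carlo error meaningfully: 500 replicates at N = 5000 per tree for
recovery bias (< 0.01) and interval coverage (92–98%), 1000 replicates at
N = 1000 for the type-I error of G²(4) and ΔG²(1) (3–7% at the 5% level),
10⁶ draws per tree for the Monte-Carlo versus analytic probability check
(3 binomial SEs), and 60 full synthetic studies for the mediation
detection rates. An independent Monte-Carlo traversal oracle, coded from
the prose process logic rather than the branch tables, guards the model
definition itself.

## Known limitations

* Aggregate fitting only: no hierarchical or latent-trait MPT extensions;
  individual differences beyond the mediation coupling are not modeled.
* Wald intervals undercover slightly for parameters near the boundary;
  profile bounds are used only when an estimate is effectively at 0 or 1.
* No bootstrap mediation CIs or structural-equation alternative; the
  Sobel test's normal approximation is known to be conservative for small
  indirect effects.
* Identifiability is checked by the counting condition only; structural
  non-identifiabilities that respect the count would not be flagged.
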