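---
title: "Accumulator-model analysis of speed-accuracy tradeoff data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accumulator-model analysis of speed-accuracy tradeoff data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speedacc)
```

## The problem

In cued two-choice decision tasks, subjects trade speed against accuracy:
emphasising speed produces faster but more error-prone responses. Sequential
sampling models explain this with a single mechanism — the decision
threshold. `speedacc` implements the full behavioural analysis chain for
such experiments: trial-level data handling, defective RT quantile
summaries, two accumulator models (the drift diffusion model and the linear
ballistic accumulator), frequentist repeated-measures tests, and a default
Bayesian t-test that quantifies evidence *for* the null hypothesis — the
relevant quantity when a pharmacological manipulation is expected, but
fails, to shift the threshold.

Because pharmacological studies of this design rarely deposit raw data, the
package ships a first-class synthetic-study generator that emulates the
task structure: two sessions (drug, placebo), two cues (speed, accuracy),
two blocks of 50 + 50 + 5 labelled dummy trials per session, and a 1.0 s
response window with censoring. Everything downstream is exercised end to
end on that generator.

## The drift diffusion model and its chi-square quantile fit

Evidence accumulates as a Wiener diffusion with drift $v$ and infinitesimal
standard deviation $s$ between absorbing boundaries $0$ and $a$, starting at
$z$; absorption at the upper boundary is the correct response (stimulus
directions are collapsed, so the model is unbiased with $z = a/2$ and drift
toward correct is positive). Observed RT is the decision time plus a
non-decision time $T_{er}$.

The first-passage density at the lower boundary is evaluated with the
classic dual series: an image-sum (small-time) expansion and a sine-series
(large-time) expansion, choosing per time point whichever needs fewer terms
for a truncation error of $10^{-8}$; the upper boundary follows by
reflection ($v \to -v$, $z \to a - z$). The defective CDF integrates the
sine series term by term, with the term count bounded by the same error
target. Across-trial drift variability $v \sim N(v, \eta)$ is integrated by
20-node Gauss–Hermite quadrature. The diffusion coefficient is the
conventional scaling constant $s = 0.1$ (configurable).

Fitting minimises the quantile chi-square: for each cue, observed RT
quantiles at probabilities $(0.1, 0.3, 0.5, 0.7, 0.9)$, computed separately
for correct and error responses, delimit 6 + 6 bins whose observed masses
are fixed by construction at $(.1, .2, .2, .2, .2, .1)$ of each response
class's probability. With $N$ the cue's responded-trial count,

$$\chi^2 = \sum_{\text{cue}} N \sum_{\text{bins}}
  \frac{(p_{\text{obs}} - p_{\text{exp}})^2}{p_{\text{exp}}},$$

with expected masses floored at $10^{-5}$ (floored bins are counted and
logged). Cells with fewer than 5 error responses are collapsed into a
single error bin rather than quantized — the standard practice for sparse
error distributions. The fitted set is $\{a_\text{speed}, a_\text{accuracy},
T_{er,\text{speed}}, T_{er,\text{accuracy}}, v, \eta\}$ — threshold and
non-decision time free per cue — with $\eta$ optionally fixed to 0, the
start point fixed at $a/2$ and no start-point or $T_{er}$ variability. The
drug and placebo sessions are fit independently.

## The linear ballistic accumulator and its likelihood fit

Two independent accumulators race linearly to a threshold $b$ from start
points uniform on $[0, A]$, with drift rates drawn per trial from normal
distributions (SD $s = 1$, the scaling constant): mean $v_c$ for the
accumulator matching the stimulus, $v_e$ for the other. The defective
density of the winner has the usual closed form (winner density times the
loser's survivor function). Draws in which both drifts are negative never
finish; the defective density is renormalised by the probability that at
least one drift is positive, and the simulator records such trials as
non-responses — mirroring the exclusion of non-response trials from real
data.

A *single* model is fit jointly to both sessions by maximum likelihood,
with the threshold free across the four cue-by-session cells and $A$,
$v_c$, $v_e$, $t_0$ shared (alternative sharing schemes were considered but
the shared scheme is the identifiable default; the paper-level analyses
only require cell thresholds). Log-densities are floored at $10^{-10}$ to
keep the objective finite; floored trials are counted.

## Optimisation

Both fits use the Nelder–Mead simplex on a logistic transform of box
constraints ($a \in [0.05, 0.40]$, $T_{er} \in [0.10, 0.60]$ s,
$v \in [0, 0.60]$, $\eta \in [0, 0.30]$ for the diffusion;
$b - A \in [0.01, 5]$, $A \in [0.01, 5]$, drifts $\in [0, 10]$,
$t_0 \in [0.05, 0.6]$ s for the LBA, with $v_e$ parameterised as a fraction
of $v_c$ so the identifiability convention $v_c > v_e$ holds throughout the
search). The LBA likelihood surface in particular is multimodal in this
parameterisation, so simplex runs are started from the best points of a
seeded uniform screen of the box (200–300 draws) and each run is iterated
from its own optimum until it no longer improves. All randomness is
seeded; identical seeds give identical fits.

## The default Bayesian t-test

For a one-sample (difference-score) design, the null fixes the
standardised effect $\delta = 0$ and the default alternative places a
Cauchy$(0, r)$ prior on $\delta$ with $r = 1$. The Bayes factor is

$$\mathrm{BF}_{01} =
  \frac{f_{t,\nu}(t)}{\int f_{t,\nu}\!\big(t;\, \delta\sqrt{n}\big)\,
  \text{Cauchy}(\delta; 0, r)\, d\delta}, \qquad \nu = n - 1,$$

evaluated by adaptive quadrature (relative tolerance $10^{-8}$), and with
equal prior odds the posterior plausibility of the null is
$P(H_0 \mid t) = \mathrm{BF}_{01} / (1 + \mathrm{BF}_{01})$. A deterministic
quadrature was chosen over the sampling-based evaluation common in older
implementations: it is reproducible and accurate to the quadrature
tolerance. Published posteriors computed by MCMC agree with it only to
about two decimals; occasional third-decimal (and rarely second-decimal)
disagreement with such values reflects their sampling error, not the
integral.

```{r bayes}
bayes_t_test(t = 0.07, n = 17)
```

## The synthetic-study generator

`study_config()` fixes the study conditions: 20 subjects, 100 trials per
cue per session split into two blocks, 5 dummy trials per block, and a
1.0 s response window. Subject-level diffusion parameters are drawn from a
population with mean threshold 0.16, non-decision time 0.30 s (speed cue)
and 0.35 s (accuracy cue), drift 0.25 ($s = 0.1$); the speed cue multiplies
the threshold by 0.5 (so the mean speed threshold is 0.08), and the drug
session multiplies it by a configurable factor whose default is 1 — no
drug effect, matching the conclusion such a study reaches under a true
null. The LBA generator uses thresholds 1.0 (speed) and 1.6 (accuracy),
$A = 0.8$, drifts 3.0 and 1.5, $t_0 = 0.25$ s. Population SDs are modest
(2–15 % of the means), keeping accuracy in the 70–95 % band with speed-cue
RTs faster than accuracy-cue RTs — qualitatively the regime of real cued
random-dot-motion data.

What the generator does *not* emulate: contaminant (non-decision) RTs,
fatigue and sequential effects, feedback-driven strategy drift, or
parameter non-stationarity across blocks. Passing recovery tests on this
generator therefore demonstrates correctness of the estimation machinery
under the model's own assumptions, not robustness to real-data
contamination.

```{r study}
tt <- generate_study(study_config(n_subjects = 3,
                                  trials_per_cue_per_session = 40,
                                  seed = 1))
nrow(tt)
head(as.data.frame(tt), 3)
```

## Numerical and design choices

* **Quantile definition.** Linear interpolation between order statistics
  (type 7, R's default), fixed because published analyses of this design
  rarely state one.
* **Exclusion rule.** Subjects with accuracy-cue accuracy strictly below
  60 % are excluded; the comparison is strict (`< 0.60`) and is assessed
  pooled over both sessions — the conservative reading when the assessment
  window is unstated. Per-session assessment is available via `per =
  "session"`. Accuracy is computed over responded trials by default;
  non-response handling is configurable.
* **Deadline censoring** is applied by the generator (responses after the
  1.0 s window become non-responses) but ignored in the fitted objectives,
  since non-responses are excluded upstream; with the default parameters
  the censored mass is small (about 1 % or less) and the approximation is
  documented rather than corrected.
* **Degenerate bins.** Quantile edges at or below the fitted non-decision
  time produce zero-mass bins; they are floored inside the chi-square and
  counted, which penalises (rather than crashes) parameter proposals with
  too-large $T_{er}$.
* **Threshold ANOVAs** arrange the diffusion's two per-session thresholds
  and the LBA's four cell thresholds as a session-by-cue 2x2, so both
  models feed the same repeated-measures design; the Bayesian t-tests are
  applied to drug-minus-placebo difference scores.
* **Problem sizes.** The validation suite runs the Monte-Carlo oracle
  checks at 6x10^4 Euler paths (step 2.5x10^-5 s) for the diffusion and
  2x10^5 exact races for the LBA, and the recovery studies at 12 replicate
  sessions (diffusion, 2000 trials/cue) and 5 replicates (LBA, 2000
  trials/cell) — sizes at which the Kolmogorov-Smirnov bounds and the 10 %
  recovery tolerances are sharp while the suite stays fast enough to run
  routinely.

## Known limitations

* The diffusion fit does not include start-point variability or a
  contaminant mixture (the full Ratcliff model), and the LBA fit does not
  allow drift rates to vary by cue or session; both restrictions follow the
  minimal models the analysis design requires, and the config exposes what
  is shared.
* Euler simulation of diffusion first passages carries an $O(\sqrt{dt})$
  boundary-crossing bias; the default step ($10^{-4}$ s) is adequate for
  data generation, and the oracle tests use a finer step where the bias
  would otherwise approach the sampling bound.
* The correlation screen is a Bonferroni-controlled Pearson screen, as in
  the original design; it is not a substitute for a hierarchical
  moderation analysis.
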