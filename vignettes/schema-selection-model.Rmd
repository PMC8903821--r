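---
title: "A basal-ganglia schema-selection model of two rule-induction tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A basal-ganglia schema-selection model of two rule-induction tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgschema)
```

## The problem

Healthy aging changes performance on rule-induction tasks of executive
function.  On the Wisconsin Card Sorting Test (WCST) older adults tend to
produce more set-loss errors (abandoning a rule that is working) but not
more perseverative errors (clinging to a rule that has stopped working),
and on the Brixton Spatial Anticipation Test (BRXT) they produce more
total errors without producing more perseverations of stimulus, response
or rule.  `bgschema` implements a neurocomputational account of these
patterns: behaviour on both tasks is modelled as competition between
*schemas* — task rules at a cognitive level, concrete responses at a
sensorimotor level — each maintained by its own cortico-striato-thalamic
loop, with learning acting on two sites: reward-driven adjustment of
striatal thresholds (subcortical control) and conflict-driven adjustment
of cortical gain (cognitive control).

## The loop model

Every schema owns a loop of seven rate-coded units — CTX, striatal D1 and
D2 populations, STN, GPe, GPi and thalamus — each updated by leaky
blending toward the logistic of its weighted input,

$$\sigma_{\beta,\alpha}(x) = \frac{1}{1 + e^{-\alpha (x - \beta)}}.$$

Connectivity follows the classic basal-ganglia selection architecture:
CTX excites D1, D2 and STN; D1 inhibits GPi; D2 inhibits GPe; GPe inhibits
STN and GPi; STN diffusely excites the GPi of *all* loops in a competing
set; GPi tonically inhibits the thalamus; the thalamus re-excites CTX.
The within-loop chain CTX → D1 ⊣ GPi ⊣ THAL → CTX is positive feedback,
and the diffuse STN → GPi projection is the off-channel surround, so with
the default constants exactly one loop per set becomes highly active: the
schema controlling behaviour.  A response is emitted when one sensorimotor
loop's activation stays above the selection threshold (`theta_sel`) for a
sustain count (`k_sel`) of cycles; the cycle count is the model's reaction
time.

### Learning

Three update rules drive adaptation, applied once per feedback event:

* **Schema feedback.**  Schemas consistent with the emitted response
  ("matching") receive $f_i = +1$; all others receive
  $f_i = 2 w_{neg} - 1 - m_r\, f_i(t-1)\, r(t-1)$, so with both
  parameters at zero the mismatch baseline is $-1$, `w_neg` raises that
  baseline, and `m_r` carries the previous trial's feedback into it.
* **Prediction error.**  $\delta_i = r\,(f_i - a_i)$, where $r = \pm 1$ is
  the environment's feedback and $a_i$ is the loop's median activation
  over the just-completed trial, rescaled to $[-1, 1]$.  (The source text
  speaks of a prediction error of zero when the previous activation is
  $-1$, which only parses if activation enters the rule on the bipolar
  scale; the logistic unit itself lives in $(0,1)$.)
* **Striatal threshold.**
  $\beta_{str,i} \leftarrow \beta_{str,i} - \varepsilon_{str}\,\delta_i\,(1 + \zeta)$,
  clipped to $[0, 1]$.  Applied to the cognitive loops only.
* **Sensorimotor gain.**  $\alpha_{sma} \leftarrow 1 + \zeta_{sma}
  \prod_i (1 + \varepsilon_{sma}\, o_{sma,i})$ over the sensorimotor
  outputs $o_{sma,i}$.  The printed form of this rule is ambiguous about
  parenthesisation ($\varepsilon + o$ vs $\varepsilon \cdot o$); we adopt
  the multiplicative reading so that $\varepsilon_{sma} = 0$ makes the
  gain constant — conflict then no longer drives confidence, the stated
  interpretation of a loss of cognitive control.  The literal reading is
  available via `eq2_literal = TRUE`.

The four free parameters are `w_neg` (mismatch reward sensitivity), `m_r`
(memory for negative feedback), `eps_str` (striatal learning rate) and
`eps_sma` (sensorimotor schema learning rate), each in $[0,1]$.

### Fixed constants and what they were set by

The loop weights, tonic drives, unit gains and thresholds, integration
rate, selection threshold and sustain count, and the noise scales are not
published for this model family.  They are therefore fixed *constants of
this implementation*, chosen once so that the selection invariants hold
(single winner under asymmetric drive, threshold increases suppress a
loop, symmetric inputs stay symmetric, a suppressed winner hands over to
a competitor) and so that the model's behavioural ranges cover the
published group tables — the calibration the fitting stage presupposes.
They were not revisited afterwards.  Three deserve comment:

* The learned threshold $\beta \in [0,1]$ is mapped affinely into the
  striatal unit's useful input range (`b_str0 + b_str_scale * beta`);
  without the offset, several loops clipping at $\beta = 0$ saturate
  their striatal units together and the competition degenerates.
* A once-per-trial attentional-capture event (probability
  `noise_trial * (6 / alpha_sma)^3`, only on trials following positive
  feedback) delivers a decisive input spike to one random response loop.
  This is the model's set-loss mechanism: conflict-adapted gain protects
  against capture, so groups fitted with high `eps_sma` lapse rarely.
  The cubic damping reflects how steeply a winner-take-all race's
  susceptibility to a fixed perturbation falls with gain; it was chosen
  so that the lapse rates implied by the younger and older tables are
  both reachable inside the $[0,1]$ parameter box.
* On the Brixton task, the first error of a streak primes the punished
  response on the next trial with probability `w_inert` (imperfect
  response inhibition — the response-perseveration channel), and rules
  consistent with the observed stimulus transition receive bottom-up
  drive `w_bu` (the rule-induction cue).

Because these constants are implementation-relative, absolute cycle
counts are not comparable across implementations; only orderings (older
slower than younger; slower after negative feedback) and the fitted-error
statistics are treated as reproduction targets.

### Two readings resolved against the data

Two scoring definitions in the source material do not survive contact
with the printed group means if read maximally strictly, and the package
adopts the reading that keeps the published rates attainable (the strict
variants remain available behind flags):

* **Set-loss eligibility.**  A set is considered established after three
  or more consecutive correct responses of which at least one was
  unambiguous (`sl3_strict = TRUE` demands all three unambiguous — but
  then only one or two trials per completed category are eligible and a
  group mean of 1.48 set-loss errors cannot arise from any plausibly
  scattered error process).
* **Perseverative errors.**  Any error that would have been correct under
  the perseverated-to rule counts (`pe_unambiguous_only = TRUE` restores
  the Heaton variant in which ambiguous matches only count inside a
  sandwich of unambiguous ones).

Similarly, "alternate between positions 1–5" is implemented as an
ascending walk through positions 1–5 (`walk15`), because the strict 1↔5
alternation predicts disk 1 from seven of the nine positions and thereby
gives rule-perseveration scores a coincidence floor of roughly two per
session, above what the printed means allow.  The strict rule is still
available as `alt15`.

## Fitting

`fit_task()` minimises the z-norm
$\sqrt{\sum_i z_i^2}$, $z_i = |\bar{x}_{sim,i} - \bar{x}_{obs,i}| /
(SD_{obs,i}/\sqrt{n_{obs}})$, by simulated annealing (geometric cooling,
Gaussian proposals shrinking with temperature, reflection at the box
bounds), re-simulating 25 sessions with fresh seeds at every objective
evaluation.  The objective is deliberately noisy and the annealer
compares noisy evaluations directly; within a small z window, the
candidate with the larger summed log Bayes-factor fit index (JZS, Cauchy
scale 1/2, t reconstructed from summary statistics) is preferred.  The
reported per-measure z values are those of the *selected* evaluation —
the minimized values a fit table prints — while `z_reval` keeps one
independent re-evaluation, which is unbiased but noisy (for the Brixton
rule-perseveration measure the 25-run simulation standard error exceeds
the target's printed standard error, so a re-evaluated z bounces by about
one unit around its expectation).

`grid_scan()` evaluates the full-range parameter grid (default 11 per
axis) per `m_r` plane; `cross_fit_swap()` evaluates one group's fitted
parameters against the other group's targets.

## The synthetic cohort

`gen_agent_session()` and `gen_cohort()` implement a stochastic
rule-following agent that is deliberately *not* the dynamical model, so
scorer and statistics tests cannot inherit model bugs.  The agent follows
a believed rule; after negative feedback it either retains it
(`persev_prob`) or switches, preferring an evidence-consistent rule
(`induce_prob`); it occasionally abandons a working rule (`lapse_prob`)
or emits a stimulus- or response-driven override (`stim_pull`,
`resp_pull`).  RT is a base plus a post-error penalty plus Gaussian
noise, so both published RT main effects hold by construction.  The
default profiles were calibrated once, by coarse search, so that
cohort-level means fall within one published SD of the younger and older
tables; they emulate the *statistical structure* of the data (group
means, orderings, the PE–SL3 coupling direction), not individual
participants, serial dependencies beyond the rule dynamics, or the
excluded all-error participant.

## Numerical choices and degenerate inputs

Logistic evaluations clamp their exponent at ±40; Bayes factors integrate
the Zellner–Siow g-mixture directly (no noncentral densities); the
Mann–Whitney p uses the tie-corrected normal approximation and is flagged
`NA` for a constant pooled sample; a zero-SD target measure is an error
in `group_z()`; selection ties at the cycle cap are broken uniformly at
random from the run's seeded stream; all randomness flows through R's
RNG, so a session is fully determined by its seed.

## Known limitations

* Absolute reaction-time magnitudes (cycle counts) are
  implementation-relative.
* The model's fixed constants were tuned for the two tasks as
  administered here; other decks, rule orders or disk geometries may need
  re-tuning.
* The acceptance-scale grid scan (5 runs per point) cannot reach the
  z < 1 plateau the full 25-run scan shows; its measurement noise floor
  alone exceeds the threshold (see the decisions ledger).
* The point parameter estimates of the source fits are not reproduction
  targets; broad good-fit plateaus make point identity meaningless.
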