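---
title: "Modelling conflict in the Stroop task: the DMC simulator, G² fitting, and permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling conflict in the Stroop task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmcstroop)
```

## The model

In a two-choice color-word Stroop task the word's meaning and its ink color
either agree (congruent) or conflict (incongruent). The diffusion model for
conflict tasks (DMC) explains the resulting response-time and accuracy
patterns with a single accumulator $X_t$ that starts at 0 and drifts toward
absorbing bounds at $+a$ (correct) and $-a$ (error). The drift is the
superposition of two processes:

* a **controlled** process (naming the ink color) with constant rate
  $\mu_c$ (evidence/ms), and
* an **automatic** process (reading the word) whose expected contribution
  follows a rescaled gamma density,
  $$E[X_a(t)] = \zeta \left(\frac{t\,e}{(\alpha-1)\tau}\right)^{\alpha-1}
  e^{-t/\tau},$$
  rising from 0 to a single maximum of exactly $\zeta$ at
  $t_{max} = (\alpha-1)\tau$ and decaying back to 0. The automatic term is
  *added* on congruent trials and *subtracted* on incongruent ones — that
  sign convention alone produces the Stroop effect (slower, more
  error-prone incongruent trials).

Observed response time is $RT = D + R$: the first-passage (decision) time
$D$ plus a residual (nondecision) time $R \sim \mathcal N(T_{er}, sr)$ with
negative draws rejected. Seven free parameters result:
$a, \mu_c, \zeta, \alpha, \tau, T_{er}, sr$. Two derived quantities,
$t_{max} = (\alpha-1)\tau$ and $t_{90}$ (the 90th percentile of
Gamma($\alpha$, $\tau$)), summarise the automatic process's timing and are
the quantities carried into inference when $\alpha$ and $\tau$ themselves
recover poorly (see below).

### Simulation scheme

`simulate_decisions()` integrates the process with an Euler scheme:
$$X_k = X_{k-1} + \mu_c\,\Delta t \pm \big(E[X_a(k\Delta t)] -
E[X_a((k-1)\Delta t)]\big) + \sigma\sqrt{\Delta t}\,\epsilon_k,$$
with $\Delta t = 1$ ms and diffusion coefficient $\sigma = 4$ by default
and a 1500 ms horizon equal to the task's trial length. The automatic
contribution uses *exact increments* of the expected activation rather
than its analytic derivative: increments telescope to the activation
itself and avoid the derivative's singularity at $t \to 0$ for
$\alpha < 2$. The start point is fixed at 0 between symmetric bounds;
neither starting-point nor drift variability is modelled.

Three numerical points deserve explicit statement:

1. **Discretization bias.** Plain Euler first-passage simulation carries a
   known $O(\sqrt{\Delta t})$ bias, equivalent to inflating the boundary
   by $\approx 0.583\,\sigma\sqrt{\Delta t}$. At $\Delta t = 1$ ms,
   $\sigma = 4$ this is $\approx 2.3$ evidence units (about +5 ms on a
   147 ms mean decision time). The package keeps the canonical
   $\Delta t = 1$ default — the reference fitting procedure is defined at
   that step, and fitting is internally consistent because data and model
   predictions share the discretization — but the test suite verifies
   convergence to the continuous-time Wiener closed form
   ($E[D] = (a/\mu)\tanh(a\mu/\sigma^2)$,
   $P(\text{correct}) = 1/(1+e^{-2a\mu/\sigma^2})$ at $\zeta = 0$) at
   $\Delta t = 0.01$ ms.
2. **Reproducible, congruency-invariant noise.** Randomness comes from a
   compiled splitmix64 generator with one stream per trial, keyed only by
   (seed, trial index). Identical seeds give bit-identical outputs; with
   $\zeta = 0$ the congruent and incongruent simulations are bit-identical
   because congruency enters only through the automatic term; and repeated
   objective evaluations during fitting reuse the same noise (common
   random numbers), making the fitted objective deterministic.
3. **Horizon handling.** Trials not absorbed within the horizon are
   flagged, scored as errors, and assigned $D$ equal to the horizon; a
   warning is raised if they exceed 0.5% of trials, which does not occur
   under plausible Stroop parameters.

## Fitting by simulated G²

No closed-form likelihood exists for the time-varying drift, so fitting is
simulation-based. Observed data per congruency are reduced to a
multinomial: correct RTs are cut at their empirical 10/30/50/70/90th
percentiles (six bins); error RTs likewise when at least 11 errors exist,
otherwise all errors pool into one bin. The pooled error bin is kept even
with zero observed errors — a zero observed proportion contributes nothing
to G², but the bin keeps the model's predicted error mass in the
accounting. Model proportions come from simulating `n_sim` trials per
congruency (50,000 at reference scale; 5,000 at the desk scale used in
tests) classified into the *observed* bin edges, floored at
$1/(2\,n_{sim})$ and renormalized so the statistic stays finite. The fit
minimises
$$G^2 = 2\sum_{\text{cond}} n_{\text{cond}} \sum_{\text{bins}}
p^{obs}\ln\frac{p^{obs}}{p^{pred}}$$
with multi-restart Nelder-Mead: each restart draws a uniform start from
configurable ranges ($a \in [40,120]$, $\mu_c \in [0.2,0.8]$,
$\zeta \in [5,40]$, $\alpha \in [1.5,4.5]$, $\tau \in [20,200]$,
$T_{er} \in [200,400]$, $sr \in [5,60]$ — package defaults; the reference
study's pilot-derived ranges are unpublished) and holds its own simulation
seed fixed. Because the parameters span three orders of magnitude, the
simplex is scaled by the start-range midpoints (`parscale`); out-of-domain
proposals receive a $10^9$ + squared-distance penalty rather than an
error. Reference scale is 250 iterations × 30 restarts; the desk scale
(100 × 5) completes a fit in ~20 s on one CPU.

### What recovery does and does not establish

`run_recovery()` draws truths from the start ranges, simulates 300 trials
per congruency, refits, and correlates truth with estimate. At desk scale
the boundary, controlled drift, nondecision mean and automatic amplitude
recover with median absolute relative errors well under 25%, while the
gamma shape $\alpha$ and scale $\tau$ recover poorly (truth–estimate
correlations below 0.5) — individually they are weakly identified because
different $(\alpha, \tau)$ pairs produce similar activation trajectories.
`grade_recovery()` therefore drops flagged raw parameters and substitutes
$t_{max}$ and $t_{90}$, reproducing the analysis set
$(a, \mu_c, \zeta, T_{er}, sr, t_{max}, t_{90})$.

## Behavioral effect tables

`apply_exclusions()` implements the published rules: practice trials are
always dropped; for RT analyses error trials and the single trial
immediately following an error are dropped (the "posterror" window is one
trial — no longer window is defined); accuracy analyses keep all main
trials. No additional RT trimming is applied beyond the 1500 ms task
window. `effect_table()` computes descriptive cell means per stimulation
condition: the Stroop effect (incongruent − congruent mean RT), its strata
by previous-trial congruency (CPT), and the Gratton contrast
(Stroop|CPT=congruent − Stroop|CPT=incongruent). The first main trial has
no predecessor and enters the overall Stroop effect but not CPT-stratified
cells. `delta_vs_sham()` differences these effects against the sham
condition. Published group-level model estimates can be fed through the
same machinery via `effect_table_from_summary()` — the package computes
descriptive cell means, not mixed-model marginal means, and treats printed
model estimates as given inputs (mixed-model estimation is out of scope).

## Permutation inference

Within-subject designs motivate blocked permutation schemes:

* **Two conditions** — paired Fisher-Pitman: statistic
  $Z = \sum d_i / \sqrt{\sum d_i^2}$ on within-pair differences, null from
  independent sign flips per pair, two-sided Monte-Carlo p with the +1
  correction (so $p \ge 1/(n_{perm}+1) > 0$).
* **Three conditions** — multivariate Kruskal-Wallis with maxT: a
  tie-corrected rank statistic per endpoint; the joint null permutes
  condition labels *within each participant*, applying the same
  permutation to all endpoints; each endpoint's p is the proportion of
  permutations whose *maximum* statistic across endpoints reaches its
  observed value. This single-step maxT is itself the multiplicity
  adjustment.
* **Holm** step-down correction is applied to the per-parameter
  Fisher-Pitman p-values.

The reference default is 10,000 permutations; tests use fewer. The
permutation blocking (within-participant) is an assumption — the source
describes approximative tests without stating the block structure — chosen
because the design is within-subject.

## The synthetic cohort generator

The study's trial-level data are available only on request, so
`simulate_cohort()` generates a stand-in world whose stated conditions are:
600 main trials per session (300 per congruency, uniformly shuffled), four
color words on two buttons (green/red vs yellow/blue) with incongruent
stimuli always crossing buttons, a practice phase of at least 50 trials
ending when 18 of the last 20 are correct (capped at 500), and chi-squared
interstimulus intervals on [0.3, 0.7] s with mean 0.5 s
(draws $0.3 + 0.075\,\chi^2_4$, resampled into range; the scale is
calibrated analytically so the truncated mean is 0.500).

Generative effects:

* **Conflict adaptation** — after an incongruent trial the automatic
  amplitude shrinks to $\zeta(1-\kappa)$, $\kappa = 0.25$ by default. This
  is the minimal mechanism consistent with the conflict-adaptation account
  (greater control after conflict, i.e. less automatic influence) and
  produces a positive Gratton contrast.
* **Stimulation** — condition multipliers on $\zeta$ applied on trials
  preceded by a *congruent* trial (default 0.7 under "6hz", 1 under sham
  and "9.7hz"), localising the reduction where the reference study found
  it; a multiplier on $\kappa$ is also available.
* **Between-subject variability** — normal draws for $a, \mu_c, T_{er}$,
  moment-matched log-normal for $\zeta, \alpha-1, \tau, sr$ (respecting
  domains), around group means
  $(75, 0.5, 20, 2, 50, 300, 30)$ with SDs $(8, 0.06, 4, 0.3, 10, 25, 6)$
  — values in the range typical for Stroop DMC fits, chosen once.

Sessions are deadline-censored: a simulated $D+R$ beyond 1500 ms becomes a
miss (RT 1500 ms, incorrect), since a real response pad stops listening at
trial end. The generator does **not** emulate response-pad timing jitter,
arousal covariates, posterror slowing, fatigue/training drift, or any
direct electrophysiological effect of stimulation — a green test on this
world establishes that the pipeline recovers the effects the generator
injects, not that the biological claims hold.

The congruency sequence is an unconstrained random permutation; cC/cI/iC/iI
cell counts are balanced only in expectation.

## Design choices made where the design was open

* The activation formula is not printed in the source; the canonical DMC
  gamma-rescaled expectation (above) is used.
* $t_{90}$ is taken as the 90th percentile of the Gamma($\alpha,\tau$)
  distribution (not of the activation trajectory).
* The G² reduction uses quantile bins (not fixed-width time bins or CAF
  bins); the bin scheme is fully configurable via `bin_spec()`.
* Residual time is Normal with rejection of negative draws; configs with
  $T_{er} > 3\,sr$ keep the rejection rate negligible.
* Accuracy denominators keep error trials (the accuracy model "includes
  all trials"); the posterror exclusion applies to RT analyses only.

## Known limitations

* Fitting cost scales linearly in `n_sim` × Nelder-Mead evaluations;
  paper-scale settings (50,000 × 250 × 30) are supported but take hours
  per dataset on one CPU, as in the original procedure.
* $\alpha$ and $\tau$ are reported by the fitter but should not be
  interpreted individually at realistic trial counts (use $t_{max}$,
  $t_{90}$).
* The Euler scheme's small-$\Delta t$ convergence is verified, but all
  default-scale quantities inherit the $\Delta t = 1$ discretization, as
  in the reference implementation.
* Monte-Carlo p-values have resolution $1/(n_{perm}+1)$; exhaustive
  enumeration is used only in tests at tiny n.
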