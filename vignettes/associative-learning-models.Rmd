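---
title: "Models, encodings and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, encodings and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kalmantd)
```

## The modeling problem

In Pavlovian conditioning an animal learns that cues (tones, lights) predict
outcomes (food, shock).  Four related accounts of this learning differ along
two axes: *what* is learned (immediate reward vs long-run discounted value)
and *how* it is represented (a point estimate vs a full posterior
distribution).

* **Rescorla-Wagner (RW)** — point estimate of immediate reward.  On trial
  $n$ with cue vector $x_n$ and reward $r_n$,
  $w_{n+1} = w_n + \alpha\, x_n (r_n - w_n^\top x_n)$.
* **Kalman filter (KF)** — Bayesian estimate of immediate reward.  Weights
  are latent states of a linear-Gaussian dynamical system: prior
  $w_0 \sim N(0, \sigma_w^2 I)$, random-walk drift
  $w_n \sim N(w_{n-1}, \tau^2 I)$, observation
  $r_n \sim N(w_n^\top x_n, \sigma_r^2)$.  The posterior stays Gaussian
  with mean $\hat w_n$ and covariance $\Sigma_n$; the Kalman gain
  $k_n = S_n x_n / (x_n^\top S_n x_n + \sigma_r^2)$ with
  $S_n = \Sigma_n + \tau^2 I$ acts as a stimulus-specific, dynamic learning
  rate.
* **TD(0)** — point estimate of value.  With linear values
  $V(x) = w^\top x$ over a real-time stimulus representation, the update is
  $w \leftarrow w + \alpha\, x_t\, \delta_t$ with
  $\delta_t = r_t + \gamma\, w^\top x_{t+1} - w^\top x_t$.
* **Kalman TD (KTD)** — Bayesian estimate of value; the synthesis.  Because
  $r_t = w^\top(x_t - \gamma x_{t+1})$ at the TD fixed point, running the
  Kalman filter on the *discounted temporal derivative*
  $h_t = x_t - \gamma x_{t+1}$ estimates value weights with full posterior
  uncertainty.

The interesting empirical territory is where the axes interact: phenomena
that need uncertainty tracking (latent inhibition, backward blocking,
retrospective revaluation) *and* real-time structure (second-order
conditioning, serial compounds).  Only KTD covers both.

## Parameters

All four rules share one parameter object, `model_params()`:

| parameter | meaning | default |
|---|---|---|
| `alpha` | RW/TD learning rate (associability), dimensionless in $[0,1]$ | 0.3 |
| `gamma` | discount per time step in $[0,1]$ | 0.98 |
| `sigma_w2` | prior weight variance (weak zero-mean prior at 1) | 1 |
| `sigma_r2` | reward noise variance, in squared reward units | 1 |
| `tau2` | per-trial weight-diffusion variance (volatility) | 0.01 |
| `bins_per_stimulus` | CSC bins per stimulus | 4 |
| `serial_overlap` | boundary steps shared between serial events | 1 |
| `lr_schedule` | `constant` or `one_over_n` (RW only) | constant |

The defaults are the settings used throughout the bundled experiment
catalog, which fixes 10 trials per trial type per phase.  `one_over_n`
exists to expose the statistical character of RW: with $\alpha_n = 1/n$ the
rule is a Robbins-Monro stochastic approximation and converges to the
maximum-likelihood (least-squares) weights, which the test suite checks
against a QR least-squares fit at $10^5$ steps.

## Design notation and trial ordering

Designs are written compactly: `"A->+ / AB->-; A->-; B->?"` is two
interleaved trial types for one phase, an extinction phase, then a test
probe.  `+` maps to reward magnitude 1, `-` to 0, and a numeric suffix
(`A->0.5`) is accepted for parameter sweeps.  Probes (`?`) are never trained
on; responses are read out from the final weights.

The notation does not say whether interleaved trial types alternate or are
shuffled.  The default is strict round-robin alternation, which makes every
simulation bit-reproducible; `schedule = "shuffled"` gives a seeded
permutation with exact per-type counts.  The catalog's directional results
do not depend on this choice.

## Real-time encoding

Real-time models use the complete serial compound (CSC): each stimulus is
split into `bins_per_stimulus` non-overlapping bins, each bin a feature
active only at its own latency after stimulus onset.  A stimulus keeps the
same feature columns wherever it appears, so learning transfers across trial
types and phases.  Reward arrives on the final step of the trial.

Two discretisation choices deserve comment.

**Serial transitions share one boundary step.**  For `Z->X`, X's onset step
coincides with Z's final bin (`serial_overlap = 1`), rather than starting
one step later.  This is the natural discretisation of "Z terminates with
the onset of X" — offset and onset are the same instant — and it is also
load-bearing: the shared step is the only place where successive serial
elements enter one observation with the same sign, which is what lets them
*compete* to predict the outcome.  That competition (classic
informational overshadowing between serial elements) produces the negative
covariance that drives recovery-from-overshadowing effects in serial
designs; with strict concatenation (`serial_overlap = 0`, also available)
successive elements only ever appear in the derivative features with
opposite signs, covariance between them stays positive everywhere, and
serial latent inhibition and serial recovery from overshadowing come out
in the wrong direction.

**Diffusion is per trial.**  The weight random walk is indexed by trial, so
the `tau2` predict step is applied once per trial (at its first time step),
not once per CSC bin.  Per-step diffusion would make the amount of
forgetting scale with trial duration — a 15-step serial trial would forget
almost four times as much as a 4-step one — which erodes pre-exposure
effects and flips the serial latent-inhibition direction for longer
representations.  `diffusion = "per_step"` is available for comparison.

**Sign of the derivative.**  The package defines $h_t = x_t - \gamma
x_{t+1}$, which yields positive weights for reward-predicting cues and is
the form consistent with the TD fixed point.  The opposite convention
(`sign = -1`) negates posterior means and leaves every covariance —
hence every directional prediction — unchanged.

**Readout.**  A probe's response is the value at stimulus onset,
$w^\top x_{\text{onset}}$ (for trial-level models, $w^\top x$): value at
onset is the conventional proxy for anticipatory responding, and is
monotone in whatever response measure a given preparation uses.

## Numerical choices

The covariance update $\Sigma' = S - k x^\top S$ is re-symmetrised after
every step ($\Sigma \leftarrow (\Sigma + \Sigma^\top)/2$); a Joseph-form
update is available behind `form = "joseph"` and agrees to $10^{-12}$ in the
tests.  Sequential filtering with $\tau^2 = 0$ is validated against the
closed-form conjugate regression posterior
$\Sigma = (I/\sigma_w^2 + X^\top X/\sigma_r^2)^{-1}$,
$\mu = \Sigma X^\top r / \sigma_r^2$ to $10^{-8}$ over randomized designs of
up to 20 features and 200 observations.  Posterior matrices are checked
symmetric with eigenvalues $\ge -10^{-8}$ after every update.  Zero-phase
designs produce zero weights and zero responses.  Test probes never change
state, and probe equality in TD contrasts is asserted to $10^{-9}$.

## The experiment catalog

`experiment_catalog()` holds ten paradigms, all at 10 trials per type per
phase.  Five are trial-level KF simulations: latent inhibition
(`A->-; A->+` vs `A->+`) and four post-training recovery designs
(unovershadowing, unblocking, recovery from overexpectation, uninhibition),
in which extinguishing one element of a formerly reinforced compound
changes responding to its *absent* partner via the negative covariance
stored during compound training.  Five are real-time KTD-vs-TD contrasts:
second-order conditioning after overshadowing, second-order extinction,
serial-compound extinction, serial latent inhibition, and recovery from
overshadowing by extinction of the second-order stimulus.  In every
contrast the point-estimate TD model predicts *no* difference between
conditions — its weights for absent stimuli are simply not eligible for
updating — which the suite checks as exact equalities.

A few encodings follow the source experiments' published designs rather
than the compact Methods summaries: the overshadowing/second-order design is
`AX->+ / BY->+; A->- (or B->-); Z->X; Z->?`, second-order extinction is
`A->+; Z->A; A->-; Z->?` against a no-extinction control, and serial
recovery from overshadowing is `Z->X->+ / W->Y->+; Z->-` probing X against
Y.  Control groups that the original studies included but the summaries
omit are omitted here too.

```{r catalog-example}
res <- run_experiment("serial_latent_inhibition")
res$responses
ordering_report(res)
```

## What the simulations do and do not show

The generator produces exactly the idealised laboratory conditions the
catalog describes: binary cues, deterministic unit rewards, fixed trial
counts, no context stimuli, no inter-trial interval, no individual
variability.  Passing the directional suite therefore shows that the
*models* order conditions as the corresponding animal experiments did — not
that they fit any animal's response rates.  Quantitative correspondence
with behavioural data is outside what these simulations can establish.

Known limitations:

* With 8 or more bins per stimulus, a two-element serial trial is a
  15-step chain; after only 10 trials per phase the bootstrapped value has
  not propagated back to the probe's onset bin (responses are at the
  $10^{-2}$ level), so condition orderings there are degenerate.  The
  robustness checks cover 2-4 bins, where orderings are stable to
  $\pm 50\%$ perturbation of `tau2`.
* The Kalman gain depends on the covariance only, never on outcomes, so no
  Pearce-Hall-style surprise modulation of associability emerges; learning
  the volatility `tau2` online is out of scope.
* The CSC is used for continuity with classic TD treatments; distributed
  temporal bases (microstimuli) and configural/state-clustering
  representations are out of scope, as are instrumental (actor-critic)
  extensions.

## Reproducing the figure-level results

Every directional claim above is enforced in `tests/testthat/`, and
`scripts/acceptance.R` recomputes the quantitative weight-sum result from a
fresh run (see the README).  The full test suite runs in well under a
minute; simulation sizes are the catalog's own (10 trials per phase;
$10^5$ steps for the stochastic-approximation check, the only long loop).
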