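# kalmantd

Simulation toolkit for a unified family of associative-learning models.
Classical (Pavlovian) conditioning has been formalised in two influential
ways that generalise the Rescorla-Wagner rule along different axes: Bayesian
models track *uncertainty* about cue-reward associations, and reinforcement
learning models track *long-run* (discounted cumulative) reward rather than
immediate reward.  This package implements both axes and their synthesis as
four learning rules over a common interface, together with a compact textual
notation for conditioning designs and a catalog of the classic paradigms
each model does or does not explain.  It is intended for computational
neuroscientists and learning theorists who want executable, testable
versions of these models' predictions.

## The models

With cue features $x$, weights $w$ and reward $r$:

* **Rescorla-Wagner** — delta rule,
  $w \leftarrow w + \alpha x (r - w^\top x)$.  With a decaying learning
  rate $\alpha_n = 1/n$ it is a Robbins-Monro stochastic approximation and
  converges to the maximum-likelihood weights.
* **Kalman filter** — Bayesian learning of immediate reward under a
  linear-Gaussian dynamical system: prior $w_0 \sim N(0, \sigma_w^2 I)$,
  drift $w_n \sim N(w_{n-1}, \tau^2 I)$, observation
  $r_n \sim N(w_n^\top x_n, \sigma_r^2)$.  The update
  $\hat w_{n+1} = \hat w_n + k_n \delta_n$,
  $\Sigma_{n+1} = S_n - k_n x_n^\top S_n$ with
  $k_n = S_n x_n / (x_n^\top S_n x_n + \sigma_r^2)$,
  $S_n = \Sigma_n + \tau^2 I$ replaces the fixed learning rate with a
  stimulus-specific, uncertainty-weighted Kalman gain.
* **TD(0)** — real-time value learning over a complete serial compound
  (CSC) stimulus representation:
  $w \leftarrow w + \alpha x_t \delta_t$,
  $\delta_t = r_t + \gamma w^\top x_{t+1} - w^\top x_t$.
* **Kalman TD** — the synthesis: the Kalman filter applied to the
  discounted temporal derivative $h_t = x_t - \gamma x_{t+1}$, giving a
  posterior distribution over *value* weights.  It inherits retrospective
  revaluation from the Kalman filter and second-order conditioning from TD,
  and captures serial-compound phenomena neither parent explains.

Experimental designs are written in a compact notation: `A->+` (A is
reinforced), `AB->-` (compound, no reward), `Z->X->+` (serial compound),
`A->+ / B->-` (interleaved trial types), `;` between phases, `B->?` (test
probe).

## Worked example

Forward blocking with recovery: A is trained, the compound AB is trained,
then A is extinguished, and B is probed.

```r
library(kalmantd)
run <- run_model("A->+; AB->+; A->-; B->?", model = "KF")
run
#> <model_run> KF on 'A→+; AB→+; A→-; B→?'
#>   test responses:
#>      B
#> 0.4756
```

B was blocked (its response after `A->+; AB->+; B->?` alone is 0.062), but
extinguishing A *recovers* responding to B (0.476): during compound
training the filter learned that the two cue weights jointly account for
the reward, storing that constraint as negative covariance, so evidence
that A is worthless is evidence that B is not.  Point-estimate models
cannot do this — absent cues are never eligible for updating.

The catalog experiments package such contrasts with their expected
directions:

```r
res <- run_experiment("serial_compound_extinction")
res$responses
#>   condition model probe      value
#>  extinction   KTD     Z 0.13949220
#>  extinction    TD     Z 0.01619227
#>     control   KTD     Z 0.20486979
#>     control    TD     Z 0.01619227
ordering_report(res)
#>   model                 description        lhs        rhs    margin pass
#> 1   KTD  control[Z] > extinction[Z] 0.20486979 0.13949220 0.0653776 TRUE
#> 2    TD control[Z] == extinction[Z] 0.01619227 0.01619227 0.0000000 TRUE
```

After serial training `Z->X->+`, extinguishing X lowers the Kalman TD value
of Z (positive covariance ties the serial partners), while TD predicts no
change at all.  `names(experiment_catalog())` lists all ten paradigms.

A command-line interface is included:

```sh
Rscript inst/scripts/kalmantd list
Rscript inst/scripts/kalmantd run --experiment latent_inhibition --out out/
Rscript inst/scripts/kalmantd sweep --experiment latent_inhibition \
    --param tau2 --values 0.005,0.01,0.02
```

`run` writes `responses.tsv`, `ordering.tsv`, `trace.tsv` (tidy per-step
weights, gains, variances and prediction errors) and `params.txt`, and
exits 0 only if every expected ordering holds (2 on an ordering failure,
1 on usage errors), so figure-level regressions can be CI-enforced.

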