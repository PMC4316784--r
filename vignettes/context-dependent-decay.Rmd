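---
title: "Models of context-dependent motor memory decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of context-dependent motor memory decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorprim)
```

## The scientific question

When people adapt reaching movements to a perturbation — a lateral force
from a robotic manipulandum, or a rotated cursor — two processes run in
parallel: trial-by-trial error correction builds a compensatory motor
command $x$, and forgetting erodes it. Error-clamp trials, in which the
experienced error is forced to zero, isolate the forgetting process.
Behavioral work has shown that forgetting is *context dependent*: a memory
trained at a target direction $\theta = 0$ decays faster during clamp
trials at $\theta = 0$ than during clamp trials at distant directions.

`motorprim` implements three trial-by-trial learning models and the
error-clamp protocols that discriminate them:

1. **Motor-primitive framework with weight decay** — the conventional
   account; forgetting is context *independent*.
2. **State-space model with effort minimization** — a scalar-memory
   account; forgetting is context independent and there is no
   generalization.
3. **Motor-primitive framework with effort minimization** — forgetting is
   weighted by how strongly the memory-carrying primitives are recruited on
   the current trial, and is therefore context *dependent*.

## The model

A population of $N$ motor primitives is tuned to target direction. Unit
$i$ has preferred direction $\varphi_i$, drawn uniformly from
$[-\pi, \pi)$, and Gaussian activity

$$A_i(\theta) = \exp\!\left(-\frac{\|\theta - \varphi_i\|^2}{2\sigma^2}\right),$$

where $\|\cdot\|$ is the wrapped angular distance (the package wraps onto
$[-\pi, \pi)$, with $+\pi \mapsto -\pi$). The compensatory command is the
linear readout $x(\theta) = \sum_i W_i A_i(\theta)$, and the movement error
on trial $t$ is $e_t = p_t - x_t(\theta_t)$ (0 on clamp trials). Gradient
descent on the cost

$$E_t = \tfrac12 e_t^2 + \tfrac{\lambda_1}{2}\textstyle\sum_i W_{i,t}^2
      + \tfrac{\lambda_2}{2} x_t^2$$

gives the master update implemented by `update_weights()`:

$$W_{i,t+1} = (1-\eta\lambda_1) W_{i,t}
  + \tfrac{\eta}{N}\,(e_t - \lambda_2 x_t(\theta_t))\,A_i(\theta_t).$$

Setting $\lambda_2 = 0$ gives the weight-decay model; $\lambda_1 = 0$ the
effort-minimization model. The scalar state-space model applies
$x_{t+1} = (1-\eta\lambda_2)x_t + \eta e_t$ on every trial
(`update_state_space()`).

### Why the gradient terms carry $1/N$

The command-level learning gain of the primitive models is the learning
rate times the recruitment overlap
$G(\theta_t,\theta_t) = \sum_i A_i(\theta_t)^2$, which grows linearly with
$N$. Without normalization, $\eta = 0.5$ with $N = 100$ and $\sigma =
\pi/4$ would give a per-trial error gain of about 11 and the dynamics would
diverge within a few trials. We therefore follow the standard convention
for population-coding learning rules and scale the error- and
effort-gradient terms by $1/N$, so that all dynamics are governed by the
normalized overlap $\hat G = G/N \in (0, 1)$ and are insensitive to the
population size. The multiplicative forgetting factor $(1-\eta\lambda_1)$
acts on each weight separately — it is not a population sum — and is left
unscaled; this keeps the clamp-phase forgetting rate at the quoted
per-trial value $\eta\lambda_1 = 0.0015$, which produces visible decay on
the 20-trial test blocks.

### Command-space recursions and fixed points

Multiplying the weight update by $A_i(\theta)$ and summing over $i$ turns
it into a recursion purely over commands
(`recursive_command_update()`):

$$x_{t+1}(\theta) = (1-\eta\lambda_1)\,x_t(\theta)
  + \eta\,(e_t - \lambda_2 x_t(\theta_t))\,\hat G(\theta_t, \theta).$$

The two regularizers now differ qualitatively: the $\lambda_1$ decay factor
is the same at every $\theta$ (context-independent forgetting), while the
$\lambda_2$ decay is weighted by $\hat G(\theta_t, \theta)$ and is maximal
at $\theta = \theta_t$ (context-dependent forgetting). The package uses
this recursion as an *independent oracle*: the weight-space engine and the
command-space recursion must agree at every trial and probe angle to
floating-point accuracy, and the test suite enforces this.

Setting the increments to zero under constant training at $\theta_t$ with
perturbation $p$ gives the asymptotes returned by `fixed_point_command()`:
$x^* = p/(1+\lambda_2)$ for both effort models, and
$x^* = p\hat G/(\lambda_1 + \hat G)$ for the weight-decay model.

### The generalization function

For uniformly distributed preferred directions, the per-primitive
expectation of $A_i(\theta_t)A_i(\theta)$ has the closed form implemented
by `generalization_closed_form()`:

$$\frac{G(\theta_t, \theta)}{N} \;\longrightarrow\;
  \frac{\sigma}{2\sqrt{\pi}} \sum_{k \in \mathbb{Z}}
  \exp\!\left(-\frac{(\Delta\theta + 2\pi k)^2}{4\sigma^2}\right),$$

a Gaussian in the wrapped separation $\Delta\theta$, wider than a tuning
curve by $\sqrt{2}$. The periodic-image sum accounts for circularity and is
exact up to overlap terms of order $e^{-\pi^2/(2\sigma^2)}$ (below
$4\times10^{-4}$ for $\sigma \le \pi/4$). The test suite validates it
against the Monte-Carlo mean over $10^5$ sampled preferred directions,
requiring better than 2% relative agreement.

### The state-space model in multi-direction protocols

The scalar model has no machinery for expressing its memory at untrained
directions. We implement the only reading consistent with both of its
defining properties — no generalization, and direction-independent decay:
the single memory $x$ is updated on **every** trial (so clamp blocks decay
it at the fixed rate $1-\eta\lambda_2$ regardless of where they are
imposed), while the command readout is gated to the trained direction
($x(\theta) = x$ at the trained direction, 0 elsewhere). Its
generalization function is therefore exactly zero off the trained
direction and its decay function is flat.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| $\eta$ | learning rate | 0.5 (primitive), 0.04 (state space) | — |
| $\eta\lambda_1$ | weight-decay forgetting per trial | 0.0015 | — |
| $\eta\lambda_2$ | effort forgetting per trial | 0.03 (primitive), 0.0015 (state space) | — |
| $N$ | number of primitives | 100 | count |
| $\sigma$ | tuning width | $\pi/4$ | rad |
| $p$ | perturbation | $\pi/4$ | N or deg |

Forgetting rates are specified as the products $\eta\lambda$ because that
product, not $\lambda$ alone, is the per-trial rate; `default_params()`
stores the implied $\lambda$. The tuning width $\sigma$ has no canonical
published value; $\pi/4$ is adopted as the default because it yields
generalization and decay profiles of realistic width (substantial transfer
at $\pi/12$–$\pi/6$, near-zero transfer beyond $\pi/2$) while keeping the
dynamics comfortably stable; it is exposed everywhere as a parameter. The
sensitivity parameter set $\eta = 0.8$, $\eta\lambda_2 = 0.01$ is used in
the tests to show the qualitative conclusions do not depend on the
defaults.

## Protocols and what the generator emulates

`build_simulation1(theta_test, p)` produces the 250-trial
train/test/retest design: 100 training trials at $\theta = 0$, 100 clamp
trials at `theta_test`, 50 clamp trials back at $\theta = 0$. Retest
levels that depend on `theta_test` are the signature of context-dependent
decay (`retest_divergence()`).

`build_simulation2(K, p, seed)` produces the alternating design modeled on
the behavioral experiments: 200 training trials, then $K = 16$ cycles of
20 clamp trials at $\theta'_k = -\pi + 2\pi k/K$ followed by 100
relearning trials at $\theta = 0$. The cycle order is a seeded uniform
permutation of $\{0, \dots, K-1\}$, drawn without replacement so every
direction is tested exactly once; ensembles re-draw it per run.
`generalization_function()` averages the first 10 test commands per cycle;
`decay_function()` averages the first 10 relearning commands and
normalizes by the end-of-training command $x_0$.

The simulations are noiseless: across-run variability in
`run_ensemble()` comes entirely from resampling the preferred directions
(and the cycle order). Real behavioral data additionally carry execution
and measurement noise, inter-subject parameter differences, and possible
multi-rate memory dynamics, so passing tests demonstrate properties of the
model class, not a fit to any data set.

## Numerical choices

* **Order of evaluation within a trial**: activities → command → error →
  record (probes pre-update) → update. Clamp trials set $e = 0$ but still
  apply the full update; this is the entire mechanism of clamp-phase decay.
* **Probes** are evaluated before the trial's update so a trial's recorded
  profile is the state that generated its movement.
* **Seeds**: `run_ensemble()` derives per-run seeds with the documented
  rule `derive_seed(base, k) = (base * 1000003 + k) mod (2^31 - 1)`;
  sampling is isolated from the caller's RNG state. Identical
  configuration and seeds give bitwise-identical outputs, including CSV
  exports (written with 17 significant digits).
* **Ensemble SDs** use the sample ($n-1$) denominator and are `NA` for a
  single run.
* **Problem sizes**: the dual-route oracle checks run full 250-trial
  protocols over 5 seeds; fixed-point checks use 500 constant-training
  trials (residual transients are below $10^{-9}$ for the slowest model);
  ensemble summaries use the standard 20 runs of the 2120-trial
  alternating design; the closed-form validation uses $N = 10^5$.
* **Angle boundary**: the wrap convention $+\pi \mapsto -\pi$ is applied
  consistently to distances and sampled preferred directions, making
  $[-\pi, \pi)$ the canonical interval.

## Known limitations

* The generalization function and the decay function produced by the
  effort-primitive model necessarily share their Gaussian width, because
  both are images of the same recruitment overlap $\hat G$. Behavioral
  reports find the decay function wider than the generalization function;
  reproducing that would require extensions (multi-rate memories, or
  error-dependent recruitment) that are outside this package's scope.
* The weight-decay model's decay function is flat only up to a small
  first-cycle transient (relative size about $10^{-8}$ under the default
  parameters, as computed in the test suite): the first cycle enters its
  test block from the end of training, later cycles from a 100-trial
  relearning block that re-converges to the fixed point geometrically but
  not exactly. This is a property of the finite protocol, not of the
  forgetting rule — cycles 2 onward agree to machine precision.

## A minimal session

```{r example, eval = FALSE}
library(motorprim)

# context-dependent decay: retest level rises with test-direction distance
traces <- lapply(c(0, pi / 12, pi / 6, pi / 4), function(tt)
  run_simulation("effort_primitive", protocol = build_simulation1(tt),
                 basis_seed = 1))
retest_divergence(traces)

# ensemble generalization and decay functions for the alternating design
ens <- run_ensemble("effort_primitive",
                    protocol_builder = function(s) build_simulation2(16, seed = s),
                    n_runs = 20, base_seed = 1)
head(generalization_function(ens))
head(decay_function(ens))
```
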