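# motorprim

Trial-by-trial simulation of motor adaptation with Gaussian motor
primitives, for computational studies of **context-dependent motor memory
decay**.

## The problem

During force-field or visuomotor-rotation adaptation, a compensatory motor
command x is learned trial by trial to cancel a perturbation p (movement
error e = p − x), and is simultaneously forgotten. Error-clamp trials —
trials in which e is forced to 0 — isolate the forgetting process, and
behavioral experiments show it is *context dependent*: memory trained at
target direction θ = 0 erodes faster during clamp trials at θ = 0 than
during clamp trials at distant directions. Classical models cannot produce
this. `motorprim` implements the three candidate models and the error-clamp
protocols that discriminate them, for researchers modeling trial-by-trial
adaptation data.

## The models

A population of N primitives with preferred directions φᵢ ~ U[−π, π) and
Gaussian tuning Aᵢ(θ) = exp(−‖θ − φᵢ‖²/2σ²) generates the command
x(θ) = Σᵢ Wᵢ Aᵢ(θ). Gradient descent on
Eₜ = ½eₜ² + (λ₁/2)ΣᵢWᵢₜ² + (λ₂/2)xₜ² gives the master update

    W[i,t+1] = (1 − η λ₁) W[i,t] + (η/N) (eₜ − λ₂ xₜ(θₜ)) Aᵢ(θₜ)

* **λ₂ = 0, weight decay** (`weight_decay_primitive`): forgetting shrinks
  every weight identically — context-*independent* decay, with
  generalization.
* **λ₁ = 0, effort minimization** (`effort_primitive`): forgetting is
  weighted by the recruitment overlap Ĝ(θₜ, θ) = Σᵢ Aᵢ(θₜ)Aᵢ(θ)/N —
  context-*dependent* decay, with generalization.
* **State space with effort** (`state_space_effort`):
  xₜ₊₁ = (1 − ηλ₂)xₜ + ηeₜ on a single scalar memory — context-independent
  decay, no generalization.

Every weight-space simulation is cross-checked against an independent
command-space recursion built on the generalization function, and training
asymptotes against the analytic fixed points x\* = p/(1 + λ₂) (effort
models) and x\* = pĜ/(λ₁ + Ĝ) (weight decay).

## Worked example

Train at θ = 0, impose 100 error-clamp trials at a test direction, then 50
clamp trials back at θ = 0, and compare the surviving memory across test
directions:

```r
library(motorprim)
traces <- lapply(c(0, pi/12, pi/6, pi/4), function(tt)
  run_simulation("effort_primitive", protocol = build_simulation1(tt),
                 basis_seed = 1))
retest_divergence(traces)
#>   theta_test  retest_x
#> 1  0.0000000 0.3566459
#> 2  0.2617994 0.3976448
#> 3  0.5235988 0.4637389
#> 4  0.7853982 0.5355934
```

The retest command (memory at the trained direction, in units of the
perturbation — here newtons of lateral force) *increases* with the test
direction's distance: testing at π/4 spared the memory (0.54) that testing
at the trained direction eroded (0.36). That is context-dependent decay;
running the same protocol with `"weight_decay_primitive"` gives four
identical retest values.

The alternating 16-direction design quantifies the decay profile
(normalized by the end-of-training command x₀, mean ± SD over 20 runs):

```r
ens <- run_ensemble("effort_primitive",
                    protocol_builder = function(s) build_simulation2(16, seed = s),
                    n_runs = 20, base_seed = 1)
d <- decay_function(ens)
head(d[order(abs(d$direction)), ], 5)
#>    direction  mean      sd
#> 9      0.000 0.924 0.00554
#> 8     -0.393 0.933 0.00759
#> 10     0.393 0.932 0.00579
#> 7     -0.785 0.954 0.00796
#> 11     0.785 0.954 0.00771
```

The decay function has its minimum at the trained direction (92.4% of the
memory retained after a test block at θ′ = 0, rising monotonically toward
100% at distant directions), while `generalization_function(ens)` returns
the matching Gaussian-shaped transfer profile.

A thin command-line wrapper drives the same machinery:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","simulate.R",package="motorprim"))')" \
  --model effort-primitive --sim 2 --runs 20 --seed 7 --out-dir out/
```

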