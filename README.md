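# kinpipe

Pipelines for repeated kinetic-model simulation and parameter estimation,
with sampled profile-likelihood analysis of the resulting fit sequences.

## The problem

Calibrating a kinetic model of a biological network against data is
unreliable when done once: optimisers stall in local minima, and — more
insidiously — parameters can be *practically non-identifiable*: the data
simply do not constrain them, however good the optimiser. Both problems
become visible only when the estimation is **repeated** many times and the
whole batch is analysed. Likewise, a single stochastic simulation of a
reaction network says little; an ensemble of repeats, summarised properly,
does. kinpipe automates exactly these repeat-and-analyse workflows for
modellers in systems biology.

## What it computes

For a mass-action reaction network with rate constants *k*, kinpipe provides:

- **Simulation** — deterministic time courses (stiff-capable ODE
  integration via `deSolve`, with a compiled right-hand side), exact
  stochastic trajectories (Gillespie SSA, bit-reproducible per seed), or
  any external program speaking a simple TSV report-file protocol. For
  linear networks an exact matrix-exponential solution is available as an
  independent oracle.
- **Repeated estimation** — N independent particle swarm optimisations of a
  weighted sum-of-squares objective
  SSE(k) = Σᵢ wᵢ (yᵢ − ŷᵢ(k))², each repeat seeded deterministically from a
  master seed, with **every** objective evaluation recorded.
- **Sampled profile likelihood (PLE)** — for each parameter the recorded
  evaluations are projected onto (value, objective) pairs; the confidence
  interval at level α is the min/max of values with objective ≤ best +
  χ²₁(α) (Δ(0.95) ≈ 3.84, Δ(0.99) ≈ 6.63). An interval that runs into a
  search bound flags the parameter *practically non-identifiable* on that
  side. Parameter correlations are computed over the best fits and over all
  sub-threshold samples.
- **Ensemble statistics** — per time point: mean, sample SD and t-based 95%
  confidence interval of the mean across stochastic repeats.
- **Parameter scans** — one- and two-parameter sweeps (linear, log10 or
  percent-of-reference scales), with envelopes and per-time-point matrices.
- **Pipelines and reports** — the four workflows (`simulate`,
  `single_param_scan`, `double_param_scan`, `param_estim`) run as
  YAML-configured pipelines chaining data generation → analysis → LaTeX and
  Markdown report generation, each task toggleable, with local
  multiprocessing and a manifest that makes every run reproducible.

## Worked example

The bundled fixture is a minimal insulin receptor model: insulin-driven
phosphorylation of IRβ on Y1164 (`k1`), inactivation into a refractory
state (`k2`), recovery (`k3`).

```r
library(kinpipe)
m <- ir_receptor_model()
m
#> Mass-action reaction model: 4 species, 3 reactions, 3 parameters
#>   IR_beta + insulin -> IR_beta_pY1164 : k1 = 0.5
#>   IR_beta_pY1164 -> IR_beta_refrac : k2 = 1
#>   IR_beta_refrac -> IR_beta : k3 = 0.1
#>   fixed inputs: insulin
#>   readouts: IR_beta, IR_beta_pY1164, IR_beta_refrac

round(as.data.frame(simulate_ode(m, seq(0, 10, by = 2))), 3)
#>   Time IR_beta IR_beta_pY1164 IR_beta_refrac
#> 1    0  16.000          0.000          0.000
#> 2    2   6.276          3.801          5.923
#> 3    4   3.419          2.298         10.283
#> 4    6   2.685          1.548         11.767
#> 5    8   2.511          1.313         12.176
#> 6   10   2.472          1.250         12.278
```

Phosphorylation peaks within the first two minutes, then the receptor pool
drains into the refractory state (total is conserved at 16). Now calibrate
the three rate constants from noise-free synthetic data on the
phosphorylated readout, with 10 independent swarm repeats:

```r
data <- make_dataset(m, c(k1 = 0.5, k2 = 1, k3 = 0.1),
                     calibration_times("sufficient"),
                     noise_sd = 0, readouts = "IR_beta_pY1164")
space <- param_space(c("k1", "k2", "k3"), rep(1e-3, 3), rep(100, 3))
fits <- run_repeats(make_objective(m, space, data), space,
                    pso_settings(), n_repeats = 10, master_seed = 1)
coef(fits)
#>         k1         k2         k3
#> 0.49999234 1.00000388 0.09999847

summary(sampled_ple(fits, space))
#> Sampled profile likelihood: 3 parameters, best objective 7.40978e-09
#>  parameter level threshold   lower    upper n_qualifying                   flag
#>         k1  0.66    0.9104 0.34330   0.8065         7766           identifiable
#>         k1  0.95    3.8410 0.22650   1.6570         9435           identifiable
#>         k1  0.99    6.6350 0.16670 100.0000        10170 non_identifiable_right
#>         k2  0.66    0.9104 0.71240   1.4860         7766           identifiable
#>         k2  0.95    3.8410 0.51100   2.2520         9435           identifiable
#>         k2  0.99    6.6350 0.44730   3.0810        10170           identifiable
#>         k3  0.66    0.9104 0.05528   0.1774         7766           identifiable
#>         k3  0.95    3.8410 0.02694   0.3448         9435           identifiable
#>         k3  0.99    6.6350 0.01385   0.5207        10170           identifiable
#> All parameters identifiable within the search bounds.
```

The generating values (0.5, 1.0, 0.1) are recovered to five decimal places,
and every 95% interval sits comfortably inside the search box, so all three
parameters are flagged identifiable. (The stray 99% endpoint for `k1`
illustrates the nature of *sampled* profile likelihood: a single
sub-optimal evaluation near the bound fell under the generous 99% cut; the
95% flags are the ones used for classification.) Re-running with
`calibration_times("insufficient")` — measurements at 0 and 1 minute only —
drives the intervals of `k1` and `k3` into the search bound and flags them
non-identifiable, the signature that the data, not the optimiser, are the
problem.

The same analysis runs as a configured pipeline from the shell:

```sh
inst/cli/kinpipe param-estim estim.yaml          # generate + analyse + report
inst/cli/kinpipe param-estim estim.yaml --only-analysis
```

with commented example configurations for all four pipelines under
`inst/extdata/configs/`.

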