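---
title: "Models, statistics and design choices in kinpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, statistics and design choices in kinpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinpipe)
```

kinpipe automates the repetitive tasks of kinetic model building — repeated
simulation and repeated parameter estimation — and extracts robustness
information from the resulting repeat sequences. This vignette explains the
underlying models and statistics, the tunable parameters that matter, and the
design choices made where the design was genuinely open.

## The kinetic model class

kinpipe's native model class is the mass-action reaction network: species
with non-negative amounts, reactions given as reactant/product multisets,
and one positive rate constant per reaction. The propensity of a reaction is
its rate constant times the product of the current reactant amounts, one
factor per multiset entry. This literal product form is used identically by
the deterministic and the stochastic engine, so that for linear networks the
stochastic mean provably solves the rate equations — the property several
tests rely on. (For reactions consuming two copies of the same species the
combinatorial convention `x(x-1)` would differ; the bundled model has no
such reaction, and models that need other rate laws can be attached through
the external-wrapper protocol instead.)

Species can be flagged *fixed*: their amount never changes and they enter
propensities as constants. This is how a clamped extracellular input such as
insulin is represented.

### The insulin receptor fixture

The worked example throughout the package is a minimal three-state model of
insulin receptor beta activation: in the presence of insulin the receptor is
phosphorylated on Y1164 (`k1`); the phosphorylated receptor is inactivated
into a refractory state (`k2`) that lumps internalisation, degradation and
synthesis into a single delay; from there it becomes functional again
(`k3`). The cyclic stoichiometry conserves total receptor.

The default values — `k1 = 0.5` per minute per unit insulin, `k2 = 1.0` and
`k3 = 0.1` per minute, 16 receptors, insulin clamped at 1 — are package
choices, selected once for a plausible minutes-scale response (fast
phosphorylation peaking inside the first five minutes, slow recovery); they
are not literature-fitted estimates, and outputs computed from them should
not be read as reproducing any published parameterisation.

Because insulin is fixed, the model is linear in the free species, and the
exact solution is available by matrix exponential of the (affine-augmented)
rate matrix. `linear_solution()` computes this with `Matrix::expm` and
serves as the independent oracle against which both numerical engines are
validated. The ODE engine is required to agree with it to 1e-6 maximum
relative error over the full 0–45 minute horizon.

## Simulators

All engines return the same `time_course` container and are described by a
common `simulator_spec`, so pipelines are agnostic to the engine.

**Deterministic (ODE).** `deSolve::lsoda` with the mass-action right-hand
side compiled in C. Defaults `rtol = 1e-8`, `atol = 1e-10` are deliberately
tight because kinetic models are routinely stiff; `lsoda` switches to an
implicit method automatically. Integration always starts at t = 0 (where
initial amounts are defined) even when the requested grid starts later.

**Stochastic (exact SSA).** The direct Gillespie method: the network is a
continuous-time Markov jump process, exponential waiting times with total
propensity rate, jump chosen proportionally to individual propensities. The
piecewise-constant path is sampled onto the requested grid by giving each
grid time the state immediately preceding it (at a grid time that coincides
with a jump, the pre-jump state). This right-continuous convention is a
package decision and is stated here because it affects reproducibility of
sampled values. Trajectories are bit-reproducible from their seed, and
amounts stay integers with exact conservation.

**External programs.** A command template with a `{report}` placeholder
(and optionally `{seed}`) is run through the shell; the external program is
responsible for writing the report file, which kinpipe parses back. This is
the portability escape hatch: any language, any rate law, as long as it can
write a TSV.

**Report files** are the interchange format everywhere: tab-separated,
header row starting with `Time`, one column per variable, values emitted
with 17 significant digits so a write/read round trip reproduces the
doubles. Columns are matched by header name, never by position.

## Estimation: weighted SSE and particle swarm

The objective is the weighted sum of squared residuals between the dataset
and a deterministic simulation at the trial parameters, evaluated at the
union of the dataset's time points. Weights default to 1; an optional
measurement standard deviation divides the residuals, which puts the
objective on the −2 log-likelihood scale (up to a constant) for Gaussian
errors. The chi-square confidence thresholds below assume that scale; with
unnormalised residuals the thresholds are in squared measurement units and
the intervals should be read comparatively rather than as calibrated
probability statements. A trial point whose simulation fails yields a large
finite penalty (1e100) with a warning instead of an error, so the swarm
routes around pathological regions rather than aborting a repeat.

The optimiser is a global-best particle swarm with constriction-style
constants — inertia 0.729, cognitive = social = 1.494 — a standard,
well-studied configuration adopted because no canonical constants attach to
this use; positions are initialised uniformly in the search box, velocities
are clamped to half the box width, and positions leaving the box are clamped
to the bounds before evaluation (which is what ultimately places sampled
points *at* the bounds, the signature of practical non-identifiability
below). Rate constants are searched on a log10 scale by default, the natural
frame when plausible values span orders of magnitude.

Crucially, *every* evaluated position is recorded — `swarm_size ×
(iterations + 1)` records per repeat, the initial swarm included. The
sub-optimal evaluations are not waste: they are the sample of parameter
space from which the profile likelihood is estimated. Recording every
evaluation (rather than only per-iteration bests) is a deliberate superset
choice; it can only densify the sample.

Repeated estimations derive each repeat's seed from a stated integer hash of
(master seed, repeat index), so the assembled fit sequence is identical
whatever the worker count or completion order; records are keyed and sorted
by (repeat, evaluation index). Worker invariance is asserted byte-for-byte
on the analysis outputs.

## Sampled profile likelihood and identifiability

For each estimated parameter, all recorded evaluations are projected onto
(parameter value, objective) pairs. The confidence region at level α is the
set of values whose objective lies within Δ(α) of the global best, and the
reported interval is the min and max of that set — no interpolation and no
re-optimisation (re-optimisation-based profile likelihood is a different,
deliberately out-of-scope method). The threshold is the chi-square quantile

Δ(α) = χ²₍df₎(α),

with df = 1 by default (pointwise intervals); df can be set to the number of
estimated parameters for simultaneous regions. Δ(0.95) ≈ 3.8415 and
Δ(0.99) ≈ 6.6349; the implementation is validated against the closed form
χ²₁(α) = Φ⁻¹((1+α)/2)², and the default level set is {0.66, 0.95, 0.99}.

A parameter is flagged *practically non-identifiable* on a side when its
interval endpoint reaches the search bound there, compared on the search
scale with a tolerance of 1e-3 of the box width. The per-parameter flag
reported is the one at the 95% level. The quality of sampled intervals
depends on how densely the swarm happened to sample near the threshold;
the quadratic-bowl fixture (below) quantifies this, and intervals from
sparse sequences should be read as lower bounds on the true profile
intervals.

Parameter correlations are Pearson, computed on the search scale, twice:
over the per-repeat best fits and over all evaluations below the 95%
threshold. A parameter constant across records has undefined correlations,
reported as `NA` rather than 0.

Ensemble summaries report, per variable and time point, the across-member
mean, sample SD (n−1 denominator) and the t-based confidence interval of
the mean, mean ± t₍1−(1−α)/2, n−1₎ · SD/√n.

## Scans

Single-parameter scans simulate once per value; values are generated with
equal spacing on a linear or log10 axis, or as *percent of a reference*,
which is how "differential scales" for simulated knockdown or
overexpression are expressed (e.g. 0–200% of an estimated level). Endpoints
are inclusive; duplicates are removed with a warning. A failed value is
recorded as missing and the scan continues; the input model is never
mutated. Double scans run the full Cartesian grid — both rate constants and
species initial amounts are scannable, since "levels" of an input or a
receptor can mean either — and extract per-time-point matrices at the
requested report times. Every grid cell is required to equal an independent
single simulation at that pair to 1e-12.

## Pipelines, tasks and reproducibility

Each of the four pipelines (`simulate`, `single_param_scan`,
`double_param_scan`, `param_estim`) runs three sequential tasks: data
generation, data analysis, report generation, each of which can be toggled
off in the YAML configuration. Analysis always consumes report files from
disk, never in-memory state, so generation can be disabled and an existing
run re-analysed under different settings (e.g. a different confidence
level) without re-simulation. A `manifest.json` at the output root records
the configuration snapshot, derived seeds, tool version, layout version and
any failed repeats; it suffices to regenerate the raw data bit-identically,
and analysis refuses output trees with a mismatched layout version.
Deterministic simulate runs collapse `runs > 1` to a single simulation with
a notice, since identical repeats carry no information. A failing repeat
never aborts a batch; it is recorded in the manifest and excluded.

Unknown configuration keys are rejected by name; cluster submission keys
are rejected explicitly (`cluster: local` only — parallelism is local
forked multiprocessing).

The report task renders LaTeX and Markdown sources. The report layer never
recomputes a number: table cells are carried verbatim from the analysis
TSVs, and compiling LaTeX to PDF is left to the user's TeX installation so
that the pipeline itself stays hermetic. Every figure is emitted alongside a
machine-readable TSV twin, and all automated checks assert on the TSVs.

## Synthetic data: what it emulates and what it does not

`make_dataset()` simulates the model at known true parameters, adds i.i.d.
Gaussian noise clipped at zero (amounts are non-negative), and writes the
experiment TSV the estimation pipeline consumes. Gaussian noise with
clipping is a package choice for a generic measurement-error model.

Two named scenarios drive the identifiability demonstrations:
`"sufficient"` measures at 11 points spanning 0–45 minutes, covering both
the fast phosphorylation transient and the slow refractory recovery;
`"insufficient"` keeps only t = 0 and t = 1 minute, before the refractory
state accumulates. With the sufficient design all three rate constants are
recovered (within 1% relative, noise-free, 50 repeats) and flagged
identifiable; with the insufficient design the interval of at least one
parameter runs into the upper search bound and is flagged non-identifiable
to the right. These scenarios are qualitative designs chosen to produce the
two regimes; they are not a reconstruction of any published dataset.

What passing these tests shows is that the machinery — simulators,
optimiser, sampled intervals, flags — behaves correctly on a small linear
model under idealised noise. Real calibration problems are nonlinear,
stiffer, noisier and non-Gaussian; results there inherit all the usual
caveats of SSE objectives and swarm optimisers, and the sampled intervals
remain approximations from whatever sample the optimiser produced.

`make_fit_sequence()` generates records whose objective is an exact
quadratic bowl; the sampled 95% interval then has the closed-form half-width
√(Δ(0.95)/curvature), which the implementation must reproduce within 2%
under dense sampling. This is the analytic calibration check for the whole
PLE pathway.

## Problem sizes and numerical choices

The package's own validation experiments use: 181-point grids for the
ODE/oracle comparison; 500 seeds for the SSA mean check (3 standard-error
band); 40-member ensembles for coverage (≥90% of time points); 50
estimation repeats with a 20-particle, 80-iteration swarm for the recovery
and identifiability experiments; 15 000 bowl records for the closed-form
interval check; and 5×5 grids for scan consistency. Repeat counts are
scaled-down versions of the thousand-repeat studies the pipeline is built
for; they were chosen once as the smallest sizes at which the statistical
assertions are stable.

Other numerical choices: objective penalty 1e100 on simulation failure;
identifiability tolerance 1e-3 of the search-box width; PSO velocity clamp
at half the box width; per-repeat seeds from a fixed 32-bit integer hash;
ties in the best-record selection broken by first occurrence; scan
duplicates deduplicated with a warning; report numbers written with 17
significant digits.

## Known limitations

- Mass-action kinetics only in the native engines; other rate laws require
  the external-wrapper route.
- The stochastic engine is exact SSA: no tau-leaping, no delays, no
  mid-run events, so very large copy numbers are slow.
- Sampled profile likelihood can only be as good as the optimiser's sample;
  it never re-optimises, so under-sampled regions shrink intervals.
- Chi-square thresholds are calibrated only when residuals are
  variance-normalised; otherwise intervals are comparative.
- Parallelism is local (forked processes); no cluster submission.
- LaTeX reports are source-only; compilation is the user's responsibility.
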