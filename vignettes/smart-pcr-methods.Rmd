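---
title: "Scoring, simulating and steering PCR: the models behind smartpcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, simulating and steering PCR: the models behind smartpcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartpcr)
library(dplyr)
```

## What problem this package addresses

Forensic STR profiling runs every sample through a fixed, manufacturer-
validated PCR program, even though samples differ enormously in template
amount, degradation and inhibition. A "smart" thermocycler would instead
watch the reaction in real time (via qPCR fluorescence), score what the
cycling conditions are producing, and adapt the next cycle's parameters —
or stop early when the outcome is already decided. `smartpcr` implements
the computational layer of such a system: the profile quality metric, the
amplification-curve model, the cycling-program algebra, two open-loop
optimizers, a closed-loop controller, and a synthetic PCR simulator that
stands in for the instrument so the whole stack is testable on a desk.

## The profile quality metric

A single-source profile $P$ with called peak heights $x_1, \dots, x_n$ is
scored

$$
f_P \;=\; K_0\!\left[\log_{10} p(\bar{x} \mid \mu_a, \sigma_a) - C_h\right]
      + K_1\!\left[\log_{10} p(cv \mid \lambda) - C_c\right]
      + K_2\, n_a + K_3\, t ,
$$

where $\bar{x}$ is the mean of the observed peaks,
$p(\cdot \mid \mu_a,\sigma_a)$ is a Normal density centred on the ideal
mean height, $cv$ is the coefficient of variation of the expected-length
height vector (missing alleles entered as 0), $p(\cdot\mid\lambda)$ is an
exponential density, $n_a$ the number of flagged artefact peaks (or their
summed RFU, by option), and $t$ the total denature + anneal cycling time in
minutes. $K_0, K_1 \ge 0$ and $K_2, K_3 \le 0$, so every component is
nonpositive: 0 is the ideal response and more negative is worse.

Two deliberate choices:

* **Per-component offsets.** Each log-density term is offset by its own
  maximum ($C_h = \log_{10} p(\mu_a \mid \mu_a, \sigma_a)$,
  $C_c = \log_{10}\lambda$). With $K_0 = K_1 = 1$ the offsets sum to the
  familiar single constant $C$, but keeping them separate guarantees every
  component stays $\le 0$ under arbitrary weights.
* **Two height views.** $\bar{x}$ averages only the peaks that were
  actually observed (dropout should not drag the height component down
  twice), whereas the COV vector carries an explicit 0 for every missing
  expected allele, so dropout, within-locus and between-locus imbalance all
  inflate $cv$.

The closed forms are simple — the height component equals
$-(\bar{x}-\mu_a)^2/(2\sigma_a^2)\log_{10}e$, the balance component
$-\lambda\, cv \log_{10} e$ — and the tests verify the implementation
against them to $10^{-12}$.

The constants are not canonical: they must be balanced per profiling kit.
Defaults are $\mu_a = 5000$ RFU (high enough to clear dropout territory,
below pull-up/saturation), $\sigma_a = 1000$ RFU, $\lambda = 2$,
$K_0 = K_1 = 1$, $K_2 = -1$ per artefact peak, $K_3 = -0.05$ per minute.
All are `score_params()` arguments.

### The power-0.8 COV adjustment

In real profiles the COV is anti-correlated with mean height: weak profiles
are relatively noisier. If that correlation distorts the metric, the mean
in the denominator can be raised to the power 0.8
(`score_params(cov_power = 0.8)`), which empirically flattens the trend.
The property suite reproduces this on simulated data: across a 5–500 pg
template sweep, the Spearman correlation between COV and mean height is
strongly negative at power 1 and materially smaller in magnitude at
power 0.8.

### Allele calling

Calling uses the standard two-threshold rule: every peak must reach the
heterozygous threshold (default 50 RFU), and a locus left with exactly one
surviving peak is treated as a homozygous candidate and held to the
homozygous threshold (default 150 RFU). Threshold comparison is inclusive
(a peak at exactly the threshold survives) — the usual analytic-threshold
convention; nothing in the procedure depends delicately on the boundary.
The "exactly one surviving peak" reading of homozygosity is one consistent
interpretation; real heterozygote dropout is indistinguishable from
homozygosity at calling time, which is precisely why the higher threshold
exists. A profile is *informative* when it shows at least 12 of the donor's
expected alleles (the national-database upload rule). Stutter is not
flagged as artefact — it occurs under every program — and off-reference
peaks only enter the metric when explicitly flagged.

## The amplification-curve model

Baseline-subtracted qPCR curves are fitted with

$$ y = A\,\frac{1 + \tanh\!\big(B\,(x - C)\big)}{2}, $$

with $A$ the plateau amplitude, $B$ the gradient and $C$ the midpoint; $x$
may be cycle index or elapsed minutes (a fit on one axis maps to the other
by a linear rescale of $B$ and $C$, which the tests assert). The baseline
is the median of the first 16 cycles by default. Fitting is unweighted
least squares via Levenberg–Marquardt with data-derived starting values
($A$ from the maximum, $C$ from the half-max crossing, $B$ from the
10–90% rise width); non-convergence is reported honestly in the
`converged` flag, never silently. Curves that never plateau are fitted
unconstrained — the flag, not a parameter bound, carries the warning. The
threshold cycle (`ct_cycle()`, default threshold 500 RFU) interpolates
linearly between the bracketing readings; the convention is arbitrary at
the sub-cycle level and documented rather than load-bearing.

## Cycling programs and the duration term

A program is initial holds, cycled stages (each an ordered step list times
a cycle count) and final holds. A step may carry an additive per-cycle ramp
(e.g. anneal/extend 60 s + 1.56 s per cycle); the ramp applies **from cycle
2**, reading the printed base duration as the cycle-1 value. The alternative
reading (increment from cycle 1) is a one-line config change. The duration
term $t$ sums only denature and anneal/extend step durations — holds and
temperature transitions are excluded. The packaged YAML fixtures reproduce
the standard and ramped 30-cycle endpoint programs, their 16-cycle
qPCR-primed variants, and the five-member qPCR series with 10/30/50/70/90 s
annealing in the final 24 cycles:

```{r}
tibble(name = list_program_fixtures()) |>
  rowwise() |>
  mutate(minutes = cycling_time_minutes(load_program_fixture(name)))
```

## The simulator

No public mechanistic model links cycling parameters to STR peak heights,
so the generator is phenomenological, shaped by the qualitative behaviours
reported for real reactions and calibrated once against the published
summary numbers. It is the package's test bed, not a claim about PCR
biophysics.

* **Efficiency.** Per-cycle efficiency is unimodal in annealing time,
  $E = e_{\max}\,(t/t_{opt})\,e^{1 - t/t_{opt}}\cdot
  e^{-(T - T_{opt})^2/2w^2}$, peaking at $t_{opt} = 70$ s: longer annealing
  helps up to a point and over-long steps are detrimental.
* **Fluorescence.** Logistic growth
  $F_{c+1} = F_c\,(1 + E_c\,(1 - F_c/K_c))\,\varepsilon_c$ with lognormal
  noise $\varepsilon_c$ and an efficiency-dependent carrying capacity
  $K_c = f_{sat}(0.4 + 0.6\,E_c/e_{\max})$, so a 10 s anneal plateaus near
  3000 RFU while 70 s approaches 5500 RFU — roughly the reported span —
  while early-cycle kinetics (and hence the threshold cycle) change little.
* **Peak heights.** Mean height couples the program's deterministic plateau
  share with a saturating response to template,
  $H = h_{cap} \cdot (F_\infty/f_{sat}) \cdot T/(T + T_{1/2})$, attenuated
  exponentially with fragment size (degradation) and perturbed by lognormal
  noise whose log-sd scales as $\text{copies}^{-0.2}$. That exponent makes
  the linear height spread grow like $\text{mean}^{0.8}$ — exactly the
  structure that motivates the power-0.8 COV adjustment, so the adjustment
  demonstrably decorrelates on simulated data. Heights below 30 RFU drop
  out (a hard floor, chosen over a binomial branch for testability).
* **Calibration** (chosen once, before the test suite was finalised, and
  not revisited): $h_{cap} = 46{,}000$ RFU and $T_{1/2} = 2000$ pg put a
  30 pg input under the standard program at a mean height of ~660 RFU with
  COV ≈ 0.9, matching the reported trace-DNA regime; `height_noise_sd = 1`
  sets that COV scale; `f0_per_pg = 2·10⁻⁵` puts detection of strong
  templates around cycle 16–22.

What the simulator does **not** emulate: stutter, pull-up, inhibition,
mixtures, degradation curves beyond a single exponential, or any
quantitative fluorescence-to-RFU transfer function. Passing tests show the
framework's logic is correct under a plausible data-generating process;
they do not validate the metric's constants against casework data.

## Open-loop optimizers

The swarm treats each candidate cycling-parameter set as a particle in a
bounds-normalised unit box (seconds and degrees become commensurable).
After evaluation, particle $i$ moves

$$ u_i \leftarrow u_i + \eta\,(T_i - u_i) + \text{jitter}, \qquad
   T_i = \frac{\sum_{j \ne i} a_{ij} u_j}{\sum_{j \ne i} a_{ij}}, \qquad
   a_{ij} = \frac{w(f_j)}{\max(d_{ij}, 10^{-6})}, $$

attraction proportional to fitness and inversely proportional to distance,
scaled by a learning rate $\eta < 1$ (rates $\ge 1$ are unstable, which the
pair-method test demonstrates). Two design points where the generic recipe
is underdetermined:

* **Fitness weighting.** Quality scores are $\le 0$ and their absolute
  differences shrink to zero as the swarm contracts, so a fixed transform
  like $e^{f/\tau}$ loses all selection pressure exactly when precision
  matters. The weights are therefore range-normalised over the current
  swarm, $w(f) = \exp\big(\beta\,(f - f_{\max})/(f_{\max} - f_{\min})\big)$
  with $\beta = 10$: still a positive, monotone transform of fitness, but
  scale-free.
* **Exploration.** A pure attraction collapse converges to a consensus
  point that is near, but biased away from, the optimum. Each move
  therefore adds a uniform jitter of amplitude `explore_alpha` (0.2,
  decaying by 0.95 per iteration) drawn from the seeded RNG — the classic
  firefly random-walk term; runs remain bit-reproducible under a seed.
  With 12 particles, $\eta = 0.1$ and 60 iterations the swarm lands within
  0.05 of the optimum of a concave 2-D objective in ≥ 90% of seeds.

Particles use their latest fitness for attraction; the best-ever
(position, fitness) is tracked separately and is non-decreasing. Failed
objective evaluations keep the particle's previous fitness and are logged
in the trace.

The gradient-pair method is the low-budget alternative: from the better of
two points, step $\eta\,(x_{hi} - x_{lo})$ away from the worse one; on
improvement drop the worst of the trio, otherwise halve the rate and flip
direction.

## Closed-loop control

Instruments typically cannot edit a running program, so the controller runs
an initial uninterrupted block (default 16 cycles — below the detection
limit nothing can be learned anyway) and then short one- or two-cycle
segments. After each segment it fetches the amplification data, estimates
the per-cycle rate of increase (least-squares slope over the last 3
readings; the window is configurable because no canonical choice exists),
and checks three mutually exclusive termination rules in fixed precedence:

1. **sufficient** — fluorescence exceeds the ceiling; the product is ready,
   and stopping avoids saturated, artefact-prone profiles;
2. **undetectable** — still below the detection threshold at the detection
   deadline;
3. **low rate** — detected but stalled.

If it continues, the nearest-condition policy consults the rule bank of
open-loop experience: distance between conditions is measured on
log₁₀ fluorescence (amplification spans orders of magnitude; sub-RFU
values are floored to one point), ties retain all equidistant entries, and
the entry with the highest recorded metric-increase rate wins, with entry
order as the final deterministic tie-break. Policy outputs are clipped to
declared parameter bounds — the controller never issues out-of-range
parameters. Conditions are keyed on concentration only; the cycle index is
stored for future extension. The per-cycle log records parameters,
fluorescence and decision; a device fault aborts with the partial record
preserved. With termination disabled and a fixed policy the loop reproduces
the open-loop simulated curve bit-for-bit under the same seed, which pins
down the controller's bookkeeping.

## Numerical conventions and degenerate inputs

* Population (divide-by-N) standard deviation in the COV, matching the
  statistic's printed definition; `peak_cov()` on an all-zero vector is a
  domain error (undefined), not a silent 0.
* Threshold comparisons are inclusive; allele calling is idempotent.
* `fit_tanh()` never throws on hard data: flat curves return $A = 0$,
  `converged = FALSE`.
* Coincident swarm particles are handled by a $10^{-6}$ distance floor;
  degenerate bounds pin a coordinate.
* All stochastic components (simulator, swarm, device stream) are
  reproducible under a fixed seed; the simulated device keeps a private
  RNG stream so interleaved host code cannot perturb a run.

## Problem sizes in the test suite

The suite exercises the stack at desk scale: 100-seed batches for the
noisy-fit and swarm-convergence checks, 200 simulated profiles for the
COV-decorrelation sweep, 30–40 cycle simulations elsewhere. These sizes
give stable pass/fail behaviour for the stochastic properties while the
full suite runs in about a minute.

## Known limitations

* The score constants are placeholders until calibrated on real casework
  profiles; the published per-protocol totals cannot be reproduced because
  the constants behind them are not public.
* The simulator's fluorescence-to-peak-height coupling is a modelling
  convenience, not a measured relationship.
* The closed-loop backend contract is exercised only against the simulator;
  a hardware adapter (HTTP instrument API) must implement the same five
  operations but is out of scope here.
* Single-source profiles only: no mixtures, no stutter-ratio modelling, no
  likelihood-ratio computation.
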