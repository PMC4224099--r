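---
title: "One-shot association learning with bootstrap-percolation retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-shot association learning with bootstrap-percolation retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(percmem)
```

## The model

`percmem` simulates hetero-associative memory — learning *relations*
between concepts rather than the concepts themselves — in a sparse,
brain-scale setting. Two populations $\mathcal{A}$ and $\mathcal{B}$ of
$N$ neurons each (default $N = 5000$, the scale of a cortical column's
input layer) are joined by directed *afferent* edges, each present
independently with probability $\rho_{aff}$; $\mathcal{B}$ additionally
carries directed *recurrent* edges with presence probability $\rho_{rec}$
and no self-loops. Every edge is binary — weak or strong — and only strong
edges count: a neuron fires as soon as at least $K$ active neurons project
to it through strong edges, and once fired it stays active (first-spike
semantics; we ignore all later spikes, so retrieval is a single fast sweep
of activity rather than a rate-based settling process).

Concepts are size-$n$ patterns. The patterns of $\mathcal{B}$ are treated
as pre-learned: when $B_i$ is stored, every present recurrent edge inside
it is clipped strong (a sparsely connected Willshaw network). Associations
$(A_i, B_i)$ arrive once each, and learning is one-shot and stochastic:

* **insert** — each present weak afferent edge from $A_i$ into $B_i$
  turns strong with probability $p^+$;
* **prune** — each present strong afferent edge into $B_i$ from outside
  $A_i$ turns weak with probability $p^-$.

Choosing
$p^- = \frac{1-r_{aff}}{r_{aff}}\cdot\frac{n}{N-n}\cdot p^+$
([derive_prune_probability()]) balances the expected gains and losses, so
the expected strong in-degree of every neuron is invariant: the memory is
a *palimpsest*, old associations fade gradually as new ones are written
over them, and the probability that a noise edge (into
$\mathcal{B}\setminus B_0$) is strong stays pinned at its initial value
$r_{aff}$ forever. The signal probability decays geometrically,
$$p_{signal}(i) = r_{aff} + \beta^i (1-r_{aff})p^+,
  \qquad \beta = 1 - (n/N)^2\, p^+/r_{aff},$$
so the retrievability margin $\Delta(i) = p_{signal}(i) - r_{aff}$ shrinks
by a factor $\beta$ per competing insertion.

Recall activates a query in $\mathcal{A}$ (sources are clamped; there is
no propagation on the source side) and lets activity percolate through
$\mathcal{B}$: neurons with afferent strong degree $\ge K$ fire first and
then recruit further pattern neurons through the clipped recurrent edges —
bootstrap percolation on a random graph. An association is *memorized* if
at least $\lceil \alpha_{fid} n\rceil$ neurons of $B_0$ end up active
(fidelity) and at most $\lfloor \alpha_{spc} n\rfloor$ outside it
(specificity). The capacity $M$ is the number of competing associations
after which the first association stops being memorized.

## Why percolation buys capacity

Without recurrent edges the afferent drive alone must push almost the
whole signal degree distribution above $K$ while keeping the noise
distribution below it — at $N = 5000$ and realistic densities the two
binomials barely separate and capacity is small. Iterative retrieval only
requires the afferent drive to ignite a small bootstrap; percolation then
completes the pattern. The package exposes both views:

* `k_bounds()` — the admissible window for $K$ from Gaussian tail bounds
  on the noise (specificity) and signal (fidelity) degree distributions;
* `janson_percolates()` / `percolation_threshold()` — the expectation
  ("Janson") condition
  $n\Pr[\mathrm{Bin}(n,\rho_{aff}p) + \mathrm{Bin}(t,\rho_{rec})\ge K] > t$
  for all exposure times $t \le \lceil\alpha_{fid}n\rceil$, solved for the
  threshold signal density by bisection (tolerance $10^{-4}$), with the
  exact convolution tail or a normal substitute;
* `predicted_capacity()` — $M = \lfloor\log(\Delta(0)/\Delta)/\log(1/\beta)\rfloor$;
* `optimal_plasticity()` — $p^{+*} = e\Delta/(1-r_{aff})$ and the maximal
  capacity $N^2 r_{aff}(1-r_{aff})/(n^2 e \Delta)$.

```{r theory}
p <- model_params(N = 5000, n = 140, rho_aff = 0.2, r_aff = 0.1,
                  rec_degree = 8, p_plus = 0.6, K = 12,
                  alpha_fid = 0.8, alpha_spc = 1.0)
thr <- percolation_threshold(p, "binomial")
beta <- decay_factor_beta(p)
c(threshold = thr,
  M_pred = predicted_capacity((1 - p$r_aff) * p$p_plus,
                              thr - p$r_aff, beta))
```

## Parameters that matter

| parameter | meaning | default / reference value | why |
|---|---|---|---|
| $N$ | population size | 5000 | input layer of a cortical column |
| $n$ | pattern size | 140 (100 in the noise studies) | capacity scales as $N^2/n^2$ but $n$ must exceed the viability floor |
| $\rho_{aff}$ | afferent density | 0.2 | inter-areal connectivity is sparse |
| $r_{aff}$ | baseline strong fraction | 0.1 | small $r_{aff}$ gives broad, stable capacity plateaus |
| $\rho_{rec} n$ | expected in-pattern recurrent degree | 8 | enough for percolation at modest $K$ |
| $p^+$ | insertion probability | 0.6 | past the threshold where percolation ignites; near-optimal |
| $K$ | activation threshold | 12 | inside the `k_bounds()` window for these densities |
| $\alpha_{fid}, \alpha_{spc}$ | fidelity / specificity fractions | 0.8, 1.0 | recall quality criterion |

Figure-caption conventions are interpreted as follows: a "recurrent degree
$d$" fixes $\rho_{rec} = d/n$ (pass `rec_degree` to `model_params()`), so
the expected strong in-degree within a pattern stays at $d$ when $n$ is
swept; passing `rho_rec` directly gives the fixed-density alternative.

## Design choices in genuinely open spots

* **Directed recurrent graph.** The connectivity is described as a
  directed graph, so recurrent edges are sampled independently per ordered
  pair and "degree" means expected strong *in*-degree within a pattern.
  Self-loops are excluded: a neuron's own spike must not count toward its
  threshold.
* **Storage timing.** Each $B_i$ is clipped into the recurrent network at
  its presentation (so recurrent-noise percolation depends on how many
  patterns are stored so far); `prestore = TRUE` stores all patterns first
  — the afferent learning is identical in both modes.
* **Rounding.** "At least $\alpha_{fid}n$" uses a ceiling, "at most
  $\alpha_{spc}n$" a floor, both guarded by a $10^{-9}$ fuzz term against
  IEEE artifacts ($0.8\times140$ is $112+6\cdot10^{-15}$ in doubles). The
  noisy-query overlap $\lambda n$ uses `round()`. These are conventions of
  this implementation, not derived facts.
* **Specificity after percolation.** Spill-over through previously stored
  patterns counts against specificity, which is what makes recurrent-noise
  interference visible.
* **Logarithms and tails.** All logs are natural; normal tail substitutes
  use no continuity correction. In the full-fidelity tail bounds the
  per-vertex failure budget is $1-\alpha_{fid}$ (with $\alpha_{fid}=1-1/n$
  this makes the fidelity log-argument $n/\sqrt{2\pi\sigma_{fid}^2}$,
  consistent with the percolation-bound variant, which differs only in the
  sign of the fidelity term). Fixed points of the implicit bounds are
  solved by bisection to $10^{-6}$; regimes where a log argument drops
  below 1 or the margin would exceed 1 raise an invalid-regime error
  rather than returning extrapolated numbers.
* **Randomness.** Every experiment driver takes one master seed and
  derives an independent per-trial seed stream (`sample.int` under the
  master seed), so trials are reproducible in isolation and results are
  identical whether trials run sequentially or concurrently.

## What the simulation machinery does

The synaptic state is a hand-indexed sparse structure (present edges in
compressed sparse-column form by target, mirrored by source, with 0/1
strengths on the present entries) held in an environment. This gives the
three hot operations — per-column stochastic flips during learning,
strong-degree gathers during retrieval, and within-pattern clipping — at
cost proportional to the edges touched, with reference semantics so a
5-million-edge afferent state is never copied. Presence is sampled exactly
from the product-Bernoulli law (binomial total, uniform placement).

`measure_capacity()` probes recall of association 0 after *every*
insertion (network evolution is path-dependent, so no bisection over the
insertion count is possible) and reports the last competing-insertion
count at which it was memorized, plus the empirical signal density at the
failing probe — the density at which percolation-based recall transitions
from success to failure. `run_sweep()`, `track_association_zero()` and
`noise_tolerance_experiment()` wrap this into the standard experiment
protocols; `capacity_prediction_comparison()` quantifies, per population
size, how far the independence assumption, the expectation assumption and
the normal approximation each move the predicted capacity from the
simulated one (the three error sources, nested by construction).

```{r capacity, eval = FALSE}
# ~10 s per trial at N = 5000; the acceptance script averages 20 trials
set.seed(42)
measure_capacity(p, M_max = 500, reliability_probes = FALSE)$capacity
```

## What the synthetic generator does and does not emulate

All inputs are generated internally: Erdős–Rényi connectivity at the
stated densities, uniformly random patterns, independent per-edge
plasticity events. This matches the model under study exactly, so passing
tests certify the implementation and the theory's internal consistency at
the stated parameter values. They do **not** certify biological realism:
real cortical connectivity is distance-dependent and clustered rather than
Erdős–Rényi, real synapses may have more than two states, inhibition and
timing are absent, and pattern statistics in the brain are not uniform
subsets. Known limitations of the theory itself are visible in the
validation module: at finite $N$ the learning process induces correlations
between edge states (a target vertex that joins a competing pattern has
all its strong in-edges exposed to pruning at once), so the idealized
threshold estimators sit a few percent below the in-system transition
density and the expectation-based capacity predictions overshoot the
simulation — the nested error decomposition makes each contribution
measurable.

## Problem sizes used by the shipped tests

The unit tests exercise a small system ($N = 1000$, $n = 50$, $K = 5$,
recurrent degree 5, capacity $\approx 25$) chosen to keep every stochastic
check well-powered; the reproduction checks and the acceptance script run
the reference system ($N = 5000$) with 20 trials for the capacity and
noise-tolerance studies, 100 instances for the empirical percolation
threshold, and 4 trials per population size on $N \in \{1250, 2500,
5000\}$ for the quadratic-growth check. These sizes are the package's own
defaults for desk-scale reproduction; the larger trial counts behind the
original figures (100–500 trials) are plain arguments to the same
functions.
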