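---
title: "Modelling period-3 dominant masting synchrony"
author: "mastSync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling period-3 dominant masting synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mastSync)
```

## The problem

Many perennial trees do not fruit steadily: a population produces a heavy
seed crop in one year (an *on-year*) and little or nothing in between, with
the whole stand fluctuating in step. Crop species such as citrus and
pistachio alternate on a strict two-year cycle ("alternate bearing",
period-2), while oak-type masting is usually irregular or intermittent. A
third pattern — a dominant three-year ON → OFF → OFF cycle, observed for
example in urban populations of *Zelkova serrata* — is dynamically the most
interesting, because in one-dimensional maps the presence of a period-3
orbit implies the coexistence of all other periods and of chaos. This
package provides (i) a mechanistic population model able to produce all
three patterns, (ii) the statistics needed to quantify which pattern a
given ensemble of annual production records contains, and (iii) a
bifurcation toolkit that explains where the period-3 regime comes from.

## The resource budget model and its coupling

Each tree carries a resource reserve $S^i(t)$. In a year it gains a surplus
$P_S$; if the accumulated reserve stays at or below a threshold $L_T$
nothing happens, otherwise the excess is spent on flowering:

$$C_f^i = \max\!\big(0,\; S^i + P_S^i - L_T\big),$$

and, scaled by the availability of outcross pollen, on pollination and
fruiting, $C_a^i = R_C\, C_f^i\, Y^i$, where the *cost ratio* $R_C \ge 0$
is the key physiological parameter. The reserve update is

$$S^i(t+1) = S^i(t) + P_S^i(t) - C_f^i(t) - C_a^i(t).$$

Pollen availability couples the trees globally. For the focal tree it is a
power of the mean flowering effort of all *other* trees,

$$Y^i(t) = \Big[\tfrac{1}{(N-1)P_0}\sum_{j \ne i} C_f^j(t)\Big]^{\beta},$$

with coupling strength $\beta \ge 0$; $\beta = 0$ switches coupling off. A
tree that flowers alone therefore sets no seed ($Y = 0$): flowering effort
is wasted without neighbours to outcross with, which is the synchronising
force. Observable seed production is $C_S^i = C_f^i Y^i$; ordinal survey
classes are treated as proportional to it.

Environmental variability enters through the annual surplus,

$$P_S^i(t) = P_0\,\{1 + e_C\,\sigma(t)\}\,\{1 + e_I\,\delta^i(t)\},$$

with standard-normal draws: one common $\sigma(t)$ per year (a
Moran-effect channel, amplitude $e_C$) and one individual $\delta^i(t)$
per tree and year (amplitude $e_I$). `simulateGCM()` integrates the
ensemble; `stepCoupled()` exposes a single year with injectable draws.

### Parameters and defaults

| parameter | meaning | default | units |
|---|---|---|---|
| `P0` | intrinsic annual surplus | 10 | resource units |
| `LT` | flowering threshold | 100 | resource units |
| `RC` | cost ratio $C_a/C_f$ | 2 | — |
| `beta` | pollen-coupling exponent | 6 | — |
| `eI`, `eC` | individual / common noise amplitude | 0 | — |
| `N` | population size | 106 | trees |
| `Ttransient` | discarded burn-in | 1000 | years |
| `Trecord` | recorded window | 15 | years |

The defaults reproduce the conditions of a 15-year, ~100-tree census:
`RC = 2, beta = 6, eI = 0.2, eC = 0` is the regime in which the model
shows period-3 dominant, imperfect synchrony. Initial reserves are drawn
uniformly on $[0, L_T]$ (one draw per tree); the generator fill order
(per year: common draw, then individual draws in tree order) is part of
the reproducibility contract. $P_S$ is not clamped — a deep negative
noise draw may withdraw resource — and reserves may go negative after a
heavy crop; only $C_f$ is floored at zero.

## The reduced map and the origin of period-3

A fully synchronised population obeys the one-dimensional map

$$f(S) = \begin{cases} S + P_0, & S + P_0 \le L_T \\
L_T - R_C\,(S + P_0 - L_T)^{\beta+1}/P_0^{\beta}, & S + P_0 > L_T,
\end{cases}$$

implemented in `reducedMap()`. It is piecewise smooth and piecewise
monotonic with a kink at the border $S_b = L_T - P_0$: the left derivative
is always 1, the right derivative is $-R_C$ for $\beta = 0$ but exactly 0
for any $\beta > 0$ (`borderDerivatives()`). Flattening the map at the
kink is what converts the uncoupled tent-like map (whose fixed point loses
stability at $R_C = 1$, `criticalCostRatio()`) into a border-collision
system with a period-adding staircase: at integer $R_C = Q$ the attractor
has period $Q + 1$.

```{r window}
edge <- periodWindowEdge(Q = 3, beta = 6, RCrange = c(1.55, 2.0),
                         resolution = 1e-4)
edge$RC
edge$attractor
```

The period-3 window opens through a tangent (saddle-node) bifurcation of
the third iterate. Just below the opening the graph of $f^3$ approaches
the diagonal without touching it at three points, found by
`findTangencyPoints()` as local minimisers of $|f^3(S) - S|$ with
bracketed refinement; true transversal crossings (genuine periodic
points, e.g. the unstable fixed point) are tagged separately. Because the
smallest two tangency points sit on the accumulation branch, the middle
point always equals the smallest plus $P_0$ — a useful internal
consistency check on any reported triple.

### Numerical conventions

* **Window edges** are reported as the first point of an ascending
  $R_C$ grid (step $10^{-4}$) whose post-transient orbit has the target
  period; each grid point uses a 20 000-step transient (the escape from
  the intermittent ghost channel just past a tangency is slow) and a
  64-point record with `detectPeriod()` at absolute tolerance $10^{-6}$.
* **Noisy runs are never period-classified**: strict period detection is
  meaningless under noise, so the composition statistics below are used
  instead.
* **Exact even-integer cost ratios are degenerate for the uncoupled
  map.** At $R_C = 2, 4$ (and partially at other integers) the border
  cycle is exactly representable in double precision and the expanding
  crash branch erodes mantissa bits until every orbit is absorbed by it —
  in perfect unison across trees. Infinite-precision dynamics stay
  chaotic there. Scans of the uncoupled model therefore sample $R_C$
  continuously (seeded uniform draws over the stated range) rather than
  on an integer-aligned grid.
* **Border derivatives** use one-sided differences with a power-of-two
  step ($2^{-10}$), keeping the difference quotient on the linear branch
  exact.

## Phase analysis

`hilbertPhase()` removes each tree's temporal mean and forms the discrete
analytic signal over the full recorded window by the one-sided FFT
spectrum — no padding, detrending or tapering, matching the convention of
the common MATLAB/SciPy `hilbert` routines. For a dominant period-3 cycle
the wrapped phase steps through the three *fundamental phases* 0 (on-year),
$2\pi/3$ (first off-year) and $-2\pi/3$ (second off-year). Edge effects of
the short (15-year) window are accepted as part of the method; a constant
series carries no phase and is flagged invalid rather than silently
assigned one.

Two on-year definitions are provided and agree exactly on model output
(`flagAgreement()` = 1 across the default $\beta \times R_C$ grid, which
the test suite asserts): production strictly above the tree's temporal
mean (`onFlagsAmplitude()`), or phase strictly inside $(-\pi/2, \pi/2)$
(`onFlagsPhase()`). Boundary cases resolve to *off* in both rules. The
representative population phase is the per-year ordinary median of the
wrapped phases (documented as non-circular; adequate while phases cluster
away from the $\pm\pi$ seam), and `orderParameter()` gives the Kuramoto
mean-phasor length $r$ per year.

## Composition and synchrony statistics

The fraction of period-$Q$, `fractionPeriod()`, counts motifs of one
on-year, $Q-1$ off-years, then an on-year at lag $Q$, over
$t = 1..T-Q$, scaled by $Q/\big((T-1) - (T-1) \bmod Q\big)$ so a perfect
period-$Q$ train scores 1, and clipped to $[0,1]$. The off-year
requirement spans all intermediate lags $1..Q-1$; a permissive variant
(`strict = TRUE`) that leaves the first lag unconstrained is retained for
comparison because the formula is sometimes written that way, but the
full-lag version is the one matching the verbal definition and is the
default everywhere. `periodFractions()` pools per-tree values over the
population (mean by default; median and mode available).

The in-phase fraction pairs trees by the sign product of their
year-on-year production changes, $\varnothing(i,j,t) =
\Delta x_i(t)\,\Delta x_j(t)$: a pair is in phase when the product is
positive, or when *both* changes are exactly zero (two silent trees move
together); exactly one zero change counts as out of phase.
`inPhaseFraction()` accumulates this by sign counts — algebraically
identical to the literal $O(N^2 T)$ double sum, which the tests verify —
and averages over pairs and then years into $F_{IN}$.

Noise-free behaviour brackets the statistic: with $\beta = 6$ every run
synchronises perfectly ($F_{IN} = 1$ across the scanned $R_C$ range),
while uncoupled ensembles from random initial reserves stay at or below
$F_{IN} \approx 0.5$. `classifyState()` turns $(F_{IN}, FP)$ into the
three regimes of the noisy model: desynchronised (I), period-2 dominant
synchrony (II), period-3-or-longer synchrony (III). The synchrony
threshold defaults to $F_{IN} \ge 0.9$; the regime boundary is sharp, so
the exact value is uncritical, and it is configurable.

## The working regime, and a caveat on its statistics

```{r fig8, warning = FALSE}
res <- runPipeline(modelParams(RC = 2, beta = 6, eI = 0.2, N = 106,
                               seed = 6), figures = FALSE)
res$fp
res$sync
```

At `RC = 2` the noise-free attractor is the 3-cycle $\{80, 90, 100\}$,
which touches the flowering border exactly — `RC = 2` is the upper edge
of the period-3 window. Individual noise of amplitude 0.2 therefore does
not merely jitter the cycle: it intermittently kicks the population into
period-2 episodes and back. Single 15-year realisations consequently
scatter widely in their composition (seed-to-seed quartiles of $FP(3)$
span roughly 0.2–0.7), and seed-averaged values (computed by
`scripts/acceptance.R`) settle near $FP(3) \approx 0.46$ and
$FP(2) \approx 0.25$ with about 68% of quantized production in the two
lowest of ten classes. Individual favourable realisations reach
$FP(3) \approx 0.73$ and $FP(2) \approx 0.26$; when comparing against
single published runs of this regime, the wide realisation-to-realisation
dispersion — not measurement error — is the dominant uncertainty.

## The synthetic survey generator

Real ordinal census tables of this kind are rarely deposited, so
`generateSurvey()` produces survey-like fixtures with controlled
statistical structure: an ON-OFF-OFF template with per-tree phase jitter
(probability 0.1 of running a year early or late), per-cycle period-2
slips (0.08), per-tree fruiting failure in an on-year (0.12), ten ordinal
classes with off-years and failed on-years confined to the two lowest
classes (giving ≈70% of all scores there), and a forced desynchronised
year. Year quality is shared: each year has one on-class and one
off-class value, so a configuration with all stochastic ingredients
disabled yields literally identical trees — the property the template
tests rely on.

Two design points deserve emphasis. First, the desynchronised year
scrambles each tree's cycle offset over a ±2-year window, not a single
year: the instantaneous phase of a 15-year record at one year is anchored
by its neighbourhood, and scrambling an isolated year barely moves the
phases. For the same reason the default desync year sits mid-series
(year 8) — at the record boundary the phase is dominated by the interior
and cannot be forced incoherent. Second, the generator is a test fixture,
not a fitted generative model: it reproduces timing structure,
class-histogram mass and coherence patterns, but not within-year
production scatter between trees in the same cycle position, tree-size
effects, or any biology of the modelled species. Passing tests on it
therefore demonstrate that the analysis stack measures what it claims to
measure, not that real survey data will take particular values.

## Problem sizes

The test suite and the acceptance script favour many small, seeded runs:
ensembles of 20–106 trees, 15 recorded years after a 1000-step transient,
40 seeds for seed-averaged statistics, 10–13 sampled cost ratios for
noise-free synchrony scans, a 40 × 40 × {0, 0.2} grid for the
flag-agreement property, and full-resolution ($10^{-4}$) window-edge
scans. These sizes were chosen to keep every quantity's sampling error
well inside its assertion band.

## Known limitations

* Coupling is global (all-to-all); no spatial or graph-structured pollen
  exchange, so nothing can be said about distance-dependent synchrony.
* The Hilbert phase on 15-year windows carries edge distortion; the
  package deliberately mirrors the standard convention instead of
  windowing it away.
* The population phase uses the ordinary median of wrapped values, which
  misbehaves if phases straddle $\pm\pi$; this does not occur for
  period-3-dominated records but would for period-2-dominated ones.
* Ordinal survey classes are treated as magnitudes. The phase, flag and
  $F_{IN}$ statistics are invariant to monotone rescaling, so only the
  class *ordering* matters, but quantitative amplitude comparisons
  between class data and simulated $C_S$ are meaningless.
* `detectPeriod()` classifies noise-free orbits only; there is no
  Lyapunov-exponent machinery, so "aperiodic" means "no period up to
  `qMax` at the stated tolerance", not a proof of chaos.
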