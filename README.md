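# mastSync

Simulation and analysis of **masting synchrony** — the population-wide,
intermittent fluctuation of annual seed production in trees — with a focus
on the *period-3 dominant* regime (one heavy crop followed by two lean
years, stand-wide), as opposed to classical period-2 alternate bearing or
irregular oak-type masting. The package is aimed at theoretical ecologists
and forest scientists who want to (a) quantify the periodic composition
and phase coherence of an ensemble of annual production records, and (b)
explain those patterns with a mechanistic coupled-map model.

## The model and the statistics

Each tree follows a **resource budget model**: reserves $S^i$ grow by an
annual surplus $P_S$ until they exceed a threshold $L_T$; the excess is
spent on flowering ($C_f^i = S^i + P_S^i - L_T$) and, scaled by the cost
ratio $R_C$ and by outcross-pollen availability, on fruiting
($C_a^i = R_C C_f^i Y^i$). Pollen availability

$$Y^i = \Big[\tfrac{1}{(N-1)P_0}\textstyle\sum_{j\ne i} C_f^j\Big]^\beta$$

couples the $N$ trees globally with strength $\beta$; observable seed
production is $C_S^i = C_f^i Y^i$. Noise enters the surplus as
$P_S^i = P_0(1 + e_C\sigma)(1 + e_I\delta^i)$ with a common (Moran) and an
individual channel. The synchronised population reduces to a piecewise
smooth 1-D map whose border-collision, period-adding structure — and the
tangent bifurcation that opens its period-3 window at $R_C = 1.6172$ for
$\beta = 6$ — is what produces three-year masting.

On the analysis side the package computes Hilbert-transform instantaneous
phases, amplitude- and phase-based on-year flags, the fraction of
period-$Q$ motifs $FP(Q)$ per tree and population, the pairwise in-phase
fraction $F_{IN}$, Kuramoto order parameters, density bifurcation
diagrams, two-parameter $\beta \times R_C$ sweeps with regime labels, and
a synthetic ordinal-survey generator for testing against census-style
data.

## Worked example

Simulate the noisy period-3 regime and run the full analysis pipeline:

```r
library(mastSync)
p <- modelParams(RC = 2, beta = 6, eI = 0.2, N = 106, seed = 6)
res <- runPipeline(p, figures = FALSE)
res$fp
#> PeriodFractions (mean over 106 trees):
#>  FP(2)  FP(3)  FP(4)  FP(5)  FP(6)
#> 0.2790 0.4929 0.2107 0.0142 0.0000
res$sync
#> SyncFractions: F_IN = 0.9733 over 14 year transitions
```

This realisation is period-3 dominant ($FP(3) = 0.49$ against
$FP(2) = 0.28$) and strongly synchronised ($F_{IN} = 0.97$); per-year
order parameters are in `res$orderParameter`. Because the working regime
sits at the upper edge of the period-3 window, single 15-year records
scatter widely between period-3- and period-2-dominated compositions —
see the vignette for why seed-averaged values matter here.

The bifurcation toolkit reproduces the deterministic anchors directly:

```r
periodWindowEdge(Q = 3, beta = 6, RCrange = c(1.55, 2), resolution = 1e-4)$RC
#> [1] 1.6172
findTangencyPoints(RC = 1.6171, beta = 6, n = 3)
#>          S     gap crossing
#> 1 84.47994 0.00047    FALSE
#> 2 94.47994 0.00047    FALSE
#> 3 97.60995 0.00000     TRUE    # unstable fixed point
#> 4 99.94148 0.00004    FALSE
```

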