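# firewoodSpread

Invasive wood-boring insects — emerald ash borer, Asian longhorned beetle —
jump between distant forests mainly because people carry untreated firewood,
most visibly campers travelling from population centres to recreational
destinations. `firewoodSpread` is an R package for managers and modellers
who want to compare, on a camper travel network, the three standard levers
against that pathway: **public outreach** (raising the net social cost `U`
of transporting firewood), **checkpoint interception** (stopping a fraction
`Ce` of infested wood on every route), and **patch quarantine**
(closing a set `V` of high-centrality sites for a time window).

## The model

The landscape is `N` patches linked by a column-stochastic trip-fraction
matrix `P` (`P[i, j]` = fraction of annual trips from patch `j` ending at
patch `i`). Each patch carries susceptible trees `S`, infested trees `I`,
infested firewood `B`, the local-strategist fraction `L`, and a
cumulative-damage tracker `T`:

    dS_i/dt = r S_i (1 - (S_i + I_i)/K) - A S_i (I_i + B_i) θ_k(I_i - I_a)
    dI_i/dt = -γ I_i + A S_i (I_i + B_i) θ_k(I_i - I_a)
              - d Σ_{j≠i} P_ji (1 - C_e)(1 - L_i) I_i
    dB_i/dt = -γ B_i + d Σ_{j≠i} P_ij (1 - C_e)(1 - L_j) I_j
    dL_i/dt = σ L_i (1 - L_i) (U + s(2L_i - 1) + f I_i)
    dT_i/dt = A S_i (I_i + B_i) θ_k(I_i - I_a)

with `θ_k(x) = 1/(1 + e^{-kx})`. Trees grow logistically to carrying
capacity `K`; infested trees and firewood decay at rate `γ`; wood leaving a
patch arrives elsewhere as `B` (total import = total export, a conservation
law the tests assert). The replicator equation for `L` models social
learning between the "buy locally" and "transport" strategies. Quarantine
multiplies every transport term with a quarantined endpoint by an
upside-down boxcar gate, zero on `[t0, t0 + Δt]`; quarantine sets are ranked
by shortest-path betweenness centrality under the edge distance
`max(P) + 1 - P_ij`. Because real reservation-derived networks are
proprietary, a gravity-model generator (`generateSyntheticNetwork()`)
emulates their shape: heavy-tailed populations, one dominant focal hub, and
per-origin route thinning that mirrors the minimum-degree core of real
data. See the vignette (`vignettes/firewood-pest-model.Rmd`) for
assumptions, parameter meanings, and known limitations.

## Worked example

```r
library(firewoodSpread)

net <- generateSyntheticNetwork(100, seed = 7)
net
#> TravelNetwork with 100 patches, 1446 directed edges
#>   focal node: n082
#>   column-stochastic trip fractions; max off-diagonal P = 0.9949

sc   <- calibratedScenario(nNodes = 100, seed = 7)   # focal patch seeded
traj <- runScenario(sc)
networkAverages(traj)[c(1, 51, 101, 151, 201), ]
#>  time        S       I     B     L        T
#>     0 4950.000  50.000 0.000 0.500   50.000
#>     5 4560.458  78.105 0.280 0.553  440.473
#>    10 2419.740 544.203 1.913 0.820 2586.812
#>    15   83.354  42.102 0.042 1.000 4934.993
#>    20   88.198   0.058 0.000 1.000 4938.440
```

The uncontrolled invasion peaks near year 10 and kills ~98% of the tree
population by year 15 (`S` falls from 4950 to 83 trees per patch); the
damage tracker `T` saturates once the outbreak burns out, and the
local-strategist fraction `L` rises to 1 as infestation makes transporting
firewood socially costly.

```r
quarantineNodeSelection(net, 3)        # top-betweenness quarantine picks
#> [1] "n082" "n016" "n081"             # the focal hub ranks first

halvingInterceptionFraction(calibratedScenario(nNodes = 100, seed = 7,
                                               tEnd = 6), tBar = 5)$Ce
#> [1] 0.6992188
```

On this 100-patch network, checkpoints must intercept ~70% of infested
firewood to halve 5-year cumulative infestation — interception has to be
strong to matter. Sweep surfaces over `(U, Ce)`, `(A, d)` or quarantine
`(|V|, Δt)` come from `parameterSweep2d()` and `quarantineSweep()`;
`marginalBenefitSlope()` fits the first-order effect of outreach on damage.
A thin CLI over the same functions lives in `inst/scripts/firewood-sim.R`.

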