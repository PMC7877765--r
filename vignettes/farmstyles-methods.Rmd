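---
title: "The farmstyles model: structure, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The farmstyles model: structure, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

farmstyles simulates a hypothetical rural community of 250 four-person
producer-consumer households on a 21x21 grid of 1-ha arable plots over 50
annual time steps. All households start as subsistence ("orphan") farmers:
manual tools, very limited purchased inputs, one worker producing on average
1000 kg of cereal equivalents per hectare-year. Of this, 700 kg feeds the
family and roughly 108 kg (an extra 2900 kcal per 150 ten-hour working days,
at 4015 kcal/kg) feeds the worker's labour. Each household holds a fixed
preference for how it would develop: by a peasant route (agroecology —
labour- and knowledge-intensive, credit-avoiding, autonomy-seeking) or an
entrepreneurial route (purchased inputs, wage labour, credit, maximizing
return on investment). This vignette explains the model a maintainer needs
to understand: the annual cycle, the economic logic of each style, the
climate and price processes, the numerical choices, and the places where the
design was genuinely open and a choice had to be made.

## The annual cycle

Each year, in order: (1) climate advances (warming, drought risk, drought
events); (2) the exogenous global price moves; (3) input prices and credit
terms are re-derived from food prices; (4) orphan households decide whether
to begin converting to their preferred style; (5) entrepreneurial households
check solvency (debt service plus half a basic diet); (6) developed farms
expand (land, working animals, tractors), visited in a random order so land
contention has no fixed bias; (7) every household forms a price expectation
and chooses a production target; (8) cash-infeasible peasant plans are
rationed; (9) production is realized under warming, drought and +/-15%
noise; (10) asking prices are formed and the local price set; (11) accounts
settle, with distress sales and abandonment; (12) optimized peasant farms
gain their slow yield increments; (13) agroecology transitions progress; and
(14) outcomes are recorded.

## Landscape and styles

Plots carry a base maximum yield, Uniform(800, 1200) kg/yr, and an
agroecology multiple, Normal(4, 1.5) truncated by rejection to [2, 7].
Agroecology transition takes three years per plot, with productivity
interpolating linearly from the base to the full multiple; all plot yields
cap at 10 t/ha. Entrepreneurial farming instead reaches up to 10x the base
yield through fertilizer (up to 500 kg/ha, priced at 10x the food price).
Peasant plots that were farmed at their unconstrained optimum gain slow
productivity increments (orphan 1%/yr, agroecology 1.5%/yr; 1.5%/3% under
the peasant policy). A farm counts as optimized only if it planned without
rationing *and* realized its target up to the ordinary +/-15% variation:
a drought or warming shortfall therefore interrupts the fine-tuning gains,
which is one of the channels through which climate change suppresses
long-run development.

Working animals let one worker farm 5 ha, a small tractor 16 ha. Peasant
farms are restricted to two family workers (so 10 ha with two animal teams
is their ceiling); entrepreneurial farms hire manual labour freely, so land
is their binding constraint. Agroecology doubles labour-diet and
necessary-input intensity per hectare but not area capacity — this is how a
10-ha agroecology farm remains manageable by family labour, which the model
takes as a fixed point.

## Production decisions

Producing an output fraction $q$ of the farm's attainable maximum requires
the input fraction $x = q^2$ on each variable channel (labour effort and its
diet, necessary inputs, fertilizer) — the simplest convex schedule with the
right endpoints for "diminishing returns". Targets are chosen on the grid
$q \in \{0, 0.01, \dots, 1\}$; because the objectives are concave parabolas
in $q$, the grid argmax coincides with the closed-form vertex to grid
resolution, which the test suite uses as an independent oracle.

Expected climate losses enter the revenue side of planning: the current
warming loss rate times warming, plus the drought risk times the scenario's
mean loss (with the agroecology reductions). Farmers therefore scale back
targets as the climate deteriorates, and realized yields are additionally
hit by the actual drought and warming factors.

**Peasants** maximize returns to labour: expected revenue minus cash costs,
with labour time not costed (the labour diet, in kind, is). If the optimum
would not raise net income per hectare above last year's (the autonomy
goal), they escalate $q$ until it does or $q = 1$. Cash-infeasible plans are
rationed according to the household's preference: "nutrition" households cut
$q$ first; "production" households tolerate a diet down to the 50% floor.

**Entrepreneurs** maximize return on investment
$(qAp - C(q))/C(q)$ where the stake $C$ counts all variable inputs, labour
at the wage (family included), debt service, and the family's basic diet
(the household's fixed reproduction cost — without a fixed term the ROI
objective degenerates to $q \to 0$). If the income at that optimum misses
the expansion goal (10% of asset value), they escalate; if the goal is out
of reach they produce at the largest scale with non-negative expected profit.
This expansion-driven behaviour is what lets entrepreneurial communities
produce near potential while margins — and eventually incomes — are
squeezed between falling food prices and drifting input costs.

## Prices

The global price is exogenous: its trend declines by a random annual rate
(Normal with mean equal to the scenario rate — 1.5, 1.25, 1.0 %/yr for no,
low, high climate change — and equal SD, truncated to [-2, +4] times the
rate, so rises occur), an additive sinusoid of amplitude 1.5 cents and
period 10 years is superimposed, and a global drought multiplies the price
by a scenario-dependent bump. The local price is the marketed-quantity
weighted average of household asking prices, adjusted by the transmission
elasticity times the global price's percent change (a +5% global change at
transmission 0.5 raises the local price by exactly 2.5%).

Asking behaviour was the least determined part of the design and the place
where dynamic stability forced choices. Every price-linked cost (wage 180%
of a basic diet at the 5-year mean price, necessary inputs 15% of a wage/ha,
fertilizer 10x the food price, land 30 t of cereal, assets 30/150 years of
orphan net income) makes the nominal system almost homogeneous of degree
one, so any systematic bias in asks compounds without bound. Asks therefore
follow a damped expectation anchor (current price plus half the recent
trend) with style-specific deviations: entrepreneurs undersell the anchor by
2% (expansion and market share), and hold a floor of 1.2x unit cash cost (a
return-on-investment margin); established peasant farms hold a cash-cost
recovery floor on their marketed surplus (autonomy: the next cycle must be
financeable without credit). Households with no marketed surplus contribute
no ask. Income-target floors and fully extrapolative asks were both tried
and discarded as dynamically unstable; the ledger of this repository's
development records the alternatives.

## Money, food and distress

Settlement values everything at the realized local price. Committed
necessary inputs claim harvest revenue before family consumption; the family
then eats from what remains (buying food with cash if production fell
short), and a household whose diet falls below 50% of basic sells assets
(animals, tractor, then land — always keeping the home plot) and abandons
the farm if that fails. Entrepreneurs bridge fertilizer bills with
short-term credit, then sell assets, then ration the diet to the floor;
unpayable debts mean abandonment. Abandoned land is deactivated — taken out
of production permanently — while distress-sold land returns to the market.
Net income throughout is income after production costs *and* after feeding
the family and its workers; at 40 c/kg the average orphan farm nets about
$76/yr before necessary inputs, which is also the base of the working-animal
and tractor price formulas.

Orphan necessary inputs deserve a note: they are set to half the
developed-farm rate. Zero makes the average orphan accumulate so fast that
every household develops within a decade; the full rate leaves the average
orphan with nothing and no one develops. The half rate reproduces the
reference dynamics — median conversion around year 15 and a fifth of
households still blocked in orphan farming at year 50 — and is the
package's reading of "very limited input use".

## Scenarios, experiments and sizes

Policy scenarios follow the reference settings: entrepreneurial (25% prefer
agroecology, transmission 0.75, 50% fertilizer subsidy, interest halved),
entrepreneurial-eroding (support returning linearly to baseline over 50
years), peasant (75%, 0.25, faster yield increments), none (50%, 0.5).
Climate scenarios set total warming (0, 1, 2 degC over 50 years), the drought
risk multiplier (1, 1.5, 2 at year 50, linear from 5%/yr), community drought
losses (mean 7.5/10/15%, max 20/25/30%, drawn Uniform(0, 2 x mean) truncated
at the max, with farm-level Uniform(0.75, 1.25) noise and a 20% agroecology
reduction), and the global price behaviour above. Sensitivity mode fixes the
agroecology potential at a chosen ratio of the entrepreneurial 10x-base
potential, disables agroecology increments, and can set the agroecology
climate sensitivity to 0.9, 1.0 or 1.1 of the entrepreneurial rates.

Reference experiments use 250 replicates per cell
(`run_batch(cfg, 250, seed)`), which `scripts/acceptance.R` reproduces. The
test suite runs the same experiments at 40 replicates per cell — chosen so
the whole suite completes in minutes while across-run means are stable to a
few percent — and states its tolerances accordingly.

## What the generator does and does not emulate

The synthetic world reproduces the study conditions: the plot and household
distributions, the price-linked input economy, and the scenario grid. It
does not represent family demography, land fragmentation, migration,
between-developed-style conversions, soil degradation, or any demand side —
all food offered at the formed price is sold. Passing tests therefore say
nothing about those processes, nor about any real community: the model is a
stylized instrument for comparing farming-style futures under controlled
conditions.

## Numerical and degenerate-case choices

Truncated normals are sampled by rejection (exact at this scale). Ties in
land choice break to the lowest (row, col). A year with zero total marketed
production carries the previous local price forward. Prices floor at 1
cent/kg. Loan books amortize as level annuities (mid-term assets use a
5-year term, the midpoint of the 3-6 year range; eroding-policy rates apply
to new loans only — existing loans keep their contracted rate). Single-run
RNG: one seeded stream per run, with all per-household draws made as
fixed-length vectors (inactive households included) so that the draw
sequence cannot desynchronize across scenarios with different survival
histories.

## Known limitations

Climate-change production losses under the subsidized entrepreneurial
policy are smaller here than in the reference experiments: rising-price
climates make lagged input prices (the 5-year mean) relatively cheap, which
props up entrepreneurial break-even production. The sensitivity gap at the
1:4 yield ratio is likewise compressed. Both are documented as open
calibration gaps rather than hidden: the acceptance suite states the
reference values and lets the corresponding checks fail where the model
disagrees.
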