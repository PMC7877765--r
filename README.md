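# farmstyles

An agent-based simulation of smallholder *farming styles* and their
consequences for hunger and rural health under climate change.

Global climate–nutrition models treat farmers as homogeneous producers and
people as homogeneous consumers. farmstyles takes the opposite standpoint:
it simulates a hypothetical rural community of 250 producer-consumer
households on a 21×21 grid of 1-ha plots, in which subsistence ("orphan")
farmers may develop along two qualitatively different routes:

- **peasant / agroecology** — labour- and knowledge-intensive, credit-avoiding,
  autonomy-seeking; a 3-year transition raises a plot's potential by a
  plot-specific multiple (mean 4, truncated Normal on [2, 7]), with slow
  further gains from fine-tuning;
- **entrepreneurial** — dependent on purchased inputs (fertilizer up to 10×
  the base yield), wage labour and credit, maximizing return on investment
  and expansion.

Scenarios vary the style-preference mix, the global-to-local price
transmission elasticity, agricultural policy (entrepreneurial / eroding /
peasant / none) and climate change (no / low / high: up to 2 °C warming over
50 years, drought risk doubling, 4%/°C yield loss, reduced by 10–20% under
agroecology). Tracked outcomes include total food production, the local food
price, farm conversions and abandonments, orphan nutrition, farm labour
(FTE), income inequality (Gini, mean-difference form), net farm incomes,
10-year income slopes, and **real land productivity**,

```
RLP [$/ha] = (net income / farm size) × endogeneity,
endogeneity = (gross value product − purchased non-labour inputs) / GVP,
```

an environmentally-sensitive intensity measure that strips out the value of
imported inputs.

## A worked example

```r
library(farmstyles)

cfg <- build_scenario("peasant", "high")     # peasant policy, high climate change
res <- run_simulation(cfg, seed = 42)
round(res[c(10, 25, 50), c("year", "total_production_t", "local_price",
                           "n_converted", "n_abandoned", "orphan_nutrition",
                           "households_feedable")], 2)
#> year total_production_t local_price n_converted n_abandoned orphan_nutrition households_feedable
#>   10             804.53       37.78         100           0             0.94                1149
#>   25            2316.02       33.18         180           0             0.81                3308
#>   50            3113.03       39.09         188          46             0.70                4447
```

Reading the numbers: by year 10, 100 of 250 households have converted to
their preferred style and community production (805 t of cereal equivalents)
has roughly tripled from its subsistence baseline of ~250 t. By year 50,
production reaches ~3100 t — enough to feed ~4400 households a basic 700-kg
diet — but 46 households have abandoned farming under drought and warming
pressure, and the remaining orphan households eat only ~70% of a basic diet:
development and hunger coexist, in different parts of the community.

Batch experiments average many seeded replicates:

```r
b <- run_batch(build_scenario("entrepreneurial", "no"), n_runs = 250, base_seed = 1)
b$mean$total_production_t[50]    # across-run mean year-50 production
```

A thin command-line front end lives at `inst/cli/farmstyles.R`:

```sh
Rscript inst/cli/farmstyles.R batch --policy peasant --climate high \
    --runs 250 --seed 1 --out out/
```

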