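# trialflow

Clinical development discards most of its candidates, and not all of the
discards deserve it. Phase II trials are typically run at ~50% power, so
half of all truly effective treatments fail their first efficacy test and
exit the pipeline as **false negatives** — missed cures and missed
revenue — while the conventional α = 5% keeps false positives rare.
trialflow is a decision-analytic simulator of this staged screening
process for statisticians and portfolio strategists who want to ask: *what
happens to productivity and profit if we move the phase II error
thresholds?*

## The model

A portfolio of 100 candidates, 25% truly effective, enters phase II (one
trial, configurable α and power) and survivors enter phase III (two
independent confirmatory trials, each α = 5%, power 90%, so an ineffective
treatment slips through with probability α² = 0.25% and an effective one
passes with 0.81). Expected counts propagate through the stages and are
classified as true/false positives/negatives. Power and sample size follow
the two-arm normal approximation

```
power = 1 − Φ(z₁₋α/2 − ES·√(n/2)),   n = 2(z₁₋α/2 + z_power)² / ES²
```

so phase II program costs scale with `(z₁₋α/2 + z_power)² / 1.96²`
relative to the reference design (α = 5%, power 50%; a 200-participant,
\$40M study at \$200,000 per participant), discounted by an
economies-of-scale factor on the incremental part. Phase III costs \$163M
per entrant; a treatment passing phase III returns \$2,500M. On top of the
deterministic layer sit a grid search over the phase II (α, power) space
and a 10,000-draw Monte Carlo probabilistic sensitivity analysis with
binomial portfolio simulation.

## Worked example

```r
library(trialflow)
scns  <- default_scenarios()    # 1: α=5%/50%, 2: 5%/80%, 3: 1%/50%, 4: 20%/95%
flows <- lapply(scns, run_flow)

render_flow_table(flows["Scenario 1"], mode = "printed")
#>     scenario       class enter_II pass_II fail_II enter_III pass_III fail_III
#> 1 Scenario 1   effective       25    12.5    12.5      12.5     10.1      2.4
#> 2 Scenario 1 ineffective       75     3.8    71.3       3.8      0.0      3.7
```

Under the status quo, 12.5 of 25 effective treatments die at phase II and
2.4 more at phase III: 14.9 false negatives, and a productivity (true
positives / effective entrants) of only 10.1/25 = 40.4%. Raising phase II
power to 80% (Scenario 2):

```r
str(productivity_metrics(flows[["Scenario 2"]], baseline = flows[[1]], mode = "printed"))
#> $ productivity_pct                   : num 64.8
#> $ pass_phase2_pct                    : num 23.8
#> $ effective_among_phase3_entrants_pct: num 84
#> $ pass_phase3_of_entrants_pct        : num 68.1
#> $ productivity_change_pct            : num 60.4

profit(scns[["Scenario 2"]], cost_model())
#> <economic_result> Scenario 2: phase II $7331M + phase III $3871M; return $40523M; profit $29322M
```

Productivity jumps 60.4% (40.4% → 64.8%), 84% of phase III entrants are
now genuinely effective, and the \$40,523M expected return dwarfs the
larger phase II bill. Searching the whole design space:

```r
find_optimum(profit_surface(search_grid()))
#> $alpha  [1] 0.2
#> $power  [1] 0.95
#> $profit [1] 33968.88
```

The profit-maximising phase II design is a *lenient* α = 20% with 95%
power (Scenario 4) — the reverse of the conventional error asymmetry.
`run_psa(psa_spec())` then checks robustness: across 10,000 sampled
effect sizes, effective proportions, unit costs and returns, Scenario 4
keeps the highest mean profit, and its advantage over the status quo
correlates positively with the return on success and the proportion of
effective candidates. `run_all(default_config(), "out/")` writes the full
bundle (flow, classification, economics, surface, sweeps, PSA) as
CSV + JSON with provenance metadata.

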