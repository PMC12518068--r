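# dietopt

Lexicographic goal programming for designing **nutritionally adequate,
low-emission diets with minimal dietary change**.

Diet models usually shift mass *between* food groups while the mix of items
inside each group stays frozen. But nutrient content and greenhouse gas
emissions (GHGE) vary enormously *within* groups — one bread against
another — so within-group substitution can buy adequacy and emission cuts
at a fraction of the dietary change. `dietopt` is for nutrition and
sustainability modelers who want that comparison as a reproducible
pipeline: observed diets in, optimized diets and acceptability metrics out.

## The model

For a diet $x \ge 0$ over food items (g/day) with observed quantities $o$:

* **Deviations.** $D_{\text{macro}}$ is the largest relative violation of
  the macronutrient bounds (protein, carbohydrate, fat, SFA in E% with
  Atwater factors 4/4/9/9; fiber and sodium in mass/day);
  $D_{\text{micro}}$ is the largest relative shortfall versus RDA (or EAR)
  references. Excess micronutrient intake is never penalized.
* **Footprint.** Composite foods decompose into primary commodities:
  $\text{GHGE} = \sum_i w_i \cdot g_i \cdot \frac{100}{100 - \ell_i}$
  per 100 g, where $w_i$ is commodity weight, $g_i$ its emission intensity
  per gram, and $\ell_i$ the farm-to-fork loss percentage.
* **Experiment 1/2** (within groups, group totals conserved, change budget
  $a$%): lexicographically minimize
  $D_{\text{macro}} + D_{\text{micro}}$, then diet GHGE $E$, then
  within-group change $C_{\text{within}}$ — the weighted form
  $\min\, D + \varepsilon_1 E + \varepsilon_2 C$
  ($\varepsilon_1 > \varepsilon_2$) is also available. Experiment 2 first
  relaxes the goals: macro bounds ±20% (protein 10–35 → 8–42 E%), RDA → EAR.
* **Experiment 3** (GHGE cap): guidelines become hard constraints,
  $E \le (1-t) E_{\text{obs}}$, and total dietary change
  $C_{\text{total}} = 100 \sum_i |x_i - o_i| / \sum_i o_i$ is minimized —
  scaling whole groups only (`between_only`) or moving items freely
  (`between_and_within`).

Everything is solved by a built-in deterministic two-phase simplex,
cross-validated in the tests against `boot::simplex` and exhaustive grid
search. See `vignettes/dietopt-methods.Rmd` for assumptions, tunables and
limitations.

## Worked example

```r
library(dietopt)

sys <- generate_food_system(generator_params(seed = 42))
sys
#> <food_system> 206 items ( 173 optimizable ), 12 nutrients, 3 classifications, 2 diets

# the observed female diet violates its guidelines and emits 8.05 kg CO2eq/day:
#> observed: 8.05 kg CO2eq/day, D_macro 0.25, D_micro 0.30

r <- solve_experiment1(sys, sys$diets$female,
                       scenario_config("within_only", "fine",
                                       allowed_change_pct = 50))
r
#> <solve_result> optimal: d_macro 0.0734, d_micro 0.1590,
#>   GHGE 7.807 kg/day (3.0% vs observed), c_total 75.1%
```

Reallocating at most 50% of each food group's mass cut the worst
macronutrient violation from 25% to 7%, the worst micronutrient shortfall
from 30% to 16%, and emissions by 3% — adequacy is prioritized over GHGE.
Requiring a 30% emission cut instead (experiment 3):

```r
tab <- run_experiment_grid(sys, 3, sexes = "female",
                           classification_ids = "fine")
tab[, c("mode", "status", "c_total_pct", "ghge_reduction", "pct_removed")]
#>                mode  status c_total_pct ghge_reduction pct_removed
#>        between_only optimal        67.3           0.30        23.3
#>  between_and_within optimal        37.2           0.30        17.0
```

Letting items move inside groups achieves the same 30% GHGE reduction with
37% total dietary change instead of 67%, and removes fewer foods — the
acceptability argument for modeling at item level.

A command-line interface wraps the pipeline
(`generate` / `run` / `report`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/dietopt.R", package="dietopt"))')" \
  generate --preset default --seed 1 --out fs
```

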