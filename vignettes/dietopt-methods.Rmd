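---
title: "Methods: goal-programming diet optimization in dietopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: goal-programming diet optimization in dietopt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietopt)
```

## The problem

Food production is a leading source of greenhouse gas emissions (GHGE), and
diet models are widely used to ask how an observed diet could shift toward
nutritional adequacy and lower emissions with as little disruption as
possible. Most models move mass *between* food groups ("less beef, more
legumes") while the mix of items inside each group stays frozen. dietopt
implements the complementary idea: items inside a food group differ a lot in
both nutrient content and footprint, so reallocating *within* groups —
swapping one bread for another — can buy adequacy and emission cuts at a
fraction of the perceived dietary change.

The package models one target group at a time (e.g. adult females) through
its *observed diet*: the average intake in g/day of each food item,
computed from dietary recalls after excluding implausible records
(ages outside 18–65; energy below 1,200/1,800 kcal or above
3,600/3,000 kcal for females/males, boundaries retained). Items reported
three times or fewer, and items in a classification's residual "other"
category, are *fixed*: they keep their observed quantities through every
optimization.

## Guideline evaluation

Nutrients are split into three kinds:

* **macro_energy** (protein, carbohydrate, fat, SFA): constrained as a
  percentage of energy intake (E%), with Atwater factors 4 kcal/g
  (protein, carbohydrate) and 9 kcal/g (fat, SFA);
* **macro_mass** (fiber, sodium): constrained in mass per day
  (fiber ≥ 14 g/1,000 kcal converted at the observed energy;
  sodium ≤ 2,300 mg);
* **micro** (calcium, folate, iron, magnesium, vitamin A, vitamin E):
  compared against RDA or EAR reference intakes.

For a diet with profile value $v$ and a bound $u$ (upper) or $l$ (lower),
the relative violation is $\max(0,(v-u)/u)$ or $\max(0,(l-v)/l)$. The
macronutrient deviation $D_{\mathrm{macro}}$ and the micronutrient deviation
$D_{\mathrm{micro}}$ are each the *maximum* violation in their block
(minimax goal programming — one auxiliary LP variable per block), so a diet
with $D=0$ meets every bound and excess micronutrient intake is never
rewarded. `relax_guidelines()` produces the *lowered* goal set: every
macronutrient lower bound × 0.8, every upper bound × 1.2 (protein 10–35 E%
becomes 8–42 E%), and the micronutrient target switches from RDA to EAR.
Relaxing twice is an error by design.

## The three experiments

All experiments are linear programs over non-negative quantities
$x_i$, with $x_i = o_i + p_i - n_i$ splitting each change into an increase
and a decrease so absolute change is linear.

**Experiment 1 (within-group, full goals).** Per food group the total mass
is conserved, $\sum_{i \in g}(p_i+n_i) \le 2\,(a/100)\sum_{i\in g} o_i$
caps the reallocated mass at the allowed-change level $a$ (the factor 2
makes $a = 100$ exactly sufficient for full redistribution), and optionally
no item may exceed the highest observed average quantity in its group. The
objective is lexicographic: minimize $D_{\mathrm{macro}}+D_{\mathrm{micro}}$
first, then GHGE, then within-group change, each stage locked at its
optimum (±`solver_tol`) before the next. A single weighted solve of
$D + \varepsilon_1 E' + \varepsilon_2 C'$ ($\varepsilon_1 = 10^{-3} >
\varepsilon_2 = 10^{-6}$, $E'$ and $C'$ normalized by their observed-diet
values) is available via `lexicographic = FALSE` and agrees with the staged
solve on the test suite.

**Experiment 2 (lowered goals)** is experiment 1 run against the relaxed
guideline set.

**Experiment 3 (minimal change under a GHGE cap)** makes the guidelines
*hard* constraints ($D=0$), adds $E \le (1-t)\,E_{\mathrm{obs}}$ for a
reduction target $t$ (default 30%), and minimizes total dietary change with
a small GHGE tiebreak. In `between_only` mode one scale factor $s_g \ge 0$
per group multiplies the whole group (distribution inside frozen; a group
scaled to 0 is removed); in `between_and_within` mode items move freely.
Because every between-only diet is also item-level reachable, the
between-and-within optimum can never require more change — the package's
central comparison.

## Acceptability metrics

Total dietary change is $100\sum_i |x_i-o_i| / \sum_i o_i$, **without
halving**, so complete replacement of a diet scores 200%, and values above
100% are meaningful. This definition was chosen because reported dietary
changes above 100% exist in the literature, which a halved, mass-conserving
definition cannot produce. Fixed items sit in the denominator and
contribute zero to the numerator. `diversity_report()` adds the number of
retained items (quantity above a 0.01 g/day presence threshold), the share
of observed items removed, and the mean over groups of the largest item
share; groups emptied entirely are excluded from that mean and counted
separately.

## Numerical choices

* **Energy anchor.** Energy intake is constrained to the observed energy
  ±5% in every experiment. Without an anchor the E% and GHGE objectives
  degenerate by shrinking the diet toward zero; ±5% keeps isocaloric
  comparability without forcing exact equality.
* **E% linearization.** A share bound $v \le u(1+D)$ is nonlinear in
  ($x$, $D$). It is linearized as
  $100\,a\,G_n(x) - u\,E(x) \le D \cdot u \cdot E_0$ with $E_0$ the
  *observed* energy. Inside the ±5% band this misstates the deviation
  coefficient by at most 5%; the deviation is exact whenever $D = 0$, and
  every reported deviation is recomputed exactly from the solved diet, so
  the approximation only affects the optimizer's internal trade-off, by a
  bounded amount.
* **Solver.** The LPs are small (a few hundred rows/columns) and must be
  bit-reproducible, so the package ships its own dense two-phase primal
  simplex: Dantzig pricing with a Bland's-rule fallback against cycling,
  deterministic tie-breaking by smallest basis index, and a fixed variable
  ordering (sorted item ids). It is cross-validated in the test suite
  against `boot::simplex` on random LPs and against exhaustive 1%-step grid
  search on small diet instances. Random seeds never reach the solver.
* **Degenerate inputs.** An empty diet yields a flagged profile with
  undefined energy shares; deviations on it are an error, not NaN.
  Single-item groups are inert in within mode (conservation pins them).
  Solver noise below `solver_tol` is snapped to zero before metrics; fixed
  items are never snapped.
* **Infeasibility** (experiment 3 only, e.g. an unreachable GHGE cap) is a
  reported status carrying the constraint rows whose phase-1 artificials
  stayed positive — never an exception, so grid sweeps continue.

## The synthetic generator

`generate_food_system()` provides the stated world the pipeline is tested
in, emulating the statistical features the method relies on without any
survey download:

* **Hierarchy:** 40 fine groups (3–8 items each) by default, merged into
  nested medium (~16) and coarse (~6) classifications — the real
  345/153/46-group hierarchy at reduced scale.
* **Within-group spread:** item nutrient content and GHGE are log-normal
  around group means (log-sd 0.5 and 0.6) — both strictly positive and
  right-skewed, with the heavy within-group variation that makes
  within-group optimization worthwhile. GHGE is realized through a shared
  pool of 50 primary commodities with loss factors in [0, 50)%; per-item
  commodity weights are scaled so the loss-adjusted footprint reproduces
  the item GHGE exactly, keeping the footprint module consistent with the
  item table to 1e-9.
* **Consumption concentration:** within-group shares are Dirichlet(1), so
  most groups have a dominant item, as real food-frequency data show.
  Group masses are uniform on 10–120 g/day (≈2.6 kg/day over 40 groups);
  the male diet scales female group masses by 1.3 with independent shares.
* **Bottlenecks by calibration, not rejection:** each nutrient column is
  rescaled once so the female observed diet hits the configured violations
  exactly (defaults: iron −30%, vitamin E −25%, fiber −25%, sodium +20%,
  SFA +15%, fat +10% — low iron/fiber/vitamin E and high sodium/SFA/fat,
  the classic pattern of population diets) at 2,000 kcal, while all other
  guidelines are met with margin (micronutrients at 125% of the RDA).
  Deterministic calibration preserves the within-group dispersion and
  makes the generator's self-check exact; mutually inconsistent targets
  (e.g. a fat excess that pushes carbohydrate out of its own range) fail
  with an explicit error rather than being silently absorbed. The male
  diet shares the calibrated composition; its violation set is reported
  but only the calibrated sex is guaranteed.

What the generator does **not** emulate: survey weighting, item-level
consistency between SFA and total fat after calibration, realistic
commodity recipes, or any marginal distribution of a real population. A
green test therefore certifies the *machinery* — constraint algebra, stage
ordering, conservation, reproducibility — not nutritional conclusions
about any real diet.

## Known limitations

* **GHGE need not fall monotonically with the allowed-change budget.**
  Adequacy outranks emissions, and a larger budget can buy a smaller
  nutrient deviation that only high-footprint items can supply; the test
  suite constructs such a case deliberately (`adequacy_vs_ghge`) and also
  observes it on bottleneck-laden synthetic systems. The monotone pattern
  holds once deviations plateau.
* **Between-only mode is often infeasible at coarse granularity**: with
  few scale factors and a dozen hard nutrient constraints the polytope can
  be empty — itself a finding about modeling at group level, and reported
  as an infeasible status with the binding constraint groups.
* One aggregate loss factor per commodity; splitting supply-chain from
  consumer losses is the data supplier's job.
* Guideline defaults (DRI-style values) are configuration shipped for
  convenience, not normative claims; only one female and one male set are
  supported, with no tolerable upper intake levels for micronutrients.
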