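# ifmcdm

Intuitionistic fuzzy multi-criteria decision analysis in R: **IF-AHP**
criterion weighting, **IF-DEMATEL** cause–effect network analysis, and
**CoCoSo** compromise ranking, in one tidy pipeline.

## The problem

Health-system managers (and anyone comparing a handful of service units on
many indicators) face three linked questions: *how much does each criterion
matter*, *which criteria drive which others*, and *which unit performs
best — and where exactly is it weak?* Expert judgment is indispensable for
the first two questions but comes with hesitation and disagreement.
`ifmcdm` models that hesitation explicitly: every judgment is an
intuitionistic fuzzy number (IFN) — a membership/non-membership pair
(μ, ν) with μ + ν ≤ 1 and hesitancy π = 1 − μ − ν — elicited on linguistic
scales, so "high influence" carries its own uncertainty through the
arithmetic instead of being flattened to a single number at the door.

The package ships the complete printed dataset of a published three-hospital
emergency-department evaluation (6 experts, 8 criteria, 35 sub-criteria,
3 departments) as plain-text fixtures, so every stage is demonstrable and
testable offline.

## The methods

**Stage 1 — IF-AHP weights.** Experts are weighted by
ω_k ∝ μ_k + π_k·μ_k/(μ_k + ν_k); pairwise judgment matrices are aggregated
cell-wise with the intuitionistic fuzzy weighted average
(μ = 1 − Π(1−μ_k)^ω_k, ν = Π ν_k^ω_k); consistency is checked via Saaty's
CR = ((λ_max − n)/(n − 1))/RI on the defuzzified reciprocal matrix
(acceptable below 0.10); local priorities come from an intuitionistic
entropy measure, and global sub-criterion weights are local × parent.

**Stage 2 — IF-DEMATEL influence network.** Influence judgments are
defuzzified by f = ½(1 + μ − ν) followed by x = l + f(m − l) on support
(0, 4); the experts' crisp grids are averaged into Z, normalised by the
largest row/column sum into N, and the total-influence matrix
T = N(I − N)⁻¹ accumulates all influence paths. Row/column sums D and R
give prominence (D + R) and relation (D − R): elements with D − R > 0 are
*dispatchers* (causes), the rest *receivers* (effects). Links with
t_ij > θ = ΣT/n² form the impact digraph.

**Stage 3 — CoCoSo ranking.** KPI values are min-max normalised with
benefit/cost directions, combined into additive (S_i = Σ w_j r_ij) and
power (P_i = Σ r_ij^w_j) comparability, blended into three appraisal
scores (M^a, M^b, M^c; balance λ = 0.5) and the final compromise index
M_i = (M^a M^b M^c)^⅓ + (M^a + M^b + M^c)/3, which ranks the units and
drives a per-unit weakness report.

## Worked example

Cause–effect analysis of the bundled human-talent cluster (the printed
4 × 4 aggregated influence matrix), then the full three-department ranking:

```r
library(ifmcdm)

Z <- load_fixture("table8_human_talent_Z")
prominence_relation(total_influence(normalize_direct_relation(Z)))
#> # A tibble: 4 × 6
#>   element     D     R prominence relation role
#>   <chr>   <dbl> <dbl>      <dbl>    <dbl> <chr>
#> 1 SH19     16.5  16.4       32.9   0.139  dispatcher
#> 2 SH20     17.2  16.4       33.6   0.844  dispatcher
#> 3 SH21     15.9  17.0       32.9  -1.08   receiver
#> 4 SH22     16.3  16.2       32.4   0.0931 dispatcher

fit <- cocoso(load_fixture("table13_decision_matrix"))
#> weights sum to 1.004000; renormalizing to 1.
fit
#> CoCoSo ranking (lambda = 0.5)
#> # A tibble: 3 × 8
#>   alternative     S     P    Ma    Mb    Mc     M  rank
#>   <chr>       <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <int>
#> 1 D2          0.784  29.9 0.375  2.78 1      2.40     1
#> 2 D1          0.737  27.9 0.350  2.60 0.933  2.24     2
#> 3 D3          0.554  21.9 0.275  2    0.732  1.74     3
```

Reading the output: among the human-talent sub-criteria, the number of
general practitioners (SH20) is the strongest *cause* (relation +0.844 —
it drives the others), while Advanced Life Support certification (SH21) is
the main *effect* (−1.08). In the ranking, department D2 wins with
compromise index M = 2.40; the weakness report pinpoints why D1 trails:

```r
head(fit$weaknesses[fit$weaknesses$alternative == "D1", ], 3)
#> # A tibble: 3 × 4
#>   alternative subcriterion value weight
#> 1 D1          SH21             0 0.0369   # lowest ALS certification
#> 2 D1          SH22             0 0.0359   # largest nurse deficit
#> 3 D1          SH5              0 0.0289   # fewest available beds
```

`tidy()`, `glance()` and `autoplot()` methods are available on every fitted
object; `run_weights()`, `run_dematel()` and `run_cocoso()` write CSV/JSON
reports with a reproducibility manifest, and `inst/cli/ifmcdm.R` exposes the
whole pipeline as a command-line tool (subcommands `weights`, `dematel`,
`cocoso`, `evaluate`, `generate`, `fixtures`).

Synthetic panels for experimentation come from `generate_panel()`, which at
zero noise produces perfectly consistent judgment matrices whose latent
priority vector is exactly recoverable.

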