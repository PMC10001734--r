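---
title: "Hybrid intuitionistic-fuzzy MCDM: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid intuitionistic-fuzzy MCDM: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifmcdm)
```

`ifmcdm` implements a three-stage multi-criteria decision pipeline for
evaluating the performance of comparable service units — its bundled case
study scores three hospital emergency departments on 8 criteria and 35
sub-criteria. The three stages are deliberately decoupled: each is a
self-contained method with its own inputs and diagnostics, and each can be
used on its own.

## The intuitionistic fuzzy number

Every expert judgment in the first two stages is an intuitionistic fuzzy
number (IFN): a pair $(\mu, \nu)$ of membership and non-membership degrees
with $\mu + \nu \le 1$. The residual $\pi = 1 - \mu - \nu$ is the hesitancy
degree, an explicit model of the expert's indecision that an ordinary fuzzy
membership cannot carry. `make_ifn()` enforces the constraint (absolute
tolerance $10^{-9}$) and always recomputes $\pi$ from $\mu$ and $\nu$, so
the three components can never drift apart.

Judgments are elicited on linguistic scales — ordered label-to-IFN maps.
Three are built in (`ahp_relevance_scale()`, `dematel_influence_scale()`,
`expert_importance_scale()`) and any scale can be supplied as JSON. Two
operators move an IFN toward a crisp number:

* `to_standard_fuzzy()` collapses the hesitancy evenly,
  $f = \tfrac12(1 + \mu - \nu)$. The even split ($\varphi = 0.5$ in the
  general $C_\varphi$ family) minimises the Euclidean distance between the
  collapsed fuzzy set and the original IFN, and we fix it rather than
  exposing $\varphi$ as a knob.
* `defuzzify_crisp()` places $f$ on a triangular support,
  $x = l + f\,(m - l)$. The influence scale uses support $(0, 4)$, so the
  five labels map to the crisp scores $0.4, 1.5, 2.1, 3.1, 3.6$. The upper
  triangular parameter $u$ of a general triangular number plays no role in
  this linear map; `linguistic_scale()` accepts and stores it unused.

## Stage 1 — priority weights (IF-AHP)

Experts first receive weights from their importance ratings via the score
$\mu_k + \pi_k\,\mu_k/(\mu_k + \nu_k)$ (`expert_weights()`): hesitancy is
credited to an expert in proportion to the membership share of their
rating, and the scores are normalised. A rating with $\mu = \nu = 0$ is
rejected because the share is undefined.

Each expert supplies pairwise relevance judgments per cluster (one matrix
for the criteria, one per criterion for its sub-criteria). The matrices are
aggregated cell-wise with the intuitionistic fuzzy weighted average
(`ifwa()`):
$\mu = 1 - \prod_k (1-\mu_k)^{w_k}$, $\nu = \prod_k \nu_k^{w_k}$. IFWA is
idempotent and keeps the aggregate a valid IFN; `0^w` is taken as 0 for
$w > 0$ (and as 1 for $w = 0$), so a zero non-membership is absorbing.

**Consistency.** The aggregated IFN matrix is collapsed to a crisp
comparison matrix before eigenvalue analysis (`crisp_reciprocal()`): each
cell through `to_standard_fuzzy()`, diagonal forced to 1, lower triangle
replaced by the reciprocal of the upper triangle. The reciprocal forcing is
a design choice: the consistency ratio
$\mathrm{CR} = \frac{(\lambda_{\max} - n)/(n-1)}{\mathrm{RI}(n)}$ is only
meaningful for a positive reciprocal matrix, and the collapsed memberships
by themselves are not reciprocal. Random indices follow Saaty's table
(orders 1–15; extendable via the `ri` argument). Matrices with
$\mathrm{CR} \ge 0.10$ raise a warning and are flagged — never silently
"fixed", since the remedy is a revision of judgments, not arithmetic.

**Priorities.** Each row of the aggregated matrix is summarised into one
IFN by averaging $\mu$ and $\nu$ across the row (`row_ifn()`); the
arithmetic mean (rather than an equal-weight IFWA) is what reproduces the
case study's printed row IFNs. Local weights then come from an
intuitionistic fuzzy entropy (`entropy_weights()`): decisive rows (low
entropy) get more weight, with $x\ln x := 0$ at $x = 0$ and a final
normalisation that makes any constant factor in the entropy immaterial.
Global sub-criterion weights are local weights scaled by the parent
criterion weight (`global_weights()`); by default parent and child vectors
are renormalised to unit sum first, so the composed weights sum to exactly
1 even when inputs carry printed-rounding residue. `eigen_weights()`
(principal eigenvector of the crisp reciprocal matrix) is provided as a
classical cross-check; on a perfectly consistent matrix it recovers the
generating priority vector exactly, which the tests exploit.

## Stage 2 — cause–effect structure (IF-DEMATEL)

Influence judgments use the same long format with the influence scale. Per
expert, the grid is defuzzified with the two-operator chain above and the
diagonal forced to 0 (`defuzzify_influence()`); the conventional diagonal
pair $[0, 0]$ is never interpreted through the scale. The crisp grids are
averaged **unweighted** across experts (`aggregate_direct_relation()`) —
the influence stage deliberately treats the panel symmetrically even though
stage 1 carries expert weights; this asymmetry mirrors the method's
standard formulation and is documented rather than harmonised.

A convergence index guards panel reliability: the mean absolute relative
change between the full-panel aggregate and the aggregate without the last
expert (input order), over off-diagonal cells
(`convergence_index()`; threshold 0.05). Cells whose reference value is 0
cannot be scaled and are skipped with a warning; a single-expert panel
skips the check entirely.

The aggregate $Z$ is normalised by the largest row or column sum
(`normalize_direct_relation()`), guaranteeing the spectral radius of $N$
is at most 1 in practice and usually well below. The total-influence matrix
$T = N (I - N)^{-1}$ (`total_influence()`) accumulates all direct and
indirect influence paths; it is computed by a dense linear solve, and a
spectral radius $\ge 1$ is an error reporting the radius — no pseudo-inverse
fallback, because a divergent series has no meaningful total influence.

Row sums $D$ (influence dispatched) and column sums $R$ (influence
received) yield the prominence $D + R$ and relation $D - R$
(`prominence_relation()`). An element is a *dispatcher* (cause) iff
$D - R > 0$, strictly; the measure-zero boundary $D = R$ is classed as
receiver. Significant links are the entries of $T$ strictly above
$\theta = \sum_{ij} t_{ij} / n^2$, the mean total influence
(`significant_links()`); raising $\theta$ can only remove edges.

## Stage 3 — ranking (CoCoSo)

Alternatives are scored on a decision matrix of KPI values with explicit
benefit/cost directions and the stage-1 global weights. Min-max
normalisation maps each sub-criterion to $[0, 1]$ in its preference
direction. A constant row (every alternative equal) is mapped to 1 — "all
tied at best" — so fully tied indicators still contribute one unit to the
power comparability; mapping them to 0 would silently delete them from
$P_i$, and the case-study fixture demonstrates the difference numerically.

Two comparability scores per alternative,
$S_i = \sum_j w_j r_{ij}$ (additive) and $P_i = \sum_j r_{ij}^{w_j}$
(power), feed three appraisal scores — a relative share
$M^a_i = (P_i + S_i)/\sum(P+S)$, a distance-from-worst
$M^b_i = S_i/\min S + P_i/\min P$, and a compromise-against-best
$M^c_i = \frac{\lambda S_i + (1-\lambda) P_i}{\lambda \max S + (1-\lambda)\max P}$
with $\lambda = 0.5$ by default — combined into the final index
$M_i = (M^a M^b M^c)^{1/3} + (M^a + M^b + M^c)/3$. Ties in $M$ break
lexicographically by alternative id, logged by the tie. $M^b$ is undefined
when $\min S$ or $\min P$ is 0 (one alternative worst on every
discriminating sub-criterion); this is raised as an error with guidance
rather than patched, since any finite substitute would be arbitrary.

The weakness report flags, per alternative, non-constant sub-criteria with
normalised value at or below a cutoff (default 0.1; 0 flags only exact
minima), ordered by weight so the heaviest deficiencies lead the
improvement agenda. Like all compromise methods, CoCoSo is not immune to
rank reversal when alternatives are added or removed; the test suite pins a
dominated-alternative smoke test on the bundled fixture but makes no
general claim.

## Numerical and data-handling choices

* Weight vectors are validated to unit sum at $10^{-6}$; the bundled
  decision matrix's printed weights sum to 1.004, so `cocoso()`
  renormalises with a message instead of failing on published data.
* The bundled aggregated influence matrix is printed at 3 decimals but its
  cells are six-expert means (exact sixths); tests that check the chain at
  the printed precision first verify the reconstruction rounds to the
  printed cells.
* The benefit/cost direction vector of the bundled decision matrix is
  reconstructed metadata: the staffing and accessory indicators are defined
  in the KPI catalog as amounts *necessitated to balance demand* — deficits
  — and are therefore costs. The column is user-editable.
* Fixture comparisons in tests use the tables' own printed precision
  (generally $5 \times 10^{-4}$ against 3-decimal prints), never tighter.

## The synthetic panel generator

`generate_panel()` creates reproducible panels for both judgment types. For
relevance (AHP-style) panels it draws a latent priority vector and sets
each upper-triangle membership to the priority ratio perturbed by
log-normal noise (default scale 0.1, clamped to $[0.1, 0.9]$), completing
the IFN with a fixed hesitancy of 0.2; mirrored cells swap $\mu$ and
$\nu$. At zero noise the collapsed reciprocal matrix is exactly consistent
(CR $= 0$) and `eigen_weights()` recovers the latent priorities — the
parameter-recovery property the tests assert at $10^{-6}$. For influence
(DEMATEL-style) panels, labels are sampled from the influence scale
(uniformly by default, or with user-supplied probabilities).

What the generator emulates: a panel sharing one underlying priority
structure with independent per-expert noise, and label-valued influence
judgments with fixed zero diagonals. What it does not emulate: correlated
expert biases, cluster-specific responsiveness, or the strategic
near-consensus visible in parts of the published tables (e.g. three
sub-criteria sharing identical local weights). Passing tests on synthetic
panels therefore demonstrate algorithmic correctness and invariants, not
that real expert panels will be consistent or convergent.

Problem sizes in the test-suite simulations (panels of 3–6 experts over
2–8 elements, a few dozen random repetitions per property) were chosen as
the smallest sizes that exercise every code path and invariant; the
published case study itself (6 experts, 8 + 35 elements, 3 alternatives) is
desk-scale and runs in well under a second.

## Known limitations

* The hierarchy is linear (criteria over sub-criteria); network-style
  feedback between the weighting and influence stages (supermatrix
  coupling) is out of scope.
* DEMATEL aggregation ignores expert importance weights by design (see
  above).
* The consistency ratio checks coherence of the panel's aggregated
  judgments, not the quality of the panel; a consistent panel can still be
  wrong.
* Printed reference tables carry rounding: a handful of published cells
  (one standard-fuzzy grid, one overall weight, the first alternative's
  distance-from-worst appraisal) disagree with exact recomputation from
  their own printed inputs at the last digit. The package pins formulas and
  unrounded chains, and documents each discrepancy where it is tested.
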