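---
title: "Connectome-wide MDMR: model, design choices and limitations"
author: "mdmrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-wide MDMR: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmrnet)
```

## The scientific problem

Alzheimer's disease progressively reorganizes the brain's white-matter
network. Mass-univariate edge statistics test each of the ~4000
connections separately and pay a crushing multiplicity price; global
graph metrics compress the network into one number and cannot say
*where* the reorganization happens. `mdmrnet` implements the middle
path: per-region **multivariate distance matrix regression (MDMR)**,
which asks, for each parcellated region, whether the *profile* of its
connections to the rest of the brain differs between diagnostic
groups — cognitively normal (CN), stable MCI (sMCI), MCI converting to
AD (cMCI), and AD.

## The model

Each subject contributes a symmetric, nonnegative weighted connectivity
matrix over `n = 90` nodes (the non-cerebellar AAL regions; any node
count is supported). Edge weights follow the connection-density
convention: streamline count per unit end-node surface with a
streamline-length correction,

$$w_{ij} = \frac{2}{S_i + S_j}\sum_f \frac{1}{l_f},$$

and a 5% density threshold keeps the strongest edges (the 95th weight
percentile over all $n(n-1)/2$ slots, zeros included; the
nonzero-only reading is available via a flag; ties at the cut are all
kept and flagged).

For region $i$, subject $u$'s connectivity vector is row $i$ of the
thresholded matrix without its diagonal entry (length $n-1$). Between
subjects $u, v$ the package uses the correlation distance

$$d_{uv} = \sqrt{2\,(1 - r_{uv})} \in [0, 2],$$

with $r_{uv}$ the Pearson correlation of the two vectors. The grouped
sum-of-squares decomposition over the subject-space distance matrix is

$$SS_T = \frac1n \sum_{u<v} d_{uv}^2,\qquad
  SS_W = \sum_g \frac{1}{n_g} \sum_{u<v\in g} d_{uv}^2,\qquad
  SS_A = SS_T - SS_W,$$

with the pseudo-F statistic $F = (n-1)\,SS_A/SS_W$. The two-group form
generalizes additively over groups; because $SS_T$ is label-invariant,
this scaling, and the classical $[SS_A/(k-1)]/[SS_W/(n-k)]$ scaling,
are strictly increasing functions of one another and give *identical*
permutation p-values (asserted exhaustively for $n \le 8$ in the test
suite).

### Covariates and permutation

The printed statistic has no covariate term, so adjustment goes
through the Gower-centered inner-product matrix $G = CAC$,
$A_{uv} = -d_{uv}^2/2$: with hat matrices $H_{cov}$ (intercept + age,
sex, ApoE-4 carrier status) and $H_{full}$ (covariates + group
indicators),

$$F_{adj} \propto
\frac{\operatorname{tr}\!\big[(H_{full}-H_{cov})\,G\big]}
     {\operatorname{tr}\!\big[(I-H_{full})\,G\big]},$$

which reduces exactly to $SS_A/SS_W$ when the covariate set is empty
(a tested identity, and cross-checked against an independent
PERMANOVA implementation). Inference is by permutation with the
add-one convention $p = (1+\#\{F^\ast \ge F\})/(B+1)$, ties counted as
extreme. With covariates the default scheme is Freedman–Lane —
residualize $G$ on the covariate design, permute its subject indices,
recompute the trace ratio — because it holds nuisance structure fixed
and nests the unadjusted test; permuting raw labels instead is
available by flag. `B` defaults to 5000 (unstated in common practice
at desk scale we use 99–999). Benjamini–Hochberg q-values are computed
across the regions of each comparison.

Degenerate inputs are kept, not dropped: a zero-variance connectivity
vector (an isolated region after thresholding) gets $r := 0$
($d = \sqrt2$) and a flag, so the subject space stays consistent
across regions; $SS_W = 0$ yields $F = \infty$ with a flag; constant
covariate columns are dropped and recorded, collinear ones are a
named error.

### Post-hoc attribution (delta) and nodal strength

MDMR says *that* a region's pattern differs, not *which* connections
drive it. The delta statistic answers that by randomization: for
partner edge $j$,

$$\delta_j = R^2 - \overline{R^2_{(j\ \text{permuted})}},$$

where $R^2 = SS_A/SS_T$ (its covariate-adjusted trace analogue in
general) is recomputed after independently permuting column $j$ across
subjects, averaged over `B_delta` (default 100) randomizations.
Destroying an informative edge's subject-ordering removes association,
so large $\delta$ marks driving connections; the top five per seed are
reported, ties broken by node order and flagged. The cited construction
of this statistic is not spelled out in full in the source literature;
the mean drop in pseudo-$R^2$ under single-column permutation is this
package's operationalization, with pseudo-$R^2$ (not pseudo-F) as the
base quantity because it is bounded and label-scale-free.

Amplitude is analyzed separately: nodal strength (the L1 norm of a
node's row) is compared between groups by an OLS partial-F on group
indicators with the same covariates, plus pairwise two-sided
permutation tests on covariate-residualized strengths (add-one
convention, α = 0.05).

### Classification

To measure predictive value, PLS-DA classifies CN vs. cMCI and CN
vs. AD from either the **key** connections (deduplicated union of
top-5 delta edges over seeds re-selected on the *training subjects
only*) or the **full** upper-triangle connectome (4005 features at 90
nodes). The protocol: stratified 80/20 splits (161 subjects give the
129/32 partition; per-class quotas by largest remainder), five
repeats, component count tuned by stratified 5-fold CV maximizing
pooled CV AUC over a 1–10 grid (smallest count wins ties; the grid is
truncated to the feasible rank, flagged), evaluation on the untouched
test set by sensitivity (patient class positive), specificity, ROC and
rank-formula AUC (midranks for ties; equal to the trapezoidal ROC
integral, asserted). Key and full modes are compared by paired
two-sided t-tests on per-repeat metrics; degenerate cases follow the
t-statistic's limits (all-zero differences give p = 1, constant
nonzero differences give p = 0). Per-repeat values and their means are
both reported, since a single-number summary hides split-to-split
variability. Test subjects never enter feature selection or tuning; a
dedicated test poisons the held-out data and asserts the selected
features are unchanged. The PLS-DA decision threshold is 0.5 on the
predicted class indicator. sMCI is not classified by default (the
planted design gives it no signal), but any pair can be requested.

## The synthetic cohort generator

Real diffusion-MRI cohorts cannot be bundled, so every stage is
exercised against a generator whose defaults emulate the target
cross-sectional staging cohort: group sizes 46/48/27/40
(CN/sMCI/cMCI/AD), age means/SDs, sex ratios and ApoE-4 carrier rates
per group matching the published demographics of such cohorts, and
covariates independent of group unless the `confounded` switch
correlates age with stage (+3 y per stage) to exercise adjustment.

Connectomes are built from a population template: each of the
$n(n-1)/2$ edge slots is structurally present with probability
`base_density` (default 0.10), present edges get log-normal weights
(location `edge_weight_scale`, scale `edge_sdlog`, default 1 —
heavy-tailed, as streamline-count-derived weights are), and each
subject multiplies template weights by log-normal noise
(`subject_sdlog` = 0.4).

**Planted alterations.** For each planted seed region a fixed per-cohort
plan perturbs affected subjects' matrices with stage magnitude
$e$: sMCI 0, cMCI $e$, AD $2e$ (progressive and nondecreasing by
construction; CN is 0 by definition). Two ingredients:

* an *attenuated* subset (30% of the seed's present edges) divided by
  $(1+e)$ — the amplitude-decline component, mirroring the reduced
  nodal strength seen in patient groups;
* a *rerouting* blend: the remaining present-edge weights move a share
  $e/(1+e)$ toward a rank-reversing reassignment of themselves over
  the seed's slots, including ~15% previously absent partners — weight
  migrates between partners and the seed's topology changes.

Both act multiplicatively/convexly on existing weights, so matrices
stay symmetric, nonnegative and zero-diagonal, and $e = 0$ is exactly
a no-op (group label independent of the connectome distribution).

Two design points here were settled empirically and deserve honesty.
First, a symmetric edge change unavoidably touches *two* regions, so
any planted mechanism leaks signal into partner regions. An earlier
variant that multiplied a few edges by $(1+e)$ planted leverage-outlier
coordinates in partners' sparse profiles, and those partners then
out-ranked the seeds themselves; bounded attenuation and
weight-migration concentrate the detectable pattern change at the seed
(many coherent coordinate changes) while each partner sees a single
noise-scale change. Second, the rerouting permutation is
rank-reversing rather than random because a random shuffle
occasionally draws a near-identity assignment and plants almost no
pattern — the deterministic reversal makes the planted effect's
magnitude reproducible across cohorts.

A companion streamline-summary generator emits per-pair counts and
mean lengths plus node surfaces consistent with the edge-weight
formula (round-trip asserted), so the network-construction path is
testable without tractography.

**What the generator does not emulate:** spatial embedding and
distance-dependent connection probability, hemispheric symmetry,
modular/hub organization, registration and tractography artifacts,
site effects, and longitudinal correlation. Passing tests therefore
demonstrate the statistical machinery's correctness and calibration on
group-structured heavy-tailed sparse networks — not performance on
real clinical diffusion-MRI cohorts.

## Reduced study conditions and calibration

Simulations in the tests and the acceptance script run at reduced
sizes chosen once, by forward power calibration, and then frozen:

* **Null calibration**: 16 nodes, 10+10 subjects, B = 199, 500
  cohorts; per-region rejection at α = 0.05 and family-wise BH
  discoveries.
* **Recovery**: 40 nodes, 25+25 subjects, 3 planted seeds,
  `effect_size` 3, `base_density` 0.25, `edge_sdlog` 0.5, B = 199.
  The density preserves the ~10 present edges per seed of a 90-node
  network at 5–10% density; the lighter weight tail tempers
  single-coordinate leverage in short (39-element) profiles, which is
  a small-n artifact that 89-element profiles dilute. Permutation
  p-values saturate at the $1/(B+1)$ floor under strong effects, so
  rank recovery breaks p-ties by pseudo-F.
* **Classification**: 30 nodes, 20+20 subjects, effect 0.5 (weak
  enough that the full 435-feature mode pays a measurable noise
  penalty), 2 repeats of 75/25 splits, 3-fold tuning; 12 null cohorts
  with 3 repeats for the chance-level check.

`effect_size = 2` is the generator default (a mid-grid value from the
same calibration); the recovery conditions above pass their ≥90%
criteria with headroom (~0.95 observed for top-3 rank recovery, ~1.0
for FDR and delta recovery).

## Numerical choices

Correlations are clamped so $2(1-r)$ is never negative before the
square root; permutation tie comparison uses an absolute $10^{-12}$
guard; the density threshold uses floor counting and keeps ties;
$SS_A \ge -10^{-10}$ always (correlation distance is
Euclidean-embeddable); all randomness flows from one master seed
through deterministically derived sub-seeds, and rerunning any entry
point with the same configuration is byte-identical (manifest
timestamps aside).

## Known limitations

* The delta statistic is an interpretation of a cited randomization
  procedure, not a re-derivation; its B_delta Monte-Carlo error is
  O(B_delta^{-1/2}) and small deltas are not distinguishable from 0.
* Freedman–Lane here permutes the residualized Gower structure, which
  is the standard but not unique choice; raw-label permutation is one
  flag away and agrees asymptotically under exchangeability.
* The pseudo-F's $(n-1)$ scaling is reported as printed in the
  source formulation; only permutation ranks matter for inference.
* Collateral significance at partner regions of planted edges is a
  property of symmetric networks, not a bug; the delta table typically
  attributes a partner's association to its single edge with the seed.
* No parametric p-values, and no graph-theoretic summaries — both are
  deliberately out of scope.
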