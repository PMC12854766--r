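---
title: "Hierarchical concentration-response modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical concentration-response modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxhier)
```

## Overview

`toxhier` maps Hill-parametrized high-throughput-screening (HTS)
concentration-response data through a biologically layered hierarchy -
assay responses to protein activity to pathway perturbation to in vivo
toxicity endpoints - and validates every stage on synthetic studies
with known ground truth. This vignette explains the model, the
numerical choices, the synthetic-data generator, and the limits of
what the validation demonstrates.

## Curve harmonization

Inputs are per-(assay, chemical) Hill parameters: AC50 (half-maximal
concentration), Hill slope, and Top (signed asymptotic response in
percent; negative = inhibition). All curves are evaluated on a shared
grid of 45 log10-uniform concentrations from 1 pM to 100 uM
(`build_grid()`), which makes heterogeneous assays dimensionally
comparable. Replicated (assay, chemical) pairs are reconciled by
selection, not averaging: the replicate with the smallest mean squared
deviation from the pointwise median is kept, which is robust to a
single aberrant profile.

Assays are classified by the sign pattern of their extreme fitted Top
values (minTop/maxTop) into positive, negative, mixed, or excluded
categories. The near-zero exclusion band is `eps = 1%` response: no
numeric cutoff is inherited from upstream data conventions, and 1% of
the response scale is comfortably below the amplitude of any
informative curve while catching fits that model essentially no
activity. It is a configurable argument.

`build_assay_tensor()` offers three response scales:

* `"assay_range"` (default): signed responses divided by the largest
  absolute Top in the assay, times 100. This preserves each compound's
  amplitude *relative to the assay's dynamic range* and its direction,
  which is what the factorization layers need - modeled protein scores
  are meaningfully signed (repression vs activation) only if direction
  survives harmonization.
* `"percent_of_top"`: each curve's own Top rescaled to 100%, bounded
  0-100. This is the right scale for comparing curve *shapes*, but it
  erases amplitude: every compound plateaus at the same height, and a
  tensor built this way is uninformative about relative potency across
  compounds within an assay. It is retained for shape-level analyses.
* `"response"`: raw evaluated responses, used when comparing against
  generative ground truth.

Untested pairs are represented by an explicit observed-entry mask;
they are never zero-filled, and masked entries are excluded from every
training loss.

## The three-layer factorization

With `Assay` the harmonized tensor (assays x concentrations x
chemicals), the model is

* `Assay ~ M1 . Prot`, `M1` (assays x proteins) masked by the curated
  assay-protein map, `Prot` latent;
* `Prot ~ M2 . Path`, `M2` (proteins x pathways) masked by gene-set
  membership, `Path` latent;
* `Path ~ M3 . Tox`, `M3` (pathways x endpoints) a fixed binary matrix
  from statistical filtering, `Tox` latent.

Each stage minimizes the mean squared error over observed entries
with Adam (initial step size 0.001), a plateau scheduler that
multiplies the step size by 0.1 when the loss stops improving
(patience 20 epochs, relative improvement threshold 1e-4), early
stopping when the relative loss improvement stays below 1e-6 for 20
consecutive epochs, and a budget of 1000 epochs. "10% rate decay" is
read as decay *to* 10% (multiply by 0.1), the standard
plateau-scheduler semantics. Layers are trained sequentially; there is
no joint refinement, no cross-validation, and no hyperparameter
search.

Three numerical choices matter and are worth recording:

1. **Training scale.** Responses are percent (0-100); training
   internally divides by 100. Adam's step magnitude is roughly the
   step size regardless of gradient scale, so on a 0-100 scale a
   0.001 step size could move parameters only ~1 unit in 1000 epochs.
   On the [0, 1] scale the same settings converge comfortably.
   Reported losses and R^2 are on the training scale.
2. **Warm start.** The default initialization (`init = "lstsq"`) runs
   a short masked alternating-least-squares phase (30 sweeps, with
   per-factor norm rebalancing to avoid the classic ALS scale seesaw,
   and a ridge of 1e-8), then Adam refines. A cold start from
   N(0, 0.01^2) (available as `init = "normal"`) cannot reach the
   optimum within the epoch budget at step size 0.001 for exactly the
   step-size reason above; the warm start makes the stated protocol
   effective rather than changing it. With the observation mask, ALS
   groups tensor columns by identical observation patterns (missing
   data are per assay-chemical pair, so patterns repeat across the
   concentration axis) and solves each group in closed form.
3. **Sign and scale conventions.** A factorization `W . P` is
   invariant to per-factor rescaling and sign flips. Latent rows are
   oriented to nonnegative means (flips folded into the mapping
   column), and the protein-to-pathway weights are constrained
   nonnegative - pathway membership aggregates protein activity, so a
   negative membership weight has no biological reading, while
   assay-level weights in `M1` stay signed to carry inhibitory assay
   direction. Tests compare reconstructions and summarized scores,
   never raw weights, because per-factor scale remains unidentified.

Pathways that no endpoint retains have an all-zero `M3` row; their
fibers are structurally unreconstructable and are excluded from the
toxicity-layer loss rather than letting them dilute the fit.

## Summarized scores and statistical filtering

The (pathway x concentration x chemical) tensor is collapsed to
scalar pathway scores by the arithmetic mean over the concentration
axis (mask-aware; `stat = "max"` is available). The mean is used
because it weights the whole tested range rather than a single
concentration; this is a package decision where upstream practice is
underdetermined, and the same rule is applied to `Tox` scores before
min-max normalization.

Filtering computes, for every (pathway, endpoint) pair:

* continuous endpoints (doses transformed to -log10 mg/kg): Pearson r
  with its t-test p-value, a Fisher-z 95% CI, and optionally a seeded
  nonparametric bootstrap percentile CI (2000 resamples; degenerate
  resamples redrawn and counted);
* binary endpoints: the Wilcoxon rank-sum test when the pooled sample
  has no ties (exact null distribution below a pooled n of 50, normal
  approximation with continuity correction above), otherwise the
  Brunner-Munzel test with Satterthwaite t degrees of freedom, plus
  the rank-biserial effect size `2A - 1` computed from the
  tie-corrected Mann-Whitney U. Ties are detected after rounding to
  12 significant digits so that binary representation noise cannot
  flip the test choice.

Retention requires, for continuous pairs, `r >= 0.1`, BH-FDR
`q < 0.05`, and `r >= 2/sqrt(n)`; for binary pairs, a positive
rank-biserial correlation with `q < 0.05`. FDR adjustment is applied
within each endpoint across its candidate pathways (the per-endpoint
retained counts are the natural reporting unit); a global family is
available via `fdr_scope = "global"`. Two-sided p-values are used
throughout, with positivity enforced by the retention rule rather than
by one-sided testing.

## Scoring, classification, and clustering

Normalized `Tox` scores (min-max to [0, 1] within endpoint; a
constant score vector maps to 0.5, the midpoint being the only choice
that does not invent extremes) are stratified into quartiles with
edges at ranks ceil(n/4), ceil(n/2), ceil(3n/4) and ties broken by
stable chemical-id order. Dose bands: GHS acute - high at LD50 <= 50
mg/kg, moderate to 2000, low above; NOAEL - high at <= 15 mg/kg
bw/day, moderate to 300, low above 1000, with the undefined gap
(300, 1000] reported as `unclassified` rather than silently assigned.

Cluster toxicity profiles standardize the cluster median against the
mean and population (n-denominator) standard deviation of all
compound-level values for the endpoint. For binary endpoints the
published recipe (z-score the 0/1 labels, multiply by -1) contradicts
its own direction convention under toxic = 1 coding; the package
z-scores the reversed coding (nontoxic = 1) and multiplies by -1,
which is algebraically the z-score of toxic = 1 coding and satisfies
"higher z = more toxic".

Structural grouping uses 166-bit MACCS keys (via OpenBabel),
Tanimoto similarity, and Taylor-Butina sphere exclusion at threshold
0.7: compounds are ranked by neighbor count, the top unassigned
compound becomes a centroid and claims its unassigned neighbors, and
clusters under 5 members are reported with a null cluster id so joins
stay total. The classic formulation is used (no false-singleton
reassignment). The per-cluster maximum common substructure is found by
a greedy, time-capped multi-seed clique search on the modular product
of element/bond-labelled molecular graphs - exact MCS is exponential,
so the best-so-far pattern is returned within the (default 10 s)
budget - and emitted as a SMARTS of atomic-number primitives joined by
any-bond primitives so the pattern matches regardless of
kekulization.

## Exposure comparison

Steady-state plasma concentrations (Css, uM, modeled externally under
a standardized 1 mg/kg/day repeated oral dose) are consumed as a
table of population percentiles; the 95th percentile (slow-clearance,
sensitive subpopulation) drives the comparison. For each modeled
curve at the assay, protein, and pathway layers, the EC50 is the
concentration where the curve first reaches half of its own maximum
absolute response, located by log-linear interpolation between
bracketing grid points (the interpolation scheme is a package choice;
modeled layer curves are not Hill-parametrized, so each curve's own
maximum - not a theoretical Top - anchors the half-max). Curves whose
maximum absolute response stays under 1% of scale have no defined
potency. A compound is exposure-relevant when any EC50 falls at or
below its Css p95.

## The synthetic-study generator

`generate_study()` emulates the statistical structure the model
assumes, with known ground truth:

* **Mappings.** Structural masks are drawn at configurable densities;
  every row keeps a "dominant" link (round-robin over columns so all
  columns are covered), and one dominant row per column is reduced to
  an exclusive anchor. True weights are positive uniform on all
  allowed entries, with a per-assay sign (30% inhibitory). Default
  densities are sparse - essentially one protein per assay and one or
  two pathways per protein - mirroring curated screening metadata,
  where an assay is designed against a single target and pathway
  membership is narrow. The anchors matter: at desk scale (8 proteins,
  5 pathways) a masked factorization without exclusive rows is
  genuinely non-identifiable - mixing matrices exist that respect the
  masks - and no trainer can recover what the data do not determine.
  Validating recovery therefore requires an identifiable design; this
  is a property of the simulated biology, not of the fitted model.
* **Latent pathway activity.** Per (pathway, chemical): AC50
  log-uniform over the central 70% of the grid (so half-max crossings
  are observable), slope uniform in [0.5, 3], amplitude log-uniform
  in [10, 100] percent.
* **Assay curves.** The matrix product of true mappings and pathway
  profiles. When a single pathway feeds an assay the curve is exactly
  Hill and the emitted parameters are analytic - these configurations
  round-trip to machine precision and anchor the exactness tests.
  Mixtures of Hill curves with different midpoints are not Hill; their
  emitted parameters are least-squares refits (Levenberg-Marquardt on
  log-concentration) of the sampled, optionally noise-added curve,
  which reproduces how real repositories summarize curves and is the
  generator's main realism-vs-exactness tradeoff. `refit_hill = FALSE`
  skips refitting (emitting dominant-route parameters) for simulations
  that only consume pathway scores and endpoints.
* **Endpoints.** Continuous endpoints are built so the population
  correlation between -log10(dose) and the planted pathway's
  standardized summarized score equals `r_true` exactly (noise
  variance `1 - sum(r_true^2)`); log10 doses are centered at 2.5
  (316 mg/kg) with sd 0.8, spanning the GHS bands the way broad
  chemical inventories do. Binary endpoints use a logistic link with
  slope `2 r_true` on the standardized latent and an intercept set by
  the target prevalence (default 0.5, which maximizes rank-test
  power); only the continuous correlation is exactly calibrated.
* **Chemistry and exposure.** SMILES are assigned from a packaged
  library of ~76 valid structures in eight homologous scaffold
  families (phenothiazines, organophosphorus esters, parabens,
  xanthines, sulfonamides, acetanilides, barbiturates, phthalates), so
  fingerprint clustering has known family structure; Css percentiles
  are log-normal around 1 uM. Neither attempts to mimic real chemical
  space or real toxicokinetics.

Everything is deterministic given the seed; `write_study()` emits the
same file formats the pipeline readers consume plus a JSON
ground-truth sidecar.

## Validation scale and what it shows

The reference validation study uses 20 assays x 45 concentrations x
300 chemicals with 8 proteins, 5 pathways, 5 endpoints, and response
noise sd 0.05; retention power and false-retention rates use 50 seeds
at n = 500 and 300 chemicals respectively; quartile trends use 20
seeds at 120 chemicals. These sizes give stable Monte-Carlo estimates
while keeping the full suite fast on a single CPU. Passing tests show
that the implementation recovers the structure its own generative
model plants - correctly routed mappings, calibrated correlations,
controlled false retention. They do not show that real HTS noise
(heteroscedastic, assay-dependent, with artifactual fits) is handled,
nor that real pathway annotations are complete enough for the
identifiability conditions above; on real data the mapping masks are
much larger and sparser, which helps identifiability but stresses
convergence.

## Known limitations

* Per-factor scale (and, absent anchors, more) is unidentified in the
  masked factorization; only reconstructions and summarized scores
  are comparable across runs.
* The greedy MCS search is not exact; patterns are valid common
  substructures but may be smaller than the true maximum.
* The Brunner-Munzel t approximation is unreliable below ~5
  observations per group (a warning is raised).
* Css values are consumed, never computed; the package takes no
  position on toxicokinetic model quality.
* Endpoints dropped during filtering (no retained pathway) are
  reported and excluded from the toxicity layer rather than modeled.
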