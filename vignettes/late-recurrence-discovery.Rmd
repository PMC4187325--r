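---
title: "Discovering late-recurrence signatures with dormsig: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering late-recurrence signatures with dormsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dormsig)
```

## The scientific problem

About a third of node-negative breast cancer patients followed long enough
relapse more than five years after their primary treatment. Such *late
recurrence* is widely interpreted as escape from tumor dormancy, and the
clinical predictors that work well for early relapse (grade, size,
basal-like subtype) carry little information about it. `dormsig` implements
a complete discovery-and-validation workflow for gene expression signatures
of late recurrence from multi-study microarray compendia:

1. **Harmonization** — cross-study (batch) structure is estimated from
   invariant control probes and removed by factor regression.
2. **Receptor and subtype calls** — ER/PR/HER2 status from bimodal mRNA
   cutoffs anchored on the samples with observed IHC labels; molecular
   subtype from the standard marker rules.
3. **Time-window survival screen** — genome-scale univariable Cox
   regressions under three censoring schemes that isolate events before
   versus at-or-after a 5-year boundary.
4. **Two-way clustering** — centroid-linkage clustering of the selected
   probes and samples, subgroup survival (Kaplan–Meier/log-rank), and 2×2
   enrichment statistics (cross-product odds ratio, Woolf CI, Fisher exact
   test).
5. **Stromal signature** — differential stroma expression of the
   late-recurrence subgroup in paired epithelium/stroma samples, summarized
   by a first-principal-component metagene (SPC1).
6. **Epithelial signature** — a three-filter cascade (correlation with
   SPC1, subgroup-specific upregulation, direct recurrence association)
   yielding an epithelial metagene (EPC1), validated against
   metastasis-timing groups.

Because the real compendia are external downloads, the package ships a
synthetic-cohort generator with the statistical structure every stage
assumes; the whole pipeline is exercised and tested end to end on generated
data.

## Censoring schemes

For records $(t_i, \delta_i)$ and boundary $b$ (default 5 years):

* **overall** — records unchanged;
* **early** — events with $t_i \ge b$ become censorings at $t_i$ (only
  early events count);
* **late** — events with $t_i < b$ become censorings at $t_i$ (only late
  events count).

An event at exactly $t=b$ is *late*. The two window transforms partition
the events, are idempotent, and never alter times. A probe is
early-associated when its early-scheme Wald p-value falls below the
discovery threshold (default $p<0.001$, no multiplicity correction in the
discovery screen; BH FDRs are reported alongside), late-associated
symmetrically, and its direction is *direct* when the overall-scheme
coefficient is positive (overexpression associated with poor outcome).
Efron tie handling is used throughout; probes with zero variance or
non-convergent fits are classified `neither` with the reason recorded,
never dropped silently.

## Harmonization model

Let $C$ be the control-probe submatrix (probes centered across samples).
The technical structure is the span of the first $k$ principal-component
score vectors of $C$ (defaults: $k=40$ for a large bulk compendium, 15 for
a smaller multi-tissue set; always bounded by the number of control probes
and samples − 1). `remove_structure()` projects every probe onto the
orthogonal complement of that score space. Two consequences worth knowing:

* removal is a projection, so re-applying the same model is a no-op and
  residuals are exactly uncorrelated with every score;
* per-probe means are preserved (the scores are centered), so expression
  stays on its original scale.

The factors are estimated jointly over the merged matrix, matching a
rebuild-everything workflow rather than per-study estimation. Mixing is
checked by `confirm_mixing()`: the share of top-probe PC1 variance
explained by study label, with a permutation null available from the fixed
embedding.

## Bimodal receptor cutoffs

For each marker, maximum-likelihood normals are fitted to the IHC-positive
and IHC-negative labeled samples, and the cutoff is the expression value
between the class means where the prior-weighted class densities are equal
(posterior 0.5). Equating log densities gives a quadratic; with unequal
variances the root between the means is taken, otherwise the root nearest
the prior-weighted pooled mean. The class prior defaults to the labeled
prevalence (equal priors by option). Samples with an observed IHC label
always keep it; a value exactly at the cutoff is called negative
(conservative positivity, a measure-zero choice). Subtypes partition the
eight call combinations: Luminal A (ER+ and/or PR+, HER2−), Luminal B
(ER+ and/or PR+, HER2+), HER2 type (ER−PR−HER2+), TNBC (triple negative).

## Clustering and enrichment

Two-way clustering uses *true* centroid linkage under the
1 − Pearson-correlation distance: cluster distances are recomputed between
size-weighted mean profiles after every merge. This is the behaviour of the
classic desktop clustering tools; it differs from the Lance–Williams
"centroid" update (exact only for squared Euclidean distances), which is
why the linkage is implemented in the package and verified in the tests
against a brute-force re-agglomeration oracle. Probes are mean-centered
before clustering (the usual gene-centering step); height inversions are
permitted and counted; trees are cut to the k-cluster partition of the
merge sequence (default 4 sample groups, 4 probe clusters), with labels
assigned in dendrogram leaf order.

Because dendrogram-order labels are arbitrary, the pipeline assigns the
late-recurrence role to the sample group with the largest share of late
events among groups that are more than a stray branch (at least
max(10, 5%) of clustered discovery samples) and that contain at least two
paired-epithelium samples. The analogous probe-cluster role goes to the
cluster holding the most late-direct screen hits.

Enrichment tables use the cross-product odds ratio $ad/bc$, the Woolf
logit interval $\exp(\ln\mathrm{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$
(the literal 1.96 of the classical formula), and the two-sided Fisher
exact p. Zero cells report OR 0 or ∞ with a Haldane–Anscombe 0.5-corrected
CI and a continuity flag.

## Metagene scores

`first_pc_score()` standardizes each probe of a set and scores samples on
the first principal component. PC signs are arbitrary, so orientation is
anchored: the score must correlate nonnegatively with the mean
standardized expression of the set's upregulated probes (all probes when no
directions are supplied). Scores have zero mean over the defining cohort.
By default the loadings are refit on each scoring cohort, matching a
workflow that recomputes the component inside every data set; a
fixed-loadings projection would be the right choice for prospective use of
a frozen signature.

## Differential expression between compartments: pooled versus Welch t

The stroma and cascade stages compare a target subgroup of roughly 7–12
pairs against ~35 at a genome-wide BH FDR of 0.05. At those sizes Welch's
approximation collapses to ~10 degrees of freedom, and even a planted
standardized shift of two cannot reach genome-wide significance; the
classical pooled two-sample t (the default of the desktop statistics
packages this kind of analysis was historically run in) retains ~44 df and
behaves as intended. The pooled test is therefore the default and Welch
remains available (`var_equal = FALSE`). This is a deliberate design
choice, made because the unequal-variance default proved unusable at
exactly the paired-sample sizes the design prescribes.

## The synthetic cohort generator

`generate_cohort()` draws, per tumor sample, two independent latent risk
factors:

* $u_e$ (early risk) and $u_l$ (late/dormancy-escape risk), each a
  standardized two-component mixture from independent binary high/low
  states (P(high) 0.42 and 0.36, separations 2.3 and 2.6, within-state SD
  0.35). The four combinations form good-prognosis, early-recurrence,
  late-recurrence and double-high classes — real prognostic subgroups for
  the clustering stage — while keeping the two axes exactly independent,
  so late genes carry no early-window association.
* Recurrence times follow a piecewise-exponential hazard: baseline 0.045/yr
  multiplied by $e^{\beta_e u_e}$ before the boundary and 0.015/yr
  multiplied by $e^{\beta_l u_l}$ at or after it (defaults
  $\beta_e=\beta_l=0.8$), with administrative censoring at 15 years. Under
  the defaults this yields roughly 25% early and 12% late events,
  comparable to an untreated node-negative cohort.
* Planted early/late probe sets load on their factor with per-probe
  loadings 1.3–1.7 in magnitude, half positive (direct) and half negative
  (inverse), as in real prognostic probe sets. The signed halves matter
  beyond realism: with only positively loaded blocks, the probe-wise
  centering inside the Pearson distance collapses the two-factor geometry
  onto the single contrast $u_e-u_l$ and no clustering could ever separate
  four groups.
* Batch structure: per-study factor scores (centered, orthogonalized, 1.2
  SD spread across studies so no planted factor is degenerate by chance)
  with per-probe loadings of decaying strength (0.5/f), shared by control
  and biological probes; control probes carry only batch plus noise
  (SD 0.1).
* Markers are drawn from two-Gaussian mixtures conditional on the true
  receptor status (itself drawn conditional on subtype so the subtype
  proportions hold), with IHC labels observed for a configurable fraction
  (default 0.5). The planted cutoff recorded in the truth uses the
  realized positive fraction as its prior — the quantity the fitted model
  estimates.
* Paired samples: epithelium samples behave like tumors; the paired stroma
  carries a latent stromal-activation factor
  $v=\rho u_l + \sqrt{1-\rho^2}\,\varepsilon$ (default $\rho=0.8$) that
  drives the planted stromal probes with loadings 2.0–2.5 (about a 2 SD
  shift between late-type pairs and the rest), again half up, half down.

All randomness flows through deterministic per-component sub-seeds of one
integer seed; generating twice with the same seed is bitwise identical.

What the generator does **not** emulate: probe-level (CEL) artifacts,
non-administrative loss to follow-up, competing risks, copy-number or
mutation structure, intra-tumor heterogeneity, and any correlation between
receptor subtype and the latent risk factors. Passing tests therefore
demonstrate that the pipeline recovers the structure it assumes — not that
real cohorts satisfy those assumptions.

## Numerical and edge-case conventions

* Expression tables round-trip exactly (`%.17g` formatting).
* A one-probe metagene degenerates to the standardized probe; probes
  missing from the matrix are an error naming the missing IDs.
* Mann–Whitney comparisons are exact below 25 per group when tie-free,
  otherwise the normal approximation with continuity and tie correction;
  the method used is recorded in the output.
* Fisher exact p-values follow the standard convention of summing
  hypergeometric probabilities not exceeding the observed table's
  (verified against exhaustive enumeration for all tables with n ≤ 40).
* `cox_adjusted()` drops constant covariates, removes collinear ones with
  a warning, and flags fits with fewer than 10 complete cases per
  covariate.
* Tests and examples use cohort sizes of roughly 200–900 samples and
  100–2300 probes; these sizes keep every property detectable (screen
  power, null calibration bands, cluster recovery) while the whole suite
  stays fast.

## Known limitations

* Centroid linkage with correlation distance has no monotonicity
  guarantee; cutting uses the merge sequence, but heavily inverted trees
  can still yield unbalanced groups, and the late-recurrence subgroup can
  be missed in unlucky draws — the pipeline then reports what it found
  rather than forcing a result.
* With only ~46 pairs, the stroma/cascade stages are intrinsically
  variable from seed to seed; the planted-set Jaccard of the cascade
  ranges from ~0.35 to 1.0 across generator seeds under the defaults, with
  the overall-scheme Cox filter (criterion c) the usual bottleneck: the
  overall window mixes the majority early events, which carry no late-risk
  information, into the test. The late-scheme mode of `cascade_select()`
  trades faithfulness to the published criterion for power.
* Wald p-values in the far tail ($p<0.001$) are only approximately
  calibrated below ~100 events, a generic property of partial-likelihood
  asymptotics.
* The screen treats probes marginally; no attempt is made to decorrelate
  co-expressed probes, so selected sets are internally redundant by
  design (the metagene step exploits exactly that redundancy).
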