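# dormsig

Discovery and validation of **late-recurrence (dormancy-escape) gene
signatures** in breast cancer from multi-study expression compendia.

A third of node-negative breast cancer patients followed beyond 10–15
years relapse late — five or more years after primary treatment — yet the
clinical predictors of early relapse (grade, size, basal-like subtype) say
little about it. `dormsig` implements the full discovery workflow for
expression signatures of late recurrence, plus a synthetic multi-study
cohort generator so every stage is testable without downloading anything:

| Stage | Function(s) | Method |
|---|---|---|
| Harmonization | `fit_control_structure()`, `remove_structure()`, `confirm_mixing()` | first 40 (or 15) PCs of the invariant control probes, removed from every probe by factor regression (orthogonal projection) |
| Receptor / subtype calls | `fit_marker_model()`, `call_receptors()`, `assign_subtype()` | two-Gaussian maximum-likelihood mRNA cutoff at the posterior-0.5 point, anchored on partial IHC labels; IHC always wins |
| Survival screen | `censor_early()`, `censor_late()`, `screen_genome()`, `cox_adjusted()`, `clinical_param_cox()` | genome-scale univariable Cox (Efron ties, Wald p) under overall / early / late time-window censoring with a 5-year boundary; discovery at p < 0.001 |
| Subgroups | `cluster_two_way()`, `enrichment_2x2()`, `cluster_category_enrichment()`, `km_logrank()` | true centroid-linkage clustering under 1 − Pearson distance into G1–G4 / C1–C4; cross-product OR with Woolf 95% CI and Fisher exact p; log-rank subgroup survival |
| Stromal signature | `paired_compartments()`, `stromal_de()`, `first_pc_score()`, `trend_across_groups()` | target-subgroup stroma DE at BH FDR < 0.05; SPC1 = oriented first-PC metagene |
| Epithelial signature | `cascade_select()`, `timing_groups()`, `validate_signature()`, `concordance_scores()` | three filters (r > 0.25 with SPC1; subgroup upregulation FDR < 0.05; direct Cox p < 0.01) → EPC1; validated against <5 / ≥5-year metastasis-timing groups |
| Synthetic cohorts | `cohort_spec()`, `generate_cohort()`, `write_cohort()` | piecewise-exponential hazards with separate pre-/post-boundary gene effects, control-probe batch structure, bimodal markers, paired epithelium/stroma with a coupled stromal factor |
| Orchestration | `pipeline_config()`, `run_pipeline()`, `make_report()` | deterministic end-to-end run with tab-delimited outputs and a hash manifest |

The early/late dichotomy is realized by re-censoring: the *early* analysis
censors events at or after the boundary, the *late* analysis censors
events before it, so each event counts in exactly one window. A probe's
direction is *direct* when overexpression carries a positive Cox
coefficient (worse outcome).

## Worked example

```r
library(dormsig)

run <- run_pipeline(pipeline_config(spec = cohort_spec(), seed = 11,
                                    out_dir = "run11"))
```

The default `cohort_spec()` synthesizes 4 studies x 200 bulk tumors plus
46 epithelium/stroma pairs on 2,000 probes (69 control probes, 40 planted
early-recurrence genes, 40 late, 40 stromal). The run above prints, stage
by stage:

```
screen: 43 early-associated, 45 late-associated probes at p<0.001

 G1  G2  G3  G4
201 240   1 181
late-event share by group:
   G1    G2    G3    G4
0.303 0.075 0.000 0.030
G4-like group: G1
stromal probes at FDR<0.05: 46
SPC1 variance explained: 0.77
SPC1 trend across subgroups, ANOVA p: 6.93e-11
cascade signature size: 17
     comparison        p               method
1 none vs early 9.01e-01 normal approximation
2  none vs late 2.63e-13 normal approximation
3 early vs late 1.44e-11 normal approximation
timing-bin ANOVA p: 2.16e-12
C4-PC1 / EPC1 concordance r: 0.998
```

Reading this: the three-scheme screen recovers the planted prognostic
probes; clustering the selected probes splits the cohort into subgroups,
and the group with the highest share of late events (G1 here — labels are
dendrogram order, the role is earned by late-event share) plays the
late-recurrence role. Its paired stroma shows 46 differentially expressed
probes whose metagene (SPC1) rises monotonically across the
outcome-ordered subgroups; the cascade then finds 17 epithelial probes
correlated with SPC1, upregulated in the late group, and directly
prognostic. Their metagene (EPC1) is higher in tumors that metastasized
late than early (Mann–Whitney p = 1.4e-11) and tracks the late probe
cluster's own metagene almost perfectly (r = 0.998).

Enrichment statistics work on plain counts, e.g. a subgroup holding 85 of
88 members of one subtype against 449 of 676 outside:

```r
enrichment_2x2(85, 3, 449, 227)
#> 2x2 enrichment: OR 14.3244 (95% CI 4.4797 - 45.8044), Fisher p 4.9e-11
```

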