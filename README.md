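# molrules

Interpretable substructure-rule mining for small molecular
structure–activity datasets.

`molrules` is built for the situation where a catalyst (here, an
Fe-loaded metal–organic layer) is tuned by a few dozen carboxylic-acid
surface modifiers, and the question is *which structural features of the
modifier drive activity*. Instead of fitting a black box to 36 samples,
the package treats hypotheses as explicit, testable rules:

1. **Rules** are ordered clauses of SMARTS substructure predicates with a
   predicted direction, plus an optional applicability scope. Compiled
   against a molecule, a rule yields `+1` (applies, predicts high yield),
   `-1` (applies, predicts low), or `0` (irrelevant) — so a rule set
   becomes a samples × rules ternary **feature matrix**.
2. **Association statistics** score each rule against median-binarised
   yield labels: support `|A|/n`, confidence (fraction of applied samples
   predicted correctly), lift (confidence over the baseline rate of the
   predicted classes) and leverage (excess correct-prediction frequency
   over independence, bounded in ±0.25). Under label permutation,
   lift centres at 1 and leverage at 0.
3. A **small-sample ML harness** validates rule matrices with the designs
   appropriate at n ≈ 36: leave-one-out over multiple seeds, balanced
   leave-P-out (test sets of 2 high + 2 low drawn from the full
   combinatorial pool), greedy forward selection by training-set LOO
   accuracy, RFECV, and seeded permutation importance on extra-trees /
   random-forest ensembles (`ranger`).
4. An **iterative multi-role refinement loop** (rule generator, commenter,
   advisor, matrix generator/checker, metric and ML evaluators, project
   manager) automates rule revision against a pluggable chat backend.
   Scripted transcripts make the loop fully deterministic and offline;
   matrix compilation and all numerics are computed in-process, never by
   the backend.
5. A **synthetic-data generator** plants known substructure rules in
   scaffold × substituent libraries with a latent activity model
   `latent = beta_fe * fe_loading + sum_r beta_r * indicator_r + noise`,
   giving every stage a recoverable ground truth.
6. **Fragment-pooled descriptors** (mean Gasteiger PEOE charge,
   Crippen LogP/MR, LabuteASA and TPSA contributions over 2/4/6-bond
   shells around the carboxylate anchor) provide a traditional-descriptor
   baseline, with deterministic correlation pruning.

SMARTS matching runs in-process through OpenBabel
(ChemmineR/ChemmineOB); per-atom descriptor contributions come from a
bundled RDKit (Python) helper. The test-suite cross-checks every compiled
matrix against an independent RDKit substructure-enumeration oracle.

## Worked example

The package ships a reference rule — *para-substituted benzoic acids with
electron-withdrawing, metal-coordinating groups yield high;
electron-donating or noncoordinating groups yield low* — and a 12-modifier
example dataset:

```r
library(molrules)

ds  <- example_modifier_dataset()
fit <- rulefit(para_ewg_rule(), ds, model = model_spec(seed = 1))
summary(fit)
#> rulefit: 1 rule(s) on 12 molecules
#>   loo accuracy 0.667 +/- 0.000
#>
#> Association metrics per rule:
#>  rule_id support confidence lift leverage n_applied undefined
#>       r2   0.667      0.875 1.75    0.125         8     FALSE
#>
#> Feature importances (permutation):
#> fe_loading         r2
#>     0.1955     0.0342
```

The rule applies to 8 of 12 modifiers (support 0.667) and predicts 7 of
those 8 correctly (confidence 0.875, lift 1.75 — 75% better than the
baseline class rate). Leave-one-out accuracy of the extra-trees model on
{rule, Fe-loading} is 0.667 on this deliberately small example set.
Prediction on new molecules follows the compiled rule features:

```r
predict(fit, c("OC(=O)c1ccc(Cl)cc1",    # para-chloro  -> rule -1
               "OC(=O)c1ccc(NC)cc1"))   # para-NHMe    -> rule +1
#> [1] low  high
```

The refinement trajectory that produced the rule can be replayed
deterministically from the bundled scripted transcript:

```r
st <- run_loop(ds, scripted_backend(replay_messages()),
               loop_config(model = model_spec(seed = 1)))
st
#> refinement loop state: iteration 4 (stopped: manager acceptance)
#>   accuracy history: 0.500 -> 0.500 -> 0.500 -> 0.500
#>   revisions: r2=3
#>   transcript: 72 messages; 0 protocol violation(s)
```

A thin command-line front end mirrors the main operations
(`validate`, `label`, `rulematrix`, `agreement`, `metrics`, `featurize`,
`evaluate`, `simulate`, `run-loop`); see
`system.file("scripts", "molrules", package = "molrules")`.

## Package layout

- `R/` — dataset I/O and labelling, the SMARTS rule engine, association
  metrics, the ML harness, fragment descriptors, the refinement loop,
  the synthetic generator, and the `rulefit` model interface.
- `inst/python/fragment_descriptors.py` — per-atom property backend.
- `inst/scripts/molrules` — command-line front end.
- `vignettes/rule-mining.Rmd` — the methods vignette: model definitions,
  parameter choices, numerical conventions and limitations.
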