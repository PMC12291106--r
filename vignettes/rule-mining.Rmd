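---
title: "Mining and validating substructure-activity rules on small modifier datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and validating substructure-activity rules on small modifier datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molrules)
```

## The problem

Surface modification of a metal-organic-layer (MOL) photocatalyst with
carboxylic-acid modifiers changes its activity in C(sp3)-H activation, but
the datasets are tiny — a few dozen modifiers, each described by a SMILES
string and a handful of experimental features (Fe-loading, modifier/SBU
ratio, Fe/Hf ratio) with a measured yield. At this scale, black-box models
overfit and tell you little about chemistry. `molrules` takes the opposite
route: hypotheses are *explicit substructure rules* ("para-substituted
benzoic acids with electron-withdrawing, metal-coordinating groups yield
high"), compiled into ternary features, scored with association statistics,
and stress-tested with cross-validation designs built for very small n.
An iterative multi-role refinement loop — generator, commenter, advisor,
matrix builder/checker, metric and ML evaluators, project manager — can
drive the rule revision automatically against a pluggable chat backend,
and is fully replayable offline from scripted transcripts.

## Data model and labelling

A dataset is a plain `data.frame` (class `modifier_dataset`) with columns
`id`, `smiles`, `yield_percent`, `fe_loading`, `modifier_sbu`, `fe_hf`
(optionally `name`, `ton`). Yields are binarised at the median:
**strictly above** the median is `"high"`, ties go to `"low"`. Strictness
makes the rule deterministic; with distinct yields the split is within one
sample of balance. Labels use the standard order-statistic median
(middle value, or mean of the two middle values).

```{r}
ds <- example_modifier_dataset()
table(ds$label)
```

## Declarative rules and the ternary encoding

A rule is an ordered list of clauses, each a substructure predicate with a
predicted direction, plus an optional scope predicate:

* `+1` — the rule applies and predicts high yield,
* `-1` — the rule applies and predicts low yield,
* `0` — the rule is irrelevant (scope fails, or no clause matches).

Predicates are SMARTS leaves composed with `and` / `or` / `not` and a
unique-match-count threshold (`count_ge`). Clause order is precedence:
the **first matching clause wins**, mirroring the if/else-if structure of
executable rule encodings; permuting non-overlapping clauses cannot change
the output, and overlapping clauses follow authored order. This
"code mode" — interpreting a formal encoding rather than letting a
language model fill the matrix in directly — is the package's canonical
path; free-text ("linguistic") matrix generation is supported only through
scripted transcripts, since interpreted encodings are reproducible and
empirically far more reliable.

Two definitional choices deserve emphasis:

* **Para** means 1,4-disubstitution on a six-membered aromatic carbocycle,
  expressed in anchored SMARTS (the carboxyl-bearing ring atom and the
  atom three ring bonds away). Ortho or meta placement of the same group
  does not satisfy a para-scoped clause and scores 0.
* Molecules are treated as neutral, explicit-H-free graphs; there is no
  tautomer or protonation-state enumeration. SMARTS matching uses unique
  (deduplicated) matches. Matching is done in-process through OpenBabel
  (ChemmineR/ChemmineOB). A practical dialect note: OpenBabel matches the
  classic nitro pattern `[NX3](=O)=O` on the uncharged written form
  `N(=O)=O`, so the bundled examples write nitro groups that way; the
  built-in rule also carries the charge-separated pattern
  `[N+](=O)[O-]` so both conventions are covered. The test-suite
  cross-checks every compiled matrix against an independent RDKit
  enumeration oracle.

```{r}
compile_rule(para_ewg_rule())(c("Nc1ccc(C(=O)O)cc1",  # 4-aminobenzoic
                                "Cc1ccc(C(=O)O)cc1",  # 4-methylbenzoic
                                "CC(=O)O"))           # acetic: out of scope
```

## Association metrics

For a rule column $c \in \{-1,0,1\}^n$ against labels $y$, with applied
set $A = \{i : c_i \neq 0\}$ and $\mathrm{correct}(i)$ meaning the signed
prediction matches the label:

* support $= |A|/n$;
* confidence $= \#\mathrm{correct}/|A|$;
* baseline $=$ the mean, over applied samples, of the full-dataset rate of
  the class the rule predicts for that sample (so a rule that always
  predicts the majority class has a high baseline);
* lift $=$ confidence / baseline;
* leverage $=$ the mean of the two one-sided association-rule leverages,
  $\mathrm{lev}(k) = P(\hat y = k \wedge y = k) - P(\hat y = k)P(y = k)$
  for $k \in \{\mathrm{high}, \mathrm{low}\}$.

The averaged leverage is bounded in $[-0.25, 0.25]$, reduces to the
classic definition for a one-directional rule, and is null-centred at 0
(lift at 1) under label permutation — properties the tests verify by
simulation. A rule that applies to no sample gets explicit `undefined`
flags rather than silent `NaN`s, so downstream commentary stages can
reason about it. No multiple-testing correction is applied across rules.

## The small-sample ML harness

The validation protocol is deliberately conservative for n around 36:

* **Extra-trees / random-forest** classifiers via `ranger`
  (100 trees, unlimited depth, single-threaded, seeded — hyperparameters
  are recorded in every report). Probability ties at 0.5 resolve to
  `"low"`, a deterministic negative-class preference.
* **Leave-one-out** (`loo_eval`): n single-sample splits per seed;
  headline accuracy is mean ± sd across seeds (the sd across splits is
  also exposed, since either convention appears in practice).
* **Balanced leave-P-out** (`lpo_balanced_splits`): test sets of P = 4
  with exactly 2 high + 2 low, sampled uniformly without replacement from
  the full combinatorial pool (for 9 + 9 labels the pool is
  $\binom{9}{2}^2 = 1296$); asking for more than the pool errors with the
  maximum.
* **Forward selection** by LOO accuracy on the training set, greedy with
  ties broken by column order, stopping on no strict improvement or a cap
  of 5 features (the cap is a termination guard; analyses typically track
  the top three).
* **RFECV** (`rfecv_select`): recursive elimination (step 1) scored by
  stratified 5-fold CV accuracy; ties prefer the smaller subset.
* **Attribution** uses seeded permutation importance (ranger's
  out-of-bag permutation measure); the backend name travels with every
  report. Tree-Shapley attribution is a drop-in alternative where an
  implementation is available; rankings, which are what the refinement
  loop consumes, agree for the dominant-feature questions asked here.

Feature scaling is immaterial for tree models and is not performed.

## Fragment-pooled descriptors

The traditional-descriptor baseline averages five per-atom properties —
Gasteiger PEOE partial charge, Wildman-Crippen LogP and MR contributions,
Labute approximate surface area, and TPSA contributions — over *fragment
levels*: bond-radius shells of 2, 4 and 6 bonds around the carboxyl
carbon (the atom through which every modifier anchors to the Hf cluster).
Radius shells are this package's operational definition of fragment
levels: they are deterministic, nested by construction, and configurable;
other fragmentation conventions exist and users can substitute their own
radii. In the whole-molecule limit the pooled TPSA mean times the atom
count recovers the standard molecular TPSA exactly, which the tests use
as an anchor. Per-atom contributions come from a bundled RDKit helper
invoked once per batch of molecules. Quantum-chemistry descriptors
(DFT/ESP) and 3D/conformer properties (e.g. SASA) are out of scope.
Redundancy pruning (`prune_correlated`) is a deterministic greedy scan —
for each pair with |Pearson r| above 0.95 the later column is dropped —
replacing any manual curation step for reproducibility.

## The refinement loop

Ten roles participate. The generator and commenter see only the current
round; the advisor and manager see the full history. Conversational
roles exchange messages that must contain **exactly one JSON payload**
(fenced block or bare JSON; surrounding prose is tolerated, because chat
models emit commentary). A malformed payload is retried once with the
error echoed back; a second failure is recorded as a protocol violation
and the round does not advance — no stage is ever silently skipped. The
matrix compilation, association metrics and cross-validated accuracy are
computed in-process each round, never delegated to the backend.

Stopping combines three conditions: manager acceptance; a revision
threshold (any rule revised more than 3 times while the last round
improved accuracy by less than epsilon = 0.01, both configurable); and a
hard iteration cap. On stop, the final matrix receives a leave-one-out
evaluation.

The bundled `replay_messages()` fixture replays a four-round refinement
of one rule: an EWG-only wording, an EDG/bulky extension, a shift to
metal coordination, and the final merged wording. Its first three rounds
deliberately carry mis-anchored (meta-substitution) SMARTS encodings that
match nothing — a classic authoring mistake surfaced by the matrix
checker — before the final round anchors the para position correctly.
With a scripted backend the entire loop is deterministic and offline.

```{r}
st <- run_loop(example_modifier_dataset(),
               scripted_backend(replay_messages()),
               loop_config(model = model_spec(seed = 1)))
st
```

## The synthetic generator

`synthetic_spec()` emulates the study conditions: 36 modifiers assembled
from para/meta/ortho benzoate, aliphatic-acid and alpha-amino-acid
scaffolds crossed with nine substituents (amino, nitro, bromomethyl,
methyl, methoxy, hydroxy, formyl, sulfanyl, fluoro). Yields follow

$$\mathrm{latent} = \beta_{Fe}\,\mathrm{Fe} + \textstyle\sum_r \beta_r\,
\mathrm{ind}_r + \varepsilon,\qquad \varepsilon \sim N(0, \sigma)$$

with Fe-loading uniform on (0.5, 2.0) arbitrary units, $\beta_{Fe} = 1$,
a planted para-EWG rule at $\beta = 1.5$ (dominant) and $\sigma = 0.5$,
mapped to (0, 100) by a scaled logistic centred on the latent mean —
monotone, so median binarisation is well defined. Libraries are sampled
so the planted rule covers at least two molecules per direction.

What the generator does *not* emulate: real measured yields, solvent or
loading chemistry, or any mechanism — it is a statistical stand-in.
Passing recovery tests therefore show that the pipeline can find a
planted signal at the study's scale and noise level, not that it would
find the real one; conversely a real dataset brings correlated
descriptors and label noise the generator only caricatures.

## Numerical choices and degenerate inputs

* Every stochastic step takes an explicit seed; reports list their seeds
  and model settings. Repeated runs are bit-identical (ML stages up to
  floating point).
* Zero-coverage rules: flagged by `check_matrix`; metrics carry
  `undefined` flags. All-constant feature candidates: forward selection
  returns an empty selection rather than crashing.
* Problem sizes in the tests and acceptance script: n = 36 datasets,
  20-seed recovery experiments, 1000-permutation nulls, 50-split
  leave-P-out plans, nine-seed LOO reports.

## Limitations

* SMARTS dialects differ at the margins (hypervalent nitro being the
  canonical example); the package pins OpenBabel semantics and documents
  the nitro convention, with an RDKit oracle guarding the fixtures.
* The refinement loop's live-backend contract is defined but the core
  package never performs network calls; only scripted transcripts are
  exercised.
* Association metrics are descriptive, not inferential — with a few dozen
  samples, lift and leverage fluctuate; the permutation machinery is
  there to calibrate expectations, not to produce p-values.
* Fragment levels are a radius-shell interpretation; absolute descriptor
  values depend on it, though the nesting and whole-molecule limits hold
  for any increasing radii.
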