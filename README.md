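# dropoutBN

Causal analysis of teenage pregnancy and school dropout with discrete
Bayesian networks.

Teenage pregnancy cannot be randomized, so its effect on school enrollment
must be estimated from observational interview data. dropoutBN implements
the full workflow used in adolescent-health survey analysis for this
question, aimed at epidemiologists and public-health analysts working with
small interview datasets:

* **Preprocessing** of raw interview records: median imputation, restriction
  to female respondents, seed-controlled class balancing on pregnancy
  status, and binarization of seven attributes — `Age` (≥15 yrs), `EG`
  (white / non-white), `TP` (ever pregnant), `MF` (mother experienced
  teenage pregnancy), `ES` (family income ≥ US$780/month), `SS` (enrolled),
  `LS` (employed).
* **Structure from experts**: majority-vote aggregation of per-expert edge
  assertions into a consensus DAG (with direction-conflict and cycle
  repair), plus a phi-coefficient correlation table annotated for spurious
  correlations by DAG reachability.
* **Exact inference** on the network `P(x_1..x_n) = Π_k P(x_k | pa(x_k))`:
  variable-elimination conditional queries, and max-product MAP profiles.
* **Causal estimation** via the do-operator: graph surgery, the backdoor
  adjustment formula `P(Y=y|do(X=x)) = Σ_z P(Y=y|X=x,Z=z) P(Z=z)`, and
  average causal effects `ACE = P(Y=y|do(X=x_i)) − P(Y=y|do(X=x_j))`, with
  backdoor-admissibility diagnostics and loud positivity failures.
* A **calibrated synthetic-record generator** (ancestral sampling from a
  ground-truth network whose exact marginals reproduce the published
  descriptive statistics) so every stage runs and is testable without the
  original deposited data.

## Worked example

A complete synthetic run — generate records, preprocess, fit the network on
the balanced table, and answer the standard query set:

```r
library(dropoutBN)

cfg <- run_config(generator = default_config(n_records = 2000, seed = 7),
                  seed = 7)
report <- run_pipeline(cfg)
print(report)
#> == dropoutBN run report (v0.1.0, seed 7) ==
#> rows: 2000 loaded -> 1712 female -> 1490 balanced
#> marginals (state 1): Age 70%, EG 53%, TP 50%, MF 59%, ES 22%, SS 65%, LS 15%
#> ACE of TP on SS=0 adjusted for Age: 0.46 (p_do: 0.584 vs 0.124)  [set not backdoor-admissible]
#> ACE of TP on SS=0 adjusted for ES: 0.48 (p_do: 0.596 vs 0.121)  [set not backdoor-admissible]
#> ACE of TP on SS=0 adjusted for EG: 0.48 (p_do: 0.595 vs 0.118)  [set not backdoor-admissible]
#> P(TP=1 | MF=1) = 0.596
#> MAP given SS=0: Age=1 EG=0 TP=1 MF=1 ES=0 SS=0 LS=0  (p = 0.0658)
```

Reading the output: after imputation, male exclusion and balancing, the
pregnancy attribute is 50/50 by construction. The three ACE lines estimate
the effect of teenage pregnancy (`TP`) on being *out* of school (`SS=0`),
each adjusting for a single covariate as in the original analysis — around
+0.46–0.48, i.e. pregnancy raises the probability of non-enrollment by
almost fifty percentage points (the flag notes that a single covariate does
not block every backdoor path in this DAG; the spread across the three
adjustments is informative). The maternal-transmission query puts the
probability of teenage pregnancy at ~0.60 given the mother's own history,
and the MAP line is the most probable profile of a girl out of school:
at least 15, white, ever pregnant, with maternal history, low family
income, not working.

Individual stages are available as plain functions (`load_raw_records()`,
`impute_missing()`, `exclude_males()`, `balance_on_attribute()`,
`binarize()`, `aggregate_consensus_dag()`, `fit_cpts()`, `query()`,
`map_assignment()`, `intervene()`, `adjustment_probability()`,
`average_causal_effect()`, …), and a thin command-line front end with
`simulate` / `preprocess` / `consensus` / `analyze` / `compare` verbs lives
at `inst/cli/dropoutbn.R`. See the vignette
(`vignettes/causal-dropout-analysis.Rmd`) for the modelling assumptions,
calibration of the generator, and known limitations.

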