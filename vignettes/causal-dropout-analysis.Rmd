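---
title: "Causal analysis of teenage pregnancy and school dropout with discrete Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal analysis of teenage pregnancy and school dropout with discrete Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropoutBN)
```

## The problem and the modelling approach

Teenage pregnancy and school dropout are entangled with age, ethnicity,
family income, employment and family history, and none of these can be
randomized. dropoutBN implements the observational strategy used in
adolescent-health survey work: a *discrete Bayesian network* whose structure
(which variable may directly influence which) comes from domain experts and
whose probabilities come from interview data, queried through the
*do-operator* so that interventional, not merely associational, questions
can be answered.

The seven analysis attributes are binary: `Age` (1 = at least 15 years),
`EG` ethnic group (0 = white), `TP` teenage pregnancy (1 = at least one
pregnancy, abortions included), `MF` maternal impact factor (1 = the
respondent's own mother experienced teenage pregnancy), `ES` economic
status (1 = family income at least US\$780/month), `SS` school enrollment
(1 = enrolled), and `LS` labor status (1 = employed).

A network over nodes $X_1,\dots,X_n$ with parent sets
$\mathrm{pa}(X_k)$ induces the joint
$$P(x_1,\dots,x_n)=\prod_{k=1}^{n} P\!\left(x_k \mid \mathrm{pa}(X_k)\right),$$
valid under the Markov condition (each variable independent of its
non-descendant non-parents given its parents). All inference in the package
is exact: conditional queries use sum-product variable elimination, most
probable completions (MAP) use max-product elimination with traceback, and
both are continuously cross-checked against exhaustive enumeration in the
test suite at a tolerance of 1e-9. With at most a dozen binary nodes all
arithmetic is done in linear (not log) space; the smallest joint
probabilities involved are around $10^{-3}$, far from underflow.

## The preprocessing protocol

Raw interview records carry age in years, sex, a free-text ethnicity
self-declaration, a pregnancy count, the maternal history flag, enrollment,
monthly family income in USD and an employment flag. Ages outside the
adolescence window of 12 to 18 years are rejected at load. The pipeline
applies four stages in a fixed order:

1. **Imputation.** Missing numeric values receive the column median of the
   observed values; binary flags are encoded 0/1 first. A median that lands
   exactly on 0.5 (an even split) is rounded down to 0, with a warning —
   the protocol needs *some* deterministic rule and the conservative choice
   avoids inventing the rarer state. Sex is the downstream exclusion key
   and is imputed by the column mode instead, since a "median sex" is not
   meaningful. Ethnicity strings pass through an explicit, case-insensitive
   white/non-white lookup; unmapped strings raise an error rather than
   silently becoming non-white.
2. **Exclusion.** The analysis is restricted to female respondents:
   pregnancy bears on girls directly, and the male share of the interviews
   is small.
3. **Balancing.** The never-pregnant and ever-pregnant groups are equalized
   by randomly undersampling the majority group without replacement. The
   subset is controlled by a seed that is recorded in the run report, so a
   run is exactly reproducible. Already balanced input passes through
   unchanged.
4. **Binarization.** Thresholds are inclusive upward (`value >= cut` is
   state 1): 15 years for `Age` (the midpoint of the adolescence window),
   US\$780/month for `ES` (about three minimum wages at the study period,
   and the sample median), one pregnancy for `TP`.

Imputation runs before exclusion so that records lacking the sex field are
not silently discarded; this ordering is a design choice of this package
(either order is defensible) and changing it changes the result only
through records whose sex was missing.

After balancing, the pregnancy attribute is 50/50 *by construction*; its
marginal in any downstream table is a consequence of the design, not a
finding.

## Structure from experts

Each expert contributes a set of directed edges ("this attribute can
causally influence that one"). The consensus rule is a simple majority by
default (configurable): an edge enters the graph when at least half of the
experts asserted it. If both directions pass, the better-supported one is
kept; an exact tie drops both, with a warning. A majority vote over
directed edges can still produce a cycle, so the aggregator repeatedly
removes the lowest-voted edge inside a strongly connected component until
the graph is acyclic, logging every repair. Majority is the
minimal-assumption reading of "consensus"; the threshold is exposed so
stricter notions can be used, and raising it can only shrink the edge set.

The correlation table computes the Pearson coefficient (equivalently, the
phi coefficient on 0/1 data) for every attribute pair. Pairs with no
directed path between them in either direction in the consensus DAG are
annotated **SC** — spurious correlation, an association the structure does
not attribute to causation. This reachability rule is a replaceable
*policy*: how the original analysts decided their SC labels is not
documented, and the raw coefficient is always retained alongside the flag
so users can re-annotate. Notably, a graph-reachability rule never flags a
pair connected through a directed chain (for example maternal history
acting on enrollment through pregnancy), whereas published tables sometimes
do; the discrepancy is inherent to any mechanical rule.

The default network shipped with the package connects `MF` to `TP`; `Age`,
`EG` and `ES` to both `TP` and `SS`; `TP` to `SS`; and `ES` to `LS`. This
is a *reconstruction* supported by the textual description of the study
design — the full published figure is not machine-readable — and any
faithful reproduction should supply its own transcription through
an edge-list file or survey data.

## Probabilities from data

CPTs are fitted by maximum likelihood with an optional Laplace
pseudocount: $(n(x,\pi)+a)/(n(\pi)+a\cdot|\mathcal{X}|)$. The module
default is $a = 0$ (pure MLE), and a parent configuration never observed in
the data is then a hard error naming the configuration — silently emitting
a uniform row would contaminate downstream causal estimates without any
trace. The *pipeline* default is $a = 1$: a balanced survey-scale table
(a few hundred rows against 16-row parent spaces) routinely leaves one or
two rare configurations empty, and one pseudo-observation per cell is the
standard mild regularizer.

## Interventions and effects

`intervene()` performs graph surgery: edges into the treatment are cut and
its CPT becomes a point mass. `adjustment_probability()` instead evaluates
the backdoor formula on the *unmutilated* network,
$$P(Y=y \mid do(X=x)) = \sum_z P(Y=y \mid X=x, Z=z)\, P(Z=z),$$
and the average causal effect of a binary contrast is
$ACE = P(Y=y\mid do(X=x_i)) - P(Y=y\mid do(X=x_j))$. When the adjustment
set equals the treatment's parents the two routes agree exactly, which the
test suite exploits as a cross-check on 200 random networks.

The default report mirrors the published analysis: three *single-variable*
adjustments (Age, ES, EG) for the effect of pregnancy on being out of
school. Under the reconstructed DAG none of these singletons blocks every
backdoor path (for example `TP <- ES -> SS` stays open when adjusting for
Age alone), so each report entry carries an admissibility flag computed by
d-separation in the treatment-pruned graph. The package warns rather than
refuses: the published sets are taken as given, and the spread among the
three estimates is itself informative. A stratum of the adjustment set in
which the treatment state never occurs (a positivity violation) is a hard
error naming the stratum, because silently dropping strata changes the
estimand.

MAP completions break exact ties (within 1e-12) canonically — the
lexicographically smallest assignment by variable name, earlier states
first — and warn, since a reported "typical profile" should not hide
non-uniqueness. Random continuous CPTs make ties a measure-zero event; they
arise mainly from hand-built degenerate tables.

## The synthetic generator

The generator emulates the *shape* of the interview data so that every
stage is testable without the deposited records: ancestral sampling of the
seven binary attributes from a configurable ground-truth network, raw-value
emission (years, dollars, counts, ethnicity strings) consistent with the
binarization thresholds, an independent sex draw (male fraction 0.143, the
published share), and missingness injected completely at random (default
2% per cell, a typical interview-survey rate; the original missingness
mechanism is undocumented).

The default ground truth was calibrated *once*, offline, by solving
logistic-style CPTs so that exact inference reproduces the published
descriptive marginals (Age 0.70, EG 0.52, MF 0.57, ES 0.24, SS 0.66,
LS 0.16) within rounding, a pre-balancing pregnancy rate of 130/294, a
surgical effect of pregnancy on non-enrollment of 0.46 (the midpoint of the
published adjusted estimates), and a post-balancing maternal-transmission
probability of 0.58. The solved values are stored explicitly in the source,
not re-derived at run time. Emission ranges (ages 12–14 vs 15–18, incomes
0–779 vs 780–2600, pregnancy counts concentrated on 1) are package choices
of realistic raw values; `roundtrip_check()` verifies they binarize back to
the sampled states, including at the inclusive boundaries 15 and 780.

What the generator does **not** emulate: respondent-level realism (it is
explicitly synthetic), associations outside the reconstructed structure
(the published tables show, for instance, an age–labor association that the
reconstruction has no path for), non-random missingness, and any
male-specific attribute distribution (male records use the same model; they
are excluded downstream anyway). Passing tests therefore demonstrate that
the *machinery* recovers what it generated, not that the reconstruction is
the true social mechanism.

Two empirical behaviours of the default configuration are worth knowing,
both surfaced by the test suite and the acceptance script:

* **Parameter recovery at rare strata.** The four-parent CPTs contain
  configurations carrying under 1% of the population mass. At 20,000
  records such a stratum holds on the order of 100–300 rows, where the
  binomial standard error of an MLE cell is 0.02–0.04 — so demanding every
  fitted entry within 0.02 of truth at that sample size fails with high
  probability for purely statistical reasons (roughly $10^5$ rows would be
  needed). Functionals that average over strata are far better behaved: the
  fitted network's causal effect lands within 0.01 of the ground truth at
  the same sample size.
* **Near-tied attributes under median imputation.** In the dropout profile
  (MAP given non-enrollment) the ethnicity coordinate is nearly tied: the
  exact posterior is 0.523 white vs 0.477 non-white. Median imputation
  sends *every* missing ethnicity cell to the majority state (non-white),
  which is enough systematic push to flip that single coordinate in fitted
  networks when missingness is present; with complete data the sampled MAP
  matches the exact one on all seven attributes. This is a property of
  median/mode imputation on near-tied binaries, not of the inference.

## Verification scale

The shipped tests run at sizes chosen to make the checks sharp but quick:
200 random networks of up to 8 nodes for the inference-vs-enumeration and
adjustment-vs-surgery equivalences (tolerance 1e-9), 20,000-record samples
for effect-recovery checks (tolerance 0.03 on the ACE), 50,000 draws for
law-of-large-numbers checks on marginals (0.01) and on a two-parent CPT
(0.02, a size at which every stratum is well populated), and study-scale
(343-record) fixtures for the preprocessing arithmetic.

## Limitations

No structure learning (structure is elicited, by design), no continuous
attributes, no approximate inference (unnecessary at this scale), and no
counterfactual (twin-network) queries — the framework stops at
interventional distributions. Estimates inherit all the usual caveats of a
small, regionally specific observational sample; the package's aim is a
transparent, reproducible computation, not a stronger epidemiological
claim.
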