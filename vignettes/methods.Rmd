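---
title: "Methods: comorbidity association rules from discharge records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comorbidity association rules from discharge records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbidrules)
```

## The analysis

`comorbidrules` treats a hospital discharge cohort as a market-basket
problem. Each patient contributes one *transaction*: the set of distinct
ICD-10 intermediate blocks among their additional diagnoses, with the
principal diagnosis excluded. Patients with no comorbidity contribute an
empty transaction that still counts in the denominator `n` of every
support computation — prevalences and rule supports are fractions of the
whole stratum, not of the comorbid subset.

For a rule $A \rightarrow B$ in a stratum of $n$ patients:

$$\mathrm{supp} = \frac{n(A \cup B)}{n}, \qquad
  \mathrm{conf} = \frac{\mathrm{supp}(A \cup B)}{\mathrm{supp}(A)}, \qquad
  \mathrm{lift} = \frac{\mathrm{supp}(A \cup B)}
                       {\mathrm{supp}(A)\,\mathrm{supp}(B)},$$

$$\mathrm{IS} = \sqrt{\mathrm{supp} \times \mathrm{lift}}
             = \frac{P(A,B)}{\sqrt{P(A)\,P(B)}}.$$

The IS (interest-support) scale is the cosine measure: it screens out
rules that are high in only one of support and lift, and is the ranking
key for the final tables. We implement IS as
$\sqrt{\mathrm{supp}\times\mathrm{lift}}$ deliberately: this is the form
consistent with every published rule table we reproduce (the printed
product form does not reproduce those values), and it is the standard
definition of the measure in the rule-mining literature.

Mining proceeds stratum by stratum over the seven principal-diagnosis
subgroups (dementia F00–F03 through adult personality disorders F60–F69)
plus the pooled `ALL` stratum. For each stratum the pipeline is
`encode_transactions()` → `apriori()` → `generate_rules()` →
`rank_rules()`, wrapped by `mine_subgroup()`.

## The block universe

Comorbidities are analysed at the ICD-10 *intermediate block* level — a
contiguous range of three-character categories such as I10–I15
"Hypertensive diseases". The shipped default table
(`default_block_table()`) is the WHO ICD-10 block list, 253 blocks, at the
granularity the analysis tables use: dementia (F00–F03) is split from the
remaining organic mental disorders (F04–F09), while composite blocks such
as M00–M25 *Arthropathies*, E70–E90 *Metabolic disorders* and Z80–Z99 are
kept whole. The Korean KCD-7 classification underlying the source registry
has 267 intermediate categories, including Korea-specific codes whose
enumeration is not published; the default table is therefore a faithful
ICD-10 stand-in, and any other universe can be supplied as a
`start,end,label` CSV via `read_block_table()`. Blocks must be pairwise
disjoint; the tests verify disjointness by exhaustive scan over all 2,600
(letter, category) pairs.

Codes that fall outside every block are dropped from transactions but
*counted*: silent loss would corrupt support denominators invisibly, so
`encode_transactions()` and `frequent_blocks()` report the number of
unmapped codes as an attribute. Subdivision digits are ignored (`I10.0`
maps like `I10`), since the intermediate classification operates on
three-character categories; the parser accepts both 3- and 4-character
codes because record formats vary.

## Eligibility and descriptive statistics

`build_cohort()` applies the study's rules: discharge year 2006–2016, age
≥ 19 at discharge, and a principal diagnosis inside the seven subgroups
(F04–F09, F70–F79, F80–F89, F90–F98, F99 and all non-F codes are
excluded). A filter report records how many records each rule removed.

Two conventions matter for reproducing the descriptive tables:

* **Chi-square without continuity correction.** The
  comorbidity-distribution tests are Pearson chi-squares with
  $df=(r-1)(c-1)$ and no Yates correction — the corrected statistic does
  not reproduce the published 2×2 values. `chi_square()` wraps
  `stats::chisq.test(correct = FALSE)` behind marginal-validity checks;
  the tests verify it against the direct $\sum (O-E)^2/E$ sum.
* **Welch t from summaries.** Group comparisons of age and length of stay
  use the unequal-variance t statistic with Welch–Satterthwaite degrees of
  freedom, computed from printed means, SDs and group sizes
  (`welch_t()`); the statistic is (mean~with~ − mean~without~)/SE. No base
  R function accepts summary statistics, so the two-line formula is
  implemented directly.
* **Counting levels.** The mean "number of comorbidities" is a
  diagnosis-level count (distinct additional codes per patient);
  block-level deduplication applies only to transactions and the block
  frequency table, where a patient contributes at most 1 to a block
  however many of their codes fall inside it.

Percentages are reported to 2 decimals and rule metrics to 3, rounded
half away from zero (base `round()` is round-half-even, which disagrees
with the published table convention on boundary values); all filtering,
ranking and comparisons use full precision, and rounding happens only at
output. This matters in practice: the dementia-stratum IS value 0.472 is
only obtained from the *unrounded* support 152/1361.

## Mining parameters

`mining_params()` collects the thresholds:

| parameter | default | role |
|---|---|---|
| `min_support` | 0.01 | floor on rule support (fraction of the stratum) |
| `min_confidence` | 0.1 | floor on confidence |
| `min_lift` | 1 | *strict* lower bound: lift must exceed it |
| `max_itemset_size` | 3 | largest itemset mined; antecedents ≤ 2 items |

The support floor of 0.01 is a deliberate choice: over 250+ candidate
blocks a "support > 0" rule set is computationally and substantively
indiscriminate, and every rule in the published tables sits at or above
0.010. The lift filter is strict (`> 1`), so a rule exactly at
independence is rejected. Consequents are always single items, matching
the reported rule form; both directions of a two-block pair are emitted
whenever both pass confidence, and for such pairs lift and IS are
necessarily equal in the two directions (an identity the test suite
asserts over every mined rule). Ties in the IS ranking are broken by
descending support, then by the rule label in C-locale order, so output
is deterministic.

`apriori()` is the package's own level-wise implementation: size-k
candidates by prefix join of the frequent (k−1)-itemsets, pruning of any
candidate with an infrequent (k−1)-subset, exact counting against a 0/1
incidence matrix. Itemsets occurring in no transaction are never reported,
even at `min_support = 0`. The independent oracle
`brute_force_frequent()` enumerates every subset of universes of up to 20
items; equivalence on random instances (≤ 12 items, random support
thresholds, 200 instances in the acceptance suite) is the core
correctness property, alongside downward closure of the reported
itemsets. `generate_rules()` requires the frequent list to be closed
downward and fails loudly on a missing subset count rather than imputing
one.

## The synthetic generator

The source registry is restricted, so `generate_cohort()` emulates the
statistical structure the analysis depends on:

* **Subgroup mixture** — multinomial over the seven subgroups with the
  study's shares (mood disorders 31.75%, schizophrenia spectrum 21.94%,
  ..., adult personality disorders 1.21%).
* **Block marginals** — independent Bernoulli per block, defaulting to
  the 35 blocks at ≥ 1% frequency in the study (hypertensive diseases
  0.1106 down to other upper-respiratory diseases 0.0101). Their sum,
  ≈ 1.05, is the expected blocks per patient; `scale_marginals()`
  rescales to a target mean count (default 1.42, the study's
  diagnosis-level mean) when that is the quantity being emulated.
* **Planted dependencies** — selected disjoint block pairs are drawn from
  the 2×2 law with $P_{11} = L\,p_A p_B$, which has marginals exactly
  $p_A, p_B$ and population lift exactly $L$. Feasibility
  ($L\,p_A p_B \le \min(p_A,p_B)$ and $P_{00} \ge 0$) is validated before
  any generation. Closed forms for what the miner should recover come
  from `expected_metrics()`, and `lift_se()` provides the delta-method
  standard error of the sample lift used by the recovery tests
  (observed lift within 3 SE of the planted value for
  $L \in \{1, 2, 4, 10\}$ at $p_A = p_B = 0.1$, $n = 20{,}000$).
* **Demographics** — sex, age group (uniform within band), insurance,
  admission route, outcome and bed size are drawn from the study's
  marginal frequencies; length of stay is lognormal (meanlog 2.7, sdlog
  1.3), chosen for a mean near 36 days with the heavy right tail
  discharge data show.

Generation uses a single explicitly seeded stream and restores the global
RNG state afterwards; a fixed seed yields byte-identical CSV output.
Records are emitted in the input dialect of `read_discharge_csv()`, with
present blocks written as the block's start code (bumped by one category
in the rare case it would equal the principal diagnosis, so the
"comorbidities exclude the principal code" invariant holds while the
block-level marginal is preserved).

What the generator does **not** emulate — and hence what passing recovery
tests do and do not show: comorbidity prevalence is homogeneous across
subgroups (the real cohort ranges from 46% in the schizophrenia stratum
to 83% in dementia); dependencies are pairwise only, so a three-block
rule pattern can be exercised qualitatively by composing overlapping
pairs but has no exact closed form; there is no survey design, hospital
clustering, or year trend; and demographics are independent of diagnosis.
Recovery on synthetic data validates the *pipeline* — encoding, counting,
metrics, ranking — not any clinical claim about real discharge data.

## Numerical and degenerate-input choices

* Support comparisons use exact integer counts against `count/n >=
  min_support`; the oracle uses the identical expression, so boundary
  ties cannot diverge between the two routes.
* Empty strata raise an error naming the stratum; an empty rule list is
  an error for graph building (there is nothing to draw) but a valid,
  empty, CSV for `write_rules()`.
* `joint_bernoulli()` at the nesting boundary ($P_{01} = 0$ or
  $P_{10} = 0$) is allowed: the rarer event becomes a subset of the
  other, which the tests exercise.
* All output files are written to a temporary file in the destination
  directory and renamed, so a failed run never leaves a partial file.
* GraphML export orders item vertices alphabetically and rule vertices by
  rank; two exports of the same graph are byte-identical.

## Problem sizes

The test suite runs on synthetic cohorts of 2,000–20,000 records and
random transaction sets of up to 12 items (where exhaustive enumeration
is the oracle); the full suite completes in under two minutes on one CPU,
and the acceptance script in under half a minute. These sizes were chosen
so that every stochastic assertion has comfortable sampling margins
(3–4 standard errors) at a fixed seed.

## Known limitations

* The default block universe is ICD-10, not KCD-7; Korea-specific codes
  are unmappable and would be counted as unmapped rather than analysed.
* Published rule tables for the pooled stratum cannot be reproduced
  cell-for-cell: the printed counts and supports there are mutually
  inconsistent (585/20,690 ≠ 0.035), and several printed confidence cells
  lie below their own support, which is impossible under the defining
  ratio. The package computes confidence from its definition and makes no
  attempt to reproduce such cells; the per-subgroup tables, which are
  internally consistent, are the reproduction surface.
* Association rules describe co-occurrence, not causation; no
  significance testing or redundancy pruning (closed/maximal itemsets) is
  performed.
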