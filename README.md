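# comorbidrules

Association-rule analysis of the comorbidities of hospital inpatients whose
principal diagnosis is a mental or behavioural disorder.

Patients admitted for a mental disorder frequently carry additional
diagnoses — hypertension, diabetes, liver disease, other mental disorders —
and the co-occurrence structure of those comorbidities matters for patient
management. `comorbidrules` implements the full pipeline for discovering
that structure from discharge records:

1. **ICD-10 block encoding** — each additional diagnosis is mapped to an
   ICD-10 intermediate classification block (e.g. `I10`–`I15` *Hypertensive
   diseases*), and each patient becomes a transaction: the set of distinct
   blocks among their comorbidities. Patients without comorbidity contribute
   empty transactions that still count in the denominator.
2. **Stratification** — cohorts are split by principal-diagnosis subgroup:
   dementia (F00–F03), psychoactive substance use (F10–F19), schizophrenia
   and delusional disorders (F20–F29), mood disorders (F30–F39), neurotic
   and somatoform disorders (F40–F48), behavioural syndromes (F50–F59), and
   adult personality disorders (F60–F69).
3. **Apriori mining** — a from-scratch level-wise frequent-itemset search
   with prefix-join candidate generation and downward-closure pruning,
   verified in the test suite against exhaustive enumeration.
4. **Rule selection and ranking** — for a rule A → B over a stratum of *n*
   patients,

   - support(A → B) = P(A, B) = n(A ∪ B) / n
   - confidence(A → B) = P(A, B) / P(A)
   - lift(A → B) = P(A, B) / (P(A) · P(B))
   - IS(A → B) = √(support × lift) = P(A, B) / √(P(A) P(B)) (the cosine
     measure)

   Rules must reach the support and confidence floors and have lift
   strictly above 1; surviving rules are ranked by the IS scale, which
   rewards rules that are high in *both* support and lift.
5. **Reporting** — rule tables as CSV, and bipartite item/rule networks
   (antecedent items → rule vertex → consequent item, with support and lift
   as vertex attributes) as GraphML.

Because the source registry (the Korean National Hospital Discharge
In-depth Injury Survey) is access-restricted, the package ships a
**synthetic discharge-record generator** that emulates the cohort's
statistical structure — the subgroup mixture, the per-block marginal
prevalences, and *planted* pairwise block dependencies with an exact target
lift — together with the closed-form metrics the miner should recover
(support = L·pA·pB, confidence = L·pB, lift = L, IS = L·√(pA·pB)). The
whole pipeline therefore runs, and is tested, end to end without the
restricted data.

## Worked example

Simulate a cohort of 20,000 discharges with the default subgroup mixture
and block marginals, planting a diabetes–hypertension dependence at lift
4.2, then mine it:

```r
library(comorbidrules)

cfg <- synthetic_config(n = 20000, seed = 42,
  planted = list(planted_association("E10-E14", "I10-I15", 4.2)))
cohort <- build_cohort(generate_cohort(cfg))
cohort
#> Discharge cohort: 20000 records, 12890 with comorbidity
#> Blocks in universe: 253

head(frequent_blocks(cohort), 3)
#>     block                      label count percent
#> 1 I10-I15      Hypertensive diseases  2206   11.03
#> 2 F30-F39 Mood (affective) disorders  1600    8.00
#> 3 E10-E14          Diabetes mellitus  1567    7.84

rules <- mine_subgroup(cohort, "ALL")
rules[, c("antecedent", "consequent", "joint_count", "support",
          "confidence", "lift", "is_scale")]
#>   antecedent consequent joint_count support confidence   lift  is_scale
#> 1    E10-E14    I10-I15         720   0.036  0.4594767 4.1657 0.3872534
#> 2    I10-I15    E10-E14         720   0.036  0.3263826 4.1657 0.3872534
```

The planted pair is recovered in both directions at the top of the
ranking: 720 of 20,000 patients (support 0.036) carry both blocks, the
empirical lift 4.17 sits within sampling error of the planted 4.2
(`lift_se(0.0798, 0.1106, 4.2, 20000)` ≈ 0.17), and both directions share
the same lift and IS scale, as they must for single-item rules. 64% of
patients have at least one comorbidity, and the hypertensive block is the
most frequent at 11% — the marginal structure the generator was configured
with.

A command-line front end covering `simulate`, `describe`, `mine` and
`graph` is included:

```sh
Rscript inst/cli/comorbidrules.R simulate --n 20000 --seed 42 --out cohort.csv
Rscript inst/cli/comorbidrules.R mine --input cohort.csv --subgroup F00-F03 \
    --min-support 0.01 --out rules.csv
Rscript inst/cli/comorbidrules.R graph --rules rules.csv --out rules.graphml
```

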