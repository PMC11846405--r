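# cbdscore

Quality-of-labeling assessment for cannabidiol (CBD)-based medicinal products,
built for regulatory scientists and pharmacists who need a reproducible,
auditable scoring pipeline rather than ad-hoc spreadsheets.

Cannabis-based products reach Brazilian patients under two ANVISA rules:
**N327** (RDC 327/2019, temporary trade permits for pharmacy sale, package
leaflet required) and **N660** (RDC 660/2022, importation for personal use with
a prescription). Whether a prescriber or patient can find the information
needed for safe use depends on what the manufacturer publishes. `cbdscore`
implements the weighted-checklist instrument used to quantify that:

- **Scoring.** A rubric of 45 binary criteria `c_i`, each with a weight
  `w_i ∈ {1, 2, 3}` and one of four domains (*prescription*, *GMP*, *safety of
  use*, *laboratory testing*). A product's score is the weighted indicator sum
  `S = Σ w_i · 1[criterion i met]`, with per-domain sub-scores summing to `S`.
- **Classification.** `S ≥ 50` → very satisfactory; `25 ≤ S ≤ 49` →
  satisfactory; `S ≤ 24` → not very satisfactory.
- **Follow-up.** Missing information is requested by e-mail (14-day window,
  then a 7-day reminder window), modeled as a deterministic state machine.
  Responses can only add evidence, so the final score satisfies
  `S_final ≥ S_preliminary`.
- **Statistics.** Median/IQR (P25–P75) summaries and a tie-corrected
  Mann–Whitney U test (exact enumeration for small samples, tie-corrected
  normal approximation with continuity correction otherwise), two-tailed at
  α = 0.05, with a Shapiro–Wilk normality gate.
- **Synthetic data.** The criterion-level evaluations behind the published
  score table are unpublished, so a seeded generator draws binary fulfillment
  vectors *uniformly over the subset-sum solutions* of any achievable target
  total (dynamic programming + backward sampling), letting every pipeline
  stage run on criterion-level data with exactly prescribed totals.

The published table of the 105 evaluated products ships as a machine-readable
fixture (`inst/extdata/table1.csv`; see `table1-NOTES.md` there for documented
inconsistencies of the printed source). The shipped 45-criterion rubric is a
clearly-labelled synthetic placeholder with the instrument's published shape —
the true criterion texts are not public — and is fully replaceable by a user
rubric file.

## Worked example

```r
library(cbdscore)

cohort <- table1_cohort()          # the packaged table of 105 products
report <- run_analysis(cohort)
report
#> <cbd_report> 105 products
#>   bands (final):  not_very_satisfactory=39, satisfactory=47, very_satisfactory=19
#>   overall group test: U = 1164, p = 7.644e-06 (normal_approx)
#>   follow-up: ? responses, 5 score increases

report$band_summaries$satisfactory$median
#> [1] 35
```

Of the 105 products, 19 score very satisfactory, 47 satisfactory and 39 not
very satisfactory; the satisfactory-band median final score is 35 points; five
products improved their score after the manufacturer consultation; and the
N327 group's scores are significantly higher than the N660 group's
(Mann–Whitney U = 1164 on n = 15 vs 90, two-sided p ≈ 7.6 × 10⁻⁶, i.e.
p < 0.001): pharmacy-channel products expose markedly more of the information
needed for safe prescribing than imported ones.

A criterion-level run (synthetic, seeded, totals matched to the table):

```r
rub <- default_rubric()
cfg <- generator_config(rub,
  target_totals = data.frame(preliminary = cohort$preliminary_score,
                             final = cohort$final_score,
                             product_name = cohort$product_name,
                             normative = cohort$normative),
  followup_response_fraction = 12/105, seed = 42)
gen <- generate_cohort(cfg)
run_analysis(gen$cohort, criterion_data = gen, rubric = rub)
#> <cbd_report> 105 products
#>   bands (final):  not_very_satisfactory=39, satisfactory=47, very_satisfactory=19
#>   overall group test: U = 1164, p = 7.644e-06 (normal_approx)
#>   follow-up: 12 responses, 5 score increases
```

with per-domain group summaries and tests now available in
`report$group_tests`.

## Command line

A thin wrapper over the package functions lives at
`inst/cli/cbdscore-cli.R` with subcommands `score`, `followup`, `stats`,
`simulate` and `report` (exit codes: 0 ok, 1 validation error, 2 usage
error). Example:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","cbdscore-cli.R",package="cbdscore"))')" \
    report --cohort my_cohort.csv --format markdown --out report.md
```
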