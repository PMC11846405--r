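---
title: "Methods: weighted-rubric labeling-quality scoring and group comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted-rubric labeling-quality scoring and group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbdscore)
```

## The measurement model

`cbdscore` quantifies how much of the information needed for safe prescribing
and use a CBD-based product makes publicly available. The instrument is a
checklist of 45 binary criteria; criterion $i$ carries an integer weight
$w_i \in \{1,2,3\}$ (3 = essential for prescription and clinical indication,
2 = promotes safe use, 1 = complementary) and belongs to one of four domains:
prescription, good manufacturing practices (GMP), safety of use, and
laboratory testing (certificate-of-analysis items). A product's score is the
weighted indicator sum

$$S \;=\; \sum_{i=1}^{45} w_i \,\mathbf{1}[\text{criterion } i \text{ met}],$$

with per-domain sub-scores defined by restricting the sum; they always add up
to $S$. Two modeling assumptions are baked in and worth making explicit:

* **Binary fulfillment.** A criterion is met when the information is publicly
  available (label, packaging, leaflet, CoA, website, or e-mail reply) and
  unmet otherwise. There is no partial credit; the instrument measures
  availability, not accuracy — chemical verification of label claims is out
  of scope.
* **Additivity.** Criteria contribute independently to the score; no
  interactions or conditional criteria (e.g. form-specific items for oils vs
  capsules) are modeled.

Totals are classified into three bands on the raw point scale, never rescaled
to the rubric maximum: **not very satisfactory** ($0\text{–}24$),
**satisfactory** ($25\text{–}49$), **very satisfactory** ($\ge 50$). The
breakpoints sit at 25 and 50 exactly; `classify()` is a step function and the
test suite pins both jumps.

### The shipped placeholder rubric

The exact criterion texts and their weight/domain allocation are not public.
The packaged default (`default_rubric()`, named `placeholder-45`) is therefore
a synthetic stand-in that preserves everything downstream code depends on:
45 criteria, four domains, weights in $\{1,2,3\}$. Its per-domain maxima —
prescription 25, GMP 8, safety of use 37, laboratory testing 12, total 82 —
were chosen once to dominate the largest per-domain and total scores the
instrument is known to produce (per-domain score endpoints of 21, 7, 37 and 4,
and a maximum observed total of 68), with the remaining freedom resolved by
assigning weight-3 items to prescription-critical and safety-critical
information and weight-1 items to the CoA checklist, mirroring how the
weighting scheme is described. Any real evaluation should supply its own
rubric file; the JSON schema (`load_rubric()` / `serialize_rubric()`) is
versioned and round-trip stable.

## Follow-up protocol

The manufacturer consultation is a deterministic state machine:
`evaluated → awaiting_first_reply` on sending the first e-mail (14-day
window), `→ awaiting_reminder_reply` when that deadline passes (reminder with
a 7-day window), closing with `closed_with_response` from either awaiting
state or `closed_no_response` after the second deadline. Two conventions had
to be fixed:

* **Deadline arithmetic** is in calendar days, inclusive start and exclusive
  end: a reply dated exactly 14 days after the first e-mail is within the
  deadline. The protocol description gives the window lengths but not the
  boundary convention, so the package picks one and enforces it consistently
  (`advance_state()` rejects a `deadline_passed` event dated before the
  deadline).
* **Reminder timing** is event-driven, not batched: the reminder may be sent
  on any date on or after the first deadline, and its 7-day window starts on
  the date it was actually sent.

A response is modeled as the set of criteria it newly evidences — the only
effect a reply can have on a score. `apply_followup()` is a pointwise union,
which makes the update monotone ($S_{\text{final}} \ge
S_{\text{preliminary}}$, matching the observation that no reply ever
contradicted public information), idempotent, and order-independent. Those
three properties are asserted over randomized cases in the test suite.

## Statistical layer

Group scores are summarized as median and IQR (P25–P75). The published
analysis does not state its quantile convention, and its printed IQRs are not
internally consistent with the printed per-product scores, so the convention
here is **explicit and swappable**: linear interpolation of order statistics
(R type 7) by default, any `stats::quantile()` type on request, and the chosen
type is recorded in every summary and report.

Groups are compared with the Mann–Whitney U test on midranks, two-tailed.
Implementation choices:

* **Exact mode.** For tie-free samples the null distribution of $U$ is built
  by the count recursion $c(m,n,u) = c(m-1,n,u-n) + c(m,n-1,u)$; counts stay
  exact in doubles for all sizes used here. With ties, the midrank-$U$ null is
  enumerated directly over all $\binom{n_1+n_2}{n_1}$ assignments, feasible
  (and allowed) only for $n_1+n_2 \le 12$.
* **Normal approximation.** Tie-corrected variance
  $\frac{n_1 n_2}{12}\bigl[(N{+}1) - \sum_t (t^3 - t)/(N(N{-}1))\bigr]$ with a
  0.5 continuity correction (on by default; standard at these sample sizes).
* **Mode selection.** `auto` uses exact when $n_1 n_2 \le 400$ and the pooled
  sample is tie-free, otherwise the approximation.
* **Two-sided p** is $2\min(\text{lower tail}, \text{upper tail})$ capped at
  1. Fully degenerate input (every observation identical) returns $p = 1$
  with a `degenerate` flag rather than dividing by a zero variance.

The exact path is validated against a brute-force enumeration oracle that
computes $U$ by direct pair counting (a different route than midranks), with
and without ties; the approximation is required to sit within 0.01 of the
exact p at $n_1 = n_2 = 15$ on tie-free samples, and both paths are
cross-checked against `stats::wilcox.test()` where its assumptions allow. The
Shapiro–Wilk gate (`shapiro_wilk()`) fronts the standard Royston
implementation in base R, adding the contract checks ($3 \le n \le 5000$,
non-constant sample) and is verified against an independently computed
reference value frozen into the tests.

## Synthetic criterion-level data

The per-criterion evaluations behind the published score table were never
released, so the generator exists to give every pipeline stage real inputs:

* **Exact targets.** `sample_fulfillment_for_target()` draws a fulfillment
  vector whose weighted sum equals the target *exactly* — achievable totals
  are precisely the subset sums of the weight multiset — and, conditional on
  the target, every solution vector is equally likely. Uniformity comes from
  dynamic programming over achievable partial sums followed by backward
  sampling proportional to suffix solution counts; rejection sampling was
  rejected because it is exponentially slow at extreme targets. A
  chi-squared check on an enumerable toy rubric (10,000 seeded draws) pins
  the uniformity claim.
* **Paired stages.** For a product with preliminary $p$ and final $f \ge p$,
  the final vector is drawn first, then the initial vector is drawn uniformly
  over subset-sum solutions of $p$ *within* the final met set (resampling the
  final support in the rare case $p$ is not realizable inside it). The
  post-follow-up matrix therefore dominates the initial one pointwise by
  construction, and the response set is their difference.
* **Event logs.** Responders reply on day 7 (inside the first window);
  non-responders pass both deadlines. Every generated log replays cleanly
  through the state machine. The response fraction defaults to the observed
  rate when reproducing the packaged table (12 of 105, of which 5 replies
  raised scores).
* **Distribution mode.** When per-group location/spread is supplied instead
  of explicit totals, totals are drawn from a normal distribution, clamped to
  the achievable range and rounded to the nearest achievable subset sum with
  ties toward the lower total; realized totals are reported.
* **Randomness** uses R's default Mersenne–Twister generator; the seed is part
  of the generator config and echoed in the output.

What the generator deliberately does **not** emulate: correlations between
criteria (e.g. products with a CoA plausibly also meet GMP items — criteria
here are independent given the total), per-domain structure of the real
products (unknown), and response latency beyond the deadline structure.
Passing tests on synthetic cohorts therefore demonstrate the pipeline's
correctness — exact totals, monotone follow-up, reproducible statistics — not
distributional fidelity to the unpublished raw evaluations.

## The packaged product table

`table1_cohort()` loads the published list of 105 products (name,
manufacturer, normative group, type, preliminary and final score),
transcribed as printed. Documented inconsistencies of the printed source —
a normative label that is only consistent with the published group median if
one row is relabeled, a lowest-band median of 16.0 where the printed rows give
17, and an impossible IQR for the top band — are recorded in
`inst/extdata/table1-NOTES.md` and deliberately **not** corrected.
Consequently the pipeline treats band counts (19/47/39), the top- and
middle-band medians (57.0, 35.0), the five follow-up upgrades and the overall
group comparison ($p < 0.001$) as reproducible quantities, while
group-stratified medians and all printed IQRs are excluded from verification.
Per-domain group comparisons are computed only when criterion-level data are
present; the score-level table cannot support them and the package never
fabricates domain scores from totals.

## Problem sizes and numerical notes

The test suite exercises: exhaustive $2^n$ scoring enumeration up to
$n = 10$ (sampled masks at $n = 15$); exact-vs-brute-force Mann–Whitney over
all sample pairs with $n_1 + n_2 \le 10$ drawn with and without ties;
approximation consistency at $n_1 = n_2 = 15$; 10,000-draw uniformity
chi-squared on a 3-criterion rubric; and full 105-product pipeline runs on
both the score-level table and generated criterion-level cohorts. These sizes
were chosen so the whole suite runs in about a minute on a single core while
still enumerating every case the correctness arguments rely on. Subset-sum
and rank-distribution counts are kept as exact doubles (all intermediate
counts are far below $2^{53}$); no floating-point tolerance is needed
anywhere except the generic `1e-12` comparisons of probabilities.

## Known limitations

* The shipped rubric is a placeholder; per-domain conclusions drawn with it
  reflect its synthetic weight allocation, not the real instrument.
* Scores measure information availability, not label accuracy; a product with
  a complete but wrong label scores high.
* Exact Mann–Whitney with ties is limited to $n_1+n_2 \le 12$; larger tied
  samples fall back to the tie-corrected approximation.
* The generator's independence-given-total assumption understates real
  between-criterion correlation; per-domain synthetic analyses should be read
  as pipeline demonstrations.
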