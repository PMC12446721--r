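---
title: "Methods: validating a questionnaire scale against categorical diagnoses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating a questionnaire scale against categorical diagnoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaleval)
```

# The validation design

A continuous symptom scale is useful as a research measure of a disorder
only if it discriminates the diagnosed from the undiagnosed. scaleval
implements that check as a case-control classification analysis with
three progressively harder contrasts, a prevalence-balanced sample, and
bootstrap inference of the AUCROC against a fixed performance bar.

**Contrasts.** With depression as the target disorder and one
reporter's diagnosis flags in hand:

* *sensitivity* — positives are all participants flagged with
  depression (comorbidity allowed); negatives are everyone else,
  including the undiagnosed. This asks whether the scale separates the
  depressed from the general pool.
* *specificity* — the same positives, but negatives are restricted to
  participants carrying at least one diagnosis, none of them
  depression. Because comorbidity is pervasive, a scale can look
  sensitive merely by tracking overall symptom burden; this contrast
  removes the healthy majority.
* *strict specificity* — positives additionally must carry no other
  diagnosis. Set-theoretically, strict positives are always a subset of
  specificity positives, and specificity negatives a subset of
  sensitivity negatives; both inclusions are asserted as invariants in
  the test suite on every simulated cohort.

A contrast with an empty side is *unconstructible*; `build_contrast()`
raises an error naming the empty side, and the pipeline converts it
into an NA report row carrying the reason, so multi-contrast runs
complete (strict specificity is routinely unconstructible in cohorts
where every case is comorbid).

**Prevalence balancing.** Population cohorts are heavily imbalanced;
classification metrics computed at 1–2% prevalence are hard to compare
across samples. `balance_to_ratio()` keeps every positive and draws
`round(n_pos · (1 − r)/r)` controls uniformly without replacement
(seeded), with `r = 0.10` by default, so positives form 10% of the
analysis sample. Rounding is half-away-from-zero; at `r = 0.10` the
count is always an exact multiple (30 positives → 270 controls,
71 → 639). When the control pool is smaller than the target, every
control is kept and `ratio_met = FALSE` marks the shortfall. Whether
the subsampling should be random at all is a design gap in the source
design; uniform seeded sampling is this package's choice, and the test
suite verifies the selection is distribution-free (each control's
selection frequency across 1000 seeds within 3 binomial SEs of its
expectation).

**Missing data.** The exclusion rule is strict by default: a
participant is dropped if any required reporter's diagnosis flags are
incomplete or if any scale item is missing (`exclude` policy). A
`prorate` policy — `round(mean(present) · n_items)` when at least 50%
of items are present — is offered as an extension because checklist
scoring manuals often tolerate limited missingness, but it is off by
default; the 50% floor and the rounding rule are package choices.

# The AUCROC threshold test

The scale score is the raw sum of 0/1/2 item responses; no t-score or
sex norming is applied (raw scores keep the analysis free of external
norm tables, at the cost of pooling sexes — a `group_by_sex` switch
reruns every analysis per sex).

**Point estimate.** `auc()` implements the tie-aware Mann-Whitney
form, `Pr(S⁺ > S⁻) + ½·Pr(S⁺ = S⁻)`, via mid-ranks. Integer summed
scores guarantee massive ties, so the half-credit convention matters:
it is symmetric, agrees exactly with trapezoidal integration of the
tie-aware ROC polygon (`roc_points()`), and is invariant under strictly
increasing transforms of the score. The suite checks exact equality
against an exhaustive pairwise oracle on a thousand random instances.

**Bootstrap.** `bootstrap_auc()` recomputes the AUC on `n_boot`
resamples (default 1000). The default scheme is *stratified* —
positives and negatives resampled separately, preserving class counts —
because at a 10% ratio with a few dozen positives, joint resampling
can produce single-class resamples. A *simple* joint scheme is kept
behind a flag for sensitivity analysis; it redraws single-class
resamples and reports how many redraws occurred.

**p-values.** The one-sided p-value for the test that performance is
below the threshold t (default 0.8) is `#{AUC_b > t}/(n_boot + 1)`:
the `+1` stands in for the original arrangement of the data, giving a
1001 denominator at 1000 bootstraps. When the count is zero the value
is reported as the floor `< 1/(n_boot + 1)` (rendered `<0.001`) rather
than zero — a resampling p-value of exactly 0 would overstate the
evidence. The two-sided p-value is `min(1, 2·min(share ≤ t, share ≥
t))` with both shares over the same denominator; this doubling
construction is a package choice (the two-sided convention is standard,
its formula rarely stated). Note a boundary effect of the finite
denominator: with the bootstrap distribution split evenly around t the
two-sided p is `1000/1001`, not exactly 1.

**Confidence interval.** The 95% CI is the percentile interval at
quantiles 0.025 and 0.975 of the bootstrap distribution, computed under
R's default linear-interpolation quantile definition (type 7), fixed
and documented so equal seeds give bit-identical intervals.

**Calibration.** The acceptance suite simulates at true AUC exactly
0.8 (binormal scores with class separation d = √2·Φ⁻¹(0.8) ≈ 1.19,
50 cases / 450 controls) and checks the one-sided test rejects in
2–9% of 500 replicates at α = 0.05 — a deliberately loose band: the
percentile bootstrap under-covers slightly at these class sizes, and
the discrete (B+1) denominator makes the achievable levels granular.

**Cutpoints.** `optimal_cutoff()` scans all midpoints between adjacent
distinct scores plus ±∞ under the rule score ≥ cutoff ⇒ positive.
The criterion defaults to Youden's J (sensitivity + specificity − 1);
closest-to-(0,1) is the alternative. Which criterion the design this
mirrors actually used is unknown, so the choice is explicit and
reported with the result. Ties among equally optimal cutoffs break
towards higher specificity (fewer false positives — a screening-
parsimony rationale); when the criterion is flat across the whole scan
(constant scores) the degenerate all-positive cutoff −∞ is returned
with a tie flag rather than an arbitrary interior value.

**Agreement.** `cross_tabulate()` builds the 2×2 cross-informant
table (pairs with a missing rating dropped pairwise and counted) and
`cohen_kappa()` the chance-corrected agreement
κ = (p_o − p_e)/(1 − p_e), undefined (NA with a warning) when both
raters are constant.

# The synthetic cohort generator

No public data carries this design's structure — the cohorts it targets
are access-restricted — so the package ships a generator whose defaults
*are* the study conditions, chosen once:

| parameter | default | rationale |
|---|---|---|
| depression prevalence | 0.02 | parent-report depression in unselected child cohorts runs ~0.5–2% |
| anxiety / ADHD prevalence | 0.06 / 0.07 | typical population rates at ages 8–11 |
| liability correlations | dep-anx 0.45, dep-adhd 0.25, anx-adhd 0.30 | moderate comorbidity, strongest for depression-anxiety |
| parent fidelity ρ | 0.9 | parents track their child's observable symptoms well |
| child fidelity ρ | 0.3 | weak parent-child concordance is the core informant-discrepancy phenomenon |
| clinician parent weight w | 0.7 | consensus diagnosis at this age leans on the parent interview |
| clinician noise SD | 0.3 | consensus adds its own judgement variance |
| items | 13, loadings 1.0–2.5, thresholds in the upper liability tail | a 13-item DSM-oriented scale; right-skewed raw scores |
| ages | 8–11, uniform | baseline-wave age window |
| sex | 50/50, independent of liability | sexes are pooled downstream |

The generative process: liabilities L ~ MVN(0, R); perceived liability
per reporter P = ρL + √(1−ρ²)ε; diagnosis when P exceeds the
prevalence quantile Φ⁻¹(1−π) (liability-threshold model); clinician
consensus C = wP_parent + (1−w)P_child + noise, thresholded at the same
quantile; item responses graded-logistic on the reporter's perceived
depression liability, Pr(x_j ≥ k) = logistic(a_j(P − b_jk)).

Every sub-draw is seeded as `stage_seed(seed, k) = (seed mod 1e5)·10007
+ k` with a fixed stage index k (1 liabilities, 2–3 parent/child
perception noise, 4 clinician noise, 5–6 parent/child item uniforms,
7 demographics, 8 missingness), so any stage is reproducible in
isolation and all derived seeds stay below 2³¹.

**What it reproduces** — the three phenomena the analysis turns on:
within-informant concordance (a reporter's items and flags share P, so
same-informant AUC is very high), cross-informant discordance (with
ρ_parent·ρ_child ≈ 0.27, concordant positives at 2% prevalence are the
smallest cell of the 2×2 table by an order of magnitude), and
comorbidity (flag co-occurrence odds ratios track R; identity R gives
OR ≈ 1).

**What it does not** — and hence what passing tests do not show about
real data: no item content or differential item functioning, no
informant-specific reporting biases beyond a single fidelity scalar
(real parent-child disagreement is structured, not just noisier), no
age or sex effects on liability, missingness only completely at random,
no longitudinal structure, and same-informant discrimination that is
*more* optimistic than real cohorts (a real checklist and a real
interview disagree for reasons beyond perception noise). The package's
validation logic is therefore tested against the model's *qualitative*
pattern, not against any real cohort's cell counts, which would require
the restricted data.

One consequence worth making explicit: because a reporter's scale score
and that same reporter's diagnosis both condition on P, the
same-informant AUC is *constant* in ρ up to Monte-Carlo noise — fidelity
moves the score's relation to the truth, not to the reporter's own
flags. The monotone-fidelity test therefore checks non-decrease within
noise against the reporter's own flags and strict increase against a
perfect-fidelity informant whose flags threshold the true liability.
Similarly, at ρ = 1 the perceived liability equals the thresholded
liability itself, so a score built from it separates that informant's
cases perfectly (AUC = 1) — the degenerate limit the suite pins down
exactly.

# Problem sizes and runtime choices

The test suite runs its stochastic checks at sizes chosen to keep
Monte-Carlo error well inside the asserted tolerances while staying
quick: prevalence and comorbidity convergence at n = 10,000 (3 binomial
SEs), fidelity monotonicity at n = 5,000 per ρ, agreement-pattern face
validity at n ≈ 6,000, binormal closed-form recovery at 2,000 + 2,000
(3 Hanley-McNeil SEs), and test calibration with 500 replicates of
50/450 at 500 bootstraps each. The end-to-end pipeline examples use
cohorts of 1,500–4,000 with 100-iteration bootstraps; the bootstrap
count never changes point estimates, only the resolution of p-values
and CIs.

# Limitations

The package validates *a* scale against *a* flag source; it does not
adjudicate which informant is right — that question needs an external
criterion the design does not have. DeLong variance estimates,
correlated-AUC comparisons, smoothed ROC curves, covariate matching and
cost-weighted cutpoints are out of scope. The default scale membership
(`item_01` … `item_13`) is a placeholder aligned with the simulator;
real instruments define membership in scoring manuals and should be
supplied as configuration.
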