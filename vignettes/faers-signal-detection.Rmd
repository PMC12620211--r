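---
title: "Disproportionality signal detection on FAERS-style spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS-style spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) accumulate millions of voluntary reports, each
linking suspect drugs to MedDRA-coded adverse events (preferred terms,
PTs). Because there is no denominator of exposed patients, safety signals
are sought by *disproportionality*: is a (drug, event) pair reported more
often than expected if drug and event were independent? `faersignal`
implements this workflow for the motivating use case of infection-related
events under the oral JAK-1 inhibitors abrocitinib and upadacitinib in
atopic dermatitis (AD), but every piece — ingestion, deduplication, cohort
selection, statistics, screening, comparison and sensitivity re-analysis —
is generic and configuration-driven.

## The contingency model

For one drug and one PT, reports are cross-classified into the fourfold
table

|              | target AEs | other AEs |
|--------------|-----------|-----------|
| target drug  | a         | b         |
| other drugs  | c         | d         |

with N = a + b + c + d. The counting unit is the **report–PT pair**: a PT
contributes at most once per report, and b (resp. d) counts the drug's
(resp. comparator's) *other* report–PT pairs, not other reports. This is
the common convention in FAERS disproportionality work; because published
analyses rarely state their unit, the choice is recorded in every output's
metadata.

Four statistics are computed per table:

* **ROR** (reporting odds ratio): ad/(bc), with the log-normal interval
  exp(ln ROR ± 1.96·s), s = sqrt(1/a + 1/b + 1/c + 1/d).
* **PRR** (proportional reporting ratio): a(c+d)/(c(a+b)), accompanied by
  the uncorrected Pearson chi-squared
  (ad − bc)²·N / ((a+b)(c+d)(a+c)(b+d)).
* **IC** (information component, BCPNN): log2(a·N/((a+c)(a+b))), the
  base-2 log of observed over expected joint reporting.
* **EBGM**: a·N/((a+c)(a+b)) with lower bound
  EBGM05 = exp(ln EBGM − 1.96·s).

Note that the EBGM implemented here is the *relative reporting ratio with
a log-normal bound*, the form now common in FAERS papers — not
DuMouchel's gamma-mixture shrinkage MGPS. A consequence worth stating
plainly: IC ≡ log2(EBGM) by construction, and the package tests enforce
this identity to machine precision. Reference tables published with this
convention show the same coupling (their IC column rounds to the log2 of
their EBGM column), which is how the convention can be recognized from
printed values alone.

### Interval conventions and V(IC)

The BCPNN interval is reported as IC ± 2·sd(IC). The literature is not
unanimous on sd(IC); the package default transfers the log-scale
delta-method standard error to base 2, `sd = sqrt(1/a+1/b+1/c+1/d)/ln 2`,
which reproduces published IC025 values of this analysis family to about
±0.03. The Bayesian posterior variance of the early BCPNN papers (priors
gamma11 = 1, alpha = beta = 2) is available via
`bcpnn_stats(t, variance = "bate")`. Similarly, published EBGM05 columns
are not always exactly consistent with the log-normal formula they quote;
`faersignal` always computes from the formula, never from a lookup.

### Screening criteria

A PT is a **positive signal** only if it meets all four criteria at once
(`screen()`):

* ROR: lower 95% bound > 1 and a ≥ 3;
* PRR: PRR ≥ 2, chi-squared ≥ 4, a ≥ 3;
* BCPNN: IC025 > 0 (strict);
* EBGM: EBGM05 > 2 (strict).

The conjunction is deliberately conservative: it trades sensitivity for a
very low false-positive rate, which the simulation suite measures (the
fraction of null PTs flagged positive is well below 5% at realistic
sizes). Thresholds are exposed as configuration; comparisons are exact
IEEE comparisons with no tolerance. The a ≥ 3 gate is always evaluated on
the *raw* count, even when the cells have been continuity-corrected.

### Zero cells

If any cell of a table is zero, 0.5 is added to all four cells before
every statistic and the row is flagged `corrected` (Haldane–Anscombe).
Such PTs have a ≤ 2 or c = 0 and can essentially never pass the combined
screen, so the correction affects reporting completeness, not verdicts.
With `correction = FALSE` the statistics for such tables are undefined
(NA) and fail their criteria.

## From raw quarters to the analysis cohort

FAERS quarters arrive as seven "$"-delimited ASCII tables (DEMO, DRUG,
REAC, OUTC, RPSR, THER, INDI). `read_quarter()` matches columns
case-insensitively (with an alias map for historical renames such as
`gndr_cod` → `sex`), reads bytes as Latin-1 with replacement, drops and
counts records whose mandatory fields do not parse, and flags child
records without a DEMO parent as orphans; orphans are retained in the raw
object for auditability but excluded from all counting. THER and RPSR are
ingested for completeness and not used by any analysis here, matching the
workflow the package implements.

**Deduplication** (`deduplicate()`): FAERS publishes successive versions
of a case under one CASEID. Per FDA practice the version with the latest
FDA_DT wins; exact ties are broken by the highest PRIMARYID. The rule is
implemented as a sort, is idempotent, and drops the losing versions'
child records.

**Cohort selection** (`select_cases()`) intersects four filters: (i) a
drug entry with the required role (default PS, primary suspect) whose
name or active ingredient matches the target dictionary (case- and
whitespace-normalized exact match; defaults cover generic and brand names);
(ii) an indication record *linked to that same drug entry* via
`indi_drug_seq` matching the indication PT set (default "Dermatitis
atopic"/"Atopic dermatitis") — drug-level linkage is the stricter,
standard reading of "reports indicating AD as the indication"; (iii) at
least one reaction PT mapping to the SOC filter (default "Infections and
infestations"); (iv) FDA_DT inside the study window (default 20190701 to
20250331, i.e. Q3 2019 through Q1 2025). The four filters commute, which
the test suite verifies.

MedDRA itself is licensed and cannot ship with the package: the PT → SOC
mapping is an input table. A small hand-built stand-in map
(`soc_minimap_synthetic.csv`) ships for tests and examples; a lookup miss
is always detectable (NA plus an unmapped-PT count), never a silent
non-match.

**Comparator population.** The default background is every deduplicated
report whose required-role drug is not a target drug — the whole-database
comparator. Whether published analyses of this design restrict the
background to same-indication reports is usually unstated; the package
exposes `comparator_scope = "indication"` for the restricted variant and
records the choice in run metadata.

A methodological caveat the synthetic experiments make visible: the
target cohort is conditioned on containing at least one infection-SOC PT,
while the comparator is not. This asymmetry inflates the infection-PT
share of the cohort's pairs and hence the disproportionality of *all*
infection PTs, including unplanted ones. That is a property of the study
design itself, not of the implementation; parameter-recovery tests
therefore measure the drug-versus-rest table without cohort conditioning.

## Descriptive and comparative reporting

`summarize_cohort()` produces the conventional characteristics table:
sex; age bands `<18`, `18-65` (closed interval — the natural reading of
the printed labels; configurable), `>65`, `Missing`, with ages converted
to years (DEC×10, MON÷12, WK÷52.1775, DY÷365.25, HR÷8766; a value with a
missing unit is assumed years and counted; results outside [0, 120] years
become missing); one outcome category per report by severity priority
Death > Life-threatening > Disability > Hospitalization > Other (the
priority makes categories sum exactly to the cohort size, which published
tables of this kind also do); top-3 reporter countries (lexicographic
tie-break); reporter type (MD/PH/HP → healthcare professional, CN/LW/OT →
non-healthcare, else missing — a documented convention, not a FAERS
rule); and reporting year from FDA_DT. Percentages are rounded half-up to
one decimal and always recomputed from counts; apparent typos in
published percentage columns are deliberately not reproducible.

`compare_signals()` performs the set algebra behind a two-drug Venn
diagram over the screened-positive PTs and assembles paired ROR intervals
for a side-by-side forest plot; `export_forest_data()` writes the
plotting contract as CSV (two rows per shared PT, deterministic order).
Rendering is intentionally out of scope.

`sensitivity_rerun()` re-runs the scan after dropping every cohort report
that lists any drug entry (any role) from the exclusion set — by default
the medications commonly co-prescribed in AD: betamethasone valerate,
beclometasone, tacrolimus, pimecrolimus, mupirocin, desloratadine,
levocetirizine, dupilumab. The comparator is left untouched: excluding
from the background would perturb every unrelated signal. An empty
exclusion set provably reproduces the primary analysis.

## The synthetic-data generator

`synthetic_spec()`/`generate()` define a fully specified sampling model
so that every pipeline stage can be validated against known ground truth
without downloading FAERS:

* each of `n_reports` reports draws one primary-suspect drug from a
  prevalence table (defaults: the two JAK-1 inhibitors at 3% and 7% of
  reports plus six generic background drugs);
* its reactions are k ~ Uniform{1..5} iid draws *with replacement* from a
  per-drug PT distribution, de-duplicated within the report. The
  with-replacement scheme was chosen because it yields the closed-form
  inclusion probability 1 − (1 − p)^k, so `expected_table()` can state
  the expected a, b, c, d exactly — the oracle the recovery tests need;
* a planted signal (drug, PT, ρ) multiplies that drug's per-draw
  probability of the PT by ρ, after which the drug's distribution is
  renormalized. Renormalization means the realized reporting-rate ratio
  is ρ/Z with Z the drug's total tilted mass (Z − 1 typically below
  0.05); recovery tests compare log ROR to log ρ within sampling error,
  which absorbs this. A ρ that would push a probability above 1 is
  rejected at spec time;
* demographics loosely echo the margins typical of AD pharmacovigilance
  cohorts (52/48 sex split, ~10%/72%/18% across age bands, mixed age
  units, configurable missingness); no attempt is made to fit any
  specific published composition;
* a `duplication_rate` fraction of caseids is emitted as two versions
  with non-decreasing FDA_DT; a `tie_rate` fraction of those ties FDA_DT
  exactly so the PRIMARYID tie-break is exercised. The generator's
  bookkeeping records the designated winner of every caseid, and the
  dedup contract test demands exact agreement;
* everything is driven by one seed; identical spec and seed give
  byte-identical files.

What the generator does *not* emulate: free-text drug-name noise and
misspellings, reporting dynamics over time, correlated reactions within a
report, region- or reporter-specific event profiles, and the legacy
pre-2012 schema. Passing tests therefore demonstrate correctness of the
pipeline's logic and statistics under a clean reporting model, not
robustness to real FAERS text noise.

## Numerical and design choices

* All identifiers are strings end to end (leading zeros survive);
  FDA_DT is compared as a YYYYMMDD integer.
* Non-numeric PRIMARYIDs in a dedup tie fall back to zero-padded string
  comparison with a warning.
* Statistics are vectorized over tables; the test suite pins them to an
  independently coded scalar oracle on the full grid of 1296 small tables
  at 1e-12 relative tolerance, and to hand-derived worked examples.
* Scan output ordering is deterministic: descending count, then PT.
* Problem sizes used by the test suite were chosen to make sampling error
  small relative to the tested tolerances: the parameter-recovery
  property runs 200 replicates of 50,000 reports with planted rate ratios
  2, 5 and 10 on PTs of decreasing baseline frequency (expected target
  counts 50–90), checking log-ROR coverage within 3 standard errors and
  the null false-positive rate; the dedup contract runs 20,000 reports at
  20% duplication with deliberate FDA_DT ties.

## Limitations

Beyond the generator's simplifications above: disproportionality measures
reporting association, not incidence or causality; no multiple-testing
adjustment is applied (matching standard practice for this screening
design); the EBGM column is the unshrunk relative reporting ratio, so for
very small a it is more extreme than a shrinkage estimate would be — the
EBGM05 > 2 criterion, evaluated on the log-normal bound, is the guard;
and the packaged SOC map is a demonstration stand-in, so real analyses
must supply a licensed MedDRA-derived mapping.
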