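---
title: "Reporting odds ratio disproportionality analysis of FAERS reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporting odds ratio disproportionality analysis of FAERS reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersror)
library(data.table)
```

## The problem

Spontaneous adverse-event reporting databases such as the FDA Adverse Event
Reporting System (FAERS) collect millions of reports, each linking one or
more drugs to one or more adverse reactions coded as MedDRA preferred terms
(PTs). Because there is no denominator of drug users, absolute risks cannot
be estimated; instead, *disproportionality analysis* asks whether a
drug–event pair is reported more often than the rest of the database would
predict. `faersror` implements the reporting odds ratio (ROR) flavour of
this analysis over the public FAERS quarterly ASCII dumps, together with the
cleaning rules such analyses conventionally apply and a subgroup (sex / age)
heterogeneity test.

## The statistic

For a drug group $A$ and a reaction $j$, reports in the analysis cohort are
cross-classified into the 2×2 table

|              | reaction $j$ | not $j$      |
|--------------|--------------|--------------|
| exposed to A | $N_{A,j}$    | $N_{A,\neg j}$ |
| not exposed  | $N_{\neg A,j}$ | $N_{\neg A,\neg j}$ |

and the reporting odds ratio is

$$\mathrm{ROR}_j = \frac{N_{A,j}/N_{A,\neg j}}{N_{\neg A,j}/N_{\neg A,\neg j}},$$

with log-scale standard error

$$\mathrm{SE}(\ln \mathrm{ROR}_j) = \sqrt{\tfrac{1}{N_{A,j}} +
\tfrac{1}{N_{A,\neg j}} + \tfrac{1}{N_{\neg A,j}} +
\tfrac{1}{N_{\neg A,\neg j}}}$$

and the Wald 95% CI $\exp(\ln\mathrm{ROR}_j \pm 1.96\,\mathrm{SE})$. The
multiplier 1.96 is fixed, not a configurable quantile. A pair is flagged as
a signal when the lower bound of the log2-transformed CI exceeds zero; since
$\log_2 L > 0 \iff L > 1$, the implementation tests `ci_low > 1` on the
natural scale and skips the second transform.

Two subgroups (for example female vs male strata) are compared with a z test
on the log RORs,

$$z = \frac{\ln\mathrm{ROR}_1 - \ln\mathrm{ROR}_2}
{\sqrt{\mathrm{SE}_1^2 + \mathrm{SE}_2^2}},
\qquad p = 2\,(1 - \Phi(|z|)),$$

where $\Phi$ is the standard-normal CDF, evaluated through the complementary
tail (`pnorm(..., lower.tail = FALSE)`, numerically
$\operatorname{erfc}(|z|/\sqrt 2)/2$), never a lookup table. A subgroup
difference is reported as significant only when the fold ratio
$\max(\mathrm{ROR}_1,\mathrm{ROR}_2)/\min(\mathrm{ROR}_1,\mathrm{ROR}_2)$
is at least 1.5 **and** $p < .05$; either condition alone does not flag.

```{r}
tab <- contingency_table(20, 80, 100, 900)
ror(tab)
```

**Zero cells.** When any raw cell is zero the ROR or its SE is undefined;
the package then adds 0.5 to *all four* cells (the Haldane–Anscombe
correction, the standard pharmacovigilance convention) and marks the result
`corrected`. Tables without zeros are computed exactly. Tables with an empty
margin — no exposed reports, or no comparator reports — are not estimable
and raise an error (scalar interface) or a flagged not-estimable row (bulk
analysis modes).

**No multiplicity adjustment.** The analysis applies no multiple-testing
correction anywhere: each PT's CI and each subgroup p-value is marginal.
With the 15 PTs of a typical reaction profile, roughly one in three null
profiles will show at least one spurious signal at the 2.5% one-sided level;
interpret forests of many rows accordingly.

## Cleaning rules

`preprocess_faers()` turns the raw DEMO/DRUG/REAC record trio into one row
per analyzable case:

1. **Reporter filter** — keep reports filed by health care professionals:
   occupation codes HP, MD, OT, PH. Consumer (CN), empty and unrecognized
   codes are dropped (disable with `professional_only = FALSE`).
2. **Deduplication** — FAERS cases are resubmitted with corrections; only
   the maximal `caseversion` per `caseid` is kept, ties broken by the
   maximal `primaryid` (compared as strings after left-zero-padding). A
   missing version is treated as 0 so any explicit version supersedes it.
3. **Primary suspect extraction** — only drug rows with role code PS
   contribute exposure; `prod_ai` strings are uppercased, whitespace
   collapsed, and `\` normalized to `/`. Combination products such as
   `NIRMATRELVIR/RITONAVIR` stay single tokens and are targeted verbatim;
   the package never expands them into components.
4. **Missing essentials** — cases without any primary-suspect ingredient or
   without any reaction PT are excluded.
5. **Single-suspect restriction** — by default (`single_ps_only = TRUE`)
   cases naming more than one distinct primary-suspect ingredient are
   excluded, so each case attributes exposure to one drug product. Set it
   to `FALSE` to keep them; they then count as exposed to every listed
   ingredient.

Every stage's exclusions are counted in the table's `provenance`, and the
buckets always sum back to the raw demo row count. The counting unit
everywhere is the *case*: repeated PT rows or drug rows within a report
never contribute twice to a contingency cell.

Cases with unknown sex or age are kept in overall analyses and silently
excluded (with a reported count) only from the corresponding subgroup
analysis. Ages are converted to years from the FAERS unit codes (DEC ×10,
YR ×1, MON ÷12, WK ÷52.1775, DY ÷365.25, HR ÷8766), rounded to 4 decimals;
values above 120 years are treated as data-entry errors and set missing.

## The two analysis modes

`most_potential_reactions()` ranks a drug group's PTs by the number of
exposed cases reporting them (ties alphabetical), keeps the top `k`
(default 15), and computes each PT's ROR against all other drugs.
`reaction_comparison()` compares selected PTs between a target group and
either the complement (`other_drugs()`) or an explicit control group; cases
exposed to both explicit groups are excluded and counted so the 2×2 cells
stay disjoint.

With `subgroup_spec("sex")` or `subgroup_spec("age", age_split = 50)` the
*entire cohort* — exposed and comparator cases alike — is restricted to each
stratum, so the comparator cells are stratum-specific and the two strata are
independent, as the z test assumes. (The alternative, restricting only the
exposed arm, would share comparator cases between strata and invalidate the
independence assumption.) The boundary age belongs to the younger stratum:
a 50-year-old falls in `age<=50`.

```{r, fig.width = 6, fig.height = 3}
cfg <- synth_config(n_cases = 20000,
                    signals = make_signal("DRUG_A", "PT_RETINOPATHY", 5),
                    seed = 2024)
co <- generate_cohort(cfg)
cases <- preprocess_faers(co$demo, co$drug, co$reac)
report <- most_potential_reactions(cases, drug_group("drug A", "DRUG_A"))
report$results[, .(pt, a, b, c, d, ror = round(ror, 2),
                   ci_low = round(ci_low, 2), ci_high = round(ci_high, 2),
                   significant)]
render_forest(forest_rows(report), tempfile(fileext = ".png"))
```

A PT requested in a comparison that no case reports is returned as a
not-estimable row rather than silently omitted, and a stratum with no
exposed cases marks only that PT's comparison not-estimable.

## The synthetic cohort generator

Real FAERS quarters are multi-gigabyte downloads, so the package ships a
generator (`synth_config()`, `generate_cohort()`, `generate_quarter()`)
that emits the same ASCII dialect with known ground truth. Each case draws
one primary-suspect ingredient from an exposure distribution, then each PT
independently with its background probability; for an injected signal
(ingredient, PT, target ROR) the exposed-case probability is odds-adjusted
via `odds_adjust()` so the population ROR against the all-other-drugs
comparator equals the target exactly. Sex- or age-specific target RORs can
be injected to exercise the subgroup machinery.

Default study conditions, chosen once for plausibility: 75% of reports from
professional occupations and 20% consumer reports plus 5% missing codes; a
55/42/3 female/male/unknown sex mix; ages from a normal distribution with
mean 55 and SD 18 years, clamped to [0, 100], encoded mostly in years with
decades and the infant units represented; a 5% superseded-version rate; and
per-field missingness of 8% (age), 3% (sex), 1% (ingredient), 1% (per
reaction row). A catch-all background reaction with probability 0.9 makes
nearly every case list at least one PT, as real reports do; because it is
independent of every signal PT and common to both arms, conditioning on
"at least one reaction" multiplies both arms' odds by the same factor and
leaves every injected ROR unchanged.

Superseded versions share the caseid with a lower version number, a
perturbed primaryid and one degraded demographic field (age or sex — never
the occupation code, so a case's professional status is version-invariant
and the manifest can predict filter survival exactly). The manifest records
every case's true and observed fields plus derived `professional`,
`essentials_ok` and `survives` flags; pipeline tests require the clean-table
counts to match these predictions *exactly*, not approximately.

What the generator does **not** emulate: PT co-occurrence structure (draws
are independent Bernoulli), realistic MedDRA vocabularies, reporting-delay
dynamics, cross-caseid duplicates, or stimulated-reporting bursts. Passing
tests therefore demonstrate correctness of counting, estimation and
accounting — not robustness to the correlated, drifting reporting behaviour
of real pharmacovigilance data.

## Numerical and design choices

* **Estimation targets, not point equality.** The generator's odds
  adjustment fixes the *population* ROR; finite cohorts deviate by sampling
  noise, so validation asserts CI coverage (≥ 90% of 200 seeded replicates
  at 50,000 cases for injected RORs 2, 5, 20) rather than equality.
* **Calibration.** Under a two-stratum null with a common ROR the subgroup
  z test rejects at close to its nominal 5% level; the validation suite
  checks the rate lies in [0.04, 0.06] over 10,000 replicates with 20,000
  cases per stratum — cell counts large enough that the Wald approximation
  is meaningful. Simulated cohorts of 10,000 cases with no signals keep the
  fraction of PTs flagged by the forest criterion at or below 7.5%,
  reflecting the mild anti-conservatism of Wald intervals at moderate
  counts.
* **Oracle agreement.** On all 1,296 tables with cells 1–6 the ror/CI
  values agree with an independent 50-digit-precision evaluation of the
  same formulas to better than 10 significant digits.
* **Problem sizes.** The validation suite runs cohorts of 4,000–50,000
  cases and 200–10,000 simulation replicates; these sizes give the
  assertions above comfortable statistical resolution while keeping a full
  run to a few minutes on one CPU.
* **Ties and degeneracies.** Reaction ranking breaks count ties
  alphabetically; empty cohorts and empty margins raise errors early with
  named causes; a PT absent from the cohort yields a valid all-zero event
  column in `count_contingency()` but a not-estimable row at the analysis
  layer, where an estimate of exactly 1 from pure correction would be
  misleading.
* **Quarter coverage is an input.** Published FAERS analyses state their
  quarter ranges inconsistently often; this package treats the set of
  quarter files handed to `preprocess_faers()` as the definition of the
  study window and records the labels in provenance rather than validating
  them against any fixed range.

## Limitations

The ROR is a reporting association, not a risk estimate: reporting rates
are shaped by publicity, indication and reporter behaviour, and a
significant ROR is a hypothesis-generating signal only. The package
implements no Bayesian shrinkage (IC/BCPNN, EBGM) and no PRR; sparse cells
rely on the Haldane–Anscombe correction instead. PT strings are opaque
labels — no MedDRA hierarchy navigation or synonym resolution is attempted —
and duplicate detection is limited to FAERS's own caseid/version mechanism;
probabilistic cross-case linkage is out of scope.
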