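---
title: "Methods: disproportionality signal mining and severe-event risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal mining and severe-event risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
options(pvsignal.quiet = TRUE)
```

## The problem

Spontaneous adverse-event reporting systems accumulate voluntary reports
of suspected drug harms. They have no denominator (the number of treated
patients is unknown), so risk cannot be estimated directly; instead,
*disproportionality analysis* asks whether an event is reported more often
with the target drug than its share of all other reports would predict.
`pvsignal` implements the full chain for a FAERS-style archive: quarterly
`$`-delimited table ingest, case-level cleaning, reporting odds ratio
(ROR) and proportional reporting ratio (PRR) screening, product-label
comparison, and logistic modelling of which reports turn severe.

## Preprocessing model

A *case* (CASEID) can appear as several *reports* (PRIMARYID) as updates
arrive. Cleaning proceeds in a fixed order, each stage logging its
removals:

1. **Deduplication.** Keep, per CASEID, the row maximizing
   `(FDA_DT, PRIMARYID)` lexicographically — the most recent receipt
   date, largest report id at ties. One total order realizes both rules,
   making the operation idempotent and independent of row order.
2. **Deleted-case lists.** Quarterly packages may name withdrawn
   CASEIDs; surviving rows never carry one.
3. **Completeness.** The default requires only drug information and at
   least one reaction PT. Demographic blanks (age, gender, reporter,
   country) are kept as explicit `"unknown"` strata rather than dropped:
   published cohort tables tabulate "Not specified" rows for age and
   gender, which a strict remove-all-missing reading would make
   impossible. The requirement set is configurable
   (`filter_complete(required_fields = ...)`) for stricter replications.
4. **Drug-name normalization.** Raw drug strings mix trade names, case
   and whitespace variants. A user-supplied variant→canonical table is
   applied case-insensitively after trimming; unmatched names pass
   through and are tallied. This replaces vocabulary services that cannot
   be redistributed; the mapping table is the interface.
5. **Target selection.** A case enters the target set only if it lists
   the target drug as *primary suspect* (role `PS`); everything else is
   background. Concomitant analyses use roles `C` and `SS`.
6. **Indication exclusion.** PTs naming the treated disease are removed
   from target cases ("indication bias"): a breast-cancer drug will
   otherwise show its own indication as a spectacular false signal.

## Disproportionality statistics

For each PT, unique cases are cross-classified against the background:
`a`/`b` target cases with/without the PT, `c`/`d` background cases
with/without. Then

\[
\mathrm{ROR} = \frac{ad}{bc}, \qquad
\mathrm{CI}_{95} = \exp\!\Big(\ln \mathrm{ROR} \pm 1.96\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\Big),
\]
\[
\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}, \qquad
\chi^2 = \frac{N(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)} .
\]

A useful identity links the two: `ROR/PRR = (1 + a/b)/(1 + c/d)`, so
`ROR > PRR` exactly when `ROR > 1`; the test suite asserts this over
randomized tables, and the χ² is checked against the brute-force
`Σ(O−E)²/E` with margin-preserving expecteds.

**Screening.** Default signal rule: `a ≥ 3`, ROR CI lower bound `> 1`,
`PRR > 2`, `χ² ≥ 4`, *both* methods required. Single-method modes are
exposed (`signal_criteria(combine=)`) because published analyses are not
always explicit about the conjunction; requiring both is the conservative
default. Raising any threshold can only remove signals (tested).

**Numerical choices.** Zero cells make both statistics undefined; such
PTs are reported as `NA` and never flag, rather than silently corrected.
A Haldane 0.5 correction (`compute_ror(correction = TRUE)`) and a Yates
χ² (`compute_prr(yates = TRUE)`) are available behind flags. The default
χ² is uncorrected: reconstructing published hematologic-signal rows with
the uncorrected form reproduces their printed CI bounds to the rounding
tolerance, which the corrected form does not. `z = 1.96` is fixed.

**Inverting published rows.** Published signal tables print
`(a, ROR, PRR, χ²)` per PT but not the table. `invert_stats()` recovers
real-valued `(b, c, d)`: `d = ROR·b·c/a` eliminates one unknown exactly,
and the PRR and χ² log-residuals are solved for `(log b, log c)` by
Newton iteration (`pracma::fsolve`) seeded from a coarse grid over
10 orders of magnitude. Log-parameterization keeps iterates positive;
a residual check at `1e-6` relative tolerance rejects inconsistent inputs
(e.g. rows violating the ROR/PRR sign identity) as infeasible rather than
returning a spurious table.

## Severe-event risk model

A report is *serious* when any outcome code is in
{`DE`, `LT`, `HO`, `DS`, `CA`, `RI`} (death, life-threatening,
hospitalization, disability, congenital anomaly, required intervention);
`OT` alone is non-serious. Covariates per target report:

- **age band**: 0–44 (reference), 45–59, 60–74, ≥75, unknown; minors fold
  into the reference band;
- **gender**: male (reference), female, unknown;
- **protein-binding class** of concomitant medication: none (reference),
  <85%, 85–<98%, ≥98%, using the *maximum* binding percentage among the
  report's concomitants. The aggregation is not dictated by the source
  analyses; the maximum matches the competitive-displacement rationale —
  one extremely bound co-medication suffices to displace the target drug;
- **CYP3A4 class**: none (reference), other concomitant, CYP3A4
  inhibitor.

Factors are univariate-screened (any non-reference level with Wald
`p < 0.05` admits the factor, `alpha` configurable); the selected set is
fitted jointly by maximum likelihood (`stats::glm`, IRLS, tolerance
`1e-8`, ≤100 iterations). Effects are odds ratios `exp(β)` with Wald 95%
CIs and two-sided Wald p-values, matching the `OR (95% CI)` presentation
convention; reference rows carry OR fixed at 1. Rows with an unknown
level are excluded from models involving that factor (no "unknown" dummy
is estimated, since published regression tables show no such stratum).

Two degeneracies are handled explicitly. Separation or non-convergence
aborts with the factor names. Exact collinearity — on idealized data the
protein-binding and CYP classes both encode "has a concomitant drug", so
their dummies are linearly dependent — is detected through aliased
coefficients, and `severity_analysis()` drops the weakest-screened factor
and refits, logging the drop. Ingested data rarely trigger this because
concomitants missing from the property table decouple the two factors.

## What the synthetic generator emulates

`generate_dataset()` produces multi-quarter table sets with known ground
truth, so every pipeline stage has an oracle:

- **Reports and duplicates.** `n_cases` unique cases with sequential ids;
  `ceiling(duplicate_rate × n)` re-emissions share the CASEID and get a
  later FDA_DT or larger PRIMARYID, clinical content copied verbatim —
  dedup correctness is then checkable purely by count. Deleted-case lists
  name cases from earlier quarters, shipped with the final quarter. The
  intended unique-case count (`n_cases −` deletions) is part of the
  ground truth and must be recovered exactly.
- **Reactions.** Each report samples every vocabulary PT independently
  (Bernoulli), with per-arm probabilities: `p_background` for background
  reports, `p_target` for target reports (defaults 0.02 both, overridden
  per injected signal). The implied true reporting odds ratio is the odds
  ratio of the two probabilities. A report with no sampled PT is redrawn
  until it has one; this conditioning inflates each arm's marginal rate
  by `1/(1 − P(\text{no PT}))` but leaves the cross-arm odds ratio within
  about 1% of the implied value under the default vocabulary (33
  samplable PTs), far inside sampling noise at the tested cohort sizes.
  The mechanism was chosen precisely because its ROR is analytically
  known. With probability `indication_rate` a report also lists its own
  indication as a PT, exercising the indication-bias exclusion.
- **Severity.** Outcome codes are drawn from a logistic model on the
  generated covariates. The default coefficients are the multivariate
  odds-ratio estimates published for a large fulvestrant cohort (age
  bands protective, highest binding class OR 1.522); the intercept
  (2.194) was solved once so the marginal serious fraction under the
  default mix equals the cohort's 85.27%, then frozen.
- **Covariate mix.** Marginals follow the published cohort: 98.5% female
  among known genders; age mass in the 60–74 band; 43.3% of reports with
  concomitants, of which 4.5% include a CYP3A4 inhibitor. The split of
  concomitant reports across binding classes is not published; 0.33 /
  0.42 / 0.25 across <85 / 85–<98 / ≥98 was fixed once as a realistic
  spread that keeps every class estimable.
- **Names and blanks.** Drug names are written as trade-name/case
  variants at `variant_rate` (default 0.3) to exercise normalization;
  demographic fields are blanked at the published cohort's missingness
  rates (e.g. 21.2% missing age). Blanks are empty strings, as in the
  real dialect. The drug-property table is synthetic: values are chosen
  so each binding class is cleanly populated and CYP3A4 inhibitors carry
  binding <85%, which keeps the max-binding ground truth exact when an
  inhibitor is added to a report.
- **Determinism.** A single seed feeds labelled substreams (cases,
  reactions, severity, deletions, duplicates, materialization), so the
  same configuration is byte-identical and changing one component's
  parameters does not perturb the others' draws.

**What it does not emulate** — and hence what passing tests do not show
about real archives: reporting-latency dynamics and secular trends,
country- or reporter-specific reporting propensities, dose and therapy
dates, correlated PT co-occurrence (events are independent given the
arm), non-random missingness, and free-text noise beyond tabulated name
variants. Calibration results on synthetic data validate the *machinery*,
not the epidemiology of any particular drug.

## Study sizes used by the checks

The bundled validation uses: 20,000-report cohorts across 50 seeded
replicates for signal recovery (the injected PT must flag and its CI
cover the implied ROR 10.25–10.3 in ≥90% of replicates); 1,000 null
tables for CI coverage; 10,000 randomized tables for the algebraic
identities; 200,000 simulated covariate profiles (20 replicates for the
bias property, one fixed-seed run for the headline odds-ratio
recoveries). These sizes keep every Monte-Carlo standard error well below
the tolerance it guards.

## Known limitations

- Disproportionality measures reporting association, not incidence or
  causation; no multiplicity adjustment is applied across PTs (matching
  standard practice for these screens), so isolated flags at the
  thresholds deserve skepticism.
- The Wald CI is asymptotic; for very sparse cells (`a` in the low single
  digits) its coverage degrades, which is one reason for the `a ≥ 3`
  floor.
- `invert_stats()` inherits the rounding of its 2-decimal inputs: the
  reconstructed cells are exact for the *printed* statistics, not the
  original data.
- The univariate-screen-then-multivariate strategy is the convention it
  reproduces, not a recommendation; it can drop confounders that only
  matter jointly.
- MedDRA hierarchy handling stops at PT and SOC via the supplied
  dictionary; LLT→PT mapping requires the licensed dictionary and is out
  of scope.
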