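---
title: "Disproportionality signal mining for spontaneous ADR reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal mining for spontaneous ADR reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsmine)
```

## The problem

Spontaneous reporting systems (SRS) collect case reports of suspected adverse
drug reactions (ADRs) from clinicians and hospitals. They have no denominator
of exposed patients, so risk cannot be estimated directly; instead,
*disproportionality analysis* asks whether a particular (drug, reaction) pair
is reported more often than the rest of the database would predict. `srsmine`
implements this workflow for antipsychotic safety surveillance: validated
report ingestion, dictionary-based name standardization (ATC generic names for
drugs, MedDRA-style preferred terms for reactions), inclusion/exclusion
filtering, expansion of reports into drug-event combinations, four
disproportionality methods with their published decision rules, descriptive
safety tables, a logistic risk-factor model of serious reactions, and
off-label annotation of detected signals.

Because real SRS databases are rarely redistributable, the package also ships
a synthetic SRS generator with analytic ground truth, so every stage can be
validated by parameter-recovery experiments rather than by eyeballing.

## The counting unit

A report may carry several suspected antipsychotics and several reaction
terms. Before mining, each report is expanded into **drug-event
combinations**: the cross-product of its suspected antipsychotics and its
standardized reaction PTs, deduplicated within the report so that
`(report_id, drug, PT)` is unique. The fourfold table of a pair
partitions this combination set:

|            | target ADR | other ADRs |
|------------|-----------|------------|
| target drug | a         | b          |
| other drugs | c         | d          |

with `n = a + b + c + d`. Two conventions deserve emphasis, because published
analyses rarely state them:

* `n` counts **combinations, not reports**. The cells must partition
  something, and after expansion the combination set is the only set they
  can partition.
* multi-suspect reports expand as the **full cross-product** of suspected
  antipsychotics and PTs. Splitting by reaction only is the alternative; the
  cross-product treats co-suspected drugs symmetrically, which is standard
  SRS practice. Suspected non-antipsychotics never generate combinations.

## The four methods

For a table `(a, b, c, d)` the package computes:

* **ROR** — reporting odds ratio `(a/c)/(b/d)`, with
  `SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)` and a Wald 95% interval.
  Signal rule: `a >= 3` and CI lower limit `> 1`.
* **PRR** — proportional reporting ratio `[a/(a+b)]/[c/(c+d)]`, with
  `SE(ln PRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`. Same rule.
* **MHRA** — `a >= 3`, `PRR >= 2`, and chi-squared `>= 4`. The chi-squared is
  Yates-corrected by default,
  `n (|ad-bc| - n/2)^2 / [(a+b)(c+d)(a+c)(b+d)]`, with the numerator clamped
  at zero (the unclamped formula is positive at exact independence, which
  would be absurd); `chi2 = "pearson"` selects the uncorrected form, which
  equals the textbook Pearson statistic.
* **BCPNN IC** — the closed-form shrinkage estimate of the information
  component, `E(IC) = log2[(a+1)(n+2)^2 / ((n+4)(a+b+1)(a+c+1))]` bits, with
  its variance `V(IC)` and the interval `E(IC) ± 2 sqrt(V(IC))`. Signal rule:
  lower limit `> 0`. The `+1` pseudo-counts keep `a = 0` tables finite.

A pair is a **consensus signal** when all four rules fire; consensus signals
are ranked by PRR (ties broken by `a`, then names, for determinism).

### Numerical choices and edge cases

* **Zero cells.** ROR and PRR are undefined when a cell or margin is zero.
  Such pairs return typed non-computable results (`NA` plus a reason), never
  `Inf`, and can never be flagged. Only pairs observed at least once
  (`a >= 1`) are enumerated; the `a >= 3` rule applies at flag time.
* **IC variant.** The typeset source of the E(IC) formula is ambiguous about
  one factor of `(n+2)/(n+4)`; the default reads it as
  `(n+2)^2/(n+4)`, and `ic_variant = "plain"` selects
  `log2[(a+1)(n+2)/((a+b+1)(a+c+1))]`. Both tend to 0 under independence
  (verified at `n = 10^6` within 0.01 bits), so the choice is immaterial for
  flagging in any realistic regime.
* **Monotonicity.** ROR and PRR are strictly increasing in `a` with
  `b, c, d` fixed. `E(IC)` is *not* globally monotone: because the margins
  grow with `a`, the shrinkage ratio tends to 1 (IC to 0) once the pair
  dominates its margins. The property suite asserts IC monotonicity only in
  the sparse regime where it holds.
* **Overflow.** The chi-squared denominator `(a+b)(c+d)(a+c)(b+d)` overflows
  32-bit integers even for moderate databases; all statistic cores coerce to
  doubles first.
* **Percentages.** Descriptive tables round percentages half-up to two
  decimals (`round_half_up()`), matching how published ADR tables print
  (e.g. `1875/3953` prints 47.43); base R's banker's rounding would
  occasionally differ.

## Preprocessing conventions

Inclusion requires: report year within the window (default 2016–2020), at
least one *suspected* drug standardizing to an antipsychotic (ATC `N05A`;
an antipsychotic listed as concomitant does not qualify), and causality rated
certain/probable/possible. Exclusion reasons are assigned by the first
failing rule in that fixed order, making the exclusion log deterministic.

Covariates follow the conventions of hospital-based ADR studies: age binned
as `<18, [18,35), [35,65), >=65` (half-open bins resolve the overlapping
labels common in published tables); meteorological seasons (spring =
Mar–May); polypharmacy = three or more total medications (suspected plus
concomitant); multiple disease = two or more diagnoses; a report whose
suspected antipsychotics span both classes codes as atypical. Dates are
ISO-8601; a year-only date is accepted and imputed to July 1 with an
imputation flag. Unknown sex and missing age are explicit missing values,
never sentinels; the regression handles them by complete-case exclusion with
a logged count.

Validation never silently drops data: every input row either parses or is
logged with a row-level reason, and `parsed + logged = input`.

## The risk-factor model

Serious-versus-non-serious is modeled at the *report* level (combinations
would double-count multi-reaction cases) by maximum-likelihood logistic
regression on dummy-coded covariates with references male / age 18–35 /
spring / typical / hospital level 1 / general hospital / single disease /
non-polypharmacy. Wald intervals and two-tailed Wald p-values are reported
per level — the conventional output of statistical software — plus a
likelihood-ratio test per factor, since published tables often print an
overall p for multi-level factors without saying which test produced it.
The fit is backed by `stats::glm`; the package owns the encoding, the
contract, and the reporting.

## Off-label annotation

A consensus signal is *off-label* when its PT is absent from the drug's
label-knowledge set — exact string membership on standardized PTs, so
synonym handling stays in the term dictionary. Drugs absent from the
knowledge file yield `undetermined`, never a silent `labeled`. The bundled
label file is **synthetic** (named accordingly): it encodes plausible label
sets for the 15-drug roster sufficient for testing the annotation logic, not
transcriptions of any real package insert.

## The synthetic world

The generator's defaults describe one fixed, study-like world:

* 15 antipsychotics (7 typical, 8 atypical) at the report shares of the
  provincial study the package emulates; ~2% of reports carry a non-
  antipsychotic suspect, and 1.5% + 0.5% carry unlikely/impossible causality,
  so the exclusion paths are exercised.
* a 44-term PT vocabulary whose top masses follow the published symptom
  profile (extrapyramidal disorder ~24% of combinations, akathisia ~6%, …),
  with the tail spread over plausible antipsychotic ADRs; 1–5 PTs per report
  with mean ~1.18 combinations per report.
* reports rising year by year over 2016–2020; onset delays log-normal with
  median 20 days and sigma 1.1 — ~91% of onsets within 3 months and well
  under 1% on day zero, matching the qualitative onset profile of
  antipsychotic ADRs.
* seriousness driven by a logistic model whose coefficients are the
  published adjusted odds ratios (psychiatric hospital 2.61, age >=65 2.17,
  hospital levels 2/3 protective at 0.41/0.37, …). The intercept (-2.9606)
  was calibrated once, by solving for the 9% marginal serious rate over a
  large Monte Carlo draw of covariates (`calibrate_serious_intercept()`),
  and then frozen.
* ten injected disproportionality pairs at reporting-rate ratios 4–8,
  echoing the strong signals of such studies. Injection multiplies the PT
  weight by `rr` conditionally on the suspected drug and renormalizes —
  chosen because it keeps every expected cell analytic (`expected_table()`),
  so recovery tests compare simulation against closed form rather than
  against another simulation.

Deliberate simplifications: one suspected drug per report (the cross-product
expansion is exercised by constructed fixtures instead), one shared onset
delay per report, no reporting biases (no Weber effect, no notoriety bias),
no duplicate reports, and covariates independent of the drug given its
class. A green recovery test therefore establishes that the pipeline
correctly recovers known disproportionality and known odds ratios from data
with this structure — not that any particular real-world signal is true, and
not that the methods are robust to biases the generator does not model.

## What the acceptance checks compute

`scripts/acceptance.R --seed <int> --out <path>` recomputes, from scratch:
the printed-percentage arithmetic of the emulated study's tables; the
worked-table statistics for all four methods; the maximum relative error of
the chi-squared against `stats::chisq.test` on 1,000 random tables; the
criteria truth table on a designed grid; consensus-signal sensitivity for
injected pairs with `rr >= 4` and expected `a >= 10` plus the null-pair
consensus rate over 50 replicates of 50,000 reports; and the psychiatric-
hospital odds ratio and pooled CI coverage of all generated coefficients
over 200 scaled replicates. The machine-readable acceptance-target list of
the build contract is empty, so the JSON keys are this package's own audit
trail.

## Known limitations

* No stratified or adjusted disproportionality, no EBGM/MGPS, no full
  Bayesian IC — the four printed methods only.
* Dictionary misses are surfaced, never fuzzily resolved.
* The consistency probe `probe_consistent_tables()` can *search* for integer
  tables compatible with a published row's rounded statistics, but multiple
  tables usually qualify; it is a plausibility check, not a reconstruction.
* The emulated study's raw data are not public, so its full dataset results
  (report counts, its 44 consensus signals) are not reproducible here; the
  package validates the machinery, not those numbers.
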