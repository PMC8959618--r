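# srsmine

Disproportionality signal mining for spontaneous adverse-drug-reaction (ADR)
reporting systems, built around antipsychotic pharmacovigilance.

Spontaneous reporting systems (SRS) collect case reports of suspected ADRs
but carry no exposure denominator, so drug-safety signals are found by
*disproportionality*: is a (drug, reaction) pair reported more often than the
rest of the database predicts? `srsmine` is for pharmacoepidemiologists and
drug-safety analysts who want that whole workflow as reproducible, tested
code:

* **Data model & I/O** — a long-format CSV schema (`reports.csv`,
  `drugs.csv`, `reactions.csv`) with row-level validation that never silently
  drops a record; dictionary files mapping raw drug names to ATC generic
  names and raw reaction terms to MedDRA-style preferred terms (PT) with
  their primary system organ class (SOC).
* **Preprocessing** — inclusion/exclusion (report-year window, suspected
  antipsychotic present, causality certain/probable/possible) with a
  deterministic exclusion log, and expansion of reports into deduplicated
  drug-event combinations, the counting unit of signal mining.
* **Four signal methods** on each pair's fourfold table
  (`a, b, c, d; n = a+b+c+d` over combinations):
  * ROR `(a/c)/(b/d)`, signal if `a >= 3` and the Wald 95% lower limit `> 1`
  * PRR `[a/(a+b)]/[c/(c+d)]`, same rule
  * MHRA: `a >= 3`, `PRR >= 2`, Yates-corrected chi-squared `>= 4`
  * BCPNN information component, signal if `E(IC) - 2 sqrt(V(IC)) > 0`
  plus the consensus flag (all four), PRR ranking, and off-label annotation
  against a drug-label knowledge file.
* **Descriptive surfaces** — yearly trend with serious proportions, onset-
  delay distribution, per-drug/per-class seriousness, SOC/PT frequency and
  outcome tables with printed-style half-up percentages.
* **Risk factors** — logistic regression of serious vs non-serious reports
  (adjusted odds ratios, Wald CIs and p-values, per-factor LRT).
* **Synthetic SRS generator** — a study-like world (15 antipsychotics, 44-PT
  vocabulary, ~9% serious, injected signal pairs with known reporting-rate
  ratios) with closed-form expected fourfold tables, powering the package's
  recovery tests.

See `vignettes/signal-mining-methods.Rmd` for the methods account and design
rationale.

## Worked example

```r
library(srsmine)

cfg <- synthetic_config(n_reports = 5000)      # the shipped study-like world
gen <- generate_reports(cfg, seed = 42)
dd  <- roster_drug_dictionary(cfg)
td  <- roster_term_dictionary(cfg)

inc    <- apply_inclusion_exclusion(gen$reports, dd)
combos <- expand_combinations(inc$included, dd, td)
sig    <- mine_signals(combos)
top    <- flag_offlabel(rank_signals(sig, top = 5), load_dictionaries()$labels)
top[, c("generic_drug", "pt", "a", "prr", "chi2", "ic_li95", "offlabel")]
```

```
    generic_drug                       pt  a   prr chi2 ic_li95  offlabel
1 chlorpromazine Blood pressure decreased  7 11.57 51.8    2.39   labeled
2   perphenazine        Tongue induration  5  9.65 25.8    1.95   labeled
3      sulpiride                 Insomnia 12  8.98 67.4    2.16   labeled
4     quetiapine     Urinary incontinence 12  7.10 37.4    1.45 off-label
5 chlorpromazine  Orthostatic hypotension  4  6.85 13.7    1.57   labeled
```

Five of the generator's injected pairs top the PRR ranking; the
quetiapine–urinary incontinence signal is flagged `off-label` because that PT
is absent from quetiapine's (synthetic) label set. Columns are the observed
pair count `a`, the proportional reporting ratio, the Yates chi-squared, and
the BCPNN IC lower limit (a signal needs it above 0).

The same dataset's serious-ADR risk model recovers the generating odds
ratios (true psychiatric-hospital OR 2.61, level-2/3 ORs 0.41/0.37):

```r
fit_serious_model(derive_covariates(inc$included, dd))
```

```
Logistic serious-ADR model: n = 4727 (54 excluded for missing covariates)
         variable       level        p   or             ci
              sex      female 4.36e-01 1.08 (0.885, 1.326)
          age_bin         <18 8.45e-04 1.67 (1.237, 2.266)
          age_bin        >=65 1.91e-05 2.65 (1.694, 4.132)
   hospital_level           2 7.62e-10 0.38 (0.275, 0.513)
   hospital_level           3 2.17e-14 0.32 (0.242, 0.432)
    hospital_type psychiatric 4.31e-09 2.34 (1.762, 3.107)
 ...
```

A single statistic on a hand table:

```r
tab <- contingency_table(5, 15, 20, 160)
ror_stats(tab)$est   # 2.667
prr_stats(tab)$est   # 2.25
chi2_stat(tab)       # 2.0317 (Yates); corrected = FALSE gives 3.1746
bcpnn_stats(tab)$eic # 1.136 bits
```

## Command line

```sh
Rscript -e 'srsmine::srsmine_cli()' simulate --outdir simdata --seed 7 --n 5000
Rscript -e 'srsmine::srsmine_cli()' run --outdir out --seed 7 --n 5000 --chi2 yates
```

`run` writes `exclusions.csv`, `combinations.csv`, `signals.csv`,
`descriptive_report.json`, `risk_factors.csv`, `offlabel_signals.csv` and a
`run_manifest.json` that reproduces the run bit-identically.

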